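---
title: "Methods: tumor-index scoring, batch-paired normalization, and hit calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-index scoring, batch-paired normalization, and hit calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modscreen)
```

## The scoring model

An F1 dominant-modifier screen crosses a sensitized mutant (here, a
gain-of-function JAK allele that drives blood-cell overproliferation and
melanotic tumors) to a panel of deficiencies and asks which deletions shift
the tumor burden of doubly heterozygous adults. The burden readout is
deliberately coarse and fast: tumor sizes are read on a quarter-segment
ruler, the abdominal segments of the adult fly.

**Tumor Index.** Each tumor receives a size on the grid
$\{0.25k : k \ge 1\}$; an animal's TI is the sum of its tumor sizes, 0 for a
tumor-free animal. `quantize_size()` maps a raw size fraction to the nearest
grid point, rounding ties upward, and floors at 0.25: the scale has no zero
for a tumor that exists. Sub-quarter handling is our convention — the scoring
scale itself starts at a quarter segment — as is the open-ended top end (a
TI may exceed the segment count when tumors are large and numerous).

**Batch-paired normalization.** Raw TIs are not comparable across batches:
crosses set up in different weeks differ in rearing conditions and scorer
drift. Every batch therefore carries its own control outcross, and each
animal is z-scored against it:
$$\mathrm{NTI} = \frac{\mathrm{TI} - \overline{\mathrm{TI}}_{\text{control}}}{\mathrm{SD}(\mathrm{TI}_{\text{control}})}.$$
Controls are never pooled across batches. The sample SD uses the $n-1$
denominator, the conventional small-sample choice (control crosses have on
the order of 15 animals). Within every batch the control animals' own NTIs
have mean 0 and sample SD 1 exactly — a machine-precision invariant the test
suite checks at $10^{-12}$.

**Hit calling.** A genotype's summary is the mean of its animals' NTIs with
a standard error (sample SD of the per-animal NTIs over $\sqrt{n}$). The
rule is: mean NTI strictly above $+1$ calls an enhancer, strictly below $-1$
a suppressor, otherwise no effect. We read "beyond 1 SD of the control" as
$|\overline{\mathrm{NTI}}| > 1$ because per-animal NTIs are already in
control-SD units and the control sits at 0; an alternative reading (±1 SE of
the genotype mean) is not the default but the threshold is a tunable
argument throughout. Boundary values exactly at ±1 are *not* called — the
rule is strict — and the tests pin this on a grid that includes exactly ±1.
A cross with zero adult progeny is synthetic-lethal and bypasses the
arithmetic. Genotypes below the intended minimum sample size (default 15)
are classified but flagged `low_n` rather than dropped, and a batch whose
control is degenerate (fewer than two animals, or all TIs identical so the
SD is zero) makes its genotypes `unusable` rather than silently vanishing,
so classification counts always sum to the number of genotypes.

No multiple-testing correction is applied — that matches the screen design
this implements — and `false_positive_rate()` therefore also reports
`expected_false_hits`, the false-positive rate times the number of null
genotypes, to make the cost of 363 uncorrected tests visible.

## The synthetic-data generator

The generator exists so the pipeline's operating characteristics can be
measured against known ground truth. It emulates the statistical structure
the analysis assumes, not the biology upstream of it:

- An animal develops at least one tumor with probability `penetrance`.
  Temperature enters only through presets: 0.68 at 25°, 0.99 at 29°, the
  observed penetrance of the sensitized background at those rearing
  temperatures.
- An affected animal's tumor count is zero-truncated Poisson with rate
  `tumor_count_mean` (default 2). The burden distribution is not something
  the screen design specifies; the zero-truncated Poisson is the simplest
  count law with a single rate that an effect multiplier can scale, and
  zero-truncation keeps "affected" and "has at least one tumor" consistent.
- Each tumor's size is $0.25g$ with $g$ geometric on $\{1, 2, \dots\}$
  (success probability `size_param`, default 0.5) — the simplest
  single-parameter law supported exactly on the quarter grid, with a tunable
  tail.
- A modifier genotype multiplies the tumor-count rate (`effect_multiplier`);
  an optional additive `penetrance_shift` is exposed because a modifier
  could act on either margin, but burden scaling is the default mechanism.
  `NA` in a screen's effect map marks a synthetic-lethal cross (zero
  progeny).
- Every cross draws from its own random stream derived from the master seed
  (one sequential draw per cross), so identical seed and configuration give
  bit-identical datasets and appending crosses does not perturb earlier
  ones.

Defaults were fixed once, before measuring operating characteristics: 363
Dfs in batches of 20, 15 animals per cross (the screen's minimum sample
size), the 25° penetrance preset (most of the screen ran at 25°), count rate
2 and size parameter 0.5 (mean burden of roughly two tumors of half a
quarter-segment each in affected animals — a modest baseline against which a
5× enhancer is obvious but not trivial).

The per-cell generator (`simulate_cell_table()`) emulates a mixed-cell
slide: control and experimental cells with normal intensities truncated at
zero (the experimental group's mean and SD both scaled by `effect_ratio`, so
the coefficient of variation is preserved), and independent P1/L1 marker
flags with EdU positivity drawn only among P1-positive cells.

What the generator does **not** emulate: scorer bias and inter-scorer
variation, batch-to-batch drift in baseline burden (batches differ only by
sampling noise), correlation between tumor count and size, viability effects
short of full lethality, or any image-level structure behind the per-cell
gray values. Passing tests therefore demonstrate that the arithmetic and the
rule behave as specified under a clean generative model — not that the rule
is robust to those real-data failure modes.

## Operating characteristics, and an asymmetry worth knowing

`false_positive_rate()` simulates replicate null screens and reports the
fraction of genotype-replicates called either way, with an exact 95%
binomial interval; `power_curve()` profiles detection probability across
effect multipliers (effect 1 reproduces the FPR by construction). Under the
default conditions the per-genotype FPR is a few percent — about one to two
expected false hits per hundred null genotypes — and power against a 5×
burden enhancer at $n = 15$ is essentially 1.

The rule is markedly asymmetric. A suppressor can at best abolish tumors,
pinning TIs at 0, so the most negative achievable expected mean NTI is
$-\overline{\mathrm{TI}}_{\text{control}} / \mathrm{SD}_{\text{control}}$.
Under the 25° defaults the control TI distribution has mean smaller than its
SD (a zero-inflated, right-skewed burden), so that floor sits *above* $-1$:
even complete suppression is not expected to cross the suppressor threshold,
and suppressor calls arise mainly through sampling noise. Enhancement has no
such ceiling. The analysis drivers make this visible (ten of ten planted 5×
enhancers recovered; zero of three 0.2× suppressors). In a real screen the
control mean/SD ratio decides how detectable suppression is — a useful thing
to check before interpreting a low suppressor count as biology.

## Numerical and degenerate-input choices

- `quantize_size` rejects non-positive fractions; grid membership of stored
  sizes is checked at $10^{-9}$ relative to the 0.25 step.
- Zero-truncated Poisson deviates use the inverse-CDF construction
  (`qpois` on a uniform over $(e^{-\lambda}, 1)$), exact for all rates and
  degenerating cleanly to a point mass at 1 as $\lambda \to 0^+$.
- Truncation of cell intensities at zero is by rejection sampling; with
  realistic gray-value means many SDs above zero the acceptance rate is
  essentially 1.
- The pooled-variance Student's *t* is the default two-group test (the
  convention for same-slide intensity comparisons); Welch's correction is
  available via `var_equal = FALSE`. Zero pooled variance is handled
  explicitly: equal means give $t = 0, p = 1$; unequal means give an
  infinite $t$ with the p value reported as the smallest representable
  positive double — an upper bound, in the spirit of "$P < \dots$"
  reporting.
- Division by a zero control SD is never performed anywhere: degenerate
  batches are flagged and reported.

## Problem sizes in the test suite

The suite exercises the estimators at sizes chosen for tight-enough
Monte-Carlo error while keeping a full run around a minute: penetrance
calibration at 10,000 animals per preset (99% binomial interval), mean-TI
monotonicity at 2,000 animals per effect level, the false-positive-rate
cross-check at 10,000 genotype-replicates for both the implementation and an
independently coded oracle (overlapping exact 95% intervals), and full-scale
recovery on one 363-Df screen with ten planted 5× enhancers at 15 animals
per cross.

## Limitations

The classification rule is a fixed-threshold z-score rule, not a hypothesis
test: its false-positive rate depends on the per-cross sample size and on
the shape of the burden distribution, and nothing corrects for testing
hundreds of genotypes. The generator's ground truth is self-defined (the
burden law is a modeling choice, not an empirical fit), so operating
characteristics measured here describe the rule under that law. Suppressor
detection is floor-limited as described above. Per-cell inputs are assumed
to be already-segmented scalar intensities; no image processing is in scope.
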