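test_that("normalize_intensities sets the control mean to exactly 1", {
  cells <- tibble::tibble(
    group = c(rep("control", 3), rep("experimental", 3)),
    gray_value = c(10, 10, 10, 20, 20, 20)
  )
  q <- normalize_intensities(cells)
  expect_identical(q$normalized_control_mean, 1)
  expect_equal(q$normalized_exp_mean, 2)

  # hand oracle: control mean 10, experimental mean 15 -> ratio 1.5
  cells2 <- tibble::tibble(
    group = c("control", "control", "experimental", "experimental", "experimental"),
    gray_value = c(8, 12, 5, 15, 25)
  )
  expect_equal(normalize_intensities(cells2)$normalized_exp_mean, 1.5)

  # identical groups: ratio 1, t = 0, p = 1
  same <- tibble::tibble(group = rep(c("control", "experimental"), each = 3),
                         gray_value = rep(c(4, 6, 8), 2))
  q3 <- normalize_intensities(same)
  expect_equal(q3$normalized_exp_mean, 1)
  expect_equal(q3$t_statistic, 0)
  expect_equal(q3$p_value, 1)

  expect_error(normalize_intensities(cells[cells$group == "control", ]), ">= 2")
  zero <- tibble::tibble(group = rep(c("control", "experimental"), each = 2),
                         gray_value = c(0, 0, 1, 2))
  expect_error(normalize_intensities(zero), "> 0")
})

test_that("compare_groups matches the hand-coded pooled-variance t", {
  res <- compare_groups(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t_statistic, -1.22474487139159, tolerance = 1e-10)
  expect_equal(res$df, 4)

  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1), mean = runif(1, 0, 10), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, 0, 10), sd = runif(1, 0.5, 3))
    res <- compare_groups(a, b)
    orc <- oracle_pooled_t(a, b)
    expect_equal(res$t_statistic, orc$t, tolerance = 1e-10)
    expect_equal(res$df, orc$df)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
  }
  expect_error(compare_groups(1, c(1, 2)), "insufficient")
})

test_that("degenerate zero-variance groups are handled, not crashed", {
  same <- compare_groups(c(2, 2), c(2, 2))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  diff_ <- compare_groups(c(0, 0), c(1, 1))
  expect_true(is.infinite(diff_$t_statistic) && diff_$t_statistic < 0)
  expect_gt(diff_$p_value, 0)     # reported as an upper bound, never exactly 0
  expect_lt(diff_$p_value, 1e-300)
})

test_that("normalized means, t, and p are invariant to common rescaling", {
  set.seed(13)
  cells <- simulate_cell_table(cell_sim_params(effect_ratio = 1.8, seed = 13))
  base <- normalize_intensities(cells)
  for (s in c(0.01, 7)) {
    scaled <- cells
    scaled$gray_value <- scaled$gray_value * s
    q <- normalize_intensities(scaled)
    expect_equal(q$normalized_exp_mean, base$normalized_exp_mean, tolerance = 1e-12)
    expect_equal(q$t_statistic, base$t_statistic, tolerance = 1e-10)
    expect_equal(q$p_value, base$p_value, tolerance = 1e-10)
  }
  # Welch variant is exposed and differs when variances do
  w <- normalize_intensities(cells, var_equal = FALSE)
  expect_true(is.finite(w$t_statistic))
})

test_that("a null cell table gives a normalized ratio near 1", {
  cells <- simulate_cell_table(cell_sim_params(n_cells_control = 400,
                                               n_cells_exp = 400,
                                               effect_ratio = 1, seed = 21))
  q <- normalize_intensities(cells)
  expect_equal(q$normalized_exp_mean, 1, tolerance = 0.05)
  expect_gt(q$p_value, 0.001)
})

test_that("edu_fraction counts double positives among P1+ cells only", {
  cells <- tibble::tibble(
    group = rep("experimental", 6),
    p1 = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    edu = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  s <- edu_fraction(cells)
  expect_equal(s$n_p1, 4)
  expect_equal(s$n_p1_edu, 1)
  expect_equal(s$fraction, 0.25)

  # forced ratio 12/100 and zero-EdU case
  big <- tibble::tibble(group = "g", p1 = rep(TRUE, 100),
                        edu = c(rep(TRUE, 12), rep(FALSE, 88)))
  expect_equal(edu_fraction(big)$fraction, 0.12)
  none <- tibble::tibble(group = "g", p1 = rep(TRUE, 10), edu = rep(FALSE, 10))
  expect_equal(edu_fraction(none)$fraction, 0)

  # group with zero P1 cells is undefined, not 0
  nop1 <- tibble::tibble(group = c("a", "a", "b"), p1 = c(TRUE, TRUE, FALSE),
                         edu = c(TRUE, FALSE, FALSE))
  s2 <- edu_fraction(nop1)
  expect_true(is.na(s2$fraction[s2$group == "b"]))
  expect_equal(s2$fraction[s2$group == "a"], 0.5)

  # invariance to ordering and to P1-negative padding
  set.seed(3)
  shuffled <- cells[sample(nrow(cells)), ]
  expect_equal(edu_fraction(shuffled), edu_fraction(cells))
  padded <- dplyr::bind_rows(cells, tibble::tibble(group = "experimental",
                                                   p1 = rep(FALSE, 50),
                                                   edu = rep(FALSE, 50)))
  expect_equal(edu_fraction(padded)$fraction, edu_fraction(cells)$fraction)
  expect_error(edu_fraction(cells[0, ]), "no cells")
})
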