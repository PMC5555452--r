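# Independent oracles, coded from the textbook formulas / the generative
# model directly. They share no code with the package implementation.

# Pooled-variance two-sample t, two-sided.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# Vectorised TI draws under the generative model, coded independently:
# zero-truncated Poisson by rejection (not inverse-CDF), geometric sizes.
oracle_draw_ti <- function(n, penetrance, lambda, size_param) {
  affected <- runif(n) < penetrance
  k <- integer(n)
  n_aff <- sum(affected)
  if (n_aff > 0) {
    draws <- rpois(n_aff, lambda)
    while (any(draws == 0)) {
      z <- draws == 0
      draws[z] <- rpois(sum(z), lambda)
    }
    k[affected] <- draws
  }
  ti <- numeric(n)
  if (sum(k) > 0) {
    sizes <- 0.25 * (rgeom(sum(k), size_param) + 1)
    agg <- rowsum(sizes, rep(seq_len(n), k))
    ti[as.integer(rownames(agg))] <- agg
  }
  ti
}

# Null detection rate of the |mean NTI| > threshold rule: n_pairs independent
# (control cross, Df cross) pairs, each of size n_per_cross, everything at
# effect 1. Returns hits, usable pair count, and an exact 95% binomial CI.
oracle_null_rate <- function(n_pairs, n_per_cross = 15, penetrance = 0.68,
                             lambda = 2, size_param = 0.5, threshold = 1,
                             effect = 1, seed = 1) {
  set.seed(seed)
  ctl <- matrix(oracle_draw_ti(n_pairs * n_per_cross, penetrance, lambda, size_param),
                nrow = n_per_cross)
  df <- matrix(oracle_draw_ti(n_pairs * n_per_cross, penetrance, lambda * effect, size_param),
               nrow = n_per_cross)
  m_c <- colMeans(ctl)
  sd_c <- sqrt(colSums((ctl - rep(m_c, each = n_per_cross))^2) / (n_per_cross - 1))
  usable <- sd_c > 0
  mean_nti <- (colMeans(df)[usable] - m_c[usable]) / sd_c[usable]
  hits <- sum(abs(mean_nti) > threshold)
  ci <- binom.test(hits, sum(usable))$conf.int
  list(rate = hits / sum(usable), hits = hits, n = sum(usable), ci = ci)
}
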