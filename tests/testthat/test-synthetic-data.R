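test_that("parameter constructors validate their ranges", {
  expect_error(sim_params(penetrance = 1.2), "penetrance")
  expect_error(sim_params(tumor_count_mean = 0), "tumor_count_mean")
  expect_error(sim_params(size_param = 0), "size_param")
  expect_error(sim_params(size_param = 1.1), "size_param")
  expect_error(sim_params(effect_multiplier = -1), "effect_multiplier")
  expect_error(sim_params(n_per_cross = 0), "n_per_cross")
  expect_error(screen_config(n_df = 0), "n_df")
  expect_error(screen_config(df_effects = c(2, 3)), "named")
  expect_error(screen_config(df_effects = c(Df_001 = -2)), "multipliers")
  expect_error(cell_sim_params(control_sd = 0), "control_sd")
  expect_error(cell_sim_params(edu_rate_exp = 1.5), "edu_rate_exp")
  # temperature presets
  expect_equal(sim_params(preset = "25C")$penetrance, 0.68)
  expect_equal(sim_params(preset = "29C")$penetrance, 0.99)
})

test_that("degenerate parameters force the documented outcomes", {
  set.seed(5)
  # penetrance 0: every animal tumor-free
  p0 <- sim_params(penetrance = 0)
  sizes <- modscreen:::draw_tumor_sizes(200, p0)
  expect_true(all(lengths(sizes) == 0))
  expect_true(all(tumor_index(sizes) == 0))

  # penetrance 1, count rate -> 0+, size_param 1: exactly one tumor of 0.25
  p1 <- sim_params(penetrance = 1, tumor_count_mean = 1e-9, size_param = 1)
  sizes1 <- modscreen:::draw_tumor_sizes(200, p1)
  expect_true(all(lengths(sizes1) == 1))
  expect_true(all(tumor_index(sizes1) == 0.25))
})

test_that("zero-truncated Poisson deviates are >= 1 with the truncated mean", {
  set.seed(6)
  k <- rztpois(20000, 2)
  expect_true(all(k >= 1))
  # E[X | X >= 1] = lambda / (1 - exp(-lambda))
  expect_equal(mean(k), 2 / (1 - exp(-2)), tolerance = 0.02)
  expect_true(all(rztpois(1000, 1e-8) == 1))
})

test_that("simulated tumor sizes lie on the quarter grid", {
  set.seed(7)
  sizes <- unlist(modscreen:::draw_tumor_sizes(2000, sim_params()))
  expect_true(all(sizes >= 0.25))
  expect_true(all(abs(sizes / 0.25 - round(sizes / 0.25)) < 1e-12))
})

test_that("empirical penetrance matches the configured penetrance", {
  set.seed(8)
  for (pen in c(0.99, 0.68)) {
    ti <- tumor_index(modscreen:::draw_tumor_sizes(10000, sim_params(penetrance = pen)))
    interval <- qbinom(c(0.005, 0.995), 10000, pen) / 10000
    frac <- mean(ti > 0)
    expect_gte(frac, interval[1])
    expect_lte(frac, interval[2])
  }
})

test_that("mean TI is increasing in the effect multiplier", {
  set.seed(9)
  means <- vapply(c(1, 2, 4), function(eff) {
    p <- sim_params(effect_multiplier = eff)
    mean(tumor_index(modscreen:::draw_tumor_sizes(2000, p)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("simulate_cross returns n_per_cross records, or none when lethal", {
  res <- simulate_cross("g1", "b1", sim_params(n_per_cross = 15), seed = 3)
  expect_equal(nrow(res$animals), 15)
  expect_equal(res$cross$n_progeny, 15L)
  expect_false(res$cross$lethal)

  lethal <- simulate_cross("g2", "b1", sim_params(lethal = TRUE), seed = 3)
  expect_equal(nrow(lethal$animals), 0)
  expect_equal(lethal$cross$n_progeny, 0L)
  expect_true(lethal$cross$lethal)
})

test_that("simulate_screen lays out batches, pairs controls, and records ground truth", {
  cfg <- screen_config(n_df = 363, batch_size = 20, seed = 17,
                       df_effects = c(Df_010 = 5))
  ds <- simulate_screen(cfg)
  df_crosses <- ds$crosses[ds$crosses$role == "df", ]
  ctl_crosses <- ds$crosses[ds$crosses$role == "control", ]
  expect_equal(nrow(df_crosses), 363)
  expect_equal(length(unique(ds$crosses$batch_id)), ceiling(363 / 20))
  expect_equal(nrow(ctl_crosses), ceiling(363 / 20))
  # exactly one control per batch
  expect_true(all(table(ctl_crosses$batch_id) == 1))
  # ground truth bookkeeping
  expect_equal(df_crosses$true_effect[df_crosses$genotype_id == "Df_010"], 5)
  expect_true(all(df_crosses$true_effect[df_crosses$genotype_id != "Df_010"] == 1))

  # null screen: every Df recorded as effect 1
  null_ds <- simulate_screen(screen_config(n_df = 10, batch_size = 5, seed = 1))
  expect_true(all(null_ds$crosses$true_effect[null_ds$crosses$role == "df"] == 1))
})

test_that("identical seed and config give bit-identical datasets", {
  cfg <- screen_config(n_df = 12, batch_size = 4, seed = 123,
                       df_effects = c(Df_003 = 2))
  expect_identical(simulate_screen(cfg), simulate_screen(cfg))
  cfg2 <- cfg; cfg2$seed <- 124L
  expect_false(identical(simulate_screen(cfg)$animals, simulate_screen(cfg2)$animals))

  cp <- cell_sim_params(seed = 55)
  expect_identical(simulate_cell_table(cp), simulate_cell_table(cp))
})

test_that("adding Df crosses does not perturb earlier crosses' draws", {
  small <- simulate_screen(screen_config(n_df = 5, batch_size = 10, seed = 42))
  big <- simulate_screen(screen_config(n_df = 8, batch_size = 10, seed = 42))
  shared <- small$animals[small$animals$role == "df", ]
  shared_big <- big$animals[big$animals$genotype_id %in% shared$genotype_id, ]
  expect_equal(shared_big$tumor_sizes, shared$tumor_sizes)
})

test_that("cell tables honor group structure, truncation, and marker rates", {
  set.seed(10)
  # degenerate noise: every experimental intensity is effect_ratio x control
  p <- cell_sim_params(n_cells_control = 20, n_cells_exp = 20,
                       control_mean = 50, control_sd = 1e-9,
                       effect_ratio = 2, seed = 2)
  cells <- simulate_cell_table(p)
  expect_equal(mean(cells$gray_value[cells$group == "experimental"]) /
                 mean(cells$gray_value[cells$group == "control"]),
               2, tolerance = 1e-6)
  expect_true(all(cells$gray_value >= 0))

  # EdU rate recovery within the binomial 99% interval
  p2 <- cell_sim_params(n_cells_control = 10, n_cells_exp = 2000,
                        p1_fraction = 1, edu_rate_exp = 0.3, seed = 4)
  cells2 <- simulate_cell_table(p2)
  ex <- cells2[cells2$group == "experimental", ]
  frac <- mean(ex$edu[ex$p1])
  n_p1 <- sum(ex$p1)
  interval <- qbinom(c(0.005, 0.995), n_p1, 0.3) / n_p1
  expect_gte(frac, interval[1])
  expect_lte(frac, interval[2])
  # EdU is scored only within P1-positive cells
  expect_true(all(!cells2$edu[!cells2$p1]))
})

test_that("YAML config round-trips into screen and cell parameters", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_df: 40",
    "batch_size: 8",
    "seed: 7",
    "control_params:",
    "  preset: 29C",
    "  n_per_cross: 20",
    "df_effects:",
    "  Df_001: 5.0",
    "  Df_002: lethal",
    "cells:",
    "  effect_ratio: 2.5",
    "  seed: 3"
  ), cfg_path)
  cfg <- read_config(cfg_path)
  expect_equal(cfg$screen$n_df, 40L)
  expect_equal(cfg$screen$control_params$penetrance, 0.99)
  expect_equal(cfg$screen$control_params$n_per_cross, 20L)
  expect_equal(unname(cfg$screen$df_effects["Df_001"]), 5)
  expect_true(is.na(cfg$screen$df_effects["Df_002"]))
  expect_equal(cfg$cells$effect_ratio, 2.5)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_df: 10", "not_a_key: 1"), bad)
  expect_error(read_config(bad), "not_a_key")
})
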