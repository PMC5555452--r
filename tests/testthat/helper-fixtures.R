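# Hand-built single-batch dataset with three Df genotypes whose summaries are
# known in closed form, plus one synthetic-lethal cross.
#
# Control TIs: 0, 0.5, 1.0, 1.5  -> mean 0.75, sample SD sqrt(1.25/3)
# gA TIs: 2.0, 2.5, 3.0          -> mean NTI (2.5 - 0.75)/sd_c  (enhancer)
# gB TIs: 0.5, 1.0               -> mean NTI 0                  (no effect)
# gC TIs: 0, 0, 0                -> mean NTI -0.75/sd_c         (suppressor)
handbuilt_dataset <- function() {
  mk <- function(ids, genotype, role, sizes) {
    tibble::tibble(animal_id = ids, genotype_id = genotype, batch_id = "b1",
                   role = role, tumor_sizes = sizes)
  }
  animals <- dplyr::bind_rows(
    mk(paste0("c", 1:4), "control_b1", "control",
       list(numeric(0), 0.5, c(0.25, 0.25, 0.5), c(1.0, 0.5))),
    mk(paste0("a", 1:3), "gA", "df", list(c(1.0, 1.0), 2.5, c(1.5, 1.5))),
    mk(paste0("b", 1:2), "gB", "df", list(0.5, c(0.5, 0.5))),
    mk(paste0("x", 1:3), "gC", "df", list(numeric(0), numeric(0), numeric(0)))
  )
  crosses <- tibble::tibble(
    genotype_id = c("control_b1", "gA", "gB", "gC", "gD"),
    batch_id = "b1",
    role = c("control", "df", "df", "df", "df"),
    n_progeny = c(4L, 3L, 2L, 3L, 0L),
    lethal = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    true_effect = c(1, 5, 1, 0.1, NA)
  )
  structure(list(animals = animals, crosses = crosses, config = NULL),
            class = "screen_dataset")
}

# Closed-form expectations for the hand-built dataset.
handbuilt_expected <- function() {
  sd_c <- sqrt(1.25 / 3)
  list(
    sd_c = sd_c,
    gA_mean = (2.5 - 0.75) / sd_c,
    gA_se = (0.5 / sd_c) / sqrt(3),
    gB_mean = 0,
    gB_se = (sqrt(0.125) / sd_c) / sqrt(2),
    gC_mean = -0.75 / sd_c,
    gC_se = 0
  )
}
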