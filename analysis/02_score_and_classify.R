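#!/usr/bin/env Rscript
# Score the simulated screen (per-animal TI, batch-paired NTI), summarize per
# genotype, and apply the strict |mean NTI| > 1 rule. Compares the calls
# against the planted ground truth from 01_simulate_screen.R.

library(modscreen)

paths <- run_analyze("results/screen/animals.tsv", "results/analysis",
                     crosses_path = "results/screen/crosses.tsv",
                     threshold = 1, min_n = 15)

summaries <- readr::read_tsv(paths[["genotypes"]], show_col_types = FALSE)
counts <- readr::read_tsv(paths[["counts"]], show_col_types = FALSE)
truth <- readr::read_tsv("results/screen/crosses.tsv", show_col_types = FALSE)

message("classification tallies:")
print(counts)

truth_df <- truth[truth$role == "df", c("genotype_id", "true_effect", "lethal")]
merged <- merge(summaries, truth_df, by = "genotype_id")
enh <- merged$true_effect > 1 & !merged$lethal
sup <- merged$true_effect < 1 & !merged$lethal
message(sprintf("planted enhancers recovered: %d/%d",
                sum(merged$classification[enh] == "enhancer"), sum(enh)))
message(sprintf("planted suppressors recovered: %d/%d",
                sum(merged$classification[sup] == "suppressor"), sum(sup)))
null_called <- merged$classification[merged$true_effect == 1 & !merged$lethal]
message(sprintf("false hits among nulls: %d/%d",
                sum(null_called %in% c("enhancer", "suppressor")),
                length(null_called)))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  class(summaries) <- class(tibble::tibble())
  p <- plot_nti(summaries)
  ggplot2::ggsave("results/analysis/nti_hits.pdf", p, width = 7, height = 4)
  message("wrote results/analysis/nti_hits.pdf")
}
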