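#!/usr/bin/env Rscript
# Stage 5 — exhaustive morning/evening permutation tests. Dataset-level
# separation statistic T over all features, referenced against every
# distinct reassignment of epoch labels to within-session timepoints
# (choose(5,3)^2 = 100 arrangements in this design; smallest possible
# p = 0.01).

suppressPackageStartupMessages({library(chronovar); library(dplyr)})

panels <- c(plasma_metabolome = "metabolome",
            saliva_metabolome = "metabolome",
            serum_proteome = "proteome",
            saliva_microbiome = "microbiome")

res <- purrr::imap_dfr(panels, function(kind, nm) {
  om <- read_omics_table(sprintf("results/data/%s_values.csv", nm),
                         sprintf("results/data/%s_meta.csv", nm),
                         kind = kind)
  mutate(exhaustive_permutation_test(om), dataset = nm, .before = 1)
})
readr::write_csv(res, "results/permutation_tests.csv")

cat("dataset-level exhaustive permutation tests:\n")
for (i in seq_len(nrow(res))) {
  cat(sprintf("  %-18s T = %8.2f  p = %.3f (floor %.3f, %d arrangements)\n",
              res$dataset[i], res$statistic[i], res$p_value[i],
              res$min_achievable_p[i], res$n_permutations[i]))
}
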