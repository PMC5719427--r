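#!/usr/bin/env Rscript
# Stage 6 — variance correlation matrix across sensor channels. Pairwise
# simple-regression R^2 over shared hourly bins (square-root transform
# for count channels), goodness-of-fit p-values Bonferroni-corrected by
# the number of pairs tested; pooled across subjects plus per-subject
# matrices to expose between-subject differences.

suppressPackageStartupMessages({library(chronovar); library(dplyr)})

binned <- readr::read_csv("results/binned_sensors.csv",
                          show_col_types = FALSE) |>
  filter(!channel %in% c("energy", "protein", "carbohydrate", "fat",
                         "sodium"))

vc <- variance_correlation(binned, pool = "pooled")
vcs <- variance_correlation(binned, pool = "per_subject")
readr::write_csv(vc, "results/variance_correlation_pooled.csv")
readr::write_csv(vcs, "results/variance_correlation_by_subject.csv")

top <- vc |> filter(var_a != var_b) |> arrange(desc(r2)) |> head(8)
cat("strongest pooled channel couplings (R^2, Bonferroni p):\n")
for (i in seq_len(nrow(top))) {
  cat(sprintf("  %-15s ~ %-15s R2 = %5.3f  p_bonf = %.2g (log10 p = %.0f)\n",
              top$var_a[i], top$var_b[i], top$r2[i], top$p_bonferroni[i],
              top$log10_p_raw[i]))
}
# spread of a coupling across subjects
sbp_act <- vcs |>
  filter((var_a == "sbp" & var_b == "activity_vm") |
           (var_a == "activity_vm" & var_b == "sbp"))
cat(sprintf("SBP ~ activity R2 ranges %.2f-%.2f across subjects\n",
            min(sbp_act$r2), max(sbp_act$r2)))
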