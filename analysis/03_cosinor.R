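#!/usr/bin/env Rscript
# Stage 3 — cosinor rhythmometry. Fits a fixed 24-h cosinor to every
# subject/channel/24-h-window and correlates circadian amplitudes
# (squared Pearson R^2, %) and acrophases (circular-circular
# correlation) across channels, Bonferroni-corrected.

suppressPackageStartupMessages({library(chronovar); library(dplyr)})

binned <- readr::read_csv("results/binned_sensors.csv",
                          show_col_types = FALSE)
fits <- cosinor_by_window(binned)
readr::write_csv(fits, "results/cosinor_fits.csv")

corr <- bind_rows(amplitude_phase_correlation(fits, "amplitude"),
                  amplitude_phase_correlation(fits, "phase"))
readr::write_csv(corr, "results/cosinor_correlations.csv")

rhythmic <- fits |>
  group_by(channel) |>
  summarise(median_amplitude = median(amplitude),
            median_acrophase = median(acrophase),
            frac_sig = mean(p_zero_amplitude < 0.05, na.rm = TRUE))
readr::write_csv(rhythmic, "results/cosinor_by_channel.csv")
cat("per-channel cosinor medians (amplitude / acrophase h / % windows p<0.05):\n")
for (i in seq_len(nrow(rhythmic))) {
  cat(sprintf("  %-15s %8.2f  %5.1f h  %4.0f%%\n", rhythmic$channel[i],
              rhythmic$median_amplitude[i], rhythmic$median_acrophase[i],
              100 * rhythmic$frac_sig[i]))
}
top <- corr |> filter(tested) |> arrange(p_bonferroni) |> head(5)
cat("strongest amplitude/phase couplings:\n")
for (i in seq_len(nrow(top))) {
  cat(sprintf("  %-9s %-15s ~ %-15s R2 = %5.1f%%  p_bonf = %.2g\n",
              top$measure[i], top$channel_a[i], top$channel_b[i],
              top$r2_percent[i], top$p_bonferroni[i]))
}
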