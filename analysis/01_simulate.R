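#!/usr/bin/env Rscript
# Stage 1 — simulate a pilot chronobiome cohort at the reference design:
# 6 subjects, two 48-h sessions two weeks apart, biospecimens at
# 0/12/24/36/48 h (3 morning / 2 evening), continuous sensor streams with
# planted nocturnal dips, and three omics panels (plasma metabolome,
# serum proteome, saliva microbiome) with subject-dominated variance and
# a small rhythmic minority. Writes tidy CSVs under results/data/.

suppressPackageStartupMessages(library(chronovar))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20160307 %% 2^31

cfg <- generator_config(seed = seed)
design <- chronovar:::design_from_config(cfg)

sens <- generate_sensor_streams(cfg, design)
write_sensor_table(sens$streams, file.path(out, "sensors.csv"))
write_sleep_diary(sens$diary, file.path(out, "sleep.csv"))
readr::write_csv(sens$truth, file.path(out, "sensor_truth.csv"))

panels <- list(
  plasma_metabolome = generate_omics(cfg, "metabolome", design),
  serum_proteome = generate_omics(cfg, "proteome", design),
  saliva_microbiome = generate_omics(cfg, "microbiome", design))
# a second metabolome panel with its own seed stands in for saliva
cfg2 <- generator_config(
  seed = seed + 1,
  omics = list(metabolome = list(n_features = 250,
                                 fraction_rhythmic = 0.056)))
panels$saliva_metabolome <- generate_omics(cfg2, "metabolome", design)

for (nm in names(panels)) {
  write_omics_table(panels[[nm]],
                    file.path(out, paste0(nm, "_values.csv")),
                    file.path(out, paste0(nm, "_meta.csv")))
  readr::write_csv(ground_truth(panels[[nm]]),
                   file.path(out, paste0(nm, "_truth.csv")))
  cat(sprintf("%-18s %4d samples x %4d features (%d planted rhythmic)\n",
              nm, nrow(panels[[nm]]$values), ncol(panels[[nm]]$values),
              sum(ground_truth(panels[[nm]])$is_rhythmic)))
}
cat(sprintf("sensors: %d records across %d channels\n",
            nrow(sens$streams), length(unique(sens$streams$channel))))
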