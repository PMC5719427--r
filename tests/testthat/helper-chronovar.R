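# Shared fixtures: light-weight generator configs so the suite stays fast.
# Sensor channels are sampled at >= 10 min and omics panels are small;
# the study structure (6 subjects, 2 sessions, 0/12/24/36/48 h) is kept.

fast_sensor <- function(...) {
  s <- sensor_defaults()
  s$interval_min <- pmax(s$interval_min, 10)
  utils::modifyList(s, list(...))
}

fast_config <- function(seed = 1, n_features = 20, ...) {
  generator_config(
    seed = seed,
    sensor = fast_sensor(),
    omics = list(metabolome = list(n_features = n_features,
                                   fraction_rhythmic = 0.25),
                 proteome = list(n_features = n_features,
                                 fraction_rhythmic = 0.25)),
    ...)
}

# A noise-free, flat sensor config: every channel constant at its mesor
# plus the subject offset (amplitude, noise, dips and jitters all zero).
flat_config <- function(seed = 1, dip_map = 0) {
  s <- fast_sensor()
  s$amplitude <- 0
  s$sigma <- 0
  s$dip <- 0
  s$dip[s$channel == "map"] <- dip_map
  generator_config(
    seed = seed, sensor = s,
    sensor_opts = list(amp_factor_sd = 0, phase_jitter_sd = 0,
                       sleep_jitter_sd = 0))
}

ref_design <- function(n_sessions = 2) {
  study_design(sessions = LETTERS[seq_len(n_sessions)])
}

# Minimal omics matrix built by hand from a values matrix on the
# reference design (1 session unless stated).
toy_omics <- function(values, design = ref_design(1), kind = "metabolome") {
  meta <- design_samples(design)
  stopifnot(nrow(values) == nrow(meta))
  rownames(values) <- meta$sample_id
  omics_matrix(values, meta, kind = kind, design = design)
}
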