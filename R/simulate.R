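#' Configuration for the synthetic chronobiome generator
#'
#' Defaults emulate the reference pilot design: 6 subjects studied over two
#' 48-hour sessions with biospecimens at 0/12/24/36/48 h (three morning,
#' two evening collections), continuous remote sensing in between, subject
#' random effects dominating omics variance, and a small minority of
#' features carrying a true morning/evening shift.
#'
#' @param n_subjects Number of subjects (default 6).
#' @param n_sessions Number of 48-h sessions (default 2).
#' @param timepoints Biospecimen hour offsets within a session.
#' @param seed Root seed; spawns per-module child seeds so stages can be
#'   regenerated independently. Identical config + seed gives identical
#'   output.
#' @param sensor Per-channel sensor parameters, see [sensor_defaults()].
#' @param sensor_opts Shared sensor options: per-subject amplitude factor
#'   sd (log scale), phase jitter sd (h), habitual sleep window (23:00 to
#'   07:00 clock time) and its per-subject jitter sd (h), wake event rates
#'   for communication (events/h) and mobility (miles/h), meal clock times
#'   and mean nutrient amounts per meal.
#' @param omics Per-kind omics parameters: `n_features`,
#'   `fraction_rhythmic` (rho), morning/evening log-effect size `beta`
#'   (natural-log scale; rhythmic features get +beta/2 in the morning and
#'   -beta/2 in the evening), subject-effect sd `sigma_s`, residual sd
#'   `sigma_e`, and log-baseline mean `mu0`. Defaults mirror the reference
#'   panel sizes (166 plasma metabolites, 1141 serum proteins) with
#'   `sigma_s > sigma_e` so subject variance dominates.
#' @param microbiome Compositional genus-table parameters: baseline
#'   proportions `p0` over 12 oral genera, Dirichlet concentration
#'   `kappa`, per-genus morning/evening log-fold effects `eta` (rhythmic
#'   genera have `eta != 0`; default plants 3 of 12), and a per-subject
#'   log-composition effect sd `subject_sd` so inter-individual
#'   differences dominate genus abundances.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 6,
                             n_sessions = 2,
                             timepoints = c(0, 12, 24, 36, 48),
                             seed = 1L,
                             sensor = sensor_defaults(),
                             sensor_opts = list(),
                             omics = list(),
                             microbiome = list()) {
  so <- utils::modifyList(list(
    amp_factor_sd = 0.25, phase_jitter_sd = 0.75,
    sleep_start_clock = 23, sleep_end_clock = 7, sleep_jitter_sd = 0.5,
    comm_wake_rate = 18.7, mobility_wake_rate = 1.6, mobility_sd = 0.8,
    meal_clock = c(8.5, 13, 19),
    meal_means = c(energy = 700, protein = 30, carbohydrate = 80,
                   fat = 25, sodium = 1.15),
    meal_cv = 0.2
  ), sensor_opts)

  om_default <- list(
    metabolome = list(n_features = 166, fraction_rhythmic = 0.054,
                      beta = 1.5, sigma_s = 1.0, sigma_e = 0.3, mu0 = 5),
    proteome   = list(n_features = 1141, fraction_rhythmic = 0.005,
                      beta = 0.3, sigma_s = 1.0, sigma_e = 0.3, mu0 = 7)
  )
  for (k in names(omics)) {
    om_default[[k]] <- utils::modifyList(
      om_default[[k]] %||% om_default$metabolome, omics[[k]])
  }

  mb <- utils::modifyList(list(
    p0 = stats::setNames(
      c(0.30, 0.14, 0.10, 0.09, 0.08, 0.07, 0.06, 0.05, 0.04, 0.03,
        0.02, 0.02),
      c("Streptococcus", "Veillonella", "Actinomyces", "Neisseria",
        "Haemophilus", "Prevotella", "Rothia", "Fusobacterium",
        "Porphyromonas", "Granulicatella", "Gemella", "Leptotrichia")),
    kappa = 200,
    eta = c(log(2), log(1.8), -log(1.8), rep(0, 9)),
    subject_sd = 0.8
  ), microbiome)

  cfg <- list(n_subjects = n_subjects, n_sessions = n_sessions,
              timepoints = timepoints, seed = as.integer(seed),
              sensor = sensor, sensor_opts = so, omics = om_default,
              microbiome = mb)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_sessions >= 1)
  for (k in names(cfg$omics)) {
    o <- cfg$omics[[k]]
    if (o$fraction_rhythmic < 0 || o$fraction_rhythmic > 1) {
      stop("fraction_rhythmic must lie in [0, 1] for kind ", k)
    }
    if (o$sigma_s < 0 || o$sigma_e < 0) stop("omics sds must be >= 0")
  }
  p0 <- cfg$microbiome$p0
  if (abs(sum(p0) - 1) > 1e-9) stop("microbiome baseline p0 must sum to 1")
  if (length(cfg$microbiome$eta) != length(p0)) {
    stop("microbiome eta must match p0 length")
  }
  if (any(cfg$sensor$sigma < 0)) stop("sensor noise sds must be >= 0")
  invisible(cfg)
}

#' Default sensor-channel parameters for the generator
#'
#' One row per channel: mesor `mesor` (channel units), diurnal amplitude
#' `amplitude`, acrophase `acrophase` (clock hour of peak), noise sd
#' `sigma`, sampling `interval_min`, nocturnal sleep dip `dip` (subtracted
#' while asleep; mmHg or bpm), and between-subject mesor sd `subject_sd`.
#' Blood-pressure and heart-rate channels carry their diurnality through
#' the planted sleep dip (amplitude 0): the mean arterial pressure dip of
#' 19.4 mmHg and heart-rate dip of 16.5 bpm match typical nocturnal
#' dipping in healthy young adults. Activity and light peak mid-afternoon.
#'
#' @return Tibble of per-channel parameters.
#' @export
sensor_defaults <- function() {
  tibble::tribble(
    ~channel,         ~mesor, ~amplitude, ~acrophase, ~sigma, ~interval_min, ~dip,  ~subject_sd,
    "activity_axis1",    600,        550,         14,    200,             1,    0,         100,
    "activity_axis2",    580,        530,         14,    200,             1,    0,         100,
    "activity_axis3",    560,        510,         14,    200,             1,    0,         100,
    "sbp",               120,          0,         15,      8,            30, 20.2,           8,
    "dbp",                75,          0,         15,      6,            30, 19.0,           6,
    "map",                90,          0,         15,      6,            30, 19.4,           6,
    "pp",                 45,          0,         15,      4,            30,  1.2,           4,
    "hr",                 70,          0,         15,      5,            30, 16.5,           5,
    "light",              25,         22,         13,     10,             1,    0,           5
  )
}

# Root seed -> reproducible per-module child seeds (< 2^31).
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

cosinor_signal <- function(t_clock, mesor, amplitude, acrophase,
                           period = 24) {
  mesor + amplitude * cos(2 * pi * (t_clock - acrophase) / period)
}

# Clock hour (UTC) of POSIXct timestamps.
clock_hour <- function(ts) (as.numeric(ts) / 3600) %% 24

# TRUE where each timestamp falls inside any of a subject's sleep intervals.
in_sleep <- function(ts, starts, ends) {
  asleep <- rep(FALSE, length(ts))
  for (i in seq_along(starts)) {
    asleep <- asleep | (ts >= starts[i] & ts < ends[i])
  }
  asleep
}

#' Generate synthetic sensor streams and sleep diaries
#'
#' For each subject and session, continuous channels are sampled at their
#' interval as `mesor + amplitude * cos(2*pi*(t - acrophase)/24) + subject
#' offset + Gaussian noise`, clipped at 0 for count channels; BP/HR
#' channels are additionally lowered by their dip during self-reported
#' sleep (habitually 23:00-07:00 with per-subject jitter). Communication,
#' mobility and nutrient channels emit events only during wake:
#' communication as hourly Poisson counts, mobility as hourly distances,
#' nutrients at three daily meals. Accelerometer axes 2 and 3 are derived
#' from axis 1 plus noise (axes of one device are strongly correlated) and
#' the vector magnitude is their Euclidean norm. Per-subject amplitude
#' factors (log-normal) and acrophase jitter are shared across channels,
#' so circadian amplitudes and phases correlate across channels within a
#' subject, as expected when behavior drives several readouts at once.
#'
#' @param config A [generator_config()].
#' @param design Optional `study_design`; defaults to one consistent with
#'   `config`.
#' @return List with `streams` (tidy tibble: subject, channel, timestamp,
#'   value, unit), `diary` (subject, sleep_start, sleep_end), and `truth`
#'   (planted per-subject channel parameters: mesor + offset, effective
#'   amplitude, acrophase, dip).
#' @export
generate_sensor_streams <- function(config, design = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(design)) design <- design_from_config(config)
  so <- config$sensor_opts
  seeds <- child_seeds(config$seed, 3)
  set.seed(seeds[1])

  subjects <- design$subjects
  ns <- length(subjects)
  amp_factor <- exp(stats::rnorm(ns, 0, so$amp_factor_sd))
  phase_shift <- stats::rnorm(ns, 0, so$phase_jitter_sd)
  sleep_j1 <- stats::rnorm(ns, 0, so$sleep_jitter_sd)
  sleep_j2 <- stats::rnorm(ns, 0, so$sleep_jitter_sd)
  sch <- config$sensor
  offsets <- matrix(stats::rnorm(ns * nrow(sch)), ns, nrow(sch)) *
    rep(sch$subject_sd, each = ns)
  dimnames(offsets) <- list(subjects, sch$channel)

  # Sleep diary: nights starting 23:00 on each day of each 48-h session.
  diary <- purrr::map_dfr(seq_along(subjects), function(si) {
    purrr::map_dfr(design$sessions, function(se) {
      t0 <- design$session_starts[[se]]
      start_off <- (so$sleep_start_clock - clock_hour(t0)) %% 24
      night0 <- t0 + (start_off + c(0, 24)) * 3600
      dur <- ((so$sleep_end_clock - so$sleep_start_clock) %% 24)
      tibble::tibble(
        subject = subjects[si],
        sleep_start = night0 + sleep_j1[si] * 3600,
        sleep_end = night0 + (dur + sleep_j2[si]) * 3600)
    })
  })

  session_grid <- function(interval_min) {
    purrr::map_dfr(design$sessions, function(se) {
      t0 <- design$session_starts[[se]]
      off <- seq(0, 48 * 60 - interval_min, by = interval_min) * 60
      tibble::tibble(session = se, timestamp = t0 + off)
    })
  }

  streams <- purrr::map_dfr(seq_along(subjects), function(si) {
    sj <- subjects[si]
    dsub <- diary[diary$subject == sj, ]
    gen_channel <- function(ch) {
      p <- sch[sch$channel == ch, ]
      g <- session_grid(p$interval_min)
      tc <- clock_hour(g$timestamp)
      mu <- cosinor_signal(tc, p$mesor + offsets[sj, ch],
                           p$amplitude * amp_factor[si],
                           p$acrophase + phase_shift[si])
      asleep <- in_sleep(g$timestamp, dsub$sleep_start, dsub$sleep_end)
      v <- mu - p$dip * asleep + stats::rnorm(length(mu), 0, p$sigma)
      tibble::tibble(subject = sj, channel = ch, timestamp = g$timestamp,
                     value = v)
    }

    ax1 <- gen_channel("activity_axis1")
    ax_noise_sd <- 0.2 * sch$sigma[sch$channel == "activity_axis1"]
    ax2 <- ax1 |> dplyr::mutate(
      channel = "activity_axis2",
      value = 0.95 * .data$value + stats::rnorm(dplyr::n(), 0, ax_noise_sd))
    ax3 <- ax1 |> dplyr::mutate(
      channel = "activity_axis3",
      value = 0.90 * .data$value + stats::rnorm(dplyr::n(), 0, ax_noise_sd))
    ax1$value <- pmax(ax1$value, 0)
    ax2$value <- pmax(ax2$value, 0)
    ax3$value <- pmax(ax3$value, 0)
    vm <- ax1 |> dplyr::mutate(
      channel = "activity_vm",
      value = sqrt(ax1$value^2 + ax2$value^2 + ax3$value^2))

    cont <- purrr::map_dfr(c("sbp", "dbp", "map", "pp", "hr", "light"),
                           gen_channel)
    cont$value[cont$channel == "light"] <-
      pmax(cont$value[cont$channel == "light"], 0)

    # Event channels: hourly counts/distances, emitted only during wake.
    hg <- session_grid(60)
    hc <- clock_hour(hg$timestamp)
    awake <- !in_sleep(hg$timestamp + 1800, dsub$sleep_start, dsub$sleep_end)
    comm_rate <- pmax(cosinor_signal(
      hc, so$comm_wake_rate, 0.4 * so$comm_wake_rate * amp_factor[si],
      14 + phase_shift[si]), 0)
    comm <- tibble::tibble(
      subject = sj, channel = "communication", timestamp = hg$timestamp,
      value = ifelse(awake, stats::rpois(nrow(hg), comm_rate), 0))
    mob_mu <- pmax(cosinor_signal(
      hc, so$mobility_wake_rate, 0.5 * so$mobility_wake_rate * amp_factor[si],
      15 + phase_shift[si]), 0)
    mob <- tibble::tibble(
      subject = sj, channel = "mobility", timestamp = hg$timestamp,
      value = ifelse(awake,
                     pmax(stats::rnorm(nrow(hg), mob_mu, so$mobility_sd), 0),
                     0))

    meals <- purrr::map_dfr(design$sessions, function(se) {
      t0 <- design$session_starts[[se]]
      day0 <- t0 - clock_hour(t0) * 3600
      mt <- day0 + rep(c(0, 24) * 3600, each = length(so$meal_clock)) +
        so$meal_clock * 3600
      mt <- mt[mt >= t0 & mt < t0 + 48 * 3600]
      purrr::map_dfr(names(so$meal_means), function(nu) {
        amt <- pmax(stats::rnorm(length(mt), so$meal_means[[nu]],
                                 so$meal_cv * so$meal_means[[nu]]), 0)
        tibble::tibble(subject = sj, channel = nu, timestamp = mt,
                       value = amt)
      })
    })

    dplyr::bind_rows(ax1, ax2, ax3, vm, cont, comm, mob, meals)
  })

  streams <- streams |>
    dplyr::arrange(.data$subject, .data$channel, .data$timestamp) |>
    dplyr::left_join(channel_schema()[, c("channel", "unit")],
                     by = "channel")

  truth <- tidyr::expand_grid(subject = subjects, channel = sch$channel) |>
    dplyr::left_join(sch, by = "channel") |>
    dplyr::mutate(
      si = match(.data$subject, subjects),
      mesor = .data$mesor + offsets[cbind(.data$subject, .data$channel)],
      amplitude = .data$amplitude * amp_factor[.data$si],
      acrophase = (.data$acrophase + phase_shift[.data$si]) %% 24) |>
    dplyr::select("subject", "channel", "mesor", "amplitude", "acrophase",
                  "dip")

  list(streams = streams, diary = diary, truth = truth)
}

design_from_config <- function(config) {
  study_design(subjects = sprintf("S%d", seq_len(config$n_subjects)),
               sessions = LETTERS[seq_len(config$n_sessions)],
               timepoints = config$timepoints)
}

#' Generate a synthetic omics matrix with planted morning/evening effects
#'
#' Metabolome/proteome: natural-log abundances are `feature baseline +
#' subject random intercept N(0, sigma_s^2) + epoch effect + residual
#' N(0, sigma_e^2)`, exponentiated. A `ceiling(rho * n_features)` subset
#' of features is rhythmic and receives `+beta/2` in morning samples and
#' `-beta/2` in evening samples. Microbiome: each sample is a Dirichlet
#' draw with concentration `kappa * p(sample)`, where `log p` adds the
#' per-genus epoch log-fold effects `eta/2` (sign by epoch) to the
#' baseline composition and renormalizes. The planted rhythmic feature
#' identities are attached as ground truth (see [ground_truth()]).
#'
#' @param config A [generator_config()].
#' @param kind `"metabolome"`, `"proteome"` or `"microbiome"`.
#' @param design Optional `study_design`.
#' @return An [omics_matrix()] with a `ground_truth` attribute.
#' @export
generate_omics <- function(config,
                           kind = c("metabolome", "proteome", "microbiome"),
                           design = NULL) {
  stopifnot(inherits(config, "generator_config"))
  kind <- match.arg(kind)
  if (is.null(design)) design <- design_from_config(config)
  meta <- design_samples(design)
  n <- nrow(meta)
  seeds <- child_seeds(config$seed, 6)
  set.seed(seeds[if (kind == "metabolome") 4 else if (kind == "proteome") 5 else 6])
  epoch_sign <- ifelse(meta$epoch == "morning", +0.5, -0.5)

  if (kind == "microbiome") {
    p0 <- config$microbiome$p0
    eta <- config$microbiome$eta
    kappa <- config$microbiome$kappa
    # per-subject log-composition offsets: inter-individual differences
    # dominate genus abundances as they do the other omics layers
    u <- matrix(stats::rnorm(length(design$subjects) * length(p0), 0,
                             config$microbiome$subject_sd),
                length(design$subjects), length(p0))
    subj_idx <- match(meta$subject, design$subjects)
    vals <- matrix(NA_real_, n, length(p0),
                   dimnames = list(meta$sample_id, names(p0)))
    for (i in seq_len(n)) {
      lp <- log(p0) + u[subj_idx[i], ] + eta * epoch_sign[i]
      p <- exp(lp) / sum(exp(lp))
      g <- stats::rgamma(length(p0), shape = kappa * p, rate = 1)
      vals[i, ] <- g / sum(g)
    }
    out <- omics_matrix(vals, meta, kind = "microbiome", design = design)
    attr(out, "ground_truth") <- tibble::tibble(
      feature_id = names(p0), is_rhythmic = eta != 0, planted_beta = eta)
    return(out)
  }

  o <- config$omics[[kind]]
  if (is.null(o)) stop("no omics config for kind ", kind)
  p <- o$n_features
  n_rhythmic <- ceiling(o$fraction_rhythmic * p)
  if (o$fraction_rhythmic > 0 && o$fraction_rhythmic * p < 1) {
    warning("fraction_rhythmic * n_features < 1; planting a single feature")
  }
  rhythmic <- seq_len(p) %in% sample.int(p, n_rhythmic)
  beta_f <- ifelse(rhythmic, o$beta, 0)

  baseline <- stats::rnorm(p, o$mu0, 1)
  subj_idx <- match(meta$subject, design$subjects)
  u <- matrix(stats::rnorm(length(design$subjects) * p, 0, o$sigma_s),
              length(design$subjects), p)
  logv <- matrix(baseline, n, p, byrow = TRUE) +
    u[subj_idx, , drop = FALSE] +
    outer(epoch_sign, beta_f) +
    matrix(stats::rnorm(n * p, 0, o$sigma_e), n, p)
  vals <- exp(logv)
  dimnames(vals) <- list(meta$sample_id, sprintf("%s_%04d", kind, seq_len(p)))
  out <- omics_matrix(vals, meta, kind = kind, design = design)
  attr(out, "ground_truth") <- tibble::tibble(
    feature_id = colnames(vals), is_rhythmic = rhythmic,
    planted_beta = beta_f)
  out
}
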