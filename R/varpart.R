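#' Time-versus-subject variance partition per feature
#'
#' For each feature, a two-factor crossed main-effects ANOVA of the
#' (transformed) values on subject and time-of-day decomposes the total
#' sum of squares into a subject component, a time component and a
#' residual (which absorbs the subject-by-time interaction); percentages
#' are `100 * SS_x / SS_total`. Metabolome/proteome values are
#' log10-transformed first; microbiome proportions are analyzed
#' untransformed. The time factor is either the 5-level within-session
#' timepoint (default; sessions are pooled as replicates of the same
#' timepoint level) or the 2-level morning/evening epoch.
#'
#' In the balanced crossed design the two main effects are orthogonal and
#' the decomposition is exact; with missing cells the sequential sums of
#' squares depend on factor order and a warning is recorded in the output.
#'
#' @param x An [omics_matrix()], or a numeric matrix plus `meta` with
#'   `subject` and timepoint/epoch columns.
#' @param time_factor `"timepoint5"` (within-session hour offsets) or
#'   `"epoch2"` (morning/evening).
#' @param transform Apply the kind's transform (log10 for
#'   metabolome/proteome) before decomposing. Percentages are invariant to
#'   affine rescaling but not to nonlinear transforms, so this matches the
#'   display convention.
#' @param meta Sample metadata when `x` is a bare matrix.
#' @return Tibble: `feature_id`, `pct_time`, `pct_subject`,
#'   `pct_residual`, `ss_total`, `balanced`.
#' @export
partition_variance <- function(x, time_factor = c("timepoint5", "epoch2"),
                               transform = TRUE, meta = NULL) {
  time_factor <- match.arg(time_factor)
  if (inherits(x, "omics_matrix")) {
    v <- x$values
    meta <- x$sample_meta
    if (transform && x$kind != "microbiome") {
      v <- transform_values(v, "log10_offset")
    }
  } else {
    v <- as.matrix(x)
    if (is.null(meta)) stop("meta required for a bare matrix")
  }
  subj <- factor(meta$subject)
  tf <- if (time_factor == "timepoint5") {
    factor(meta$timepoint_hour)
  } else {
    factor(meta$epoch)
  }
  if (nlevels(subj) < 2) stop("subject factor needs >= 2 levels")
  if (nlevels(tf) < 2) stop("time factor needs >= 2 levels")
  # Proportional cell frequencies keep the two main effects orthogonal,
  # so sequential sums of squares are order-invariant.
  cells <- table(subj, tf)
  expected_cells <- outer(rowSums(cells), colSums(cells)) / sum(cells)
  balanced <- all(cells == expected_cells)
  if (!balanced) {
    warning("unbalanced subject x time design: sequential sums of squares")
  }

  res <- purrr::map_dfr(seq_len(ncol(v)), function(j) {
    # only the sums of squares are used, so the F-test warning emitted for
    # zero-residual features is irrelevant here
    an <- withCallingHandlers(
      stats::anova(stats::lm(v[, j] ~ subj + tf)),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    ss <- an[["Sum Sq"]]
    tot <- sum(ss)
    tibble::tibble(
      feature_id = colnames(v)[j],
      pct_subject = 100 * ss[1] / tot,
      pct_time = 100 * ss[2] / tot,
      pct_residual = 100 * ss[3] / tot,
      ss_total = tot)
  })
  res$balanced <- balanced
  res[, c("feature_id", "pct_time", "pct_subject", "pct_residual",
          "ss_total", "balanced")]
}

#' Classify time-varying features by percent-variance cutoff
#'
#' A feature is flagged time-varying when its time-of-day variance
#' contribution reaches the cutoff (default 5% of total variance). The
#' complementary rule `pct_time > pct_subject` is emitted alongside but
#' the headline counts use the cutoff.
#'
#' @param partitions Output of [partition_variance()].
#' @param cutoff_pct Percent-of-total-variance cutoff (default 5).
#' @return `partitions` with logical columns `flag_time_varying`
#'   (`pct_time >= cutoff`) and `time_exceeds_subject`.
#' @export
classify_time_varying <- function(partitions, cutoff_pct = 5) {
  dplyr::mutate(partitions,
                flag_time_varying = .data$pct_time >= cutoff_pct,
                time_exceeds_subject = .data$pct_time > .data$pct_subject)
}

#' Summary counts for a flagged feature set
#'
#' The headline "x% (k/n) of features show time-specific variability"
#' arithmetic: percentage of flagged features rounded to 1 decimal.
#'
#' @param flags Logical vector of per-feature flags (or the output of
#'   [classify_time_varying()], whose `flag_time_varying` column is used).
#' @param dataset Optional dataset label.
#' @return Tibble `dataset`, `n_features`, `n_flagged`, `pct_flagged`.
#' @export
flag_summary <- function(flags, dataset = NA_character_) {
  if (is.data.frame(flags)) flags <- flags$flag_time_varying
  n <- length(flags)
  k <- sum(flags)
  tibble::tibble(dataset = dataset, n_features = n, n_flagged = k,
                 pct_flagged = if (n > 0) round(100 * k / n, 1) else NA_real_)
}
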