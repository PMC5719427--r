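#' Morning/evening separation statistic
#'
#' The dataset-level statistic aggregated over features: each feature is
#' standardized to unit variance (zero-variance features are excluded and
#' reported), then `T = sum over features of (morning mean - evening
#' mean)^2`. Larger T means stronger morning/evening separation. T is
#' invariant to feature order and, after standardization, to affine
#' rescaling of any feature. Metabolome/proteome matrices are analyzed on
#' the log10 scale.
#'
#' @param values Numeric samples x features matrix (already transformed).
#' @param morning Logical vector per sample (TRUE = morning).
#' @return List: `statistic`, `n_features_used`, `excluded` (feature ids
#'   dropped for zero variance).
#' @export
epoch_statistic <- function(values, morning) {
  stopifnot(nrow(values) == length(morning))
  if (all(morning) || !any(morning)) stop("both epochs must be non-empty")
  sds <- apply(values, 2, stats::sd)
  keep <- sds > 0
  excluded <- colnames(values)[!keep]
  if (!any(keep)) {
    return(list(statistic = 0, n_features_used = 0L, excluded = excluded))
  }
  z <- scale(values[, keep, drop = FALSE])
  d <- colMeans(z[morning, , drop = FALSE]) -
    colMeans(z[!morning, , drop = FALSE])
  list(statistic = sum(d^2), n_features_used = sum(keep),
       excluded = excluded)
}

# All distinct epoch relabelings: per session, every way to pick which
# within-session timepoints are "morning", preserving the observed
# per-session morning count; the same relabeling applies to all subjects
# (the timepoint column is the permutation unit). Returns a logical
# matrix (arrangement x sample), first row = observed labels.
enumerate_epoch_assignments <- function(meta, design) {
  sess <- design$sessions
  tp <- design$timepoints
  n_morning <- sum(epoch_of(design, tp) == "morning")
  per_session <- utils::combn(length(tp), n_morning, simplify = FALSE)
  # observed assignment first within each session's list
  obs <- which(epoch_of(design, tp) == "morning")
  ord <- c(which(vapply(per_session, function(s) identical(s, obs),
                        logical(1))),
           which(!vapply(per_session, function(s) identical(s, obs),
                         logical(1))))
  per_session <- per_session[ord]
  idx <- expand.grid(rep(list(seq_along(per_session)), length(sess)))
  n_arr <- nrow(idx)
  out <- matrix(FALSE, n_arr, nrow(meta))
  for (a in seq_len(n_arr)) {
    lab <- rep(FALSE, nrow(meta))
    for (si in seq_along(sess)) {
      m_tp <- tp[per_session[[idx[a, si]]]]
      lab <- lab | (meta$session == sess[si] &
                      meta$timepoint_hour %in% m_tp)
    }
    out[a, ] <- lab
  }
  out
}

#' Exhaustive morning/evening permutation test
#'
#' Significance of the observed morning/evening separation by enumerating
#' every distinct reassignment of epoch labels to within-session
#' timepoints. The permutation unit is the timepoint column: a relabeling
#' applies to all subjects simultaneously, preserving the within-subject
#' pairing, and per-session morning/evening counts are preserved.
#' Arrangements equivalent under within-epoch exchange are enumerated
#' once (the statistic depends only on the epoch partition), giving
#' `choose(5, 3)` arrangements per session — 100 in the two-session
#' reference design — so the smallest achievable p is 1/100. The p-value
#' is the proportion of arrangements (identity included) with `T >=
#' T_observed`, which guarantees `p > 0`. Designs with more than
#' `max_exhaustive` arrangements fall back to Monte-Carlo sampling.
#'
#' @param x An [omics_matrix()], or a numeric matrix with `meta`.
#' @param design Optional `study_design` (defaults to one inferred from
#'   the metadata).
#' @param scope `"dataset"` (one test aggregating all features) or
#'   `"feature"` (one test per feature).
#' @param transform log10-transform metabolome/proteome values first.
#' @param mode `"exhaustive"`, `"montecarlo"`, or `"auto"`.
#' @param n_mc Monte-Carlo draws when sampling.
#' @param max_exhaustive Arrangement-count ceiling for exhaustive mode.
#' @param meta Metadata when `x` is a bare matrix.
#' @return For `scope = "dataset"` a one-row tibble: `scope`,
#'   `statistic`, `n_permutations`, `n_at_least_as_extreme`, `p_value`,
#'   `min_achievable_p`, `mode`, `n_features_used`. For `scope =
#'   "feature"`, one row per feature.
#' @export
exhaustive_permutation_test <- function(x, design = NULL,
                                        scope = c("dataset", "feature"),
                                        transform = TRUE,
                                        mode = c("auto", "exhaustive",
                                                 "montecarlo"),
                                        n_mc = 10000,
                                        max_exhaustive = 1e6,
                                        meta = NULL) {
  scope <- match.arg(scope)
  mode <- match.arg(mode)
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
  if (is.null(design)) {
    design <- study_design(subjects = unique(meta$subject),
                           sessions = unique(meta$session),
                           timepoints = sort(unique(meta$timepoint_hour)))
  }
  if (length(unique(epoch_of(design, design$timepoints))) < 2) {
    stop("design has a single epoch; no morning/evening contrast to test")
  }

  n_sess <- length(design$sessions)
  n_tp <- length(design$timepoints)
  n_m <- sum(epoch_of(design, design$timepoints) == "morning")
  n_total <- choose(n_tp, n_m)^n_sess
  if (mode == "auto") {
    mode <- if (n_total <= max_exhaustive) "exhaustive" else "montecarlo"
  }

  # Standardize once; zero-variance features drop out for every
  # arrangement alike.
  sds <- apply(v, 2, stats::sd)
  keep <- sds > 0
  z <- if (any(keep)) scale(v[, keep, drop = FALSE]) else
    matrix(0, nrow(v), 0)

  if (mode == "exhaustive") {
    arr <- enumerate_epoch_assignments(meta, design)
  } else {
    arr <- matrix(FALSE, n_mc + 1, nrow(meta))
    arr[1, ] <- meta$epoch == "morning"
    tp <- design$timepoints
    for (a in seq_len(n_mc) + 1) {
      lab <- rep(FALSE, nrow(meta))
      for (se in design$sessions) {
        m_tp <- sample(tp, n_m)
        lab <- lab | (meta$session == se & meta$timepoint_hour %in% m_tp)
      }
      arr[a, ] <- lab
    }
  }
  n_arr <- nrow(arr)
  # Contrast rows: (1/n_m) on morning samples minus (1/n_e) on evening.
  nm <- rowSums(arr)
  D <- arr / nm - (!arr) / (nrow(meta) - nm)
  stat_all <- if (ncol(z) > 0) rowSums((D %*% z)^2) else rep(0, n_arr)

  mk_result <- function(stats_vec, feature_id = NA_character_,
                        n_used = ncol(z)) {
    obs <- stats_vec[1]
    k <- sum(stats_vec >= obs - 1e-12)
    tibble::tibble(
      feature_id = feature_id, scope = scope, statistic = obs,
      n_permutations = n_arr, n_at_least_as_extreme = k,
      p_value = k / n_arr, min_achievable_p = 1 / n_arr, mode = mode,
      n_features_used = n_used)
  }

  if (scope == "dataset") {
    out <- mk_result(stat_all)
    out$feature_id <- NULL
    return(out)
  }
  per_feat <- (D %*% z)^2
  purrr::map_dfr(seq_len(ncol(z)), function(j) {
    mk_result(per_feat[, j], feature_id = colnames(z)[j], n_used = 1L)
  })
}
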