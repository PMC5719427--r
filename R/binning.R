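#' Bin a sensor stream onto a regular grid
#'
#' Records are assigned to half-open intervals `[bin_start, bin_start +
#' width)` anchored at midnight, and aggregated per bin: the mean for
#' continuous channels, the sum for event/nutrient channels (so totals are
#' conserved). Bins without any observation are absent from the output
#' (missing, never zero-filled for continuous channels).
#'
#' @param streams Tidy sensor tibble (`subject`, `channel`, `timestamp`,
#'   `value`), one or several streams.
#' @param width Bin width in minutes; must divide 24 h.
#' @param agg `"auto"` (mean for continuous/count channels, sum for event
#'   channels, per the channel schema), `"mean"` or `"sum"`.
#' @return Tibble `subject`, `channel`, `bin_start` (POSIXct), `value`,
#'   `n_obs`.
#' @export
bin_stream <- function(streams, width = 60, agg = c("auto", "mean", "sum")) {
  agg <- match.arg(agg)
  if ((24 * 60) %% width != 0) stop("bin width must divide 24 h")
  if (nrow(streams) == 0) {
    return(tibble::tibble(subject = character(), channel = character(),
                          bin_start = as.POSIXct(character(), tz = "UTC"),
                          value = numeric(), n_obs = integer()))
  }
  sch <- channel_schema()
  agg_of <- function(ch) {
    if (agg != "auto") return(agg)
    cls <- sch$class[match(ch, sch$channel)]
    ifelse(!is.na(cls) & cls == "event", "sum", "mean")
  }
  wsec <- width * 60
  streams |>
    dplyr::mutate(
      bin_start = as.POSIXct(floor(as.numeric(.data$timestamp) / wsec) * wsec,
                             origin = "1970-01-01", tz = "UTC"),
      .agg = agg_of(.data$channel)) |>
    dplyr::group_by(.data$subject, .data$channel, .data$bin_start) |>
    dplyr::summarise(
      value = if (.data$.agg[1] == "sum") sum(.data$value) else mean(.data$value),
      n_obs = dplyr::n(), .groups = "drop")
}

#' Wake/sleep summary and nocturnal dip per subject and channel
#'
#' Bins whose midpoint falls inside a self-reported sleep interval are
#' sleep bins; all others are wake. Returns per-(subject, channel) wake
#' and sleep means and the nocturnal dip `wake_mean - sleep_mean`.
#' Midpoint assignment avoids double-counting bins that straddle a sleep
#' boundary. When a subject/channel has bins in only one epoch the other
#' mean is `NA` and the row is flagged incomplete.
#'
#' @param binned Output of [bin_stream()].
#' @param diary Sleep diary tibble (`subject`, `sleep_start`, `sleep_end`).
#' @param width Bin width in minutes (to locate midpoints).
#' @return Tibble `subject`, `channel`, `wake_mean`, `sleep_mean`, `dip`,
#'   `n_wake`, `n_sleep`, `complete`.
#' @export
wake_sleep_summary <- function(binned, diary, width = 60) {
  stopifnot(all(c("subject", "channel", "bin_start", "value") %in%
                  names(binned)))
  binned |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_modify(function(df, key) {
      dsub <- diary[diary$subject == key$subject, ]
      mid <- df$bin_start + width * 30
      asleep <- in_sleep(mid, dsub$sleep_start, dsub$sleep_end)
      df |>
        dplyr::mutate(asleep = asleep) |>
        dplyr::group_by(.data$channel) |>
        dplyr::summarise(
          wake_mean = mean(.data$value[!.data$asleep]),
          sleep_mean = mean(.data$value[.data$asleep]),
          n_wake = sum(!.data$asleep),
          n_sleep = sum(.data$asleep), .groups = "drop")
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(dip = .data$wake_mean - .data$sleep_mean,
                  complete = .data$n_wake >= 1 & .data$n_sleep >= 1) |>
    dplyr::select("subject", "channel", "wake_mean", "sleep_mean", "dip",
                  "n_wake", "n_sleep", "complete")
}

#' Per-subject and pooled wake/sleep means across subjects
#'
#' Both ways of averaging a panel: per subject then averaged across
#' subjects (`per_subject` rows, mean of subject means with sd), and
#' pooled over all subjects' bins (`pooled` rows).
#'
#' @inheritParams wake_sleep_summary
#' @return Tibble `channel`, `mode`, `wake_mean`, `sleep_mean`, `dip`,
#'   `dip_sd` (across subjects; `NA` for pooled).
#' @export
wake_sleep_panel <- function(binned, diary, width = 60) {
  per <- wake_sleep_summary(binned, diary, width)
  by_subj <- per |>
    dplyr::filter(.data$complete) |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(mode = "per_subject",
                     dip_sd = stats::sd(.data$dip),
                     wake_mean = mean(.data$wake_mean),
                     sleep_mean = mean(.data$sleep_mean),
                     dip = mean(.data$dip), .groups = "drop") |>
    dplyr::select("channel", "mode", "wake_mean", "sleep_mean", "dip",
                  "dip_sd")
  pooled <- binned |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_modify(function(df, key) {
      dsub <- diary[diary$subject == key$subject, ]
      mid <- df$bin_start + width * 30
      dplyr::mutate(df, asleep = in_sleep(mid, dsub$sleep_start,
                                          dsub$sleep_end))
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(mode = "pooled",
                     wake_mean = mean(.data$value[!.data$asleep]),
                     sleep_mean = mean(.data$value[.data$asleep]),
                     dip = wake_mean - sleep_mean,
                     dip_sd = NA_real_, .groups = "drop")
  dplyr::bind_rows(by_subj, pooled)
}

#' Group means and sds of an omics matrix by epoch or timepoint
#'
#' Aggregates each feature over the 2 epoch groups (morning/evening) or
#' the within-session timepoint groups, on log10-transformed values for
#' metabolome/proteome (offset handling as in [transform_values()]) and on
#' untransformed proportions for microbiome. Groups with fewer than 2
#' samples get `sd = NA` and are flagged.
#'
#' @param x An [omics_matrix()].
#' @param level `"epoch"` or `"timepoint"`.
#' @param transform Apply the kind's display transform first (default TRUE).
#' @return Tibble `feature_id`, `group`, `mean`, `sd`, `n`, `sd_defined`.
#' @export
epoch_aggregate <- function(x, level = c("epoch", "timepoint"),
                            transform = TRUE) {
  stopifnot(inherits(x, "omics_matrix"))
  level <- match.arg(level)
  v <- x$values
  if (transform && x$kind != "microbiome") {
    v <- transform_values(v, "log10_offset")
  }
  grp <- if (level == "epoch") x$sample_meta$epoch else
    sprintf("t%02d", as.integer(x$sample_meta$timepoint_hour))
  purrr::map_dfr(sort(unique(grp)), function(g) {
    rows <- grp == g
    tibble::tibble(
      feature_id = colnames(v),
      group = g,
      mean = colMeans(v[rows, , drop = FALSE]),
      sd = if (sum(rows) >= 2) apply(v[rows, , drop = FALSE], 2, stats::sd)
           else NA_real_,
      n = sum(rows),
      sd_defined = sum(rows) >= 2)
  })
}
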