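#' @importFrom rlang .data
NULL

# Known sensor channels and their fixed units. Count-like channels are
# clipped at zero by the generator and square-root transformed for display
# and cross-channel regression; event channels carry per-interval event
# totals emitted only during wake.
channel_schema <- function() {
  tibble::tribble(
    ~channel,         ~unit,            ~class,
    "activity_axis1", "counts/min",     "count",
    "activity_axis2", "counts/min",     "count",
    "activity_axis3", "counts/min",     "count",
    "activity_vm",    "counts/min",     "count",
    "sbp",            "mmHg",           "continuous",
    "dbp",            "mmHg",           "continuous",
    "map",            "mmHg",           "continuous",
    "pp",             "mmHg",           "continuous",
    "hr",             "bpm",            "continuous",
    "light",          "lux/min",        "count",
    "communication",  "events",         "event",
    "mobility",       "miles",          "event",
    "energy",         "kcal",           "event",
    "protein",        "g",              "event",
    "carbohydrate",   "g",              "event",
    "fat",            "g",              "event",
    "sodium",         "g",              "event"
  )
}

assert_known_channels <- function(channels) {
  unknown <- setdiff(unique(channels), channel_schema()$channel)
  if (length(unknown) > 0) {
    stop("unknown sensor channel(s): ", paste(unknown, collapse = ", "))
  }
}

validate_streams <- function(streams) {
  assert_known_channels(streams$channel)
  neg_classes <- c("count", "event")
  sch <- channel_schema()
  nonneg <- sch$channel[sch$class %in% neg_classes]
  bad <- streams$channel %in% nonneg & streams$value < 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("negative value %.3f for count/event channel %s",
                 streams$value[i], streams$channel[i]))
  }
  dup <- streams |>
    dplyr::group_by(.data$subject, .data$channel) |>
    dplyr::arrange(.data$timestamp, .by_group = TRUE) |>
    dplyr::filter(duplicated(.data$timestamp)) |>
    dplyr::ungroup()
  if (nrow(dup) > 0) {
    stop(sprintf("duplicate timestamp %s in stream (%s, %s)",
                 format(dup$timestamp[1]), dup$subject[1], dup$channel[1]))
  }
  invisible(streams)
}

#' Read a long-format sensor table
#'
#' Expects a delimited file with header `subject, channel, timestamp,
#' value`; timestamps ISO-8601 (read as UTC). Returns one tidy tibble with
#' records sorted within each (subject, channel) stream and units attached
#' from the channel schema. Unknown channels and duplicate timestamps
#' within a stream are rejected.
#'
#' @param path File path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return Tibble `subject`, `channel`, `timestamp` (POSIXct UTC), `value`,
#'   `unit`.
#' @export
read_sensor_table <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, col_types = "ccTd",
                          progress = FALSE)
  need <- c("subject", "channel", "timestamp", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("sensor table missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- df |>
    dplyr::arrange(.data$subject, .data$channel, .data$timestamp)
  validate_streams(df)
  df |> dplyr::left_join(channel_schema()[, c("channel", "unit")],
                         by = "channel")
}

#' Write a long-format sensor table
#' @param streams Tibble with `subject`, `channel`, `timestamp`, `value`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_sensor_table <- function(streams, path, delim = ",") {
  out <- streams[, c("subject", "channel", "timestamp", "value")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read a self-reported sleep diary
#'
#' Columns `subject, sleep_start, sleep_end` (ISO-8601). Intervals must be
#' positive-length and non-overlapping within a subject.
#' @param path File path.
#' @param delim Field delimiter.
#' @return Tibble `subject`, `sleep_start`, `sleep_end` (POSIXct UTC).
#' @export
read_sleep_diary <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, col_types = "cTT",
                          progress = FALSE)
  validate_sleep_diary(df)
}

validate_sleep_diary <- function(df) {
  need <- c("subject", "sleep_start", "sleep_end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("sleep diary missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(df$sleep_end <= df$sleep_start)) {
    stop("sleep interval with sleep_end <= sleep_start")
  }
  df <- df |> dplyr::arrange(.data$subject, .data$sleep_start)
  overlap <- df |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(prev_end = dplyr::lag(.data$sleep_end)) |>
    dplyr::filter(!is.na(.data$prev_end) &
                    .data$sleep_start < .data$prev_end) |>
    dplyr::ungroup()
  if (nrow(overlap) > 0) {
    stop("overlapping sleep intervals for subject ", overlap$subject[1])
  }
  df[, need]
}

#' Write a sleep diary
#' @param diary Tibble `subject`, `sleep_start`, `sleep_end`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_sleep_diary <- function(diary, path, delim = ",") {
  out <- diary[, c("subject", "sleep_start", "sleep_end")]
  out$sleep_start <- format(out$sleep_start, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out$sleep_end <- format(out$sleep_end, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read an omics matrix from a values/metadata CSV pair
#'
#' The values file has `sample_id` as first column and one column per
#' feature; the metadata file has columns `sample_id, subject, session,
#' timepoint_hour, epoch`. Every sample row must be covered by metadata and
#' epoch labels must agree with the design's timepoint mapping.
#'
#' @param values_path,meta_path File paths.
#' @param kind Matrix kind (`"metabolome"`, `"proteome"`, `"microbiome"`).
#' @param delim Field delimiter.
#' @param design Optional `study_design` for epoch validation.
#' @return An [omics_matrix()].
#' @export
read_omics_table <- function(values_path, meta_path,
                             kind = c("metabolome", "proteome", "microbiome"),
                             delim = ",", design = NULL) {
  kind <- match.arg(kind)
  vals <- readr::read_delim(values_path, delim = delim, progress = FALSE,
                            col_types = readr::cols(
                              sample_id = readr::col_character(),
                              .default = readr::col_double()))
  if (names(vals)[1] != "sample_id") {
    stop("omics values file must have sample_id as its first column")
  }
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$sample_id
  meta <- readr::read_delim(meta_path, delim = delim, col_types = "cccdc",
                            progress = FALSE)
  omics_matrix(m, meta, kind = kind, design = design)
}

#' Write an omics matrix to a values/metadata CSV pair
#' @param x An `omics_matrix`.
#' @param values_path,meta_path Output paths.
#' @param delim Field delimiter.
#' @return Named character of the two paths, invisibly.
#' @export
write_omics_table <- function(x, values_path, meta_path, delim = ",") {
  stopifnot(inherits(x, "omics_matrix"))
  vals <- tibble::as_tibble(x$values)
  vals <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(x$values)),
                           vals)
  readr::write_delim(vals, values_path, delim = delim, progress = FALSE)
  readr::write_delim(x$sample_meta, meta_path, delim = delim,
                     progress = FALSE)
  invisible(c(values = values_path, meta = meta_path))
}
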