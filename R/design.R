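#' Study design for a multi-session 12-hourly chronobiome protocol
#'
#' Describes the sampling design shared by all downstream stages: the
#' subjects, the repeated 48-hour sessions, the within-session sampling
#' offsets (hours), and the morning/evening epoch induced by 12-hourly
#' sampling. The reference design has 6 subjects, 2 sessions, and samples
#' at 0, 12, 24, 36 and 48 h, i.e. three morning (0, 24, 48 h) and two
#' evening (12, 36 h) collections per session.
#'
#' @param subjects Character vector of subject identifiers (>= 1).
#' @param sessions Character vector of session identifiers.
#' @param timepoints Numeric vector of hour offsets within a session (>= 2
#'   values).
#' @param session_starts POSIXct start of each session (clock time); used
#'   to convert session offsets to timestamps. Defaults to two sessions two
#'   weeks apart starting at 08:00 UTC.
#'
#' @return An object of class `study_design`.
#' @export
#' @examples
#' d <- study_design()
#' epoch_of(d, c(0, 12, 24, 36, 48))
study_design <- function(subjects = paste0("S", 1:6),
                         sessions = c("A", "B"),
                         timepoints = c(0, 12, 24, 36, 48),
                         session_starts = NULL) {
  stopifnot(length(subjects) >= 1, length(timepoints) >= 2,
            length(sessions) >= 1)
  if (anyDuplicated(subjects)) stop("duplicate subject identifiers")
  if (anyDuplicated(timepoints)) stop("duplicate timepoints")
  if (any(timepoints %% 12 != 0)) {
    stop("timepoints must be multiples of 12 h so each maps to one epoch")
  }
  if (is.null(session_starts)) {
    t0 <- as.POSIXct("2016-03-07 08:00:00", tz = "UTC")
    session_starts <- t0 + (seq_along(sessions) - 1) * 14 * 86400
  }
  stopifnot(length(session_starts) == length(sessions))
  names(session_starts) <- sessions
  structure(
    list(subjects = as.character(subjects),
         sessions = as.character(sessions),
         timepoints = sort(as.numeric(timepoints)),
         session_starts = session_starts),
    class = "study_design"
  )
}

#' Epoch (morning/evening) of a within-session timepoint
#'
#' The 12-hourly grid aliases time of day to a two-level contrast: offsets
#' congruent to 0 modulo 24 h fall in the morning epoch, offsets congruent
#' to 12 h in the evening epoch. In the reference design \{0, 24, 48\} are
#' morning and \{12, 36\} evening. The mapping is a function of the hour
#' offset alone.
#'
#' @param design A `study_design`.
#' @param timepoint_hour Numeric vector of hour offsets.
#' @return Character vector, `"morning"` or `"evening"`.
#' @export
epoch_of <- function(design, timepoint_hour) {
  stopifnot(inherits(design, "study_design"))
  if (!all(timepoint_hour %in% design$timepoints)) {
    stop("timepoint_hour not part of the design: ",
         paste(setdiff(timepoint_hour, design$timepoints), collapse = ", "))
  }
  ifelse(timepoint_hour %% 24 == 0, "morning", "evening")
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", length(x$subjects), "subjects,",
      length(x$sessions), "sessions, timepoints",
      paste(x$timepoints, collapse = "/"), "h\n")
  ep <- epoch_of(x, x$timepoints)
  cat("  epochs:", paste(sprintf("%gh=%s", x$timepoints, ep), collapse = ", "),
      "\n")
  invisible(x)
}

#' Expected sample metadata for a design
#'
#' One row per (subject, session, timepoint) with its epoch label and a
#' `sample_id` of the form `subject_session_tXX`.
#'
#' @param design A `study_design`.
#' @return A tibble with columns `sample_id`, `subject`, `session`,
#'   `timepoint_hour`, `epoch`.
#' @export
design_samples <- function(design) {
  stopifnot(inherits(design, "study_design"))
  grid <- tidyr::expand_grid(subject = design$subjects,
                             session = design$sessions,
                             timepoint_hour = design$timepoints)
  tibble::tibble(
    sample_id = sprintf("%s_%s_t%02d", grid$subject, grid$session,
                        as.integer(grid$timepoint_hour)),
    subject = grid$subject,
    session = grid$session,
    timepoint_hour = grid$timepoint_hour,
    epoch = epoch_of(design, grid$timepoint_hour)
  )
}
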