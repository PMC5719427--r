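#' Omics feature matrix with design metadata
#'
#' Container for a samples x features abundance matrix (plasma/saliva
#' metabolome, serum proteome, or microbiome genus-level relative
#' abundances) aligned 1:1 with per-sample design metadata. Microbiome
#' matrices are compositional: each sample's feature values must sum to 1;
#' values within `1e-6` of 1 are renormalized (sequencing-derived
#' proportions commonly carry rounding error), larger deviations are
#' rejected.
#'
#' @param values Numeric samples x features matrix, non-negative, with
#'   rownames = sample ids and colnames = feature ids.
#' @param sample_meta Tibble/data.frame with columns `sample_id`,
#'   `subject`, `session`, `timepoint_hour`, `epoch`, one row per matrix
#'   row (same order or reorderable by `sample_id`).
#' @param kind `"metabolome"`, `"proteome"` or `"microbiome"`.
#' @param design Optional `study_design` used to validate epoch labels
#'   against the timepoint mapping; defaults to [study_design()] restricted
#'   to the metadata's levels.
#'
#' @return An object of class `omics_matrix`: a list with elements
#'   `values`, `sample_meta`, `kind`.
#' @export
omics_matrix <- function(values, sample_meta,
                         kind = c("metabolome", "proteome", "microbiome"),
                         design = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  if (any(is.na(values))) stop("values contain NA")
  if (any(values < 0)) stop("negative abundance values not allowed")
  if (is.null(rownames(values))) stop("values must carry sample ids as rownames")
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%04d", seq_len(ncol(values)))
  }
  sample_meta <- tibble::as_tibble(sample_meta)
  need <- c("sample_id", "subject", "session", "timepoint_hour", "epoch")
  missing_cols <- setdiff(need, names(sample_meta))
  if (length(missing_cols) > 0) {
    stop("sample_meta missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  missing_ids <- setdiff(rownames(values), sample_meta$sample_id)
  if (length(missing_ids) > 0) {
    stop("sample(s) in values missing from metadata: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  sample_meta <- sample_meta[match(rownames(values), sample_meta$sample_id), ]

  if (is.null(design)) {
    design <- study_design(subjects = unique(sample_meta$subject),
                           sessions = unique(sample_meta$session),
                           timepoints = unique(sample_meta$timepoint_hour))
  }
  expected <- epoch_of(design, sample_meta$timepoint_hour)
  bad <- which(sample_meta$epoch != expected)
  if (length(bad) > 0) {
    stop(sprintf(
      "epoch label '%s' contradicts timepoint %g h (expected '%s') for sample %s",
      sample_meta$epoch[bad[1]], sample_meta$timepoint_hour[bad[1]],
      expected[bad[1]], sample_meta$sample_id[bad[1]]))
  }

  if (kind == "microbiome") {
    rs <- rowSums(values)
    off <- which(abs(rs - 1) > 1e-6)
    if (length(off) > 0) {
      stop(sprintf(
        "microbiome sample %s sums to %.6f, outside tolerance 1e-6 of 1",
        rownames(values)[off[1]], rs[off[1]]))
    }
    values <- values / rs
  }

  structure(list(values = values, sample_meta = sample_meta, kind = kind),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix (%s): %d samples x %d features\n", x$kind,
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  subjects: %d  sessions: %d  timepoints: %s h\n",
              length(unique(x$sample_meta$subject)),
              length(unique(x$sample_meta$session)),
              paste(sort(unique(x$sample_meta$timepoint_hour)),
                    collapse = "/")))
  invisible(x)
}

#' Planted rhythmic-feature ground truth of a generated matrix, if any
#' @param x An `omics_matrix`.
#' @return Tibble (`feature_id`, `is_rhythmic`, `planted_beta`) or `NULL`.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")
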