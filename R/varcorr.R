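#' Pairwise variance-correlation matrix across sensor channels
#'
#' For every unordered pair of channels aligned on a shared bin grid, a
#' simple linear regression of one on the other over bins where both are
#' present; its R-squared equals the squared Pearson correlation (so the
#' matrix is symmetric by construction) and its goodness-of-fit F-test
#' p-value informs significance, Bonferroni-corrected by the number of
#' pairs actually tested. Count/event channels are square-root
#' transformed first by default, matching display conventions. Channels
#' with zero variance have their pairs reported but flagged untested.
#' Because corrected p-values underflow in long recordings, `log10_p_raw`
#' is reported alongside.
#'
#' @param binned Output of [bin_stream()] covering several channels on
#'   one grid.
#' @param pool `"pooled"` (default: all subjects' bins concatenated;
#'   subject/bin pairs are the regression observations) or
#'   `"per_subject"` (one matrix per subject).
#' @param transform Square-root transform count/event channels.
#' @param min_obs Minimum complete paired observations (default 3).
#' @return Long-format tibble: `subject` (`"all"` when pooled), `var_a`,
#'   `var_b`, `n_obs`, `r2`, `p_raw`, `log10_p_raw`, `p_bonferroni`,
#'   `tested`, `n_pairs_tested`. Includes the diagonal (`r2 = 1`).
#' @export
variance_correlation <- function(binned, pool = c("pooled", "per_subject"),
                                 transform = TRUE, min_obs = 3) {
  pool <- match.arg(pool)
  sch <- channel_schema()
  df <- binned |>
    dplyr::mutate(
      .cls = sch$class[match(.data$channel, sch$channel)],
      value = ifelse(transform & .data$.cls %in% c("count", "event"),
                     sqrt(pmax(.data$value, 0)), .data$value))
  groups <- if (pool == "pooled") list(all = df) else
    split(df, df$subject)
  purrr::imap_dfr(groups, function(g, label) {
    wide <- g |>
      dplyr::select("subject", "channel", "bin_start", "value") |>
      tidyr::pivot_wider(names_from = "channel", values_from = "value")
    chans <- setdiff(names(wide), c("subject", "bin_start"))
    prs <- c(lapply(chans, function(ch) c(ch, ch)),
             utils::combn(chans, 2, simplify = FALSE))
    rows <- purrr::map_dfr(prs, function(pr) {
      a <- wide[[pr[1]]]; b <- wide[[pr[2]]]
      ok <- !is.na(a) & !is.na(b)
      a <- a[ok]; b <- b[ok]
      base <- tibble::tibble(subject = label, var_a = pr[1],
                             var_b = pr[2], n_obs = length(a))
      diag_pair <- pr[1] == pr[2]
      if (length(a) < min_obs || stats::sd(a) == 0 || stats::sd(b) == 0) {
        return(dplyr::mutate(base, r2 = if (diag_pair) 1 else NA_real_,
                             p_raw = NA_real_, log10_p_raw = NA_real_,
                             tested = FALSE))
      }
      if (diag_pair) {
        return(dplyr::mutate(base, r2 = 1, p_raw = NA_real_,
                             log10_p_raw = NA_real_, tested = FALSE))
      }
      ct <- stats::cor.test(a, b)
      lp <- log10_pearson_p(unname(ct$estimate), length(a))
      dplyr::mutate(base, r2 = unname(ct$estimate)^2, p_raw = ct$p.value,
                    log10_p_raw = lp, tested = TRUE)
    })
    n_tested <- sum(rows$tested)
    dplyr::mutate(rows,
                  p_bonferroni = ifelse(.data$tested,
                                        pmin(1, .data$p_raw * n_tested),
                                        NA_real_),
                  n_pairs_tested = n_tested)
  })
}

# log10 of the two-sided Pearson p-value via the t reference
# distribution on the log scale, stable when p underflows.
log10_pearson_p <- function(r, n) {
  if (abs(r) >= 1) return(-Inf)
  tstat <- abs(r) * sqrt((n - 2) / (1 - r^2))
  (stats::pt(tstat, df = n - 2, lower.tail = FALSE, log.p = TRUE) +
      log(2)) / log(10)
}

#' Square matrix view of a variance-correlation table
#'
#' @param vc Output of [variance_correlation()] for one subject/pool.
#' @param what Column to spread (`"r2"` by default).
#' @return Symmetric numeric matrix, channels in alphabetical order.
#' @export
varcorr_matrix <- function(vc, what = "r2") {
  chans <- sort(unique(c(vc$var_a, vc$var_b)))
  m <- matrix(NA_real_, length(chans), length(chans),
              dimnames = list(chans, chans))
  for (i in seq_len(nrow(vc))) {
    m[vc$var_a[i], vc$var_b[i]] <- vc[[what]][i]
    m[vc$var_b[i], vc$var_a[i]] <- vc[[what]][i]
  }
  m
}
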