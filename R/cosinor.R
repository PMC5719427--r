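#' Single-component cosinor fit
#'
#' Fits `y(t) = M + A * cos(2*pi*(t - phi)/tau)` by least squares through
#' the standard linear reparameterization `y = M + b*cos(w t) + g*sin(w t)`
#' with `w = 2*pi/tau`, so `A = sqrt(b^2 + g^2)` and `phi = atan2(g, b)/w`
#' reduced to `[0, tau)`. The mesor M is the rhythm-adjusted mean, the
#' amplitude A half the peak-to-trough range, and the acrophase phi the
#' clock time of the fitted peak. The zero-amplitude test is the F-test of
#' `(b, g)` jointly zero against the intercept-only model.
#'
#' @param t Numeric times in hours (clock or elapsed; phi is reported on
#'   the same clock modulo `period`).
#' @param y Numeric response, same length as `t`.
#' @param period Fixed period tau in hours (default 24; the 48-h design
#'   cannot resolve period, so it is never estimated).
#' @return Tibble with one row: `mesor`, `amplitude`, `acrophase`,
#'   `period`, `resid_sd`, `r_squared`, `p_zero_amplitude`, `n`.
#' @export
#' @examples
#' t <- seq(0, 47)
#' y <- 10 + 2 * cos(2 * pi * (t - 8) / 24)
#' fit_cosinor(t, y)
fit_cosinor <- function(t, y, period = 24) {
  keep <- !is.na(t) & !is.na(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 4 || length(unique(t)) < 4) {
    stop("cosinor fit needs >= 4 distinct time points")
  }
  if (diff(range(t)) <= period / 2) {
    stop("time points must span more than half a period")
  }
  w <- 2 * pi / period
  cw <- cos(w * t); sw <- sin(w * t)
  # All timestamps congruent modulo tau/2 collapse cos/sin to +-1 scalings
  # of each other: the design matrix is rank deficient.
  X <- cbind(1, cw, sw)
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sum(sv > max(sv) * 1e-9) < 3) {
    stop("degenerate cosinor design: timestamps congruent modulo period/2")
  }
  fit <- stats::lm(y ~ cw + sw)
  co <- stats::coef(fit)
  A <- sqrt(co[["cw"]]^2 + co[["sw"]]^2)
  phi <- (atan2(co[["sw"]], co[["cw"]]) / w) %% period
  null_fit <- stats::lm(y ~ 1)
  an <- stats::anova(null_fit, fit)
  p_amp <- an[["Pr(>F)"]][2]
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  tibble::tibble(
    mesor = co[["(Intercept)"]],
    amplitude = A,
    acrophase = phi,
    period = period,
    resid_sd = sqrt(rss / stats::df.residual(fit)),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    p_zero_amplitude = if (tss > 0) p_amp else NA_real_,
    n = length(y))
}

#' Cosinor fits per subject, channel and 24-h window
#'
#' Splits each subject/channel binned series into consecutive windows
#' (default one fit per 24 h, the unit on which circadian amplitude and
#' phase are compared across channels) and fits a fixed-period cosinor to
#' each. Windows with too few points or a degenerate design are skipped.
#' Count channels are square-root transformed first when
#' `transform = TRUE`, matching display conventions.
#'
#' @param binned Output of [bin_stream()].
#' @param window_h Window length in hours (default 24).
#' @param period Cosinor period (h).
#' @param transform Square-root transform count/event channels first.
#' @return Tibble: `subject`, `channel`, `window_start`, cosinor fit
#'   columns.
#' @export
cosinor_by_window <- function(binned, window_h = 24, period = 24,
                              transform = TRUE) {
  sch <- channel_schema()
  binned |>
    dplyr::mutate(
      .t = as.numeric(.data$bin_start) / 3600,
      .win = floor(.t / window_h) * window_h,
      .cls = sch$class[match(.data$channel, sch$channel)],
      .v = ifelse(transform & .data$.cls %in% c("count", "event"),
                  sqrt(pmax(.data$value, 0)), .data$value)) |>
    dplyr::group_by(.data$subject, .data$channel, .data$.win) |>
    dplyr::group_modify(function(df, key) {
      out <- tryCatch(fit_cosinor(df$.t, df$.v, period = period),
                      error = function(e) NULL)
      if (is.null(out)) tibble::tibble() else out
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(window_start = ".win")
}

# Jammalamadaka-SenGupta circular-circular correlation with its
# asymptotic test. Inputs in radians.
circular_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  am <- atan2(mean(sin(a)), mean(cos(a)))
  bm <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - am); sb <- sin(b - bm)
  r <- sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
  n <- length(a)
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  if (l22 > 0) {
    z <- sqrt(n * l20 * l02 / l22) * r
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    p <- NA_real_
  }
  list(r = r, p_value = p)
}

#' Cross-channel correlation of circadian amplitude or phase
#'
#' Pairs channels on matching (subject, window) cosinor fits. For
#' `measure = "amplitude"` the squared Pearson correlation is reported as
#' a percent (R^2) with the regression p-value; for `measure = "phase"`
#' acrophases are mapped to angles and the Jammalamadaka-SenGupta
#' circular-circular correlation coefficient is used, with the mean
#' circular phase offset (h) reported. P-values are Bonferroni-corrected
#' over the number of channel pairs actually tested. Pairs with fewer
#' than `min_pairs` observations, or a zero-variance amplitude vector,
#' are skipped and flagged.
#'
#' @param fits Output of [cosinor_by_window()].
#' @param measure `"amplitude"` or `"phase"`.
#' @param min_pairs Minimum paired fits per channel pair (default 3).
#' @param period Period (h) used for the phase-to-angle mapping.
#' @return Tibble: `channel_a`, `channel_b`, `measure`, `n`, `r`,
#'   `r2_percent`, `offset_h` (phase only), `p_raw`, `p_bonferroni`,
#'   `tested`.
#' @export
amplitude_phase_correlation <- function(fits,
                                        measure = c("amplitude", "phase"),
                                        min_pairs = 3, period = 24) {
  measure <- match.arg(measure)
  val_col <- if (measure == "amplitude") "amplitude" else "acrophase"
  wide <- fits |>
    dplyr::select("subject", "channel", "window_start",
                  value = dplyr::all_of(val_col)) |>
    tidyr::pivot_wider(names_from = "channel", values_from = "value")
  chans <- setdiff(names(wide), c("subject", "window_start"))
  pairs <- utils::combn(chans, 2, simplify = FALSE)

  rows <- purrr::map_dfr(pairs, function(pr) {
    a <- wide[[pr[1]]]; b <- wide[[pr[2]]]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    base <- tibble::tibble(channel_a = pr[1], channel_b = pr[2],
                           measure = measure, n = length(a))
    if (length(a) < min_pairs) {
      return(dplyr::mutate(base, r = NA_real_, r2_percent = NA_real_,
                           offset_h = NA_real_, p_raw = NA_real_,
                           tested = FALSE))
    }
    if (measure == "amplitude") {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        return(dplyr::mutate(base, r = NA_real_, r2_percent = NA_real_,
                             offset_h = NA_real_, p_raw = NA_real_,
                             tested = FALSE))
      }
      ct <- stats::cor.test(a, b)
      dplyr::mutate(base, r = unname(ct$estimate),
                    r2_percent = 100 * unname(ct$estimate)^2,
                    offset_h = NA_real_, p_raw = ct$p.value, tested = TRUE)
    } else {
      w <- 2 * pi / period
      cc <- circular_correlation(a * w, b * w)
      d <- (b - a) * w
      off <- (atan2(mean(sin(d)), mean(cos(d))) / w) %% period
      if (off > period / 2) off <- off - period
      dplyr::mutate(base, r = cc$r, r2_percent = 100 * cc$r^2,
                    offset_h = off, p_raw = cc$p_value, tested = TRUE)
    }
  })
  n_tested <- sum(rows$tested)
  rows |>
    dplyr::mutate(p_bonferroni = ifelse(.data$tested,
                                        pmin(1, .data$p_raw * n_tested),
                                        NA_real_),
                  n_pairs_tested = n_tested)
}
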