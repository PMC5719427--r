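#' Display/analysis transforms for non-negative measurements
#'
#' Count-like sensor channels (accelerometer counts, lux, communication
#' events) are conventionally displayed and regressed on the square-root
#' scale; omics abundances on the log10 scale. Both transforms are
#' order-preserving on non-negative input. For `log10_offset` an offset
#' `delta > 0` handles zeros; the conventional default is half the smallest
#' positive value present.
#'
#' @param x Numeric vector or matrix, all values >= 0.
#' @param mode `"sqrt"` or `"log10_offset"`.
#' @param delta Positive offset added before log10; defaults to half the
#'   smallest positive value of `x` (1 if `x` is all zero).
#' @return Transformed values, same shape as `x`.
#' @export
#' @examples
#' transform_values(c(1, 4, 9), "sqrt")
#' transform_values(99, "log10_offset", delta = 1)
transform_values <- function(x, mode = c("sqrt", "log10_offset"),
                             delta = NULL) {
  mode <- match.arg(mode)
  if (any(x < 0, na.rm = TRUE)) {
    stop("transform_values: negative input not allowed (min = ",
         min(x, na.rm = TRUE), ")")
  }
  if (mode == "sqrt") return(sqrt(x))
  if (is.null(delta)) delta <- default_log_offset(x)
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0) {
    stop("log10_offset requires a single offset delta > 0")
  }
  log10(x + delta)
}

# Half the smallest positive value; 1 when no positive values exist.
default_log_offset <- function(x) {
  pos <- x[!is.na(x) & x > 0]
  if (length(pos) == 0) return(1)
  min(pos) / 2
}
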