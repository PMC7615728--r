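#' Robust standard deviation scores
#'
#' Centers by the median and scales by 1.4826 times the median absolute
#' deviation (the MAD rescaled to be a consistent estimate of the standard
#' deviation under normality).
#'
#' @param x Numeric vector (length at least 2, non-constant majority).
#' @return Vector of robust SDS scores; the score at the median is 0.
#' @examples
#' robust_sds(c(1, 2, 3, 4, 5))
#' @export
robust_sds <- function(x) {
  if (length(x) < 2) stop("robust_sds: need at least 2 values")
  s <- stats::mad(x, constant = 1.4826)
  if (s == 0) stop("robust_sds: MAD is zero (constant-majority data)")
  (x - stats::median(x)) / s
}

#' Flag scores outside a symmetric interval
#'
#' @param scores Robust SDS scores.
#' @param limit Threshold; cells with `|score| > limit` are flagged (strict,
#'   so a score exactly at the limit is not flagged). Default 2.
#' @return Logical flags.
#' @export
sds_flags <- function(scores, limit = 2) {
  if (any(!is.finite(scores))) stop("sds_flags: scores must be finite")
  abs(scores) > limit
}

#' Tukey boxplot fences
#'
#' First and third quartiles are computed by linear interpolation of the
#' empirical CDF (`quantile()` type 7); the fences sit 1.5 IQR beyond them.
#'
#' @param x Numeric vector of length at least 4.
#' @return An object of class `boxplot_fences` with elements `q1`, `q3`,
#'   `iqr`, `lower`, `upper`.
#' @export
boxplot_fences <- function(x) {
  if (length(x) < 4) stop("boxplot_fences: need at least 4 values")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr,
                 lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr),
            class = "boxplot_fences")
}

#' Flag values outside the boxplot fences
#'
#' @param x Numeric vector.
#' @param fences A [boxplot_fences()] object (computed from `x` if omitted).
#' @return Logical flags; values strictly outside `[lower, upper]`.
#' @export
boxplot_flags <- function(x, fences = boxplot_fences(x)) {
  x < fences$lower | x > fences$upper
}
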