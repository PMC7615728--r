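#' Define an error pattern
#'
#' Four patterns of height errors are supported, mimicking plausible
#' data-entry and measurement failures:
#' \describe{
#'   \item{skip_last_digit}{the final digit of the recorded height is
#'     dropped (e.g. 176 becomes 17), as when a digit fails to register;}
#'   \item{swap_last_digits}{the last two digits are transposed (163
#'     becomes 136), a classic transcription error;}
#'   \item{add_shift}{a constant number of centimetres (default 40) is
#'     added, as under unit confusion or instrument mis-calibration;}
#'   \item{sample_first_percentile}{the height is replaced by a draw from a
#'     normal distribution truncated above at the age/sex-specific first
#'     percentile — an extreme but individually plausible short stature.}
#' }
#'
#' @param name One of `"skip_last_digit"`, `"swap_last_digits"`,
#'   `"add_shift"`, `"sample_first_percentile"`.
#' @param shift_cm Shift in cm, used by `add_shift` only; must be positive.
#' @return An object of class `error_pattern`.
#' @export
error_pattern <- function(name = c("skip_last_digit", "swap_last_digits",
                                   "add_shift", "sample_first_percentile"),
                          shift_cm = 40) {
  name <- match.arg(name)
  if (name == "add_shift" && (!is.finite(shift_cm) || shift_cm <= 0)) {
    stop("error_pattern: shift_cm must be positive")
  }
  structure(list(name = name, shift_cm = shift_cm), class = "error_pattern")
}

#' Select the cells to contaminate
#'
#' Draws exactly `round(prevalence * n)` record indices uniformly without
#' replacement (ties at .5 round up).
#'
#' @param n Number of records.
#' @param prevalence Error prevalence in (0, 1).
#' @param seed Optional integer seed.
#' @return Logical vector of length `n`; `TRUE` marks a cell selected for
#'   contamination.
#' @export
select_error_cells <- function(n, prevalence, seed = NULL) {
  if (prevalence <= 0 || prevalence >= 1) {
    stop("select_error_cells: prevalence must lie in (0, 1)")
  }
  k <- floor(prevalence * n + 0.5)
  if (k < 1) stop("select_error_cells: prevalence * n rounds to zero cells")
  if (!is.null(seed)) set.seed(seed)
  mask <- rep(FALSE, n)
  mask[sample.int(n, k)] <- TRUE
  mask
}

#' @rdname height_errors
#' @export
skip_last_digit <- function(h) {
  if (any(h != round(h)) || any(h < 10)) {
    stop("skip_last_digit: heights must be whole cm >= 10")
  }
  h %/% 10
}

#' Elementary height-corruption rules
#'
#' `skip_last_digit` removes the final decimal digit (integer division by
#' 10); `swap_last_digits` exchanges the last two decimal digits;
#' `add_shift` adds a constant. All act on heights recorded in whole cm.
#'
#' @param h Height(s) in whole cm (at least 10 for the digit operations).
#' @param shift_cm Positive shift in cm.
#' @return Corrupted height(s).
#' @name height_errors
#' @export
swap_last_digits <- function(h) {
  if (any(h != round(h)) || any(h < 10)) {
    stop("swap_last_digits: heights must be whole cm >= 10")
  }
  d <- h %% 100
  h - d + (d %% 10) * 10 + d %/% 10
}

#' @rdname height_errors
#' @export
add_shift <- function(h, shift_cm = 40) {
  if (!is.finite(shift_cm) || shift_cm <= 0) {
    stop("add_shift: shift_cm must be positive")
  }
  h + shift_cm
}

#' Draw heights from below the age-specific first percentile
#'
#' Draws from a Normal(mean = M, sd = M*S) distribution truncated above at
#' the first percentile `P1` of the record's age/sex LMS distribution,
#' using the inverse-CDF method, and rounds to whole cm. The untruncated
#' (M, M*S) normal is the natural approximation to the LMS distribution at
#' that age.
#'
#' @param entry A one-row data frame (or list) with `L`, `M`, `S` for the
#'   record's age/sex group; vectors are accepted for vectorized use.
#' @param seed Optional integer seed.
#' @return Height(s) in whole cm, never above `P1`.
#' @export
sample_first_percentile <- function(entry, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- entry$L; M <- entry$M; S <- entry$S
  p1 <- lms_quantile(L, M, S, 0.01)
  mu <- M
  sigma <- M * S
  u <- stats::runif(length(mu))
  h <- mu + sigma * stats::qnorm(u * stats::pnorm((p1 - mu) / sigma))
  pmin(round(h), floor(p1))
}

#' Contaminate height cells of a simulated cohort
#'
#' Applies one error pattern to a randomly selected fraction of height
#' cells and returns both the contaminated table and the ground-truth mask.
#' All cells not selected by the mask — and all non-height columns — are
#' left bit-identical. For the `swap_last_digits` pattern, records whose
#' last two digits are equal are still counted as errors in the mask even
#' though the value is unchanged: the corruption was applied, it just
#' happens to be invisible.
#'
#' @param table A cohort from [simulate_growth()].
#' @param pattern An [error_pattern()].
#' @param prevalence Fraction of height cells to corrupt, in (0, 1).
#' @param seed Optional integer seed (drives both cell selection and, for
#'   `sample_first_percentile`, the replacement draws).
#' @param stature_table LMS table used by `sample_first_percentile` to find
#'   each record's age/sex parameters; ignored by the other patterns.
#' @return A list with elements `table` (contaminated cohort) and `mask`
#'   (logical ground-truth error indicator per height cell).
#' @export
contaminate <- function(table, pattern, prevalence, seed = NULL,
                        stature_table = NULL) {
  if (!nrow(table)) stop("contaminate: empty table")
  if (!inherits(pattern, "error_pattern")) pattern <- error_pattern(pattern)
  if (!is.null(seed)) set.seed(seed)
  mask <- select_error_cells(nrow(table), prevalence)
  h <- table$height_cm[mask]
  new_h <- switch(pattern$name,
    skip_last_digit = skip_last_digit(h),
    swap_last_digits = swap_last_digits(h),
    add_shift = add_shift(h, pattern$shift_cm),
    sample_first_percentile = {
      if (is.null(stature_table)) {
        stop("contaminate: sample_first_percentile needs a stature_table")
      }
      key <- paste(table$sex[mask], table$age_months[mask])
      i <- match(key, paste(stature_table$sex, stature_table$age_months))
      if (anyNA(i)) stop("contaminate: record age/sex missing from stature_table")
      sample_first_percentile(stature_table[i, , drop = FALSE])
    })
  table$height_cm[mask] <- new_h
  list(table = table, mask = mask)
}
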