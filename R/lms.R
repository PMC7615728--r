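#' Evaluate the LMS (Box-Cox) growth model at a standard-normal deviate
#'
#' The LMS parameterization describes an age- and sex-specific measurement
#' distribution by three parameters: the Box-Cox power `L`, the median `M`,
#' and the generalized coefficient of variation `S`. A measurement at
#' standard-normal deviate `Z` is `M * (1 + L*S*Z)^(1/L)`; for `L = 0` the
#' limiting form `M * exp(S*Z)` applies.
#'
#' @param L Box-Cox power (recycled against the other arguments).
#' @param M Median of the measure; must be positive.
#' @param S Generalized coefficient of variation; must be positive.
#' @param Z Standard-normal deviate(s).
#' @return Numeric vector of measurement values, strictly increasing in `Z`.
#' @examples
#' lms_value(L = -0.5, M = 150, S = 0.05, Z = 1)
#' lms_value(L = 0, M = 150, S = 0.05, Z = 1)  # log-normal limit
#' @export
lms_value <- function(L, M, S, Z) {
  n <- max(length(L), length(M), length(S), length(Z))
  L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n); Z <- rep_len(Z, n)
  if (any(M <= 0)) stop("lms_value: M must be positive")
  if (any(S <= 0)) stop("lms_value: S must be positive")
  out <- numeric(n)
  zero <- L == 0
  out[zero] <- M[zero] * exp(S[zero] * Z[zero])
  if (any(!zero)) {
    base <- 1 + L[!zero] * S[!zero] * Z[!zero]
    if (any(base <= 0)) {
      stop("lms_value: 1 + L*S*Z <= 0; deviate implausible for these parameters")
    }
    out[!zero] <- M[!zero] * base^(1 / L[!zero])
  }
  out
}

#' Quantile of the LMS distribution
#'
#' @inheritParams lms_value
#' @param p Probability in (0, 1).
#' @return The `p`-quantile of the LMS distribution, i.e. [lms_value()] at
#'   `Z = qnorm(p)`.
#' @export
lms_quantile <- function(L, M, S, p) {
  if (any(p <= 0 | p >= 1)) stop("lms_quantile: p must lie in (0, 1)")
  lms_value(L, M, S, stats::qnorm(p))
}

new_lms_table <- function(df, measure) {
  df <- df[order(df$sex, df$age_months), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, measure = measure, class = c("lms_table", "data.frame"))
}

validate_lms_table <- function(df, what = "LMS table") {
  required <- c("sex", "age_months", "L", "M", "S")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(what, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(df$M) | df$M <= 0 | !is.finite(df$S) | df$S <= 0 |
                 !is.finite(df$L) | !is.finite(df$age_months) | df$age_months <= 0)
  if (length(bad)) {
    stop(what, ": invalid L/M/S or age in row(s) ", paste(bad, collapse = ", "))
  }
  for (s in unique(df$sex)) {
    a <- df$age_months[df$sex == s]
    if (any(diff(sort(a)) == 0)) stop(what, ": duplicated ages for sex ", s)
  }
  invisible(df)
}

#' Read an LMS parameter table from a CDC-style CSV file
#'
#' Understands the dialect of the CDC 2000 growth-chart percentile data
#' files: a header row, sex coded 1 = male / 2 = female, an `Agemos` column,
#' and `L`, `M`, `S` columns (any additional percentile columns are
#' ignored). Only rows with age of 24 months or more are retained, matching
#' the 2-20 year charts.
#'
#' @param path Path to a CSV file.
#' @param measure Either `"stature"` or `"weight"`; stored as an attribute.
#' @return An `lms_table`: a data frame with columns `sex` (factor
#'   male/female), `age_months`, `L`, `M`, `S`, ordered by sex then age.
#' @export
load_lms_table <- function(path, measure = c("stature", "weight")) {
  measure <- match.arg(measure)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(raw))
  pick <- function(candidates, label) {
    i <- which(nm %in% candidates)[1]
    if (is.na(i)) stop("load_lms_table: no ", label, " column in ", path)
    raw[[i]]
  }
  sex_raw <- pick(c("sex"), "sex")
  age <- suppressWarnings(as.numeric(pick(c("agemos", "age_months", "age"), "age")))
  L <- suppressWarnings(as.numeric(pick("l", "L")))
  M <- suppressWarnings(as.numeric(pick("m", "M")))
  S <- suppressWarnings(as.numeric(pick("s", "S")))
  sex <- ifelse(sex_raw %in% c(1, "1", "male", "m", "M"), "male",
                ifelse(sex_raw %in% c(2, "2", "female", "f", "F"), "female", NA))
  if (anyNA(sex)) {
    stop("load_lms_table: unrecognized sex code in row(s) ",
         paste(which(is.na(sex)), collapse = ", "))
  }
  df <- data.frame(sex = factor(sex, levels = c("male", "female")),
                   age_months = age, L = L, M = M, S = S)
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) {
    stop("load_lms_table: malformed row(s) ", paste(bad, collapse = ", "))
  }
  validate_lms_table(df, what = paste0("load_lms_table(", path, ")"))
  df <- df[df$age_months >= 24, , drop = FALSE]
  if (!nrow(df)) stop("load_lms_table: no rows with age >= 24 months")
  new_lms_table(df, measure)
}

# Anchor medians (cm / kg) for the builtin fallback parameterization.
# Values are plausible paediatric medians chosen to track published growth
# references; they are synthetic stand-ins, not chart values.
.builtin_anchors <- function(measure) {
  ages <- seq(24, 240, by = 12)
  if (measure == "stature") {
    list(ages = ages,
         male = c(86.9, 95.3, 102.9, 109.2, 115.7, 122.0, 128.1, 133.7,
                  138.8, 143.7, 149.3, 156.4, 163.8, 170.1, 173.9, 175.5,
                  176.2, 176.5, 176.8),
         female = c(85.4, 94.2, 101.6, 108.4, 115.1, 121.7, 127.8, 133.3,
                    138.6, 144.7, 151.2, 157.0, 160.4, 161.8, 162.5, 162.9,
                    163.1, 163.2, 163.3),
         S = 0.042)
  } else {
    list(ages = ages,
         male = c(12.7, 14.3, 16.3, 18.4, 20.7, 23.1, 25.8, 28.7, 32.1,
                  36.0, 40.6, 45.8, 51.2, 56.3, 60.6, 64.0, 66.6, 68.6,
                  70.6),
         female = c(12.1, 13.9, 15.9, 17.9, 20.2, 22.8, 25.8, 29.2, 33.1,
                    37.4, 41.8, 45.9, 49.4, 52.0, 53.9, 55.1, 56.2, 57.0,
                    57.9),
         S = 0.18)
  }
}

#' Built-in fallback LMS table
#'
#' A smooth synthetic stand-in for a downloadable growth-chart file, so the
#' whole pipeline runs without any external data. The Box-Cox power is fixed
#' at `L = 1` (normal within each age/sex group), the median is
#' piecewise-linear in age between yearly anchor values per sex, and `S` is
#' constant per measure (0.042 for stature, 0.18 for weight). Ages run
#' monthly from 24 to 240 months for both sexes. The values approximate
#' typical paediatric growth but are not chart values.
#'
#' @inheritParams load_lms_table
#' @return An `lms_table` (see [load_lms_table()]).
#' @examples
#' tab <- builtin_lms_table("stature")
#' range(tab$age_months)
#' @export
builtin_lms_table <- function(measure = c("stature", "weight")) {
  measure <- match.arg(measure)
  a <- .builtin_anchors(measure)
  ages <- 24:240
  df <- do.call(rbind, lapply(c("male", "female"), function(s) {
    data.frame(sex = s, age_months = ages,
               L = 1,
               M = stats::approx(a$ages, a[[s]], xout = ages)$y,
               S = a$S)
  }))
  df$sex <- factor(df$sex, levels = c("male", "female"))
  new_lms_table(df, measure)
}

#' Simulate a growth cohort from LMS tables
#'
#' Records are allocated as evenly as possible across all (age, sex) groups
#' in the stature table (any remainder is assigned round-robin in sex/age
#' sort order, so the allocation does not depend on the seed). Within each
#' group one standard-normal deviate per record and per measure is drawn
#' independently; height follows the stature LMS model and is rounded to
#' whole centimetres, weight follows the weight LMS model and is kept
#' continuous, with its natural logarithm stored alongside.
#'
#' @param n Number of records to generate.
#' @param stature_table,weight_table `lms_table` objects covering the same
#'   (sex, age) groups.
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame with columns `id`, `age_months`, `sex`, `height_cm`
#'   (integer cm), `weight_kg`, `log_weight`.
#' @examples
#' tab_h <- builtin_lms_table("stature")
#' tab_w <- builtin_lms_table("weight")
#' cohort <- simulate_growth(1000, tab_h, tab_w, seed = 1)
#' summary(cohort$height_cm)
#' @export
simulate_growth <- function(n, stature_table, weight_table, seed = NULL) {
  stopifnot(n > 0)
  if (!nrow(stature_table) || !nrow(weight_table)) {
    stop("simulate_growth: empty LMS table")
  }
  if (!setequal(unique(stature_table$sex), unique(weight_table$sex))) {
    stop("simulate_growth: stature and weight tables cover different sexes")
  }
  groups <- stature_table[order(stature_table$sex, stature_table$age_months), ]
  g <- nrow(groups)
  base <- n %/% g
  counts <- rep(base, g)
  rem <- n - base * g
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  idx <- rep(seq_len(g), counts)

  key <- function(tab) paste(tab$sex, tab$age_months)
  w <- weight_table[match(key(groups), key(weight_table)), , drop = FALSE]
  if (anyNA(w$M)) {
    stop("simulate_growth: weight table lacks some (sex, age) groups of the stature table")
  }

  if (!is.null(seed)) set.seed(seed)
  z_h <- stats::rnorm(n)
  z_w <- stats::rnorm(n)
  height <- round(lms_value(groups$L[idx], groups$M[idx], groups$S[idx], z_h))
  weight <- lms_value(w$L[idx], w$M[idx], w$S[idx], z_w)
  data.frame(id = seq_len(n),
             age_months = groups$age_months[idx],
             sex = groups$sex[idx],
             height_cm = height,
             weight_kg = weight,
             log_weight = log(weight))
}
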