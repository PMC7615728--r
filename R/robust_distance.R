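new_location_scatter <- function(center, scatter, method, h = NULL,
                                 objective = NULL) {
  structure(list(center = center, scatter = scatter, method = method,
                 h = h, objective = objective),
            class = "location_scatter")
}

.log_det <- function(m) {
  d <- determinant(m, logarithm = TRUE)
  if (d$sign <= 0) return(-Inf)
  as.numeric(d$modulus)
}

#' Classical location and scatter
#'
#' Sample mean and sample covariance (denominator n - 1).
#'
#' @param X Numeric matrix (n x p, n > p, full column rank).
#' @return A `location_scatter` object with `method = "classic"`.
#' @export
classic_estimates <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop("classic_estimates: need n > p")
  S <- stats::cov(X)
  if (!is.finite(.log_det(S))) stop("classic_estimates: singular covariance")
  new_location_scatter(colMeans(X), S, "classic")
}

# Draw a (p+1)-row starting subset, growing it until its covariance is
# nonsingular (the usual FastMCD degeneracy handling).
.seed_subset <- function(X, n, p) {
  J <- sample.int(n, p + 1)
  repeat {
    S <- stats::cov(X[J, , drop = FALSE])
    if (is.finite(.log_det(S))) {
      return(list(center = colMeans(X[J, , drop = FALSE]), cov = S))
    }
    if (length(J) == n) return(NULL)
    J <- c(J, sample.int(n, 1))  # may repeat; harmless for seeding
    J <- unique(J)
  }
}

#' Minimum covariance determinant (MCD) location and scatter
#'
#' FastMCD-style stochastic search: random (p+1)-point starting subsets,
#' two concentration steps (C-steps) each, then full C-step iteration to
#' convergence for the most promising candidates. A C-step replaces the
#' current h-subset by the h observations with the smallest Mahalanobis
#' distances under the current estimates; it never increases the
#' determinant. The returned scatter is the covariance of the best
#' h-subset rescaled by the standard small-h consistency factor
#' `(h/n) / P(chi^2_{p+2} <= q)` with `q` the `h/n` quantile of
#' `chi^2_p`, so it estimates the full-population covariance under
#' normality.
#'
#' @param X Numeric matrix (n x p).
#' @param h Subset size; defaults to `floor((n + p + 1) / 2)`. Must lie in
#'   `[floor(n/2) + 1, n]`.
#' @param n_trials Number of random starting subsets (default 500).
#' @param seed Optional integer seed.
#' @return A `location_scatter` with `method = "mcd"`; `objective` is the
#'   log-determinant of the (unscaled) best-subset covariance.
#' @export
mcd_estimates <- function(X, h = NULL, n_trials = 500, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(h)) h <- floor((n + p + 1) / 2)
  if (h < floor(n / 2) + 1 || h > n) stop("mcd_estimates: h out of range")
  if (!is.null(seed)) set.seed(seed)

  cstep <- function(center, cov_) {
    d2 <- tryCatch(stats::mahalanobis(X, center, cov_),
                   error = function(e) NULL)  # numerically singular subset
    if (is.null(d2)) return(NULL)
    idx <- order(d2)[seq_len(h)]
    sub <- X[idx, , drop = FALSE]
    list(center = colMeans(sub), cov = stats::cov(sub))
  }

  run_steps <- function(cand, max_steps) {
    obj <- .log_det(cand$cov)
    for (i in seq_len(max_steps)) {
      if (!is.finite(obj)) break
      nxt <- cstep(cand$center, cand$cov)
      if (is.null(nxt)) { obj <- Inf; break }
      obj_next <- .log_det(nxt$cov)
      if (!is.finite(obj_next)) { cand <- nxt; obj <- obj_next; break }
      done <- obj - obj_next < 1e-9
      cand <- nxt
      obj <- obj_next
      if (done) break
    }
    cand$objective <- obj
    cand
  }

  short <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    st <- .seed_subset(X, n, p)
    if (is.null(st)) next
    short[[t]] <- run_steps(st, 2)
  }
  short <- Filter(function(s) !is.null(s) && is.finite(s$objective), short)
  if (!length(short)) stop("mcd_estimates: all starting subsets singular")
  objs <- vapply(short, `[[`, numeric(1), "objective")
  keep <- order(objs)[seq_len(min(10, length(short)))]
  best <- NULL
  for (i in keep) {
    cand <- run_steps(short[[i]], 100)
    if (is.null(best) || cand$objective < best$objective) best <- cand
  }
  if (!is.finite(best$objective)) {
    stop("mcd_estimates: best subset singular (exact-fit situation)")
  }
  alpha <- h / n
  cons <- alpha / stats::pchisq(stats::qchisq(alpha, p), p + 2)
  new_location_scatter(best$center, best$cov * cons, "mcd", h = h,
                       objective = best$objective)
}

#' Minimum volume ellipsoid (MVE) location and scatter
#'
#' Stochastic search over random (p+1)-point subsets: each subset's mean
#' and covariance define an ellipsoid shape, which is inflated just enough
#' to cover h observations; the candidate minimizing the resulting
#' ellipsoid volume wins. The covering scatter is then divided by the
#' chi-square median `qchisq(0.5, p)` so that, under normality, it is a
#' consistent estimate of the covariance matrix.
#'
#' @inheritParams mcd_estimates
#' @return A `location_scatter` with `method = "mve"`; `objective` is the
#'   log squared-volume (up to a constant): `p*log(m2) + log det(C)` with
#'   `m2` the h-th smallest squared distance under the subset shape `C`.
#' @export
mve_estimates <- function(X, h = NULL, n_trials = 500, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(h)) h <- floor((n + p + 1) / 2)
  if (h < floor(n / 2) + 1 || h > n) stop("mve_estimates: h out of range")
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (t in seq_len(n_trials)) {
    st <- .seed_subset(X, n, p)
    if (is.null(st)) next
    ld <- .log_det(st$cov)
    if (!is.finite(ld)) next
    d2 <- tryCatch(stats::mahalanobis(X, st$center, st$cov),
                   error = function(e) NULL)  # numerically singular subset
    if (is.null(d2)) next
    m2 <- sort(d2, partial = h)[h]
    if (m2 <= 0) next
    obj <- p * log(m2) + ld
    if (is.null(best) || obj < best$objective) {
      best <- list(center = st$center, cov = st$cov * m2, objective = obj)
    }
  }
  if (is.null(best)) stop("mve_estimates: all starting subsets singular")
  new_location_scatter(best$center, best$cov / stats::qchisq(0.5, p), "mve",
                       h = h, objective = best$objective)
}

#' Squared Mahalanobis distances
#'
#' @param X Numeric matrix (n x p).
#' @param est A `location_scatter` object.
#' @return Vector of squared distances
#'   `(x - center)' scatter^{-1} (x - center)`.
#' @export
mahalanobis_sq <- function(X, est) {
  stopifnot(inherits(est, "location_scatter"))
  if (!is.finite(.log_det(est$scatter))) {
    stop("mahalanobis_sq: scatter is not positive definite")
  }
  stats::mahalanobis(as.matrix(X), est$center, est$scatter)
}

#' Chi-square flagging of squared distances
#'
#' Under multivariate normality, squared Mahalanobis distances follow a
#' chi-square distribution with p degrees of freedom; observations are
#' flagged when their squared distance strictly exceeds the `tolProb`
#' quantile (about 11.345 for 3 df at 0.99).
#'
#' @param d2 Vector of squared distances.
#' @param df Degrees of freedom (number of variables), default 3.
#' @param tolProb Tolerance probability, default 0.99.
#' @return A `distance_result` list: `d2`, `threshold`, `flags`.
#' @export
distance_flags <- function(d2, df = 3, tolProb = 0.99) {
  if (any(d2 < 0)) stop("distance_flags: d2 must be non-negative")
  thr <- stats::qchisq(tolProb, df)
  structure(list(d2 = d2, threshold = thr, flags = d2 > thr),
            class = "distance_result")
}
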