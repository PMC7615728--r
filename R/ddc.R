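#' Parameters of the cellwise detector
#'
#' @param corrlim Minimum absolute robust correlation for a variable to
#'   contribute to another variable's cell predictions (default 0.5).
#'   Variables with no connection are treated as standalone.
#' @param tolProb Tolerance probability driving every flagging cutoff
#'   (default 0.99). The univariate cutoff is
#'   `c = sqrt(qchisq(tolProb, 1))`, about 2.576 at 0.99.
#' @return A `ddc_params` list with elements `corrlim`, `tolProb`, `c`.
#' @export
ddc_params <- function(corrlim = 0.5, tolProb = 0.99) {
  stopifnot(corrlim > 0, corrlim < 1, tolProb > 0, tolProb < 1)
  structure(list(corrlim = corrlim, tolProb = tolProb,
                 c = sqrt(stats::qchisq(tolProb, 1))),
            class = "ddc_params")
}

#' Robust column standardization with trimming
#'
#' Each column is centered at its median and scaled by 1.4826 times its
#' MAD. Cells with `|z| > c` are set aside (NA in `z_trim`) so that the
#' later correlation and slope estimates are not driven by marginal
#' outliers.
#'
#' @param X Numeric matrix, at least two columns, each with positive MAD.
#' @param params A [ddc_params()] object.
#' @return List with `z` (full standardized matrix), `z_trim` (outlying
#'   cells NA), `center`, `scale`.
#' @export
ddc_standardize <- function(X, params = ddc_params()) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("ddc_standardize: need at least 2 columns")
  center <- apply(X, 2, stats::median)
  scale <- apply(X, 2, stats::mad, constant = 1.4826)
  if (any(scale == 0)) stop("ddc_standardize: zero-MAD column")
  z <- sweep(sweep(X, 2, center), 2, scale, `/`)
  z_trim <- z
  z_trim[abs(z) > params$c] <- NA
  list(z = z, z_trim = z_trim, center = center, scale = scale)
}

#' Robust pairwise correlations and connected variable sets
#'
#' Product-moment correlation computed on the trimmed standardized matrix,
#' pairwise over rows where neither cell was set aside (robustness comes
#' from the univariate trimming). Pairs with fewer than 3 complete rows
#' get correlation 0. Variable k is "connected" to j when
#' `|r_jk| >= corrlim`.
#'
#' @param std Output of [ddc_standardize()].
#' @param params A [ddc_params()] object.
#' @return List with `corr` (symmetric p x p matrix, unit diagonal) and
#'   `connected` (per-column integer vector of connected columns).
#' @export
ddc_correlations <- function(std, params = ddc_params()) {
  zt <- std$z_trim
  p <- ncol(zt)
  R <- diag(1, p)
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) {
      ok <- !is.na(zt[, j]) & !is.na(zt[, k])
      r <- if (sum(ok) < 3) 0 else stats::cor(zt[ok, j], zt[ok, k])
      if (!is.finite(r)) r <- 0
      R[j, k] <- R[k, j] <- r
    }
  }
  connected <- lapply(seq_len(p), function(j) {
    setdiff(which(abs(R[, j]) >= params$corrlim), j)
  })
  dimnames(R) <- list(colnames(zt), colnames(zt))
  list(corr = R, connected = connected)
}

#' Predict each standardized cell from its connected columns
#'
#' For each connected pair (j, k) a robust slope `b_jk` is the median of
#' the ratios `z_ij / z_ik` over rows where both cells survived trimming
#' and `|z_ik|` is non-negligible. The raw prediction of cell (i, j) is
#' the `|r_jk|`-weighted mean of `b_jk * z_ik` over available connected
#' columns. Because medians of ratios shrink predictions, each column's
#' raw predictions are de-shrunk by the median ratio of observed on
#' predicted. Standalone columns (no connection) are predicted as 0 — the
#' column median in data units — as are rows with no usable predictor;
#' the attached `has_info` attribute records which cells had at least one
#' usable predictor, so flagging can fall back to the univariate z-score
#' for the rest.
#'
#' @param std Output of [ddc_standardize()].
#' @param corr Output of [ddc_correlations()].
#' @param params A [ddc_params()] object.
#' @return Matrix of predicted standardized values (finite everywhere),
#'   with a logical attribute `has_info` of the same shape.
#' @export
ddc_predict <- function(std, corr, params = ddc_params()) {
  z <- std$z
  zt <- std$z_trim
  n <- nrow(z)
  p <- ncol(z)
  pred <- matrix(0, n, p, dimnames = dimnames(z))
  has_info <- matrix(FALSE, n, p)
  for (j in seq_len(p)) {
    H <- corr$connected[[j]]
    if (!length(H)) next  # standalone: predicted 0
    num <- matrix(0, n, length(H))
    ok <- matrix(FALSE, n, length(H))
    w <- abs(corr$corr[H, j])
    for (m in seq_along(H)) {
      k <- H[m]
      use <- !is.na(zt[, j]) & !is.na(zt[, k]) & abs(zt[, k]) > 1e-6
      b <- if (any(use)) stats::median(zt[use, j] / zt[use, k]) else 0
      avail <- !is.na(zt[, k])
      num[avail, m] <- b * zt[avail, k]
      ok[, m] <- avail
    }
    wmat <- matrix(w, n, length(H), byrow = TRUE) * ok
    wsum <- rowSums(wmat)
    raw <- ifelse(wsum > 0, rowSums(num * wmat) / pmax(wsum, 1e-12), 0)
    usable <- !is.na(zt[, j]) & abs(raw) > 1e-6
    a <- if (any(usable)) stats::median(zt[usable, j] / raw[usable]) else 1
    if (!is.finite(a)) a <- 1
    pred[, j] <- a * raw
    has_info[, j] <- wsum > 0
  }
  attr(pred, "has_info") <- has_info
  pred
}

#' Standardized cell residuals and cellwise flags
#'
#' Residuals (observed minus predicted standardized value) are robustly
#' standardized per column — centered at their median and scaled by 1.4826
#' times their MAD — over the cells that had at least one usable predictor
#' (the scale is floored at a small epsilon so that an exact linear
#' dependence still yields flags for corrupted cells). Cells without any
#' usable predictor — standalone columns, or rows whose connected cells
#' were all set aside — fall back to the univariate criterion: their
#' standardized residual is the cell's own z-score. Cells with
#' `|standardized residual| > c` are flagged.
#'
#' @param std Output of [ddc_standardize()].
#' @param predicted Output of [ddc_predict()].
#' @param params A [ddc_params()] object.
#' @return List with `residual` (standardized residual matrix) and
#'   `cell_flags` (logical matrix).
#' @export
ddc_flag_cells <- function(std, predicted, params = ddc_params()) {
  has_info <- attr(predicted, "has_info")
  if (is.null(has_info)) has_info <- matrix(TRUE, nrow(std$z), ncol(std$z))
  r <- std$z - predicted
  ctr <- vapply(seq_len(ncol(r)), function(j) {
    if (!any(has_info[, j])) return(0)
    stats::median(r[has_info[, j], j])
  }, numeric(1))
  s <- vapply(seq_len(ncol(r)), function(j) {
    if (!any(has_info[, j])) return(1)
    stats::mad(r[has_info[, j], j], center = ctr[j], constant = 1.4826)
  }, numeric(1))
  s <- pmax(s, 1e-8)
  stdres <- sweep(sweep(r, 2, ctr), 2, s, `/`)
  stdres[!has_info] <- std$z[!has_info]
  dimnames(stdres) <- dimnames(std$z)
  list(residual = stdres, cell_flags = abs(stdres) > params$c)
}

#' Rowwise aggregation of cell anomalies
#'
#' The row statistic is the mean over columns of the chi-square(1) CDF of
#' the squared standardized cell residual; it grows with both the number
#' and the magnitude of anomalous cells in the row. Rows are flagged when
#' the robustly standardized statistic exceeds `c`.
#'
#' @param residual Standardized residual matrix from [ddc_flag_cells()].
#' @param params A [ddc_params()] object.
#' @return List with `row_stat` and logical `row_flags`.
#' @export
ddc_flag_rows <- function(residual, params = ddc_params()) {
  T_i <- rowMeans(stats::pchisq(residual^2, df = 1))
  s <- stats::mad(T_i, constant = 1.4826)
  s <- max(s, 1e-8)
  zT <- (T_i - stats::median(T_i)) / s
  list(row_stat = T_i, row_flags = zT > params$c)
}

#' Cellwise outlier detection (DetectDeviatingCells)
#'
#' Runs the full deterministic pipeline: robust standardization with
#' trimming, robust pairwise correlations, prediction of every cell from
#' its correlated columns, cellwise flagging of large standardized
#' residuals, and rowwise flagging of records whose accumulated cell
#' anomalies are large. Predicted values are also returned in data units
#' (the conditional-expectation output that makes the method usable for
#' single imputation, not evaluated here).
#'
#' @param X Numeric matrix or data frame of continuous variables (p >= 2).
#' @param params A [ddc_params()] object.
#' @return Object of class `ddc_result`: `z`, `corr`, `connected`,
#'   `predicted_z`, `predicted` (data units), `residual` (standardized),
#'   `cell_flags`, `row_stat`, `row_flags`, `params`, `center`, `scale`.
#' @examples
#' x <- cbind(a = rnorm(200), b = rnorm(200))
#' x[, "b"] <- 2 * x[, "a"]
#' x[5, "b"] <- 25
#' fit <- ddc_fit(x)
#' which(fit$cell_flags[, "b"])
#' @export
ddc_fit <- function(X, params = ddc_params()) {
  X <- as.matrix(X)
  std <- ddc_standardize(X, params)
  corr <- ddc_correlations(std, params)
  pred_z <- ddc_predict(std, corr, params)
  cells <- ddc_flag_cells(std, pred_z, params)
  rows <- ddc_flag_rows(cells$residual, params)
  predicted <- sweep(sweep(`attr<-`(pred_z, "has_info", NULL), 2,
                           std$scale, `*`), 2, std$center, `+`)
  structure(list(z = std$z, corr = corr$corr, connected = corr$connected,
                 predicted_z = pred_z, predicted = predicted,
                 residual = cells$residual, cell_flags = cells$cell_flags,
                 row_stat = rows$row_stat, row_flags = rows$row_flags,
                 params = params, center = std$center, scale = std$scale),
            class = "ddc_result")
}
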