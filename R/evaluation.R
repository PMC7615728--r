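#' Cross-tabulate detector flags against the ground-truth mask
#'
#' @param flags Logical flags emitted by a detector, one per height cell.
#' @param truth Logical ground-truth error mask of the same length.
#' @return A `confusion_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(flags, truth) {
  if (length(flags) != length(truth)) stop("confusion: length mismatch")
  flags <- as.logical(flags)
  truth <- as.logical(truth)
  structure(list(tp = sum(flags & truth), fp = sum(flags & !truth),
                 fn = sum(!flags & truth), tn = sum(!flags & !truth)),
            class = "confusion_counts")
}

.cp_interval <- function(x, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(stats::binom.test(x, n)$conf.int)
}

#' Detection performance metrics with 95% confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, positive predictive
#' value `tp/(tp+fp)` and positive likelihood ratio `Se/(1-Sp)`.
#' Proportions carry Clopper-Pearson exact intervals; the likelihood
#' ratio carries a log-method interval. A likelihood ratio with `fp = 0`
#' is reported as `Inf`; PPV with no flagged cells is reported missing.
#'
#' @param counts A [confusion()] result.
#' @return Data frame with columns `metric`, `estimate`, `ci_low`,
#'   `ci_high` (proportions on the 0-1 scale).
#' @export
binary_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (tp + fn == 0 || fp + tn == 0) {
    stop("binary_metrics: need both true-error and clean cells")
  }
  se <- tp / (tp + fn)
  sp <- tn / (fp + tn)
  se_ci <- .cp_interval(tp, tp + fn)
  sp_ci <- .cp_interval(tn, fp + tn)
  if (tp + fp > 0) {
    ppv <- tp / (tp + fp)
    ppv_ci <- .cp_interval(tp, tp + fp)
  } else {
    ppv <- NA_real_
    ppv_ci <- c(NA_real_, NA_real_)
  }
  if (fp == 0) {
    lr <- if (tp > 0) Inf else NA_real_
    lr_ci <- c(NA_real_, Inf)
  } else if (tp == 0) {
    lr <- 0
    lr_ci <- c(0, NA_real_)
  } else {
    lr <- se / (1 - sp)
    se_log <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
    lr_ci <- exp(log(lr) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  }
  data.frame(metric = c("sensitivity", "specificity", "ppv", "lr_plus"),
             estimate = c(se, sp, ppv, lr),
             ci_low = c(se_ci[1], sp_ci[1], ppv_ci[1], lr_ci[1]),
             ci_high = c(se_ci[2], sp_ci[2], ppv_ci[2], lr_ci[2]))
}

#' ROC curve, AUC with DeLong interval, and Youden-index cutoff
#'
#' Builds the empirical ROC over all distinct score thresholds (higher
#' scores indicate errors), with AUC equal to the Mann-Whitney statistic
#' (ties counted 1/2) and a 95% DeLong confidence interval. The Youden
#' index `J = Se + Sp - 1` is maximized over the curve; when two cutoffs
#' tie, the one with the higher specificity is reported.
#'
#' @param scores Finite numeric scores, one per height cell.
#' @param truth Logical ground-truth error mask.
#' @return A `roc_summary` list: `points` (data frame `threshold`, `fpr`,
#'   `tpr`), `auc`, `auc_ci`, `youden_j`, `youden_cutoff`, `youden_se`,
#'   `youden_sp`.
#' @export
roc_summary <- function(scores, truth) {
  truth <- as.logical(truth)
  if (any(!is.finite(scores))) stop("roc_summary: scores must be finite")
  if (!any(truth) || all(truth)) stop("roc_summary: need both classes")
  r <- pROC::roc(response = truth, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  pts <- data.frame(threshold = r$thresholds,
                    fpr = 1 - r$specificities,
                    tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  j <- pts$tpr + (1 - pts$fpr) - 1
  sel <- which(j == max(j))
  if (length(sel) > 1) sel <- sel[which.min(pts$fpr[sel])]
  structure(list(points = pts, auc = auc, auc_ci = c(ci[1], ci[3]),
                 youden_j = max(j), youden_cutoff = pts$threshold[sel],
                 youden_se = pts$tpr[sel], youden_sp = 1 - pts$fpr[sel]),
            class = "roc_summary")
}
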