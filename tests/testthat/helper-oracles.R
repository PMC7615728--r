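# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations.

# Halfspace depth by direct enumeration of directions: the count can only
# change at directions orthogonal to a (query, cloud-point) line, so scan
# those plus tiny rotations either side of each.
depth_oracle <- function(point, cloud) {
  cloud <- as.matrix(cloud)
  dd <- sweep(cloud, 2, point)
  coinc <- dd[, 1] == 0 & dd[, 2] == 0
  rest <- dd[!coinc, , drop = FALSE]
  if (!nrow(rest)) return(sum(coinc))
  ang <- atan2(rest[, 2], rest[, 1])
  cand <- c(ang + pi / 2, ang - pi / 2)
  cand <- c(cand, cand + 1e-7, cand - 1e-7)
  best <- Inf
  for (a in cand) {
    u <- c(cos(a), sin(a))
    best <- min(best, sum(rest %*% u >= -1e-12))
  }
  sum(coinc) + best
}

# Mann-Whitney AUC by exhaustive pair counting (ties count one half).
auc_oracle <- function(scores, truth) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Best Youden index by sweeping every threshold between observed scores.
youden_oracle <- function(scores, truth) {
  truth <- as.logical(truth)
  s <- sort(unique(scores))
  cuts <- c(-Inf, (s[-1] + s[-length(s)]) / 2, s, Inf)
  best <- -Inf
  for (t in cuts) {
    flags <- scores > t
    se <- sum(flags & truth) / sum(truth)
    sp <- sum(!flags & !truth) / sum(!truth)
    best <- max(best, se + sp - 1)
  }
  best
}

# A tiny two-sex LMS table for fast tests (normal within groups).
toy_lms_table <- function(ages = c(24, 120, 240), measure = "stature") {
  M <- if (measure == "stature") c(86, 139, 170) else c(13, 32, 64)
  df <- do.call(rbind, lapply(c("male", "female"), function(s) {
    data.frame(sex = s, age_months = ages, L = 1,
               M = M[seq_along(ages)] + if (s == "male") 1 else 0,
               S = if (measure == "stature") 0.042 else 0.18)
  }))
  df$sex <- factor(df$sex, levels = c("male", "female"))
  structure(df[order(df$sex, df$age_months), ],
            measure = measure, class = c("lms_table", "data.frame"))
}
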