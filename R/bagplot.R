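#' Tukey halfspace depth of a point in the plane
#'
#' The halfspace (Tukey) depth of a query point relative to a cloud is the
#' smallest number of cloud points contained in any closed halfplane whose
#' boundary passes through the query. Computed exactly by sorting the
#' angles of the cloud points around the query and scanning all halfplane
#' boundary directions at which the count can change (each data angle, its
#' antipode, and the midpoints between consecutive critical directions).
#'
#' @param point Numeric length-2 vector (x, y).
#' @param cloud Two-column matrix or data frame of cloud points.
#' @return Integer depth in `[0, nrow(cloud)]`.
#' @export
halfspace_depth <- function(point, cloud) {
  cloud <- as.matrix(cloud)
  stopifnot(ncol(cloud) == 2, nrow(cloud) >= 1)
  dx <- cloud[, 1] - point[1]
  dy <- cloud[, 2] - point[2]
  coincident <- dx == 0 & dy == 0
  t0 <- sum(coincident)
  m <- sum(!coincident)
  if (m == 0) return(t0)
  ang <- atan2(dy[!coincident], dx[!coincident])
  e <- sort(ang)
  wrap <- function(a) ((a + pi) %% (2 * pi)) - pi  # to (-pi, pi]
  crit <- sort(unique(c(e, wrap(e + pi))))
  mids <- (crit + c(crit[-1], crit[1] + 2 * pi)) / 2
  b <- c(crit, wrap(mids))
  E <- c(e, e + 2 * pi)
  eps <- 1e-9
  lo <- findInterval(b - eps, E)
  hi <- findInterval(b + pi + eps, E)
  t0 + min(hi - lo)
}

# Depth of every row of xy with respect to the full cloud; duplicates are
# computed once (heights and ages are discrete, so cohorts repeat points).
.depth_all <- function(xy) {
  key <- paste(xy[, 1], xy[, 2])
  uniq <- !duplicated(key)
  d_u <- vapply(which(uniq), function(i) halfspace_depth(xy[i, ], xy), numeric(1))
  d_u[match(key, key[uniq])]
}

#' Build a bagplot (bivariate boxplot)
#'
#' The "bag" is the convex hull of the deepest half of the points: the
#' depth threshold is the smallest depth such that at most half the points
#' are at least that deep (quasi-concavity of halfspace depth guarantees
#' the hull contains no shallower points). The "fence" inflates the bag by
#' `inflation` (default 3) about the depth median — the average of the
#' points attaining maximal depth. Points outside the fence are outliers.
#'
#' @param xy Two-column matrix or data frame of at least 10 non-collinear
#'   points.
#' @param inflation Fence inflation factor (default 3).
#' @return An object of class `bagplot` with elements `depth_median`,
#'   `bag` (polygon vertex matrix), `fence` (polygon vertex matrix),
#'   `inflation`, and `depths`.
#' @export
build_bagplot <- function(xy, inflation = 3) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  stopifnot(ncol(xy) == 2, n >= 10)
  sv <- svd(scale(xy, scale = FALSE))$d
  if (sv[2] <= 1e-10 * sv[1]) stop("build_bagplot: data are (nearly) collinear")
  depths <- .depth_all(xy)

  levels <- sort(unique(depths))
  cnt <- vapply(levels, function(d) sum(depths >= d), numeric(1))
  ok <- which(cnt <= floor(n / 2) & cnt >= 3)
  if (!length(ok)) ok <- which(cnt <= ceiling(n / 2) & cnt >= 3)
  if (!length(ok)) ok <- length(levels)  # tiny/tied clouds: deepest level
  dstar <- levels[ok[1]]
  deep <- xy[depths >= dstar, , drop = FALSE]
  hull <- grDevices::chull(deep)
  if (length(hull) < 3) stop("build_bagplot: degenerate bag geometry")
  bag <- deep[hull, , drop = FALSE]

  dm <- colMeans(xy[depths == max(depths), , drop = FALSE])
  fence <- sweep(sweep(bag, 2, dm), 2, rep(inflation, 2), `*`)
  fence <- sweep(fence, 2, dm, `+`)
  structure(list(depth_median = dm, bag = bag, fence = fence,
                 inflation = inflation, depths = depths),
            class = "bagplot")
}

# Convex polygon membership (boundary counts as inside).
.in_convex <- function(pts, poly) {
  pts <- as.matrix(pts)
  k <- nrow(poly)
  scale_eps <- 1e-9 * max(abs(poly), 1)
  pos <- rep(FALSE, nrow(pts))
  neg <- rep(FALSE, nrow(pts))
  for (i in seq_len(k)) {
    a <- poly[i, ]
    b <- poly[if (i == k) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    pos <- pos | cr > scale_eps
    neg <- neg | cr < -scale_eps
  }
  !(pos & neg)
}

#' Flag points outside the bagplot fence
#'
#' @param xy Two-column matrix of points to classify.
#' @param bag A [build_bagplot()] object.
#' @return Logical flags; `TRUE` for points strictly outside the fence
#'   (points on the fence boundary are not flagged).
#' @export
bagplot_flags <- function(xy, bag) {
  stopifnot(inherits(bag, "bagplot"))
  !.in_convex(as.matrix(xy), bag$fence)
}
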