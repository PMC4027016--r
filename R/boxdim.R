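## Box-counting (Minkowski) dimension of a 1-D sampled curve.
##
## The sampled sequence is normalized into the unit square, the square
## is covered with dyadic grids of side s, the number N(s) of cells
## intersected by the polyline through the samples is counted, and the
## dimension is the least-squares slope of log N(s) against log(1/s).
##
## Counting convention: cells are half-open [a, a+s) x [b, b+s) with
## the closing edges at 1 included, and the set counted is the set of
## points actually attained by the polyline.  Per grid column the
## attained amplitudes form an interval whose endpoints are sample
## values or column-boundary crossing values; a crossing value at the
## right (open) column edge is approached but not attained inside the
## column, which only matters when it lands exactly on a horizontal
## grid line (handled explicitly below so that e.g. a grid-aligned
## diagonal occupies exactly 1/s cells).

#' Normalize a sequence into the unit square
#'
#' Applies peak normalization `x / max(abs(x))` followed by the affine
#' map to `[0, 1]`; time is mapped to `[0, 1]` with equal spacing.
#'
#' @param x Numeric sequence, length `>= 2`, not all zero.
#' @return A list with components `t` and `v`, both in `[0, 1]`.
#' @examples
#' normalizeUnitSquare(c(-2, 0, 2))
#' @export
normalizeUnitSquare <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(x))) stop("samples must be finite")
  peak <- max(abs(x))
  if (peak == 0) stop("all-zero sequence: peak normalization undefined")
  list(
    t = seq.int(0L, length(x) - 1L) / (length(x) - 1L),
    v = (x / peak + 1) / 2
  )
}

## index range of the samples falling in each of m half-open columns
.colRanges <- function(L, m) {
  colStart <- ceiling((0:(m - 1)) * (L - 1) / m - 1e-9) + 1L
  colStart[1L] <- 1L
  list(start = colStart, end = c(colStart[-1L] - 1L, L))
}

## per-column extremes of the sample values (+-Inf for empty columns)
.colExtremes <- function(v, ranges) {
  m <- length(ranges$start)
  mn <- rep(Inf, m)
  mx <- rep(-Inf, m)
  for (j in seq_len(m)) {
    a <- ranges$start[j]
    b <- ranges$end[j]
    if (a <= b) {
      sl <- v[a:b]
      mn[j] <- min(sl)
      mx[j] <- max(sl)
    }
  }
  list(mn = mn, mx = mx)
}

## polyline values at the m-1 interior column boundaries
.boundaryCrossings <- function(v, m) {
  L <- length(v)
  if (m < 2L) return(numeric(0))
  tb <- (1:(m - 1)) / m
  i0 <- base::pmin(base::pmax(floor(tb * (L - 1)), 0), L - 2)
  frac <- tb * (L - 1) - i0
  v[i0 + 1L] * (1 - frac) + v[i0 + 2L] * frac
}

## total cells touched, given per-column sample extremes and boundary
## crossings at this scale.  A right-boundary crossing is approached
## but not attained inside its column; when it is the strict supremum
## and lies exactly on a horizontal grid line the top cell is excluded.
.countAtScale <- function(mn, mx, cross, m) {
  s <- 1 / m
  rightNA <- c(cross, -Inf)
  lo <- base::pmin(mn, c(Inf, cross), c(cross, Inf))
  hiAtt <- base::pmax(mx, c(-Inf, cross))
  top <- floor(hiAtt / s)
  open <- which(rightNA > hiAtt)
  if (length(open)) {
    r <- rightNA[open] / s
    rr <- round(r)
    onGrid <- abs(r - rr) < 1e-9
    top[open] <- floor(r)
    top[open][onGrid] <- rr[onGrid] - 1
  }
  top <- base::pmin(top, m - 1)
  bottom <- base::pmin(floor(lo / s), m - 1)
  as.integer(sum(top - bottom + 1))
}

## covering counts at scales 2^-1 .. 2^-M in one pass over the data
.dyadicCounts <- function(v, M) {
  L <- length(v)
  mF <- 2^M
  ext <- .colExtremes(v, .colRanges(L, mF))
  crossF <- .boundaryCrossings(v, mF)
  counts <- integer(M)
  mn <- ext$mn
  mx <- ext$mx
  for (k in seq.int(M, 1L)) {
    m <- 2^k
    stride <- mF %/% m
    cross <- if (m > 1L) crossF[(1:(m - 1)) * stride] else numeric(0)
    counts[k] <- .countAtScale(mn, mx, cross, m)
    odd <- seq.int(1L, m, by = 2L)
    mn <- base::pmin(mn[odd], mn[odd + 1L])
    mx <- base::pmax(mx[odd], mx[odd + 1L])
  }
  counts
}

## slope-only estimator used in feature extraction loops (no S4)
.boxDimFast <- function(x, maxScaleExp = 8L) {
  peak <- max(abs(x))
  if (peak == 0) stop("all-zero sequence: peak normalization undefined")
  M <- min(floor(log2(length(x))), maxScaleExp)
  counts <- .dyadicCounts((x / peak + 1) / 2, M)
  xs <- seq_len(M) * log(2)
  y <- log(counts)
  (sum(y) * sum(xs) - M * sum(y * xs)) / (sum(xs)^2 - M * sum(xs^2))
}

#' Count occupied grid cells at one scale
#'
#' Number of cells of a dyadic grid of side `s` intersected by the
#' polyline joining consecutive points of a unit-square-normalized
#' curve.
#'
#' @param curve A curve from [normalizeUnitSquare()] (list with `t`,
#'   `v`).
#' @param s Box side; `1/s` must be an integer and `1/s <= length`.
#' @param interpolation `"polyline"` (default) counts cells crossed by
#'   the linearly interpolated curve; `"points"` counts only cells
#'   containing sample points.
#' @return Integer cell count.
#' @examples
#' boxCount(normalizeUnitSquare(rep(c(-1, 1), 32)), 1 / 4)
#' @export
boxCount <- function(curve, s, interpolation = c("polyline", "points")) {
  interpolation <- match.arg(interpolation)
  t <- curve$t
  v <- curve$v
  L <- length(v)
  m <- round(1 / s)
  if (abs(1 / s - m) > 1e-9) stop("1/s must be an integer (dyadic grid)")
  if (s <= 0 || s > 1) stop("scale must lie in (0, 1]")
  if (m > L) stop("scale finer than the sampling density (1/s > length)")

  if (interpolation == "points") {
    col <- base::pmin(floor(t / s), m - 1)
    row <- base::pmin(floor(v / s), m - 1)
    return(length(unique(col * m + row)))
  }

  ext <- .colExtremes(v, .colRanges(L, m))
  .countAtScale(ext$mn, ext$mx, .boundaryCrossings(v, m), m)
}

#' Covering counts over a sequence of scales
#'
#' @param curve A normalized curve (see [normalizeUnitSquare()]).
#' @param scales Decreasing dyadic box sides; by default
#'   `2^-(1:M)` with `M = min(floor(log2(L)), maxScaleExp)`.
#' @param maxScaleExp Cap on the number of dyadic scales (default 8,
#'   i.e. finest grid 1/256).
#' @param interpolation Passed to [boxCount()].
#' @return A [BoxCountCurve].
#' @export
countOverScales <- function(curve, scales = NULL, maxScaleExp = 8L,
                            interpolation = "polyline") {
  L <- length(curve$v)
  if (is.null(scales)) {
    M <- min(floor(log2(L)), maxScaleExp)
    scales <- 2^-(seq_len(M))
  }
  if (length(scales) < 4L)
    stop("need at least 4 admissible scales (sequence too short)")

  ks <- log2(1 / scales)
  dyadicChain <- all(abs(ks - round(ks)) < 1e-9) &&
    interpolation == "polyline"
  if (!dyadicChain) {
    counts <- vapply(scales, function(s)
      boxCount(curve, s, interpolation), integer(1))
    return(BoxCountCurve(scales = as.numeric(scales), counts = counts))
  }

  ## power-of-two grids nest, so per-column sample extremes are
  ## computed once at the finest grid and merged pairwise upward;
  ## boundary crossings at a coarse grid are a stride of the finest
  ## grid's crossings
  ks <- as.integer(round(ks))
  if (2^max(ks) > L) stop("finest scale exceeds the sampling density")
  counts <- .dyadicCounts(curve$v, max(ks))
  BoxCountCurve(scales = as.numeric(scales), counts = counts[ks])
}

#' Least-squares box-dimension fit
#'
#' Fits the line `y = k x + b` through
#' `(x_i, y_i) = (log(1/s_i), log N(s_i))` by the closed-form
#' least-squares slope
#' `k = ((sum y)(sum x) - M sum xy) / ((sum x)^2 - M sum x^2)`;
#' `k` is the box dimension estimate.  Natural logarithms are used
#' (the slope is base-invariant; the intercept is reported for the
#' natural log).
#'
#' @param bcc A [BoxCountCurve].
#' @return A [DimensionFit].
#' @export
fitBoxDimension <- function(bcc) {
  x <- log(1 / bcc@scales)
  y <- log(as.numeric(bcc@counts))
  M <- length(x)
  if (M < 2L) stop("need at least 2 scales")
  if (var(x) == 0) stop("zero variance in log(1/s)")
  slope <- (sum(y) * sum(x) - M * sum(y * x)) /
    (sum(x)^2 - M * sum(x^2))
  intercept <- mean(y) - slope * mean(x)
  ss <- sum((y - mean(y))^2)
  r2 <- if (ss > 0) 1 - sum((y - intercept - slope * x)^2) / ss else 1
  DimensionFit(slope = slope, intercept = intercept, rSquared = r2,
               points = cbind(x = x, y = y))
}

#' Box-counting fractal dimension of a sequence
#'
#' Composition of [normalizeUnitSquare()], [countOverScales()] and
#' [fitBoxDimension()]: the standard estimator applied to a sampled
#' amplitude sequence.  For bounded discrete signals the estimate lies
#' in `[1, 2]` (1 for smooth curves, approaching 2 for noise-like
#' ones).
#'
#' @param x Numeric sequence, length `>= 16`.
#' @param scales,maxScaleExp,interpolation Passed to
#'   [countOverScales()].
#' @param fit If `FALSE`, return the full [DimensionFit] instead of
#'   just the slope.
#' @return The fitted dimension (numeric scalar), or a [DimensionFit]
#'   when `fit = FALSE`.
#' @examples
#' boxDimension(seq(0, 1, length.out = 1024))        # ~1: straight line
#' set.seed(1)
#' boxDimension(rnorm(1024))                          # close to 2
#' @export
boxDimension <- function(x, scales = NULL, maxScaleExp = 8L,
                         interpolation = "polyline", fit = TRUE) {
  if (length(x) < 16L) stop("sequence too short (need >= 16 samples)")
  curve <- normalizeUnitSquare(x)
  bcc <- countOverScales(curve, scales, maxScaleExp, interpolation)
  dfit <- fitBoxDimension(bcc)
  if (fit) dfit@slope else dfit
}
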