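# Evaluation-metric suite. Each metric is implemented directly from its
# defining formula; tests cross-check against independent oracles.

#' Calinski-Harabasz score (variance ratio criterion)
#'
#' `CH = (BCSS/(k-1)) / (WCSS/(n-k))` where BCSS is the weighted sum of
#' squared distances from cluster centroids to the overall centroid and WCSS
#' the sum of squared distances from points to their cluster centroid. Higher
#' values indicate better-separated, tighter clusters.
#'
#' @param points Numeric matrix, n x d.
#' @param labels Cluster label per row; at least 2 distinct, fewer than n.
#' @return Positive scalar.
#' @export
calinski_harabasz <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.factor(labels)
  n <- nrow(points); k <- nlevels(labels)
  if (k < 2) stop("need at least 2 clusters")
  if (k >= n) stop("need fewer clusters than points")
  overall <- colMeans(points)
  bcss <- 0; wcss <- 0
  for (lv in levels(labels)) {
    idx <- labels == lv
    ci <- colMeans(points[idx, , drop = FALSE])
    bcss <- bcss + sum(idx) * sum((ci - overall)^2)
    wcss <- wcss + sum(sweep(points[idx, , drop = FALSE], 2, ci)^2)
  }
  if (wcss == 0) stop("zero within-cluster dispersion: CH score is degenerate")
  (bcss / (k - 1)) / (wcss / (n - k))
}

#' Pearson correlation coefficient
#'
#' Computed from the raw-moment form
#' `r = (n * sum(xy) - sum(x) sum(y)) / sqrt((n sum(x^2) - sum(x)^2)(n sum(y^2) - sum(y)^2))`.
#'
#' @param x,y Equal-length numeric vectors, each non-constant.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den2 <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  if (den2 <= 0) stop("correlation undefined for a constant vector")
  num / sqrt(den2)
}

#' Kendall's tau-b coefficient
#'
#' `tau = (P - Q) / sqrt((P + Q + T)(P + Q + U))` with P concordant pairs, Q
#' discordant pairs, T ties solely in x, U ties solely in y; pairs tied in
#' both vectors enter none of the four counts.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Scalar in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  prod_sign <- (dx * dy)[up]
  P <- sum(prod_sign > 0)
  Q <- sum(prod_sign < 0)
  T_ <- sum(dx[up] == 0 & dy[up] != 0)
  U_ <- sum(dy[up] == 0 & dx[up] != 0)
  den <- sqrt((P + Q + T_) * (P + Q + U_))
  if (den == 0) stop("tau undefined: all pairs tied in x or in y")
  (P - Q) / den
}

#' Jensen-Shannon divergence of two probability vectors
#'
#' `JS(P, Q) = (KL(P || M) + KL(Q || M)) / 2` with `M = (P + Q)/2`, using
#' base-2 logarithms so the value lies in `[0, 1]`; `0 * log(0/x)` terms are
#' defined as 0.
#'
#' @param p,q Equal-length non-negative vectors each summing to 1 (to 1e-9).
#' @return Scalar in `[0, 1]`.
#' @export
js_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0)) stop("probability vectors must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("inputs must each sum to 1")
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Structural similarity of two spatial value maps (global window)
#'
#' Single-window SSIM over the full value vectors:
#' `((2 mu_x mu_y + C1)(2 sigma_xy + C2)) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`
#' with population moments, `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, and `L` the
#' pooled value range floored at 1e-8. Spots are irregular points, not a
#' raster, so no sliding window is used.
#'
#' @param x,y Equal-length numeric value vectors (>= 2 locations).
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("ssim needs at least 2 locations")
  L <- max(max(x, y) - min(x, y), 1e-8)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

#' Mean squared error between two value matrices
#'
#' @param a,b Numeric vectors or matrices of equal shape.
#' @return Mean of squared elementwise differences.
#' @export
mse <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop("mse: shape mismatch")
  mean((as.numeric(a) - as.numeric(b))^2)
}

#' Impact score ranking of decomposition methods
#'
#' Standardizes each method's mean SSIM and mean JS divergence across methods
#' (population standard deviation), inverts the JS z-score (lower JS is
#' better), and averages the two z-scores into a single impact score. If a
#' metric has zero variance across methods its z-scores are set to 0 for all
#' methods (with a warning).
#'
#' @param summary Data frame with columns `method`, `mean_ssim`, `mean_js`
#'   (one row per method; >= 2 methods).
#' @return The input with added columns `z_ssim`, `z_js`, `impact`, ordered
#'   by decreasing impact.
#' @export
impact_score <- function(summary) {
  stopifnot(is.data.frame(summary),
            all(c("method", "mean_ssim", "mean_js") %in% names(summary)))
  if (nrow(summary) < 2) stop("impact score needs at least 2 methods")
  zscore <- function(v, label) {
    s <- sqrt(mean((v - mean(v))^2)) # population sd
    if (s == 0) {
      warning("zero variance across methods in ", label,
              "; z-scores set to 0")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  summary$z_ssim <- zscore(summary$mean_ssim, "SSIM")
  summary$z_js <- -zscore(summary$mean_js, "JS divergence") # lower JS better
  summary$impact <- (summary$z_ssim + summary$z_js) / 2
  summary[order(-summary$impact), , drop = FALSE]
}
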