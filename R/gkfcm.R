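# Gaussian kernel-based fuzzy c-means (GKFCM) on pixel intensities.
#
# The clustering operates on the flattened intensity values of a 2D image
# (scalar feature space). Distances are measured through a Gaussian radial
# basis function kernel whose width is estimated automatically from the data,
# so no kernel parameter has to be supplied by the user.

#' Automatic kernel-width estimate
#'
#' Estimates the squared width \eqn{\sigma^2} of the Gaussian radial basis
#' function kernel from the data as \eqn{(\max_i x_i - \min_i x_i)^2 / n}.
#' The estimate shrinks with the sample size, so on whole images the kernel
#' is very sharp; see the package vignette for the numerical consequences.
#'
#' @param x Numeric vector or matrix of intensities (finite, length >= 2).
#' @return Positive scalar, the kernel width in squared intensity units.
#' @examples
#' estimate_sigma2(c(0, 2))        # (2-0)^2 / 2 = 2
#' estimate_sigma2(matrix(runif(64), 8))
#' @export
estimate_sigma2 <- function(x) {
  x <- as.vector(x)
  if (length(x) < 2L) stop("need at least two intensity values", call. = FALSE)
  if (!all(is.finite(x))) stop("intensities must be finite", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop_degenerate("degenerate image: all intensities identical, clustering undefined")
  }
  (rng[2] - rng[1])^2 / length(x)
}

#' Gaussian radial basis function kernel
#'
#' \eqn{K(x, v) = \exp(-(x - v)^2 / \sigma^2)}. Vectorized over `x` and `v`.
#'
#' @param x,v Intensities (recycled to common length).
#' @param sigma2 Positive kernel width (squared intensity units).
#' @return Similarities in `(0, 1]`; exactly 1 where `x == v`.
#' @export
kernel_value <- function(x, v, sigma2) {
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) || sigma2 <= 0) {
    stop("`sigma2` must be a positive scalar", call. = FALSE)
  }
  exp(-((x - v)^2) / sigma2)
}

# Kernel-induced squared distance 1 - K, clipped below to keep the
# membership exponentiation defined when a point coincides with a centroid.
# Exact coincidence with several centroids yields equal clipped distances and
# therefore an equal membership split.
kernel_dist <- function(x, V, sigma2, clip = 1e-12) {
  D <- vapply(V, function(v) 1 - kernel_value(x, v, sigma2), numeric(length(x)))
  D <- matrix(pmax(D, clip), nrow = length(x), ncol = length(V))
  t(D) # c x n
}

#' Membership update
#'
#' Closed-form minimizer of the kernelized fuzzy objective over the membership
#' matrix under the per-pixel sum-to-one constraint:
#' \deqn{u_{ik} = \frac{(1 - K(x_k, v_i))^{-1/(m-1)}}{\sum_j (1 - K(x_k, v_j))^{-1/(m-1)}}.}
#'
#' @param x Numeric vector of n intensities.
#' @param V Numeric vector of c >= 2 centroids.
#' @param sigma2 Kernel width (positive scalar).
#' @param m Fuzzifier, > 1 (default 2).
#' @return A c x n membership matrix with columns summing to 1.
#' @export
update_memberships <- function(x, V, sigma2, m = 2) {
  x <- as.vector(x)
  if (length(V) < 2L) stop("need at least two centroids", call. = FALSE)
  if (m <= 1) stop("fuzzifier `m` must exceed 1", call. = FALSE)
  D <- kernel_dist(x, V, sigma2)
  W <- D^(-1 / (m - 1))
  sweep(W, 2L, colSums(W), "/")
}

#' Centroid update
#'
#' One fixed-point sweep of the centroid stationarity condition
#' \deqn{v_i = \frac{\sum_k u_{ik}^m K(x_k, v_i)\, x_k}{\sum_k u_{ik}^m K(x_k, v_i)},}
#' a kernel-weighted mean evaluated at the current centroids. For the
#' Gaussian kernel each sweep does not increase the clustering objective.
#'
#' @param x Numeric vector of n intensities.
#' @param U c x n membership matrix.
#' @param sigma2 Kernel width.
#' @param m Fuzzifier (default 2).
#' @param V Current centroids (length c), at which the kernel weights are
#'   evaluated.
#' @param seed Integer controlling the reseeding of a centroid whose weight
#'   mass collapses below `1e-12` (drawn uniformly from the data; the
#'   caller's RNG state is preserved).
#' @return Updated centroid vector, each entry within `range(x)`.
#' @export
update_centroids <- function(x, U, sigma2, m = 2, V, seed = 0L) {
  x <- as.vector(x)
  n <- length(x)
  cc <- nrow(U)
  if (length(V) != cc) stop("`V` must have one entry per membership row", call. = FALSE)
  out <- numeric(cc)
  for (i in seq_len(cc)) {
    w <- U[i, ]^m * kernel_value(x, V[i], sigma2)
    den <- sum(w)
    if (den < 1e-12) {
      idx <- with_seed(seed + i, sample.int(n, 1L))
      message(sprintf("centroid %d lost support; reseeded to data point %d", i, idx))
      out[i] <- x[idx]
    } else {
      out[i] <- sum(w * x) / den
    }
  }
  out
}

# Objective J_m = 2 * sum_i sum_k u_ik^m * (1 - K(x_k, v_i))
gkfcm_objective <- function(x, U, V, sigma2, m) {
  D <- vapply(V, function(v) 1 - kernel_value(x, v, sigma2), numeric(length(x)))
  2 * sum(t(U^m) * D)
}

#' Fit a Gaussian kernel-based fuzzy c-means partition
#'
#' Alternates the closed-form membership update and the fixed-point centroid
#' update on the kernelized fuzzy objective
#' \eqn{J_m = 2\sum_i\sum_k u_{ik}^m (1 - K(x_k, v_i))}, with the kernel
#' width estimated once from the data by [estimate_sigma2()]. Centroids are
#' initialized at evenly spaced quantiles of the intensity distribution, so
#' the fit is deterministic; `seed` only controls the (rare) reseeding of a
#' centroid that loses all weight mass.
#'
#' @param image Numeric matrix (2D intensity image) or vector of intensities.
#' @param c Number of clusters (>= 2). Must not exceed the number of distinct
#'   intensities.
#' @param m Fuzzifier (> 1, default 2).
#' @param tol Convergence tolerance on the maximum centroid change
#'   (default 1e-5).
#' @param max_iter Maximum number of update cycles (default 100).
#' @param seed Integer seed for degenerate-centroid reseeding (default 0).
#' @return An object of class `fuzzy_partition`: a list with membership
#'   matrix `U` (c x n), centroids `V`, kernel width `sigma2`, fuzzifier `m`,
#'   cluster count `c`, per-cycle `objective_trace`, `iterations`, the input
#'   `values`, and the image `dims` (NULL for vector input).
#' @examples
#' img <- matrix(rep(c(0.2, 0.8), each = 32), 8)
#' p <- fit_gkfcm(img, c = 2)
#' p$V
#' @export
fit_gkfcm <- function(image, c = 2L, m = 2, tol = 1e-5, max_iter = 100L, seed = 0L) {
  dims <- if (is.matrix(image)) dim(image) else NULL
  x <- as.vector(image)
  if (c < 2L) stop("`c` must be at least 2", call. = FALSE)
  if (max_iter < 1L) stop("`max_iter` must be at least 1", call. = FALSE)
  sigma2 <- estimate_sigma2(x) # errors on all-constant input
  n_distinct <- length(unique(x))
  if (c > n_distinct) {
    stop_degenerate(sprintf(
      "too many clusters: c = %d exceeds the %d distinct intensities", c, n_distinct))
  }

  probs <- (2 * seq_len(c) - 1) / (2 * c)
  V <- unname(stats::quantile(x, probs = probs, type = 7))
  if (anyDuplicated(V)) {
    u <- sort(unique(x))
    V <- u[round(seq(1, length(u), length.out = c))]
  }

  trace <- numeric(0)
  U <- NULL
  it <- 0L
  for (it in seq_len(max_iter)) {
    U <- update_memberships(x, V, sigma2, m)
    V_new <- update_centroids(x, U, sigma2, m, V, seed = seed)
    delta <- max(abs(V_new - V))
    V <- V_new
    trace <- c(trace, gkfcm_objective(x, U, V, sigma2, m))
    if (delta < tol) break
  }
  U <- update_memberships(x, V, sigma2, m)

  structure(
    list(U = U, V = V, sigma2 = sigma2, m = m, c = c,
         objective_trace = trace, iterations = it,
         values = x, dims = dims),
    class = "fuzzy_partition")
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("GKFCM partition: c = %d clusters, n = %d pixels\n", x$c, ncol(x$U)))
  cat(sprintf("  centroids: %s\n", paste(signif(x$V, 5), collapse = ", ")))
  cat(sprintf("  sigma2 = %.4g, m = %g, %d iterations, final J = %.6g\n",
              x$sigma2, x$m, x$iterations, utils::tail(x$objective_trace, 1)))
  invisible(x)
}
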