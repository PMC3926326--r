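# Synthetic phantom generator realizing the image model I = b*J + n:
# a piecewise-constant true image J over a simple geometry, a smooth
# multiplicative bias field b (normalized to mean 1), and additive
# zero-mean Gaussian noise n. Every stage of the pipeline can be verified
# against the stored ground truth.

#' Synthetic bias-field models
#'
#' Smooth multiplicative shading fields, parameterized by a fractional
#' modulation `beta` about mean 1:
#' \describe{
#'   \item{`none`}{constant 1.}
#'   \item{`linear_ramp`}{`1 + beta * t` with `t` a symmetric linear ramp in
#'     `[-1, 1]` along columns; `max(b)/min(b) = (1+beta)/(1-beta)`.}
#'   \item{`gaussian_blob`}{centered Gaussian bump of relative width 1/3 of
#'     the smaller image side, renormalized to mean 1.}
#'   \item{`polynomial`}{centered quadratic bowl (darker corners),
#'     renormalized to mean 1.}
#' }
#'
#' @param name One of `"none"`, `"linear_ramp"`, `"gaussian_blob"`,
#'   `"polynomial"`.
#' @param shape Integer vector `(rows, cols)`.
#' @param beta Fractional modulation amplitude in `[0, 0.6]`.
#' @return A positive matrix with mean 1.
#' @export
bias_models <- function(name, shape, beta) {
  if (beta < 0 || beta > 0.6) stop("`beta` must lie in [0, 0.6]", call. = FALSE)
  nr <- shape[1]; nc <- shape[2]
  b <- switch(name,
    none = matrix(1, nr, nc),
    linear_ramp = {
      t <- seq(-1, 1, length.out = nc)
      matrix(1 + beta * t, nr, nc, byrow = TRUE)
    },
    gaussian_blob = {
      s <- min(nr, nc) / 3
      r2 <- outer((seq_len(nr) - (nr + 1) / 2)^2, (seq_len(nc) - (nc + 1) / 2)^2, "+")
      b0 <- 1 + beta * exp(-r2 / (2 * s^2))
      b0 / mean(b0)
    },
    polynomial = {
      u <- (seq_len(nr) - (nr + 1) / 2) / (nr / 2)
      v <- (seq_len(nc) - (nc + 1) / 2) / (nc / 2)
      b0 <- 1 + beta * (1 - outer(u^2, v^2, "+") / 2)
      b0 / mean(b0)
    },
    stop(sprintf("unknown bias model '%s'", name), call. = FALSE)
  )
  b
}

phantom_geometry <- function(geometry, shape) {
  nr <- shape[1]; nc <- shape[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  s <- min(nr, nc)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  fg <- switch(geometry,
    disk = (rr - cy)^2 + (cc - cx)^2 <= (0.3 * s)^2,
    square = abs(rr - cy) <= 0.25 * s & abs(cc - cx) <= 0.25 * s,
    two_blob = {
      r <- 0.16 * s
      ((rr - 0.35 * nr)^2 + (cc - 0.35 * nc)^2 <= r^2) |
        ((rr - 0.68 * nr)^2 + (cc - 0.68 * nc)^2 <= r^2)
    },
    ring = {
      d2 <- (rr - cy)^2 + (cc - cx)^2
      d2 <= (0.32 * s)^2 & d2 >= (0.18 * s)^2
    },
    stop(sprintf("unknown geometry '%s'", geometry), call. = FALSE)
  )
  matrix(1L + fg, nr, nc) # 1 = background, 2 = foreground
}

#' Generate a synthetic phantom with ground truth
#'
#' Realizes `I = b * J + n` on a simple two-region geometry: `J` is
#' piecewise constant at the given region intensities, `b` comes from
#' [bias_models()] (mean 1), and `n` is i.i.d. zero-mean Gaussian noise of
#' standard deviation `noise_sigma`, drawn once under `seed` (the caller's
#' RNG state is preserved). Values pushed outside `[0, 1]` are clipped with
#' a warning.
#'
#' @param shape Integer `(rows, cols)` (default `c(128, 128)`).
#' @param geometry `"disk"` (default), `"square"`, `"two_blob"` or `"ring"`.
#' @param intensities Length-2 numeric in `[0, 1]`, background then
#'   foreground region constants (default `c(0.35, 0.65)`), distinct.
#' @param bias_model Bias-field model name (default `"linear_ramp"`).
#' @param beta Bias modulation amplitude (default 0.4).
#' @param noise_sigma Noise standard deviation (default 0.02).
#' @param seed Integer seed for the noise draw (default 1).
#' @return An object of class `phantom_truth`: list with the observed
#'   `image`, integer `labels` (1 background / 2 foreground), true `bias`,
#'   the `noise` realization, and the generating `spec`.
#' @examples
#' ph <- make_phantom(shape = c(64, 64), seed = 3)
#' range(ph$image)
#' @export
make_phantom <- function(shape = c(128L, 128L), geometry = "disk",
                         intensities = c(0.35, 0.65),
                         bias_model = "linear_ramp", beta = 0.4,
                         noise_sigma = 0.02, seed = 1L) {
  if (length(intensities) != 2L || intensities[1] == intensities[2]) {
    stop("`intensities` must be two distinct region constants", call. = FALSE)
  }
  if (any(intensities < 0) || any(intensities > 1)) {
    stop("`intensities` must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be nonnegative", call. = FALSE)
  labels <- phantom_geometry(geometry, shape)
  J <- matrix(intensities[labels], shape[1], shape[2])
  b <- bias_models(bias_model, shape, beta)
  n <- if (noise_sigma > 0) {
    with_seed(seed, matrix(stats::rnorm(prod(shape), 0, noise_sigma), shape[1], shape[2]))
  } else {
    matrix(0, shape[1], shape[2])
  }
  I <- b * J + n
  if (any(I < 0) || any(I > 1)) {
    warning("phantom intensities clipped to [0, 1]", call. = FALSE)
    I <- pmin(pmax(I, 0), 1)
  }
  spec <- list(shape = as.integer(shape), geometry = geometry,
               intensities = intensities, bias_model = bias_model,
               beta = beta, noise_sigma = noise_sigma, seed = as.integer(seed))
  structure(list(image = I, labels = labels, bias = b, noise = n, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  s <- x$spec
  cat(sprintf("phantom: %d x %d '%s', intensities %s, bias '%s' (beta = %g), noise sd %g, seed %d\n",
              s$shape[1], s$shape[2], s$geometry,
              paste(s$intensities, collapse = "/"),
              s$bias_model, s$beta, s$noise_sigma, s$seed))
  invisible(x)
}

#' Ground-truth foreground mask of a phantom
#'
#' @param phantom A `phantom_truth`.
#' @return Logical matrix, TRUE on the foreground region.
#' @export
phantom_mask <- function(phantom) phantom$labels == 2L
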