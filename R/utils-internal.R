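# Internal numerical helpers shared across modules. Not exported.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# 1D convolution along rows of a matrix with a centered odd-length kernel,
# zero padding outside the domain.
conv_rows <- function(x, k1d) {
  n <- nrow(x)
  r <- (length(k1d) - 1L) %/% 2L
  if (r == 0L) return(x * k1d[1L])
  xp <- rbind(matrix(0, r, ncol(x)), x, matrix(0, r, ncol(x)))
  out <- matrix(0, n, ncol(x))
  for (j in seq_along(k1d)) {
    if (k1d[j] != 0) out <- out + k1d[j] * xp[j:(j + n - 1L), , drop = FALSE]
  }
  out
}

conv_cols <- function(x, k1d) {
  m <- ncol(x)
  r <- (length(k1d) - 1L) %/% 2L
  if (r == 0L) return(x * k1d[1L])
  xp <- cbind(matrix(0, nrow(x), r), x, matrix(0, nrow(x), r))
  out <- matrix(0, nrow(x), m)
  for (j in seq_along(k1d)) {
    if (k1d[j] != 0) out <- out + k1d[j] * xp[, j:(j + m - 1L), drop = FALSE]
  }
  out
}

# Separable 2D convolution (zero padding). `k1d` must be symmetric, so
# convolution and correlation coincide.
conv_sep <- function(x, k1d) conv_cols(conv_rows(x, k1d), k1d)

# Sum of kernel weights falling inside the domain, per position along an axis.
border_weights <- function(n, k1d) {
  as.vector(conv_rows(matrix(1, n, 1L), k1d))
}

as_numeric_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  x
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("kfls_degenerate_error", "error")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("kfls_config_error", "error")))
}
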