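# Independent brute-force oracles used by the unit and acceptance tests.
# Each re-derives the quantity under test from first principles (loops,
# grids, direct sums), without calling the implementation path it checks.

# Minimize u^m * d1 + (1-u)^m * d2 over a grid on the 1-simplex (c = 2).
oracle_membership_grid <- function(d1, d2, m, step = 1e-4) {
  u <- seq(0, 1, by = step)
  obj <- u^m * d1 + (1 - u)^m * d2
  u[which.min(obj)]
}

# Direct (non-separable, zero-padded) 2D convolution by explicit loops.
oracle_conv2 <- function(x, k2d) {
  r <- (nrow(k2d) - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= m) {
        acc <- acc + k2d[di + r + 1L, dj + r + 1L] * x[ii, jj]
      }
    }
    out[i, j] <- acc
  }
  out
}

# Data force by the explicit double sum e_i(x) = sum_y K(y-x) [I(x) - b(y) c_i]^2
# restricted to the image domain.
oracle_data_force <- function(I, b, c_i, k2d) {
  r <- (nrow(k2d) - 1L) %/% 2L
  n <- nrow(I); m <- ncol(I)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= m) {
        acc <- acc + k2d[di + r + 1L, dj + r + 1L] * (I[i, j] - b[ii, jj] * c_i)^2
      }
    }
    out[i, j] <- acc
  }
  out
}

# Region constant by the explicit double-sum ratio
# sum_{x,y} K(y-x) b(y) I(x) M(x) / sum_{x,y} K(y-x) b(y)^2 M(x).
oracle_region_constant <- function(I, b, M, k2d) {
  bK <- oracle_conv2(b, k2d)
  b2K <- oracle_conv2(b^2, k2d)
  sum(bK * I * M) / sum(b2K * M)
}

# All 2^9 binary 3x3 masks, as a 512 x 9 logical matrix.
all_3x3_masks <- function() {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 9))
  as.matrix(grid)
}
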