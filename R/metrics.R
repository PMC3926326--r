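# Segmentation and bias-recovery scoring.

#' Dice overlap coefficient
#'
#' \eqn{\mathrm{Dice}(A, B) = 2|A \cap B| / (|A| + |B|)} between two binary
#' masks of identical shape. Two empty masks score 1 by convention (logged
#' via a message).
#'
#' @param A,B Logical matrices (or vectors) of identical shape.
#' @return Scalar in `[0, 1]`; 1 iff the masks are identical and nonempty.
#' @examples
#' A <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' dice(A, A) # 1
#' @export
dice <- function(A, B) {
  if (!identical(dim(A), dim(B)) || length(A) != length(B)) {
    stop("mask shapes differ", call. = FALSE)
  }
  A <- as.logical(A); B <- as.logical(B)
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0L) {
    message("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(A & B) / (na + nb)
}

#' Bias-recovery score
#'
#' Pearson correlation between an estimated and a true bias field after
#' dividing each by its mean. The mean normalization removes the inherent
#' scale ambiguity of the multiplicative model (only the product `b * J` is
#' identifiable up to a constant factor).
#'
#' @param b_est,b_true Numeric matrices of identical shape, non-constant.
#' @return Correlation in `[-1, 1]`; 1 for `b_est = s * b_true`, `s > 0`.
#' @export
bias_recovery_score <- function(b_est, b_true) {
  if (!identical(dim(b_est), dim(b_true))) stop("field shapes differ", call. = FALSE)
  if (stats::sd(b_est) == 0 || stats::sd(b_true) == 0) {
    stop("constant field: bias-recovery score undefined", call. = FALSE)
  }
  stats::cor(as.vector(b_est / mean(b_est)), as.vector(b_true / mean(b_true)))
}
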