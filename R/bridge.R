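# Bridge between the fuzzy clustering stage and the level-set stage:
# defuzzification, binary-step initialization of phi, and automatic
# derivation of the evolution's controlling parameters.

#' Defuzzify a fuzzy partition
#'
#' Assigns each pixel the class with the highest membership. On a bare
#' membership matrix this is a per-column argmax with ties broken by the
#' lowest class index. On a fitted [fit_gkfcm()] partition the max-membership
#' rule is evaluated in exact arithmetic: memberships are monotone in the
#' kernel distance to each centroid, so the argmax equals the nearest
#' centroid even where the stored memberships saturate to equal values in
#' double precision (see the vignette).
#'
#' @param x A c x n membership matrix, or a `fuzzy_partition`.
#' @param roi_cluster Optional class index to record as the region of
#'   interest (see [select_roi_cluster()]).
#' @return An object of class `crisp_labeling`: list with integer `labels`
#'   (matrix if image dimensions are known, else vector, values in `1..c`),
#'   `c`, and `roi_cluster` (possibly `NA`).
#' @export
defuzzify <- function(x, roi_cluster = NULL) UseMethod("defuzzify")

#' @rdname defuzzify
#' @export
defuzzify.default <- function(x, roi_cluster = NULL) {
  U <- as_numeric_matrix(x, "x")
  if (nrow(U) < 1L || ncol(U) < 1L) stop("empty membership matrix", call. = FALSE)
  labels <- max.col(t(U), ties.method = "first")
  new_crisp_labeling(labels, c = nrow(U), dims = NULL, roi_cluster = roi_cluster)
}

#' @rdname defuzzify
#' @export
defuzzify.fuzzy_partition <- function(x, roi_cluster = NULL) {
  # membership order per pixel = reverse order of |x_k - v_i|
  d <- vapply(x$V, function(v) abs(x$values - v), numeric(length(x$values)))
  labels <- max.col(-d, ties.method = "first")
  new_crisp_labeling(labels, c = x$c, dims = x$dims, roi_cluster = roi_cluster)
}

new_crisp_labeling <- function(labels, c, dims, roi_cluster = NULL) {
  if (!is.null(dims)) labels <- matrix(labels, dims[1], dims[2])
  if (!is.null(roi_cluster) && !is.na(roi_cluster) &&
      (roi_cluster < 1L || roi_cluster > c)) {
    stop(sprintf("roi_cluster %d out of range 1..%d", roi_cluster, c), call. = FALSE)
  }
  structure(list(labels = labels, c = c,
                 roi_cluster = if (is.null(roi_cluster)) NA_integer_ else as.integer(roi_cluster)),
            class = "crisp_labeling")
}

#' Select the region-of-interest cluster
#'
#' The clustering does not know which class is the anatomical target, so the
#' choice is made here: mode `"brightest"` (default) picks the cluster with
#' the largest centroid (ties to the lowest index); mode `"index:<k>"` (or a
#' plain integer) selects class `k` verbatim.
#'
#' @param partition A fitted `fuzzy_partition`.
#' @param mode `"brightest"`, `"index:<k>"`, or an integer index.
#' @return The selected class index.
#' @export
select_roi_cluster <- function(partition, mode = "brightest") {
  cc <- partition$c
  k <- if (is.numeric(mode)) {
    as.integer(mode)
  } else if (identical(mode, "brightest")) {
    which.max(partition$V) # ties: lowest index
  } else if (grepl("^index:[0-9]+$", mode)) {
    as.integer(sub("^index:", "", mode))
  } else {
    stop_config(sprintf("unknown roi mode '%s'", mode))
  }
  if (k < 1L || k > cc) {
    stop_config(sprintf("roi cluster %d out of range 1..%d", k, cc))
  }
  as.integer(k)
}

#' Binary-step initial level set
#'
#' Builds \eqn{\phi_0 = -c_0 A_k + (1 - A_k) c_0} from the crisp labeling,
#' where \eqn{A_k} is the binary mask of the region-of-interest class:
#' \eqn{\phi_0 = -c_0} inside the ROI and \eqn{+c_0} outside
#' (negative-inside convention).
#'
#' @param labeling A `crisp_labeling` with `roi_cluster` set, or a logical
#'   matrix used directly as the ROI mask \eqn{A_k}.
#' @param c0 Magnitude of the binary step (default 4).
#' @return An object of class `initial_levelset`: list with matrix `phi0`
#'   taking exactly the two values `-c0`, `+c0`, and `c0`.
#' @export
init_levelset <- function(labeling, c0 = 4) {
  if (is.logical(labeling) && is.matrix(labeling)) {
    A <- labeling
  } else if (inherits(labeling, "crisp_labeling")) {
    if (is.na(labeling$roi_cluster)) {
      stop("labeling has no roi_cluster; call select_roi_cluster() first", call. = FALSE)
    }
    if (!is.matrix(labeling$labels)) {
      stop("labeling carries no image dimensions", call. = FALSE)
    }
    A <- labeling$labels == labeling$roi_cluster
  } else {
    stop("`labeling` must be a crisp_labeling or a logical matrix", call. = FALSE)
  }
  if (all(A) || !any(A)) stop_degenerate("empty or full ROI: cannot initialize level set")
  phi0 <- matrix(c0, nrow(A), ncol(A))
  phi0[A] <- -c0
  structure(list(phi0 = phi0, c0 = c0), class = "initial_levelset")
}

#' Area-to-length ratio of an initial level set
#'
#' \eqn{\tau = \mathrm{area}(\phi_0) / \mathrm{length}(\phi_0)}, where the
#' area is the crisp pixel count on the ROI (negative) side of \eqn{\phi_0}
#' and the length is the smoothed Dirac integral
#' \eqn{\sum \delta_\epsilon(\phi_0)} over the grid. A high ratio indicates
#' low topological complexity of the ROI and permits a faster evolution.
#'
#' @param phi0 An `initial_levelset` or a numeric matrix with both signs.
#' @param epsilon Dirac regularization width (default 1).
#' @return Positive scalar \eqn{\tau} (pixels).
#' @export
estimate_tau <- function(phi0, epsilon = 1) {
  if (inherits(phi0, "initial_levelset")) phi0 <- phi0$phi0
  phi0 <- as_numeric_matrix(phi0, "phi0")
  if (!any(phi0 < 0) || !any(phi0 > 0)) {
    stop_degenerate("phi0 must take both signs")
  }
  area <- sum(phi0 < 0)
  len <- sum(dirac(phi0, epsilon))
  if (len < 1e-12) stop("zero contour length", call. = FALSE)
  area / len
}

#' Derive the controlling parameters of the evolution
#'
#' Applies the automatic rules \eqn{\mu = 0.2 / \tau} (time step),
#' \eqn{\lambda = 1 / \tau} (length weight) and \eqn{\nu = 1} (data weight).
#' By construction \eqn{\mu \tau = 0.2}, strictly below the 0.25 stability
#' bound for the evolution.
#'
#' @param tau Positive area-to-length ratio from [estimate_tau()].
#' @param epsilon Heaviside/Dirac width carried along (default 1).
#' @return An object of class `derived_params`: list with `tau`, `mu`,
#'   `lambda`, `nu`, `epsilon`.
#' @examples
#' derive_params(2) # mu = 0.1, lambda = 0.5, nu = 1
#' @export
derive_params <- function(tau, epsilon = 1) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("`tau` must be a positive scalar", call. = FALSE)
  }
  structure(list(tau = tau, mu = 0.2 / tau, lambda = 1 / tau, nu = 1,
                 epsilon = epsilon),
            class = "derived_params")
}

#' @export
print.derived_params <- function(x, ...) {
  cat(sprintf("derived evolution parameters: tau = %.4g, mu = %.4g, lambda = %.4g, nu = %g (mu*tau = %.3g)\n",
              x$tau, x$mu, x$lambda, x$nu, x$mu * x$tau))
  invisible(x)
}
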