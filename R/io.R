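# Image, mask and configuration I/O.
#
# On-disk conventions: grayscale PNG (8/16-bit) or TIFF in; masks out as
# 0/255 PNG; float fields (bias, corrected image, phi) out as 32-bit float
# TIFF, rescaled into [0,1] by a factor recorded in the run report because
# the TIFF writer clamps values outside that range.

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG or a TIFF and normalizes it to `[0, 1]` by the
#' bit-depth maximum. RGB images are collapsed to luminance
#' (0.2126 R + 0.7152 G + 0.0722 B) with a warning; an alpha channel is
#' dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix in `[0, 1]` with attribute `"path"`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s' (expected PNG or TIFF): %s", ext, path),
         call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) {
      warning(sprintf("RGB image collapsed to luminance: %s", path), call. = FALSE)
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img <- pmin(pmax(img, 0), 1)
  attr(img, "path") <- path
  img
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask from a PNG
#'
#' Pixels above 0.5 (of the bit-depth maximum) are foreground.
#'
#' @param path Path to a PNG mask.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  read_image(path) > 0.5
}

# Write a float field as 32-bit TIFF, rescaled into [0,1]; returns the scale
# factor by which the stored values must be multiplied to recover the field.
write_float_tiff <- function(x, path) {
  lo <- min(x)
  if (lo < 0) x <- x - lo else lo <- 0
  scale <- max(x, 1e-12)
  suppressWarnings(tiff::writeTIFF(x / scale, path, bits.per.sample = 32L))
  c(scale = scale, offset = lo)
}

#' Default pipeline configuration
#'
#' Nested list of every tunable setting of the segment pipeline, grouped by
#' stage (`gkfcm`, `bridge`, `evolve`). Unknown keys in a user config are
#' rejected by [merge_config()].
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    gkfcm = list(c = 2L, m = 2, tol = 1e-5, max_iter = 100L, seed = 0L),
    bridge = list(c0 = 4, roi_mode = "brightest", epsilon = 1),
    evolve = list(sigma_K = NA, epsilon = 1, max_iter = 500L, stop_tol = 1e-4,
                  mu_R = 1, intensity_scale = 255)
  )
}

#' Merge a user configuration over the defaults
#'
#' @param config Nested list (possibly partial) of settings, e.g. from
#'   [read_config()]. Unknown groups or keys raise a config error.
#' @return Complete configuration list.
#' @export
merge_config <- function(config = list()) {
  base <- default_config()
  if (length(config) == 0L) return(base)
  if (is.null(names(config)) || any(names(config) == "")) {
    stop_config("configuration entries must be named")
  }
  for (grp in names(config)) {
    if (!grp %in% names(base)) {
      stop_config(sprintf("unknown configuration group '%s'", grp))
    }
    entries <- config[[grp]]
    if (!is.list(entries)) stop_config(sprintf("group '%s' must be a mapping", grp))
    for (key in names(entries)) {
      if (!key %in% names(base[[grp]])) {
        stop_config(sprintf("unknown configuration key '%s.%s'", grp, key))
      }
      base[[grp]][[key]] <- entries[[key]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML file with the groups of [default_config()]; missing keys fall back
#' to the defaults, unknown keys are rejected.
#'
#' @param path Path to a YAML config file.
#' @return Complete configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  merge_config(yaml::read_yaml(path))
}

#' Write a configuration to YAML
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
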