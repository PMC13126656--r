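#' RF C-scan volume container
#'
#' A raw (or filtered) radiofrequency volume: per-A-line samples along the
#' first dimension, lateral position along the second, B-scan frame along
#' the third. Carries the temporal sampling rate and the lateral pixel
#' pitch (scanner step size, 3 um by default for the OR-PAM system this
#' package targets).
#'
#' @param samples numeric 3D array, `time x lateral x frame`.
#' @param sampling_rate_hz positive scalar, temporal sampling rate.
#' @param pixel_size_um positive scalar, lateral step size in micrometers.
#' @return An object of class `rf_volume`.
#' @examples
#' v <- rf_volume(array(rnorm(64 * 4 * 4), c(64, 4, 4)), 250e6)
#' dim(v$samples)
#' @export
rf_volume <- function(samples, sampling_rate_hz, pixel_size_um = 3) {
  check_that(is.numeric(samples) && length(dim(samples)) == 3L, "samples",
             "must be a numeric 3D array (time x lateral x frame)")
  check_that(all(is.finite(samples)), "samples", "must be finite")
  check_scalar_num(sampling_rate_hz, "sampling_rate_hz", lower = 1e-12)
  check_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-12)
  structure(list(samples = samples,
                 sampling_rate_hz = sampling_rate_hz,
                 pixel_size_um = pixel_size_um),
            class = "rf_volume")
}

#' @export
print.rf_volume <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<rf_volume> %d samples x %d A-lines x %d frames, fs = %.3g MHz, step = %g um\n",
              d[1], d[2], d[3], x$sampling_rate_hz / 1e6, x$pixel_size_um))
  invisible(x)
}

#' Maximum intensity projection image container
#'
#' @param intensity nonnegative numeric matrix (rows x cols).
#' @param pixel_size_um positive scalar, physical pixel size.
#' @param dynamic_range_db dynamic range already applied to `intensity`
#'   (in dB), or `NULL` for a linear-scale image.
#' @return An object of class `mip_image`.
#' @export
mip_image <- function(intensity, pixel_size_um = 3, dynamic_range_db = NULL) {
  check_that(is.matrix(intensity) && is.numeric(intensity), "intensity",
             "must be a numeric matrix")
  check_that(all(is.finite(intensity)) && all(intensity >= 0), "intensity",
             "must be finite and nonnegative")
  check_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-12)
  if (!is.null(dynamic_range_db))
    check_scalar_num(dynamic_range_db, "dynamic_range_db", lower = 1e-12)
  structure(list(intensity = intensity,
                 pixel_size_um = pixel_size_um,
                 dynamic_range_db = dynamic_range_db),
            class = "mip_image")
}

#' @export
print.mip_image <- function(x, ...) {
  cat(sprintf("<mip_image> %d x %d px @ %g um/px%s\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size_um,
              if (is.null(x$dynamic_range_db)) " (linear)"
              else sprintf(", %g dB dynamic range", x$dynamic_range_db)))
  invisible(x)
}

#' Binary vessel mask container
#'
#' @param mask logical matrix; `TRUE` marks vessel pixels.
#' @param pixel_size_um positive scalar, physical pixel size.
#' @return An object of class `vessel_mask`.
#' @export
vessel_mask <- function(mask, pixel_size_um = 3) {
  check_that(is.matrix(mask) && is.logical(mask), "mask",
             "must be a logical matrix")
  check_that(!anyNA(mask), "mask", "must not contain NA")
  check_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-12)
  structure(list(mask = mask, pixel_size_um = pixel_size_um),
            class = "vessel_mask")
}

#' Skeleton (centerline) mask container
#'
#' One-pixel-wide centerlines under 8-connectivity; a subset of the vessel
#' mask it was thinned from.
#'
#' @inheritParams vessel_mask
#' @return An object of class `skeleton_mask`.
#' @export
skeleton_mask <- function(mask, pixel_size_um = 3) {
  check_that(is.matrix(mask) && is.logical(mask), "mask",
             "must be a logical matrix")
  check_that(!anyNA(mask), "mask", "must not contain NA")
  check_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-12)
  structure(list(mask = mask, pixel_size_um = pixel_size_um),
            class = "skeleton_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d px, %d vessel px (%.1f%%)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
print.skeleton_mask <- function(x, ...) {
  cat(sprintf("<skeleton_mask> %d x %d px, %d centerline px\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}
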