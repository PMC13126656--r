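#' Distance-transform diameter map
#'
#' At every centerline (skeleton) pixel, the local vessel radius is the
#' shortest Euclidean distance from that pixel to the vessel boundary,
#' read off the exact Euclidean distance transform of the vessel mask;
#' the local diameter is twice that radius, scaled to physical units.
#'
#' @param mask a [vessel_mask()].
#' @param skeleton a [skeleton_mask()]; must be a pixelwise subset of
#'   `mask`.
#' @return An object of class `diameter_map`: data.frame `entries` with
#'   columns `row`, `col`, `diameter_um`, plus `pixel_size_um`.
#' @export
diameter_map <- function(mask, skeleton) {
  if (!inherits(mask, "vessel_mask"))
    stop("`mask` must be a vessel_mask", call. = FALSE)
  if (!inherits(skeleton, "skeleton_mask"))
    stop("`skeleton` must be a skeleton_mask", call. = FALSE)
  check_that(identical(dim(mask$mask), dim(skeleton$mask)), "skeleton",
             "must have the same shape as the mask")
  if (any(skeleton$mask & !mask$mask))
    stop("skeleton pixel off mask", call. = FALSE)
  dt <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask$mask * 1),
                                            metric = "euclidean"))
  idx <- which(skeleton$mask, arr.ind = TRUE)
  entries <- data.frame(row = idx[, 1L], col = idx[, 2L],
                        diameter_um = 2 * dt[idx] * mask$pixel_size_um)
  structure(list(entries = entries, pixel_size_um = mask$pixel_size_um),
            class = "diameter_map")
}

# Smallest most-frequent bin center of a 1-pixel-width diameter histogram.
diameter_mode <- function(d, pixel_size_um) {
  bins <- floor(d / pixel_size_um)
  tab <- table(bins)
  b <- as.numeric(names(tab)[tab == max(tab)])
  (min(b) + 0.5) * pixel_size_um
}

#' Morphometric feature set of a diameter map
#'
#' Sample statistics of the per-centerline-pixel diameter distribution
#' (mean, SD, median, mode on a one-pixel-wide histogram with ties broken
#' toward the smallest value, min, max, skewness, excess kurtosis) plus
#' mask-derived densities: vessel area fraction, centerline length per
#' ROI area, and intersection (branch-node cluster) density. Eleven
#' features in all, on physically calibrated scales.
#'
#' @param dmap a [diameter_map()].
#' @param mask the [vessel_mask()] the map was computed from.
#' @param roi_area_um2 ROI area in um^2 (see [roi_area()]); defaults to
#'   the full mask area.
#' @return A one-row data.frame with columns `mean_diameter_um`,
#'   `sd_diameter_um`, `median_diameter_um`, `mode_diameter_um`,
#'   `min_diameter_um`, `max_diameter_um`, `diameter_skewness`,
#'   `diameter_kurtosis`, `vessel_area_fraction`,
#'   `vessel_density_um_per_um2`, `intersection_density_per_um2`.
#'   An empty diameter map gives all-`NA` features with a warning (the
#'   image is then excluded downstream).
#' @export
morphometric_features <- function(dmap, mask,
                                  roi_area_um2 = roi_area(dim(mask$mask),
                                                          mask$pixel_size_um)) {
  if (!inherits(dmap, "diameter_map"))
    stop("`dmap` must be a diameter_map", call. = FALSE)
  if (!inherits(mask, "vessel_mask"))
    stop("`mask` must be a vessel_mask", call. = FALSE)
  check_scalar_num(roi_area_um2, "roi_area_um2", lower = 1e-12)
  cols <- c("mean_diameter_um", "sd_diameter_um", "median_diameter_um",
            "mode_diameter_um", "min_diameter_um", "max_diameter_um",
            "diameter_skewness", "diameter_kurtosis",
            "vessel_area_fraction", "vessel_density_um_per_um2",
            "intersection_density_per_um2")
  if (nrow(dmap$entries) == 0L) {
    warning("empty diameter map: morphometric features are missing")
    out <- as.data.frame(as.list(setNames(rep(NA_real_, length(cols)), cols)))
    return(out)
  }
  d <- dmap$entries$diameter_um
  px <- dmap$pixel_size_um

  skel <- matrix(FALSE, nrow(mask$mask), ncol(mask$mask))
  skel[cbind(dmap$entries$row, dmap$entries$col)] <- TRUE
  center_len_um <- centerline_length_px(skel) * px
  n_clusters <- nrow(branch_clusters(skel)$nodes)

  data.frame(
    mean_diameter_um = mean(d),
    sd_diameter_um = if (length(d) > 1) sd(d) else 0,
    median_diameter_um = median(d),
    mode_diameter_um = diameter_mode(d, px),
    min_diameter_um = min(d),
    max_diameter_um = max(d),
    diameter_skewness = if (length(d) > 2 && sd(d) > 0)
      sample_skewness(d) else 0,
    diameter_kurtosis = if (length(d) > 3 && sd(d) > 0)
      sample_kurtosis(d) else 0,
    vessel_area_fraction = mean(mask$mask),
    vessel_density_um_per_um2 = center_len_um / roi_area_um2,
    intersection_density_per_um2 = n_clusters / roi_area_um2)
}
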