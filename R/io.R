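#' Write / read a MIP image as 16-bit TIFF
#'
#' Intensities are scaled to the 16-bit range on write; the scale, the
#' physical pixel size, and any applied dynamic range travel in a JSON
#' sidecar file (`<path>.json`) and are restored on read.
#'
#' @param mip an [mip_image()].
#' @param path output file path.
#' @return `write_mip_tiff()` returns `path` invisibly; `read_mip_tiff()`
#'   returns an [mip_image()].
#' @export
write_mip_tiff <- function(mip, path) {
  if (!inherits(mip, "mip_image"))
    stop("`mip` must be a mip_image", call. = FALSE)
  mx <- max(mip$intensity)
  img <- if (mx > 0) mip$intensity / mx else mip$intensity
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_um = mip$pixel_size_um,
                            intensity_max = mx,
                            dynamic_range_db = mip$dynamic_range_db),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_mip_tiff
#' @param path input file path.
#' @param pixel_size_um fallback pixel size when the file has no JSON
#'   sidecar.
#' @export
read_mip_tiff <- function(path, pixel_size_um = 3) {
  img <- tiff::readTIFF(path)
  px <- pixel_size_um; mx <- 1; dr <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    parsed <- tryCatch(jsonlite::fromJSON(side), error = function(e) NULL)
    if (!is.null(parsed)) {
      px <- parsed$pixel_um %||% px
      mx <- parsed$intensity_max %||% 1
      dr <- parsed$dynamic_range_db
    }
  }
  m <- if (is.matrix(img)) img else img[, , 1]
  mip_image(m * mx, pixel_size_um = px, dynamic_range_db = dr)
}

#' Write / read a binary mask as TIFF
#'
#' @param mask a [vessel_mask()] or [skeleton_mask()].
#' @param path file path.
#' @return `write_mask_tiff()` returns `path` invisibly;
#'   `read_mask_tiff()` returns a [vessel_mask()].
#' @export
write_mask_tiff <- function(mask, path) {
  if (!inherits(mask, c("vessel_mask", "skeleton_mask")))
    stop("`mask` must be a vessel_mask or skeleton_mask", call. = FALSE)
  tiff::writeTIFF(mask$mask * 1, path, bits.per.sample = 8L)
  jsonlite::write_json(list(pixel_um = mask$pixel_size_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @param pixel_size_um fallback pixel size.
#' @export
read_mask_tiff <- function(path, pixel_size_um = 3) {
  img <- tiff::readTIFF(path)
  px <- pixel_size_um
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    parsed <- tryCatch(jsonlite::fromJSON(side), error = function(e) NULL)
    px <- parsed$pixel_um %||% px
  }
  m <- if (is.matrix(img)) img else img[, , 1]
  vessel_mask(m > 0.5, pixel_size_um = px)
}

#' Write / read a labeled feature table as CSV
#'
#' Plain CSV with a header row, sample ids in the first column, and the
#' class label in a `label` column.
#'
#' @param features data.frame of features (optionally with `label`).
#' @param path file path.
#' @return `write_feature_csv()` returns `path` invisibly;
#'   `read_feature_csv()` returns the data.frame with row names restored
#'   and `label` as a factor.
#' @export
write_feature_csv <- function(features, path) {
  out <- cbind(sample_id = rownames(features) %||%
                 as.character(seq_len(nrow(features))), features)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  check_that("sample_id" %in% names(tab), "path",
             "CSV must have a sample_id column")
  rownames(tab) <- tab$sample_id
  tab$sample_id <- NULL
  if ("label" %in% names(tab))
    tab$label <- factor(tab$label, levels = c("normal_benign", "ec_ein"))
  tab
}
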