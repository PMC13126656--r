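#' Pipeline configuration
#'
#' Bundles every tunable parameter of the end-to-end pipeline with the
#' defaults the package targets: a 3-um scanner step, a 30 kHz to 50 MHz
#' analysis band, a 45-dB display dynamic range, a 5x5 spectral averaging
#' window gated at the median envelope maximum, and a five-feature
#' selection with |r| < 0.5 correlation pruning.
#'
#' @param band_hz numeric length-2, bandpass edges in Hz.
#' @param dynamic_range_db display dynamic range in dB.
#' @param pixel_size_um lateral pixel size in um.
#' @param clahe_clip,ball_radius_px,min_area_px segmentation parameters
#'   (see [enhance_and_subtract()], [binarize()]).
#' @param binarize_method `"otsu"` or `"adaptive"`.
#' @param spectral_window_px,noise_floor_quantile spectral-map parameters
#'   (see [power_spectral_map()]).
#' @param k,corr_threshold feature-selection parameters.
#' @param layout_iter force-layout iterations.
#' @param seed RNG seed used for the embedding and any stochastic step.
#' @return A list of class `pam_config`.
#' @export
pam_config <- function(band_hz = c(30e3, 50e6), dynamic_range_db = 45,
                       pixel_size_um = 3, clahe_clip = 2,
                       ball_radius_px = 25, min_area_px = 10,
                       binarize_method = "otsu",
                       spectral_window_px = 5, noise_floor_quantile = 0.5,
                       k = 5, corr_threshold = 0.5, layout_iter = 500,
                       seed = 42L) {
  check_that(is.numeric(band_hz) && length(band_hz) == 2L &&
               band_hz[1] > 0 && band_hz[1] < band_hz[2], "band_hz",
             "must be increasing positive edges")
  check_scalar_num(dynamic_range_db, "dynamic_range_db", lower = 1e-12)
  check_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-12)
  structure(list(band_hz = band_hz, dynamic_range_db = dynamic_range_db,
                 pixel_size_um = pixel_size_um, clahe_clip = clahe_clip,
                 ball_radius_px = ball_radius_px, min_area_px = min_area_px,
                 binarize_method = binarize_method,
                 spectral_window_px = spectral_window_px,
                 noise_floor_quantile = noise_floor_quantile,
                 k = k, corr_threshold = corr_threshold,
                 layout_iter = layout_iter, seed = as.integer(seed)),
            class = "pam_config")
}

# Feature extraction for a single image (rf_volume or mip_image).
extract_one <- function(input, config) {
  mean_freq <- NA_real_
  if (inherits(input, "rf_volume")) {
    filt <- bandpass_filter(input, config$band_hz[1], config$band_hz[2])
    env <- hilbert_envelope(filt)
    mip <- max_intensity_projection(env, pixel_size_um = input$pixel_size_um)
    w <- min(config$spectral_window_px, dim(filt$samples)[2:3])
    if (w %% 2 == 0) w <- w - 1  # window must be odd and fit the image
    mf <- tryCatch({
      sm <- power_spectral_map(filt, window_px = w,
                               noise_floor_quantile =
                                 config$noise_floor_quantile)
      mean_frequency(sm)$mean_freq_hz
    }, error = function(e) NA_real_)
    mean_freq <- mf / 1e6
  } else if (inherits(input, "mip_image")) {
    mip <- input
  } else stop("input must be an rf_volume or mip_image", call. = FALSE)

  disp <- apply_dynamic_range(mip, config$dynamic_range_db)
  enh <- enhance_and_subtract(disp, clahe_clip = config$clahe_clip,
                              ball_radius_px = min(config$ball_radius_px,
                                                   (min(dim(disp$intensity)) - 3) %/% 2))
  mask <- binarize(enh, method = config$binarize_method,
                   min_area_px = config$min_area_px)
  if (!any(mask$mask)) stop("empty vessel mask", call. = FALSE)
  skel <- skeletonize_mask(mask)
  area <- roi_area(dim(mask$mask), mask$pixel_size_um)
  dmap <- diameter_map(mask, skel)
  morph <- morphometric_features(dmap, mask, area)
  topo <- suppressWarnings(
    topology_features(build_skeleton_graph(skel), area))
  cbind(data.frame(mean_frequency_mhz = mean_freq), morph, topo)
}

#' Extract the per-image feature table from a batch of inputs
#'
#' Runs the full structural (and, for RF inputs, spectral) feature
#' extraction on each input and binds one row per image. Failing inputs
#' are skipped with their error recorded; the run continues.
#'
#' @param inputs named list of [rf_volume()] and/or [mip_image()] objects.
#' @param config a [pam_config()].
#' @return data.frame of features, one row per successful image, with
#'   attribute `failures` (named character vector of error messages) and
#'   row names from `inputs` names.
#' @export
run_extract <- function(inputs, config = pam_config()) {
  check_that(is.list(inputs), "inputs", "must be a list")
  if (length(inputs) == 0L) {
    warning("empty input list: empty feature table")
    return(structure(data.frame(), failures = character(0)))
  }
  nms <- names(inputs) %||% sprintf("img%02d", seq_along(inputs))
  nms[nms == ""] <- sprintf("img%02d", which(nms == ""))
  rows <- list(); fails <- character(0)
  for (i in seq_along(inputs)) {
    res <- tryCatch(extract_one(inputs[[i]], config),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) fails[nms[i]] <- res
    else { rownames(res) <- nms[i]; rows[[nms[i]]] <- res }
  }
  if (length(fails))
    warning(sprintf("feature extraction failed for %d input(s): %s",
                    length(fails),
                    paste(names(fails), fails, sep = ": ", collapse = "; ")))
  out <- do.call(rbind, rows)
  attr(out, "failures") <- fails
  out
}

#' Run the separability analysis on a labeled feature table
#'
#' Feature screening and de-correlation, cosine-similarity network,
#' force-directed embedding with in-sample logistic boundary, and the
#' leave-one-out cross-validated similarity classifier, composed into a
#' single report.
#'
#' @param features data.frame with numeric feature columns and a `label`
#'   column (`normal_benign` / `ec_ein`).
#' @param config a [pam_config()].
#' @return A list of class `pam_report`: `selection`, `similarity`,
#'   `embedding`, `boundary`, `cv`, `config`.
#' @export
run_full <- function(features, config = pam_config()) {
  check_that(is.data.frame(features) && "label" %in% names(features),
             "features", "must be a data.frame with a `label` column")
  sel <- select_features(features, k = config$k,
                         corr_threshold = config$corr_threshold)
  if (length(sel$selected) < 2L)
    stop(sprintf(paste("feature selection retained %d feature(s); the",
                       "cosine-similarity framework needs at least two",
                       "(one-dimensional L2-normalized vectors are all",
                       "identical). Relax corr_threshold or supply more",
                       "features."), length(sel$selected)), call. = FALSE)
  sim <- cosine_similarity(features, features = sel$selected)
  emb <- force_layout(sim, seed = config$seed, n_iter = config$layout_iter)
  bnd <- boundary_2d(emb)
  cv <- loocv_similarity(sim)
  structure(list(selection = sel, similarity = sim, embedding = emb,
                 boundary = bnd, cv = cv, config = config),
            class = "pam_report")
}

#' @export
print.pam_report <- function(x, ...) {
  cat("== pamvasc separability report ==\n")
  print(x$selection)
  cat(sprintf("Embedding: %d/%d points on their label's side of the logistic boundary\n",
              x$boundary$n_correct_side, x$boundary$n))
  print(x$cv)
  invisible(x)
}
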