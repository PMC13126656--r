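#' Pixel-wise power spectral map of an RF volume
#'
#' Computes a per-A-line periodogram (Hann window, one-sided) and averages
#' it over a `window_px x window_px` sliding spatial neighborhood of
#' A-lines. The averaging is robust: A-lines whose envelope maximum falls
#' below the `noise_floor_quantile` of all envelope maxima in the image
#' (or is exactly zero) are treated as signal-free and excluded from every
#' window; pixels whose window contains no signal A-line get an excluded
#' (all-`NA`) spectrum.
#'
#' @param vol an [rf_volume()], already band-limited.
#' @param window_px odd positive window side length in pixels (A-lines).
#' @param noise_floor_quantile quantile of the envelope-maximum
#'   distribution used to gate signal A-lines, in `[0, 1)`.
#' @return An object of class `spectral_map`: list with `power`
#'   (`freq x lateral x frame` array, `NA` where excluded), `freq_axis_hz`,
#'   `included` (logical matrix of gated A-lines), `sampling_rate_hz`.
#' @export
power_spectral_map <- function(vol, window_px = 5, noise_floor_quantile = 0.5) {
  if (!inherits(vol, "rf_volume"))
    stop("`vol` must be an rf_volume", call. = FALSE)
  check_scalar_num(window_px, "window_px", lower = 1)
  check_that(window_px %% 2 == 1, "window_px", "must be odd")
  check_scalar_num(noise_floor_quantile, "noise_floor_quantile",
                   lower = 0, upper = 1)
  check_that(noise_floor_quantile < 1, "noise_floor_quantile", "must be < 1")
  d <- dim(vol$samples)
  n <- d[1]; nl <- d[2]; nf <- d[3]
  check_that(window_px <= nl && window_px <= nf, "window_px",
             "must not exceed the lateral/frame image size")

  # one-sided Hann periodogram per A-line
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))     # Hann
  x <- matrix(vol$samples, nrow = n) * w
  nb <- floor(n / 2) + 1L
  P <- Mod(mvfft(x))^2
  P <- P[seq_len(nb), , drop = FALSE]
  freq <- (seq_len(nb) - 1L) * vol$sampling_rate_hz / n

  # robustness gate on envelope maxima
  env <- hilbert_envelope(vol)
  emax <- matrix(apply(matrix(env, nrow = n), 2L, max), nl, nf)
  thr <- quantile(emax, noise_floor_quantile, names = FALSE)
  included <- emax > 0 & emax >= thr
  if (!any(included)) stop("no signal pixels", call. = FALSE)

  # sliding-window average over included A-lines
  Parr <- array(P, c(nb, nl, nf))
  num <- array(0, c(nb, nl, nf))
  den <- matrix(0, nl, nf)
  h <- (window_px - 1) / 2
  incn <- matrix(as.numeric(included), nl, nf)
  Pinc <- Parr * rep(incn, each = nb)  # zero out excluded spectra
  for (dr in -h:h) for (dc in -h:h) {
    r1 <- max(1, 1 + dr):min(nl, nl + dr)
    c1 <- max(1, 1 + dc):min(nf, nf + dc)
    num[, r1, c1] <- num[, r1, c1] + Pinc[, r1 - dr, c1 - dc, drop = FALSE]
    den[r1, c1] <- den[r1, c1] + incn[r1 - dr, c1 - dc]
  }
  avg <- num / rep(den, each = nb)     # NaN where den == 0
  avg[!is.finite(avg)] <- NA_real_
  structure(list(power = avg, freq_axis_hz = freq,
                 included = included,
                 sampling_rate_hz = vol$sampling_rate_hz),
            class = "spectral_map")
}

#' Image-level spectral mean frequency
#'
#' Averages the power spectrum across all non-excluded pixels of a
#' [power_spectral_map()] and returns its power-weighted centroid
#' `sum(f * P) / sum(P)` — the spectral mean frequency of the PA signal.
#' Lower values indicate larger effective absorbers.
#'
#' @param map a `spectral_map`.
#' @return List of class `mean_frequency_result`: `mean_freq_hz`,
#'   `n_pixels_used`.
#' @export
mean_frequency <- function(map) {
  if (!inherits(map, "spectral_map"))
    stop("`map` must be a spectral_map", call. = FALSE)
  nb <- length(map$freq_axis_hz)
  pm <- matrix(map$power, nrow = nb)
  ok <- !apply(is.na(pm), 2L, any)
  if (!any(ok)) stop("no included pixels in spectral map", call. = FALSE)
  spec <- rowMeans(pm[, ok, drop = FALSE])
  tot <- sum(spec)
  if (tot <= 0) stop("spectral map has zero total power", call. = FALSE)
  structure(list(mean_freq_hz = sum(map$freq_axis_hz * spec) / tot,
                 n_pixels_used = sum(ok)),
            class = "mean_frequency_result")
}

#' @export
print.mean_frequency_result <- function(x, ...) {
  cat(sprintf("<mean_frequency_result> %.3f MHz over %d pixels\n",
              x$mean_freq_hz / 1e6, x$n_pixels_used))
  invisible(x)
}
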