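#' Specification for a synthetic RF phantom
#'
#' Describes an RF C-scan volume in which selected A-lines carry
#' Gaussian-modulated cosine pulses (emulating photoacoustic point
#' responses through a band-limited transducer) plus white noise. The
#' analytic spectral centroid of the noise-free pulse is available in
#' closed form, which makes the spectral pipeline testable.
#'
#' Absorber size enters as a spectral surrogate, not an acoustic
#' simulation: a diameter `d` multiplies the pulse spectrum by a Gaussian
#' low-pass with cutoff `c / (pi * d)` (`c` = 1540 m/s). The product of
#' the transducer Gaussian (center `carrier_freq_hz`, SD
#' `gaussian_bandwidth_hz`) and this low-pass is again Gaussian, with an
#' effective carrier that decreases strictly with `d` — so larger
#' absorbers yield lower spectral centroids, the direction expected of
#' enlarged vessels.
#'
#' @param seed integer RNG seed.
#' @param sampling_rate_hz temporal sampling rate (Hz).
#' @param n_samples_per_aline samples per A-line.
#' @param n_lateral,n_frames lateral and frame dimensions of the volume.
#' @param carrier_freq_hz transducer center frequency (Hz); must satisfy
#'   Nyquist: `carrier_freq_hz < sampling_rate_hz / 2`.
#' @param gaussian_bandwidth_hz SD of the Gaussian pulse spectrum (Hz).
#' @param absorber_positions data.frame with columns `lateral`, `frame`,
#'   `depth_sample`, and optionally `size_um`; `NULL` draws one absorber in
#'   each of a random half of the A-lines.
#' @param absorber_size_um default absorber diameter (um) for positions
#'   without their own `size_um`; 0 means a point absorber.
#' @param amplitude pulse peak amplitude.
#' @param noise_sd SD of additive white Gaussian noise.
#' @return An object of class `rf_phantom_spec`.
#' @seealso [generate_rf_phantom()]
#' @export
rf_phantom_spec <- function(seed = 1L,
                            sampling_rate_hz = 250e6,
                            n_samples_per_aline = 256L,
                            n_lateral = 16L,
                            n_frames = 16L,
                            carrier_freq_hz = 40e6,
                            gaussian_bandwidth_hz = 7.5e6,
                            absorber_positions = NULL,
                            absorber_size_um = 0,
                            amplitude = 1,
                            noise_sd = 0) {
  check_scalar_num(seed, "seed")
  check_scalar_num(sampling_rate_hz, "sampling_rate_hz", lower = 1)
  check_scalar_num(n_samples_per_aline, "n_samples_per_aline", lower = 16)
  check_scalar_num(n_lateral, "n_lateral", lower = 1)
  check_scalar_num(n_frames, "n_frames", lower = 1)
  check_scalar_num(carrier_freq_hz, "carrier_freq_hz", lower = 0)
  check_that(carrier_freq_hz < sampling_rate_hz / 2, "carrier_freq_hz",
             "must be below Nyquist (sampling_rate_hz / 2)")
  check_scalar_num(gaussian_bandwidth_hz, "gaussian_bandwidth_hz", lower = 1)
  check_scalar_num(absorber_size_um, "absorber_size_um", lower = 0)
  check_scalar_num(amplitude, "amplitude", lower = 0)
  check_scalar_num(noise_sd, "noise_sd", lower = 0)
  if (!is.null(absorber_positions)) {
    check_that(is.data.frame(absorber_positions) &&
                 all(c("lateral", "frame", "depth_sample") %in%
                       names(absorber_positions)),
               "absorber_positions",
               "must be a data.frame with lateral, frame, depth_sample")
  }
  structure(list(seed = as.integer(seed),
                 sampling_rate_hz = sampling_rate_hz,
                 n_samples_per_aline = as.integer(n_samples_per_aline),
                 n_lateral = as.integer(n_lateral),
                 n_frames = as.integer(n_frames),
                 carrier_freq_hz = carrier_freq_hz,
                 gaussian_bandwidth_hz = gaussian_bandwidth_hz,
                 absorber_positions = absorber_positions,
                 absorber_size_um = absorber_size_um,
                 amplitude = amplitude,
                 noise_sd = noise_sd),
            class = "rf_phantom_spec")
}

# Effective Gaussian pulse parameters after the absorber-size low-pass.
# Product of N(fc, sf^2) and N(0, fcut^2) profiles in frequency.
effective_pulse <- function(fc, sf, size_um) {
  if (size_um <= 0) return(list(fc = fc, sf = sf))
  fcut <- 1540 / (pi * size_um * 1e-6)  # Hz
  s2 <- 1 / (1 / sf^2 + 1 / fcut^2)
  list(fc = fc * s2 / sf^2, sf = sqrt(s2))
}

#' Generate a synthetic RF volume with known spectral content
#'
#' Builds the volume described by an [rf_phantom_spec()]: each listed
#' absorber adds a Gaussian-modulated cosine pulse to its A-line, then
#' white Gaussian noise is added everywhere. The analytic spectral
#' centroid of the (noise-free) pulse — the effective carrier frequency
#' after the absorber-size low-pass — is attached as attribute
#' `analytic_centroid_hz`, and the realized absorber table as attribute
#' `absorbers`.
#'
#' @param spec an [rf_phantom_spec()].
#' @return An [rf_volume()] with attributes `analytic_centroid_hz` and
#'   `absorbers`.
#' @examples
#' v <- generate_rf_phantom(rf_phantom_spec(seed = 3, noise_sd = 0))
#' attr(v, "analytic_centroid_hz") / 1e6
#' @export
generate_rf_phantom <- function(spec) {
  if (!inherits(spec, "rf_phantom_spec"))
    stop("`spec` must be an rf_phantom_spec", call. = FALSE)
  with_seed(spec$seed, {
    n <- spec$n_samples_per_aline
    nl <- spec$n_lateral; nf <- spec$n_frames
    fs <- spec$sampling_rate_hz
    ab <- spec$absorber_positions
    if (is.null(ab)) {
      all_lines <- expand.grid(lateral = seq_len(nl), frame = seq_len(nf))
      pick <- sample(nrow(all_lines), max(1L, floor(nrow(all_lines) / 2)))
      ab <- all_lines[pick, , drop = FALSE]
      ab$depth_sample <- sample(seq(round(n * 0.25), round(n * 0.75)),
                                nrow(ab), replace = TRUE)
      rownames(ab) <- NULL
    }
    if (is.null(ab$size_um)) ab$size_um <- spec$absorber_size_um

    vol <- array(0, c(n, nl, nf))
    t_idx <- seq_len(n)
    centroids <- numeric(nrow(ab))
    if (spec$amplitude > 0 && nrow(ab) > 0) {
      for (i in seq_len(nrow(ab))) {
        ep <- effective_pulse(spec$carrier_freq_hz,
                              spec$gaussian_bandwidth_hz, ab$size_um[i])
        centroids[i] <- ep$fc
        sigma_t <- 1 / (2 * pi * ep$sf)            # seconds
        tt <- (t_idx - ab$depth_sample[i]) / fs    # seconds from pulse center
        pulse <- spec$amplitude * exp(-tt^2 / (2 * sigma_t^2)) *
          cos(2 * pi * ep$fc * tt)
        vol[, ab$lateral[i], ab$frame[i]] <-
          vol[, ab$lateral[i], ab$frame[i]] + pulse
      }
    }
    if (spec$noise_sd > 0)
      vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), dim(vol))

    out <- rf_volume(vol, sampling_rate_hz = fs)
    attr(out, "analytic_centroid_hz") <-
      if (spec$amplitude > 0 && nrow(ab) > 0) mean(centroids) else NA_real_
    attr(out, "absorbers") <- ab
    out
  })
}
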