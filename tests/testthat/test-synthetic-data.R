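test_that("vessel phantom generation is deterministic and validates its spec", {
  expect_error(vessel_network_spec(mean_diameter_um = 4, pixel_size_um = 3),
               "mean_diameter_um")
  expect_error(vessel_network_spec(branch_prob_per_step = 1.5),
               "branch_prob_per_step")
  expect_error(vessel_network_spec(isolated_fragment_fraction = 1),
               "isolated_fragment_fraction")
  expect_error(vessel_network_spec(sd_diameter_um = -1), "sd_diameter_um")

  a <- small_phantom(31)
  b <- small_phantom(31)
  expect_identical(a, b)
  c <- small_phantom(32)
  expect_false(identical(a$image$intensity, c$image$intensity))
})

test_that("phantom ground truth matches its construction rules", {
  # no fragments requested -> no isolated length
  ph0 <- small_phantom(5, isolated_fragment_fraction = 0)
  expect_identical(ph0$truth$true_isolated_length_um, 0)

  # a single unbranched tree has no branch nodes
  ph1 <- small_phantom(6, n_trees = 1L, branch_prob_per_step = 0,
                       isolated_fragment_fraction = 0)
  expect_identical(ph1$truth$true_n_branch_nodes, 0L)

  ph <- small_phantom(7)
  tr <- ph$truth
  expect_lte(tr$true_isolated_length_um, tr$true_total_centerline_length_um)
  expect_true(all(ph$image$intensity >= 0))
  # the centerline lies inside the rendered tube
  expect_false(any(tr$centerline_mask & !tr$tube_mask))
  # diameters respect the resolvability floor
  expect_true(all(tr$diameters$diameter_um >= 2 * 3))
})

test_that("ground-truth centerline length is self-consistent with the stored mask", {
  for (s in c(3, 14)) {
    ph <- small_phantom(s)
    recomputed <- pamvasc:::centerline_length_px(ph$truth$centerline_mask) * 3
    expect_equal(recomputed, ph$truth$true_total_centerline_length_um,
                 tolerance = 1e-12)
  }
})

test_that("rf phantom validates Nyquist and reproduces its closed-form pulses", {
  expect_error(rf_phantom_spec(carrier_freq_hz = 130e6,
                               sampling_rate_hz = 250e6), "carrier_freq_hz")

  # symmetric Gaussian pulse about the carrier: analytic centroid = carrier
  v <- generate_rf_phantom(rf_phantom_spec(seed = 2, noise_sd = 0))
  expect_equal(attr(v, "analytic_centroid_hz"), 40e6)

  # zero amplitude -> all-zero volume, centroid flagged undefined
  v0 <- generate_rf_phantom(rf_phantom_spec(seed = 2, amplitude = 0))
  expect_true(all(v0$samples == 0))
  expect_true(is.na(attr(v0, "analytic_centroid_hz")))

  # determinism
  expect_identical(generate_rf_phantom(rf_phantom_spec(seed = 9)),
                   generate_rf_phantom(rf_phantom_spec(seed = 9)))

  # direct FFT of a generated noise-free pulse peaks near the carrier and
  # has its centroid there
  spec <- rf_phantom_spec(seed = 4, noise_sd = 0)
  v <- generate_rf_phantom(spec)
  ab <- attr(v, "absorbers")
  pulse <- v$samples[, ab$lateral[1], ab$frame[1]]
  n <- length(pulse)
  P <- Mod(fft(pulse))^2
  nb <- floor(n / 2) + 1
  fr <- (seq_len(nb) - 1) * spec$sampling_rate_hz / n
  expect_equal(sum(fr * P[1:nb]) / sum(P[1:nb]), 40e6, tolerance = 0.005)
})

test_that("absorber size lowers the analytic pulse centroid monotonically", {
  cents <- vapply(c(0, 10, 25, 50), function(d)
    attr(generate_rf_phantom(rf_phantom_spec(seed = 1, noise_sd = 0,
                                             absorber_size_um = d)),
         "analytic_centroid_hz"), numeric(1))
  expect_true(all(diff(cents) < 0))
})

test_that("feature tables are reproducible, nonnegative, and labeled", {
  expect_error(generate_feature_table(
    effect_spec = transform(default_effect_spec(), sd = 0)), "effect_spec")

  t1 <- generate_feature_table(seed = 11)
  t2 <- generate_feature_table(seed = 11)
  expect_identical(t1, t2)
  expect_setequal(setdiff(names(t1), "label"), selected_feature_names())
  expect_equal(as.vector(table(t1$label)), c(10, 30))
  expect_true(all(as.matrix(t1[selected_feature_names()]) >= 0))
})

test_that("null feature tables give calibrated Welch p-values", {
  # no class effect: rejection rate at alpha = 0.05 stays near nominal
  nrep <- 200
  rej <- matrix(FALSE, nrep, 5)
  for (r in seq_len(nrep)) {
    tab <- generate_feature_table(
      effect_spec = default_effect_spec(separation = 0), seed = 7000 + r)
    for (j in 1:5) {
      x <- tab[[selected_feature_names()[j]]]
      rej[r, j] <- welch_t(x[tab$label == "normal_benign"],
                           x[tab$label == "ec_ein"])$p < 0.05
    }
  }
  rate <- colMeans(rej)
  expect_true(all(rate >= 0.02 & rate <= 0.09))
})
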