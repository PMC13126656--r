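test_that("diameter map reproduces forced strip widths", {
  # 11-px-tall bar at 3 um pixels: interior centerline diameter ~ 33 um
  bar <- make_bar_mask(height = 11L, width = 60L)
  mask <- vessel_mask(bar, pixel_size_um = 3)
  sk <- skeletonize_mask(mask)
  dm <- diameter_map(mask, sk)
  interior <- dm$entries[dm$entries$col > 25 & dm$entries$col < 55, ]
  expect_true(all(abs(interior$diameter_um - 33) <= 3))
})

test_that("diameter map equals the exhaustive nearest-background oracle", {
  cases <- list(
    random_blob_mask(201), random_blob_mask(202), random_blob_mask(203))
  for (m in cases) {
    if (!any(m)) next
    mask <- vessel_mask(m, pixel_size_um = 3)
    sk <- skeletonize_mask(mask)
    if (!any(sk$mask)) next
    dm <- diameter_map(mask, sk)
    idx <- which(sk$mask)
    oracle <- brute_nearest_background(m, idx)
    expect_identical(dm$entries$diameter_um, 2 * oracle * 3)
  }

  # mask identical to a 1-px line: distances to the flanking background
  line <- matrix(FALSE, 9, 30); line[5, 3:28] <- TRUE
  mask <- vessel_mask(line, pixel_size_um = 2)
  sk <- skeleton_mask(line, pixel_size_um = 2)
  dm <- diameter_map(mask, sk)
  oracle <- brute_nearest_background(line, which(line))
  expect_identical(dm$entries$diameter_um, 2 * oracle * 2)
})

test_that("diameter map rejects skeletons leaving the mask", {
  m <- make_bar_mask(height = 5L, width = 20L)
  off <- matrix(FALSE, nrow(m), ncol(m)); off[1, 1] <- TRUE
  expect_error(diameter_map(vessel_mask(m), skeleton_mask(off)),
               "skeleton pixel off mask")
})

test_that("morphometric features summarize the diameter distribution", {
  # constant diameters
  bar <- make_bar_mask(height = 11L, width = 60L)
  mask <- vessel_mask(bar, pixel_size_um = 3)
  dmap <- structure(list(
    entries = data.frame(row = rep(23L, 10), col = 20:29,
                         diameter_um = rep(33, 10)),
    pixel_size_um = 3), class = "diameter_map")
  f <- morphometric_features(dmap, mask)
  expect_equal(f$mean_diameter_um, 33)
  expect_equal(f$sd_diameter_um, 0)
  expect_equal(f$min_diameter_um, 33)
  expect_equal(f$max_diameter_um, 33)
  expect_equal(f$median_diameter_um, 33)
  expect_equal(f$vessel_area_fraction, mean(bar))

  # empty map -> all features missing, with a warning
  empty <- structure(list(entries = data.frame(row = integer(0),
                                               col = integer(0),
                                               diameter_um = numeric(0)),
                          pixel_size_um = 3), class = "diameter_map")
  expect_warning(fe <- morphometric_features(empty, mask), "missing")
  expect_true(all(is.na(unlist(fe))))

  # mean/sd match an independent two-pass computation
  ph <- small_phantom(21)
  mk <- binarize(ph$image); sk <- skeletonize_mask(mk)
  dm <- diameter_map(mk, sk)
  fm <- morphometric_features(dm, mk)
  d <- dm$entries$diameter_um
  mu <- sum(d) / length(d)
  s2 <- sum((d - mu)^2) / (length(d) - 1)
  expect_equal(fm$mean_diameter_um, mu, tolerance = 1e-9)
  expect_equal(fm$sd_diameter_um, sqrt(s2), tolerance = 1e-9)
})

test_that("features transform correctly under pixel-size and rigid-motion changes", {
  ph <- small_phantom(22)
  mk <- binarize(ph$image); sk <- skeletonize_mask(mk)
  dm1 <- diameter_map(mk, sk)
  f1 <- morphometric_features(dm1, mk)

  # doubling the pixel size doubles diameters and rescales densities
  mk2 <- vessel_mask(mk$mask, pixel_size_um = 6)
  sk2 <- skeleton_mask(sk$mask, pixel_size_um = 6)
  dm2 <- diameter_map(mk2, sk2)
  f2 <- morphometric_features(dm2, mk2)
  expect_equal(f2$mean_diameter_um, 2 * f1$mean_diameter_um)
  expect_equal(f2$max_diameter_um, 2 * f1$max_diameter_um)
  expect_equal(f2$vessel_density_um_per_um2,
               f1$vessel_density_um_per_um2 / 2)
  expect_equal(f2$intersection_density_per_um2,
               f1$intersection_density_per_um2 / 4)
  expect_equal(f2$vessel_area_fraction, f1$vessel_area_fraction)

  # 90-degree rotation leaves every feature unchanged
  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  mkr <- vessel_mask(rot(mk$mask), pixel_size_um = 3)
  skr <- skeleton_mask(rot(sk$mask), pixel_size_um = 3)
  fr <- morphometric_features(diameter_map(mkr, skr), mkr)
  expect_equal(fr, f1, tolerance = 1e-12)
})
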