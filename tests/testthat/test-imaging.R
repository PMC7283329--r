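make_refs <- function(d, W = 4000, D = 100) {
  list(white = array(W, d), dark = array(D, d))
}

test_that("calibration satisfies the white/dark/midpoint identities", {
  d <- c(4, 5, 3); wl <- c(450, 650, 850)
  r <- make_refs(d)
  expect_equal(calibrate(r$white, r$white, r$dark, wl)$values,
               array(1, d), tolerance = 1e-12)
  expect_equal(calibrate(r$dark, r$white, r$dark, wl)$values,
               array(0, d), tolerance = 1e-12)
  expect_equal(calibrate((r$white + r$dark) / 2, r$white, r$dark, wl)$values,
               array(0.5, d), tolerance = 1e-12)
})

test_that("calibration is invariant to a common positive rescaling", {
  set.seed(2)
  d <- c(3, 3, 4); wl <- seq(500, 800, 100)
  raw <- array(runif(prod(d), 200, 3000), d)
  r <- make_refs(d)
  a <- calibrate(raw, r$white, r$dark, wl)$values
  b <- calibrate(raw * 7.3, r$white * 7.3, r$dark * 7.3, wl)$values
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("calibration rejects non-positive white-dark differences", {
  d <- c(2, 2, 2); wl <- c(500, 600)
  r <- make_refs(d)
  bad_white <- r$white; bad_white[1, 2, 1] <- 50
  err <- tryCatch(calibrate(r$dark, bad_white, r$dark, wl), error = identity)
  expect_s3_class(err, "calibration_error")
  expect_match(conditionMessage(err), "pixel \\(1, 2\\), band 1")
})

test_that("optional clipping bounds the output range", {
  d <- c(2, 2, 2); wl <- c(500, 600)
  r <- make_refs(d)
  hot <- r$white * 1.5
  out <- calibrate(hot, r$white, r$dark, wl, clip = c(0, 1))
  expect_true(all(out$values <= 1))
})

test_that("segmentation recovers the rendered ellipses exactly at zero noise", {
  cfg <- tiny_cfg(seed = 4, noise_sd = 0)
  s <- scene_spectra(cfg)
  expect_identical(s$mask$mask, s$scene$labels > 0L)
})

test_that("segmentation errors on degenerate input", {
  wl <- c(700, 750, 800)
  flat <- hyperspectral_cube(array(0.05, c(20, 20, 3)), wl)
  expect_error(segment_grains(flat), class = "segmentation_error")
  # a single component below min_area is removed, leaving nothing
  v <- array(0.05, c(30, 30, 3))
  v[10:15, 10:15, ] <- 0.6
  cube <- hyperspectral_cube(v, wl)
  expect_error(segment_grains(cube, min_area = 600), class = "segmentation_error")
  expect_error(segment_grains(cube, roi_wavelength = 200), class = "segmentation_error")
})

test_that("segmentation is stable when reapplied to its own mask band", {
  v <- array(0.05, c(30, 30, 3))
  v[5:12, 5:12, ] <- 0.6
  v[20:26, 18:25, ] <- 0.55
  cube <- hyperspectral_cube(v, c(700, 750, 800))
  m1 <- segment_grains(cube, min_area = 5)
  mask_cube <- hyperspectral_cube(array(m1$mask * 1 + 1e-6, c(30, 30, 3)),
                                  cube$wavelengths)
  m2 <- segment_grains(mask_cube, min_area = 5, threshold = 0.5)
  expect_identical(m1$mask, m2$mask)
  expect_identical(m1$labels, m2$labels)
})

test_that("spectrum extraction averages masked pixels per sample", {
  v <- array(0.3, c(10, 10, 3))
  cube <- hyperspectral_cube(v, c(700, 750, 800))
  lab <- matrix(0L, 10, 10); lab[2:4, 2:4] <- 1L; lab[7:9, 7:9] <- 2L
  mask <- structure(list(mask = lab > 0, labels = lab,
                         sample_ids = c("a", "b")), class = "grain_mask")
  sp <- extract_spectra(cube, mask)
  expect_equal(unname(sp$spectra), matrix(0.3, 2, 3))

  # two pixels with spectra a and b average to (a+b)/2
  v2 <- array(0, c(2, 1, 3))
  v2[1, 1, ] <- c(1, 2, 3); v2[2, 1, ] <- c(3, 4, 5)
  cube2 <- hyperspectral_cube(v2, c(700, 750, 800))
  lab2 <- matrix(1L, 2, 1)
  mask2 <- structure(list(mask = lab2 > 0, labels = lab2, sample_ids = "s"),
                     class = "grain_mask")
  expect_equal(unname(extract_spectra(cube2, mask2)$spectra)[1, ], c(2, 3, 4))
})

test_that("extraction is permutation-equivariant in sample order", {
  cfg <- tiny_cfg(seed = 15)
  s <- scene_spectra(cfg)
  perm <- rev(seq_along(s$mask$sample_ids))
  relab <- s$mask$labels
  relab[s$mask$labels > 0] <- match(s$mask$labels[s$mask$labels > 0], perm)
  mask2 <- structure(list(mask = s$mask$mask, labels = relab,
                          sample_ids = s$mask$sample_ids[perm]),
                     class = "grain_mask")
  sp2 <- extract_spectra(s$cube, mask2)
  expect_equal(sp2$spectra[s$spectra$sample_ids, ], s$spectra$spectra)
})

test_that("extracted spectra match the design within the noise budget", {
  cfg <- tiny_cfg(seed = 16, noise_sd = 0.02)
  s <- scene_spectra(cfg)
  npix <- min(tabulate(s$mask$labels[s$mask$labels > 0]))
  tol <- 6 * 0.02 / sqrt(npix)
  design <- s$scene$design[s$spectra$sample_ids, ]
  expect_lt(max(abs(s$spectra$spectra - design)), tol)
})
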