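stats_from <- function(vals) {
  a <- array(vals, c(length(vals), 1, 1))
  roi_stats(a, array(TRUE, dim(a)))
}

test_that("roi_stats returns exact sample mean and n-1 SD", {
  s <- stats_from(c(90, 100, 110))
  expect_equal(s$si_mean, 100)
  expect_equal(s$si_sd, 10)
  expect_equal(s$n_voxels, 3)

  const <- stats_from(rep(7, 40))
  expect_equal(const$si_mean, 7)
  expect_equal(const$si_sd, 0)

  expect_warning(single <- stats_from(5), "single-voxel")
  expect_equal(single$si_sd, 0)

  a <- array(1, c(2, 2, 2))
  expect_error(roi_stats(a, array(FALSE, c(2, 2, 2))), "empty")
})

test_that("SNR and CNR follow their defining ratios and identities", {
  roi <- function(m, s) structure(list(si_mean = m, si_sd = s, n_voxels = 50),
                                  class = "roi_stats")
  bone <- roi(100, 5); muscle <- roi(60, 4); air <- roi(2, 10)
  expect_equal(compute_snr(bone, air), 10)
  expect_equal(compute_snr(roi(0, 1), air), 0)
  expect_equal(compute_cnr(bone, muscle, air), 4)
  expect_equal(compute_cnr(muscle, bone, air), -4)            # antisymmetry
  expect_equal(compute_cnr(bone, bone, air), 0)
  # shared-denominator identity to machine precision
  expect_equal(compute_cnr(bone, muscle, air),
               compute_snr(bone, air) - compute_snr(muscle, air),
               tolerance = 1e-15)
  expect_error(compute_snr(bone, roi(2, 0)), "positive")
  expect_error(compute_cnr(bone, muscle, roi(2, 0)), "positive")
})

test_that("SNR/CNR are scale invariant but not offset invariant", {
  lm <- build_phantom(roi_spec())
  s <- roi_slice_for(lm)
  rois <- derive_roi_masks(lm, s)
  es <- simulate_echo_series(lm, ute_sequence(), noise_sigma = 0.03, seed = 21)
  img <- process_multi_echo(es)
  m1 <- compute_image_metrics(img, rois)
  scaled <- img; scaled$data <- img$data * 3.7
  m2 <- compute_image_metrics(scaled, rois)
  expect_equal(m2$bone_snr, m1$bone_snr, tolerance = 1e-12)
  expect_equal(m2$bone_muscle_cnr, m1$bone_muscle_cnr, tolerance = 1e-12)
  shifted <- img; shifted$data <- img$data + 5
  m3 <- compute_image_metrics(shifted, rois)
  expect_false(isTRUE(all.equal(m3$bone_snr, m1$bone_snr)))
})

test_that("slice CoV reproduces hand-computed values and scale invariance", {
  a <- array(rep(c(90, 100, 110), each = 16), c(4, 4, 3))
  m <- matrix(TRUE, 4, 4)
  expect_equal(slice_cov(a, m, 1:3), 10)            # sd 10 / mean 100
  expect_equal(slice_cov(a * 2.5, m, 1:3), 10)      # scale invariant
  expect_equal(slice_cov(array(5, c(4, 4, 3)), m, 1:3), 0)
  expect_error(slice_cov(a, m, c(1, 3)), "consecutive")
  expect_error(slice_cov(a, m, 1), "at least 2")
  expect_error(slice_cov(a, matrix(FALSE, 4, 4), 1:3), "empty")
  expect_error(slice_cov(a - 100, m, 1:3), "zero")
})

test_that("profiles sample the volume faithfully", {
  a <- array(3.5, c(8, 8, 8))
  p <- extract_profile(a, c(0, 3, 3), c(7, 3, 3), n_samples = 29)
  expect_equal(p$value, rep(3.5, 29))
  expect_equal(p$position, seq(0, 7, length.out = 29))

  withr::local_seed(2)
  a2 <- array(runif(8^3), c(8, 8, 8))
  row <- extract_profile(a2, c(0, 2, 4), c(7, 2, 4), n_samples = 8)
  expect_equal(row$value, a2[, 3, 5])               # voxel centres, exact
  rev_p <- extract_profile(a2, c(7, 2, 4), c(0, 2, 4), n_samples = 8)
  expect_equal(rev_p$value, rev(row$value))
  expect_error(extract_profile(a2, c(-1, 0, 0), c(5, 0, 0)), "outside")
  expect_error(extract_profile(a2, c(0, 0, 0), c(5, 0, 0), n_samples = 1), "n_samples")
})

test_that("FWHM recovers closed-form widths of canonical shapes", {
  # Gaussian peak: FWHM = 2 sqrt(2 ln 2) sigma, within one sample spacing
  x <- seq(-10, 10, by = 0.1)
  sigma <- 2
  g <- tibble::tibble(position = x, value = exp(-x^2 / (2 * sigma^2)))
  fw <- measure_fwhm(g, "peak")
  expect_equal(fw$fwhm, 2 * sqrt(2 * log(2)) * sigma, tolerance = 0.1 / fw$fwhm)

  # rectangular dip of width 4 on a flat baseline, within one spacing
  x2 <- seq(0, 20, by = 0.2)
  rect <- tibble::tibble(position = x2,
                         value = ifelse(x2 >= 8 & x2 < 12, 2, 10))
  fr <- measure_fwhm(rect, "dip")
  expect_lte(abs(fr$fwhm - 4), 0.2)

  # triangular peak of base 8 -> FWHM exactly 4 (similar triangles)
  x3 <- seq(0, 20, by = 0.5)
  tri <- tibble::tibble(position = x3,
                        value = pmax(0, 1 - abs(x3 - 10) / 4))
  ft <- measure_fwhm(tri, "peak")
  expect_equal(ft$fwhm, 4)
})

test_that("FWHM is invariant to amplitude scaling and translation", {
  x <- seq(-8, 8, by = 0.05)
  prof <- tibble::tibble(position = x, value = 3 + exp(-x^2 / 2))
  ref <- measure_fwhm(prof, "peak")$fwhm
  scaled <- tibble::tibble(position = x, value = prof$value * 12.3)
  expect_equal(measure_fwhm(scaled, "peak")$fwhm, ref)
  shifted <- tibble::tibble(position = x + 100, value = prof$value)
  expect_equal(measure_fwhm(shifted, "peak")$fwhm, ref)
})

test_that("FWHM reports no crossing instead of failing", {
  x <- seq(0, 10, by = 0.1)
  mono <- tibble::tibble(position = x, value = x)   # extremum at the end
  expect_true(is.na(measure_fwhm(mono, "peak")$fwhm))
  half_dip <- tibble::tibble(position = x, value = c(rep(10, 50), seq(10, 2, length.out = 51)))
  expect_true(is.na(measure_fwhm(half_dip, "dip")$fwhm))
})
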