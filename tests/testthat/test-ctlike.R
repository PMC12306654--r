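test_that("reciprocal inversion maps the spec fixed points", {
  v <- array(c(1, 2, 0, 0.5), c(2, 2, 1))
  out <- invert_image(v, epsilon = 1e-3)$data
  expect_equal(out[1, 1, 1], 1)      # 1 -> 1
  expect_equal(out[2, 1, 1], 0.5)    # 2 -> 1/2
  expect_equal(out[1, 2, 1], 1000)   # void -> 1/epsilon cap
  expect_equal(out[2, 2, 1], 2)
  expect_error(invert_image(v, epsilon = 0), "epsilon")
  expect_error(invert_image(v, epsilon = -1), "epsilon")
})

test_that("inversion reverses intensity order below the cap", {
  withr::local_seed(1)
  v <- array(runif(1000, 0.01, 2), c(10, 10, 10))
  for (inv in c("reciprocal", "linear")) {
    out <- invert_image(v, epsilon = 1e-3, inversion = inv)$data
    o <- order(v)
    expect_true(all(diff(out[o]) <= 0))
    expect_true(all(is.finite(out)) && all(out >= 0))
  }
})

test_that("first-echo processing depends only on the earliest echo", {
  lm <- build_phantom(tiny_spec())
  es <- simulate_echo_series(lm, ute_sequence(), noise_sigma = 0.05, seed = 4)
  eps <- default_epsilon(es)
  ref <- process_first_echo(es, eps)
  perturbed <- es
  perturbed$volumes[[2]] <- perturbed$volumes[[2]] * 2
  perturbed$volumes[[3]] <- perturbed$volumes[[3]] + 1
  expect_identical(process_first_echo(perturbed, eps)$data, ref$data)
  expect_equal(ref$mode, "first_echo")

  single <- es
  single$volumes <- es$volumes[1]
  single$echo_times <- es$echo_times[1]
  expect_identical(process_first_echo(single, eps)$data,
                   invert_image(es$volumes[[1]], eps)$data)
})

test_that("multi-echo processing equals first-echo processing on identical echoes", {
  lm <- build_phantom(tiny_spec())
  es <- simulate_echo_series(lm, ute_sequence(), noise_sigma = 0.05, seed = 8)
  es$volumes <- list(es$volumes[[1]], es$volumes[[1]], es$volumes[[1]])
  eps <- default_epsilon(es)
  expect_identical(process_multi_echo(es, eps)$data,
                   process_first_echo(es, eps)$data)
})

test_that("multi-echo processing matches the brute-force voxel-loop oracle", {
  withr::local_seed(7)
  vols <- lapply(1:3, function(i) array(runif(16^3, 0, 2), c(16, 16, 16)))
  es <- structure(list(volumes = vols, echo_times = c(1, 2, 3),
                       voxel_size = c(1, 1, 1), sequence = "X"),
                  class = "echo_series")
  eps <- 1e-3
  got <- process_multi_echo(es, eps)$data
  expect_equal(as.vector(got), as.vector(oracle_multi_echo(vols, eps)),
               tolerance = 1e-12)
  expect_equal(process_multi_echo(es, eps)$mode, "multi_echo")

  # tiny hand case: voxel (1,2,3) across echoes -> mean 2 -> 0.5
  one <- lapply(1:3, function(i) array(i, c(1, 1, 1)))
  es1 <- structure(list(volumes = one, echo_times = 1:3,
                        voxel_size = c(1, 1, 1), sequence = "X"),
                   class = "echo_series")
  expect_equal(as.numeric(process_multi_echo(es1, eps)$data), 0.5)
})

test_that("bone appears brighter than muscle after inverting a bone-void image", {
  lm <- build_phantom(roi_spec())
  es <- simulate_echo_series(lm, fe_sequence(), noise_sigma = 0.02, seed = 12)
  img <- process_first_echo(es)
  s <- roi_slice_for(lm)
  rois <- derive_roi_masks(lm, s)
  bone <- roi_stats(img, rois$bone_mask, s)
  muscle <- roi_stats(img, rois$muscle_mask, s)
  expect_gt(bone$si_mean, muscle$si_mean)
})

test_that("echo averaging lowers the air-measured noise of the processed image", {
  lm <- build_phantom(roi_spec())
  s <- roi_slice_for(lm)
  rois <- derive_roi_masks(lm, s)
  wins <- vapply(1:12, function(seed) {
    es <- simulate_echo_series(lm, ute_sequence(), noise_sigma = 0.03, seed = seed)
    eps <- default_epsilon(es)
    sd_first <- roi_stats(process_first_echo(es, eps), rois$air_mask, s)$si_sd
    sd_multi <- roi_stats(process_multi_echo(es, eps), rois$air_mask, s)$si_sd
    sd_multi < sd_first
  }, logical(1))
  # one-sided sign test at alpha = 0.05: >= 10 of 12 successes
  expect_gte(sum(wins), 10)
})

test_that("empty series are rejected", {
  es <- structure(list(volumes = list(), echo_times = numeric(0),
                       voxel_size = c(1, 1, 1), sequence = "X"),
                  class = "echo_series")
  expect_error(process_first_echo(es, 1e-3), "at least one echo")
  expect_error(process_multi_echo(es, 1e-3), "at least one echo")
})
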