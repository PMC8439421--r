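test_that("a noiseless linear voxel is an LTI system (superposition)", {
  # response to a 6-s event equals the 3-s response plus its 3-s shift
  p3 <- new_test_paradigm(duration = 3)
  p6 <- new_test_paradigm(duration = 6)
  hrf <- compact_hrf()
  y3 <- simulate_voxel(p3, hrf, neural_model(), zero_noise())$values
  y6 <- simulate_voxel(p6, hrf, neural_model(), zero_noise())$values
  sig3 <- y3 - 100  # signal part about the raw baseline
  shift <- c(rep(0, 3), sig3[1:(length(sig3) - 3)])
  expect_lt(max(abs((sig3 + shift) - (y6 - 100))), 1e-10)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  par <- generate_paradigm("adaptation", seed = 2)
  a <- simulate_voxel(par, compact_hrf(), neural_model(),
                      noise_model(seed = 7))
  b <- simulate_voxel(par, compact_hrf(), neural_model(),
                      noise_model(seed = 7))
  expect_identical(a$values, b$values)
  d1 <- simulate_dataset(3, seed = 5)
  d2 <- simulate_dataset(3, seed = 5)
  expect_identical(lapply(d1$voxels, function(v) v$runs),
                   lapply(d2$voxels, function(v) v$runs))
})

test_that("per-voxel streams are split: voxel count does not perturb them", {
  small <- simulate_dataset(2, seed = 9)
  big <- simulate_dataset(4, seed = 9)
  expect_identical(small$voxels[[1]]$runs, big$voxels[[1]]$runs)
  expect_identical(small$voxels[[2]]$runs, big$voxels[[2]]$runs)
})

test_that("zero-noise adaptation run rises at 30 s and decays to a pedestal", {
  par <- generate_paradigm("adaptation", seed = 0)
  tc <- simulate_voxel(par, compact_hrf(), neural_model(), zero_noise())
  v <- tc$values
  expect_lt(max(abs(v[1:28] - 100)), 1e-8)  # flat baseline before adaptation
  peak_idx <- which.max(v[1:91])
  expect_gt(peak_idx, 31)                   # rise after adaptation onset
  expect_gt(max(v[31:91]) - 100, 0.5)
  expect_lt(v[90], max(v[31:91]))           # decayed from the early peak
})

test_that("inactive fraction and ground-truth bounds hold", {
  ds <- simulate_dataset(20, seed = 4, active_fraction = 0.5, noise_sd = 0.2)
  gains <- vapply(ds$voxels, function(v) v$neural$base_gain, 0)
  expect_equal(sum(gains == 0), 10)
  mu1 <- vapply(ds$voxels, function(v) v$hrf$mu1, 0)
  expect_true(all(mu1 >= 0.5 & mu1 <= 8))
  b <- hrf_bounds("restricted")
  for (v in ds$voxels) {
    th <- unlist(v$hrf[names(b$lower)])
    expect_true(all(th >= b$lower & th <= b$upper))
  }
})

test_that("invalid generator configs are rejected by field name", {
  expect_error(simulate_dataset(0), "n_voxels")
  expect_error(simulate_dataset(4, active_fraction = 1.2), "active_fraction")
  expect_error(simulate_dataset(4, noise_sd = -1), "noise_sd")
  p <- generate_paradigm("adaptation", seed = 0)
  p$events$onset_s[24] <- p$run_length_s - 1  # event past run end
  expect_error(simulate_voxel(p, compact_hrf()), "past the run end|overlap")
})

test_that("raising the 1-s gain above the 3-s gain raises contrast(1->3)", {
  base <- simulate_dataset(1, seed = 21, noise_sd = 0, drift = NULL,
                           linear_trend = 0)
  boosted <- base
  boosted$voxels[[1]]$neural$duration_gain <- c(`1` = 1.5, `3` = 1, `6` = 1)
  boosted$voxels[[1]]$neural$decrement_duration_gain <- NULL
  boosted$voxels[[1]]$runs$adaptation <- lapply(1:3, function(r) {
    simulate_voxel(base$paradigms$adaptation[[r]], base$voxels[[1]]$hrf,
                   boosted$voxels[[1]]$neural, zero_noise())
  })
  ct <- function(ds) {
    mr <- preprocess_adaptation(ds$voxels[[1]]$runs$adaptation,
                                ds$paradigms$adaptation, voxel_id = 1)
    a1 <- fit_hrf(mr$increment_1, 1, seed = 1, baseline = "trial_mean")
    a3 <- fit_hrf(mr$increment_3, 3, seed = 1, baseline = "trial_mean")
    contrast_index(a1$amplitude, a3$amplitude)$contrast
  }
  expect_gt(ct(boosted), ct(base) + 0.05)
})

test_that("signal band covers the block fundamental and a pure tone", {
  loc <- generate_paradigm("localizer")
  band <- estimate_signal_band(loc, compact_hrf(), power_fraction = 0.95)
  expect_equal(unname(band["f_low"]), 1 / 60, tolerance = 1e-9)
  # pure sinusoid on an exact DFT bin collapses to that bin
  n <- 200
  x <- sin(2 * pi * 0.1 * (0:(n - 1)))
  expect_equal(unname(signal_band(x, 1, 0.9)), c(0.1, 0.1))
  expect_error(signal_band(rep(1, 100)), "degenerate spectrum")
})

test_that("adaptation-run signal stays below the 0.2-Hz low-pass", {
  band <- estimate_signal_band(generate_paradigm("adaptation", seed = 0),
                               compact_hrf(), power_fraction = 0.99)
  expect_lte(unname(band["f_high"]), 0.2)
})

test_that("datasets round-trip through the CSV exporter", {
  ds <- simulate_dataset(3, seed = 13, noise_sd = 0.5)
  dir <- withr::local_tempdir()
  write_dataset_csv(ds, dir)
  back <- read_dataset_csv(dir)
  expect_equal(back$runs$localizer[[2]]$values,
               ds$voxels[[2]]$runs$localizer$values)
  expect_equal(back$runs$adaptation[[3]][[1]]$values,
               ds$voxels[[1]]$runs$adaptation[[3]]$values)
  expect_equal(back$paradigms$adaptation[[2]]$events$onset_s,
               ds$paradigms$adaptation[[2]]$events$onset_s)
})
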