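test_that("FIR r2 is 1 on noiseless block responses, ~0 off-design", {
  loc <- generate_paradigm("localizer")
  stim <- localizer_stimulus(loc)
  tc <- simulate_voxel(loc, compact_hrf(), neural_model(), zero_noise())
  psc <- percent_signal_change(tc)
  est <- fir_r2(psc, stim, L = 25)
  expect_equal(est$r2, 1, tolerance = 1e-9)
  # stimulus-orthogonal input: sinusoid at a non-block frequency, L = 1
  t <- 0:239
  orth <- time_course(sin(2 * pi * 18.5 * t / 240), unit = "percent")
  expect_lt(fir_r2(orth, stim, L = 1)$r2, 0.02)
})

test_that("FIR solution matches a pseudoinverse normal-equations oracle", {
  set.seed(3)
  loc <- generate_paradigm("localizer")
  stim <- localizer_stimulus(loc)
  y <- rnorm(240)
  est <- fir_r2(time_course(y, unit = "percent"), stim, L = 25)
  X <- matrix(0, 240, 25)
  for (lag in 0:24) X[(lag + 1):240, lag + 1] <- stim[1:(240 - lag)]
  D <- cbind(1, X)
  beta <- solve(t(D) %*% D, t(D) %*% y)
  fitted <- drop(D %*% beta)
  r2_oracle <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  expect_lt(max(abs(est$taps - beta[-1])), 1e-10)
  expect_equal(est$r2, r2_oracle, tolerance = 1e-10)
  expect_gt(est$r2, 0)
})

test_that("r2 is invariant to affine rescaling of the course", {
  set.seed(8)
  loc <- generate_paradigm("localizer")
  stim <- localizer_stimulus(loc)
  y <- rnorm(240) + stim
  a <- fir_r2(time_course(y, unit = "percent"), stim, L = 10)$r2
  b <- fir_r2(time_course(3.7 * y + 42, unit = "percent"), stim, L = 10)$r2
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("null thresholds are empirical quantiles with calibrated tails", {
  null <- structure(list(samples = (1:100) / 100, n_samples = 100,
                         statistic = "r2", tail = "upper", seed = 1L),
                    class = "null_distribution")
  expect_equal(null_threshold(null, 0.05), 0.95)
  expect_equal(null_threshold(null, 0.001), 1.00)
  expect_gte(null_threshold(null, 0.01), null_threshold(null, 0.05))
  # fraction of null samples above threshold(0.05) is 0.05 by construction
  set.seed(5)
  s <- rnorm(2000)
  null2 <- structure(list(samples = s, n_samples = 2000, statistic = "r2",
                          tail = "upper", seed = 1L),
                     class = "null_distribution")
  thr <- null_threshold(null2, 0.05)
  expect_equal(mean(s > thr), 0.05, tolerance = 2 * sqrt(0.05 * 0.95 / 2000))
})

test_that("shuffled-course nulls preserve value multisets and calibrate", {
  loc <- generate_paradigm("localizer")
  stim <- localizer_stimulus(loc)
  set.seed(2)
  courses <- lapply(1:3, function(i) time_course(rnorm(240, 100, 1)))
  null <- build_null(courses, stim, n_total = 200, seed = 3)
  expect_length(null$samples, 200)
  expect_true(all(null$samples >= 0 & null$samples <= 1))
  # same machinery, shuffle preserves the multiset
  x <- courses[[1]]$values
  perm <- with(list(), {set.seed(1); sample(x)})
  expect_equal(sort(perm), sort(x))
})

test_that("BH correction equals the brute-force step-up oracle", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04))$adjusted, rep(0.04, 4))
  expect_equal(fdr_bh(0.03)$adjusted, 0.03)
  expect_true(all(fdr_bh(rep(5e-4, 20), q = 0.001)$reject))
  set.seed(11)
  for (i in 1:40) {
    p <- runif(25)^2
    expect_lt(max(abs(fdr_bh(p)$adjusted - bh_oracle(p))), 1e-12)
  }
})

test_that("selection finds a planted active block and obeys cluster rules", {
  # 8 active voxels fill a 2x2x2 block (grid 2x2x3), 4 inactive
  ds <- simulate_dataset(12, seed = 31, active_fraction = 8 / 12,
                         noise_sd = 0.6, grid_dims = c(2, 2, 3))
  stim <- localizer_stimulus(ds$paradigms$localizer)
  courses <- lapply(ds$voxels[1:4], function(v) v$runs$localizer)
  null <- build_null(courses, stim, n_total = 150, seed = 5)
  tab <- select_voxels(ds, null, q = 0.05, min_cluster = 4)
  expect_setequal(tab$voxel_id[tab$selected], 1:8)
  # an isolated significant voxel is dropped by the cluster filter
  tab1 <- select_voxels(ds, null, q = 0.05, min_cluster = 9)
  expect_false(any(tab1$selected))
  expect_true(all(tab$r2[1:8] > tab$r2[9:12]))
})

test_that("sub-threshold data yield an empty selection", {
  ds <- simulate_dataset(4, seed = 17, active_fraction = 0, noise_sd = 1)
  stim <- localizer_stimulus(ds$paradigms$localizer)
  null <- build_null(lapply(ds$voxels, function(v) v$runs$localizer),
                     stim, n_total = 150, seed = 9)
  tab <- select_voxels(ds, null, q = 0.001, min_cluster = 1)
  expect_false(any(tab$selected))
})

test_that("false-selection rate on pure noise is within 2 SE of nominal", {
  # 50 noise datasets of 4 voxels at q = 0.05, min_cluster = 1, no FDR bite:
  # selection uses BH, so the familywise proportion stays conservative;
  # check the raw empirical-FPR calibration instead plus selection <= nominal
  loc <- generate_paradigm("localizer")
  stim <- localizer_stimulus(loc)
  set.seed(23)
  courses <- lapply(1:4, function(i) time_course(rnorm(240, 100, 1)))
  null <- build_null(courses, stim, n_total = 1000, seed = 3)
  n_rep <- 50
  hits <- 0
  n_vox <- 0
  for (r in 1:n_rep) {
    r2s <- vapply(1:4, function(i) {
      tc <- time_course(rnorm(240, 100, 1))
      fir_r2(preprocess_localizer(tc), stim, L = 25)$r2
    }, 0)
    hits <- hits + sum(r2s > null_threshold(null, 0.05))
    n_vox <- n_vox + 4
  }
  # variance of the observed rate has a binomial term and a term from the
  # empirical-quantile threshold itself
  se <- sqrt(0.05 * 0.95 * (1 / n_vox + 1 / null$n_samples))
  expect_lte(hits / n_vox, 0.05 + 2 * se)
})
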