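mk_mr <- function(values, dur, type = "increment") {
  structure(list(values = values, tr_s = 1, n_trials = 12, voxel_id = 1,
                 response_type = type, test_duration_s = dur),
            class = "measured_response")
}

test_that("superposition prediction sums shifted copies with zero padding", {
  imp <- mk_mr(c(1, rep(0, 24)), dur = 1)
  p13 <- superposition_predict(imp, 3)
  expect_equal(p13$values, c(1, 1, 1, rep(0, 22)))
  tri <- mk_mr(c(0, 1, 2, rep(0, 22)), dur = 3)
  p36 <- superposition_predict(tri, 6)
  expect_equal(p36$values, c(0, 1, 2, 0, 1, 2, rep(0, 19)))
  expect_error(superposition_predict(mk_mr(rnorm(25), dur = 3), 5),
               "integer multiple")
})

test_that("superposition is a linear operator", {
  set.seed(4)
  x <- rnorm(25)
  y <- rnorm(25)
  pr <- function(v) superposition_predict(mk_mr(v, 3), 6)$values
  expect_equal(pr(2 * x - 5 * y), 2 * pr(x) - 5 * pr(y))
})

test_that("prediction matches the simulated long response for an LTI voxel", {
  hrf <- compact_hrf()
  m3 <- mk_mr(hrf_boxcar_response(hrf, 3), 3)
  m6 <- hrf_boxcar_response(hrf, 6)
  p <- superposition_predict(m3, 6)
  expect_lt(max(abs(p$values - m6)), 1e-8)
})

test_that("Dice index obeys its defining identities", {
  m <- as.numeric(1:25)
  expect_equal(dice_index(m, m), 1)
  expect_equal(dice_index(-m, m), -1)
  expect_equal(dice_index(c(2, rep(0, 24)), c(1, rep(0, 24))), 0.8)
  expect_error(dice_index(rep(0, 25), rep(0, 25)), "undefined similarity")
  # scale sensitivity: dice(kM, M) = 2k / (k^2 + 1)
  set.seed(6)
  M <- rnorm(25)
  for (k in c(0.5, 1, 2)) {
    expect_equal(dice_index(k * M, M), 2 * k / (k^2 + 1), tolerance = 1e-12)
  }
  # bounds on random nonzero inputs
  for (i in 1:50) {
    a <- rnorm(25)
    b <- rnorm(25)
    d <- dice_index(a, b)
    expect_true(d >= -1 && d <= 1)
  }
  # invariant to a joint sign flip (decrement mirror of an increment voxel)
  expect_equal(dice_index(-M, -(M + 0.3)), dice_index(M, M + 0.3))
})

test_that("chance thresholds follow the empirical quantile and monotonicity", {
  null <- structure(list(samples = (1:100) / 100, n_samples = 100,
                         statistic = "dice", tail = "upper", seed = 1L),
                    class = "null_distribution")
  expect_equal(dice_chance_threshold(null, 0.05), 0.95)
  sym <- structure(list(samples = seq(-1, 1, length.out = 201),
                        n_samples = 201, statistic = "dice", tail = "upper",
                        seed = 1L), class = "null_distribution")
  expect_equal(dice_chance_threshold(sym, 0.5), 0, tolerance = 0.011)
  expect_gte(dice_chance_threshold(null, 0.01), dice_chance_threshold(null, 0.05))
  r2null <- structure(list(samples = 1:10 / 10, statistic = "r2"),
                      class = "null_distribution")
  expect_error(dice_chance_threshold(r2null, 0.05), "Dice null")
})

test_that("Dice calibration: noise exceeds the 5% threshold 5% of the time", {
  set.seed(12)
  null_draws <- replicate(1500, {
    dice_index(rnorm(25), rnorm(25))
  })
  null <- structure(list(samples = null_draws, n_samples = 1500,
                         statistic = "dice", tail = "upper", seed = 1L),
                    class = "null_distribution")
  thr <- dice_chance_threshold(null, 0.05)
  fresh <- replicate(1500, dice_index(rnorm(25), rnorm(25)))
  se <- sqrt(0.05 * 0.95 / 1500)
  expect_lt(abs(mean(fresh > thr) - 0.05), 2 * se)
})

test_that("an LTI dataset scores near-perfect Dice in all six conditions", {
  ds <- linear_dataset(6)
  lin <- evaluate_linearity(measured_for(ds))
  expect_true(all(lin$table$dice >= 0.99))
  expect_equal(nrow(lin$table), 6 * 6)
})

test_that("onset/offset transients hurt 1-s-based predictions most", {
  ds <- cached("overest_12", simulate_dataset(12, seed = 42,
                                              nonlinearity = "overest",
                                              noise_sd = 1))
  lin <- evaluate_linearity(measured_for(ds))
  med <- lin$summary$median_dice
  get <- function(type, pair) med$dice[med$response_type == type &
                                         med$pair == pair]
  expect_lt(get("increment", "1->6"), get("increment", "3->6"))
  expect_lt(get("decrement", "1->6"), get("decrement", "3->6"))
})

test_that("dice_null pools pipeline-faithful shuffled statistics", {
  ds <- linear_dataset(2)
  filtered <- lapply(ds$voxels[[1]]$runs$adaptation, function(tc) {
    fourier_filter(percent_signal_change(tc, 90), high_cut_hz = 0.2,
                   detrend = TRUE)
  })
  null <- dice_null(filtered, ds$paradigms$adaptation, n_total = 60,
                    seed = 2)
  expect_gte(null$n_samples, 60)
  expect_true(all(abs(null$samples) <= 1))
  expect_identical(null$samples,
                   dice_null(filtered, ds$paradigms$adaptation,
                             n_total = 60, seed = 2)$samples)
  # shuffled-course Dice should hover near zero, far below the LTI values
  expect_lt(abs(median(null$samples)), 0.3)
})
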