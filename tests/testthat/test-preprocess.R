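test_that("percent signal change is 100*(x - m)/m over the retained part", {
  tc <- time_course(rep(100, 50))
  expect_equal(percent_signal_change(tc)$values, rep(0, 50))
  tc2 <- time_course(c(90, 110))
  expect_equal(percent_signal_change(tc2)$values, c(-10, 10))
  long <- time_course(rnorm(890, mean = 100, sd = 1))
  out <- percent_signal_change(long, n_discard = 90)
  expect_length(out$values, 800)
  expect_equal(mean(out$values), 0)
  expect_error(percent_signal_change(time_course(c(-1, -1, -1))),
               "invalid baseline")
})

test_that("fourier_filter removes trends and masks bins like an FFT oracle", {
  n <- 400
  t <- 0:(n - 1)
  ramp <- time_course(5 + 0.02 * t)
  out <- fourier_filter(ramp, detrend = TRUE)
  expect_lt(max(abs(out$values)), 1e-10)

  tone <- function(f) time_course(sin(2 * pi * f * t))
  keep <- fourier_filter(tone(0.1), 0.0125, 0.2)
  expect_lt(max(abs(keep$values - tone(0.1)$values)), 1e-8)
  kill <- fourier_filter(tone(0.3), high_cut_hz = 0.2)
  expect_lt(max(abs(kill$values)), 1e-8)
  expect_error(fourier_filter(tone(0.1), low_cut_hz = 0.6), "Nyquist")
})

test_that("fourier_filter is idempotent and never gains energy", {
  set.seed(42)
  for (i in 1:5) {
    tc <- time_course(rnorm(300) + 0.01 * (1:300))
    # the DFT mask is a projection: exactly idempotent
    once <- fourier_filter(tc, 0.0125, 0.2)
    twice <- fourier_filter(once, 0.0125, 0.2)
    expect_lt(max(abs(twice$values - once$values)), 1e-10)
    # detrend + mask never increases total energy (both are projections)
    full <- fourier_filter(tc, 0.0125, 0.2, detrend = TRUE)
    expect_lte(sum(full$values^2), sum(tc$values^2) + 1e-9)
    expect_lte(sum(once$values^2), sum(tc$values^2) + 1e-9)
  }
})

test_that("component high-pass removes components 1..k and keeps the rest", {
  n <- 372
  t <- 0:(n - 1)
  comp_tone <- function(k) time_course(cos(2 * pi * k * t / n))
  hp <- highpass_by_component(comp_tone(12), k = 10)
  expect_lt(max(abs(hp$values - comp_tone(12)$values)), 1e-8)
  expect_equal(attr(hp, "cutoff_hz"), 10 / 372)
  gone <- highpass_by_component(comp_tone(5), k = 10)
  expect_lt(max(abs(gone$values)), 1e-8)
  gone10 <- highpass_by_component(comp_tone(10), k = 10)
  expect_lt(max(abs(gone10$values)), 1e-8)
  expect_error(highpass_by_component(comp_tone(2), k = 200), "length > 2k")
})

test_that("trial windows follow the volume-numbering convention", {
  # 1-s stimulus at 200 s -> volumes 201-231 (1-based), 31 samples
  run <- time_course(seq_len(300), unit = "percent")
  events <- data.frame(onset_s = 200, duration_s = 1,
                       response_type = "increment", test_duration_s = 1,
                       stringsAsFactors = FALSE)
  par <- boldlin:::new_paradigm(events, 300, 1, "adaptation")
  rec <- extract_and_recombine(list(run), list(par), "increment", 1)
  expect_length(rec$values, 31)
  expect_equal(rec$values, as.numeric(201:231))
})

test_that("recombination across 3 runs gives 12 trials and 372 samples", {
  ds <- linear_dataset(2)
  filtered <- lapply(ds$voxels[[1]]$runs$adaptation, function(tc) {
    fourier_filter(percent_signal_change(tc, 90), high_cut_hz = 0.2,
                   detrend = TRUE)
  })
  rec <- extract_and_recombine(filtered, ds$paradigms$adaptation,
                               "increment", 1, offset_s = 90)
  expect_length(rec$values, 31 * 12)
  mr <- preprocess_adaptation(ds$voxels[[1]]$runs$adaptation,
                              ds$paradigms$adaptation, voxel_id = 1)
  expect_length(mr, 6)
  expect_true(all(vapply(mr, function(m) length(m$values), 0) == 25))
  expect_true(all(vapply(mr, function(m) m$n_trials, 0) == 12))
  expect_error(extract_and_recombine(filtered, ds$paradigms$adaptation,
                                     "increment", 2, offset_s = 90),
               "absent")
})

test_that("measured_response averages trials and truncates to 25 samples", {
  trial <- sin(seq(0, 3, length.out = 31))
  rec <- time_course(rep(trial, 12), unit = "percent")
  mr <- measured_response(rec, 31)
  expect_equal(mr$values, trial[1:25])
  alt <- time_course(c(rep(trial, 6), rep(-trial, 6)), unit = "percent")
  expect_equal(measured_response(alt, 31)$values, rep(0, 25))
  expect_error(measured_response(rec, 30), "divisible")
})

test_that("preprocessing is linear on equal-baseline raw courses", {
  set.seed(7)
  base <- 100
  a <- rnorm(890, sd = 0.5)
  b <- rnorm(890, sd = 0.5)
  chain <- function(x) {
    tc <- time_course(base + x)
    # shift so the retained-part mean is the shared baseline
    tc$values <- tc$values - mean(tc$values[-(1:90)]) + base
    psc <- percent_signal_change(tc, 90)
    fourier_filter(psc, high_cut_hz = 0.2, detrend = TRUE)$values
  }
  lhs_ <- chain(a + b)
  rhs <- chain(a) + chain(b)
  expect_lt(max(abs(lhs_ - rhs)), 1e-8)
})

test_that("round-trip: pipeline reproduces the forward event response", {
  # zero-noise linear voxel: the measured response must match the
  # forward-model event response up to filter edge effects (< 2% RMS)
  ds <- linear_dataset(2)
  vox <- ds$voxels[[1]]
  mr <- preprocess_adaptation(vox$runs$adaptation, ds$paradigms$adaptation,
                              voxel_id = 1)
  for (dur in c(1, 3, 6)) {
    truth_full <- hrf_boxcar_response(vox$hrf, dur, n_out = dur + 30)
    truth <- (truth_full - mean(truth_full))[1:25]
    got <- mr[[paste0("increment_", dur)]]$values
    rel_rms <- sqrt(mean((got - truth)^2)) / sqrt(mean(truth^2))
    expect_lt(rel_rms, 0.02)
  }
})
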