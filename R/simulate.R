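#' BOLD time-course container
#'
#' @param values Numeric series (raw scanner units or percent signal change).
#' @param tr_s Repetition time (s).
#' @param unit `"raw"` or `"percent"`.
#' @param origin Optional provenance tag (run / condition).
#' @return A `time_course` object.
#' @export
time_course <- function(values, tr_s = 1, unit = c("raw", "percent"),
                        origin = NULL) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) < 2L) stop("time course must have length >= 2")
  if (!all(is.finite(values))) stop("time course values must be finite")
  stopifnot_scalar(tr_s, "tr_s", positive = TRUE)
  structure(list(values = values, tr_s = tr_s, unit = unit, origin = origin),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> n=%d, TR=%g s, unit=%s%s\n", length(x$values),
              x$tr_s, x$unit,
              if (is.null(x$origin)) "" else paste0(", origin=", x$origin)))
  invisible(x)
}

#' Neural drive model for the synthetic generator
#'
#' The neural drive to a test event is a boxcar whose height is
#' `base_gain * duration_gain[duration]`, negated and scaled by
#' `decrement_ratio` for contrast decrements (decrements carry less signal
#' than increments). Optional additions emulate known sources of BOLD
#' nonlinearity: transient activity bursts of fixed size at stimulus onset
#' and offset (relatively larger for short stimuli, hence overestimation for
#' increments and underestimation for decrements), and exponential
#' habituation of the sustained response. The adaptation-phase pedestal is
#' the drive to the 25%-contrast adapting stimulus: a sustained level plus
#' an initial exponentially decaying transient starting at adaptation onset.
#'
#' With `duration_gain` all 1, no transients and `habituation_tau_s = Inf`
#' the drive is an exact boxcar and the voxel is a perfectly linear
#' time-invariant system.
#'
#' @param base_gain Response gain for the test contrast step (0 = inactive
#'   voxel).
#' @param duration_gain Named numeric vector mapping test durations (`"1"`,
#'   `"3"`, `"6"`) to multiplicative amplitude factors, applied to
#'   increments.
#' @param decrement_duration_gain Like `duration_gain` but for decrements;
#'   `NULL` means use `duration_gain`.
#' @param decrement_ratio Magnitude of the decrement drive relative to the
#'   increment drive.
#' @param transient List with `amplitude` and `width_s`: positive drive
#'   bursts added at each test-stimulus onset and offset (both response
#'   types), scaled by `base_gain`.
#' @param habituation_tau_s Exponential decay constant of the sustained
#'   drive within an event (`Inf` = none).
#' @param adaptation_baseline List with `amplitude`, `sustained`, `tau_s`
#'   describing the adaptation-phase pedestal drive (scaled by `base_gain`).
#' @return A `neural_model` object.
#' @export
neural_model <- function(base_gain = 1,
                         duration_gain = c(`1` = 1, `3` = 1, `6` = 1),
                         decrement_duration_gain = NULL,
                         decrement_ratio = 0.6,
                         transient = list(amplitude = 0, width_s = 0.5),
                         habituation_tau_s = Inf,
                         adaptation_baseline = list(amplitude = 1,
                                                    sustained = 0.3,
                                                    tau_s = 15)) {
  stopifnot_scalar(base_gain, "base_gain")
  if (!all(is.finite(duration_gain))) stop("duration_gain must be finite")
  if (!(is.infinite(habituation_tau_s) || habituation_tau_s > 0)) {
    stop("habituation_tau_s must be > 0 or Inf")
  }
  if (adaptation_baseline$tau_s <= 0) {
    stop("adaptation_baseline tau_s must be > 0")
  }
  if (decrement_ratio < 0) stop("decrement_ratio must be >= 0")
  structure(list(base_gain = base_gain,
                 duration_gain = duration_gain,
                 decrement_duration_gain = decrement_duration_gain,
                 decrement_ratio = decrement_ratio,
                 transient = transient,
                 habituation_tau_s = habituation_tau_s,
                 adaptation_baseline = adaptation_baseline),
            class = "neural_model")
}

#' Additive noise model for the synthetic generator
#'
#' @param white_sd Standard deviation of white noise (percent-signal units).
#' @param drift Data frame with columns `freq_hz`, `amplitude`: low-frequency
#'   sinusoidal drift components (random phase per run). Frequencies should
#'   stay below the 0.0125-Hz high-pass so the preprocessing can remove them.
#' @param linear_trend Percent-signal drift across one run (peak-to-peak).
#' @param seed Integer seed of the noise stream.
#' @return A `noise_model` object.
#' @export
noise_model <- function(white_sd = 1,
                        drift = data.frame(freq_hz = c(0.005, 0.009),
                                           amplitude = c(0.5, 0.3)),
                        linear_trend = 0.5, seed = 1L) {
  if (white_sd < 0) stop("white_sd must be >= 0")
  if (!is.null(drift) && nrow(drift) > 0 && any(drift$freq_hz <= 0)) {
    stop("drift frequencies must be > 0")
  }
  structure(list(white_sd = white_sd, drift = drift,
                 linear_trend = linear_trend, seed = as.integer(seed)),
            class = "noise_model")
}

# Gain lookup: durations outside the map (e.g. 30-s localizer blocks) get 1.
event_gain <- function(neural, duration_s, response_type) {
  map <- neural$duration_gain
  if (response_type == "decrement" &&
      !is.null(neural$decrement_duration_gain)) {
    map <- neural$decrement_duration_gain
  }
  key <- as.character(duration_s)
  g <- if (key %in% names(map)) unname(map[key]) else 1
  if (response_type == "decrement") -neural$decrement_ratio * g else g
}

# Neural drive on the fine grid (dt seconds) for one run.
neural_drive <- function(paradigm, neural, dt) {
  n_fine <- round(paradigm$run_length_s / dt)
  t_fine <- (seq_len(n_fine) - 1L) * dt
  drive <- numeric(n_fine)
  ev <- paradigm$events
  for (i in seq_len(nrow(ev))) {
    on <- ev$onset_s[i]
    dur <- ev$duration_s[i]
    idx <- which(t_fine >= on & t_fine < on + dur)
    amp <- neural$base_gain * event_gain(neural, ev$test_duration_s[i],
                                         ev$response_type[i])
    shape <- rep(1, length(idx))
    if (is.finite(neural$habituation_tau_s)) {
      shape <- exp(-(t_fine[idx] - on) / neural$habituation_tau_s)
    }
    drive[idx] <- drive[idx] + amp * shape
    tramp <- neural$transient
    if (!is.null(tramp) && tramp$amplitude != 0) {
      for (t0 in c(on, on + dur)) {
        bidx <- which(t_fine >= t0 & t_fine < t0 + tramp$width_s)
        drive[bidx] <- drive[bidx] + neural$base_gain * tramp$amplitude
      }
    }
  }
  if (paradigm$kind == "adaptation") {
    ab <- neural$adaptation_baseline
    t_adapt <- 30
    idx <- which(t_fine >= t_adapt)
    drive[idx] <- drive[idx] + neural$base_gain *
      (ab$sustained + ab$amplitude * exp(-(t_fine[idx] - t_adapt) / ab$tau_s))
  }
  drive
}

#' Simulate one voxel's raw BOLD time course for a run
#'
#' Forward model: the neural drive (boxcar events, optional transients and
#' habituation, adaptation pedestal) is built at `dt`-second resolution,
#' convolved with the voxel's two-gamma HRF, and sampled at the TR; seeded
#' white noise, sinusoidal drift and a linear trend (percent-signal units)
#' are added, and the sum is mapped onto a raw baseline of 100 scanner
#' units. Decrement events contribute with negative sign. With an all-zero
#' noise model and unit duration gains the output is an exactly linear
#' time-invariant response.
#'
#' @param paradigm A [generate_paradigm()] object.
#' @param hrf An [hrf_params()] object (ground-truth HRF).
#' @param neural A [neural_model()].
#' @param noise A [noise_model()].
#' @param dt Fine-grid step (s).
#' @return A raw-unit [time_course()].
#' @export
simulate_voxel <- function(paradigm, hrf, neural = neural_model(),
                           noise = noise_model(), dt = 0.1) {
  validate_paradigm(paradigm)
  drive <- neural_drive(paradigm, neural, dt)
  n_fine <- length(drive)
  t_fine <- (seq_len(n_fine) - 1L) * dt
  h <- hrf_eval(hrf, t_fine)
  sig_fine <- stats::convolve(drive, rev(h), type = "open")[seq_len(n_fine)] * dt
  n_vol <- round(paradigm$run_length_s / paradigm$tr_s)
  idx <- round((seq_len(n_vol) - 1L) * paradigm$tr_s / dt) + 1L
  signal <- sig_fine[idx]
  t_vol <- (seq_len(n_vol) - 1L) * paradigm$tr_s
  noise_series <- with_seed(noise$seed, {
    out <- stats::rnorm(n_vol, sd = noise$white_sd)
    if (!is.null(noise$drift) && nrow(noise$drift) > 0) {
      for (i in seq_len(nrow(noise$drift))) {
        phase <- stats::runif(1, 0, 2 * pi)
        out <- out + noise$drift$amplitude[i] *
          sin(2 * pi * noise$drift$freq_hz[i] * t_vol + phase)
      }
    }
    out + noise$linear_trend * (t_vol / max(t_vol) - 0.5)
  })
  raw <- 100 * (1 + (signal + noise_series) / 100)
  time_course(raw, tr_s = paradigm$tr_s, unit = "raw",
              origin = paradigm$kind)
}

# Ground-truth HRF sampler: uniform within a plausible interior of the
# restricted box so fits never sit on a bound.
sample_hrf_truth <- function(sign = 1) {
  hrf_params(
    A = stats::runif(1, 3, 8),
    mu1 = stats::runif(1, 4, 7),
    mu2 = stats::runif(1, 9, 14),
    beta1 = stats::runif(1, 0.8, 1.6),
    beta2 = stats::runif(1, 0.8, 1.6),
    c = stats::runif(1, 0.2, 0.5),
    t_onset = stats::runif(1, 0, 1.5),
    sign = sign,
    bounds_mode = "restricted"
  )
}

nonlinearity_presets <- function(kind) {
  switch(kind,
    none = list(duration_gain = c(`1` = 1, `3` = 1, `6` = 1),
                dec_gain = c(`1` = 1, `3` = 1, `6` = 1),
                transient_amp = 0),
    overest = list(duration_gain = c(`1` = 1.6, `3` = 1.15, `6` = 1),
                   dec_gain = c(`1` = 1.6, `3` = 1.15, `6` = 1),
                   transient_amp = 0.8),
    underest = list(duration_gain = c(`1` = 0.7, `3` = 0.9, `6` = 1),
                    dec_gain = c(`1` = 0.7, `3` = 0.9, `6` = 1),
                    transient_amp = 0),
    mixed = list(duration_gain = c(`1` = 1.6, `3` = 1.15, `6` = 1),
                 dec_gain = NULL,  # sampled per voxel, under- to over-
                 transient_amp = 0.8),
    stop("unknown nonlinearity preset: ", kind)
  )
}

#' Simulate a full synthetic dataset
#'
#' Generates one localizer paradigm, three adaptation paradigms (independent
#' seeded trial orders) and, for each voxel, ground-truth HRF parameters
#' inside the restricted bounds, a neural model per the requested
#' nonlinearity preset, and raw time courses for all four runs. Voxels are
#' laid out on a 3D grid (filled x-fastest) so cluster-based selection can
#' be exercised; the first `round(active_fraction * n_voxels)` voxels are
#' active, the rest have `base_gain = 0`. Per-voxel random streams are split
#' from the master seed, so adding voxels never perturbs earlier ones.
#'
#' @param n_voxels Number of voxels (>= 1).
#' @param seed Master seed.
#' @param active_fraction Fraction of active voxels.
#' @param nonlinearity `"none"`, `"overest"`, `"underest"` or `"mixed"`
#'   (increments overestimating, decrements spanning under- to
#'   overestimation).
#' @param noise_sd White-noise SD (percent signal); 0 gives deterministic
#'   noiseless courses.
#' @param drift,linear_trend Passed to [noise_model()]; `drift = NULL`
#'   disables sinusoidal drift.
#' @param grid_dims Integer triple; defaults to a near-cubic box that holds
#'   `n_voxels`.
#' @return A `synthetic_dataset`: list with `voxels` (each `voxel_id`,
#'   `coords`, `hrf`, `neural`, `runs$localizer`, `runs$adaptation[[r]]`),
#'   `paradigms` (`localizer`, `adaptation` list of 3), `seed`, `config`.
#' @export
simulate_dataset <- function(n_voxels, seed = 1L, active_fraction = 1,
                             nonlinearity = "none", noise_sd = 1,
                             drift = data.frame(freq_hz = c(0.005, 0.009),
                                                amplitude = c(0.5, 0.3)),
                             linear_trend = 0.5, grid_dims = NULL) {
  if (!is.numeric(n_voxels) || n_voxels < 1) {
    stop("invalid config: n_voxels must be >= 1")
  }
  if (!is.numeric(active_fraction) || active_fraction < 0 ||
      active_fraction > 1) {
    stop("invalid config: active_fraction must be in [0, 1]")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("invalid config: noise_sd must be >= 0")
  }
  preset <- nonlinearity_presets(nonlinearity)
  n_voxels <- as.integer(n_voxels)
  if (is.null(grid_dims)) {
    side <- ceiling(n_voxels^(1 / 3))
    nz <- ceiling(n_voxels / side^2)
    grid_dims <- c(side, side, nz)
  }
  if (prod(grid_dims) < n_voxels) {
    stop("invalid config: grid_dims too small for n_voxels")
  }
  coords <- arrayInd(seq_len(n_voxels), .dim = grid_dims)
  loc <- generate_paradigm("localizer")
  adapt <- lapply(1:3, function(r) {
    generate_paradigm("adaptation", seed = child_seed(seed, 100L + r))
  })
  n_active <- round(active_fraction * n_voxels)
  voxels <- vector("list", n_voxels)
  for (v in seq_len(n_voxels)) {
    vseed <- child_seed(seed, v)
    active <- v <= n_active
    vox <- with_seed(vseed, {
      hrf <- sample_hrf_truth(sign = 1)
      dec_gain <- preset$dec_gain
      if (is.null(dec_gain)) {
        g1 <- stats::runif(1, 0.6, 1.6)  # per-voxel under- to overestimation
        dec_gain <- c(`1` = g1, `3` = stats::runif(1, 0.85, 1.15), `6` = 1)
      }
      neural <- neural_model(
        base_gain = if (active) 1 else 0,
        duration_gain = preset$duration_gain,
        decrement_duration_gain = dec_gain,
        transient = list(amplitude = preset$transient_amp, width_s = 0.5)
      )
      list(hrf = hrf, neural = neural)
    })
    runs <- list(
      localizer = simulate_voxel(loc, vox$hrf, vox$neural,
                                 noise_model(noise_sd, drift, linear_trend,
                                             seed = child_seed(vseed, 1L))),
      adaptation = lapply(1:3, function(r) {
        simulate_voxel(adapt[[r]], vox$hrf, vox$neural,
                       noise_model(noise_sd, drift, linear_trend,
                                   seed = child_seed(vseed, 1L + r)))
      })
    )
    voxels[[v]] <- list(voxel_id = v, coords = coords[v, ], active = active,
                        hrf = vox$hrf, neural = vox$neural, runs = runs)
  }
  structure(
    list(voxels = voxels,
         paradigms = list(localizer = loc, adaptation = adapt),
         seed = as.integer(seed),
         config = list(n_voxels = n_voxels, active_fraction = active_fraction,
                       nonlinearity = nonlinearity, noise_sd = noise_sd,
                       linear_trend = linear_trend, grid_dims = grid_dims)),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d voxels (%s nonlinearity, noise_sd=%g), seed=%d\n",
    length(x$voxels), x$config$nonlinearity, x$config$noise_sd, x$seed))
  invisible(x)
}

#' Narrowest frequency band holding a given fraction of signal power
#'
#' @param values Numeric series.
#' @param tr_s Sampling interval (s).
#' @param power_fraction Fraction of non-DC spectral power the band must
#'   contain (0 < f < 1).
#' @return Numeric `c(f_low, f_high)` in Hz.
#' @export
signal_band <- function(values, tr_s = 1, power_fraction = 0.95) {
  if (power_fraction <= 0 || power_fraction >= 1) {
    stop("power_fraction must be in (0, 1)")
  }
  n <- length(values)
  spec <- Mod(stats::fft(values - mean(values)))^2
  k <- seq_len(floor(n / 2))  # positive-frequency bins, DC excluded
  p <- spec[k + 1L]
  total <- sum(p)
  if (total <= .Machine$double.eps * n) stop("degenerate spectrum")
  target <- power_fraction * total
  best <- NULL
  j <- 0L
  acc <- 0
  for (i in seq_along(p)) {
    if (j < i - 1L) {
      j <- i - 1L
      acc <- 0
    }
    while (acc < target && j < length(p)) {
      j <- j + 1L
      acc <- acc + p[j]
    }
    if (acc >= target) {
      if (is.null(best) || (j - i) < (best[2] - best[1])) best <- c(i, j)
    } else {
      break
    }
    acc <- acc - p[i]
  }
  freqs <- k / (n * tr_s)
  c(f_low = freqs[best[1]], f_high = freqs[best[2]])
}

#' Signal band of the noiseless response to a paradigm
#'
#' Simulates the noiseless, perfectly linear BOLD response of a voxel with
#' the given HRF to the paradigm and locates the narrowest contiguous
#' frequency interval containing `power_fraction` of the non-DC power. This
#' is how the pass band of the preprocessing filters is justified: the
#' localizer band starts at the block fundamental (1/60 Hz) and the
#' adaptation-run signal lives below 0.2 Hz. For adaptation runs the first
#' 90 s (baseline + adaptation transient) are dropped first, mirroring the
#' preprocessing.
#'
#' @param paradigm A [generate_paradigm()] object.
#' @param hrf An [hrf_params()] object.
#' @param power_fraction Fraction of power the band must contain.
#' @return Numeric `c(f_low, f_high)` in Hz.
#' @export
estimate_signal_band <- function(paradigm, hrf, power_fraction = 0.95) {
  tc <- simulate_voxel(paradigm, hrf, neural_model(),
                       noise_model(white_sd = 0, drift = NULL,
                                   linear_trend = 0, seed = 0L))
  vals <- tc$values
  if (paradigm$kind == "adaptation") {
    vals <- vals[-seq_len(round(90 / paradigm$tr_s))]
  }
  signal_band(vals, tr_s = paradigm$tr_s, power_fraction = power_fraction)
}
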