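#' Convert a raw time course to percent signal change
#'
#' Drops the first `n_discard` volumes (baseline + adaptation transient for
#' adaptation runs), then expresses the retained part as
#' `100 * (x - m) / m` about its own mean `m`.
#'
#' @param tc A raw-unit [time_course()].
#' @param n_discard Number of leading volumes to discard.
#' @return A percent-unit [time_course()] of length
#'   `length(tc$values) - n_discard`.
#' @export
percent_signal_change <- function(tc, n_discard = 0) {
  stopifnot(inherits(tc, "time_course"))
  if (n_discard >= length(tc$values)) stop("n_discard leaves no data")
  x <- if (n_discard > 0) tc$values[-seq_len(n_discard)] else tc$values
  m <- mean(x)
  if (m <= 0) stop("invalid baseline")
  time_course(100 * (x - m) / m, tr_s = tc$tr_s, unit = "percent",
              origin = tc$origin)
}

# Least-squares removal of mean and linear trend.
detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::lm.fit(cbind(1, t), x)$residuals
}

#' Hard Fourier band-pass filter
#'
#' Mimics AFNI 3dFourier-style temporal filtering: optionally removes the
#' mean and linear trend by least squares, then zeroes every discrete
#' Fourier bin whose frequency is strictly below `low_cut_hz` or strictly
#' above `high_cut_hz` (brick-wall mask; DC counts as frequency 0) and
#' inverse-transforms. Output is real and the same length as the input.
#'
#' @param tc A [time_course()].
#' @param low_cut_hz High-pass cutoff (Hz) or `NULL`.
#' @param high_cut_hz Low-pass cutoff (Hz) or `NULL`.
#' @param detrend Remove mean and linear trend first?
#' @return Filtered [time_course()].
#' @export
fourier_filter <- function(tc, low_cut_hz = NULL, high_cut_hz = NULL,
                           detrend = FALSE) {
  stopifnot(inherits(tc, "time_course"))
  n <- length(tc$values)
  nyquist <- 1 / (2 * tc$tr_s)
  for (cut in c(low_cut_hz, high_cut_hz)) {
    if (!is.null(cut) && (cut <= 0 || cut > nyquist)) {
      stop("filter cutoffs must lie in (0, Nyquist]")
    }
  }
  if (!is.null(low_cut_hz) && !is.null(high_cut_hz) &&
      low_cut_hz >= high_cut_hz) {
    stop("low_cut_hz must be below high_cut_hz")
  }
  x <- tc$values
  if (detrend) x <- detrend_linear(x)
  freqs <- dft_freqs(n, tc$tr_s)
  keep <- rep(TRUE, n)
  if (!is.null(low_cut_hz)) keep <- keep & (freqs >= low_cut_hz)
  if (!is.null(high_cut_hz)) keep <- keep & (freqs <= high_cut_hz)
  y <- apply_dft_mask(x, keep)
  time_course(y, tr_s = tc$tr_s, unit = tc$unit, origin = tc$origin)
}

# Frequency (Hz) of each DFT bin, folded so bin n-k matches bin k.
dft_freqs <- function(n, tr_s) {
  k <- 0:(n - 1)
  k <- pmin(k, n - k)
  k / (n * tr_s)
}

apply_dft_mask <- function(x, keep) {
  X <- stats::fft(x)
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / length(x)
}

#' Extract per-trial windows and recombine them into one course
#'
#' For every trial of `condition` (a `d`-s test stimulus followed by 30 s of
#' adaptation stimulus), the window of `d + 30` samples starting at the
#' stimulus onset is extracted; windows are concatenated in run-then-onset
#' order. With 3 runs of 4 trials per condition this yields 12 trials, e.g.
#' 31 x 12 = 372 samples for the 1-s condition. Onsets are interpreted on
#' the 0-based sample grid internally; a 1-s trial at 200 s thus covers
#' volumes 201-231 in 1-based volume numbering.
#'
#' @param runs List of percent-unit, low-passed [time_course()]s (one per
#'   run). When the runs were shortened by [percent_signal_change()]'s
#'   `n_discard`, pass that as `offset_s`.
#' @param paradigms List of matching [generate_paradigm()] objects.
#' @param response_type `"increment"` or `"decrement"`.
#' @param test_duration_s 1, 3 or 6.
#' @param offset_s Seconds already removed from the start of each run.
#' @return A [time_course()] of `n_trials * (test_duration_s + 30)` samples.
#' @export
extract_and_recombine <- function(runs, paradigms, response_type,
                                  test_duration_s, offset_s = 0) {
  stopifnot(length(runs) == length(paradigms))
  tr <- runs[[1]]$tr_s
  win_s <- test_duration_s + 30
  if (abs(win_s / tr - round(win_s / tr)) > 1e-9) {
    stop("trial window is not an integer number of samples at this TR")
  }
  win_n <- round(win_s / tr)
  pieces <- list()
  n_found <- 0L
  for (r in seq_along(runs)) {
    ev <- paradigms[[r]]$events
    sel <- ev$response_type == response_type &
      ev$test_duration_s == test_duration_s
    if (!any(sel)) next
    onsets <- sort(ev$onset_s[sel])
    vals <- runs[[r]]$values
    for (on in onsets) {
      start <- round((on - offset_s) / tr) + 1L
      stop_ <- start + win_n - 1L
      if (start < 1L || stop_ > length(vals)) {
        stop("trial window does not fit its run")
      }
      pieces[[length(pieces) + 1L]] <- vals[start:stop_]
      n_found <- n_found + 1L
    }
  }
  if (n_found == 0L) {
    stop(sprintf("condition (%s, %g s) absent from paradigm", response_type,
                 test_duration_s))
  }
  time_course(unlist(pieces), tr_s = tr, unit = runs[[1]]$unit,
              origin = sprintf("%s_%gs", response_type, test_duration_s))
}

#' High-pass filter indexed by FFT component number
#'
#' Zeroes the DC term and Fourier components 1..k (cycles per whole course),
#' i.e. everything at or below the frequency of the k-th FFT component,
#' `k / (length * TR)` Hz. Used on recombined courses, where k = 10 over a
#' 372-s course gives a 0.0269-Hz cutoff.
#'
#' @param tc A [time_course()].
#' @param k Component index (>= 1); the course must be longer than `2k`.
#' @return Filtered [time_course()]; attribute `cutoff_hz` records the
#'   cutoff frequency.
#' @export
highpass_by_component <- function(tc, k = 10) {
  stopifnot(inherits(tc, "time_course"))
  n <- length(tc$values)
  if (k < 1 || n <= 2 * k) stop("need k >= 1 and length > 2k")
  comp <- 0:(n - 1)
  comp <- pmin(comp, n - comp)
  y <- apply_dft_mask(tc$values, comp > k)
  out <- time_course(y, tr_s = tc$tr_s, unit = tc$unit, origin = tc$origin)
  attr(out, "cutoff_hz") <- k / (n * tc$tr_s)
  out
}

#' Trial-average a recombined course into a measured response
#'
#' Reshapes the recombined course into trials of `trial_length` samples,
#' averages across trials, and keeps the first `keep` samples (25 volumes =
#' 25 s, unifying the response length across conditions).
#'
#' @param recombined A [time_course()] from [extract_and_recombine()].
#' @param trial_length Samples per trial (test duration + 30 at TR = 1 s).
#' @param keep Samples to keep from the trial average.
#' @param voxel_id,response_type,test_duration_s Optional labels carried on
#'   the result.
#' @return A `measured_response`: list with `values` (length `keep`),
#'   `tr_s`, `n_trials`, plus the labels.
#' @export
measured_response <- function(recombined, trial_length, keep = 25,
                              voxel_id = NA, response_type = NA,
                              test_duration_s = NA) {
  vals <- recombined$values
  if (length(vals) %% trial_length != 0) {
    stop("recombined length is not divisible by trial_length")
  }
  if (keep > trial_length) stop("keep must be <= trial_length")
  n_trials <- length(vals) %/% trial_length
  m <- matrix(vals, nrow = trial_length)
  avg <- rowMeans(m)[seq_len(keep)]
  structure(list(values = avg, tr_s = recombined$tr_s, n_trials = n_trials,
                 voxel_id = voxel_id, response_type = response_type,
                 test_duration_s = test_duration_s),
            class = "measured_response")
}

#' @export
print.measured_response <- function(x, ...) {
  cat(sprintf(
    "<measured_response> voxel=%s, %s %s s, %d samples (avg of %d trials)\n",
    as.character(x$voxel_id), as.character(x$response_type),
    as.character(x$test_duration_s), length(x$values), x$n_trials))
  invisible(x)
}

#' Preprocess one voxel's localizer run
#'
#' Percent signal change, then linear detrend and a 0.0125-0.2-Hz Fourier
#' band-pass (the signal band of the 60-s block design is 0.0167-0.15 Hz).
#'
#' @param tc Raw localizer [time_course()].
#' @param low_cut_hz,high_cut_hz Band-pass edges (Hz).
#' @return Percent-unit filtered [time_course()].
#' @export
preprocess_localizer <- function(tc, low_cut_hz = 0.0125,
                                 high_cut_hz = 0.2) {
  psc <- percent_signal_change(tc, n_discard = 0)
  fourier_filter(psc, low_cut_hz, high_cut_hz, detrend = TRUE)
}

#' Preprocess one voxel's adaptation runs into six measured responses
#'
#' Per run: discard the first `n_discard` volumes (baseline + adaptation
#' transient), convert to percent signal change, remove the linear trend of
#' the test period, and low-pass at `low_pass_hz`. Then, per condition:
#' recombine the 12 trial windows across the three runs, high-pass at the
#' `hp_k`-th FFT component of the recombined course, and average trials into
#' a 25-sample measured response.
#'
#' @param runs List of 3 raw adaptation [time_course()]s.
#' @param paradigms List of 3 matching paradigms.
#' @param n_discard Leading volumes dropped per run (90 = 30-s baseline +
#'   60-s adaptation phase).
#' @param low_pass_hz Per-run low-pass cutoff (Hz).
#' @param hp_k Component index of the recombined-course high-pass.
#' @param keep Samples kept in each measured response.
#' @param voxel_id Label carried onto the responses.
#' @return Named list of 6 `measured_response`s, names like
#'   `"increment_1"`, ..., `"decrement_6"`.
#' @export
preprocess_adaptation <- function(runs, paradigms, n_discard = 90,
                                  low_pass_hz = 0.2, hp_k = 10, keep = 25,
                                  voxel_id = NA) {
  filtered <- lapply(runs, function(tc) {
    psc <- percent_signal_change(tc, n_discard = n_discard)
    fourier_filter(psc, high_cut_hz = low_pass_hz, detrend = TRUE)
  })
  conds <- condition_labels()
  out <- vector("list", nrow(conds))
  names(out) <- paste(conds$response_type, conds$test_duration_s, sep = "_")
  for (i in seq_len(nrow(conds))) {
    rec <- extract_and_recombine(filtered, paradigms,
                                 conds$response_type[i],
                                 conds$test_duration_s[i],
                                 offset_s = n_discard * runs[[1]]$tr_s)
    rec <- highpass_by_component(rec, k = hp_k)
    trial_len <- round((conds$test_duration_s[i] + 30) / runs[[1]]$tr_s)
    out[[i]] <- measured_response(rec, trial_len, keep = keep,
                                  voxel_id = voxel_id,
                                  response_type = conds$response_type[i],
                                  test_duration_s = conds$test_duration_s[i])
  }
  out
}

#' Per-trial 25-sample segments of one condition group (for SNR)
#'
#' Converts each run to percent signal change and removes its linear trend,
#' then returns the individual trial segments (rows) of all trials of one
#' response type across the three durations and runs, each truncated to
#' `keep` samples from stimulus onset. No low-pass is applied by default:
#' the SNR noise band (0.33-0.50 Hz) must retain the high-frequency noise
#' the statistic measures, which a 0.2-Hz low-pass would empty.
#'
#' @inheritParams preprocess_adaptation
#' @param response_type `"increment"` or `"decrement"`.
#' @param low_pass_hz Optional low-pass cutoff (`NULL` = none).
#' @return Matrix with one row per trial and `keep` columns.
#' @export
trial_segments <- function(runs, paradigms, response_type, n_discard = 90,
                           low_pass_hz = NULL, keep = 25) {
  filtered <- lapply(runs, function(tc) {
    psc <- percent_signal_change(tc, n_discard = n_discard)
    fourier_filter(psc, high_cut_hz = low_pass_hz, detrend = TRUE)
  })
  segs <- list()
  for (dur in c(1, 3, 6)) {
    rec <- extract_and_recombine(filtered, paradigms, response_type, dur,
                                 offset_s = n_discard * runs[[1]]$tr_s)
    trial_len <- round((dur + 30) / runs[[1]]$tr_s)
    m <- matrix(rec$values, nrow = trial_len)
    segs[[length(segs) + 1L]] <- t(m[seq_len(keep), , drop = FALSE])
  }
  do.call(rbind, segs)
}
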