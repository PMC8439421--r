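#' FFT-based signal-to-noise ratio of trial-locked responses
#'
#' Concatenates the per-trial 25-sample segments (task periodicity 25 s per
#' cycle, i.e. 0.04 Hz at TR = 1 s), takes the DFT, and returns the
#' magnitude at the task-frequency bin (`n_trials` cycles per course)
#' divided by the mean magnitude over the high-frequency noise band
#' (default 0.33-0.50 Hz, endpoints inclusive).
#'
#' @param trials Matrix with one row per trial, 25 columns, or a list of
#'   25-sample vectors.
#' @param tr_s Repetition time (s).
#' @param noise_band `c(low, high)` in Hz, or `"all_but_task"` to use every
#'   non-DC frequency except the task bin (robustness check).
#' @return List with `snr`, `task_freq_hz`, `noise_band_hz`, `n_trials`.
#' @export
compute_snr <- function(trials, tr_s = 1, noise_band = c(0.33, 0.50)) {
  if (is.list(trials)) trials <- do.call(rbind, trials)
  if (!is.matrix(trials) || nrow(trials) < 2) stop("need >= 2 trials")
  trial_len <- ncol(trials)
  x <- as.numeric(t(trials))
  n <- length(x)
  mag <- Mod(stats::fft(x))
  cycles <- 0:(n - 1)
  cycles <- pmin(cycles, n - cycles)
  freqs <- cycles / (n * tr_s)
  task_bin <- nrow(trials) + 1L  # n_trials cycles per course
  task_freq <- freqs[task_bin]
  half <- which(cycles == 0:(n - 1))  # non-negative-frequency bins
  if (identical(noise_band, "all_but_task")) {
    noise_idx <- setdiff(half[-1], task_bin)
    band <- range(freqs[noise_idx])
  } else {
    noise_idx <- half[freqs[half] >= noise_band[1] &
                        freqs[half] <= noise_band[2]]
    band <- noise_band
  }
  if (length(noise_idx) == 0) stop("empty noise band")
  noise_mag <- mean(mag[noise_idx])
  if (noise_mag <= 0) stop("degenerate noise band")
  list(snr = mag[task_bin] / noise_mag, task_freq_hz = task_freq,
       noise_band_hz = band, n_trials = nrow(trials))
}

#' Median split of per-voxel statistics
#'
#' Voxels at or below the median go to the low group (`tie = "median_to_low"`,
#' the default) or strictly below (`tie = "median_to_high"`); the rule is
#' configurable because an odd voxel count leaves the median voxel's group
#' ambiguous.
#'
#' @param values Named (or plain) numeric vector, one value per voxel.
#' @param tie `"median_to_low"` or `"median_to_high"`.
#' @return List with logical vector `low` (TRUE = low group), `median`.
#' @export
median_split <- function(values, tie = c("median_to_low", "median_to_high")) {
  tie <- match.arg(tie)
  if (length(values) < 2) stop("need >= 2 values")
  med <- stats::median(values)
  low <- if (tie == "median_to_low") values <= med else values < med
  list(low = low, median = med)
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Drops zero differences, ranks `|x - y|` with midranks for ties, and
#' tests the two-sided hypothesis of symmetry about zero. For more than 25
#' nonzero pairs the normal approximation with tie correction and
#' continuity correction is used and a Z statistic is reported; otherwise
#' the exact distribution (via [stats::wilcox.test()]) gives the p-value.
#'
#' @param x,y Equal-length paired vectors.
#' @return List with `W` (positive-rank sum), `z`, `p`, `n` (nonzero pairs),
#'   `method`.
#' @export
paired_compare <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero")
    return(list(W = 0, z = 0, p = 1, n = 0, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  if (n > 25 || any(ties > 1)) {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
    method <- "exact"
  }
  list(W = W, z = z, p = min(p, 1), n = n, method = method)
}

#' Kolmogorov-Smirnov distribution comparison
#'
#' One-sample mode compares `x` against a normal distribution with mean 0
#' and the sample's own standard deviation (the null that deviations from
#' linearity are symmetric noise about zero); two-sample mode compares two
#' voxel groups.
#'
#' @param x Numeric sample.
#' @param y Optional second sample (two-sample test).
#' @param reference `"centered_normal"` for the one-sample test.
#' @return List with `D` and `p`.
#' @export
distribution_compare <- function(x, y = NULL, reference = "centered_normal") {
  if (length(x) == 0) stop("x must be nonempty")
  if (!is.null(y)) {
    res <- suppressWarnings(stats::ks.test(x, y))
  } else {
    if (reference != "centered_normal") stop("unknown reference")
    s <- stats::sd(x)
    if (s == 0) stop("sd is zero: degenerate distribution")
    res <- suppressWarnings(stats::ks.test(x, "pnorm", mean = 0, sd = s))
  }
  list(D = unname(res$statistic), p = res$p.value)
}

#' Per-voxel SNR table with median-split groups
#'
#' Computes [compute_snr()] for each voxel and response type from the
#' trial segments of the adaptation runs, then median-splits voxels into
#' low/high SNR groups separately per response type.
#'
#' @param dataset A [simulate_dataset()] object.
#' @param voxel_ids Voxels to include (default all).
#' @param noise_band Passed to [compute_snr()].
#' @param tie Median tie rule, see [median_split()].
#' @param n_discard,low_pass_hz Preprocessing settings (no low-pass by
#'   default, so the noise band keeps its content; see [trial_segments()]).
#' @return Data frame `voxel_id, response_type, snr, group`.
#' @export
snr_table <- function(dataset, voxel_ids = NULL, noise_band = c(0.33, 0.50),
                      tie = "median_to_low", n_discard = 90,
                      low_pass_hz = NULL) {
  if (is.null(voxel_ids)) {
    voxel_ids <- vapply(dataset$voxels, `[[`, 0, "voxel_id")
  }
  rows <- list()
  for (vid in voxel_ids) {
    vox <- dataset$voxels[[which(
      vapply(dataset$voxels, `[[`, 0, "voxel_id") == vid)]]
    for (type in c("increment", "decrement")) {
      segs <- trial_segments(vox$runs$adaptation,
                             dataset$paradigms$adaptation, type,
                             n_discard = n_discard,
                             low_pass_hz = low_pass_hz)
      res <- compute_snr(segs, tr_s = vox$runs$adaptation[[1]]$tr_s,
                         noise_band = noise_band)
      rows[[length(rows) + 1L]] <- data.frame(
        voxel_id = vid, response_type = type, snr = res$snr,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$group <- NA_character_
  for (type in c("increment", "decrement")) {
    idx <- tab$response_type == type
    split_ <- median_split(tab$snr[idx], tie = tie)
    tab$group[idx] <- ifelse(split_$low, "low", "high")
  }
  tab
}
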