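#' The three short-to-long prediction pairs
#'
#' Linear predictions are built for 1 s -> 3 s, 1 s -> 6 s and 3 s -> 6 s
#' (the long duration is always an integer multiple of the short one).
#'
#' @return Data frame with columns `short_dur_s`, `long_dur_s`, `label`.
#' @export
prediction_pairs <- function() {
  data.frame(short_dur_s = c(1, 1, 3), long_dur_s = c(3, 6, 6),
             label = c("1->3", "1->6", "3->6"), stringsAsFactors = FALSE)
}

#' Superposition prediction of a long-stimulus response
#'
#' Under linearity, the response to a `d_long`-s stimulus is the sum of the
#' `d_short`-s response and its copies shifted by multiples of `d_short`
#' seconds: `P = sum_{j=0}^{r-1} shift(M_short, j * d_short)`, with zeros
#' shifted in and the sum truncated to the measured-response length
#' (contributions that would extend past the window are kept only insofar as
#' they fall inside it).
#'
#' @param short A `measured_response` for the short duration.
#' @param long_dur_s Target duration (integer multiple of the short one).
#' @return List with `values` (same length as `short$values`), `pair` label,
#'   `voxel_id`, `response_type`; class `prediction`.
#' @export
superposition_predict <- function(short, long_dur_s) {
  d_short <- short$test_duration_s
  if (is.na(d_short)) d_short <- attr(short, "duration_s")
  shift_n <- d_short / short$tr_s
  if (abs(shift_n - round(shift_n)) > 1e-9 || shift_n <= 0) {
    stop("shift is not a positive integer number of samples")
  }
  r <- long_dur_s / d_short
  if (abs(r - round(r)) > 1e-9) {
    stop("long duration must be an integer multiple of the short duration")
  }
  shift_n <- round(shift_n)
  x <- short$values
  n <- length(x)
  p <- numeric(n)
  for (j in 0:(round(r) - 1L)) {
    off <- j * shift_n
    if (off >= n) break
    p[(off + 1L):n] <- p[(off + 1L):n] + x[1:(n - off)]
  }
  structure(list(values = p,
                 pair = sprintf("%g->%g", d_short, long_dur_s),
                 voxel_id = short$voxel_id,
                 response_type = short$response_type),
            class = "prediction")
}

#' Signed, amplitude-sensitive Dice index between two time courses
#'
#' \deqn{s_{Dice} = \frac{2 \sum_t P_t M_t}{\sum_t P_t^2 + \sum_t M_t^2}}
#'
#' Ranges from -1 to 1; equals 1 iff `P = M` and -1 iff `P = -M`. Unlike the
#' correlation coefficient it penalises amplitude mismatch:
#' `dice(k M, M) = 2k / (k^2 + 1)`.
#'
#' @param p,m Numeric vectors of equal length (a `prediction` /
#'   `measured_response` is also accepted).
#' @return Scalar in \[-1, 1\].
#' @export
dice_index <- function(p, m) {
  if (is.list(p)) p <- p$values
  if (is.list(m)) m <- m$values
  if (length(p) != length(m)) stop("P and M must have equal lengths")
  denom <- sum(p^2) + sum(m^2)
  if (denom == 0) stop("undefined similarity: both inputs are all-zero")
  2 * sum(p * m) / denom
}

#' Permutation null distribution of the Dice index
#'
#' Permutes the time points of the pre-processed (percent, detrended,
#' low-passed) per-run adaptation courses, rebuilds measured responses and
#' superposition predictions from the shuffled data through the identical
#' recombine / high-pass / trial-average chain, and pools the Dice values of
#' all six (pair x response type) combinations per draw.
#'
#' @param filtered_runs List of 3 preprocessed adaptation [time_course()]s.
#' @param paradigms Matching paradigms.
#' @param n_total Minimum number of pooled Dice samples.
#' @param seed Integer seed.
#' @param hp_k Component index for the recombined-course high-pass.
#' @param offset_s Seconds removed from the start of each run upstream.
#' @return A `null_distribution` with `statistic = "dice"`.
#' @export
dice_null <- function(filtered_runs, paradigms, n_total = 1000, seed = 1L,
                      hp_k = 10, offset_s = 90) {
  pairs <- prediction_pairs()
  n_draws <- ceiling(n_total / 6)
  samples <- with_seed(seed, {
    out <- numeric(0)
    for (d in seq_len(n_draws)) {
      perm <- lapply(filtered_runs, function(tc) {
        time_course(sample(tc$values), tr_s = tc$tr_s, unit = tc$unit)
      })
      mr <- list()
      for (type in c("increment", "decrement")) {
        for (dur in c(1, 3, 6)) {
          rec <- extract_and_recombine(perm, paradigms, type, dur,
                                       offset_s = offset_s)
          rec <- highpass_by_component(rec, k = hp_k)
          mr[[paste(type, dur, sep = "_")]] <-
            measured_response(rec, round((dur + 30) / perm[[1]]$tr_s),
                              response_type = type, test_duration_s = dur)
        }
      }
      for (type in c("increment", "decrement")) {
        for (i in seq_len(nrow(pairs))) {
          p <- superposition_predict(
            mr[[paste(type, pairs$short_dur_s[i], sep = "_")]],
            pairs$long_dur_s[i])
          m <- mr[[paste(type, pairs$long_dur_s[i], sep = "_")]]
          out <- c(out, dice_index(p, m))
        }
      }
    }
    out
  })
  structure(list(samples = samples, n_samples = length(samples),
                 statistic = "dice", tail = "upper", seed = as.integer(seed)),
            class = "null_distribution")
}

#' Chance-level Dice threshold
#'
#' One-tailed upper threshold at the requested false-positive rate. With a
#' single voxel this is the plain empirical `(1 - fpr)` quantile of the
#' null. Across several voxels a multiplicity-corrected threshold is
#' returned: when the observed Dice values are supplied, Benjamini-Hochberg
#' step-up is applied to their empirical upper-tail p-values and the
#' threshold is the smallest observed value that is rejected (`+Inf` when
#' nothing is); without observed values a conservative Bonferroni-adjusted
#' quantile at `fpr / n_voxels` is used.
#'
#' @param null A `null_distribution` with `statistic = "dice"`.
#' @param fpr False-positive rate.
#' @param n_voxels Number of voxels in the comparison family.
#' @param observed Optional vector of observed Dice values.
#' @return Scalar threshold.
#' @export
dice_chance_threshold <- function(null, fpr = 0.05, n_voxels = 1,
                                  observed = NULL) {
  if (null$statistic != "dice") stop("null must be a Dice null")
  if (n_voxels <= 1) return(null_threshold(null, fpr))
  if (!is.null(observed)) {
    pvals <- null_fpr(null, observed)
    rej <- fdr_bh(pvals, q = fpr)$reject
    if (!any(rej)) return(Inf)
    return(min(observed[rej]))
  }
  null_threshold(null, fpr / n_voxels)
}

#' Dice linearity evaluation across selected voxels
#'
#' For every selected voxel and each of the six (pair x response type)
#' combinations, builds the superposition prediction from the short-duration
#' measured response and scores it against the long-duration measured
#' response with the Dice index. The summary reports per-condition medians,
#' the fraction of voxels above the chance threshold (when a Dice null is
#' supplied), and paired Wilcoxon comparisons across response types and
#' durations.
#'
#' @param measured_by_voxel Named list (by voxel) of 6-element measured
#'   response lists as returned by [preprocess_adaptation()].
#' @param null Optional Dice `null_distribution` for chance thresholds.
#' @param fpr False-positive rate for the chance threshold.
#' @return List with `table` (voxel_id, response_type, pair, dice,
#'   above_chance) and `summary`.
#' @export
evaluate_linearity <- function(measured_by_voxel, null = NULL, fpr = 0.05) {
  pairs <- prediction_pairs()
  rows <- list()
  for (vox in names(measured_by_voxel)) {
    mr <- measured_by_voxel[[vox]]
    for (type in c("increment", "decrement")) {
      for (i in seq_len(nrow(pairs))) {
        p <- superposition_predict(mr[[paste(type, pairs$short_dur_s[i],
                                             sep = "_")]],
                                   pairs$long_dur_s[i])
        m <- mr[[paste(type, pairs$long_dur_s[i], sep = "_")]]
        rows[[length(rows) + 1L]] <- data.frame(
          voxel_id = vox, response_type = type, pair = pairs$label[i],
          dice = dice_index(p, m), stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$above_chance <- NA
  threshold <- NA_real_
  if (!is.null(null)) {
    threshold <- dice_chance_threshold(null, fpr,
                                       n_voxels = length(measured_by_voxel),
                                       observed = tab$dice)
    tab$above_chance <- tab$dice > threshold
  }
  med <- stats::aggregate(dice ~ response_type + pair, tab, stats::median)
  pct <- if (!is.null(null)) {
    stats::aggregate(above_chance ~ response_type + pair, tab,
                     function(z) 100 * mean(z))
  } else {
    NULL
  }
  comparisons <- linearity_comparisons(tab)
  list(table = tab,
       summary = list(median_dice = med, percent_above_chance = pct,
                      chance_threshold = threshold,
                      comparisons = comparisons))
}

# Paired Wilcoxon family: increments vs decrements per pair, and 1-s vs 3-s
# based predictions per response type; BH-corrected.
linearity_comparisons <- function(tab) {
  tab$condition <- paste(tab$response_type, tab$pair, sep = ".")
  wide <- stats::reshape(tab[, c("voxel_id", "condition", "dice")],
                         idvar = "voxel_id", timevar = "condition",
                         direction = "wide", v.names = "dice")
  tests <- list(
    inc_vs_dec_1to3 = c("increment.1->3", "decrement.1->3"),
    inc_vs_dec_1to6 = c("increment.1->6", "decrement.1->6"),
    inc_vs_dec_3to6 = c("increment.3->6", "decrement.3->6"),
    inc_1to6_vs_3to6 = c("increment.1->6", "increment.3->6"),
    dec_1to6_vs_3to6 = c("decrement.1->6", "decrement.3->6")
  )
  out <- lapply(tests, function(cond) {
    x <- wide[[paste0("dice.", cond[1])]]
    y <- wide[[paste0("dice.", cond[2])]]
    paired_compare(x, y)
  })
  p_adj <- fdr_bh(vapply(out, `[[`, 0, "p"), q = 0.05)$adjusted
  for (i in seq_along(out)) out[[i]]$p_corrected <- p_adj[i]
  out
}
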