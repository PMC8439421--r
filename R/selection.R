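#' Finite-impulse-response deconvolution and variance accounted for
#'
#' Estimates an unconstrained impulse response (one weight per lag
#' `0..L-1`) by least squares from a stimulus indicator, together with an
#' intercept (percent-signal-change conversion leaves a constant offset the
#' lagged indicator cannot absorb). `r2` is the fraction of variance about
#' the mean accounted for by the fitted course, clipped to \[0, 1\]: 1 when
#' the estimate explains all variance, 0 when it explains none.
#'
#' @param tc A percent-unit, filtered [time_course()].
#' @param stimulus Numeric indicator series (same length as `tc`), 1 while
#'   the stimulus is on.
#' @param L FIR window length in samples (default 25 = the measured-response
#'   length).
#' @return List with `taps` (length `L`), `intercept`, `fitted`, `r2`.
#' @export
fir_r2 <- function(tc, stimulus, L = 25) {
  y <- tc$values
  n <- length(y)
  if (length(stimulus) != n) stop("stimulus must match the time course")
  if (n <= L) stop("time course must be longer than the FIR window")
  X <- matrix(0, n, L)
  for (lag in 0:(L - 1L)) {
    X[(lag + 1L):n, lag + 1L] <- stimulus[1:(n - lag)]
  }
  design <- cbind(intercept = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop("rank-deficient FIR design (stimulus indicator is degenerate)")
  }
  coefs <- qr.coef(qrd, y)
  fitted <- drop(design %*% coefs)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) stop("rank-deficient FIR design (constant time course)")
  r2 <- min(max(1 - ss_res / ss_tot, 0), 1)
  list(taps = unname(coefs[-1]), intercept = unname(coefs[1]),
       fitted = fitted, r2 = r2)
}

#' Permutation null distribution of a pipeline statistic
#'
#' Repeatedly permutes the time points of the supplied raw courses
#' (uniform random permutation, seeded), pushes each permuted course through
#' the same preprocessing as the observed data, computes the statistic, and
#' pools all values. For `statistic = "r2"` the courses are localizer runs
#' and the statistic is [fir_r2()] against `stimulus`; for
#' `statistic = "dice"` use [dice_null()], which rebuilds measured responses
#' and predictions from shuffled adaptation runs.
#'
#' @param timecourses List of raw [time_course()]s to shuffle.
#' @param stimulus Stimulus indicator aligned to the preprocessed courses.
#' @param n_total Total pooled null samples (>= 100); the study-scale run
#'   used 1e5, desk-scale defaults are smaller.
#' @param seed Integer seed.
#' @param preprocess Function mapping a raw [time_course()] to the
#'   preprocessed one (default [preprocess_localizer()]).
#' @param L FIR window length.
#' @param null_model `"shuffle"` (permute time points) or `"ar1"`
#'   (AR(1) surrogate series with the coefficient and innovation scale
#'   estimated from each course, a check that temporal autocorrelation does
#'   not inflate the null).
#' @return A `null_distribution`: list with `samples`, `n_samples`,
#'   `statistic`, `tail`, `seed`.
#' @export
build_null <- function(timecourses, stimulus, n_total = 1000, seed = 1L,
                       preprocess = preprocess_localizer, L = 25,
                       null_model = c("shuffle", "ar1")) {
  null_model <- match.arg(null_model)
  if (n_total < 100) stop("n_total must be >= 100")
  samples <- with_seed(seed, {
    out <- numeric(n_total)
    for (i in seq_len(n_total)) {
      src <- timecourses[[(i - 1L) %% length(timecourses) + 1L]]
      vals <- if (null_model == "shuffle") {
        sample(src$values)
      } else {
        ar1_surrogate(src$values)
      }
      perm <- time_course(vals, tr_s = src$tr_s, unit = src$unit)
      proc <- preprocess(perm)
      out[i] <- fir_r2(proc, stimulus, L = L)$r2
    }
    out
  })
  structure(list(samples = samples, n_samples = n_total, statistic = "r2",
                 tail = "upper", seed = as.integer(seed)),
            class = "null_distribution")
}

# AR(1) surrogate with lag-1 coefficient and marginal variance matched to x.
ar1_surrogate <- function(x) {
  x0 <- x - mean(x)
  phi <- sum(x0[-1] * x0[-length(x0)]) / sum(x0^2)
  phi <- max(min(phi, 0.99), -0.99)
  innov_sd <- stats::sd(x0) * sqrt(1 - phi^2)
  e <- stats::rnorm(length(x), sd = innov_sd)
  as.numeric(stats::filter(e, phi, method = "recursive")) + mean(x)
}

#' Upper-tail threshold of a null distribution
#'
#' `threshold(fpr)` is the empirical `(1 - fpr)` quantile of the pooled null
#' samples: a statistic ranked in the top `fpr` fraction of the null exceeds
#' it.
#'
#' @param null A `null_distribution`.
#' @param fpr False-positive rate (proportion).
#' @return Numeric threshold.
#' @export
null_threshold <- function(null, fpr) {
  if (fpr <= 0 || fpr >= 1) stop("fpr must be in (0, 1)")
  unname(stats::quantile(null$samples, probs = 1 - fpr, type = 1))
}

#' Empirical upper-tail false-positive rate of observed statistics
#'
#' Uses the add-one estimator `(1 + #\{null >= observed\}) / (1 + n)` so no
#' observed value gets an exactly-zero rate.
#'
#' @param null A `null_distribution`.
#' @param observed Numeric vector of observed statistics.
#' @return Numeric vector of empirical false-positive rates.
#' @export
null_fpr <- function(null, observed) {
  s <- sort(null$samples)
  n <- length(s)
  ge <- n - findInterval(observed - .Machine$double.eps^0.5, s)
  (1 + ge) / (1 + n)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment: `adjusted_(i) = min_{j >= i} (m * p_(j) / j)` capped
#' at 1, rejecting where the adjusted value is at or below `q`. The
#' adjustment is delegated to [stats::p.adjust()].
#'
#' @param p Vector of raw p-values (proportions).
#' @param q FDR level.
#' @return List with `adjusted` and logical `reject`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

# Face-connected (6-neighbour) components on an integer voxel grid.
# Returns a cluster id per voxel (only among `which_idx` voxels).
cluster_labels <- function(coords) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  key <- function(xyz) paste(xyz, collapse = ",")
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) assign(key(coords[i, ]), i, envir = lookup)
  labels <- integer(n)
  cl <- 0L
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (o in seq_len(6)) {
        nb <- key(coords[v, ] + offsets[o, ])
        j <- if (exists(nb, envir = lookup)) get(nb, envir = lookup) else NULL
        if (!is.null(j) && labels[j] == 0L) {
          labels[j] <- cl
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Select significantly activated voxels from localizer runs
#'
#' Computes each voxel's FIR-deconvolution r-squared on its preprocessed
#' localizer course, converts it to an empirical false-positive rate against
#' the permutation null, applies Benjamini-Hochberg correction across
#' voxels, flags voxels with corrected rate below `q`, requires a positive
#' early localizer response (mean FIR impulse response over 0-15 s > 0,
#' since the localizer stimulus elicits a BOLD increment in selected
#' voxels), and finally keeps only voxels in face-connected clusters of at
#' least `min_cluster` significant voxels.
#'
#' @param dataset A [simulate_dataset()] object (or a list with the same
#'   `voxels` / `paradigms` shape).
#' @param null A `null_distribution` built with matching preprocessing.
#' @param q Corrected false-positive-rate threshold.
#' @param min_cluster Minimum face-connected cluster size.
#' @param L FIR window length.
#' @return Data frame with one row per voxel: `voxel_id, x, y, z, r2,
#'   fpr_raw, fpr_fdr, positive, selected`.
#' @export
select_voxels <- function(dataset, null, q = 0.001, min_cluster = 4, L = 25) {
  stim <- localizer_stimulus(dataset$paradigms$localizer)
  n <- length(dataset$voxels)
  r2 <- numeric(n)
  positive <- logical(n)
  coords <- matrix(0L, n, 3)
  for (v in seq_len(n)) {
    vox <- dataset$voxels[[v]]
    if (is.null(vox$coords) && min_cluster > 1) {
      stop("grid coordinates required when min_cluster > 1")
    }
    proc <- preprocess_localizer(vox$runs$localizer)
    est <- fir_r2(proc, stim, L = L)
    r2[v] <- est$r2
    positive[v] <- mean(est$taps[seq_len(min(16L, L))]) > 0
    coords[v, ] <- vox$coords
  }
  fpr_raw <- null_fpr(null, r2)
  corr <- fdr_bh(fpr_raw, q = q)
  candidate <- corr$adjusted < q & positive
  selected <- candidate
  if (min_cluster > 1 && any(candidate)) {
    labs <- cluster_labels(coords[candidate, , drop = FALSE])
    sizes <- table(labs)
    keep <- labs %in% as.integer(names(sizes)[sizes >= min_cluster])
    selected[candidate] <- keep
  }
  data.frame(voxel_id = vapply(dataset$voxels, `[[`, 0, "voxel_id"),
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             r2 = r2, fpr_raw = fpr_raw, fpr_fdr = corr$adjusted,
             positive = positive, selected = selected)
}

#' Stimulus indicator series of a localizer paradigm
#'
#' @param paradigm A localizer [generate_paradigm()] object.
#' @return 0/1 vector with one entry per volume.
#' @export
localizer_stimulus <- function(paradigm) {
  n <- round(paradigm$run_length_s / paradigm$tr_s)
  t_vol <- (seq_len(n) - 1L) * paradigm$tr_s
  stim <- numeric(n)
  for (i in seq_len(nrow(paradigm$events))) {
    on <- paradigm$events$onset_s[i]
    stim[t_vol >= on & t_vol < on + paradigm$events$duration_s[i]] <- 1
  }
  stim
}
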