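#' Two-gamma hemodynamic response function parameters
#'
#' The HRF is a difference of two gamma densities,
#' \deqn{h(t) = A [g(t - t_0; \alpha_1, \beta_1) - c\, g(t - t_0; \alpha_2,
#'   \beta_2)]}{h(t) = A (g1(t - t0) - c g2(t - t0))}
#' for \eqn{t \ge t_0} and 0 before onset, where
#' \eqn{g(x; \alpha, \beta) = x^{\alpha-1}\beta^{\alpha} e^{-\beta x} /
#' \Gamma(\alpha)} and each shape is tied to the time-to-peak by
#' \eqn{\alpha_i = \mu_i \beta_i + 1}, so that \eqn{\mu_i} is the peak time
#' of component *i*. `sign = -1` models a negative HRF (BOLD decrement) as
#' zero minus the canonical shape.
#'
#' @param A Amplitude scale (percent-signal units).
#' @param mu1,mu2 Times-to-peak of the positive and undershoot components (s).
#' @param beta1,beta2 Rate parameters (1/s).
#' @param c Undershoot ratio in \[0, 1\].
#' @param t_onset Onset delay (s).
#' @param sign `+1` (positive HRF) or `-1` (negative HRF).
#' @param bounds_mode `"restricted"` or `"flexible"` (see [hrf_bounds()]).
#' @return An `hrf_params` object (named list).
#' @export
hrf_params <- function(A = 5, mu1 = 5, mu2 = 12, beta1 = 1, beta2 = 1,
                       c = 0.35, t_onset = 0, sign = 1,
                       bounds_mode = "restricted") {
  p <- list(A = A, mu1 = mu1, mu2 = mu2, beta1 = beta1, beta2 = beta2,
            c = c, t_onset = t_onset, sign = sign, bounds_mode = bounds_mode)
  for (nm in c("A", "mu1", "mu2", "beta1", "beta2", "c", "t_onset")) {
    stopifnot_scalar(p[[nm]], nm)
  }
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  structure(p, class = "hrf_params")
}

#' Parameter box bounds for the two-gamma HRF fit
#'
#' `restricted` keeps the fit in a physiologically plausible region;
#' `flexible` relaxes every range (used to check that deviation patterns do
#' not come from the restriction). Rate and amplitude upper bounds in the
#' flexible mode are large finite values standing in for +Inf, which the
#' box-constrained optimizer requires.
#'
#' @param mode `"restricted"` or `"flexible"`.
#' @return List with numeric vectors `lower` and `upper`, named by parameter
#'   (`A, mu1, mu2, beta1, beta2, c, t_onset`).
#' @export
hrf_bounds <- function(mode = c("restricted", "flexible")) {
  mode <- match.arg(mode)
  if (mode == "restricted") {
    list(
      lower = c(A = 0, mu1 = 0.5, mu2 = 4, beta1 = 0, beta2 = 0, c = 0,
                t_onset = 0),
      upper = c(A = 20, mu1 = 8, mu2 = 16, beta1 = 5, beta2 = 5, c = 1,
                t_onset = 5)
    )
  } else {
    list(
      lower = c(A = 0, mu1 = 0, mu2 = 0, beta1 = 0, beta2 = 0, c = 0,
                t_onset = 0),
      upper = c(A = 1e3, mu1 = 24, mu2 = 24, beta1 = 1e3, beta2 = 1e3, c = 1,
                t_onset = 24)
    )
  }
}

# Single gamma-density component with the mu/beta parameterisation.
# beta = 0 is the degenerate limit: the component vanishes.
gamma_component <- function(x, mu, beta) {
  if (beta <= 0) return(numeric(length(x)))
  alpha <- mu * beta + 1
  out <- numeric(length(x))
  ok <- x >= 0
  out[ok] <- stats::dgamma(x[ok], shape = alpha, rate = beta)
  out
}

#' Evaluate a two-gamma HRF on a time grid
#'
#' @param params An [hrf_params()] object.
#' @param t Non-negative time grid (seconds).
#' @return Numeric vector `h(t)`; zero for `t < t_onset`, multiplied by
#'   `params$sign`.
#' @export
hrf_eval <- function(params, t) {
  x <- t - params$t_onset
  h <- params$A * (gamma_component(x, params$mu1, params$beta1) -
                     params$c * gamma_component(x, params$mu2, params$beta2))
  h[t < params$t_onset] <- 0
  params$sign * h
}

#' Peak amplitude of a fitted HRF
#'
#' The amplitude is the magnitude of the HRF peak: the maximum of a positive
#' HRF or the minimum of a negative HRF. Post-peak undershoot/overshoot is
#' excluded by searching only `[t_onset, t_onset + mu2]`, where the signed
#' extremum of the first (response) component lives.
#'
#' @param params An [hrf_params()] object.
#' @param dt Grid step for the numeric search (s).
#' @return Non-negative peak magnitude (percent-signal units).
#' @export
hrf_amplitude <- function(params, dt = 0.01) {
  t_hi <- params$t_onset + max(params$mu2, params$mu1, dt)
  grid <- seq(params$t_onset, t_hi, by = dt)
  h <- hrf_eval(params, grid)
  if (params$sign >= 0) max(h, 0) else abs(min(h, 0))
}

#' Model BOLD response to a boxcar stimulus
#'
#' Convolves a boxcar of the given duration with the signed HRF on a fine
#' grid (`dt` seconds), then samples at volume times `0, tr, 2 tr, ...`.
#' This is the model curve fitted to 25-sample measured responses and the
#' noiseless kernel of the synthetic-data generator.
#'
#' @param params An [hrf_params()] object.
#' @param duration_s Stimulus duration (s).
#' @param n_out Number of output samples (volumes).
#' @param tr_s Repetition time (s).
#' @param dt Internal grid step (s); must divide `tr_s`.
#' @return Numeric vector of length `n_out`.
#' @export
hrf_boxcar_response <- function(params, duration_s, n_out = 25, tr_s = 1,
                                dt = 0.1) {
  if (abs(tr_s / dt - round(tr_s / dt)) > 1e-9) {
    stop("dt must divide tr_s")
  }
  n_fine <- ceiling((n_out - 1) * tr_s / dt) + 1L
  t_fine <- (seq_len(n_fine) - 1L) * dt
  h <- hrf_eval(params, t_fine)
  # boxcar (x) h == windowed running sum of h: C(t) - C(t - duration)
  cs <- cumsum(h) * dt
  nd <- round(duration_s / dt)
  lagged <- c(rep(0, min(nd, n_fine)), cs[seq_len(max(n_fine - nd, 0))])
  y <- cs - lagged
  idx <- round((seq_len(n_out) - 1L) * tr_s / dt) + 1L
  y[idx]
}
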