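# Shared fixtures, built in code and cached for the session: datasets are
# deterministic in (config, seed), so caching only saves wall time.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Noise-free, perfectly linear dataset: the LTI oracle surface.
linear_dataset <- function(n_voxels = 6, seed = 11) {
  cached(sprintf("lin_%d_%d", n_voxels, seed),
         simulate_dataset(n_voxels, seed = seed, noise_sd = 0, drift = NULL,
                          linear_trend = 0))
}

measured_for <- function(dataset) {
  key <- sprintf("mbv_%d_%d_%s", length(dataset$voxels), dataset$seed,
                 dataset$config$nonlinearity)
  cached(key, {
    out <- list()
    for (v in dataset$voxels) {
      out[[as.character(v$voxel_id)]] <- preprocess_adaptation(
        v$runs$adaptation, dataset$paradigms$adaptation,
        voxel_id = v$voxel_id)
    }
    out
  })
}

# A compact-support restricted-bounds HRF: negligible mass beyond 25 s, so
# FIR and fitting oracles are exact to float precision.
compact_hrf <- function(sign = 1) {
  hrf_params(A = 5, mu1 = 4.5, beta1 = 2, mu2 = 8.5, beta2 = 2, c = 0.3,
             t_onset = 0, sign = sign)
}

zero_noise <- function(seed = 1L) {
  noise_model(white_sd = 0, drift = NULL, linear_trend = 0, seed = seed)
}

# Evaluate expr under a temporary seed without touching the global stream.
with_seed_local <- function(seed, expr) {
  boldlin:::with_seed(seed, expr)
}

# Single-event paradigm without the adaptation pedestal (localizer kind),
# for clean LTI checks on event responses.
new_test_paradigm <- function(duration, onset = 30, len = 120) {
  events <- data.frame(onset_s = onset, duration_s = duration,
                       response_type = "increment",
                       test_duration_s = duration,
                       stringsAsFactors = FALSE)
  boldlin:::new_paradigm(events, run_length_s = len, tr_s = 1,
                         kind = "localizer")
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}
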