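#!/usr/bin/env Rscript
# Generate the synthetic study: one localizer run and three 890-s contrast
# adaptation runs for a grid of voxels, under three nonlinearity regimes
# (none / increment-overestimation with transients / mixed decrements).
# Writes raw time courses, paradigms and ground truth under results/data/.

suppressPackageStartupMessages(library(boldlin))

seed <- 20210831
out_root <- "results/data"

configs <- list(
  linear = list(nonlinearity = "none", noise_sd = 0, drift = NULL,
                linear_trend = 0, n_voxels = 20),
  mixed = list(nonlinearity = "mixed", noise_sd = 1, n_voxels = 50)
)

for (nm in names(configs)) {
  cfg <- configs[[nm]]
  ds <- do.call(simulate_dataset, c(list(seed = seed), cfg))
  dir <- file.path(out_root, nm)
  write_dataset_csv(ds, dir)
  cat(sprintf("%-7s %2d voxels -> %s (runs: %d s localizer, 3 x %d s)\n",
              nm, length(ds$voxels), dir,
              ds$paradigms$localizer$run_length_s,
              ds$paradigms$adaptation[[1]]$run_length_s))
}
cat("Adaptation runs hold 24 trials each: 4 per condition,",
    "12 per condition across runs.\n")
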