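# boldlin

Voxel-wise linearity analysis of BOLD signal increments and decrements.

Most fMRI analyses assume the BOLD response is a linear time-invariant
function of neural activity, so that the response to a long stimulus equals
the response to a short one plus its temporally shifted copies (the
superposition principle). `boldlin` tests that assumption per voxel, for
both positive BOLD deflections (contrast *increments*) and negative ones
(contrast *decrements*) elicited from a common adapted baseline in a
contrast adaptation design. It is aimed at fMRI methodologists who want a
tested, reproducible implementation of the full chain — and a synthetic-data
generator with controllable nonlinearity to validate it against known
ground truth.

## What it computes

For each selected voxel and each prediction pair (1 s → 3 s, 1 s → 6 s,
3 s → 6 s, per response type):

- **Superposition prediction** `P = Σ_j shift(M_short, j · d_short)`,
  scored against the measured long-stimulus response `M` with the signed,
  amplitude-sensitive **Dice index**

  `s_Dice = 2 Σ_t P_t M_t / (Σ_t P_t² + Σ_t M_t²) ∈ [−1, 1]`,

  with chance thresholds from permutation nulls (shuffled time courses
  pushed through the identical preprocessing).
- **Two-gamma HRF fits** (bounded nonlinear least squares, multi-start) of
  each 25-s measured response, `h(t) = A(g(t−t₀; μ₁β₁+1, β₁) −
  c·g(t−t₀; μ₂β₂+1, β₂))`, and the **contrast index** of peak amplitudes
  across durations, `(Amp_short − Amp_long)/(Amp_short + Amp_long)` —
  0 under linearity, > 0 for overestimation, < 0 for underestimation.
- **Voxel selection** from a block-design localizer via FIR-deconvolution
  r², permutation nulls, Benjamini–Hochberg FDR and cluster filtering.
- **FFT-based SNR** (task bin at 0.04 Hz over mean magnitude at
  0.33–0.50 Hz) with median-split groups and Wilcoxon / Kolmogorov–Smirnov
  comparisons.

The synthetic generator produces the full study layout — a 240-s localizer
and three 890-s adaptation runs (24 trials each, 4 per condition) at
TR = 1 s — from per-voxel two-gamma HRFs, with injectable duration gains,
onset/offset transients, habituation, drift and white noise, plus retained
ground truth for recovery tests.

## Worked example

```r
library(boldlin)

ds  <- simulate_dataset(6, seed = 1, nonlinearity = "overest", noise_sd = 1)
vox <- ds$voxels[[1]]
mr  <- preprocess_adaptation(vox$runs$adaptation, ds$paradigms$adaptation,
                             voxel_id = 1)

p16 <- superposition_predict(mr$increment_1, 6)
p36 <- superposition_predict(mr$increment_3, 6)
dice_index(p16, mr$increment_6)   # 0.688
dice_index(p36, mr$increment_6)   # 0.958

f1 <- fit_hrf(mr$increment_1, 1, seed = 1, baseline = "trial_mean")
f6 <- fit_hrf(mr$increment_6, 6, seed = 1, baseline = "trial_mean")
contrast_index(f1$amplitude, f6$amplitude)
# $contrast 0.417   $ratio 2.43
```

Read: with overestimation injected (duration-dependent gain plus
onset/offset transients), the 3-s-based prediction of the 6-s response is
still near-linear (Dice 0.958) while the 1-s-based prediction deviates
(Dice 0.688), and the fitted 1-s HRF amplitude (3.15%) overshoots the 6-s
amplitude (1.30%), giving a positive contrast index of 0.417 — the
overestimation signature. On a zero-noise linear dataset
(`noise_sd = 0, nonlinearity = "none"`) every Dice is ≥ 0.99 and every
|contrast| ≤ 0.05.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on synthetic
data and write tables under `results/`:

1. `01_simulate.R` — generate the datasets (linear control + mixed
   nonlinearity) and export them as CSV/JSON.
2. `02_select_voxels.R` — localizer FIR r², permutation null, FDR,
   clusters → `results/voxels.csv`.
3. `03_linearity.R` — Dice table, chance thresholds, Wilcoxon comparisons
   → `results/dice.csv`.
4. `04_hrf_contrast.R` — HRF fits and contrast indices
   → `results/contrast.csv`, `results/hrf_fits.csv`.
5. `05_snr_report.R` — SNR groups, group comparisons, consolidated
   JSON/CSV report → `results/report/`.

The methods vignette (`vignettes/bold-linearity-methods.Rmd`) documents the
model, every tunable parameter with its default and rationale, the
numerical conventions, and what the generator does and does not emulate.

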