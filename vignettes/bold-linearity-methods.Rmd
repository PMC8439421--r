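---
title: "Testing superposition in BOLD increments and decrements: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing superposition in BOLD increments and decrements: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldlin)
```

## The question and the design

Most fMRI analyses presume the BOLD response is a linear time-invariant
(LTI) function of neural activity: the response to a long stimulus should
equal the response to a short stimulus plus its temporally shifted copies
(superposition). `boldlin` implements a voxel-wise test of this property
for both BOLD signal *increments* and *decrements*, using a contrast
adaptation design: after adapting to an intermediate (25%) contrast, brief
contrast steps up (to 100%) or down (to 6.25%) elicit positive or negative
BOLD deflections from a common adapted baseline, so both response types can
be compared under identical conditions.

The design crosses 2 response types with 3 test durations (1, 3, 6 s). An
adaptation run lasts 890 s: 30 s blank baseline, 60 s adaptation, then 24
trials (4 per condition, seeded random order), each a test stimulus
followed by 30 s of adapting stimulus. A separate 240-s localizer run
alternates 30-s rest and 30-s full-contrast blocks four times and is used
only for voxel selection, so selection cannot leak into the linearity test.

## Forward model of the generator

Each synthetic voxel is an HRF-convolution machine. The neural drive is a
boxcar per event, built at 0.1-s resolution (onset delays and times-to-peak
are sub-second, so TR-resolution evaluation would alias them), convolved
with the voxel's ground-truth two-gamma HRF

$$
h(t) = A\!\left(\frac{(t-t_0)^{\alpha_1-1}\beta_1^{\alpha_1}
e^{-\beta_1 (t-t_0)}}{\Gamma(\alpha_1)}
- c\,\frac{(t-t_0)^{\alpha_2-1}\beta_2^{\alpha_2}
e^{-\beta_2 (t-t_0)}}{\Gamma(\alpha_2)}\right),\qquad t \ge t_0,
$$

with $\alpha_i = \mu_i\beta_i + 1$ so that $\mu_i$ is each component's time
to peak, and $h(t)=0$ before the onset delay $t_0$. Decrement events enter
with negative sign at 0.6 times the increment magnitude, reflecting the
weaker signal decrements carry in this paradigm. Ground-truth parameters
are drawn per voxel from the interior of the restricted fitting box
(`hrf_bounds("restricted")`), so every truth is recoverable by the fit.

Controllable departures from linearity:

* **duration gains** scale the drive per test duration (all 1 = exact LTI
  ground truth); raising the 1-s gain produces overestimation by 1-s-based
  predictions;
* **onset/offset transients** add fixed-size positive bursts (0.5 s wide)
  at stimulus onset and offset, emulating transient neural activity; being
  duration-independent they inflate short-stimulus responses relative to
  long ones, pushing increments toward overestimation and decrements toward
  underestimation;
* **habituation** decays the sustained drive within an event.

The adaptation pedestal is a sustained drive from adaptation onset plus an
exponentially decaying transient (tau = 15 s), giving the characteristic
rapid rise at 30 s and slow decay toward a plateau. Noise is additive in
percent-signal units: white noise (default SD 1%, a typical single-voxel
3T value at TR = 1 s), two low-frequency sinusoids below the 0.0125-Hz
high-pass (amplitudes 0.5% and 0.3%), and a 0.5% linear trend per run.
The `mixed` preset (the default study condition for pattern analyses) sets
increment duration gains to 1.6/1.15/1 for 1/3/6 s with transient amplitude
0.8, and samples each voxel's 1-s decrement gain uniformly in 0.6-1.6, so
decrement deviations span under- to overestimation across voxels while
increments overestimate consistently.

Per-voxel RNG streams are split deterministically from the master seed, so
a dataset is bit-reproducible and earlier voxels are unchanged when the
voxel count grows. What the generator does **not** emulate: head motion,
spatial correlation and smoothing, physiological (cardiac/respiratory)
rhythms, susceptibility artifacts, sub-TR contrast ramps, or retinotopy.
Passing tests therefore demonstrate correctness of the analysis chain under
its stated statistical assumptions, not robustness to every artifact of
scanner data.

## Preprocessing

Localizer runs: percent signal change about the run mean, then linear
detrend and a hard Fourier band-pass of 0.0125-0.2 Hz. The band is
justified by `estimate_signal_band()`: the noiseless block response
concentrates its power from the 1/60-Hz block fundamental up to about
0.15 Hz, and the adaptation-run test signal stays below 0.2 Hz.

Adaptation runs, per run: discard the first 90 volumes (baseline plus
adaptation transient, whose ramp would otherwise contaminate a linear
detrend), percent signal change about the retained-part mean, linear
detrend of the test period, 0.2-Hz low-pass. Then per condition: extract
each trial's window (test duration + 30 s, e.g. 31 samples for a 1-s
trial - a 1-s stimulus at 200 s covers volumes 201-231 in 1-based
numbering), concatenate the 12 trials across the three runs (372 samples
for the 1-s condition), high-pass the recombined course at its 10th FFT
component (10/372 = 0.0269 Hz for the 1-s condition), and average trials
into a 25-sample measured response.

Numerical conventions fixed here (the underlying tools leave them open):
filters are brick-wall DFT masks with mean and trend removed beforehand and
not restored; band-pass masks drop bins strictly outside the cut
frequencies, while the component-indexed high-pass removes DC and
components 1..k inclusive (either convention keeps the trial-locked signal,
which lives at multiples of 12 cycles per course; inclusive removal was
fixed for determinism). Trial windows use 0-based half-open sample
intervals internally. A non-integer trial window at the given TR is a hard
error rather than an interpolation, since every in-scope design has
TR = 1 s.

## Voxel selection

Activation is scored with finite-impulse-response (FIR) deconvolution:
least squares on lagged copies of the stimulus indicator (window L = 25
samples, matching the measured-response length; the window is not dictated
by the design, only by the requirement to cover the HRF) plus an intercept
(percent conversion leaves a constant the lagged indicator cannot absorb).
`r2` is the fraction of variance about the mean explained by the fit.
Significance comes from a permutation null: time points of the raw courses
are shuffled, pushed through the identical preprocessing, and refit; the
empirical false-positive rate of a voxel uses the add-one estimator
$(1 + \#\{null \ge obs\})/(1 + n)$ so no p-value is exactly zero. Rates
are BH-corrected across voxels; selected voxels must also show a positive
early localizer response (mean FIR taps over 0-15 s > 0) and belong to a
face-connected cluster of at least `min_cluster` voxels (default 4; the
source analysis sized clusters to its visual stimuli without giving a
number, so this is a parameter). An AR(1)-surrogate null
(`null_model = "ar1"`) is available to check that temporal autocorrelation
does not inflate the shuffle null. Desk-scale null sizes default to
500-2000 pooled samples; the study-scale figure is 100 000.

## Linearity scoring

Superposition predictions: the 3-s response shifted by 3 s and summed
predicts the 6-s response, and likewise 1 s -> 3 s and 1 s -> 6 s.
Truncation to the 25-sample window happens after summation. Similarity is
the signed, amplitude-sensitive Dice index

$$ s_{Dice} = \frac{2\sum_t P_t M_t}{\sum_t P_t^2 + \sum_t M_t^2} \in [-1, 1], $$

which equals 1 iff $P = M$ and, unlike correlation, penalises pure
amplitude mismatch: $s_{Dice}(kM, M) = 2k/(k^2+1)$. Chance levels come
from a Dice permutation null. The construction shuffles the *pre-processed
per-run courses* and rebuilds measured responses and predictions through
the identical recombine/high-pass/average chain - the most
pipeline-faithful of the possible choices (shuffling raw runs or the final
25-sample responses were the alternatives; the original description does
not say which object was shuffled). Thresholds are one-tailed at
FPR = 0.05; across voxels the "corrected" threshold applies BH to the
empirical upper-tail p-values (the correction method was unnamed in the
source; BH matches the selection step).

## HRF fitting and the contrast index

Each measured response is fitted by the two-gamma model response: boxcar of
the condition's duration convolved with the signed HRF on a 0.1-s grid
(computed as a windowed running sum of $h$, which is exact for a boxcar)
and sampled at volume times. Decrements are fitted with the negative HRF.
The optimizer is bounded Levenberg-Marquardt least squares
(`minpack.lm::nls.lm`, ftol = ptol = 1e-10, up to 2000 evaluations per
start) with 10 seeded Latin-hypercube starts inside the box; restricted
bounds are $\mu_1\in[0.5,8]$, $\mu_2\in[4,16]$, $\beta_i\in[0,5]$,
$c\in[0,1]$, $t_0\in[0,5]$, $A\in[0,20]$ (A in percent signal change, the
natural unit of the data), with a flexible alternative used to confirm that
deviation patterns are not bound artifacts. $\beta_i = 0$ is treated as the
degenerate limit in which that gamma component vanishes.

One pipeline-specific subtlety: the component-indexed high-pass zeroes the
DC of the recombined course, so measured responses are mean-zero over the
full trial window and sit a constant below the raw convolution. Fits of
pipeline outputs therefore use `baseline = "trial_mean"`, which subtracts
the model's own mean over the trial window (duration + 30 s) before
comparing - the model then contains the preprocessed LTI generator exactly,
with no extra free parameter. Fits of raw forward-model responses (e.g.
parameter-recovery studies) use `baseline = "none"`.

The fitted amplitude is the peak magnitude of the HRF itself - the maximum
of a positive or the magnitude of the minimum of a negative HRF, searched
on $[t_0, t_0 + \mu_2]$ so the post-peak under/overshoot is excluded.
Deviation from linearity is summarised by the contrast index

$$ \mathrm{Contrast} = \frac{Amp_{short} - Amp_{long}}
{Amp_{short} + Amp_{long}}, $$

zero under linearity, positive for overestimation, negative for
underestimation; the amplitude ratio is also reported
($\mathrm{Contrast} = (ratio-1)/(ratio+1)$), but the contrast index is the
primary statistic because it is bounded and symmetric. Each contrast
distribution is compared against a zero-mean normal with the distribution's
own SD (one-sample Kolmogorov-Smirnov), mirroring the question "is this
centred noise or a shifted/shaped deviation?".

## SNR analysis

Per voxel and response type, all 36 trials (12 per duration) are truncated
to 25 samples and concatenated, making the task periodicity 25 s per cycle
(0.04 Hz). SNR is the DFT magnitude at the task bin divided by the mean
magnitude over 0.33-0.50 Hz (endpoints inclusive; inclusivity was
unspecified). The SNR input is the percent-change, detrended course
*without* the 0.2-Hz low-pass: a noise band at 0.33-0.50 Hz is only
meaningful if the high-frequency noise it measures has not been filtered
out, so the low-pass used elsewhere in the pipeline is deliberately skipped
here (it remains available as an argument). An `"all_but_task"` noise band reproduces the robustness
check that the band choice does not drive group differences. Voxels are
median-split into low/high SNR groups per response type; the voxel sitting
exactly at the median goes to the low group by default (`median_to_low`),
and the rule is configurable because a 223-voxel split into 111/112 does
not disclose its tie handling. Note the related figure caption in the
source describes the split by median $r^2$ while its text says median SNR;
the text's rule is what `snr_table()` implements. Group comparisons use
Wilcoxon signed-rank (normal approximation with tie and continuity
correction above n = 25, exact enumeration below) and two-sample KS tests,
BH-corrected per reported family.

## Problem sizes and runtime choices

The packaged analyses and tests run at desk scale, chosen so the full suite
completes in minutes while every statistical property remains testable:
20-50 voxels per dataset, permutation nulls of 400-2000 pooled samples
(with the 1e5 study scale reachable by argument), 10 optimizer starts per
fit, and 100-fit parameter-recovery batches. The acceptance checks assert
the exact design arithmetic (890-s runs, 372-sample recombined courses,
0.0269-Hz cutoff, 0.04-Hz task frequency), analytic statistic identities,
near-perfect recovery of linearity on noise-free LTI data (Dice >= 0.99,
|contrast| <= 0.05 - the residual is filter edge effect, not model error),
and the qualitative deviation patterns under injected nonlinearity.

## Known limitations

* The generator's nonlinearities act on the neural drive; hemodynamic
  nonlinearity (e.g. balloon-model dynamics) is not modeled, so the package
  can emulate the *patterns* of deviation but not adjudicate their
  physiological origin.
* Voxels are simulated independently; spatially correlated noise would
  make the cluster filter's false-positive behaviour optimistic here.
* The Dice permutation null destroys temporal autocorrelation along with
  signal; the AR(1) surrogate option exists for the r2 null, and the same
  caveat applies to chance thresholds.
* Real-data ingestion (4D NIfTI plus paradigm tables) is supported at the
  container level (`read_dataset_csv()`, `write_dataset_nifti()`), but no
  motion correction, slice timing, registration or anatomical masking is
  provided - inputs are assumed motion-corrected and V1-masked upstream.
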