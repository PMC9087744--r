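---
title: "Methods: multimodal seizure analysis with ictalwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal seizure analysis with ictalwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ictalwave)
```

## The analysis problem

`ictalwave` analyzes acute hippocampal seizures observed simultaneously
at two scales: extracellular voltage on a small planar microelectrode
grid (nominally a 4 x 4 array at 0.5 mm pitch sampled at 20 kHz) and
somatic calcium fluorescence of tens to hundreds of CA1 pyramidal cells
imaged at 5-10 Hz through a transparent electrode substrate. The four
analysis families, and the statistics each one produces, are:

1. **Cellular recruitment.** Per-cell dF/F onset times at seizure
   start, the recruitment duration (last minus first onset), and the
   reliability of the cell recruitment order across recurrent seizures
   (pairwise Spearman correlations; Kendall's W with a permutation
   null).
2. **Oscillatory coupling.** High-gamma (80-150 Hz) bursts and
   multiunit spikes (300-3000 Hz) detected per channel and referred to
   the instantaneous phase of the low-frequency (4-30 Hz) discharge;
   observed phase distributions are compared against matched-size
   uniform null samples with circular tests.
3. **Traveling waves.** Each ictal discharge is reduced to per-channel
   peak times, grouped across the array, and fit with a plane
   $t = a x + b y + c$; the gradient $(a, b)$ gives the propagation
   direction `atan2(b, a)` and speed $1/\sqrt{a^2 + b^2}$.
   Direction distributions are tested for nonuniformity (Hodges-Ajne)
   and compared across datasets (Kolmogorov-Smirnov on linearized
   angles); speeds from the first and last quarter of the seizure are
   compared with a Mann-Whitney U test.
4. **Speed prediction.** Ten features per sliding window (five
   electrophysiological, five calcium-derived) predict the per-window
   median wave speed through ensembles of bagged CART regression trees
   with 5-fold cross validation, out-of-bag permutation importance,
   and evaluation on a withheld seizure.

## Signal-processing conventions

* **Zero-phase filtering.** All band filters are second-order
  Butterworth designs applied forward and backward
  (`signal::filtfilt`). Phase analyses presuppose undistorted phase, so
  causal filtering is not offered; the effective magnitude order is
  doubled, which is documented rather than compensated.
* **Rates.** Low-frequency and high-gamma analyses run at 2 kHz
  (anti-aliased decimation from the acquisition rate); the spike band
  stays at the native rate because a 1 ms biphasic waveform cannot be
  represented at 2 kHz.
* **Phase convention.** Instantaneous phase comes from the FFT-based
  analytic signal with phase 0 at a positive peak of the band-limited
  waveform. The first and last 5% of samples are flagged unreliable
  (circular-continuation artifact) but are not silently dropped.
* **Event definitions.** A high-gamma event is a suprathreshold
  (mean + 2.5 SD of the envelope) local maximum of the Hilbert
  amplitude with a one-cycle (1/80 s) refractory separation. A
  multiunit event is a trough below
  $t = -4\,\mathrm{median}(|x|/0.6745)$ with a 1 ms refractory
  separation; the median-based scale estimate makes the threshold
  insensitive to the spikes themselves and exactly scale-equivariant.
* **Discharge peaks** are detected on the rectified low-frequency
  signal (threshold mean + 2 SD of $|x|$, both moments on the
  rectified signal) so that discharge polarity does not matter; an
  `sd_of = "signal"` variant is provided because the moment convention
  is a free choice. One rectified oscillation can produce suprathreshold
  peaks on more than one carrier cycle; the 150 ms single-linkage
  grouping step keeps one peak per channel per discharge (largest
  amplitude, earliest on ties), and events on at most 60% of functional
  channels are discarded.

## Calcium conventions

dF/F is normalized to the mean of the preseizure baseline epoch;
traces are smoothed with the order-2, window-7 Savitzky-Golay filter.
The onset threshold for each cell is mean + 5 SD of the 25 frames
immediately preceding the analysis window, and the onset is the first
in-window frame above threshold. The analysis window itself (a manual
step in typical practice) is auto-selected as the 80-frame window
centered on the first population-mean threshold crossing, with a
manual override. Ties in onset frame receive average (fractional)
ranks, consistent with the Spearman/Kendall conventions used
downstream; sample SD (n-1) is used everywhere.

For the onset-direction vector, the rank-1 and maximum-rank cell
centroids are averaged and differenced; the vector is reflected about
the image x-axis and rotated 30 degrees toward the y-axis to map the
camera frame onto anatomical axes. The rotation sense is
counterclockwise by default and exposed as a signed parameter, because
the transformation is rig-specific.

## Circular statistics

No circular-statistics package is part of this stack, so the package
implements the standard procedures directly: the Best-Fisher von Mises
sampler; the Watson-Williams multisample F test with the usual
concentration correction `1 + 3/(8 kappa)`; Fisher's nonparametric
common-median test; and the Hodges-Ajne omnibus test (exact tail for
n <= 50, the classical approximation otherwise). Two-sample phase
comparisons use Watson-Williams when the pooled mean resultant length
is at least 0.45 and otherwise fall back to the common-median test.
For two samples the common-median p value is computed from the exact
conditional (hypergeometric) distribution of the below-median count
rather than the chi-squared approximation: at these sample sizes the
chi-squared version runs measurably liberal (about 7% rejections at
the 5% level in uniform-vs-uniform calibration), while the exact
version is correctly calibrated. The chi-squared statistic is still
reported.

The Kendall's W permutation null redraws each seizure's rank vector as
a random permutation of 1..max observed rank (sampling with
replacement when ties leave the maximum rank below the cell count,
since a permutation cannot cover more cells than ranks). The
permutation p value uses the add-one convention
$(1 + \#\{W_{perm} \ge W_{obs}\})/(1 + n_{perm})$ so it is never
exactly zero.

## Feature extraction

Sliding windows are 4 s long with 1 s overlap, i.e. a 3 s step; the
step is a parameter because "1 s overlap" could also be read as a 1 s
step. Band filtering and envelope extraction are done once on the full
record rather than per window, to avoid per-window filter transients.
Fractional band powers divide the Hann-tapered periodogram integral
over 4-30 Hz (or 80-150 Hz) by the integral over all frequencies. The
phase-locking value is

$$PLV = \Big|\tfrac1N \sum_n \exp\!\big(i(\varphi_{4-30}[n] -
\varphi_{a(80-150)}[n])\big)\Big|,$$

where $\varphi_{a(80-150)}$ is the phase of the high-gamma amplitude
envelope; the envelope is band-passed to 4-30 Hz before its Hilbert
phase is taken, which removes its DC offset and makes its phase well
defined. Calcium windows use frames whose (sync-offset-corrected)
timestamps fall in `[start, end)`; the per-cell "SD of the first
derivative" is computed per cell then averaged (a pooled variant is a
flag). The per-window speed target is the median of the speeds of
discharges whose peak time falls in the window; windows without any
discharge are marked missing and excluded from model training.

## The tree ensemble

Each ensemble draws `cv_folds = 5` folds; a bagged forest (bootstrap
resamples, deep CART trees, minimum leaf size 5) is grown per fold and
the fold model with the best held-out Pearson r is kept — a literal
reading of storing "the model that best generalized" to the withheld
fraction. Split selection is standard variance-reduction CART rather
than a curvature-test-based unbiased selector: with ten continuous
features and no categorical predictors, the two selectors differ least,
and no unbiased-selection implementation is available in this stack.
Surrogate splits are likewise off by default — they exist to route
missing values, and the pipeline produces none by construction.
Out-of-bag importance permutes each feature across a tree's out-of-bag
rows and records the rise in OOB mean squared error, averaged over
trees and divided by its SD over trees. Training is balanced by
subsampling the longer seizures to the shortest seizure's usable row
count, so each training seizure contributes equally.

Full-scale runs use 1000 ensembles of 100 trees; the package defaults
to 200 x 50 for desk-scale work, and the test suite and acceptance
script use 100-200 ensembles of 50 trees with 10 smaller replicate runs
(20 x 25) for importance-stability checks. These sizes were chosen so a
complete run stays in the minutes range on a single core while leaving
the ensemble statistics (medians over ensembles, importance rankings)
stable.

## The synthetic study

The generator plants every quantity the pipeline later estimates:

* Each discharge is an 8 Hz carrier under a Gaussian envelope
  (sigma = 40 ms), keeping its energy inside the 4-30 Hz band; its
  per-channel peak times lie exactly on the plane implied by the
  planted speed and direction, plus Gaussian timing jitter (default
  SD 2 ms). Discharges arrive at 1 Hz; the planted speed starts at
  500 mm/s and is multiplied by `speed_trend` (default 0.995) at each
  discharge, modeling late-seizure slowing.
* High-gamma bursts (120 Hz carrier, 30 ms envelope) and biphasic
  1 ms multiunit spikes are planted at times whose analyzed
  low-frequency phase equals a von Mises draw around the configured
  locking phase. Because the discharge wavelet is not narrowband, the
  instantaneous phase away from its peak is not simply the carrier
  phase; the generator therefore measures the wavelet's filtered
  analytic-phase profile once and inverts it, so planted phases are
  exact by construction. Multiunit amplitude defaults to 6 noise SDs
  within the spike band, after compensating the band-pass attenuation
  of the pulse shape, so threshold detection succeeds by design.
* Calcium traces are zero until the cell's planted onset, then a
  sustained onset response plus one indicator transient per subsequent
  discharge (rise 0.2 s, decay 1.5 s — GCaMP6s-like; indicator
  saturation is not modeled). Transient amplitudes follow
  `dff_amp_trend` (defaulting to `speed_trend`), which plants calcium
  amplitude and line length that co-decay with the wave speed while
  high-gamma burst amplitude stays stationary — the causal coupling
  the speed model is later asked to recover. Onsets spread over
  1.2 s (the emulated median recruitment duration) in a study-level
  template order perturbed per seizure by `onset_rank_noise` (SD in
  units of `n_cells` ranks); centroids advance along the +x image axis
  with template rank so the onset-direction vector is recoverable.
* All randomness derives from one master seed through fixed
  per-component substreams, so e.g. adding cells does not perturb the
  LFP noise, and identical configurations are bit-identical.

What the generator does **not** emulate: 1/f background spectra,
electrode impedance differences, movement and neuropil contamination,
imaging gaps between acquisition series, indicator saturation, and
non-planar (curved or colliding) wavefronts. Passing parameter-recovery
tests on this generator therefore demonstrates correctness of the
estimators under the stated signal model, not robustness to every
artifact of real recordings.

## Numerical choices and degenerate inputs

* Plane fits with a gradient norm below $10^{-9}$ s/mm are flagged
  degenerate (simultaneous discharge) rather than reported as
  near-infinite speeds; collinear channel geometry is an error.
* Peak pickers resolve competing candidates greedily by amplitude,
  earliest-first on exact ties.
* Mann-Whitney tests use the normal approximation without continuity
  correction, so identical epoch distributions give p = 1 exactly.
* Cells with zero baseline SD are excluded from onset analysis with a
  warning; windows in which every cell is constant are errors; pairs
  involving a constant cell are dropped from correlation features with
  a logged count.
* Epoch comparisons ("first vs last 25% of the seizure duration") are
  time-based, not count-based, and consider only windows carrying a
  wave observation, so the seizure span is measured from discharge
  activity rather than recording bounds.
* Spearman p values use the large-sample approximation
  (`cor.test(..., exact = FALSE)`); onset-vector endpoints use the
  literal maximum rank (not a top bin).

## Scale of the bundled analyses

Simulated studies in the tests and the acceptance script use 2 kHz
electrophysiology (the rate at which all band analyses run), 120-240 s
seizures, 4 x 4 grids, 12-30 cells, and 3 + 1 seizures for model
training and withholding; multiunit tests use short 20 kHz records.
These sizes keep a full run on one core in the minutes range while
every statistic of interest (event counts in the hundreds, feature
tables with ~40-80 rows per seizure) remains comfortably estimable.

## Known limitations

* The bundle format is a plain-text directory (CSV + JSON), chosen for
  portability and inspectability; very long recordings would warrant a
  binary hierarchical container instead.
* The Watson-Williams applicability rule is the standard pooled-
  resultant criterion (>= 0.45); borderline concentrations near the
  cutoff switch tests discontinuously.
* KS tests on directions operate on linearized angles on
  $(-\pi, \pi]$; a cut-point sensitivity re-run (cut at 0) is included
  as a diagnostic, but a genuinely circular two-sample test (Kuiper)
  is not implemented.
* Recruitment analysis assumes one contiguous onset per seizure;
  re-entrant or multi-focal onsets are outside the model.
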