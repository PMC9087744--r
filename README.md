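# ictalwave

Multimodal analysis of acute hippocampal seizures recorded
simultaneously with a planar microelectrode array and two-photon
calcium imaging of CA1 pyramidal cells. The package is written for
experimenters using transparent-electrode preparations (or any paired
grid-electrophysiology + cellular-imaging recording) who want to move
from raw traces to the standard battery of seizure statistics:

* **Cellular recruitment** — per-cell dF/F onset detection
  (mean + 5 SD of a 25-frame pre-window baseline), recruitment
  duration, and recruitment-order reliability across recurrent
  seizures: pairwise Spearman r and Kendall's W with a permutation
  null, plus onset-direction vectors in anatomical coordinates.
* **Phase coupling** — high-gamma (80–150 Hz) bursts and multiunit
  spikes (300–3000 Hz, threshold
  `t = -4 median(|x|/0.6745)`) referred to the instantaneous 4–30 Hz
  phase; 18-bin phase histograms and circular tests
  (Watson–Williams, common-median fallback, Hodges–Ajne omnibus)
  against matched-size uniform nulls.
* **Traveling waves** — per-channel discharge peaks grouped across the
  array (150 ms linkage, >60% channel gate) and fit with a plane
  `t = a·x + b·y + c`; direction `atan2(b, a)`, speed
  `1/sqrt(a² + b²)`; nonuniformity and between-dataset comparisons of
  directions; Mann–Whitney comparison of speeds in the first versus
  last 25% of the seizure.
* **Speed prediction** — ten sliding-window features (mean/SD
  high-gamma amplitude, fractional 4–30 and 80–150 Hz power, the
  phase-locking value `PLV = |mean exp(i(φ_lf − φ_env))|`; mean dF/F,
  line length `LL = Σ|d(ΔF/F)/dt|`, SD of the dF/F derivative, and
  mean/SD pairwise correlations) feed bagged CART regression-tree
  ensembles with 5-fold cross validation, out-of-bag permutation
  importance, and evaluation on a withheld seizure.

A seeded synthetic generator (`synth_config()`, `generate_study()`)
produces paired recordings with planted wave speed/direction,
phase-locked bursts and spikes, and a reproducible cell-recruitment
order, so every estimator is validated by parameter recovery.

## Worked example

```r
library(ictalwave)

cfg <- synth_config(seed = 20, duration_s = 115, ephys_rate = 2000,
                    n_cells = 4, speed_trend = 1, timing_jitter_ms = 2)
rec <- generate_lfp(cfg)

ev <- wave_events(rec$recording)   # detect, group, and fit every discharge
nrow(ev)
#> [1] 104
median(ev$speed_mm_s)              # planted: 500 mm/s, 2 ms timing jitter
#> [1] 455.4588
median(ev$direction_rad) * 180 / pi  # planted: 45 degrees
#> [1] 41.84242
```

The 104 fitted events recover the planted propagation direction to
within ~3 degrees; the median speed sits ~9% below the planted
500 mm/s, the expected attenuation from 2 ms per-channel timing jitter
on a 0.5 mm-pitch grid. With jitter removed both recover exactly:

```r
cfg0 <- synth_config(seed = 3, duration_s = 20, ephys_rate = 2000,
                     wave_direction_rad = 0, timing_jitter_ms = 0,
                     noise_sd_ephys = 0, speed_trend = 1)
ev0 <- wave_events(generate_lfp(cfg0)$recording)
median(ev0$speed_mm_s)
#> [1] 500
```

The full pipeline — simulation, onsets, phase coupling, waves,
features, tree ensembles, epoch comparisons — runs in one call:

```r
res <- run_pipeline(pipeline_config(
  synth = synth_config(seed = 1, duration_s = 150, ephys_rate = 2000,
                       n_cells = 20, speed_trend = 0.995),
  n_seizures = 4, n_ensembles = 100, n_trees = 50, seed = 1))
res$reliability$kendall_w           # recruitment-order concordance
res$speed_epochs[[1]]               # early vs late wave speeds
res$model$evaluation$importance_summary
```

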