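# Sliding-window multimodal feature extraction: five electrophysiology
# features, five calcium features, and the per-window median
# traveling-wave speed target.

#' Sliding analysis windows
#'
#' Windows of `win` seconds with `win - step` seconds of overlap
#' (default 4 s windows, 1 s overlap, i.e. step 3 s), while the window
#' end stays within the record.
#'
#' @param total_duration_s record duration, seconds.
#' @param win window length, seconds (default 4).
#' @param step window step, seconds (default 3).
#' @return data.frame with `start_s`, `end_s`; zero rows (with a
#'   warning) if the record is shorter than one window.
#' @export
make_windows <- function(total_duration_s, win = 4, step = 3) {
  if (total_duration_s < win) {
    warning("record shorter than one window")
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  starts <- seq(0, total_duration_s - win, by = step)
  data.frame(start_s = starts, end_s = starts + win)
}

#' Phase-locking value
#'
#' \deqn{PLV = |N^{-1} \sum_n \exp(i(\phi_1[n] - \phi_2[n]))|}
#' the magnitude of the mean unit phasor of the phase difference:
#' 1 for a constant phase difference, ~0 for independent phases.
#'
#' @param phi1,phi2 numeric vectors of phases, radians, equal length.
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(phi1, phi2) {
  stopifnot(length(phi1) == length(phi2), length(phi1) > 0)
  Mod(mean(exp(1i * (phi1 - phi2))))
}

# Hann-tapered periodogram band-power fraction: integral of the power
# spectrum over [lo, hi] divided by the integral over all frequencies.
frac_band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  X <- fft((x - mean(x)) * w)
  nf <- floor(n / 2) + 1
  pw <- Mod(X[seq_len(nf)])^2
  f <- (seq_len(nf) - 1) * rate / n
  tot <- sum(pw)
  if (tot == 0) return(0)
  sum(pw[f >= lo & f <= hi]) / tot
}

#' Electrophysiology features of one channel over sliding windows
#'
#' Filters the whole record once (zero-phase, avoiding per-window edge
#' transients), then per window computes: mean and SD of the high-gamma
#' (80-150 Hz) Hilbert amplitude; fractional 4-30 Hz and 80-150 Hz
#' band power (Hann periodogram); and the phase-locking value between
#' the 4-30 Hz phase and the phase of the high-gamma amplitude envelope
#' (the envelope is itself band-passed to 4-30 Hz before its Hilbert
#' phase is taken, removing its DC offset).
#'
#' @param x numeric vector: one channel at `rate` (use the 2 kHz
#'   downsampled signal).
#' @param rate sampling rate, Hz.
#' @param windows data.frame from [make_windows()].
#' @return data.frame: `start_s`, `end_s`, `mean_hg_amp`, `sd_hg_amp`,
#'   `frac_power_4_30`, `frac_power_80_150`, `plv`.
#' @export
ephys_window_features <- function(x, rate, windows) {
  if (nrow(windows) == 0)
    return(cbind(windows, mean_hg_amp = numeric(0), sd_hg_amp = numeric(0),
                 frac_power_4_30 = numeric(0), frac_power_80_150 = numeric(0),
                 plv = numeric(0)))
  if (any(windows$end_s - windows$start_s < 2 / 4))
    stop("window shorter than two cycles of the low-frequency band edge")
  lf <- bandpass(x, rate, c(4, 30))
  hg <- bandpass(x, rate, c(80, 150))
  lf_an <- analytic_signal(lf, rate)
  hg_an <- analytic_signal(hg, rate)
  env_lf <- bandpass(hg_an$amplitude, rate, c(4, 30))
  env_an <- analytic_signal(env_lf, rate)
  n <- length(x)
  out <- lapply(seq_len(nrow(windows)), function(i) {
    a <- max(1L, floor(windows$start_s[i] * rate) + 1L)
    b <- min(n, ceiling(windows$end_s[i] * rate))
    seg <- a:b
    data.frame(
      start_s = windows$start_s[i], end_s = windows$end_s[i],
      mean_hg_amp = mean(hg_an$amplitude[seg]),
      sd_hg_amp = sd(hg_an$amplitude[seg]),
      frac_power_4_30 = frac_band_power(x[seg], rate, 4, 30),
      frac_power_80_150 = frac_band_power(x[seg], rate, 80, 150),
      plv = plv(lf_an$phase[seg], env_an$phase[seg]))
  })
  do.call(rbind, out)
}

#' Calcium features over sliding windows
#'
#' Per window (frames with timestamps in `[start, end)` after applying
#' the modality sync offset): mean dF/F over all cells and frames;
#' per-cell line length \eqn{LL = \sum |\mathrm{diff}(\Delta F/F)|}
#' averaged over cells; per-cell SD of the first difference averaged
#' over cells; and the mean and SD of all pairwise Pearson correlations
#' between cells (pairs involving a constant cell are dropped and
#' counted).
#'
#' @param traces a `"calcium_traces"` object.
#' @param windows data.frame from [make_windows()] (ephys clock).
#' @param sync_offset_s seconds added to frame times to align the
#'   imaging clock with the ephys clock (default 0).
#' @return data.frame: `start_s`, `end_s`, `mean_dff_amp`,
#'   `mean_dff_line_length`, `mean_sd_dff_derivative`, `mean_pair_corr`,
#'   `sd_pair_corr`, `n_dropped_pairs`.
#' @export
calcium_window_features <- function(traces, windows, sync_offset_s = 0) {
  dff <- traces$dff
  nc <- nrow(dff)
  if (nc < 2) stop("need at least 2 cells")
  t_f <- (seq_len(ncol(dff)) - 1) / traces$frame_rate + sync_offset_s
  out <- lapply(seq_len(nrow(windows)), function(i) {
    idx <- which(t_f >= windows$start_s[i] & t_f < windows$end_s[i])
    if (length(idx) < 3) stop("fewer than 3 frames in a window")
    w <- dff[, idx, drop = FALSE]
    d <- t(apply(w, 1, diff))
    sds <- apply(w, 1, sd)
    if (all(sds == 0)) stop("no variance: all cells constant in window")
    cm <- suppressWarnings(cor(t(w)))
    pc <- cm[upper.tri(cm)]
    dropped <- sum(is.na(pc))
    pc <- pc[!is.na(pc)]
    data.frame(
      start_s = windows$start_s[i], end_s = windows$end_s[i],
      mean_dff_amp = mean(w),
      mean_dff_line_length = mean(rowSums(abs(d))),
      mean_sd_dff_derivative = mean(apply(d, 1, sd)),
      mean_pair_corr = mean(pc),
      sd_pair_corr = if (length(pc) > 1) sd(pc) else 0,
      n_dropped_pairs = dropped)
  })
  do.call(rbind, out)
}

#' Per-window traveling-wave speed targets
#'
#' The target of a window is the median of the speeds of all discharge
#' events whose peak time falls in `[start, end)`; windows without any
#' event get `NA` ("missing").
#'
#' @param event_times,event_speeds numeric vectors (one entry per
#'   discharge event).
#' @param windows data.frame from [make_windows()].
#' @return numeric vector of targets, one per window.
#' @export
window_speed_targets <- function(event_times, event_speeds, windows) {
  stopifnot(length(event_times) == length(event_speeds))
  vapply(seq_len(nrow(windows)), function(i) {
    inw <- event_times >= windows$start_s[i] & event_times < windows$end_s[i]
    if (!any(inw)) NA_real_ else median(event_speeds[inw])
  }, 0)
}

#' Assemble the per-seizure multimodal feature table
#'
#' Runs the full window pipeline for one seizure: downsamples the
#' selected channel to `analysis_rate`, extracts the five ephys and five
#' calcium features on identical windows, and attaches the median wave
#' speed target from the discharge-event table.
#'
#' @param recording a `grid_recording`.
#' @param calcium a `calcium_traces` object.
#' @param channel_id id of the electrode above the imaging plane.
#' @param events discharge-event table from [wave_events()].
#' @param win,step window length and step, seconds.
#' @param sync_offset_s imaging-to-ephys clock offset, seconds.
#' @param analysis_rate rate for the band analyses, Hz (default 2000).
#' @return data.frame with window bounds, the ten features in fixed
#'   column order, and `target_speed_mm_s` (NA where no discharge event
#'   fell in the window).
#' @export
build_feature_table <- function(recording, calcium, channel_id, events,
                                win = 4, step = 3, sync_offset_s = 0,
                                analysis_rate = 2000) {
  ch <- match(channel_id, recording$geometry$channel)
  if (is.na(ch)) stop("unknown channel_id")
  dur <- ncol(recording$signals) / recording$rate
  windows <- make_windows(dur, win = win, step = step)
  ds <- downsample_signal(recording$signals[ch, ], recording$rate,
                          target_rate = min(analysis_rate, recording$rate))
  ef <- ephys_window_features(ds$x, ds$rate, windows)
  cf <- calcium_window_features(calcium, windows, sync_offset_s)
  stopifnot(nrow(ef) == nrow(cf))
  tab <- cbind(ef,
               cf[, c("mean_dff_amp", "mean_dff_line_length",
                      "mean_sd_dff_derivative", "mean_pair_corr",
                      "sd_pair_corr")])
  tab$target_speed_mm_s <- window_speed_targets(
    events$t_center_s, events$speed_mm_s, windows)
  tab
}

# the ten model features, in contract column order
feature_names <- function(modality = c("multimodal", "ephys", "calcium")) {
  modality <- match.arg(modality)
  e <- c("mean_hg_amp", "sd_hg_amp", "frac_power_4_30",
         "frac_power_80_150", "plv")
  c0 <- c("mean_dff_amp", "mean_dff_line_length", "mean_sd_dff_derivative",
          "mean_pair_corr", "sd_pair_corr")
  switch(modality, multimodal = c(e, c0), ephys = e, calcium = c0)
}
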