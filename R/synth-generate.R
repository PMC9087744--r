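# Synthetic multimodal seizure generator.
#
# Signal model: each ictal discharge is an 8 Hz carrier under a Gaussian
# envelope (sigma = 40 ms), so its energy sits inside the 4-30 Hz
# analysis band and its instantaneous low-frequency phase near the peak
# is the carrier phase (0 at the peak, cosine convention). Per-channel
# peak times lie on a plane determined by the planted speed/direction,
# plus optional Gaussian jitter. High-gamma bursts (120 Hz carrier,
# 30 ms Gaussian envelope) and brief biphasic multiunit spikes are
# planted at times whose low-frequency phase is a von Mises draw around
# the configured locking phase.

# fixed waveform constants (see vignette)
.WAVELET_F <- 8        # Hz, discharge carrier
.WAVELET_SIGMA <- 0.040  # s, discharge envelope SD
.HG_F <- 120           # Hz, high-gamma carrier
.HG_SIGMA <- 0.0075    # s, burst envelope SD
.MUA_WIDTH <- 0.001    # s, biphasic spike duration

# RNG substream indices
.SUB_NOISE <- 1L; .SUB_JITTER <- 2L; .SUB_HG <- 3L; .SUB_MUA <- 4L
.SUB_TEMPLATE <- 5L; .SUB_RANKS <- 6L; .SUB_DFF_NOISE <- 7L
.SUB_CENTROIDS <- 8L; .SUB_STUDY <- 9L

grid_geometry <- function(cfg) {
  rows <- cfg$grid_shape[1]; cols <- cfg$grid_shape[2]
  rc <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  data.frame(channel = seq_len(nrow(rc)),
             x_mm = (rc$col - (cols + 1) / 2) * cfg$pitch_mm,
             y_mm = (rc$row - (rows + 1) / 2) * cfg$pitch_mm,
             functional = TRUE)
}

discharge_schedule <- function(cfg) {
  t0 <- cfg$baseline_s + 1
  t1 <- cfg$duration_s - 0.5
  if (t1 <= t0) stop("record too short for any discharge")
  times <- seq(t0, t1, by = 1 / cfg$discharge_rate_hz)
  k <- seq_along(times)
  list(times = times,
       speeds = cfg$wave_speed_mm_s * cfg$speed_trend^(k - 1),
       hg_amps = cfg$hg_amp_uv * cfg$hg_amp_trend^(k - 1),
       dff_amps = cfg$dff_transient_amp * cfg$dff_amp_trend^(k - 1))
}

# clipped slice bounds for adding an m-sample waveform at index i1
clip_at <- function(n, i1, m) {
  a <- max(1L, i1); b <- min(n, i1 + m - 1L)
  if (a > b) NULL else list(dst = a:b, src = (a - i1 + 1L):(b - i1 + 1L))
}

#' Generate a grid electrophysiology recording with ground truth
#'
#' Simulates a seizure on the configured electrode grid: a train of
#' low-frequency discharges propagating as plane waves at the planted
#' speed and direction (with optional per-discharge slowing), high-gamma
#' bursts and multiunit spikes phase-locked to the discharge, and
#' additive white noise. Multiunit spikes are only synthesized when
#' `ephys_rate >= 8000` Hz (a 1-ms biphasic pulse cannot be represented
#' below that).
#'
#' @param config a [synth_config()].
#' @return list with `recording` (class `"grid_recording"`: `signals`
#'   channels x samples in microvolts, `rate`, `geometry`) and `truth`
#'   (class `"ground_truth"`: discharge times/speeds/directions, the
#'   per-channel planted peak-time matrix, and data.frames of planted
#'   high-gamma bursts and multiunit spikes with their phases).
#' @export
generate_lfp <- function(config) {
  cfg <- validate_synth_config(config)
  if (6 * .WAVELET_SIGMA >= 1 / cfg$discharge_rate_hz)
    stop("discharge wavelet half-width >= inter-discharge interval: events would merge")
  rate <- cfg$ephys_rate
  n <- round(cfg$duration_s * rate)
  geom <- grid_geometry(cfg)
  n_ch <- nrow(geom)
  sched <- discharge_schedule(cfg)
  n_ev <- length(sched$times)
  proj <- geom$x_mm * cos(cfg$wave_direction_rad) +
    geom$y_mm * sin(cfg$wave_direction_rad)

  jitter <- with_seed(derive_seed(cfg$seed, .SUB_JITTER),
                      matrix(rnorm(n_ch * n_ev, 0, cfg$timing_jitter_ms / 1000),
                             n_ch, n_ev))
  # planted per-channel peak times: plane + jitter
  peak_t <- outer(proj, 1 / sched$speeds) +
    matrix(sched$times, n_ch, n_ev, byrow = TRUE) + jitter

  # plant locked-event tables first (they only need the peak times)
  ph_to_tau <- wavelet_phase_inverter(rate)
  hg <- with_seed(derive_seed(cfg$seed, .SUB_HG),
                  plant_locked_events(cfg, peak_t, sched$hg_amps,
                                      cfg$hg_per_discharge,
                                      cfg$hg_lock_phase_rad, ph_to_tau))
  mua <- NULL
  if (rate >= 8000 && cfg$mua_per_discharge > 0) {
    mua_amp <- cfg$mua_amp_uv %||% {
      nyq <- rate / 2
      band_frac <- (min(3000, 0.999 * nyq) - 300) / nyq
      # the 300-3000 Hz filter attenuates the pulse trough; compensate so
      # the planted spike reads -6 band-noise SDs after filtering
      m0 <- round(.MUA_WIDTH * rate)
      tmpl <- numeric(200 * m0)
      tmpl[100 * m0 + seq_len(m0)] <-
        -sin(2 * pi * (seq_len(m0) - 1) / m0)
      hi <- min(3000, 0.999 * nyq)
      att <- abs(min(bandpass(tmpl, rate, c(300, hi))))
      6 * cfg$noise_sd_ephys * sqrt(band_frac) / max(att, 0.1)
    }
    mua <- with_seed(derive_seed(cfg$seed, .SUB_MUA),
                     plant_locked_events(cfg, peak_t, rep(mua_amp, n_ev),
                                         cfg$mua_per_discharge,
                                         cfg$mua_lock_phase_rad, ph_to_tau))
  }

  # assemble per channel on a local vector: slice additions stay in place
  half <- ceiling(3 * .WAVELET_SIGMA * rate)
  tau <- (-half:half) / rate
  halfb <- ceiling(3 * .HG_SIGMA * rate)
  taub <- (-halfb:halfb) / rate
  m <- round(.MUA_WIDTH * rate)
  taum <- (seq_len(m) - 1) / rate
  mua_shape <- -sin(2 * pi * taum / .MUA_WIDTH)

  sig <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    row <- numeric(n)
    for (k in seq_len(n_ev)) {
      tp <- peak_t[ch, k]
      i0 <- round(tp * rate) + 1L
      frac <- tp - (i0 - 1L) / rate
      w <- cfg$discharge_amp_uv *
        exp(-(tau - frac)^2 / (2 * .WAVELET_SIGMA^2)) *
        cos(2 * pi * .WAVELET_F * (tau - frac))
      s <- clip_at(n, i0 - half, length(w))
      if (!is.null(s)) row[s$dst] <- row[s$dst] + w[s$src]
    }
    hgc <- hg[hg$channel == ch, , drop = FALSE]
    for (j in seq_len(nrow(hgc))) {
      tb <- hgc$time[j]
      i0 <- round(tb * rate) + 1L
      frac <- tb - (i0 - 1L) / rate
      w <- hgc$amp[j] * exp(-(taub - frac)^2 / (2 * .HG_SIGMA^2)) *
        cos(2 * pi * .HG_F * (taub - frac))
      s <- clip_at(n, i0 - halfb, length(w))
      if (!is.null(s)) row[s$dst] <- row[s$dst] + w[s$src]
    }
    if (!is.null(mua)) {
      muc <- mua[mua$channel == ch, , drop = FALSE]
      for (j in seq_len(nrow(muc))) {
        # trough of the biphasic pulse sits a quarter-width after its
        # start; shift so the planted phase refers to the trough
        i0 <- round((muc$time[j] - .MUA_WIDTH / 4) * rate) + 1L
        s <- clip_at(n, i0, m)
        if (!is.null(s))
          row[s$dst] <- row[s$dst] + muc$amp[j] * mua_shape[s$src]
      }
    }
    sig[ch, ] <- row
  }

  if (cfg$noise_sd_ephys > 0) {
    noise <- with_seed(derive_seed(cfg$seed, .SUB_NOISE),
                       matrix(rnorm(n_ch * n, 0, cfg$noise_sd_ephys), n_ch, n))
    sig <- sig + noise
  }

  recording <- structure(list(signals = sig, rate = rate, geometry = geom),
                         class = "grid_recording")
  truth <- structure(list(
    config = cfg,
    discharge_times = sched$times,
    speeds = sched$speeds,
    directions = rep(cfg$wave_direction_rad, n_ev),
    channel_peak_times = peak_t,
    hg = hg,
    mua = mua
  ), class = "ground_truth")
  list(recording = recording, truth = truth)
}

# The instantaneous 4-30 Hz phase of the discharge wavelet is not simply
# the carrier phase away from the peak (the Gaussian envelope is not
# narrow relative to the 8 Hz carrier). To plant events at an exact
# analysis phase we measure the wavelet's filtered analytic-phase
# profile once and invert it: phase_to_offset(phi) returns the time
# offset from the wavelet peak at which the analyzed phase equals phi.
wavelet_phase_inverter <- function(rate) {
  pad <- 2  # seconds either side, kills filter edge effects
  tt <- seq(-pad, pad, by = 1 / rate)
  w <- exp(-tt^2 / (2 * .WAVELET_SIGMA^2)) * cos(2 * pi * .WAVELET_F * tt)
  lf <- bandpass(w, rate, c(4, 30))
  ph <- analytic_signal(lf, rate)$phase
  keep <- abs(tt) <= 2 / .WAVELET_F  # two carrier cycles around the peak
  tau <- tt[keep]
  # unwrap, then anchor phase 0 at the peak (tau = 0)
  p <- ph[keep]
  p <- p + cumsum(c(0, ifelse(diff(p) < -pi, 2 * pi,
                              ifelse(diff(p) > pi, -2 * pi, 0))))
  p <- p - p[which.min(abs(tau))]
  ok <- !duplicated(p)
  function(phi) stats::approx(p[ok], tau[ok], xout = phi, rule = 2)$y
}

# Draw locked event times for every (channel, discharge) pair: phase
# from von Mises(mu, kappa), converted to a time offset within the
# central carrier cycle via the measured phase profile.
plant_locked_events <- function(cfg, peak_t, amps, per_discharge, mu,
                                phase_to_offset) {
  n_ch <- nrow(peak_t); n_ev <- ncol(peak_t)
  total <- n_ch * n_ev * per_discharge
  if (total == 0)
    return(data.frame(channel = integer(0), time = numeric(0),
                      phase = numeric(0), amp = numeric(0)))
  ph <- rvonmises(total, mu, cfg$hg_lock_kappa)
  idx <- expand.grid(rep = seq_len(per_discharge),
                     ch = seq_len(n_ch), ev = seq_len(n_ev))
  tt <- peak_t[cbind(idx$ch, idx$ev)] + phase_to_offset(ph)
  data.frame(channel = idx$ch, time = tt, phase = ph,
             amp = amps[idx$ev])
}

#' Generate calcium traces paired with a simulated recording
#'
#' Builds per-cell dF/F traces for the seizure in `truth`: each trace is
#' baseline noise until the cell's planted onset time, then a sustained
#' onset response plus one indicator transient (rise
#' `calcium_rise_s`, decay `calcium_decay_s`) per subsequent discharge,
#' whose amplitudes follow `dff_amp_trend`. Onset times spread over
#' `onset_span_s` in the study's planted recruitment order, perturbed
#' per seizure by `onset_rank_noise`. Cell centroids are laid out so the
#' planted order advances along the +x image axis, giving a recoverable
#' onset-direction vector.
#'
#' @param config a [synth_config()].
#' @param truth the `truth` element returned by [generate_lfp()] for
#'   the same config.
#' @return list with `calcium` (class `"calcium_traces"`: `dff` cells x
#'   frames, `frame_rate`, `centroids`, `baseline_epoch`) and `truth`
#'   (the input truth extended with `onset_time`, `onset_frame`,
#'   `planted_rank` -- frame-resolution ranks with average ties -- and
#'   `planted_order`).
#' @export
generate_calcium <- function(config, truth) {
  cfg <- validate_synth_config(config)
  nc <- cfg$n_cells
  if (nc < 2) stop("need at least 2 cells")
  fr <- cfg$frame_rate
  n_f <- floor(cfg$duration_s * fr)
  t_f <- (seq_len(n_f) - 1) / fr

  # study-level recruitment-order template and cell geometry
  template <- with_seed(derive_seed(cfg$rank_template_seed, .SUB_TEMPLATE),
                        sample.int(nc))  # template[c] = template rank of cell c
  centroids <- with_seed(derive_seed(cfg$rank_template_seed, .SUB_CENTROIDS),
                         data.frame(
                           cell = seq_len(nc),
                           x_um = 280 * (template - 1) / (nc - 1) +
                             rnorm(nc, 0, 10),
                           y_um = runif(nc, 0, 300)))

  # per-seizure perturbation of the template order
  scores <- with_seed(derive_seed(cfg$seed, .SUB_RANKS),
                      template + cfg$onset_rank_noise * nc * rnorm(nc))
  planted_order <- rank(scores, ties.method = "first")
  onset_time <- cfg$baseline_s +
    (planted_order - 1) / (nc - 1) * cfg$onset_span_s
  # first frame strictly after onset (where the response is positive)
  onset_frame <- vapply(onset_time,
                        function(o) sum(t_f <= o + 1e-12) + 1L, 1L)
  planted_rank <- rank(onset_frame, ties.method = "average")

  kern <- function(u) {
    v <- numeric(length(u))
    pos <- u > 0
    v[pos] <- (1 - exp(-u[pos] / cfg$calcium_rise_s)) *
      exp(-u[pos] / cfg$calcium_decay_s)
    v
  }
  sched_t <- truth$discharge_times
  amps <- cfg$dff_transient_amp * cfg$dff_amp_trend^(seq_along(sched_t) - 1)
  dff <- matrix(0, nc, n_f)
  for (c0 in seq_len(nc)) {
    tr <- cfg$dff_onset_amp * kern(t_f - onset_time[c0])
    after <- which(sched_t >= onset_time[c0])
    for (j in after) tr <- tr + amps[j] * kern(t_f - sched_t[j])
    dff[c0, ] <- tr
  }
  if (cfg$noise_sd_dff > 0) {
    dff <- dff + with_seed(derive_seed(cfg$seed, .SUB_DFF_NOISE),
                           matrix(rnorm(nc * n_f, 0, cfg$noise_sd_dff),
                                  nc, n_f))
  }

  calcium <- structure(list(dff = dff, frame_rate = fr,
                            centroids = centroids,
                            baseline_epoch = seq_len(floor(cfg$baseline_s * fr))),
                       class = "calcium_traces")
  truth$onset_time <- onset_time
  truth$onset_frame <- onset_frame
  truth$planted_rank <- planted_rank
  truth$planted_order <- planted_order
  truth$template <- template
  list(calcium = calcium, truth = truth)
}

#' Generate a multi-seizure synthetic study
#'
#' Produces `n_seizures` paired (recording, calcium, truth) datasets
#' that share the study-level recruitment-order template and cell
#' geometry (up to `onset_rank_noise`) and the planted wave-direction
#' distribution, with independent noise per seizure. `speed_trend`
#' applies within each seizure, so later discharges travel slower
#' whenever it is below 1.
#'
#' @param config a [synth_config()]; its `seed` is the study master
#'   seed unless `seed` is given.
#' @param n_seizures number of seizures (>= 1).
#' @param seed optional master seed overriding `config$seed`.
#' @return list of length `n_seizures`; each element has `recording`,
#'   `calcium`, `truth`.
#' @export
generate_study <- function(config, n_seizures = 4, seed = NULL) {
  stopifnot(n_seizures >= 1)
  master <- seed %||% config$seed
  template_seed <- derive_seed(master, .SUB_STUDY)
  lapply(seq_len(n_seizures), function(s) {
    cfg <- config
    cfg$seed <- derive_seed(master, 100L + s)
    cfg$rank_template_seed <- template_seed
    lf <- generate_lfp(cfg)
    ca <- generate_calcium(cfg, lf$truth)
    list(recording = lf$recording, calcium = ca$calcium, truth = ca$truth)
  })
}
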