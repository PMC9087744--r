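#' Configuration for the synthetic multimodal seizure generator
#'
#' Collects every parameter of the simulated preparation: a planar
#' electrode grid over which ictal discharges propagate as plane waves,
#' high-gamma bursts and multiunit spikes locked to the low-frequency
#' discharge phase, and a population of imaged cells recruited in a
#' planted, reproducible order with calcium-indicator kinetics.
#'
#' Defaults describe the emulated preparation: a 4 x 4 grid at 0.5 mm
#' pitch sampled at 20 kHz, 5-10 Hz frame-rate imaging of a few dozen
#' pyramidal cells, ~1 discharge per second traveling at ~500 mm/s, a
#' recruitment spread of 1.2 s at seizure onset, and a mild per-discharge
#' slowing of the wave late in the seizure.
#'
#' @param seed master seed; all randomness in the generated dataset
#'   derives from it via fixed per-component substreams.
#' @param duration_s total record duration, seconds.
#' @param ephys_rate electrophysiology sampling rate, Hz.
#' @param frame_rate imaging frame rate, Hz.
#' @param grid_shape integer `(rows, cols)` of the electrode grid.
#' @param pitch_mm electrode pitch, millimeters.
#' @param n_cells number of imaged cells (>= 2).
#' @param baseline_s preseizure baseline duration, seconds.
#' @param discharge_rate_hz ictal discharge rate, events/second.
#' @param wave_speed_mm_s planted traveling-wave speed of the first
#'   discharge, mm/s.
#' @param wave_direction_rad planted propagation direction, radians.
#' @param timing_jitter_ms SD of per-channel peak-time jitter, ms.
#' @param hg_lock_phase_rad,hg_lock_kappa von Mises mean phase and
#'   concentration of high-gamma burst times relative to the
#'   low-frequency discharge phase.
#' @param mua_lock_phase_rad von Mises mean phase of multiunit spikes
#'   (same concentration as the high-gamma locking).
#' @param onset_span_s spread of planted cell onset times, seconds.
#' @param onset_rank_noise SD of the per-seizure perturbation of the
#'   cell recruitment-order template, in units of `n_cells` ranks
#'   (0 = identical order in every seizure).
#' @param calcium_rise_s,calcium_decay_s indicator kinetics, seconds.
#' @param noise_sd_ephys additive white noise SD on the ephys, microvolts.
#' @param noise_sd_dff additive white noise SD on the traces, dF/F units.
#' @param speed_trend multiplicative factor applied to the wave speed at
#'   each successive discharge (< 1 models late-seizure slowing).
#' @param discharge_amp_uv peak amplitude of the discharge wavelet, uV.
#' @param hg_amp_uv peak amplitude of a high-gamma burst, uV.
#' @param hg_per_discharge,mua_per_discharge bursts / spikes planted per
#'   discharge per channel.
#' @param mua_amp_uv multiunit spike amplitude, uV; `NULL` (default)
#'   sets 6 x the noise SD within the 300-3000 Hz band so that
#'   median-based threshold detection succeeds by design.
#' @param dff_amp_trend multiplicative per-discharge factor on the
#'   calcium transient amplitude; `NULL` (default) follows
#'   `speed_trend`, planting calcium amplitude / line length that
#'   co-decay with the wave speed.
#' @param hg_amp_trend multiplicative per-discharge factor on the
#'   high-gamma burst amplitude (default 1: stationary).
#' @param dff_transient_amp per-discharge calcium transient amplitude,
#'   dF/F units.
#' @param dff_onset_amp amplitude of the sustained onset response, dF/F.
#' @param rank_template_seed seed of the study-level recruitment-order
#'   template and cell positions; defaults to `seed`. Seizures of one
#'   study share this value so they share cells and rank structure.
#' @return object of class `"synth_config"` (a validated list).
#' @export
synth_config <- function(seed = 1L,
                         duration_s = 120,
                         ephys_rate = 20000,
                         frame_rate = 10,
                         grid_shape = c(4L, 4L),
                         pitch_mm = 0.5,
                         n_cells = 30L,
                         baseline_s = 10,
                         discharge_rate_hz = 1,
                         wave_speed_mm_s = 500,
                         wave_direction_rad = pi / 4,
                         timing_jitter_ms = 2,
                         hg_lock_phase_rad = 0,
                         hg_lock_kappa = 8,
                         mua_lock_phase_rad = 0,
                         onset_span_s = 1.2,
                         onset_rank_noise = 0.1,
                         calcium_rise_s = 0.2,
                         calcium_decay_s = 1.5,
                         noise_sd_ephys = 10,
                         noise_sd_dff = 0.05,
                         speed_trend = 0.995,
                         discharge_amp_uv = 200,
                         hg_amp_uv = 30,
                         hg_per_discharge = 2L,
                         mua_per_discharge = 3L,
                         mua_amp_uv = NULL,
                         dff_amp_trend = NULL,
                         hg_amp_trend = 1,
                         dff_transient_amp = 0.4,
                         dff_onset_amp = 0.5,
                         rank_template_seed = NULL) {
  cfg <- list(seed = seed, duration_s = duration_s, ephys_rate = ephys_rate,
              frame_rate = frame_rate, grid_shape = as.integer(grid_shape),
              pitch_mm = pitch_mm, n_cells = as.integer(n_cells),
              baseline_s = baseline_s, discharge_rate_hz = discharge_rate_hz,
              wave_speed_mm_s = wave_speed_mm_s,
              wave_direction_rad = wave_direction_rad,
              timing_jitter_ms = timing_jitter_ms,
              hg_lock_phase_rad = hg_lock_phase_rad,
              hg_lock_kappa = hg_lock_kappa,
              mua_lock_phase_rad = mua_lock_phase_rad,
              onset_span_s = onset_span_s, onset_rank_noise = onset_rank_noise,
              calcium_rise_s = calcium_rise_s,
              calcium_decay_s = calcium_decay_s,
              noise_sd_ephys = noise_sd_ephys, noise_sd_dff = noise_sd_dff,
              speed_trend = speed_trend,
              discharge_amp_uv = discharge_amp_uv, hg_amp_uv = hg_amp_uv,
              hg_per_discharge = as.integer(hg_per_discharge),
              mua_per_discharge = as.integer(mua_per_discharge),
              mua_amp_uv = mua_amp_uv,
              dff_amp_trend = dff_amp_trend %||% speed_trend,
              hg_amp_trend = hg_amp_trend,
              dff_transient_amp = dff_transient_amp,
              dff_onset_amp = dff_onset_amp,
              rank_template_seed = rank_template_seed %||% seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    stop_if_not_scalar_pos(duration_s, "duration_s")
    stop_if_not_scalar_pos(ephys_rate, "ephys_rate")
    stop_if_not_scalar_pos(frame_rate, "frame_rate")
    stop_if_not_scalar_pos(wave_speed_mm_s, "wave_speed_mm_s")
    stop_if_not_scalar_pos(discharge_rate_hz, "discharge_rate_hz")
    if (baseline_s <= 0 || duration_s <= baseline_s)
      stop("need duration_s > baseline_s > 0")
    if (onset_span_s <= 0 || onset_span_s >= duration_s - baseline_s)
      stop("need 0 < onset_span_s < duration_s - baseline_s")
    if (prod(grid_shape) < 4) stop("grid must have at least 4 channels")
    if (onset_rank_noise < 0) stop("onset_rank_noise must be >= 0")
    if (hg_lock_kappa < 0) stop("hg_lock_kappa must be >= 0")
  })
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<synth_config> %gs record, %d x %d grid @ %.2g mm, %g Hz ephys, ",
    "%g Hz imaging, %d cells\n  wave %g mm/s @ %.2f rad, trend %g; ",
    "onset span %gs; seed %s\n"),
    x$duration_s, x$grid_shape[1], x$grid_shape[2], x$pitch_mm,
    x$ephys_rate, x$frame_rate, x$n_cells, x$wave_speed_mm_s,
    x$wave_direction_rad, x$speed_trend, x$onset_span_s,
    format(x$seed)))
  invisible(x)
}
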