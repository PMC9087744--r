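# Event detection in band-limited signals and phase extraction at events.

# Greedy peak picking: keep candidate extremes in order of decreasing
# prominence value, discarding any within min_sep_samples of a kept peak.
pick_peaks <- function(value, candidates, min_sep_samples) {
  if (length(candidates) == 0) return(integer(0))
  ord <- candidates[order(value[candidates], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_sep_samples)) kept <- c(kept, i)
  }
  sort(kept)
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect high-gamma events from an amplitude envelope
#'
#' Events are local maxima of the high-gamma (80-150 Hz) Hilbert
#' amplitude exceeding `mean + k * SD` of the envelope, with a refractory
#' separation of one high-gamma cycle (1/80 s) between events.
#'
#' @param hg an [analytic_signal()] result for the high-gamma band
#'   (or any list with `amplitude` and `rate`).
#' @param k threshold in SD units above the mean amplitude (default 2.5).
#' @return numeric vector of event (peak) times in seconds.
#' @export
detect_hg_events <- function(hg, k = 2.5) {
  amp <- hg$amplitude
  rate <- hg$rate
  s <- sd(amp)
  if (!is.finite(s) || s == 0) stop("degenerate amplitude (SD = 0)")
  thr <- mean(amp) + k * s
  cand <- local_maxima(amp)
  cand <- cand[amp[cand] > thr]
  kept <- pick_peaks(amp, cand, min_sep_samples = rate / 80)
  (kept - 1) / rate
}

#' Detect multiunit activity in the spike band
#'
#' Multiunit events are negative deflections of the 300-3000 Hz signal
#' crossing the robust threshold
#' \deqn{t = -4 \, \mathrm{median}(|x| / 0.6745),}
#' i.e. -4 estimated noise SDs, where the median-based estimate is
#' insensitive to the spikes themselves. Events are troughs below `t`
#' with a 1 ms refractory separation.
#'
#' @param x numeric vector, spike-band signal at the native rate.
#' @param rate sampling rate, Hz.
#' @return list with `times` (trough times, s) and `threshold`.
#' @export
detect_mua <- function(x, rate) {
  stopifnot(is.numeric(x))
  if (all(x == 0)) stop("all-zero spike-band signal")
  thr <- -4 * median(abs(x) / 0.6745)
  cand <- local_maxima(-x)
  cand <- cand[x[cand] < thr]
  kept <- pick_peaks(-x, cand, min_sep_samples = rate / 1000)
  list(times = (kept - 1) / rate, threshold = thr)
}

#' Low-frequency phase at event times
#'
#' Reads the instantaneous phase of the low-frequency (4-30 Hz) signal
#' at the sample nearest to each event, and bins the phases into the
#' standard 18-bin histogram over \eqn{[-\pi, \pi)}.
#'
#' @param lfp_phase an [analytic_signal()] result for the low-frequency
#'   band.
#' @param events numeric vector of event times in seconds.
#' @return object of class `"phase_sample"`: list with `event_times`,
#'   `phases`, and `histogram` (18 counts).
#' @export
phases_at_events <- function(lfp_phase, events) {
  rate <- lfp_phase$rate
  n <- length(lfp_phase$phase)
  if (length(events) == 0) {
    warning("no events: empty phase sample")
    return(structure(list(event_times = numeric(0), phases = numeric(0),
                          histogram = phase_histogram(numeric(0))),
                     class = "phase_sample"))
  }
  idx <- round(events * rate) + 1L
  if (any(idx < 1L | idx > n)) stop("event times outside signal support")
  ph <- lfp_phase$phase[idx]
  structure(list(event_times = events, phases = ph,
                 histogram = phase_histogram(ph)),
            class = "phase_sample")
}

#' 18-bin phase histogram on \eqn{[-\pi, \pi)}
#'
#' @param phases numeric vector of angles in radians; \eqn{+\pi} wraps
#'   into the first bin.
#' @param n_bins number of equal bins (default 18).
#' @return named integer vector of counts (names are bin centers).
#' @export
phase_histogram <- function(phases, n_bins = 18) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  ph <- wrap_pi(phases)
  ph[ph >= pi] <- -pi  # right-open final bin
  bin <- findInterval(ph, edges, rightmost.closed = FALSE)
  bin[bin > n_bins] <- n_bins
  counts <- tabulate(bin, nbins = n_bins)
  names(counts) <- sprintf("%.3f", (edges[-1] + edges[-(n_bins + 1)]) / 2)
  counts
}
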