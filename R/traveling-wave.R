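# Traveling-wave estimation: per-channel discharge peaks, grouping into
# array-wide events, plane fits, and distributional comparisons.

#' Detect seizure discharge peaks on one channel
#'
#' Peaks are local maxima of the rectified low-frequency (4-30 Hz)
#' signal that exceed `mean(|x|) + k * SD(|x|)`, with at most one peak
#' per oscillation cycle (minimum separation 1/30 s). Working on the
#' rectified signal makes detection insensitive to discharge polarity
#' and to overall rescaling.
#'
#' @param x numeric vector, low-frequency band signal of one channel.
#' @param rate sampling rate, Hz.
#' @param k threshold in SD units (default 2).
#' @param sd_of `"rectified"` (default) takes the SD of `|x|`;
#'   `"signal"` the SD of `x` itself.
#' @return data.frame with columns `time_s` and `amp` (rectified
#'   amplitude at the peak).
#' @export
detect_discharge_peaks <- function(x, rate, k = 2, sd_of = c("rectified", "signal")) {
  sd_of <- match.arg(sd_of)
  r <- abs(x)
  s <- if (sd_of == "rectified") sd(r) else sd(x)
  if (!is.finite(s) || s == 0) stop("degenerate signal (SD = 0)")
  thr <- mean(r) + k * s
  cand <- local_maxima(r)
  cand <- cand[r[cand] > thr]
  kept <- pick_peaks(r, cand, min_sep_samples = rate / 30)
  data.frame(time_s = (kept - 1) / rate, amp = r[kept])
}

#' Group per-channel peaks into array-wide discharge events
#'
#' Peaks from all channels are chained in time by single linkage:
#' consecutive peaks separated by at most `max_gap` seconds belong to
#' the same ictal discharge. Within an event each channel contributes
#' one peak (largest rectified amplitude; earliest time on exact ties),
#' and events detected on a fraction of functional channels not
#' exceeding `min_frac` are discarded.
#'
#' @param peaks data.frame with columns `channel`, `time_s`, `amp`
#'   (pooled over channels).
#' @param geometry data.frame with columns `channel`, `x_mm`, `y_mm`,
#'   `functional` (logical).
#' @param max_gap maximum within-event gap between consecutive peaks,
#'   seconds (default 0.150).
#' @param min_frac minimal fraction of functional channels; events with
#'   channel fraction `<= min_frac` are dropped (default 0.6).
#' @return list of ungraded events, each a data.frame with columns
#'   `channel`, `x_mm`, `y_mm`, `t_s`.
#' @export
group_discharges <- function(peaks, geometry, max_gap = 0.150, min_frac = 0.6) {
  stopifnot(all(c("channel", "time_s", "amp") %in% names(peaks)))
  n_functional <- sum(geometry$functional)
  geometry <- geometry[geometry$functional, , drop = FALSE]
  peaks <- peaks[peaks$channel %in% geometry$channel, , drop = FALSE]
  if (nrow(peaks) == 0) return(list())
  peaks <- peaks[order(peaks$time_s), , drop = FALSE]
  new_event <- c(TRUE, diff(peaks$time_s) > max_gap)
  peaks$event <- cumsum(new_event)
  out <- list()
  for (ev in split(peaks, peaks$event)) {
    # one peak per channel: largest amplitude, earliest on ties
    ev <- ev[order(ev$channel, -ev$amp, ev$time_s), , drop = FALSE]
    ev <- ev[!duplicated(ev$channel), , drop = FALSE]
    if (nrow(ev) / n_functional <= min_frac) next
    gi <- match(ev$channel, geometry$channel)
    out[[length(out) + 1L]] <- data.frame(
      channel = ev$channel,
      x_mm = geometry$x_mm[gi], y_mm = geometry$y_mm[gi],
      t_s = ev$time_s)
  }
  out
}

#' Fit a plane to one discharge and derive wave speed and direction
#'
#' Ordinary least squares fit of \eqn{t = a x + b y + c} to the
#' per-channel points \eqn{(x, y, t)}. The spatial gradient \eqn{(a, b)}
#' (s/mm) points in the direction of propagation; the wave direction is
#' `atan2(b, a)` and the speed is the inverse gradient norm
#' \eqn{1/\sqrt{a^2+b^2}} in mm/s. A gradient norm below `1e-9` s/mm
#' (simultaneous discharge across the array) flags the event degenerate.
#'
#' @param event data.frame with columns `x_mm`, `y_mm`, `t_s` (one row
#'   per channel), as produced by [group_discharges()].
#' @return object of class `"discharge_event"`: list with `points`,
#'   `plane` (a, b, c), `gradient`, `speed_mm_s`, `speed_m_s`,
#'   `direction_rad`, `n_channels`, `residual_rms`, `degenerate`,
#'   `t_center_s`.
#' @export
fit_plane <- function(event) {
  stopifnot(all(c("x_mm", "y_mm", "t_s") %in% names(event)))
  n <- nrow(event)
  if (n < 3) stop("need at least 3 channels to fit a plane")
  X <- cbind(x = event$x_mm, y = event$y_mm, 1)
  qrX <- qr(X)
  if (qrX$rank < 3) stop("rank-deficient geometry (collinear channel positions)")
  coefs <- unname(qr.coef(qrX, event$t_s))
  a <- coefs[1]; b <- coefs[2]; c0 <- coefs[3]
  resid <- event$t_s - X %*% coefs
  gnorm <- sqrt(a^2 + b^2)
  degenerate <- gnorm < 1e-9
  speed <- if (degenerate) NA_real_ else 1 / gnorm
  structure(list(
    points = event,
    plane = c(a = a, b = b, c = c0),
    gradient = c(a = a, b = b),
    speed_mm_s = speed,
    speed_m_s = speed / 1000,
    direction_rad = if (degenerate) NA_real_ else atan2(b, a),
    n_channels = n,
    residual_rms = sqrt(mean(resid^2)),
    degenerate = degenerate,
    t_center_s = mean(event$t_s)
  ), class = "discharge_event")
}

#' Detect, group and fit all discharges in a grid recording
#'
#' Convenience wrapper: band-passes every functional channel to 4-30 Hz,
#' detects per-channel peaks, groups them into events, and fits a plane
#' to each. Channels are analysed at the recording's stored rate.
#'
#' @param recording a `grid_recording` (see [generate_lfp()] /
#'   [read_bundle()]).
#' @param k,sd_of passed to [detect_discharge_peaks()].
#' @param max_gap,min_frac passed to [group_discharges()].
#' @return data.frame (one row per non-degenerate fitted event) with
#'   columns `event_id`, `t_center_s`, `n_channels`, `a`, `b`, `c`,
#'   `residual_rms`, `speed_mm_s`, `speed_m_s`, `direction_rad`,
#'   `degenerate`.
#' @export
wave_events <- function(recording, k = 2, sd_of = "rectified",
                        max_gap = 0.150, min_frac = 0.6) {
  geom <- recording$geometry
  keep <- which(geom$functional)
  lf <- bandpass(recording$signals[keep, , drop = FALSE],
                 recording$rate, c(4, 30))
  pk <- lapply(seq_along(keep), function(i) {
    p <- detect_discharge_peaks(lf[i, ], recording$rate, k = k, sd_of = sd_of)
    if (nrow(p)) p$channel <- geom$channel[keep[i]]
    p
  })
  pk <- do.call(rbind, pk[vapply(pk, nrow, 0L) > 0])
  if (is.null(pk) || nrow(pk) == 0) return(empty_wave_table())
  groups <- group_discharges(pk, geom, max_gap = max_gap, min_frac = min_frac)
  if (length(groups) == 0) return(empty_wave_table())
  rows <- lapply(seq_along(groups), function(i) {
    f <- fit_plane(groups[[i]])
    data.frame(event_id = i, t_center_s = f$t_center_s,
               n_channels = f$n_channels,
               a = f$plane[["a"]], b = f$plane[["b"]], c = f$plane[["c"]],
               residual_rms = f$residual_rms,
               speed_mm_s = f$speed_mm_s, speed_m_s = f$speed_m_s,
               direction_rad = f$direction_rad, degenerate = f$degenerate)
  })
  do.call(rbind, rows)
}

empty_wave_table <- function() {
  data.frame(event_id = integer(0), t_center_s = numeric(0),
             n_channels = integer(0), a = numeric(0), b = numeric(0),
             c = numeric(0), residual_rms = numeric(0),
             speed_mm_s = numeric(0), speed_m_s = numeric(0),
             direction_rad = numeric(0), degenerate = logical(0))
}

#' Distributional statistics of wave directions
#'
#' Per dataset, a Hodges-Ajne omnibus test of nonuniformity of discharge
#' directions; per dataset pair, a two-sample Kolmogorov-Smirnov test on
#' the directions linearized on \eqn{(-\pi, \pi]}. As a cut-point
#' diagnostic the KS test is repeated with the circle cut at 0 (angles
#' mapped to \eqn{[0, 2\pi)}).
#'
#' @param direction_sets named list of numeric vectors of directions
#'   (radians), one per dataset; each of length \eqn{\ge 8}.
#' @return list with `omnibus` (per dataset) and `ks` (data.frame of
#'   pairwise results, including the alternative-cut p value).
#' @export
direction_stats <- function(direction_sets) {
  if (any(lengths(direction_sets) < 8)) stop("need >= 8 events per dataset")
  omni <- lapply(direction_sets, omnibus_test)
  nm <- names(direction_sets) %||% as.character(seq_along(direction_sets))
  ks <- NULL
  if (length(direction_sets) >= 2) {
    idx <- utils::combn(length(direction_sets), 2)
    ks <- do.call(rbind, lapply(seq_len(ncol(idx)), function(j) {
      a <- wrap_pi(direction_sets[[idx[1, j]]])
      b <- wrap_pi(direction_sets[[idx[2, j]]])
      k1 <- suppressWarnings(ks.test(a, b))
      k2 <- suppressWarnings(ks.test(a %% (2 * pi), b %% (2 * pi)))
      data.frame(set_a = nm[idx[1, j]], set_b = nm[idx[2, j]],
                 D = unname(k1$statistic), p = k1$p.value,
                 p_cut0 = k2$p.value)
    }))
  }
  list(omnibus = stats::setNames(omni, nm), ks = ks)
}

#' Compare wave speeds between seizure epochs
#'
#' Two-sided Mann-Whitney U test between discharge speeds in the first
#' and last fraction `frac` of the seizure duration (epochs are defined
#' by time, from the first to the last event).
#'
#' @param times numeric vector of event times, seconds.
#' @param speeds numeric vector of event speeds (same length).
#' @param frac epoch fraction of the seizure duration (default 0.25).
#' @return list with `U`, `p`, `median_first`, `median_last`,
#'   `n_first`, `n_last`.
#' @export
speed_epoch_comparison <- function(times, speeds, frac = 0.25) {
  stopifnot(length(times) == length(speeds))
  ok <- is.finite(times) & is.finite(speeds)
  times <- times[ok]; speeds <- speeds[ok]
  t0 <- min(times); t1 <- max(times); span <- t1 - t0
  first <- speeds[times <= t0 + frac * span]
  last <- speeds[times >= t1 - frac * span]
  if (length(first) < 4 || length(last) < 4)
    stop("need at least 4 events in each epoch")
  w <- suppressWarnings(
    wilcox.test(first, last, exact = FALSE, correct = FALSE))
  list(U = unname(w$statistic), p = w$p.value,
       median_first = median(first), median_last = median(last),
       n_first = length(first), n_last = length(last))
}
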