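#' Zero-phase Butterworth band-pass filter
#'
#' Applies a second-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`), so the output is free of phase distortion --
#' a requirement for downstream phase analyses. The effective magnitude
#' response is the square of the single-pass response.
#'
#' @param x numeric vector (one channel) or channels-by-samples matrix.
#' @param rate sampling rate, Hz.
#' @param band length-2 numeric, `(low, high)` edges in Hz; must satisfy
#'   `0 < low < high < rate/2`.
#' @param order filter order of the single pass (default 2).
#' @return filtered signal, same shape and length as `x`.
#' @examples
#' t <- seq(0, 2, by = 1/1000)
#' x <- sin(2 * pi * 10 * t) + sin(2 * pi * 200 * t)
#' y <- bandpass(x, 1000, c(4, 30))  # keeps the 10 Hz component
#' @export
bandpass <- function(x, rate, band, order = 2) {
  stop_if_not_scalar_pos(rate, "rate")
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1])
    stop("'band' must be (low, high) with 0 < low < high")
  if (band[2] >= rate / 2)
    stop("band edge at or above Nyquist frequency")
  bf <- signal::butter(order, band / (rate / 2), type = "pass")
  filt1 <- function(v) as.numeric(signal::filtfilt(bf, v))
  if (is.matrix(x)) t(apply(x, 1, filt1)) else filt1(x)
}

#' Anti-aliased decimation
#'
#' Low-pass filters at 80% of the target Nyquist frequency (zero-phase
#' order-4 Butterworth, effectively order 8 after the forward-backward
#' pass) and keeps every `rate/target_rate`-th sample.
#' Used to bring wide-band recordings to the 2 kHz rate at which the
#' low-frequency and high-gamma analyses run; spike-band analysis stays
#' at the native rate.
#'
#' @inheritParams bandpass
#' @param target_rate desired output rate, Hz; `rate/target_rate` must
#'   be a whole number.
#' @return list with `x` (decimated signal, same shape) and `rate`.
#' @export
downsample_signal <- function(x, rate, target_rate = 2000) {
  stop_if_not_scalar_pos(rate, "rate")
  stop_if_not_scalar_pos(target_rate, "target_rate")
  if (target_rate > rate) stop("target_rate exceeds input rate")
  q <- rate / target_rate
  if (abs(q - round(q)) > 1e-8)
    stop("rate must be an integer multiple of target_rate")
  q <- round(q)
  if (q == 1) return(list(x = x, rate = rate))
  bf <- signal::butter(4, 0.8 / q, type = "low")
  dec1 <- function(v) {
    y <- as.numeric(signal::filtfilt(bf, v))
    y[seq(1, length(y), by = q)]
  }
  out <- if (is.matrix(x)) t(apply(x, 1, dec1)) else dec1(x)
  list(x = out, rate = target_rate)
}

#' Analytic signal: instantaneous phase and amplitude
#'
#' FFT-based Hilbert transform. Phase follows the cosine convention:
#' phase 0 at a positive peak of the (band-limited) input. The first and
#' last 5% of samples are flagged unreliable because the transform
#' assumes circular continuation.
#'
#' @param x numeric vector, a band-limited signal.
#' @param rate sampling rate, Hz.
#' @return object of class `"analytic_series"`: list with `phase`
#'   (radians, \eqn{[-\pi, \pi]}), `amplitude` (\eqn{\ge 0}), `rate`,
#'   and `valid` (logical, FALSE in the edge zones).
#' @export
analytic_signal <- function(x, rate) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(fft(x) * h, inverse = TRUE) / n
  edge <- max(1L, ceiling(0.05 * n))
  valid <- rep(TRUE, n)
  valid[c(seq_len(edge), seq(n - edge + 1L, n))] <- FALSE
  structure(list(phase = Arg(z), amplitude = Mod(z), rate = rate,
                 valid = valid),
            class = "analytic_series")
}
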