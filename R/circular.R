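#' Circular summary statistics
#'
#' `circ_mean()` returns the circular mean direction of a sample of
#' angles; `circ_resultant()` returns the mean resultant length
#' \eqn{\bar R \in [0, 1]} (1 = all angles identical, 0 = balanced).
#'
#' @param theta numeric vector of angles in radians.
#' @return `circ_mean()`: mean direction in \eqn{(-\pi, \pi]};
#'   `circ_resultant()`: mean resultant length.
#' @examples
#' circ_mean(c(-0.1, 0, 0.1))
#' circ_resultant(c(0, pi))  # balanced: 0
#' @export
circ_mean <- function(theta) {
  if (length(theta) == 0) return(NA_real_)
  atan2(mean(sin(theta)), mean(cos(theta)))
}

#' @rdname circ_mean
#' @export
circ_resultant <- function(theta) {
  if (length(theta) == 0) return(NA_real_)
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

# circular SD from resultant length (Mardia): sqrt(-2 log R)
circ_sd <- function(theta) sqrt(-2 * log(max(circ_resultant(theta), 1e-300)))

# circular median: the data angle minimizing summed arc distance
circ_median <- function(theta) {
  d <- outer(theta, theta, function(a, b) pi - abs(pi - abs(a - b)))
  theta[which.min(rowSums(d))]
}

# Maximum-likelihood inverse of A1(kappa) = I1(kappa)/I0(kappa)
# (Fisher 1993, eq. 4.40-4.42 piecewise approximation).
a1inv <- function(r) {
  if (r >= 1) return(Inf)
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` gives the circular
#' uniform; `kappa = Inf` degenerates to the point mass at `mu`.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration parameter, \eqn{\ge 0}.
#' @return angles in \eqn{(-\pi, \pi]}.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (is.infinite(kappa)) return(rep(wrap_pi(mu), n))
  if (kappa < 1e-8) return(wrap_pi(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    if (u[2] < cc * (2 - cc) || log(cc) - log(u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
    }
  }
  wrap_pi(mu + out)
}

#' Uniform null sample of phases
#'
#' Draws `n` phases uniformly on \eqn{(-\pi, \pi]}; the null model for
#' observed-versus-random phase-distribution comparisons.
#'
#' @param n sample size.
#' @return angles in \eqn{(-\pi, \pi]}.
#' @export
null_phases <- function(n) wrap_pi(runif(n, -pi, pi))

#' Watson-Williams test for equal mean directions
#'
#' Two-sample (more generally, multisample) circular analogue of the
#' one-way ANOVA F test. The test assumes von Mises samples with common,
#' sufficiently large concentration; `applicable` reports the standard
#' criterion that the pooled mean resultant length is at least 0.45.
#'
#' @param ... two or more numeric vectors of angles (radians), or a
#'   single list of them.
#' @return list with `F`, `df`, `p`, pooled resultant `rw`, and
#'   `applicable`.
#' @export
watson_williams_test <- function(...) {
  samples <- list(...)
  if (length(samples) == 1 && is.list(samples[[1]])) samples <- samples[[1]]
  r <- length(samples)
  if (r < 2) stop("need at least two samples")
  n_i <- lengths(samples)
  if (any(n_i < 8)) stop("each sample must have n >= 8")
  N <- sum(n_i)
  R_i <- vapply(samples, function(s) length(s) * circ_resultant(s), 0)
  R <- N * circ_resultant(unlist(samples))
  rw <- sum(R_i) / N
  kappa <- a1inv(rw)
  beta <- 1 + 3 / (8 * kappa)
  denom <- N - sum(R_i)
  Fstat <- if (denom <= .Machine$double.eps * N) Inf
  else beta * ((N - r) * (sum(R_i) - R)) / ((r - 1) * denom)
  Fstat <- max(Fstat, 0)
  p <- pf(Fstat, r - 1, N - r, lower.tail = FALSE)
  list(F = Fstat, df = c(r - 1, N - r), p = p, rw = rw,
       applicable = rw >= 0.45)
}

#' Nonparametric test for a common median direction
#'
#' Fisher's multisample test that several circular samples share a
#' median direction; the fallback used when the Watson-Williams
#' concentration assumption fails. The chi-squared statistic `P` counts
#' observations on either side of the pooled circular median. For two
#' samples the p value comes from the exact conditional (hypergeometric)
#' distribution of the below-median count, which is well calibrated
#' where the chi-squared approximation runs slightly liberal; for three
#' or more samples the chi-squared approximation is used.
#'
#' @inheritParams watson_williams_test
#' @return list with statistic `P`, `df`, and `p`.
#' @export
circ_median_test <- function(...) {
  samples <- list(...)
  if (length(samples) == 1 && is.list(samples[[1]])) samples <- samples[[1]]
  r <- length(samples)
  if (r < 2) stop("need at least two samples")
  n_i <- lengths(samples)
  if (any(n_i < 8)) stop("each sample must have n >= 8")
  N <- sum(n_i)
  med <- circ_median(unlist(samples))
  below <- function(s) sum(wrap_pi(s - med) < 0)
  m_i <- vapply(samples, below, 0)
  M <- sum(m_i)
  if (M == 0 || M == N) return(list(P = 0, df = r - 1, p = 1))
  P <- N^2 / (M * (N - M)) * sum(m_i^2 / n_i) - N * M / (N - M)
  p <- if (r == 2) {
    tab <- rbind(m_i, n_i - m_i)
    stats::fisher.test(tab)$p.value
  } else {
    pchisq(P, r - 1, lower.tail = FALSE)
  }
  list(P = P, df = r - 1, p = p)
}

#' Hodges-Ajne omnibus test of circular uniformity
#'
#' Nonparametric test based on `m`, the minimum number of observations
#' falling in any closed half-circle. Exact tail probability for
#' \eqn{n \le 50}; the standard large-sample approximation otherwise.
#'
#' @param theta numeric vector of angles in radians.
#' @return list with `m`, `n`, and `p`.
#' @export
omnibus_test <- function(theta) {
  n <- length(theta)
  if (n < 4) stop("need at least 4 angles")
  th <- sort(wrap_pi(theta))
  ext <- c(th, th + 2 * pi)
  # count of points in [th[i], th[i] + pi) for every boundary at a data angle
  upper <- findInterval(th + pi, ext, left.open = TRUE)
  cnt <- upper - (seq_len(n) - 1L)
  m <- min(cnt, n - cnt)
  if (n - 2 * m <= 0) return(list(m = m, n = n, p = 1))
  if (n <= 50) {
    p <- 2^(1 - n) * (n - 2 * m) * choose(n, m)
  } else {
    A <- pi * sqrt(n) / (2 * (n - 2 * m))
    p <- sqrt(2 * pi) / A * exp(-pi^2 / (8 * A^2))
  }
  list(m = m, n = n, p = min(max(p, 0), 1))
}

#' Compare two phase distributions
#'
#' Runs the Watson-Williams test for equal mean directions and, when its
#' concentration assumption is not met (pooled resultant < 0.45), falls
#' back to the nonparametric common-median test; `p` and `method` report
#' the test actually used. Per-sample omnibus uniformity tests are
#' included for reference.
#'
#' @param sample_a,sample_b numeric vectors of angles (radians), each of
#'   length \eqn{\ge 8}.
#' @return list with elements `ww` (Watson-Williams report), `median`
#'   (common-median report), `omnibus_a`, `omnibus_b`, `method`
#'   (`"watson_williams"` or `"common_median"`), and the selected `p`.
#' @seealso [null_phases()] to draw a matched-size uniform null sample.
#' @export
circular_tests <- function(sample_a, sample_b) {
  if (length(sample_a) < 8 || length(sample_b) < 8)
    stop("each sample must have n >= 8")
  ww <- watson_williams_test(sample_a, sample_b)
  medt <- circ_median_test(sample_a, sample_b)
  method <- if (ww$applicable) "watson_williams" else "common_median"
  list(ww = ww, median = medt,
       omnibus_a = omnibus_test(sample_a),
       omnibus_b = omnibus_test(sample_b),
       method = method,
       p = if (method == "watson_williams") ww$p else medt$p)
}
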