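# Calcium-transient onset detection, recruitment statistics, and
# onset-direction vectors.

#' Normalize raw fluorescence to baseline (dF/F)
#'
#' \eqn{\Delta F/F_0[c,t] = (F[c,t] - F_0[c]) / F_0[c]} with
#' \eqn{F_0[c]} the mean of each cell's preseizure baseline epoch.
#'
#' @param raw_f cells x frames matrix of raw fluorescence.
#' @param baseline_epoch integer vector of baseline frame indices.
#' @param frame_rate frames per second.
#' @param centroids optional data.frame `cell, x_um, y_um`.
#' @return object of class `"calcium_traces"`.
#' @export
compute_dff <- function(raw_f, baseline_epoch, frame_rate, centroids = NULL) {
  stopifnot(is.matrix(raw_f), length(baseline_epoch) >= 1)
  if (max(baseline_epoch) > ncol(raw_f))
    stop("baseline_epoch outside trace support")
  f0 <- rowMeans(raw_f[, baseline_epoch, drop = FALSE])
  if (any(f0 <= 0)) stop("non-positive baseline")
  structure(list(dff = sweep(sweep(raw_f, 1, f0, "-"), 1, f0, "/"),
                 frame_rate = frame_rate, centroids = centroids,
                 baseline_epoch = baseline_epoch),
            class = "calcium_traces")
}

#' Savitzky-Golay smoothing of calcium traces
#'
#' Smooths every trace with the order-2, window-7 Savitzky-Golay filter
#' (local quadratic least squares). Quadratic series pass through
#' unchanged; edges are handled by the polynomial fit on the truncated
#' window.
#'
#' @param traces a `"calcium_traces"` object.
#' @return the object with smoothed `dff`.
#' @export
smooth_traces <- function(traces) {
  if (ncol(traces$dff) < 7) stop("need at least 7 frames")
  traces$dff <- t(apply(traces$dff, 1,
                        function(x) signal::sgolayfilt(x, p = 2, n = 7)))
  traces
}

#' Auto-select the seizure-onset analysis window
#'
#' Reproducible stand-in for manual segmentation: the window is
#' `win_len` frames centered where the population-mean trace first
#' exceeds the mean + `k` SD of its own baseline epoch.
#'
#' @param traces a `"calcium_traces"` object.
#' @param win_len window length in frames (default 80).
#' @param k threshold in baseline SD units (default 5).
#' @return integer vector `(first_frame, last_frame)`.
#' @export
select_onset_window <- function(traces, win_len = 80, k = 5) {
  pop <- colMeans(traces$dff)
  base <- pop[traces$baseline_epoch]
  thr <- mean(base) + k * sd(base)
  cand <- which(pop > thr)
  cand <- cand[cand > max(traces$baseline_epoch)]
  if (length(cand) == 0) stop("no population onset found")
  ctr <- cand[1]
  first <- max(1L, ctr - win_len %/% 2)
  last <- min(ncol(traces$dff), first + win_len - 1L)
  c(first, last)
}

#' Detect per-cell seizure onsets and recruitment statistics
#'
#' Each cell's onset threshold is the mean + `k` SD of its own signal in
#' the `n_baseline` frames immediately preceding the analysis window;
#' its onset is the first in-window frame exceeding the threshold. Cells
#' never crossing threshold are "not recruited"; cells with zero
#' baseline SD are excluded with a warning. Recruited cells get
#' fractional ranks by onset frame (average ties), and the recruitment
#' duration is the time from the first to the last detected onset.
#'
#' @param traces a `"calcium_traces"` object.
#' @param window integer `(first, last)` analysis window in frames, or
#'   `NULL` to auto-select via [select_onset_window()].
#' @param n_baseline frames before the window used as baseline
#'   (default 25).
#' @param k threshold in baseline SD units (default 5).
#' @return object of class `"onset_result"`: list with per-cell
#'   `onset_frame` (NA = not recruited), `onset_threshold`, `ranks`
#'   (NA for unrecruited/excluded cells), `recruitment_duration_s`,
#'   `analysis_window`, `excluded` (degenerate-baseline cells).
#' @export
detect_onsets <- function(traces, window = NULL, n_baseline = 25, k = 5) {
  dff <- traces$dff
  nc <- nrow(dff)
  if (is.null(window)) window <- select_onset_window(traces)
  stopifnot(length(window) == 2, window[1] <= window[2])
  if (window[1] <= n_baseline)
    stop("window must leave 'n_baseline' frames before its start")
  base_idx <- (window[1] - n_baseline):(window[1] - 1L)
  base <- dff[, base_idx, drop = FALSE]
  mu <- rowMeans(base)
  sdv <- apply(base, 1, sd)
  excluded <- which(sdv == 0)
  if (length(excluded))
    warning(sprintf("%d cell(s) excluded: degenerate baseline (SD = 0)",
                    length(excluded)))
  thr <- mu + k * sdv
  win_idx <- window[1]:window[2]
  onset <- rep(NA_integer_, nc)
  for (c0 in setdiff(seq_len(nc), excluded)) {
    hit <- which(dff[c0, win_idx] > thr[c0])
    if (length(hit)) onset[c0] <- win_idx[hit[1]]
  }
  recruited <- which(!is.na(onset))
  ranks <- rep(NA_real_, nc)
  ranks[recruited] <- rank(onset[recruited], ties.method = "average")
  dur <- if (length(recruited) >= 2)
    (max(onset[recruited]) - min(onset[recruited])) / traces$frame_rate
  else 0
  structure(list(onset_frame = onset, onset_threshold = thr, ranks = ranks,
                 recruitment_duration_s = dur,
                 analysis_window = as.integer(window),
                 excluded = excluded),
            class = "onset_result")
}

#' Kendall's coefficient of concordance
#'
#' Concordance of `m` rank vectors over `n` subjects, with the standard
#' tie correction; 0 = no agreement, 1 = identical orderings.
#'
#' @param rank_matrix n x m matrix, one column of ranks per observation
#'   (seizure).
#' @return Kendall's W in `[0, 1]`.
#' @export
kendall_w <- function(rank_matrix) {
  n <- nrow(rank_matrix); m <- ncol(rank_matrix)
  stopifnot(n >= 2, m >= 2)
  R <- rowSums(rank_matrix)
  S <- sum((R - mean(R))^2)
  Tj <- apply(rank_matrix, 2, function(r) {
    tab <- table(r)
    sum(tab^3 - tab)
  })
  denom <- m^2 * (n^3 - n) - m * sum(Tj)
  if (denom <= 0) return(NA_real_)
  12 * S / denom
}

#' Reliability of the recruitment order across seizures
#'
#' Pairwise Spearman rank correlations (over cells recruited in both
#' seizures of a pair; large-sample p values) and Kendall's W (over
#' cells recruited in every seizure) with a permutation null: each
#' shuffled matrix redraws every seizure's ranks as a random permutation
#' of 1..max observed rank (sampling with replacement when the maximum
#' rank is below the number of cells, i.e. under ties). The permutation
#' p value uses the add-one convention, so it lies in (0, 1].
#'
#' @param rank_matrix cells x seizures matrix of recruitment ranks, NA
#'   for cells not recruited in a seizure.
#' @param n_perm number of shuffled matrices (default 1000).
#' @param seed RNG seed for the permutation null.
#' @return object of class `"reliability_result"`: list with
#'   `spearman_r`, `spearman_p` (seizure-pair matrices), `kendall_w`,
#'   `kendall_p`, `n_permutations`, `n_common`.
#' @export
rank_reliability <- function(rank_matrix, n_perm = 1000, seed = 1) {
  m <- ncol(rank_matrix)
  if (m < 2) stop("need at least 2 seizures")
  complete <- which(rowSums(is.na(rank_matrix)) == 0)
  if (length(complete) < 3) stop("insufficient overlap (< 3 common cells)")

  r_mat <- diag(1, m); p_mat <- diag(0, m); diag(p_mat) <- NA
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    both <- which(!is.na(rank_matrix[, i]) & !is.na(rank_matrix[, j]))
    ct <- suppressWarnings(
      cor.test(rank_matrix[both, i], rank_matrix[both, j],
               method = "spearman", exact = FALSE))
    r_mat[i, j] <- r_mat[j, i] <- unname(ct$estimate)
    p_mat[i, j] <- p_mat[j, i] <- ct$p.value
  }

  common <- rank_matrix[complete, , drop = FALSE]
  W <- kendall_w(common)
  n <- nrow(common)
  maxr <- apply(common, 2, max)
  # lean permutation null: when a seizure's max rank equals the cell
  # count the redraw is an untied permutation and the tie term vanishes
  mr <- round(maxr)
  Wnull <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      Rsum <- numeric(n); Tsum <- 0
      for (j in seq_len(m)) {
        if (mr[j] >= n) v <- sample.int(n)
        else {
          v <- sample.int(mr[j], n, replace = TRUE)
          tb <- tabulate(v, mr[j])
          Tsum <- Tsum + sum(tb^3 - tb)
        }
        Rsum <- Rsum + v
      }
      S <- sum((Rsum - mean(Rsum))^2)
      denom <- m^2 * (n^3 - n) - m * Tsum
      if (denom <= 0) NA_real_ else 12 * S / denom
    }, 0)
  })
  kp <- (1 + sum(Wnull >= W, na.rm = TRUE)) / (1 + n_perm)
  structure(list(spearman_r = r_mat, spearman_p = p_mat,
                 kendall_w = W, kendall_p = kp,
                 n_permutations = n_perm, n_common = n),
            class = "reliability_result")
}

#' Seizure onset-direction vector from cell recruitment
#'
#' The raw vector runs from the mean centroid of all rank-1 cells to the
#' mean centroid of all maximum-rank cells. The anatomical vector
#' reflects it about the image x-axis and rotates it by `rotation_deg`
#' toward the y-axis (counterclockwise by default) to compensate for the
#' animal's rotation relative to the optical path.
#'
#' @param onsets an `"onset_result"`.
#' @param centroids data.frame `cell, x_um, y_um` matching the traces.
#' @param rotation_deg signed rotation applied after reflection
#'   (default +30, counterclockwise).
#' @return object of class `"onset_vector"`: list with `x1`, `x2`,
#'   `raw_vector`, `anatomical_vector`, `direction_rad`.
#' @export
onset_direction <- function(onsets, centroids, rotation_deg = 30) {
  r <- onsets$ranks
  rec <- which(!is.na(r))
  if (length(rec) == 0 || min(r[rec]) == max(r[rec]))
    stop("no rank spread among recruited cells")
  first_cells <- rec[r[rec] == min(r[rec])]
  last_cells <- rec[r[rec] == max(r[rec])]
  x1 <- c(mean(centroids$x_um[first_cells]), mean(centroids$y_um[first_cells]))
  x2 <- c(mean(centroids$x_um[last_cells]), mean(centroids$y_um[last_cells]))
  raw <- x2 - x1
  refl <- c(raw[1], -raw[2])
  th <- rotation_deg * pi / 180
  rot <- c(cos(th) * refl[1] - sin(th) * refl[2],
           sin(th) * refl[1] + cos(th) * refl[2])
  structure(list(x1 = x1, x2 = x2, raw_vector = raw,
                 anatomical_vector = rot,
                 direction_rad = atan2(rot[2], rot[1])),
            class = "onset_vector")
}
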