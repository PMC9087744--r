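test_that("dF/F normalization matches its definition and guards baseline", {
  f <- rbind(rep(100, 50), c(rep(100, 25), rep(200, 25)))
  tr <- compute_dff(f, 1:25, frame_rate = 10)
  expect_equal(tr$dff[1, ], rep(0, 50))
  expect_equal(tr$dff[2, 30], 1.0)
  bad <- rbind(rep(0, 50))
  expect_error(compute_dff(bad, 1:25, 10), "non-positive baseline")
})

test_that("Savitzky-Golay smoothing is exact on quadratics and has the
           known impulse response", {
  t0 <- 0:99
  quad <- 2 + 0.3 * t0 + 0.01 * t0^2
  tr <- structure(list(dff = rbind(quad), frame_rate = 10,
                       baseline_epoch = 1:10), class = "calcium_traces")
  sm <- smooth_traces(tr)
  expect_equal(sm$dff[1, 4:97], quad[4:97], tolerance = 1e-8)
  # central coefficient of the order-2, length-7 kernel is 7/21 = 1/3
  imp <- numeric(31); imp[16] <- 1
  tri <- structure(list(dff = rbind(imp), frame_rate = 10,
                        baseline_epoch = 1:5), class = "calcium_traces")
  smi <- smooth_traces(tri)
  expect_equal(unname(smi$dff[1, 16]), 1 / 3, tolerance = 1e-10)
  short <- structure(list(dff = rbind(1:5), frame_rate = 10),
                     class = "calcium_traces")
  expect_error(smooth_traces(short), "7 frames")
})

test_that("onset detection recovers planted steps and handles edge cases", {
  set.seed(9)
  n_sim <- 300
  hits <- replicate(n_sim, {
    x <- rnorm(120, 0, 0.01)
    f0 <- 60
    x[f0:120] <- x[f0:120] + 1.0
    tr <- structure(list(dff = rbind(x), frame_rate = 10,
                         baseline_epoch = 1:25), class = "calcium_traces")
    o <- detect_onsets(tr, window = c(30, 110))
    o$onset_frame[1] %in% c(f0, f0 + 1)
  })
  expect_gte(mean(hits), 0.99)

  # never-crossing cell is "not recruited" and excluded from ranks
  set.seed(10)
  dff <- rbind(c(rnorm(40, 0, 0.01), rnorm(40, 1, 0.01)),
               c(rnorm(40, 0, 0.01), rnorm(40, 1, 0.01) - 1),
               c(rnorm(35, 0, 0.01), rnorm(45, 1, 0.01)))
  tr <- structure(list(dff = dff, frame_rate = 10, baseline_epoch = 1:25),
                  class = "calcium_traces")
  o <- detect_onsets(tr, window = c(30, 80))
  expect_true(is.na(o$onset_frame[2]))
  expect_true(is.na(o$ranks[2]))
  expect_equal(sort(o$ranks[c(1, 3)]), c(1, 2))
  # onsets at frames 36 and 41 at 10 Hz: duration 0.5 s
  expect_equal(o$recruitment_duration_s,
               diff(range(o$onset_frame, na.rm = TRUE)) / 10)
  # degenerate baseline flagged and excluded
  dff2 <- rbind(dff[1, ], rep(0, 80))
  tr2 <- structure(list(dff = dff2, frame_rate = 10, baseline_epoch = 1:25),
                   class = "calcium_traces")
  expect_warning(o2 <- detect_onsets(tr2, window = c(30, 80)), "degenerate")
  expect_identical(o2$excluded, 2L)
})

test_that("recruitment duration is onset-span arithmetic", {
  dff <- matrix(0.0, 2, 40)
  dff[1, 10:40] <- 1
  dff[2, 22:40] <- 1
  dff <- dff + matrix(rnorm(80, 0, 1e-4), 2, 40)
  tr <- structure(list(dff = dff, frame_rate = 10, baseline_epoch = 1:5),
                  class = "calcium_traces")
  o <- detect_onsets(tr, window = c(6, 40), n_baseline = 5)
  expect_equal(o$onset_frame, c(10L, 22L))
  expect_equal(o$recruitment_duration_s, 1.2)
})

test_that("rank reliability reproduces hand-computed Spearman and W limits", {
  # identical rank vectors across 4 seizures
  r <- sample.int(12)
  rel <- rank_reliability(cbind(r, r, r, r), n_perm = 1000, seed = 2)
  expect_equal(rel$kendall_w, 1)
  expect_lte(rel$kendall_p, 0.005)
  expect_true(all(rel$spearman_r[upper.tri(rel$spearman_r)] == 1))
  # exactly reversed ranks: Spearman -1, W = 0
  rev2 <- cbind(1:10, 10:1)
  rel2 <- rank_reliability(rev2, n_perm = 100, seed = 3)
  expect_equal(rel2$spearman_r[1, 2], -1)
  expect_equal(rel2$kendall_w, 0)
  # hand value: ranks (1,2,3) vs (2,1,3) -> r = 1 - 6*2/(27-3) = 0.5
  rel3 <- rank_reliability(cbind(1:3, c(2, 1, 3)), n_perm = 100, seed = 4)
  expect_equal(rel3$spearman_r[1, 2], 0.5)
  expect_error(rank_reliability(cbind(c(1, 2, NA), c(1, NA, 2))),
               "insufficient overlap")
})

test_that("onset vectors follow the reflect-then-rotate construction", {
  onsets <- structure(list(ranks = c(1, 1, 3, NA)), class = "onset_result")
  cent <- data.frame(cell = 1:4, x_um = c(0, 2, 4, 9), y_um = c(0, 0, 0, 9))
  v <- onset_direction(onsets, cent)
  expect_equal(v$raw_vector, c(3, 0))
  # reflected (3, 0) rotated +30 degrees
  expect_equal(v$anatomical_vector, 3 * c(cos(pi / 6), sin(pi / 6)))
  expect_equal(v$direction_rad, pi / 6)
  # pure-y raw vector: reflection flips its sign before rotation
  onsets2 <- structure(list(ranks = c(1, 2)), class = "onset_result")
  cent2 <- data.frame(cell = 1:2, x_um = c(0, 0), y_um = c(0, 1))
  v2 <- onset_direction(onsets2, cent2, rotation_deg = 0)
  expect_equal(v2$anatomical_vector, c(0, -1))
  # |anatomical| = |raw| under any rotation
  expect_equal(sqrt(sum(v$anatomical_vector^2)), sqrt(sum(v$raw_vector^2)))
  onsets3 <- structure(list(ranks = c(2, 2, 2)), class = "onset_result")
  expect_error(onset_direction(onsets3, cent[1:3, ]), "no rank spread")
})
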