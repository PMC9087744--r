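test_that("discharge peak detection thresholds on the rectified signal and
           is scale invariant", {
  rate <- 2000
  tt <- seq(0, 10, by = 1 / rate)
  # sub-threshold sinusoid: constant-amplitude oscillation never clears
  # mean(|x|) + 2 SD(|x|)
  x <- sin(2 * pi * 8 * tt)
  expect_equal(nrow(detect_discharge_peaks(x, rate)), 0)
  set.seed(4)
  g <- generate_lfp(quick_cfg(noise_sd_ephys = 0, timing_jitter_ms = 0))
  lf <- bandpass(g$recording$signals[1, ], 2000, c(4, 30))
  p1 <- detect_discharge_peaks(lf, 2000)
  # every planted discharge yields a suprathreshold peak within half a
  # carrier cycle of its planted per-channel time (side-cycle peaks of
  # the same discharge are absorbed later by event grouping)
  planted <- g$truth$channel_peak_times[1, ]
  expect_true(all(vapply(planted,
                         function(t) min(abs(p1$time_s - t)) < 1 / 16, TRUE)))
  expect_gte(nrow(p1), length(planted))
  p3 <- detect_discharge_peaks(3 * lf, 2000)
  expect_equal(p1$time_s, p3$time_s)
  expect_error(detect_discharge_peaks(numeric(100), rate), "degenerate")
})

test_that("grouping chains peaks within 150 ms and applies the channel gate", {
  geom <- data.frame(channel = 1:16,
                     x_mm = rep(0:3, 4) * 0.5, y_mm = rep(0:3, each = 4) * 0.5,
                     functional = TRUE)
  # 16 peaks spanning 15 ms: one event with 16 points
  pk <- data.frame(channel = 1:16, time_s = seq(1, 1.015, length.out = 16),
                   amp = 1)
  ev <- group_discharges(pk, geom)
  expect_length(ev, 1)
  expect_equal(nrow(ev[[1]]), 16)
  # 8 of 16 channels (50% <= 60%) discarded
  ev8 <- group_discharges(pk[1:8, ], geom)
  expect_length(ev8, 0)
  # two bursts 1 s apart: two events
  pk2 <- rbind(pk, transform(pk, time_s = time_s + 1))
  expect_length(group_discharges(pk2, geom), 2)
  # duplicate peaks on one channel: largest amplitude wins
  pkd <- rbind(pk, data.frame(channel = 1, time_s = 1.010, amp = 9))
  evd <- group_discharges(pkd, geom)
  expect_equal(evd[[1]]$t_s[evd[[1]]$channel == 1], 1.010)
})

test_that("plane fit matches the normal-equations oracle and inverts planted
           planes exactly", {
  # t = 0.002 x: direction 0, speed 500 mm/s, zero residual
  ev <- plane_event(a = 0.002, b = 0)
  f <- fit_plane(ev)
  expect_equal(f$direction_rad, 0)
  expect_equal(f$speed_mm_s, 500)
  expect_lt(f$residual_rms, 1e-12)
  expect_equal(f$speed_m_s, f$speed_mm_s / 1000)
  # 45 degrees at 250 mm/s
  a45 <- cos(pi / 4) / 250
  f45 <- fit_plane(plane_event(a = a45, b = a45 * tan(pi / 4)))
  expect_equal(f45$direction_rad, pi / 4, tolerance = 1e-9)
  expect_equal(f45$speed_mm_s, 250, tolerance = 1e-6)
  # all channels simultaneous: degenerate flag
  fd <- fit_plane(plane_event(a = 0, b = 0))
  expect_true(fd$degenerate)
  expect_true(is.na(fd$speed_mm_s))
  # collinear geometry is an error
  col <- data.frame(x_mm = 0:3, y_mm = 2 * (0:3), t_s = runif(4))
  expect_error(fit_plane(col), "rank-deficient")
  # oracle agreement on random events
  set.seed(12)
  for (i in 1:25) {
    n <- sample(4:16, 1)
    evr <- data.frame(x_mm = runif(n), y_mm = runif(n), t_s = runif(n))
    f1 <- fit_plane(evr)
    expect_equal(unname(f1$plane), unname(plane_oracle(evr)),
                 tolerance = 1e-10)
  }
})

test_that("recovered directions are equivariant to grid rotation", {
  set.seed(13)
  ev <- plane_event(a = 0.001, b = 0.0015)
  ev$t_s <- ev$t_s + rnorm(16, 0, 1e-4)
  f0 <- fit_plane(ev)
  rho <- 0.7
  evr <- ev
  evr$x_mm <- cos(rho) * ev$x_mm - sin(rho) * ev$y_mm
  evr$y_mm <- sin(rho) * ev$x_mm + cos(rho) * ev$y_mm
  fr <- fit_plane(evr)
  ddir <- ((fr$direction_rad - f0$direction_rad - rho + pi) %% (2 * pi)) - pi
  expect_equal(ddir, 0, tolerance = 1e-9)
  expect_equal(fr$speed_mm_s, f0$speed_mm_s, tolerance = 1e-9)
})

test_that("direction distributions: omnibus flags concentration, KS is null
           on self-comparison", {
  set.seed(14)
  d1 <- rvonmises(60, 1, 6)
  d2 <- rvonmises(60, -2, 6)
  st <- direction_stats(list(a = d1, b = d2, self = d1))
  expect_lt(st$omnibus$a$p, 0.001)
  ks_self <- st$ks[st$ks$set_a == "a" & st$ks$set_b == "self", ]
  expect_equal(ks_self$D, 0)
  expect_equal(ks_self$p, 1)
  expect_lt(st$ks$p[1], 0.01)  # a vs b differ
  expect_error(direction_stats(list(d1[1:4])), ">= 8 events")
})

test_that("epoch speed comparison detects slowing and is null on ties", {
  set.seed(15)
  times <- seq(0, 99)
  speeds <- 500 * 0.99^times
  r <- speed_epoch_comparison(times, speeds)
  expect_lt(r$p, 0.01)
  expect_lt(r$median_last, r$median_first)
  # identical epoch value distributions (period 5 aligns both 10-event
  # epochs) give p = 1 under tie handling without continuity correction
  same <- speed_epoch_comparison(1:40, rep(c(1, 2, 3, 4, 5), 8))
  expect_equal(same$p, 1)
  expect_error(speed_epoch_comparison(1:8 / 8, 1:8), "at least 4")
})

test_that("epoch comparison false-positive rate is nominal under constant
           speed", {
  set.seed(16)
  rej <- replicate(200, {
    sp <- 500 + rnorm(60, 0, 30)
    speed_epoch_comparison(seq_len(60), sp)$p < 0.05
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.09)
})
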