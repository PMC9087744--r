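test_that("configuration invariants are enforced", {
  expect_error(synth_config(duration_s = 5, baseline_s = 10), "baseline")
  expect_error(synth_config(onset_span_s = 0), "onset_span")
  expect_error(synth_config(grid_shape = c(1, 3)), "at least 4 channels")
  expect_error(synth_config(wave_speed_mm_s = -1), "positive")
  expect_error(synth_config(discharge_rate_hz = 10), NA)
  # wavelet merge guard: 25 Hz discharges would overlap the 240 ms support
  cfg <- quick_cfg(discharge_rate_hz = 30)
  expect_error(generate_lfp(cfg), "merge")
})

test_that("identical seed and config give bit-identical datasets", {
  cfg <- quick_cfg(seed = 14)
  a <- generate_lfp(cfg)
  b <- generate_lfp(cfg)
  expect_identical(a, b)
  ca1 <- generate_calcium(cfg, a$truth)
  ca2 <- generate_calcium(cfg, b$truth)
  expect_identical(ca1, ca2)
  c2 <- generate_lfp(quick_cfg(seed = 15))
  expect_false(identical(a$recording$signals, c2$recording$signals))
})

test_that("planted geometry yields exact peak-time differences and plane
           consistency", {
  cfg <- quick_cfg(wave_direction_rad = 0, timing_jitter_ms = 0,
                   noise_sd_ephys = 0, speed_trend = 1)
  g <- generate_lfp(cfg)
  pt <- g$truth$channel_peak_times
  geom <- g$recording$geometry
  # adjacent columns 0.5 mm apart at 500 mm/s: exactly 1 ms
  expect_equal(pt[2, 1] - pt[1, 1], 0.5 / 500)
  # all planted times lie exactly on the plane
  proj <- geom$x_mm  # direction 0: gradient along x
  for (k in c(1, ncol(pt))) {
    fit <- lm(pt[, k] ~ geom$x_mm + geom$y_mm)
    expect_lt(max(abs(residuals(fit))), 1e-12)
  }
  # wavelet argmax per channel lands on the planted plane within 1 sample
  ev <- wave_events(g$recording)
  expect_equal(nrow(ev), length(g$truth$discharge_times))
  expect_lt(max(ev$residual_rms), 1 / cfg$ephys_rate)
  expect_equal(median(ev$speed_mm_s), 500, tolerance = 1e-3)
})

test_that("phase locking is exact for infinite concentration and tight for
           kappa >= 50", {
  cfg <- quick_cfg(hg_lock_kappa = Inf, noise_sd_ephys = 0,
                   timing_jitter_ms = 0, hg_lock_phase_rad = 0.8)
  g <- generate_lfp(cfg)
  expect_equal(g$truth$hg$phase, rep(0.8, nrow(g$truth$hg)),
               tolerance = 1e-12)
  cfg50 <- quick_cfg(hg_lock_kappa = 50)
  g50 <- generate_lfp(cfg50)
  ph <- g50$truth$hg$phase
  expect_lt(sqrt(-2 * log(circ_resultant(ph))), 0.15)
})

test_that("calcium traces honor planted onsets, spans and rank structure", {
  cfg <- quick_cfg(noise_sd_dff = 0, n_cells = 13, onset_span_s = 1.2,
                   frame_rate = 10)
  g <- generate_lfp(cfg)
  ca <- generate_calcium(cfg, g$truth)
  # exactly zero before each planted onset frame
  for (c0 in seq_len(13)) {
    f <- ca$truth$onset_frame[c0]
    expect_true(all(ca$calcium$dff[c0, seq_len(f - 1)] == 0))
    expect_gt(ca$calcium$dff[c0, f], 0)
  }
  # 1.2 s span at 10 Hz: 12 frames between first and last onset
  expect_equal(diff(range(ca$truth$onset_frame)), 12)
  expect_error(generate_calcium(quick_cfg(n_cells = 1), g$truth),
               "at least 2 cells")
})

test_that("studies share the rank template and apply the speed trend", {
  cfg <- quick_cfg(onset_rank_noise = 0, speed_trend = 0.995)
  st <- generate_study(cfg, n_seizures = 4)
  expect_length(st, 4)
  ranks <- vapply(st, function(s) s$truth$planted_rank, numeric(10))
  expect_true(all(ranks == ranks[, 1]))  # identical rank vectors
  expect_equal(cor(st[[1]]$truth$planted_rank, st[[2]]$truth$planted_rank,
                   method = "spearman"), 1)
  # distinct noise realizations
  expect_false(identical(st[[1]]$recording$signals,
                         st[[2]]$recording$signals))
  # speed trend: last = 0.995^(n-1) x first; trend 1 = constant
  sp <- st[[1]]$truth$speeds
  n <- length(sp)
  expect_equal(sp[n], 0.995^(n - 1) * sp[1], tolerance = 1e-12)
  st1 <- generate_study(quick_cfg(speed_trend = 1), n_seizures = 1)
  expect_true(all(st1[[1]]$truth$speeds == st1[[1]]$truth$speeds[1]))
  # rank noise decorrelates orders across seizures
  stn <- generate_study(quick_cfg(onset_rank_noise = 0.5), n_seizures = 2)
  rn <- cor(stn[[1]]$truth$planted_rank, stn[[2]]$truth$planted_rank,
            method = "spearman")
  expect_lt(rn, 1)
})

test_that("recovered rank order degrades monotonically with rank noise", {
  rho <- vapply(c(0, 0.15, 0.6), function(nz) {
    st <- generate_study(quick_cfg(seed = 31, onset_rank_noise = nz,
                                   n_cells = 20), n_seizures = 2)
    cor(st[[1]]$truth$planted_rank, st[[2]]$truth$planted_rank,
        method = "spearman")
  }, 0)
  expect_true(all(diff(rho) < 0))
  expect_equal(rho[1], 1)
})
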