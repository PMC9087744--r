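# Shared fixture configurations, all generated in code at test time.

# small, fast ephys-only record (no MUA at 2 kHz)
quick_cfg <- function(seed = 3, duration_s = 20, n_cells = 10, ...) {
  synth_config(seed = seed, duration_s = duration_s, ephys_rate = 2000,
               n_cells = n_cells, ...)
}

# short wide-band record carrying representable multiunit spikes
mua_cfg <- function(seed = 7, ...) {
  synth_config(seed = seed, duration_s = 8, baseline_s = 2,
               onset_span_s = 1.2, ephys_rate = 20000, n_cells = 4, ...)
}

# deterministic planted-plane event: times exactly on t = a x + b y + c
plane_event <- function(a, b, c0 = 0.5, geom = expand.grid(
  x_mm = (0:3) * 0.5, y_mm = (0:3) * 0.5)) {
  data.frame(x_mm = geom$x_mm, y_mm = geom$y_mm,
             t_s = a * geom$x_mm + b * geom$y_mm + c0)
}

# brute-force normal-equations plane fit: the independent oracle
plane_oracle <- function(event) {
  X <- cbind(event$x_mm, event$y_mm, 1)
  solve(t(X) %*% X, t(X) %*% event$t_s)[, 1]
}
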