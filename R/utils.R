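# internal helpers shared across modules

# wrap angles to (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Derive a 32-bit sub-seed from a master seed and a fixed component index.
# Keeps each signal component on its own reproducible stream so that e.g.
# adding cells does not perturb the LFP noise draws.
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  (as.double(seed) * 7919 + 104729 * as.double(component)) %% 2147483629
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}
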