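# Shared fixtures: small, fast parameter sets used across the suite.

# Default chemistry on a tiny lattice (cheap spatial runs).
tiny_params <- function(shape = c(4L, 4L, 4L), ...) {
  default_params(lattice_shape = as.integer(shape), ...)
}

# Single well-mixed box spanning 1 mL (the batch-culture limit).
one_ml_params <- function(...) {
  default_params(lattice_shape = c(1L, 1L, 1L), box_len = 1e4, ...)
}

# Random well-mixed state for pointwise rhs comparisons.
random_wm_state <- function(seed) {
  set.seed(seed)
  wm_state(
    n = runif(1, 1e7, 1e9),
    B = runif(1, 1e2, 1e7),
    P = runif(1, 1e2, 1e7),
    I = runif(10, 0, 1e5)
  )
}

run_totals <- function(run) {
  s <- tidy(run)
  s[nrow(s), ]
}
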