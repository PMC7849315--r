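# Shared fixtures. Full-horizon regime runs are expensive (~5 s each), so
# they are computed once per test session and reused.

.run_cache <- new.env(parent = emptyenv())

cached_regime_run <- function(condition) {
  key <- paste0("run_", condition)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_simulation(model_parameters(), condition,
                                        dt = 0.001, horizon = 300,
                                        snapshot_every = 2)
  }
  .run_cache[[key]]
}

# Forward-Euler integration of a single scalar ODE dx/dt = f(x); the
# brute-force oracle for closed-form steady states.
euler_to_steady <- function(f, x0, dt = 0.01, t_end = 2000) {
  x <- x0
  for (k in seq_len(ceiling(t_end / dt))) x <- x + dt * f(x)
  x
}

# A hand-built nontrivial two-file state for integrator cross-checks.
nontrivial_state <- function(params, n = 6) {
  mk <- function(shift) {
    list(A = seq(0.5, 2, length.out = n) + shift,
         PINc = rep(200, n) - 10 * seq_len(n),
         PINm_apical = seq(20, 120, length.out = n),
         PINm_basal = rep(0, n),
         PINm_outer = seq(5, 60, length.out = n),
         DIV = rep(1, n), length = rep(12, n), zone = rep(0L, n))
  }
  list(epidermis = mk(0), cortex = mk(0.3))
}
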