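# Shared fixtures, built once per test run. The default models come from
# the bundled rate table; grids are cached because they are the expensive
# part of the hybrid tests.

.fixtures <- new.env(parent = emptyenv())

fix_lti <- function(set = "set1") {
  key <- paste0("lti_", set)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- make_lti_model(os_set = set)
  }
  .fixtures[[key]]
}

fix_non_lti <- function() {
  if (is.null(.fixtures$non_lti)) .fixtures$non_lti <- make_non_lti_model()
  .fixtures$non_lti
}

fix_grid <- function(model, dt = 0.02) {
  key <- paste0(model$variant, "_",
                if (is.null(model$os_rates)) "" else model$os_rates$os$k0,
                "_", dt)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- transition_grid(model, dt)
  }
  .fixtures[[key]]
}

rested <- function(model, V = -80) {
  stationary_distribution(build_generator(as_scheme_for_test(model), V))
}

as_scheme_for_test <- function(x) if (inherits(x, "nav_model")) x$scheme else x

# a small random reversible-ish scheme for oracle tests
random_scheme <- function(n_states, seed) {
  set.seed(seed)
  states <- paste0("X", seq_len(n_states))
  from <- to <- character(0)
  for (i in seq_len(n_states - 1)) {
    from <- c(from, states[i], states[i + 1])
    to <- c(to, states[i + 1], states[i])
  }
  kinetic_scheme(states, conducting = rep(FALSE, n_states),
                 transitions = data.frame(
                   from = from, to = to,
                   k0 = stats::runif(length(from), 0.1, 3),
                   k1 = stats::runif(length(from), -0.05, 0.05)))
}

# forward-Euler reference integrator (independent oracle for the
# matrix-exponential path); step-doubling Richardson extrapolation removes
# the O(dt) truncation error of the raw Euler sweep
euler_propagate <- function(P0, Q, t_end, dt = 1e-4) {
  run <- function(h) {
    P <- P0
    for (i in seq_len(round(t_end / h))) P <- P + h * (P %*% Q)
    drop(P)
  }
  2 * run(dt / 2) - run(dt)
}
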