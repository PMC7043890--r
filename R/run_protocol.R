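#' Simulate state occupancies under a voltage-clamp protocol
#'
#' Propagates the occupancy vector through a piecewise-constant protocol.
#' Within each constant-voltage segment the master equation is solved
#' exactly with the matrix exponential: the per-sample transition matrix
#' `expm(Q * dt_out)` is computed once per (voltage, step) pair and the
#' occupancy is advanced by repeated vector-matrix products, so the result
#' is independent of `dt_out` at shared time points.
#'
#' @param scheme A [kinetic_scheme()] or a [nav_model()].
#' @param protocol A [voltage_protocol()].
#' @param P0 Initial occupancy vector. Default (`NULL`) uses the
#'   stationary distribution at the protocol's holding potential (the
#'   `v_hold` attribute set by the protocol generators, falling back to
#'   the first segment's voltage): a fully rested channel population, as
#'   after the long inter-sweep holding interval of the experimental
#'   protocols.
#' @param dt_out Output sampling interval in ms; either a scalar or one
#'   value per protocol segment (coarse sampling of long holding periods
#'   keeps trajectories small).
#' @return An object of class `occupancy_trajectory`: a list with `times`
#'   (ms), `voltage` (mV per sample), `P` (samples x states occupancy
#'   matrix), `states` and `conducting`.
#' @export
run_protocol <- function(scheme, protocol, P0 = NULL, dt_out = 0.02) {
  scheme <- as_scheme(scheme)
  stopifnot(inherits(protocol, "voltage_protocol"))
  nseg <- nrow(protocol)
  if (any(!is.finite(dt_out)) || any(dt_out <= 0)) {
    stop("`dt_out` must be positive")
  }
  dt_seg <- rep_len(dt_out, nseg)

  if (is.null(P0)) {
    v_rest <- attr(protocol, "v_hold")
    if (is.null(v_rest)) v_rest <- protocol$level[1]
    P0 <- stationary_distribution(build_generator(scheme, v_rest))
  }
  P0 <- check_occupancy(P0, n_states(scheme))

  cache <- new.env(parent = emptyenv())
  get_tm <- function(V, dt) {
    key <- paste(format(V, digits = 15), format(dt, digits = 15))
    if (is.null(cache[[key]])) {
      cache[[key]] <- transition_matrix(build_generator(scheme, V), dt)
    }
    cache[[key]]
  }

  times <- list(0)
  volts <- list(protocol$level[1])
  chunks <- list(matrix(P0, nrow = 1))
  P <- P0
  t0 <- 0
  for (s in seq_len(nseg)) {
    dur <- protocol$duration[s]
    V <- protocol$level[s]
    dt <- dt_seg[s]
    n_full <- floor(dur / dt + 1e-9)
    rem <- dur - n_full * dt
    if (n_full > 0) {
      M <- get_tm(V, dt)
      traj <- cpp_chain(P, M, n_full)
      P <- traj[nrow(traj), ]
      times[[length(times) + 1L]] <- t0 + seq_len(n_full) * dt
      volts[[length(volts) + 1L]] <- rep(V, n_full)
      chunks[[length(chunks) + 1L]] <- traj
    }
    if (rem > 1e-9) {
      P <- drop(P %*% get_tm(V, rem))
      times[[length(times) + 1L]] <- t0 + dur
      volts[[length(volts) + 1L]] <- V
      chunks[[length(chunks) + 1L]] <- matrix(P, nrow = 1)
    }
    t0 <- t0 + dur
  }

  Pmat <- do.call(rbind, chunks)
  colnames(Pmat) <- scheme$states
  out <- structure(
    list(times = unlist(times),
         voltage = unlist(volts),
         P = Pmat,
         states = scheme$states,
         conducting = scheme$conducting),
    class = "occupancy_trajectory"
  )
  err <- max(abs(rowSums(Pmat) - 1))
  if (err > 1e-9) {
    stop(sprintf("probability conservation violated (max |sum - 1| = %.2e)",
                 err))
  }
  out
}

as_scheme <- function(x) {
  if (inherits(x, "nav_model")) return(x$scheme)
  if (inherits(x, "kinetic_scheme")) return(x)
  stop("expected a `kinetic_scheme` or `nav_model`")
}

#' @export
print.occupancy_trajectory <- function(x, ...) {
  cat(sprintf("<occupancy trajectory> %d samples over %g ms, %d states\n",
              length(x$times), max(x$times), ncol(x$P)))
  invisible(x)
}

#' Summed occupancy of a set of states
#'
#' @param traj An `occupancy_trajectory`.
#' @param states Character vector of state labels to sum over.
#' @return Numeric vector, one value per sample.
#' @export
occupancy_of <- function(traj, states) {
  missing <- setdiff(states, colnames(traj$P))
  if (length(missing) > 0) {
    stop("unknown state(s): ", paste(missing, collapse = ", "))
  }
  if (length(states) == 1L) traj$P[, states] else rowSums(traj$P[, states])
}

#' Open probability of a trajectory
#'
#' Summed occupancy of all conducting states.
#' @param traj An `occupancy_trajectory`.
#' @return Numeric vector per sample.
#' @export
open_probability <- function(traj) {
  occupancy_of(traj, traj$states[traj$conducting])
}

#' @export
as.data.frame.occupancy_trajectory <- function(x, ...) {
  data.frame(time_ms = x$times, voltage_mV = x$voltage, x$P,
             check.names = FALSE)
}
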