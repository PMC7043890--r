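#' Current-simulation settings
#'
#' Settings for converting open probability into macroscopic sodium
#' current, `I(t) = G_Na * P_O(t) * (V(t) - E_Na)` (pA when conductance is
#' in nS and voltage in mV; inward current is negative for `V < E_Na`).
#' Conductance can be given either as a total (`g_na`, nS) or as a density
#' (`g_na_density`, nS/pF) together with the membrane capacitance `c_m`
#' (pF), matching the units used for conductance injection.
#'
#' @param g_na Total sodium conductance, nS.
#' @param g_na_density Sodium conductance density, nS/pF (used with
#'   `c_m` when `g_na` is not given).
#' @param c_m Membrane capacitance, pF (default 20).
#' @param e_na Sodium reversal potential, mV (default +60).
#' @return An object of class `current_sim_settings`.
#' @export
current_sim_settings <- function(g_na = NULL, g_na_density = NULL,
                                 c_m = 20, e_na = 60) {
  if (is.null(g_na)) {
    if (is.null(g_na_density)) {
      stop("give either `g_na` (nS) or `g_na_density` (nS/pF)")
    }
    stopifnot(g_na_density > 0, c_m > 0)
    g_na <- g_na_density * c_m
  }
  stopifnot(is.numeric(g_na), g_na > 0, is.finite(e_na))
  structure(list(g_na = g_na, c_m = c_m, e_na = e_na),
            class = "current_sim_settings")
}

#' Simulate macroscopic sodium current under a voltage-clamp protocol
#'
#' Runs [run_protocol()] and converts the conducting-state occupancy into
#' an ohmic current trace.
#'
#' @param model A [nav_model()] (or any [kinetic_scheme()] with
#'   conducting states).
#' @param protocol A [voltage_protocol()].
#' @param settings A [current_sim_settings()].
#' @param dt_out Output sampling in ms (scalar or per segment); the
#'   default 0.01 ms corresponds to 100 kHz digitisation.
#' @param P0 Initial occupancy (default: rested at the first segment
#'   voltage).
#' @return An object of class `current_trace`: a list with `times` (ms),
#'   `I` (pA), `voltage` (mV) and the underlying `trajectory`.
#' @export
simulate_current <- function(model, protocol, settings, dt_out = 0.01,
                             P0 = NULL) {
  stopifnot(inherits(settings, "current_sim_settings"))
  traj <- run_protocol(model, protocol, P0 = P0, dt_out = dt_out)
  po <- open_probability(traj)
  I <- settings$g_na * po * (traj$voltage - settings$e_na)
  structure(list(times = traj$times, I = I, voltage = traj$voltage,
                 trajectory = traj, settings = settings),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current trace> %d samples over %g ms, peak |I| = %.1f pA\n",
              length(x$times), max(x$times), max(abs(x$I))))
  invisible(x)
}

#' @export
as.data.frame.current_trace <- function(x, ...) {
  data.frame(time_ms = x$times, voltage_mV = x$voltage, current_pA = x$I)
}
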