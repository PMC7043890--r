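#' @useDynLib navlti, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

nav_state_names <- function(lti = TRUE) {
  s <- c(paste0("C", 1:5), "O6", paste0("I", 7:12))
  if (lti) s <- c(s, "S13")
  s
}

#' Printed O6-S13 rate-constant sets
#'
#' The two published parameter sets for the open <-> long-term-inactivated
#' transition, on the canonical per-ms scale. Set 1 gives a leak time
#' constant of about 435 ms with an 80%/20% normal-inactivation/LTI split;
#' set 2 gives about 820 ms and 90%/10%. Both give an equilibrium S-state
#' occupancy near 0.7 because they share the k(O->S)/k(S->O) ratio.
#'
#' @param set `"set1"` or `"set2"`.
#' @return A list with `rate_constant`s `os` (O6 -> S13) and `so`
#'   (S13 -> O6).
#' @export
os_param_set <- function(set = c("set1", "set2")) {
  set <- match.arg(set)
  if (set == "set1") {
    list(os = rate_constant(400.8e-3, -0.011),
         so = rate_constant(0.207e-3, -0.031))
  } else {
    list(os = rate_constant(205.7e-3, -0.011),
         so = rate_constant(0.106e-3, -0.031))
  }
}

#' Bundled Nav rate table
#'
#' Loads the rate-constant table shipped with the package
#' (`nav_rates_synthetic.csv`). The table implements the canonical
#' 13-state topology - a five-state closed (activation) ladder C1..C5, one
#' open state O6, a parallel inactivated ladder I7..I12, and the
#' long-term inactivated state S13 attached to the open state. The
#' O6-S13 rates are the published set-1 values; all other rates are this
#' package's own calibration, chosen once so the model reproduces the
#' published emergent kinetics (see the methods vignette).
#'
#' @return A rate-table `data.frame` (per-ms scale), as from
#'   [read_rate_table()].
#' @export
nav_rate_table <- function() {
  path <- system.file("extdata", "nav_rates_synthetic.csv",
                      package = "navlti", mustWork = TRUE)
  read_rate_table(path)
}

#' Nav gating models with and without long-term inactivation
#'
#' `make_lti_model()` builds the 13-state model in which the open state
#' O6 is coupled to a long-lived non-conducting state S13 (open-channel
#' block by an FHF-type auxiliary factor). `make_non_lti_model()` builds
#' the 12-state control model: identical rates, but with S13 and the
#' O6-S13 transitions removed.
#'
#' @param rate_table A rate table from [read_rate_table()]; default the
#'   bundled [nav_rate_table()].
#' @param os_set Which O6-S13 parameter set to install: `"set1"`
#'   (default), `"set2"`, or `"custom"` (then supply `os_rates`).
#' @param os_rates For `os_set = "custom"`: a list with `rate_constant`s
#'   `os` (O6 -> S13) and `so` (S13 -> O6).
#' @return An object of class `nav_model`: a list with the
#'   [kinetic_scheme()], the `variant` (`"lti"` or `"non_lti"`) and, for
#'   the LTI variant, the installed `os_rates`.
#' @export
make_lti_model <- function(rate_table = nav_rate_table(),
                           os_set = c("set1", "set2", "custom"),
                           os_rates = NULL) {
  os_set <- match.arg(os_set)
  states <- nav_state_names(lti = TRUE)
  missing <- setdiff(states, unique(c(rate_table$from, rate_table$to)))
  if (length(missing) > 0) {
    stop("LTI model requires all 13 states; missing: ",
         paste(missing, collapse = ", "))
  }
  if (os_set == "custom") {
    if (is.null(os_rates) || !all(c("os", "so") %in% names(os_rates))) {
      stop("`os_set = \"custom\"` needs `os_rates = list(os = , so = )`")
    }
  } else {
    os_rates <- os_param_set(os_set)
  }
  tab <- rate_table
  tab <- tab[!(tab$from == "O6" & tab$to == "S13") &
             !(tab$from == "S13" & tab$to == "O6"), ]
  tab <- rbind(tab,
               data.frame(from = c("O6", "S13"), to = c("S13", "O6"),
                          k0 = c(os_rates$os$k0, os_rates$so$k0),
                          k1 = c(os_rates$os$k1, os_rates$so$k1)))
  scheme <- kinetic_scheme(states, conducting = states == "O6",
                           transitions = tab)
  structure(list(scheme = scheme, variant = "lti", os_rates = os_rates),
            class = "nav_model")
}

#' @rdname make_lti_model
#' @export
make_non_lti_model <- function(rate_table = nav_rate_table()) {
  states <- nav_state_names(lti = FALSE)
  tab <- rate_table[rate_table$from != "S13" & rate_table$to != "S13", ]
  missing <- setdiff(states, unique(c(tab$from, tab$to)))
  if (length(missing) > 0) {
    stop("rate table is missing state(s): ", paste(missing, collapse = ", "))
  }
  scheme <- kinetic_scheme(states, conducting = states == "O6",
                           transitions = tab)
  structure(list(scheme = scheme, variant = "non_lti", os_rates = NULL),
            class = "nav_model")
}

#' @export
print.nav_model <- function(x, ...) {
  cat(sprintf("<nav model> %s variant, %d states\n",
              x$variant, n_states(x$scheme)))
  invisible(x)
}

#' State groups of a Nav model
#'
#' @param model A [nav_model()].
#' @return A list of state-label vectors: `C` (closed), `O` (open), `I`
#'   (normal inactivated), `S` (long-term inactivated; empty for the
#'   non-LTI variant).
#' @export
nav_state_groups <- function(model) {
  s <- model$scheme$states
  list(C = grep("^C", s, value = TRUE),
       O = grep("^O", s, value = TRUE),
       I = grep("^I", s, value = TRUE),
       S = grep("^S", s, value = TRUE))
}

#' Occupancy summaries of a Nav trajectory
#'
#' Convenience accessors for the four summed occupancies tracked
#' throughout: available (closed plus open), open, normal-inactivated and
#' long-term-inactivated probability.
#'
#' @param traj An `occupancy_trajectory` from [run_protocol()] run on a
#'   [nav_model()].
#' @return Numeric vector per sample.
#' @export
p_available <- function(traj) {
  occupancy_of(traj, grep("^[CO]", traj$states, value = TRUE))
}

#' @rdname p_available
#' @export
p_inactivated <- function(traj) {
  occupancy_of(traj, grep("^I", traj$states, value = TRUE))
}

#' @rdname p_available
#' @export
p_lti <- function(traj) {
  s <- grep("^S", traj$states, value = TRUE)
  if (length(s) == 0) return(rep(0, length(traj$times)))
  occupancy_of(traj, s)
}

#' Emergent leak properties of an LTI Nav model
#'
#' Quantifies the model's leaky-integrator parameters with the same
#' protocol used experimentally: from the rested state at `V_rest`, a
#' single brief pulse to `V_pulse` measures the per-pulse LTI share
#' (`lti_fraction`, the S-state occupancy at `split_at_ms` into the
#' pulse), the subsequent S-state decay back at `V_rest` is fitted with a
#' single exponential on its tail (`tau_leak`), and the stationary S
#' occupancy at `V_pulse` gives the equilibrium under sustained
#' depolarisation (`ps_inf`).
#'
#' @param model An LTI [nav_model()].
#' @param V_rest Holding potential, mV (default -80).
#' @param V_pulse Pulse potential, mV (default 0).
#' @param pulse_ms Pulse duration, ms (default 5).
#' @param split_at_ms Time into the pulse at which the LTI share is read
#'   (default, end of pulse).
#' @param hold_ms Post-pulse observation window for the tail fit, ms.
#' @param fit_start_ms Tail-fit start, ms after the pulse; the default
#'   (50 ms) is beyond ten times the fast recovery time constant, so the
#'   fast component has fully decayed.
#' @return An object of class `leak_properties`: a list with `tau_leak`
#'   (ms), `lti_fraction`, and `ps_inf`.
#' @export
derive_leak_properties <- function(model, V_rest = -80, V_pulse = 0,
                                   pulse_ms = 5, split_at_ms = pulse_ms,
                                   hold_ms = 3000, fit_start_ms = 50) {
  stopifnot(inherits(model, "nav_model"))
  if (model$variant != "lti") {
    stop("leak properties are defined for the LTI variant only")
  }
  P_rest <- stationary_distribution(build_generator(model$scheme, V_rest))
  pulse <- run_protocol(model, voltage_protocol(pulse_ms, V_pulse),
                        P0 = P_rest, dt_out = 0.01)
  ps_pulse <- p_lti(pulse)
  i_split <- which.min(abs(pulse$times - split_at_ms))
  lti_fraction <- ps_pulse[i_split]

  P_end <- pulse$P[nrow(pulse$P), ]
  tail_traj <- run_protocol(model, voltage_protocol(hold_ms, V_rest),
                            P0 = P_end, dt_out = 1)
  ps <- p_lti(tail_traj)
  ps_rest <- stationary_distribution(
    build_generator(model$scheme, V_rest))[["S13"]]
  keep <- tail_traj$times >= fit_start_ms & (ps - ps_rest) > 0
  y <- log(ps[keep] - ps_rest)
  t <- tail_traj$times[keep]
  fit <- stats::lm(y ~ t)
  tau_leak <- -1 / stats::coef(fit)[["t"]]

  ps_inf <- stationary_distribution(
    build_generator(model$scheme, V_pulse))[["S13"]]
  structure(list(tau_leak = tau_leak, lti_fraction = lti_fraction,
                 ps_inf = ps_inf),
            class = "leak_properties")
}

#' @export
print.leak_properties <- function(x, ...) {
  cat(sprintf(paste0("<leak properties> tau_leak = %.1f ms, ",
                     "per-pulse LTI share = %.3f, Ps_inf = %.3f\n"),
              x$tau_leak, x$lti_fraction, x$ps_inf))
  invisible(x)
}
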