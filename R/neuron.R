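#' Surrogate pacemaker host neuron
#'
#' A minimal conductance-based host cell for in-silico dynamic clamp. It
#' is an invented stand-in for the live neurons used in the original
#' conductance-injection experiments: a single compartment with a passive
#' leak whose reversal sits depolarised (producing the slow interspike
#' ramp characteristic of serotonergic pacemakers), a delayed-rectifier
#' potassium conductance with deliberately slow activation (producing
#' broad spikes), an optional slow adaptation conductance (off by
#' default), and a constant bias current. The sodium current is supplied
#' entirely by the injected Nav gating model. The default parameters are
#' a one-time calibration to the documented phenotype - repetitive firing
#' at a few Hz with broad action potentials when driven by the non-LTI
#' model at 10 nS/pF - and are then treated as frozen.
#'
#' @param cm Membrane capacitance, pF.
#' @param g_leak,e_leak Leak conductance (nS) and reversal (mV).
#' @param g_k,e_k Delayed-rectifier maximal conductance (nS) and reversal
#'   (mV).
#' @param n_vhalf,n_slope,tau_n,n_pow Potassium activation: half-activation
#'   voltage (mV), slope (mV), time constant (ms) and gate exponent.
#' @param tau_n_slow,tau_n_vhalf,tau_n_kslope Voltage dependence of the
#'   potassium time constant: it relaxes from `tau_n` at spike voltages to
#'   `tau_n_slow` below `tau_n_vhalf` (slow deactivation paces the
#'   interspike release; `tau_n_slow = tau_n` disables the voltage
#'   dependence).
#' @param g_adapt,e_adapt,z_vhalf,z_slope,tau_z Optional slow adaptation
#'   conductance (nS; 0 disables it) with its reversal and kinetics.
#' @param g_shoulder,e_shoulder,s_vhalf,s_slope,tau_s Spike-shoulder
#'   conductance (nS; 0 disables it): a fast depolarising conductance that
#'   activates during the spike and broadens it, the stand-in for the
#'   calcium shoulder of the modelled pacemakers.
#' @param i_bias Constant bias current, pA.
#' @param e_na Sodium reversal used for the injected current, mV.
#' @return An object of class `host_neuron`.
#' @export
host_neuron <- function(cm = 20,
                        g_leak = 0.4, e_leak = -50,
                        g_k = 160, e_k = -90,
                        n_vhalf = -30, n_slope = 4,
                        tau_n = 6, n_pow = 2,
                        tau_n_slow = tau_n, tau_n_vhalf = -35,
                        tau_n_kslope = 5,
                        g_adapt = 5, e_adapt = -90,
                        z_vhalf = -20, z_slope = 5, tau_z = 300,
                        g_shoulder = 80, e_shoulder = 30,
                        s_vhalf = -30, s_slope = 2.5, tau_s = 2.5,
                        i_bias = 0, e_na = 60) {
  stopifnot(cm > 0, g_leak >= 0, g_k >= 0, tau_n > 0, tau_z > 0,
            g_shoulder >= 0, tau_s > 0)
  structure(list(cm = cm, g_leak = g_leak, e_leak = e_leak,
                 g_k = g_k, e_k = e_k, n_vhalf = n_vhalf,
                 n_slope = n_slope, tau_n = tau_n, n_pow = n_pow,
                 tau_n_slow = tau_n_slow, tau_n_vhalf = tau_n_vhalf,
                 tau_n_kslope = tau_n_kslope,
                 g_adapt = g_adapt, e_adapt = e_adapt, z_vhalf = z_vhalf,
                 z_slope = z_slope, tau_z = tau_z,
                 g_shoulder = g_shoulder, e_shoulder = e_shoulder,
                 s_vhalf = s_vhalf, s_slope = s_slope, tau_s = tau_s,
                 i_bias = i_bias, e_na = e_na),
            class = "host_neuron")
}

#' Precompute per-step transition matrices on a voltage grid
#'
#' The hybrid loop advances the channel occupancies with the matrix
#' method: at each time step the occupancy vector is multiplied by
#' `expm(Q(V) * dt)`. These matrices are precomputed on a regular voltage
#' grid and linearly interpolated at run time (the interpolation of two
#' row-stochastic matrices is row-stochastic, so conservation is exact).
#'
#' @param model A [nav_model()] or [kinetic_scheme()].
#' @param dt Time step, ms.
#' @param v_range Grid limits, mV; a membrane potential leaving this
#'   range during a hybrid run is treated as numerical divergence.
#' @param dv Grid spacing, mV.
#' @return An object of class `transition_grid`.
#' @export
transition_grid <- function(model, dt, v_range = c(-120, 60), dv = 0.5) {
  scheme <- as_scheme(model)
  vs <- seq(v_range[1], v_range[2], by = dv)
  k <- n_states(scheme)
  tm <- array(0, dim = c(k, k, length(vs)))
  for (i in seq_along(vs)) {
    tm[, , i] <- transition_matrix(build_generator(scheme, vs[i]), dt)
  }
  structure(list(v0 = v_range[1], dv = dv, dt = dt, tm = tm,
                 states = scheme$states,
                 open = which(scheme$conducting) - 1L,
                 slow = which(grepl("^S", scheme$states)) - 1L),
            class = "transition_grid")
}

#' Stepped current-injection protocol
#'
#' @param durations Step durations, ms.
#' @param pA Injected current per step, pA.
#' @return A `data.frame` with `duration` and `pA`.
#' @export
current_steps <- function(durations, pA) {
  stopifnot(length(durations) == length(pA), all(durations > 0))
  if (any(pA > 40)) {
    warning("injected bias currents above 40 pA risk depolarisation ",
            "block; shipped protocols stay at or below 40 pA")
  }
  data.frame(duration = durations, pA = pA)
}

expand_steps <- function(steps, dt, n_steps) {
  if (is.null(steps)) return(numeric(0))
  if (is.numeric(steps) && length(steps) == 1L) return(as.numeric(steps))
  counts <- round(steps$duration / dt)
  out <- rep(steps[[2]], counts)
  length(out) <- n_steps
  out[is.na(out)] <- steps[[2]][nrow(steps)]
  out
}

#' In-silico dynamic-clamp simulation
#'
#' Runs the closed loop of the dynamic-clamp experiments entirely in
#' silico: at every time step (default 0.02 ms, the 50 kHz real-time
#' loop rate) the Nav occupancies are advanced with the matrix method at
#' the present membrane potential, the sodium current
#' `I_Na = G_Na * C_m * P_O * (V - E_Na)` of the active model is
#' computed, and the host membrane equation is advanced one Euler step.
#' A second Nav model may be integrated in parallel, with an injection
#' schedule selecting which model's current drives the cell (the
#' model-swap protocol).
#'
#' @param host A [host_neuron()].
#' @param nav A [nav_model()] (always integrated; injects unless the
#'   schedule selects model 2).
#' @param g_na_density Injected conductance density, nS/pF.
#' @param duration Simulated time, ms.
#' @param i_inj Constant bias current (pA) or a [current_steps()]
#'   staircase.
#' @param nav2 Optional second [nav_model()].
#' @param inject_schedule Optional `data.frame(duration, model)` with
#'   `model` 1 or 2; default model 1 throughout.
#' @param dt Loop time step, ms.
#' @param v_init Initial membrane potential, mV; occupancies start at the
#'   stationary distribution for `v_init` (a long rest at that holding
#'   level).
#' @param out_every Record every `out_every`-th step.
#' @param grid,grid2 Optional precomputed [transition_grid()]s (rebuilt
#'   when absent or when `dt` differs).
#' @return An object of class `hybrid_sim`: sampled `times`, `V`,
#'   `I_Na`, `n_gate`, open and S-state occupancies per model
#'   (`po1`, `ps1`, `po2`, `ps2`), `spikes` (detected with the default
#'   threshold), and bookkeeping fields. Numerical divergence (V leaving
#'   the grid range) is an error reporting the failure time.
#' @export
simulate_hybrid <- function(host, nav, g_na_density = 10,
                            duration = 10000, i_inj = 0,
                            nav2 = NULL, inject_schedule = NULL,
                            dt = 0.02, v_init = -65, out_every = 25,
                            grid = NULL, grid2 = NULL) {
  stopifnot(inherits(host, "host_neuron"), inherits(nav, "nav_model"),
            g_na_density > 0, duration > 0, dt > 0)
  if (is.null(grid) || grid$dt != dt) grid <- transition_grid(nav, dt)
  has2 <- !is.null(nav2)
  if (has2 && (is.null(grid2) || grid2$dt != dt)) {
    grid2 <- transition_grid(nav2, dt)
  }
  n_steps <- round(duration / dt)

  P1 <- stationary_distribution(build_generator(as_scheme(nav), v_init))
  P2 <- if (has2) {
    stationary_distribution(build_generator(as_scheme(nav2), v_init))
  } else 0

  iinj_vec <- expand_steps(i_inj, dt, n_steps)
  inj <- if (is.null(inject_schedule)) {
    1L
  } else {
    as.integer(expand_steps(inject_schedule, dt, n_steps))
  }

  ninf0 <- 1 / (1 + exp(-(v_init - host$n_vhalf) / host$n_slope))
  zinf0 <- 1 / (1 + exp(-(v_init - host$z_vhalf) / host$z_slope))

  res <- cpp_hybrid(grid$tm,
                    if (has2) grid2$tm else array(0, c(1, 1, 2)),
                    has2,
                    P1, if (has2) P2 else numeric(1),
                    grid$open, if (has2) grid2$open else integer(0),
                    grid$slow, if (has2) grid2$slow else integer(0),
                    grid$v0, grid$dv, dt, n_steps, unclass(host),
                    iinj_vec, inj,
                    g_na_density * host$cm,
                    v_init, ninf0, zinf0, as.integer(out_every))
  if (res$status != 0) {
    stop(sprintf("hybrid simulation diverged at t = %.2f ms (V left [%g, %g] mV)",
                 res$t_fail, grid$v0, grid$v0 + grid$dv * (dim(grid$tm)[3] - 1)))
  }
  if (res$conservation_err > 1e-8) {
    stop(sprintf("occupancy conservation violated in hybrid loop (%.2e)",
                 res$conservation_err))
  }
  spikes <- detect_spikes(res$times, res$V)
  structure(list(times = res$times, V = res$V, I_Na = res$I_Na,
                 n_gate = res$n_gate,
                 po1 = res$Po1, ps1 = res$Ps1,
                 po2 = res$Po2, ps2 = res$Ps2,
                 spikes = spikes,
                 conservation_err = res$conservation_err,
                 dt = dt, duration = duration,
                 g_na_density = g_na_density),
            class = "hybrid_sim")
}

#' @export
print.hybrid_sim <- function(x, ...) {
  cat(sprintf("<hybrid simulation> %g ms, %d spikes, V in [%.1f, %.1f] mV\n",
              x$duration, length(x$spikes), min(x$V), max(x$V)))
  invisible(x)
}

#' Detect action potentials in a voltage trace
#'
#' Upward threshold crossings, refractory-filtered: crossings closer than
#' `min_isi` to the previous accepted spike are discarded, and each spike
#' time is the local voltage maximum between the crossing and the return
#' below threshold.
#'
#' @param times Sample times, ms.
#' @param V Membrane potential samples, mV.
#' @param threshold Detection threshold, mV.
#' @param min_isi Refractory interval, ms.
#' @return Numeric vector of spike times (ms), strictly increasing.
#' @export
detect_spikes <- function(times, V, threshold = -20, min_isi = 5) {
  stopifnot(length(times) == length(V))
  n <- length(V)
  if (n < 2) return(numeric(0))
  above <- V >= threshold
  ups <- which(!above[-n] & above[-1]) + 1L
  if (length(ups) == 0) return(numeric(0))
  downs <- which(above[-n] & !above[-1])
  spikes <- numeric(0)
  for (u in ups) {
    d <- downs[downs >= u]
    end <- if (length(d)) d[1] else n
    seg <- u:end
    t_spike <- times[seg][which.max(V[seg])]
    if (length(spikes) == 0 || t_spike - spikes[length(spikes)] >= min_isi) {
      spikes <- c(spikes, t_spike)
    }
  }
  spikes
}

#' Instantaneous spiking frequency
#'
#' One value per interspike interval, `f = 1000 / ISI` (Hz), timestamped
#' at the later spike.
#'
#' @param spikes Spike times, ms.
#' @return A `data.frame` with `time_ms` and `freq_hz` (empty for fewer
#'   than two spikes).
#' @export
instantaneous_frequency <- function(spikes) {
  if (length(spikes) < 2) {
    return(data.frame(time_ms = numeric(0), freq_hz = numeric(0)))
  }
  data.frame(time_ms = spikes[-1], freq_hz = 1000 / diff(spikes))
}

#' Quasi-steady spiking frequency over a step window
#'
#' Mean instantaneous frequency over the second half of the window (the
#' convention used for stationary frequency-versus-input curves).
#'
#' @param spikes Spike times, ms.
#' @param window Two-element window `c(t0, t1)`, ms.
#' @return Frequency in Hz (0 when fewer than two spikes fall in the
#'   second half).
#' @export
steady_frequency <- function(spikes, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  half <- c(mean(window), window[2])
  inst <- instantaneous_frequency(spikes)
  keep <- inst$time_ms >= half[1] & inst$time_ms <= half[2] &
    (inst$time_ms - 1000 / inst$freq_hz) >= window[1]
  if (sum(keep) < 1) return(0)
  mean(inst$freq_hz[keep])
}

#' Spike width of the average action potential
#'
#' Mean width of detected spikes, measured as the time the membrane
#' potential stays above `level` around each spike.
#'
#' @param sim A `hybrid_sim`.
#' @param level Measurement level, mV.
#' @return Mean width in ms (`NA` without spikes).
#' @export
spike_width <- function(sim, level = -25) {
  if (length(sim$spikes) == 0) return(NA_real_)
  widths <- vapply(sim$spikes, function(ts) {
    i <- which.min(abs(sim$times - ts))
    lo <- i
    while (lo > 1 && sim$V[lo - 1] > level) lo <- lo - 1
    hi <- i
    while (hi < length(sim$V) && sim$V[hi + 1] > level) hi <- hi + 1
    sim$times[hi] - sim$times[lo]
  }, numeric(1))
  mean(widths)
}

#' Spiking frequency versus injected Nav conductance
#'
#' For each conductance density and each Nav model variant, runs a free-
#' running hybrid simulation and reports the quasi-steady frequency
#' (second half of the run), together with a least-squares line per
#' variant.
#'
#' @param host A [host_neuron()].
#' @param navs Named list of [nav_model()]s (e.g.
#'   `list(lti = , non_lti = )`).
#' @param gna_list Conductance densities, nS/pF.
#' @param duration Simulated time per run, ms.
#' @param dt Loop step, ms.
#' @return A list with `curve` (`data.frame`: `variant`, `g_na`,
#'   `freq_hz`) and `fits` (per-variant named vector with `slope`,
#'   `intercept`).
#' @export
frequency_vs_gna <- function(host, navs, gna_list = seq(5, 20, by = 2.5),
                             duration = 10000, dt = 0.02) {
  stopifnot(is.list(navs), length(navs) >= 1, !is.null(names(navs)))
  rows <- list()
  for (nm in names(navs)) {
    grid <- transition_grid(navs[[nm]], dt)
    for (g in gna_list) {
      sim <- simulate_hybrid(host, navs[[nm]], g_na_density = g,
                             duration = duration, dt = dt, grid = grid)
      rows[[length(rows) + 1L]] <-
        data.frame(variant = nm, g_na = g,
                   freq_hz = steady_frequency(sim$spikes,
                                              c(0, duration)))
    }
  }
  curve <- do.call(rbind, rows)
  fits <- lapply(split(curve, curve$variant), function(df) {
    cf <- stats::coef(stats::lm(freq_hz ~ g_na, data = df))
    c(slope = unname(cf[["g_na"]]), intercept = unname(cf[["(Intercept)"]]))
  })
  list(curve = curve, fits = fits)
}

#' Spiking frequency versus depolarising bias current
#'
#' Reproduces the structure of the bias-current experiments: for each
#' current step and model variant the cell is rested at -65 mV (the
#' occupancies equilibrated at the rest potential), then depolarised for
#' `step_ms`; the quasi-steady frequency is the mean instantaneous
#' frequency over the second half of the step, the initial frequency the
#' mean over the first quarter, and the adaptation depth their relative
#' difference. With `mode = "alternate"` a single continuous staircase is
#' run per ordering instead, with both models integrated throughout and
#' the injected current switched between them halfway through each step.
#'
#' @param host A [host_neuron()].
#' @param navs Named list of exactly two [nav_model()]s for
#'   `"alternate"` mode, one or more for `"rest"` mode.
#' @param iinj_steps Bias currents, pA (at most 40 pA in shipped
#'   protocols).
#' @param g_na_density Conductance density, nS/pF.
#' @param mode `"rest"` (each step from a rested cell) or
#'   `"alternate"` (model swap within each step).
#' @param step_ms Step duration, ms.
#' @param dt Loop step, ms.
#' @return A `data.frame` with `variant`, `i_inj`, `freq_initial`,
#'   `freq_steady` and `adapt_depth` (for `"alternate"` mode, the
#'   steady frequency of each model's injection half-step).
#' @export
frequency_vs_iinj <- function(host, navs, iinj_steps = c(0, 10, 20, 30, 40),
                              g_na_density = 10,
                              mode = c("rest", "alternate"),
                              step_ms = 10000, dt = 0.02) {
  mode <- match.arg(mode)
  if (any(iinj_steps > 40)) {
    warning("bias currents above 40 pA risk depolarisation block")
  }
  if (mode == "rest") {
    rows <- list()
    for (nm in names(navs)) {
      grid <- transition_grid(navs[[nm]], dt)
      for (ii in iinj_steps) {
        sim <- simulate_hybrid(host, navs[[nm]],
                               g_na_density = g_na_density,
                               duration = step_ms, i_inj = ii,
                               dt = dt, grid = grid)
        f_init <- {
          inst <- instantaneous_frequency(sim$spikes)
          keep <- inst$time_ms <= step_ms / 4
          if (sum(keep) < 1) 0 else mean(inst$freq_hz[keep])
        }
        f_steady <- steady_frequency(sim$spikes, c(0, step_ms))
        rows[[length(rows) + 1L]] <-
          data.frame(variant = nm, i_inj = ii,
                     freq_initial = f_init, freq_steady = f_steady,
                     adapt_depth = if (f_init > 0) {
                       (f_init - f_steady) / f_init
                     } else NA_real_)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }

  # alternate mode: both models integrated, injection swapped mid-step
  stopifnot(length(navs) == 2)
  nms <- names(navs)
  grid1 <- transition_grid(navs[[1]], dt)
  grid2 <- transition_grid(navs[[2]], dt)
  half <- step_ms / 2
  n_step <- length(iinj_steps)
  i_prot <- current_steps(rep(step_ms, n_step), iinj_steps)
  sched <- data.frame(duration = rep(half, 2 * n_step),
                      model = rep(c(1L, 2L), n_step))
  sim <- simulate_hybrid(host, navs[[1]], g_na_density = g_na_density,
                         duration = step_ms * n_step, i_inj = i_prot,
                         nav2 = navs[[2]], inject_schedule = sched,
                         dt = dt, grid = grid1, grid2 = grid2)
  rows <- list()
  for (s in seq_len(n_step)) {
    t0 <- (s - 1) * step_ms
    for (m in 1:2) {
      w0 <- t0 + (m - 1) * half
      rows[[length(rows) + 1L]] <-
        data.frame(variant = nms[m], i_inj = iinj_steps[s],
                   freq_initial = NA_real_,
                   freq_steady = steady_frequency(sim$spikes,
                                                  c(w0, w0 + half)),
                   adapt_depth = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sim") <- sim
  out
}
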