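#' Per-pulse peak currents and availability of a pulse-train trace
#'
#' Extracts the peak current inside each depolarising pulse window of a
#' train and normalises to the first pulse. The peak is the extremum of
#' `|I|` strictly within the pulse window; availability is
#' `I_peak(p) / I_peak(1)`.
#'
#' @param trace A [simulate_current()] trace (or a synthetic one from
#'   [synth_pulse_train_trace()]).
#' @param protocol The [pulse_train_protocol()] the trace was recorded
#'   under.
#' @return A `data.frame` of class `peak_series` with columns
#'   `pulse_index`, `t_peak`, `peak_I` (signed, pA) and `availability`.
#' @export
peaks_from_train <- function(trace, protocol) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  v_pulse <- attr(protocol, "v_pulse")
  if (is.null(v_pulse)) v_pulse <- max(protocol$level)
  is_pulse <- protocol$level == v_pulse
  if (sum(is_pulse) < 1 || nrow(protocol) < 2) {
    stop("protocol is not a pulse train")
  }
  ends <- cumsum(protocol$duration)
  starts <- c(0, ends[-length(ends)])
  windows <- which(is_pulse)
  out <- lapply(seq_along(windows), function(i) {
    s <- windows[i]
    in_win <- trace$times >= starts[s] & trace$times <= ends[s]
    if (!any(in_win)) stop("no samples inside pulse window ", i)
    I_win <- trace$I[in_win]
    t_win <- trace$times[in_win]
    j <- which.max(abs(I_win))
    data.frame(pulse_index = i, t_peak = t_win[j], peak_I = I_win[j])
  })
  out <- do.call(rbind, out)
  if (abs(out$peak_I[1]) < .Machine$double.eps) {
    stop("first-pulse peak is zero; cannot normalise availability")
  }
  out$availability <- out$peak_I / out$peak_I[1]
  class(out) <- c("peak_series", "data.frame")
  out
}

#' LTI-state occupancy estimated from peak availability
#'
#' Applies the availability identity `P_S = 1 - I_peak(p) / I_peak(1)`:
#' when the inter-pulse interval is long enough for complete recovery from
#' normal (fast) inactivation, the missing fraction of peak current equals
#' the fraction of channels still trapped in the long-term inactivated
#' state. Estimates are clipped to `[0, 1]` (noise can push availability
#' slightly above 1).
#'
#' @param peaks A `peak_series` from [peaks_from_train()].
#' @return A `data.frame` of class `ps_trace` with columns `pulse_index`
#'   and `ps`.
#' @export
ps_from_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "peak_series"))
  ps <- pmin(pmax(1 - peaks$availability, 0), 1)
  structure(data.frame(pulse_index = peaks$pulse_index, ps = ps),
            class = c("ps_trace", "data.frame"))
}

#' Bi-exponential recovery curve
#'
#' Fractional availability after a recovery interval `t`:
#' `A(t) = a_fast (1 - exp(-t / tau_fast)) + a_slow (1 - exp(-t / tau_slow))`.
#'
#' @param t Recovery delay(s), ms.
#' @param a_fast,tau_fast Fast-component amplitude and time constant (ms).
#' @param a_slow,tau_slow Slow-component amplitude and time constant (ms).
#' @return Availability value(s).
#' @export
biexp_availability <- function(t, a_fast, tau_fast, a_slow, tau_slow) {
  a_fast * (1 - exp(-t / tau_fast)) + a_slow * (1 - exp(-t / tau_slow))
}

#' Fit a bi-exponential recovery-from-inactivation curve
#'
#' Least-squares fit of the two-component recovery model to availability
#' versus delay. Starting values come from a two-segment split of the
#' delays at their geometric mean plus a small multi-start grid, and the
#' best converged fit (lowest residual sum of squares) is kept. Components
#' are ordered so that `tau_fast < tau_slow` after fitting.
#'
#' @param delays Recovery delays, ms (at least 6, spanning both time
#'   scales).
#' @param availability Fractional availability at each delay.
#' @param init Optional list with starting values `a_fast`, `tau_fast`,
#'   `a_slow`, `tau_slow`.
#' @return An object of class `biexp_fit`: `a_fast`, `tau_fast`,
#'   `a_slow`, `tau_slow`, `rss`, `se` (standard errors from the fit
#'   covariance, where available) and `flags` (character vector:
#'   `"mono"` when the slow amplitude is negligible, `"degenerate_tau"`
#'   when the time-constant ratio is below 3, so the component split is
#'   unreliable).
#' @export
fit_biexp_recovery <- function(delays, availability, init = NULL) {
  stopifnot(length(delays) == length(availability))
  if (length(delays) < 6) {
    stop("need at least 6 delay points spanning both time scales")
  }
  o <- order(delays)
  d <- as.numeric(delays)[o]
  a <- as.numeric(availability)[o]
  if (any(d <= 0)) stop("delays must be positive")

  starts <- list()
  if (!is.null(init)) {
    starts[[length(starts) + 1L]] <-
      c(af = init$a_fast, tf = init$tau_fast,
        as = init$a_slow, ts = init$tau_slow)
  }
  # two-segment heuristic: split at the geometric mean delay
  g <- exp(mean(log(d)))
  af0 <- max(min(stats::approx(d, a, xout = g, rule = 2)$y, 0.98), 0.05)
  as0 <- max(max(a) - af0, 0.02)
  early <- d[d <= g]
  tf0 <- if (length(early) > 1) stats::median(early) / 2 else g / 10
  ts0 <- max(d) / 3
  starts[[length(starts) + 1L]] <- c(af = af0, tf = tf0, as = as0, ts = ts0)
  for (tfg in c(tf0 / 3, tf0 * 3)) {
    for (tsg in c(ts0 / 3, ts0 * 3)) {
      starts[[length(starts) + 1L]] <- c(af = af0, tf = tfg, as = as0,
                                         ts = tsg)
    }
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        a ~ af * (1 - exp(-d / tf)) + as * (1 - exp(-d / ts)),
        start = as.list(st),
        lower = c(af = 0, tf = 1e-4, as = 0, ts = 1e-4),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    # effectively mono-exponential data: the slow component collapses and
    # the two-component Jacobian becomes singular; fall back to one
    # component and flag the result
    mono <- tryCatch(
      minpack.lm::nlsLM(a ~ af * (1 - exp(-d / tf)),
                        start = list(af = max(a), tf = tf0),
                        lower = c(af = 0, tf = 1e-4),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(mono)) {
      stop("bi-exponential fit failed to converge from all starting points")
    }
    cfm <- stats::coef(mono)
    sem <- tryCatch(sqrt(diag(stats::vcov(mono))),
                    error = function(e) rep(NA_real_, 2))
    return(structure(
      list(a_fast = cfm[["af"]], tau_fast = cfm[["tf"]],
           a_slow = 0, tau_slow = NA_real_,
           rss = sum(stats::residuals(mono)^2),
           se = c(a_fast = sem[[1]], tau_fast = sem[[2]],
                  a_slow = NA_real_, tau_slow = NA_real_),
           flags = c("mono", "degenerate_tau"), fit = mono),
      class = "biexp_fit"))
  }
  cf <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))),
                 error = function(e) rep(NA_real_, 4))
  names(se) <- names(cf)
  # order components: fast first
  if (cf[["tf"]] > cf[["ts"]]) {
    cf <- cf[c("as", "ts", "af", "tf")]
    se <- se[c("as", "ts", "af", "tf")]
    names(cf) <- names(se) <- c("af", "tf", "as", "ts")
  }
  flags <- character(0)
  if (cf[["as"]] < 0.01) flags <- c(flags, "mono")
  if (cf[["ts"]] / cf[["tf"]] < 3) flags <- c(flags, "degenerate_tau")
  structure(
    list(a_fast = cf[["af"]], tau_fast = cf[["tf"]],
         a_slow = cf[["as"]], tau_slow = cf[["ts"]],
         rss = best$rss,
         se = c(a_fast = se[["af"]], tau_fast = se[["tf"]],
                a_slow = se[["as"]], tau_slow = se[["ts"]]),
         flags = flags, fit = best$fit),
    class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(paste0("<bi-exponential fit> a_fast = %.3f, tau_fast = %.3g ms, ",
                     "a_slow = %.3f, tau_slow = %.4g ms (rss %.3g)%s\n"),
              x$a_fast, x$tau_fast, x$a_slow, x$tau_slow, x$rss,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "),
                                          "]") else ""))
  invisible(x)
}

#' Simulated two-pulse recovery availability
#'
#' Runs the two-pulse recovery protocol on a Nav model for each delay and
#' returns the test-pulse peak current normalised to the conditioning
#' pulse peak.
#'
#' @param model A [nav_model()].
#' @param delays Recovery delays, ms.
#' @param V_hold,V_pulse,pulse_ms Protocol parameters (mV, mV, ms).
#' @param settings A [current_sim_settings()].
#' @param dt_fine Sampling inside pulses, ms.
#' @return A `data.frame` with `delay_ms` and `availability`.
#' @export
recovery_availability <- function(model, delays, V_hold = -80,
                                  V_pulse = -15, pulse_ms = 5,
                                  settings = current_sim_settings(g_na = 100),
                                  dt_fine = 0.01) {
  protocols <- recovery_protocol(V_hold, V_pulse, pulse_ms, delays)
  P0 <- stationary_distribution(build_generator(as_scheme(model), V_hold))
  out <- lapply(protocols, function(p) {
    delay <- attr(p, "delay_ms")
    dt_out <- c(dt_fine, min(1, delay / 10), dt_fine)
    trace <- simulate_current(model, p, settings, dt_out = dt_out, P0 = P0)
    peaks <- peaks_from_train(trace, p)
    data.frame(delay_ms = delay,
               availability = peaks$availability[2])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Steady-state S occupancy versus pulse frequency
#'
#' Drives the model with a pulse train at each frequency until the
#' S-state occupancy reaches a steady oscillation, then reports the
#' within-cycle minimum (end of the inter-pulse interval), maximum (end
#' of the pulse) and time-average. The cycle map is iterated with exact
#' per-segment matrix exponentials, extending the run until the
#' cycle-to-cycle drift of the maximum falls below `drift_tol`;
#' failure to reach drift below 1e-4 within the allowed extensions is an
#' error. A frequency of 0 means holding at `V_hold`; a pulse equal to
#' the full period is the constant-depolarisation limit, where min, max
#' and mean all equal the stationary S occupancy at `V_pulse`.
#'
#' @param model An LTI [nav_model()] (the non-LTI variant returns zeros).
#' @param freqs Pulse repetition rates, Hz.
#' @param pulse_ms Pulse duration, ms.
#' @param V_hold,V_pulse Holding and pulse potentials, mV.
#' @param duration Minimum simulated time per frequency, ms; should be at
#'   least ten leak time constants (default 6000 ms).
#' @param drift_tol Target cycle-to-cycle drift of the cycle maximum.
#' @param max_extend Maximum number of run extensions.
#' @return A `data.frame` with `freq_hz`, `ps_min`, `ps_max`, `ps_mean`
#'   and `n_cycles`.
#' @export
frequency_response <- function(model, freqs, pulse_ms = 5, V_hold = -80,
                               V_pulse = 0, duration = 6000,
                               drift_tol = 1e-7, max_extend = 10) {
  scheme <- as_scheme(model)
  s_states <- grep("^S", scheme$states, value = TRUE)
  Q_hold <- build_generator(scheme, V_hold)
  Q_pulse <- build_generator(scheme, V_pulse)
  P_rest <- stationary_distribution(Q_hold)
  ps_of <- function(P) if (length(s_states)) sum(P[s_states]) else 0

  one_freq <- function(f) {
    if (f <= 0) {
      ps0 <- ps_of(stationary_distribution(Q_hold))
      return(data.frame(freq_hz = f, ps_min = ps0, ps_max = ps0,
                        ps_mean = ps0, n_cycles = 0))
    }
    period <- 1000 / f
    if (pulse_ms >= period - 1e-9) {
      psc <- ps_of(stationary_distribution(Q_pulse))
      return(data.frame(freq_hz = f, ps_min = psc, ps_max = psc,
                        ps_mean = psc, n_cycles = 0))
    }
    gap <- period - pulse_ms
    Mp <- transition_matrix(Q_pulse, pulse_ms)
    Mg <- transition_matrix(Q_hold, gap)
    P <- P_rest
    n0 <- max(ceiling(duration / period), 10)
    ps_max_prev <- -Inf
    drift <- Inf
    total <- 0
    for (ext in 0:max_extend) {
      n_run <- if (ext == 0) n0 else max(ceiling(n0 / 2), 10)
      for (i in seq_len(n_run)) {
        P <- drop(P %*% Mp)
        ps_max <- ps_of(P)
        P <- drop(P %*% Mg)
      }
      total <- total + n_run
      # per-cycle drift of the cycle maximum, measured with one extra cycle
      P1 <- drop(drop(P %*% Mp) %*% Mg)
      drift <- abs(ps_of(drop(P1 %*% Mp)) - ps_of(drop(P %*% Mp)))
      ps_max_prev <- ps_max
      if (drift < drift_tol) break
    }
    if (drift > 1e-4) {
      stop(sprintf("steady oscillation not reached at %g Hz (drift %.2g)",
                   f, drift))
    }
    # within-cycle statistics over one steady cycle, finely sampled
    cyc <- run_protocol(scheme,
                        voltage_protocol(c(pulse_ms, gap),
                                         c(V_pulse, V_hold)),
                        P0 = P,
                        dt_out = c(min(0.05, pulse_ms / 20),
                                   min(0.5, gap / 20)))
    ps_t <- if (length(s_states) == 1) cyc$P[, s_states] else
      if (length(s_states)) rowSums(cyc$P[, s_states]) else
        rep(0, length(cyc$times))
    tt <- cyc$times
    ps_mean <- sum(diff(tt) * (utils::head(ps_t, -1) +
                               utils::tail(ps_t, -1)) / 2) / max(tt)
    data.frame(freq_hz = f, ps_min = min(ps_t), ps_max = max(ps_t),
               ps_mean = ps_mean, n_cycles = total)
  }
  out <- do.call(rbind, lapply(freqs, one_freq))
  rownames(out) <- NULL
  out
}
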