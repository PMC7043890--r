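#' Leaky-integrator parameters
#'
#' Parameters of the discrete-time leaky integrator used as the
#' mathematical reference for the S-state occupancy: the leak time
#' constant `tau_leak` (ms), the sampling interval `dt` (ms), the maximum
#' per-pulse output increment `y_inc` (the per-pulse LTI share of the
#' channel model, 0.2 by default), and the pulse duration `t_p` (ms) over
#' which that increment is spread.
#'
#' @param tau_leak Leak time constant, ms.
#' @param dt Sampling interval, ms.
#' @param y_inc Maximum per-pulse increment, in (0, 1].
#' @param t_p Pulse duration, ms (`dt <= t_p`).
#' @return An object of class `leaky_integrator_params`.
#' @export
leaky_integrator_params <- function(tau_leak = 435, dt = 0.05,
                                    y_inc = 0.2, t_p = 5) {
  stopifnot(tau_leak > 0, dt > 0, t_p > 0, y_inc > 0, y_inc <= 1)
  if (dt > t_p) {
    stop("`dt` must not exceed the pulse duration `t_p` ",
         "(the per-pulse increment is spread over the pulse)")
  }
  structure(list(tau_leak = tau_leak, dt = dt, y_inc = y_inc, t_p = t_p),
            class = "leaky_integrator_params")
}

#' Continuous-time leaky integrator
#'
#' Solves `dy/dt = x(t) - y(t) / tau_leak` exactly for a piecewise-
#' constant input: within each segment with constant input `x`,
#' `y(t) = x tau + (y0 - x tau) exp(-t / tau)`.
#'
#' @param times Segment end times, ms, strictly increasing, starting after
#'   0.
#' @param x Constant input value on each segment (same length as
#'   `times`).
#' @param tau_leak Leak time constant, ms.
#' @param y0 Initial output value.
#' @param dt_out Output sampling, ms.
#' @return A `data.frame` with `time_ms` and `y`.
#' @export
integrate_continuous <- function(times, x, tau_leak, y0 = 0,
                                 dt_out = 0.1) {
  stopifnot(length(times) == length(x), all(diff(c(0, times)) > 0),
            tau_leak > 0)
  t_grid <- seq(0, max(times), by = dt_out)
  seg <- findInterval(t_grid, c(0, times), rightmost.closed = TRUE,
                      left.open = TRUE)
  seg[t_grid == 0] <- 1
  starts <- c(0, times[-length(times)])
  y <- numeric(length(t_grid))
  y_seg0 <- y0
  for (s in seq_along(times)) {
    idx <- which(seg == s)
    fix <- x[s] * tau_leak
    if (length(idx)) {
      y[idx] <- fix + (y_seg0 - fix) * exp(-(t_grid[idx] - starts[s]) /
                                             tau_leak)
    }
    y_seg0 <- fix + (y_seg0 - fix) *
      exp(-(times[s] - starts[s]) / tau_leak)
  }
  data.frame(time_ms = t_grid, y = y)
}

#' Discrete-time leaky integrator
#'
#' The elementary recursion
#' `y[t + dt] = y[t] * exp(-dt / tau_leak) + x[t + dt] * dt`:
#' leak first, then add the incoming input sample scaled by the sampling
#' interval. With `tau_leak >> dt` this reduces to a running sum (an event
#' counter for digital inputs); with `tau_leak << dt` the output is a
#' scaled copy of the input.
#'
#' @param x Input samples (the first sample is the input arriving at the
#'   first step after `y0`).
#' @param dt Sampling interval, ms.
#' @param tau_leak Leak time constant, ms.
#' @param y0 Initial output.
#' @return Numeric vector `y` of the same length as `x`.
#' @export
integrate_discrete <- function(x, dt, tau_leak, y0 = 0) {
  stopifnot(dt > 0, tau_leak > 0)
  decay <- exp(-dt / tau_leak)
  y <- numeric(length(x))
  yt <- y0
  for (i in seq_along(x)) {
    yt <- yt * decay + x[i] * dt
    y[i] <- yt
  }
  y
}

#' Saturating leaky integrator for digital pulse inputs
#'
#' The modified recursion that mirrors the channel model's bounded
#' S-state occupancy:
#' `y[t + dt] = y[t] e + x[t + dt] * f[t + dt]` with
#' `f[t + dt] = y_inc * (dt / t_p) * (1 - y[t] e)` and
#' `e = exp(-dt / tau_leak)`. The input must be digital (0 during the
#' interspike interval, 1 during a pulse); during a pulse the output can
#' only grow by `y_inc` times its distance from 1, so `y` stays in
#' `[0, 1]` for every input sequence.
#'
#' @param x Digital input samples (0/1).
#' @param params A [leaky_integrator_params()].
#' @param y0 Initial output in `[0, 1]`.
#' @return Numeric vector `y` of the same length as `x`.
#' @export
integrate_saturating <- function(x, params, y0 = 0) {
  stopifnot(inherits(params, "leaky_integrator_params"),
            y0 >= 0, y0 <= 1)
  if (!all(x %in% c(0, 1))) {
    stop("the saturating integrator takes a digital (0/1) input")
  }
  decay <- exp(-params$dt / params$tau_leak)
  gain <- params$y_inc * params$dt / params$t_p
  y <- numeric(length(x))
  yt <- y0
  for (i in seq_along(x)) {
    leaked <- yt * decay
    yt <- leaked + x[i] * gain * (1 - leaked)
    y[i] <- yt
  }
  y
}

#' Digital pulse-train input signal
#'
#' @param freq Pulse rate, Hz (0 gives an all-zero input).
#' @param pulse_ms Pulse duration, ms.
#' @param duration Total signal duration, ms.
#' @param dt Sampling interval, ms.
#' @return A 0/1 vector sampled at `dt` (value at the END of each step).
#' @export
pulse_train_input <- function(freq, pulse_ms, duration, dt) {
  t <- seq(dt, duration, by = dt)
  if (freq <= 0) return(rep(0, length(t)))
  period <- 1000 / freq
  as.numeric((t - dt / 2) %% period < pulse_ms)
}

#' Compare the channel model's S occupancy with the saturating integrator
#'
#' Runs the saturating integrator on the same pulse trains as
#' [frequency_response()] and tabulates, per frequency, the steady-state
#' levels of both systems and their difference. The integrator is run to
#' steady state by simulating `n_settle` leak time constants before
#' measuring one full cycle.
#'
#' @param model_response Output of [frequency_response()].
#' @param params A [leaky_integrator_params()] (`t_p` must match the
#'   pulse duration of the model run).
#' @param pulse_ms Pulse duration of the train, ms.
#' @param n_settle Settling time, in multiples of `tau_leak`.
#' @return A `data.frame` with the model and integrator steady `min`,
#'   `max` and `mean` per frequency, the difference of the means, and an
#'   `rms` attribute with the overall root-mean-square deviation of the
#'   means.
#' @export
compare_ps_vs_integrator <- function(model_response, params,
                                     pulse_ms = 5, n_settle = 12) {
  stopifnot(inherits(params, "leaky_integrator_params"))
  rows <- lapply(seq_len(nrow(model_response)), function(i) {
    f <- model_response$freq_hz[i]
    dur <- n_settle * params$tau_leak
    x <- pulse_train_input(f, pulse_ms, dur, params$dt)
    y <- integrate_saturating(x, params)
    if (f > 0) {
      period <- 1000 / f
      n_cycle <- max(round(period / params$dt), 1)
      tail_y <- utils::tail(y, n_cycle)
    } else {
      tail_y <- utils::tail(y, 1)
    }
    data.frame(freq_hz = f,
               model_min = model_response$ps_min[i],
               model_max = model_response$ps_max[i],
               model_mean = model_response$ps_mean[i],
               integ_min = min(tail_y),
               integ_max = max(tail_y),
               integ_mean = mean(tail_y))
  })
  out <- do.call(rbind, rows)
  out$mean_diff <- out$model_mean - out$integ_mean
  attr(out, "rms") <- sqrt(mean(out$mean_diff^2))
  out
}
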