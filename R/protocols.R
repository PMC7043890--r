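#' Piecewise-constant voltage-clamp protocol
#'
#' A command-voltage protocol is an ordered list of constant-voltage
#' segments, each with a duration (ms) and a level (mV). Ramps are not
#' supported: all protocols in this package are steps and trains.
#'
#' @param durations Segment durations in ms, all `> 0`.
#' @param levels Segment command voltages in mV.
#' @param label Optional protocol label.
#' @return An object of class `voltage_protocol` (a `data.frame` with
#'   columns `duration` and `level`).
#' @export
voltage_protocol <- function(durations, levels, label = NULL) {
  stopifnot(is.numeric(durations), is.numeric(levels),
            length(durations) == length(levels), length(durations) >= 1L)
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("all segment durations must be positive and finite")
  }
  if (any(!is.finite(levels))) stop("all voltage levels must be finite")
  structure(
    data.frame(duration = durations, level = levels),
    label = label,
    class = c("voltage_protocol", "data.frame")
  )
}

#' @export
print.voltage_protocol <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<voltage protocol%s> %d segments, %g ms total\n",
              if (is.null(lab)) "" else paste0(": ", lab),
              nrow(x), sum(x$duration)))
  invisible(x)
}

protocol_duration <- function(protocol) sum(protocol$duration)

#' Pulse-train protocol
#'
#' Builds a train of brief depolarising pulses from a holding potential:
#' `n_pulses` repetitions of (`pulse_ms` at `V_pulse`, then the remainder
#' of the period at `V_hold`). When `pulse_ms` equals the period exactly,
#' the degenerate limit of a single continuous depolarisation is returned.
#'
#' @param V_hold Holding potential, mV.
#' @param V_pulse Pulse potential, mV.
#' @param pulse_ms Pulse duration, ms.
#' @param freq Repetition rate, Hz.
#' @param n_pulses Number of pulses.
#' @return A [voltage_protocol()] with attributes `v_hold`, `v_pulse`,
#'   `pulse_ms` and `freq_hz` used by the analysis helpers.
#' @examples
#' p <- pulse_train_protocol(-80, -15, 5, 5, 3)   # 195 ms inter-pulse
#' @export
pulse_train_protocol <- function(V_hold, V_pulse, pulse_ms, freq, n_pulses) {
  stopifnot(pulse_ms > 0, freq > 0, n_pulses >= 1)
  period <- 1000 / freq
  if (pulse_ms > period + 1e-9) {
    stop("`pulse_ms` exceeds the period 1000/freq")
  }
  gap <- period - pulse_ms
  if (gap <= 1e-9) {
    # continuous-depolarisation limit
    prot <- voltage_protocol(n_pulses * period, V_pulse,
                             label = sprintf("constant %g mV", V_pulse))
  } else {
    durations <- rep(c(pulse_ms, gap), n_pulses)
    levels <- rep(c(V_pulse, V_hold), n_pulses)
    prot <- voltage_protocol(durations, levels,
                             label = sprintf("train %g Hz", freq))
  }
  attr(prot, "v_hold") <- V_hold
  attr(prot, "v_pulse") <- V_pulse
  attr(prot, "pulse_ms") <- pulse_ms
  attr(prot, "freq_hz") <- freq
  prot
}

#' Two-pulse recovery protocols
#'
#' One protocol per recovery delay: a conditioning pulse (`pulse_ms` at
#' `V_pulse`) that inactivates the channels, a recovery interval at
#' `V_hold`, and an identical test pulse probing availability.
#'
#' @param V_hold Holding/recovery potential, mV.
#' @param V_pulse Conditioning and test pulse potential, mV.
#' @param pulse_ms Pulse duration, ms.
#' @param delays Recovery delays in ms, all `> 0`.
#' @return A named list of [voltage_protocol()]s, one per delay, each with
#'   attribute `delay_ms`.
#' @export
recovery_protocol <- function(V_hold, V_pulse, pulse_ms, delays) {
  if (length(delays) == 0) stop("`delays` must be non-empty")
  if (any(!is.finite(delays)) || any(delays <= 0)) {
    stop("all delays must be positive and finite")
  }
  delays <- sort(delays)
  out <- lapply(delays, function(d) {
    p <- voltage_protocol(c(pulse_ms, d, pulse_ms),
                          c(V_pulse, V_hold, V_pulse),
                          label = sprintf("recovery %g ms", d))
    attr(p, "v_hold") <- V_hold
    attr(p, "v_pulse") <- V_pulse
    attr(p, "pulse_ms") <- pulse_ms
    attr(p, "delay_ms") <- d
    p
  })
  names(out) <- sprintf("delay_%g", delays)
  out
}

#' Log-spaced recovery delays
#'
#' @param from,to Shortest and longest delay in ms.
#' @param n Number of delays.
#' @return Numeric vector of log-spaced delays.
#' @export
log_spaced_delays <- function(from = 1, to = 6000, n = 20) {
  exp(seq(log(from), log(to), length.out = n))
}
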