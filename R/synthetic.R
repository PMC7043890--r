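#' Published recovery-from-inactivation parameter sets
#'
#' The four bi-exponential recovery parameter sets reported for sodium
#' currents in serotonergic raphe neurons (mean +/- SE over n cells):
#' neonatal brain-slice and acutely isolated mature preparations, each at
#' -80 and -100 mV. These ground-truth sets drive the synthetic recovery
#' generator.
#'
#' @return A `data.frame` with one row per set: `preparation`,
#'   `voltage_mV`, the four parameters (`a_fast`, `tau_fast_ms`,
#'   `a_slow`, `tau_slow_ms`), their standard errors (`se_*`) and the
#'   number of cells `n_cells`.
#' @export
builtin_param_sets <- function() {
  data.frame(
    preparation = c("neonatal", "neonatal", "mature", "mature"),
    voltage_mV = c(-80, -100, -80, -100),
    a_fast = c(0.786, 0.775, 0.81, 0.74),
    tau_fast_ms = c(3.14, 1.45, 8.54, 5.25),
    a_slow = c(0.212, 0.199, 0.187, 0.252),
    tau_slow_ms = c(612, 209, 517, 247),
    se_a_fast = c(0.013, 0.017, 0.022, 0.042),
    se_tau_fast = c(0.126, 0.07, 0.59, 0.69),
    se_a_slow = c(0.007, 0.01, 0.017, 0.033),
    se_tau_slow = c(76, 39, 126, 84),
    n_cells = c(18, 6, 6, 5)
  )
}

#' Look up one published recovery parameter set
#'
#' @param preparation `"neonatal"` or `"mature"`.
#' @param voltage `-80` or `-100` (mV).
#' @return A single-row `data.frame` from [builtin_param_sets()].
#' @export
recovery_ground_truth <- function(preparation = c("neonatal", "mature"),
                                  voltage = -80) {
  preparation <- match.arg(preparation)
  sets <- builtin_param_sets()
  row <- sets[sets$preparation == preparation &
              sets$voltage_mV == voltage, ]
  if (nrow(row) != 1) {
    stop("no built-in parameter set for ", preparation, " at ", voltage,
         " mV")
  }
  row
}

#' Noise model for synthetic recordings
#'
#' @param availability_sd Additive Gaussian SD on the normalised
#'   availability (the measured quantity of a recovery curve).
#' @param peak_sd_pA Additive Gaussian SD on raw current samples (used by
#'   the pulse-train generator).
#' @param seed Integer RNG seed recorded in the output metadata; every
#'   generator is a pure function of (parameters, seed).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(availability_sd = 0.02, peak_sd_pA = 0,
                        seed = 1L) {
  stopifnot(availability_sd >= 0, peak_sd_pA >= 0)
  structure(list(availability_sd = availability_sd,
                 peak_sd_pA = peak_sd_pA, seed = as.integer(seed)),
            class = "noise_model")
}

#' Synthetic multi-cell recovery-from-inactivation dataset
#'
#' Emulates a cohort of recovery measurements: for each synthetic cell,
#' availability at each delay is the bi-exponential ground-truth curve
#' plus additive Gaussian noise, clipped to `[0, 1.05]`. With
#' `cell_jitter = TRUE` each cell additionally receives its own parameter
#' values drawn around the published means with SD = SE * sqrt(n) (the
#' cell-level spread implied by the printed standard errors); draws are
#' rejected until amplitudes are positive and `0 < tau_fast < tau_slow`.
#' The published per-cell values are not available, so this is an
#' emulation of the cohort's statistical structure, not a
#' reconstruction.
#'
#' @param truth A single-row ground-truth set from
#'   [recovery_ground_truth()].
#' @param delays Recovery delays, ms (default 20 log-spaced points over
#'   1 ms - 6 s; a warning is issued if the delays do not span both time
#'   scales).
#' @param n_cells Number of synthetic cells.
#' @param noise A [noise_model()].
#' @param cell_jitter Draw per-cell parameters around the means
#'   (default `TRUE`)?
#' @return A `data.frame` with `delay_ms`, `availability` and
#'   `replicate`, with attributes `truth`, `noise` and `seed`.
#' @export
synth_recovery_dataset <- function(truth, delays = log_spaced_delays(),
                                   n_cells = 18,
                                   noise = noise_model(),
                                   cell_jitter = TRUE) {
  stopifnot(n_cells >= 1, inherits(noise, "noise_model"))
  if (min(delays) > truth$tau_fast_ms ||
      max(delays) < truth$tau_slow_ms) {
    warning("delays do not span both recovery time scales")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(noise$seed)

  draw_cell_params <- function() {
    if (!cell_jitter) {
      return(c(af = truth$a_fast, tf = truth$tau_fast_ms,
               as = truth$a_slow, ts = truth$tau_slow_ms))
    }
    scale <- sqrt(truth$n_cells)
    repeat {
      p <- c(af = stats::rnorm(1, truth$a_fast, truth$se_a_fast * scale),
             tf = stats::rnorm(1, truth$tau_fast_ms,
                               truth$se_tau_fast * scale),
             as = stats::rnorm(1, truth$a_slow, truth$se_a_slow * scale),
             ts = stats::rnorm(1, truth$tau_slow_ms,
                               truth$se_tau_slow * scale))
      if (all(p > 0) && p[["tf"]] < p[["ts"]]) return(p)
    }
  }

  rows <- lapply(seq_len(n_cells), function(cell) {
    p <- draw_cell_params()
    a <- biexp_availability(delays, p[["af"]], p[["tf"]],
                            p[["as"]], p[["ts"]])
    a <- a + stats::rnorm(length(delays), 0, noise$availability_sd)
    data.frame(delay_ms = delays,
               availability = pmin(pmax(a, 0), 1.05),
               replicate = cell)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "noise") <- noise
  attr(out, "seed") <- noise$seed
  out
}

#' Fit every cell of a synthetic recovery dataset
#'
#' @param dataset Output of [synth_recovery_dataset()].
#' @return A `data.frame` with one row per replicate: the four fitted
#'   parameters and the fit flags (collapsed to a single string).
#' @export
fit_recovery_cells <- function(dataset) {
  reps <- split(dataset, dataset$replicate)
  rows <- lapply(reps, function(df) {
    fit <- fit_biexp_recovery(df$delay_ms, df$availability)
    data.frame(replicate = df$replicate[1],
               a_fast = fit$a_fast, tau_fast = fit$tau_fast,
               a_slow = fit$a_slow, tau_slow = fit$tau_slow,
               rss = fit$rss,
               flags = paste(fit$flags, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic noisy pulse-train current trace
#'
#' Simulates the model current under a pulse train and adds seeded
#' Gaussian current noise, to exercise the peak-extraction analysis on
#' imperfect data. Zero noise reduces exactly to [simulate_current()].
#'
#' @param model A [nav_model()].
#' @param freq Pulse repetition rate, Hz.
#' @param n_pulses Number of pulses.
#' @param V_hold,V_pulse,pulse_ms Train parameters.
#' @param settings A [current_sim_settings()].
#' @param noise A [noise_model()] (`peak_sd_pA` is the per-sample current
#'   SD).
#' @param dt_out Sampling interval, ms.
#' @return A `current_trace` with attribute `protocol`.
#' @export
synth_pulse_train_trace <- function(model, freq, n_pulses = 20,
                                    V_hold = -80, V_pulse = -15,
                                    pulse_ms = 5,
                                    settings = current_sim_settings(
                                      g_na = 100),
                                    noise = noise_model(peak_sd_pA = 0),
                                    dt_out = 0.02) {
  protocol <- pulse_train_protocol(V_hold, V_pulse, pulse_ms, freq,
                                   n_pulses)
  trace <- simulate_current(model, protocol, settings, dt_out = dt_out)
  if (noise$peak_sd_pA > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    })
    set.seed(noise$seed)
    trace$I <- trace$I + stats::rnorm(length(trace$I), 0,
                                      noise$peak_sd_pA)
  }
  attr(trace, "protocol") <- protocol
  trace
}
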