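#' Voltage-dependent rate constant
#'
#' A transition rate with exponential voltage dependence,
#' \eqn{k(V) = k^0 e^{k^1 V}}, the standard single-barrier (Eyring-type)
#' parameterisation used for ion-channel gating rates. `k0` is the rate at
#' 0 mV (per ms) and `k1` (per mV) sets the voltage sensitivity; `k1 = 0`
#' gives a voltage-independent rate.
#'
#' @param k0 Pre-exponential factor, in ms^-1. Must be strictly positive.
#' @param k1 Exponential voltage factor, in mV^-1. May be zero or negative,
#'   must be finite.
#' @return An object of class `rate_constant`.
#' @examples
#' rc <- rate_constant(0.4008, -0.011)
#' eval_rate(rc, -80)
#' @export
rate_constant <- function(k0, k1) {
  stopifnot(is.numeric(k0), length(k0) == 1L, is.numeric(k1), length(k1) == 1L)
  if (!is.finite(k0) || k0 <= 0) {
    stop("`k0` must be a finite, strictly positive pre-exponential factor")
  }
  if (!is.finite(k1)) {
    stop("`k1` must be finite (it may be zero or negative)")
  }
  structure(list(k0 = k0, k1 = k1), class = "rate_constant")
}

#' @export
print.rate_constant <- function(x, ...) {
  cat(sprintf("<rate constant> k(V) = %g * exp(%g * V)  [ms^-1, V in mV]\n",
              x$k0, x$k1))
  invisible(x)
}

#' Evaluate a voltage-dependent rate
#'
#' Computes \eqn{k^0 e^{k^1 V}} at one or more membrane potentials.
#' The exponent is bounded to avoid silent overflow/underflow: an exponent
#' with magnitude above 700 (the double-precision exp range) signals an
#' out-of-range voltage.
#'
#' @param rc A [rate_constant()], or anything with numeric `k0` and `k1`
#'   fields.
#' @param V Membrane potential(s) in mV; must be finite.
#' @return Rate(s) in ms^-1, strictly positive.
#' @export
eval_rate <- function(rc, V) {
  if (!is.numeric(V) || any(!is.finite(V))) {
    stop("`V` must be finite numeric (mV)")
  }
  expo <- rc$k1 * V
  if (any(abs(expo) > 700)) {
    stop("voltage out of range: |k1 * V| exceeds the representable exponent")
  }
  rc$k0 * exp(expo)
}

#' Read a rate-constant table
#'
#' Reads a CSV table of directed transitions with columns
#' `from,to,k0,k1`. Comment lines starting with `#` may carry metadata; a
#' line of the form `# units: per_ms` or `# units: per_s` declares the unit
#' of the `k0` column. Rates are always returned on the canonical per-ms
#' scale (a `per_s` table is divided by 1000; `k1`, in per mV, is unit
#' independent).
#'
#' @param path Path to the CSV file.
#' @param units Optional override of the unit declaration; one of
#'   `"per_ms"` or `"per_s"`. When `NULL` (default) the file's `# units:`
#'   line is used, falling back to `per_ms`.
#' @return A `data.frame` with columns `from`, `to`, `k0` (ms^-1), `k1`
#'   (mV^-1), with attribute `units_declared` recording the source scale.
#' @export
read_rate_table <- function(path, units = NULL) {
  lines <- readLines(path)
  meta <- grep("^\\s*#", lines, value = TRUE)
  body <- grep("^\\s*#", lines, value = TRUE, invert = TRUE)
  declared <- "per_ms"
  um <- regmatches(meta, regexpr("units:\\s*(per_ms|per_s)", meta))
  if (length(um) > 0) {
    declared <- sub("units:\\s*", "", um[[1]])
  }
  if (!is.null(units)) {
    units <- match.arg(units, c("per_ms", "per_s"))
    declared <- units
  }
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE)
  required <- c("from", "to", "k0", "k1")
  if (!all(required %in% names(tab))) {
    stop("rate table must have columns `from,to,k0,k1`")
  }
  tab <- tab[, required]
  if (declared == "per_s") {
    tab$k0 <- tab$k0 / 1000
  }
  validate_rate_rows(tab)
  attr(tab, "units_declared") <- declared
  tab
}

validate_rate_rows <- function(tab) {
  if (any(!is.finite(tab$k0)) || any(tab$k0 <= 0)) {
    stop("all `k0` entries must be finite and strictly positive")
  }
  if (any(!is.finite(tab$k1))) {
    stop("all `k1` entries must be finite")
  }
  key <- paste(tab$from, tab$to, sep = "->")
  if (anyDuplicated(key)) {
    stop("duplicate directed transition(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (any(tab$from == tab$to)) {
    stop("self-transitions are not allowed")
  }
  invisible(tab)
}
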