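#' Kinetic scheme for a channel gating model
#'
#' A kinetic scheme is a set of named states, a conducting flag per state,
#' and a list of directed transitions, each carrying a voltage-dependent
#' [rate_constant()]. The scheme graph must be connected (ignoring edge
#' direction), so that a unique stationary distribution exists when all
#' rates are positive.
#'
#' @param states Character vector of unique state labels, e.g.
#'   `c("C1", ..., "O6", ..., "S13")`.
#' @param conducting Logical vector, one flag per state (`TRUE` for open,
#'   current-passing states).
#' @param transitions A `data.frame` with columns `from`, `to`, `k0`
#'   (ms^-1), `k1` (mV^-1), one row per directed transition, as returned by
#'   [read_rate_table()].
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(states, conducting, transitions) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("state labels must be unique")
  if (length(conducting) != length(states) || !is.logical(conducting)) {
    stop("`conducting` must be one logical flag per state")
  }
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  validate_rate_rows(transitions)
  unknown <- setdiff(unique(c(transitions$from, transitions$to)), states)
  if (length(unknown) > 0) {
    stop("transition(s) reference unknown state(s): ",
         paste(unknown, collapse = ", "))
  }
  orphan <- setdiff(states, unique(c(transitions$from, transitions$to)))
  if (length(orphan) > 0) {
    stop("state(s) not connected to any transition: ",
         paste(orphan, collapse = ", "))
  }
  if (!is_connected(states, transitions)) {
    stop("the scheme graph must be connected")
  }
  structure(
    list(states = states,
         conducting = stats::setNames(conducting, states),
         transitions = transitions),
    class = "kinetic_scheme"
  )
}

# undirected breadth-first search over the transition graph
is_connected <- function(states, transitions) {
  n <- length(states)
  if (n == 1L) return(TRUE)
  idx <- stats::setNames(seq_len(n), states)
  adj <- vector("list", n)
  for (r in seq_len(nrow(transitions))) {
    i <- idx[[transitions$from[r]]]
    j <- idx[[transitions$to[r]]]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic scheme> %d states (%s conducting), %d transitions\n",
              length(x$states),
              paste(x$states[x$conducting], collapse = ", "),
              nrow(x$transitions)))
  invisible(x)
}

#' Number of states in a scheme
#' @param scheme A [kinetic_scheme()].
#' @return Integer number of states.
#' @export
n_states <- function(scheme) length(scheme$states)
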