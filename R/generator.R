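#' Build the generator (Q) matrix of a scheme at a fixed voltage
#'
#' Constructs the continuous-time Markov generator with the row-vector
#' convention `dP/dt = P %*% Q`: `Q[i, j]` is the i -> j rate (ms^-1) at
#' voltage `V`, and each diagonal entry is minus its row sum, so rows sum
#' to zero.
#'
#' @param scheme A [kinetic_scheme()].
#' @param V Membrane potential in mV.
#' @return A square numeric matrix with `dimnames` given by the state
#'   labels and attribute `V` recording the voltage it was built at.
#' @examples
#' s <- two_state_scheme(a = 1, b = 2)
#' build_generator(s, 0)
#' @export
build_generator <- function(scheme, V) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            is.numeric(V), length(V) == 1L, is.finite(V))
  n <- n_states(scheme)
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  tr <- scheme$transitions
  for (r in seq_len(nrow(tr))) {
    Q[tr$from[r], tr$to[r]] <-
      eval_rate(list(k0 = tr$k0[r], k1 = tr$k1[r]), V)
  }
  diag(Q) <- -rowSums(Q)
  attr(Q, "V") <- V
  Q
}

# Matrix exponential of Q*dt, row-renormalised so the result is exactly
# row-stochastic. Without the renormalisation the ~1e-13 row-sum error of
# the Pade approximant compounds multiplicatively over the 1e5-1e6 steps of
# a long protocol and would break the 1e-9 conservation contract.
transition_matrix <- function(Q, dt) {
  if (any(!is.finite(Q))) stop("generator matrix has non-finite entries")
  if (dt < 0) stop("`dt` must be non-negative")
  if (dt == 0) return(diag(nrow(Q)))
  M <- as.matrix(Matrix::expm(Matrix::Matrix(Q * dt)))
  M / rowSums(M)
}

#' Propagate an occupancy vector for a fixed time at fixed voltage
#'
#' Advances the state occupancy by `dt` under a constant-voltage generator,
#' using the matrix exponential: `P(dt) = P0 %*% expm(Q * dt)`. This is
#' exact for piecewise-constant voltage (up to the Pade approximation of
#' the exponential), with probability conserved to better than 1e-9.
#'
#' @param P0 Occupancy vector (probabilities summing to 1).
#' @param Q Generator matrix from [build_generator()].
#' @param dt Time step in ms, `>= 0`.
#' @return The propagated occupancy vector.
#' @export
propagate <- function(P0, Q, dt) {
  P0 <- check_occupancy(P0, nrow(Q))
  out <- drop(P0 %*% transition_matrix(Q, dt))
  names(out) <- rownames(Q)
  out
}

check_occupancy <- function(P, n, tol = 1e-9) {
  if (!is.numeric(P) || length(P) != n) {
    stop("occupancy vector has the wrong length for this scheme")
  }
  if (any(!is.finite(P)) || any(P < -1e-12) || abs(sum(P) - 1) > tol) {
    stop("occupancy vector must be non-negative and sum to 1 (tol 1e-9)")
  }
  P
}

#' Stationary distribution of a generator matrix
#'
#' Solves `P %*% Q = 0` with `sum(P) = 1` through the null space of
#' `t(Q)`, taking the singular vector of the smallest singular value and
#' renormalising. A second near-zero singular value indicates a reducible
#' scheme (absorbing subsets), which is signalled as an error.
#'
#' @param Q Generator matrix from [build_generator()].
#' @param tol Relative threshold below which a singular value is treated
#'   as zero.
#' @return Named stationary occupancy vector.
#' @examples
#' Q <- build_generator(two_state_scheme(1, 3), 0)
#' stationary_distribution(Q)  # (0.75, 0.25)
#' @export
stationary_distribution <- function(Q, tol = 1e-8) {
  if (any(!is.finite(Q))) stop("generator matrix has non-finite entries")
  n <- nrow(Q)
  sv <- svd(t(Q))
  scale <- max(sv$d)
  null_dim <- sum(sv$d <= tol * scale)
  if (null_dim > 1L) {
    stop("scheme is reducible: the stationary distribution is not unique")
  }
  P <- sv$v[, n]
  P <- P / sum(P)
  if (any(P < -1e-8)) {
    stop("null-space solve returned negative occupancies; ",
         "the scheme may be reducible or badly scaled")
  }
  P[P < 0] <- 0
  P <- P / sum(P)
  names(P) <- rownames(Q)
  P
}

#' Minimal two-state scheme
#'
#' Convenience constructor for a two-state scheme `1 <-> 2` with
#' voltage-independent rates `a` (1 to 2) and `b` (2 to 1). Used in
#' examples and as a closed-form oracle (relaxation rate `a + b`,
#' stationary distribution `(b, a) / (a + b)`).
#'
#' @param a,b Forward and backward rates in ms^-1.
#' @return A [kinetic_scheme()].
#' @export
two_state_scheme <- function(a, b) {
  kinetic_scheme(
    states = c("S1", "S2"),
    conducting = c(FALSE, FALSE),
    transitions = data.frame(from = c("S1", "S2"), to = c("S2", "S1"),
                             k0 = c(a, b), k1 = c(0, 0))
  )
}
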