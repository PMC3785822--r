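#' Enumerate all spin states of a small system
#'
#' @param n Number of units (`n <= 20`).
#' @return `2^n x n` matrix of `{-1, +1}` states; row `i` encodes the state
#'   with binary index `i - 1`, unit `j` on bit `j - 1` (`+1` = bit set).
#' @export
enumerate_spin_states <- function(n) {
  if (n > 20L) stop("enumeration limited to n <= 20 units")
  idx <- 0:(2^n - 1)
  m <- sapply(seq_len(n), function(j) ifelse(bitwAnd(idx, bitwShiftL(1L, j - 1L)) > 0, 1L, -1L))
  matrix(m, nrow = 2^n, ncol = n)
}

#' Index of a spin state in the enumeration order
#' @param states A `{-1, +1}` vector (or matrix, one state per row).
#' @return 1-based index/indices matching [enumerate_spin_states()] rows.
#' @export
state_index <- function(states) {
  if (is.matrix(states))
    return(apply(states, 1, function(s) state_index(s)))
  sum((states == 1L) * 2^(seq_along(states) - 1)) + 1L
}

#' Total interaction energy of a system state
#' @param states A `{-1, +1}` vector.
#' @param network An [interaction_network()].
#' @param coupling Ferromagnetic coupling `J`.
#' @return `-J * sum over edges of s_a * s_b`.
#' @export
total_energy <- function(states, network, coupling = 1) {
  e <- network$edges
  -coupling * sum(states[e[, 1]] * states[e[, 2]])
}

#' Exact Gibbs distribution of a small system
#'
#' Normalized Boltzmann weights `exp(-E(S)/T)` over all `2^n` system states,
#' the stationary distribution of both single-site update rules.
#'
#' @param network An [interaction_network()] with at most 20 units.
#' @param params A [dynamics_params()].
#' @return Probability vector over states in [enumerate_spin_states()] order.
#' @export
gibbs_distribution <- function(network, params) {
  st <- enumerate_spin_states(network$n_units)
  en <- apply(st, 1, total_energy, network = network,
              coupling = params$coupling)
  w <- exp(-(en - min(en)) / params$temperature)
  w / sum(w)
}

#' Exact single-update transition matrix of a small system
#'
#' Transition matrix of one single-site update under the random-site
#' schedule: the updated site is uniform over units, then the site follows
#' the configured rule. One sweep corresponds to the `n`-th matrix power.
#'
#' @param network An [interaction_network()] with at most 12 units.
#' @param params A [dynamics_params()].
#' @return `2^n x 2^n` row-stochastic matrix over enumeration-ordered states.
#' @export
update_transition_matrix <- function(network, params) {
  n <- network$n_units
  if (n > 12L) stop("transition matrix limited to n <= 12 units")
  st <- enumerate_spin_states(n)
  K <- nrow(st)
  P <- matrix(0, K, K)
  for (a in seq_len(K)) {
    s <- st[a, ]
    for (i in seq_len(n)) {
      h <- sum(s[network$adjacency[[i]]])
      b <- a + (if (s[i] == 1L) -1L else 1L) * 2^(i - 1)  # state with site i flipped
      if (params$rule == "glauber") {
        x <- 2 * params$coupling * h * s[i] / params$temperature
        P[a, a] <- P[a, a] + stats::plogis(x) / n   # keep current state
        P[a, b] <- P[a, b] + stats::plogis(-x) / n  # flip
      } else {
        dE <- 2 * params$coupling * s[i] * h
        p_flip <- if (dE <= 0) 1 else exp(-dE / params$temperature)
        P[a, b] <- P[a, b] + p_flip / n
        P[a, a] <- P[a, a] + (1 - p_flip) / n
      }
    }
  }
  P
}

#' Matrix power by repeated squaring
#' @param P Square matrix.
#' @param k Nonnegative integer power.
#' @return `P %^% k`.
#' @export
matrix_power <- function(P, k) {
  stopifnot(k >= 0, k == round(k))
  out <- diag(nrow(P))
  base <- P
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% base
    base <- base %*% base
    k <- k %/% 2
  }
  out
}

#' Total-variation distance between two distributions
#' @param p,q Probability vectors of equal length.
#' @return `sum(abs(p - q)) / 2`.
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  sum(abs(p - q)) / 2
}

#' Long-run state frequencies of a simulated chain
#'
#' Simulates the chain and counts visits to each of the `2^n` system states,
#' sampling once per sweep after burn-in. Comparing the result with
#' [gibbs_distribution()] checks stationarity of the samplers against the
#' exact enumeration oracle.
#'
#' @param network An [interaction_network()] with at most 20 units.
#' @param params A [dynamics_params()]; its `seed`, if set, seeds the run.
#' @param n_samples Number of per-sweep samples after burn-in.
#' @param burn_in_sweeps Burn-in length in sweeps.
#' @param init Initial configuration or `"random"`.
#' @param schedule `"random-site"` or `"sweep"`.
#' @return Empirical probability vector over enumeration-ordered states.
#' @export
state_frequencies <- function(network, params, n_samples,
                              burn_in_sweeps = 1000L, init = "random",
                              schedule = c("random-site", "sweep")) {
  schedule <- match.arg(schedule)
  if (!is.null(params$seed)) set.seed(params$seed)
  if (identical(init, "random"))
    init <- random_spin_configuration(network$n_units)
  csr <- .adjacency_csr(network)
  counts <- cpp_state_counts(csr$adj, csr$offsets, as.integer(init),
                             as.integer(n_samples), as.integer(burn_in_sweeps),
                             params$temperature, params$coupling,
                             params$rule == "metropolis",
                             if (schedule == "sweep") 1L else 0L)
  counts / sum(counts)
}
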