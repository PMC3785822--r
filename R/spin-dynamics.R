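#' Dynamics parameters for Gibbs-measure spin updates
#'
#' Binary ferromagnetic units with interaction energy
#' `E = -J * sum_(i,j) s_i s_j` evolve by single-site updates in a heat bath
#' of temperature `T`: the Gibbs measure makes a state's probability
#' exponential in minus its local energy over `T`. Temperatures are in units
#' of the coupling `J` (default `J = 1`).
#'
#' @param temperature Heat-bath temperature `T > 0`.
#' @param coupling Ferromagnetic coupling `J > 0` (default 1).
#' @param rule Update rule: `"glauber"` (draw the new state from the local
#'   conditional Gibbs distribution, the LTE update) or `"metropolis"`
#'   (propose a flip; accept always if the energy drops, else with
#'   probability `exp(-dE/T)`).
#' @param seed Optional integer seed recorded with the parameters and applied
#'   by simulation drivers for reproducibility.
#' @return Object of class `dynamics_params`.
#' @export
dynamics_params <- function(temperature, coupling = 1,
                            rule = c("glauber", "metropolis"), seed = NULL) {
  rule <- match.arg(rule)
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (!(temperature > 0)) stop("temperature must be > 0")
  stopifnot(is.numeric(coupling), length(coupling) == 1L)
  if (!(coupling > 0)) stop("coupling must be > 0")
  structure(list(temperature = temperature, coupling = coupling,
                 rule = rule, seed = seed),
            class = "dynamics_params")
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat(sprintf("<dynamics_params> rule = %s, T = %g, J = %g%s\n", x$rule,
              x$temperature, x$coupling,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

#' Spin configuration
#'
#' @param states Vector with every entry in `{-1, +1}`.
#' @return Integer vector of class `spin_configuration`.
#' @export
spin_configuration <- function(states) {
  if (!all(states %in% c(-1, 1))) stop("states must all be in {-1, +1}")
  structure(as.integer(states), class = "spin_configuration")
}

#' Uniformly random spin configuration
#' @param n Number of units.
#' @return A [spin_configuration()].
#' @export
random_spin_configuration <- function(n) {
  spin_configuration(sample(c(-1L, 1L), n, replace = TRUE))
}

#' Local interaction energy of a unit state
#'
#' `E(state | neighbours) = -J * state * sum(neighbor_states)`: the energy
#' depends on the neighbour states only through their sum, i.e. on the
#' distribution of neighbour states, not on which neighbour holds which
#' state. An empty neighbourhood has energy 0.
#'
#' @param state A spin value in `{-1, +1}`.
#' @param neighbor_states Vector (multiset) of neighbour spin values.
#' @param coupling Ferromagnetic coupling `J`.
#' @return Energy (same units as `J`).
#' @export
local_energy <- function(state, neighbor_states, coupling = 1) {
  if (!state %in% c(-1, 1)) stop("state must be in {-1, +1}")
  -coupling * state * sum(neighbor_states)
}

#' Gibbs transition probabilities of a single unit
#'
#' `P(r) ~ exp(-E(r | neighbours) / T)` normalized over `r` in `{-1, +1}`.
#' With no neighbours the landscape is flat and both states have probability
#' one half; in the infinite-temperature limit the distribution is uniform
#' regardless of the neighbourhood.
#'
#' @param neighbor_states Vector of neighbour spin values (may be empty).
#' @param params A [dynamics_params()].
#' @return Named numeric vector `c("-1" = ..., "+1" = ...)`.
#' @export
gibbs_transition_probs <- function(neighbor_states, params) {
  stopifnot(inherits(params, "dynamics_params"))
  h <- sum(neighbor_states)
  x <- 2 * params$coupling * h / params$temperature
  # both tails via the logistic directly: full relative precision even when
  # one probability is within 1e-12 of 1 (detailed-balance checks need it)
  c("-1" = stats::plogis(-x), "+1" = stats::plogis(x))
}

#' Single Glauber update
#'
#' Draws the site's new state from its conditional Gibbs distribution given
#' the instantaneous neighbour states (local thermodynamic equilibrium); all
#' other unit states are unchanged.
#'
#' @param config A [spin_configuration()].
#' @param site Unit id (1-based).
#' @param network An [interaction_network()].
#' @param params A [dynamics_params()] (the `rule` field is ignored here).
#' @return The updated [spin_configuration()].
#' @export
glauber_step <- function(config, site, network, params) {
  .check_site(config, site, network)
  pr <- gibbs_transition_probs(config[network$adjacency[[site]]], params)
  config[site] <- if (stats::runif(1) < pr[["+1"]]) 1L else -1L
  config
}

#' Single Metropolis-Hastings update
#'
#' Proposes flipping the site's spin; the flip is always accepted if it
#' lowers the interaction energy (`dE <= 0`, including ties), otherwise it is
#' accepted with probability `exp(-dE / T)`.
#'
#' @inheritParams glauber_step
#' @return The updated [spin_configuration()].
#' @export
metropolis_step <- function(config, site, network, params) {
  .check_site(config, site, network)
  h <- sum(config[network$adjacency[[site]]])
  dE <- 2 * params$coupling * config[site] * h
  if (dE <= 0 || stats::runif(1) < exp(-dE / params$temperature))
    config[site] <- -config[site]
  config
}

.check_site <- function(config, site, network) {
  if (length(config) != network$n_units)
    stop("configuration length does not match network size")
  if (length(site) != 1L || site < 1L || site > network$n_units ||
      site != round(site))
    stop("invalid site id")
  invisible(TRUE)
}

#' Run a single-site Markov chain
#'
#' Drives repeated single-site updates of the configured rule over the
#' network. One time step is one full sweep of `n_units` single-site updates,
#' so lag axes do not depend on the network size. With the `"random-site"`
#' schedule each update targets a uniformly chosen unit; with `"sweep"` each
#' pass uses a fresh random permutation of all units.
#'
#' @param network An [interaction_network()].
#' @param params A [dynamics_params()]; its `seed`, if set, seeds the run.
#' @param n_steps Number of sweeps, `>= 1`.
#' @param init Initial [spin_configuration()] or `"random"`.
#' @param schedule `"random-site"` (default) or `"sweep"`.
#' @param record_stride Sweeps between recorded snapshots (0 records nothing
#'   but the final state).
#' @return Object of class `trajectory`: list with `snapshots` (matrix,
#'   one recorded sweep per row), `final`, `record_stride`, `schedule`,
#'   `params`, `n_sweeps`.
#' @export
run_chain <- function(network, params, n_steps, init = "random",
                      schedule = c("random-site", "sweep"),
                      record_stride = 1L) {
  schedule <- match.arg(schedule)
  stopifnot(inherits(network, "interaction_network"),
            inherits(params, "dynamics_params"))
  if (length(n_steps) != 1L || n_steps < 1L || n_steps != round(n_steps))
    stop("n_steps must be an integer >= 1")
  if (!is.null(params$seed)) set.seed(params$seed)
  if (identical(init, "random")) init <- random_spin_configuration(network$n_units)
  if (length(init) != network$n_units)
    stop("init length does not match network size")
  if (!all(init %in% c(-1L, 1L))) stop("init states must be in {-1, +1}")
  csr <- .adjacency_csr(network)
  res <- cpp_run_chain(csr$adj, csr$offsets, as.integer(init),
                       as.integer(n_steps), params$temperature,
                       params$coupling, params$rule == "metropolis",
                       if (schedule == "sweep") 1L else 0L,
                       as.integer(record_stride))
  structure(list(snapshots = res$snapshots, final = res$final,
                 record_stride = as.integer(record_stride),
                 schedule = schedule, params = params,
                 n_sweeps = as.integer(n_steps)),
            class = "trajectory")
}

# 0-based CSR adjacency for the compiled core
.adjacency_csr <- function(network) {
  lens <- lengths(network$adjacency)
  list(adj = as.integer(unlist(network$adjacency, use.names = FALSE) - 1L),
       offsets = as.integer(c(0L, cumsum(lens))))
}

#' Write a trajectory to CSV
#'
#' `layout = "long"` writes columns `(sweep, unit_id, state)` (0-based unit
#' ids); `layout = "matrix"` writes one row per recorded sweep with a column
#' per unit.
#'
#' @param trajectory A trajectory from [run_chain()].
#' @param path File path.
#' @param layout `"long"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, layout = c("long", "matrix")) {
  layout <- match.arg(layout)
  sn <- trajectory$snapshots
  sweeps <- seq_len(nrow(sn)) * trajectory$record_stride
  if (layout == "long") {
    d <- data.frame(sweep = rep(sweeps, ncol(sn)),
                    unit_id = rep(seq_len(ncol(sn)) - 1L, each = nrow(sn)),
                    state = as.vector(sn))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    d <- as.data.frame(sn)
    names(d) <- paste0("u", seq_len(ncol(sn)) - 1L)
    utils::write.csv(cbind(sweep = sweeps, d), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
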