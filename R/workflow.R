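#' Default run configuration
#'
#' Flat key-value document driving the command-level pipelines. Keys carry
#' explicit units in their names (sweeps, bits) to avoid steps-versus-sweeps
#' ambiguity. Round-trips losslessly through YAML.
#'
#' @return Named list of configuration keys.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "idtnet-out",
    # network ensemble
    n_units = 500L,
    gamma = 1.6,
    k_min = 1L,
    k_max = NA,                 # NA -> floor(sqrt(n_units))
    # dynamics
    temperature = 9.0,
    coupling_J = 1.0,
    rule = "metropolis",
    schedule = "random-site",
    burn_in_sweeps = 1000L,
    # analytic curve
    analytic_epsilon_bits = 1e-3,
    c_eff = 1.0,
    uniqueness_mode = "upper-bound-1",
    neighbor_magnetization = "equilibrium",
    # empirical experiment
    n_realizations = 6L,
    n_series = 5000L,
    tau_max_sweeps = 15L,
    n_prior_sweeps = 2000L,
    empirical_epsilon_bits = 0.01,
    # trajectory output
    trajectory_layout = "long"
  )
}

#' Read / write a run configuration
#'
#' YAML with flat keys; unknown keys are rejected so typos fail loudly.
#' Values in `overrides` (and any keys missing from the file) fall back to
#' [default_run_config()].
#'
#' @param path YAML file path.
#' @param overrides Named list applied on top of the file.
#' @param config Named list to write.
#' @return `read_run_config` returns the resolved configuration list;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  file_cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (src in list(file_cfg, overrides)) {
    if (length(src) == 0) next
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown))
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    cfg[names(src)] <- src
  }
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.resolve_k_max <- function(config) {
  if (is.null(config$k_max) || is.na(config$k_max))
    floor(sqrt(config$n_units)) else as.integer(config$k_max)
}

.cfg_dynamics <- function(config) {
  dynamics_params(temperature = config$temperature,
                  coupling = config$coupling_J, rule = config$rule,
                  seed = config$seed)
}

.write_log <- function(entries, path) {
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Generate and write a configuration-model network
#'
#' Samples a power-law degree sequence, realizes it as a simple graph and
#' writes the edge list, the parametric degree table and a JSON run log
#' recording the seed, odd-sum resampling and repair-swap counts.
#'
#' @param config Configuration list (see [default_run_config()]).
#' @return Invisible list of written paths plus the network.
#' @export
cmd_generate_network <- function(config = default_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  k_max <- .resolve_k_max(config)
  degs <- sample_power_law_degrees(config$n_units, config$gamma,
                                   config$k_min, k_max)
  net <- build_configuration_graph(degs)
  edge_path <- file.path(config$out_dir, "network_edges.txt")
  dist_path <- file.path(config$out_dir, "degree_distribution.csv")
  log_path <- file.path(config$out_dir, "generate_network_log.json")
  write_edge_list(net, edge_path)
  write_degree_distribution(
    power_law_distribution(config$gamma, config$k_min, k_max), dist_path)
  .write_log(list(seed = config$seed, n_units = config$n_units,
                  gamma = config$gamma, k_min = config$k_min, k_max = k_max,
                  odd_sum_resamples = attr(degs, "odd_sum_resamples"),
                  repair_swaps = attr(net, "repair_swaps"),
                  matchings = attr(net, "matchings")), log_path)
  invisible(list(edge_list = edge_path, degree_distribution = dist_path,
                 log = log_path, network = net))
}

#' Evaluate and write the analytic IDT curve
#'
#' Builds the configured power-law ensemble, evaluates `D(k)` on the full
#' degree range and writes the curve CSV plus its JSON parameter sidecar.
#'
#' @param config Configuration list (see [default_run_config()]).
#' @return Invisible list with the curve and the written path.
#' @export
cmd_analytic_curve <- function(config = default_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  k_max <- .resolve_k_max(config)
  dist <- power_law_distribution(config$gamma, config$k_min, k_max)
  dyn <- dynamics_params(config$temperature, config$coupling_J, "glauber")
  nm <- config$neighbor_magnetization
  if (!identical(nm, "equilibrium")) nm <- as.numeric(nm)
  params <- analytic_idt_params(dist, dyn,
                                epsilon_bits = config$analytic_epsilon_bits,
                                c_eff = config$c_eff,
                                uniqueness = config$uniqueness_mode,
                                neighbor_magnetization = nm)
  curve <- idt_curve(seq.int(config$k_min, k_max), params)
  path <- file.path(config$out_dir, "idt_curve.csv")
  write_idt_curve(curve, path)
  invisible(list(curve = curve, path = path))
}

#' Run and write the empirical IDT experiment
#'
#' @param config Configuration list (see [default_run_config()]).
#' @return Invisible list with the `empirical_idt` result and output dir.
#' @export
cmd_empirical_idt <- function(config = default_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dyn <- .cfg_dynamics(config)
  res <- empirical_idt(
    n_units = config$n_units, gamma = config$gamma, dynamics = dyn,
    n_realizations = config$n_realizations, n_series = config$n_series,
    tau_max = config$tau_max_sweeps,
    burn_in_sweeps = config$burn_in_sweeps,
    n_prior_sweeps = config$n_prior_sweeps,
    epsilon_bits = config$empirical_epsilon_bits,
    k_min = config$k_min, k_max = .resolve_k_max(config),
    schedule = config$schedule)
  write_empirical_results(res, config$out_dir)
  invisible(list(result = res, out_dir = config$out_dir))
}

#' Write the toy fixtures and exact-oracle tables
#'
#' Writes edge lists for the star, path, triangle and 8-unit random toy
#' networks, exact Gibbs probability tables (from `2^N` enumeration) for
#' each at the configured temperature, and the sweep transition matrix of
#' the two-unit chain for lag oracles.
#'
#' @param config Configuration list (see [default_run_config()]).
#' @return Invisible vector of written paths.
#' @export
cmd_make_fixtures <- function(config = default_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  nets <- fixture_networks()
  dyn <- dynamics_params(config$temperature, config$coupling_J, config$rule)
  paths <- character(0)
  for (nm in names(nets)) {
    p_edge <- file.path(config$out_dir, sprintf("fixture_%s_edges.txt", nm))
    write_edge_list(nets[[nm]], p_edge)
    st <- enumerate_spin_states(nets[[nm]]$n_units)
    gp <- gibbs_distribution(nets[[nm]], dyn)
    p_tab <- file.path(config$out_dir, sprintf("fixture_%s_gibbs.csv", nm))
    utils::write.csv(
      data.frame(state_index = seq_along(gp) - 1L,
                 spins = apply(st, 1, function(s)
                   paste(ifelse(s == 1, "+", "-"), collapse = "")),
                 probability = gp),
      p_tab, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p_edge, p_tab)
  }
  chain2 <- make_path_network(2L)
  P_sweep <- matrix_power(update_transition_matrix(chain2, dyn),
                          chain2$n_units)
  p_mat <- file.path(config$out_dir, "two_spin_sweep_transition.csv")
  utils::write.csv(as.data.frame(P_sweep), p_mat, row.names = FALSE,
                   quote = FALSE)
  paths <- c(paths, p_mat)
  invisible(paths)
}
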