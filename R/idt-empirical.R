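#' Equilibrium (unconditioned) state samples
#'
#' Runs the chain past burn-in and records the full state once per
#' `stride_sweeps`. These samples supply the unconditioned prior entropy of
#' each unit for the mutual-information decay curves.
#'
#' @param network An [interaction_network()].
#' @param params A [dynamics_params()].
#' @param n_samples Number of recorded states.
#' @param stride_sweeps Sweeps between recorded states.
#' @param burn_in_sweeps Burn-in length in sweeps, `>= 1`.
#' @param init Initial configuration or `"random"`.
#' @return Integer matrix (`n_samples` x `n_units`) of `{-1, +1}` states.
#' @export
equilibrium_samples <- function(network, params, n_samples,
                                stride_sweeps = 1L, burn_in_sweeps = 1000L,
                                init = "random") {
  if (burn_in_sweeps < 1L) stop("burn_in_sweeps must be >= 1")
  total <- burn_in_sweeps + n_samples * stride_sweeps
  traj <- run_chain(network, params, n_steps = total, init = init,
                    record_stride = stride_sweeps)
  sn <- traj$snapshots
  sn[seq.int(nrow(sn) - n_samples + 1L, nrow(sn)), , drop = FALSE]
}

#' Conditioned trajectory ensemble around a reference state
#'
#' Implements the conditioning protocol of the empirical IDT experiment:
#' equilibrate, pick a reference system state `S*`, then collect many
#' trajectories that lead up to `S*` and read off each unit's state `tau`
#' sweeps before the end. Because the stationary chain satisfies detailed
#' balance it is time-reversible, so trajectories ending at `S*` are sampled
#' as independent forward runs started at `S*`, with the lag-`tau` state
#' interpreted as the state `tau` sweeps before the ending.
#'
#' @param network An [interaction_network()].
#' @param params A [dynamics_params()]; its `seed`, if set, seeds the run.
#' @param n_series Number of trajectories, `>= 100`.
#' @param tau_max Largest lag in sweeps, `>= 1`.
#' @param burn_in_sweeps Equilibration length before choosing `S*`, `>= 1`.
#' @param reference_state Optional [spin_configuration()] to condition on
#'   (skips equilibration).
#' @param schedule `"random-site"` or `"sweep"`.
#' @param count_states Also accumulate counts over full system states per
#'   lag (only for `n_units <= 12`); used by exact-oracle checks.
#' @return Object of class `conditioned_ensemble`: `reference_state`,
#'   `plus_counts` (`n_units x (tau_max + 1)` counts of `+1` per lag),
#'   `state_counts` (optional), `lags`, `n_series`, `params`, `network_size`.
#' @export
conditioned_ensemble <- function(network, params, n_series, tau_max,
                                 burn_in_sweeps = 1000L,
                                 reference_state = NULL,
                                 schedule = c("random-site", "sweep"),
                                 count_states = FALSE) {
  schedule <- match.arg(schedule)
  stopifnot(inherits(network, "interaction_network"),
            inherits(params, "dynamics_params"))
  if (n_series < 100L) stop("n_series must be >= 100")
  if (tau_max < 1L) stop("tau_max must be >= 1")
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(reference_state)) {
    if (burn_in_sweeps < 1L) stop("burn_in_sweeps must be >= 1")
    traj <- run_chain(network, params, n_steps = burn_in_sweeps,
                      record_stride = 0L, schedule = schedule)
    reference_state <- spin_configuration(traj$final)
  }
  if (length(reference_state) != network$n_units)
    stop("reference state length does not match network size")
  csr <- .adjacency_csr(network)
  res <- cpp_conditioned_ensemble(csr$adj, csr$offsets,
                                  as.integer(reference_state),
                                  as.integer(n_series), as.integer(tau_max),
                                  params$temperature, params$coupling,
                                  params$rule == "metropolis",
                                  if (schedule == "sweep") 1L else 0L,
                                  isTRUE(count_states))
  structure(list(reference_state = as.integer(reference_state),
                 plus_counts = res$plus_counts,
                 state_counts = res$state_counts,
                 lags = 0:tau_max, n_series = as.integer(n_series),
                 params = params, network_size = network$n_units,
                 schedule = schedule),
            class = "conditioned_ensemble")
}

#' Mutual-information decay curve of one unit
#'
#' Information (bits) that the reference ending retains about the unit's
#' state `tau` sweeps earlier:
#' `info(tau) = H_prior(s_i) - H(s_i at lag tau | ending at S*)`,
#' both terms plug-in estimates (the prior from unconditioned equilibrium
#' samples, the conditional from the ensemble counts). Negative estimates
#' are floored at zero and the number of floored lags is recorded.
#'
#' @param ensemble A [conditioned_ensemble()].
#' @param unit_id Unit id (1-based).
#' @param prior Unconditioned sample matrix from [equilibrium_samples()] on
#'   the same chain.
#' @return Object of class `mi_decay_curve`: `unit_id`, `lags`, `info_bits`,
#'   `prior_entropy_bits`, `n_series`, `n_floored`.
#' @export
mi_decay_curve <- function(ensemble, unit_id, prior) {
  stopifnot(inherits(ensemble, "conditioned_ensemble"))
  if (is.null(prior) || !is.matrix(prior) || nrow(prior) == 0L)
    stop("prior samples are required")
  if (unit_id < 1L || unit_id > ensemble$network_size) stop("invalid unit id")
  p_prior <- mean(prior[, unit_id] == 1L)
  h_prior <- .h2(p_prior)
  p_cond <- ensemble$plus_counts[unit_id, ] / ensemble$n_series
  info <- h_prior - .h2(p_cond)
  n_floored <- sum(info < 0)
  structure(list(unit_id = unit_id, lags = ensemble$lags,
                 info_bits = pmax(0, info), prior_entropy_bits = h_prior,
                 n_series = ensemble$n_series, n_floored = n_floored),
            class = "mi_decay_curve")
}

#' Estimation noise floor for the decay curves
#'
#' Plug-in information estimates are biased upward, so the regression must
#' ignore lags indistinguishable from noise. The floor is the 97.5th
#' percentile of the same statistic computed on surrogate conditional
#' samples drawn from the unit's unconditioned prior (i.e. with the pairing
#' to the reference state destroyed), which is what a lag carrying no
#' information would produce at the same sample size.
#'
#' @param prior Unconditioned sample matrix from [equilibrium_samples()].
#' @param unit_id Unit id (1-based).
#' @param n_series Conditional sample size the floor must match.
#' @param n_boot Number of surrogate draws.
#' @param level Percentile of the null statistic (default 0.975).
#' @return Noise floor in bits.
#' @export
mi_noise_floor <- function(prior, unit_id, n_series, n_boot = 200L,
                           level = 0.975) {
  p_prior <- mean(prior[, unit_id] == 1L)
  h_prior <- .h2(p_prior)
  draws <- stats::rbinom(n_boot, n_series, p_prior) / n_series
  stats::quantile(pmax(0, h_prior - .h2(draws)), level, names = FALSE)
}

#' Per-unit information dissipation time by regression
#'
#' Fits `log2(info)` against lag by least squares over the lags whose
#' information exceeds the noise floor, and reports the lag at which the
#' fitted line crosses the floor `epsilon_bits`. A curve that never exceeds
#' `epsilon_bits` has already dissipated: `d_i = 0`. Results resting on
#' fewer than 3 usable lags, or on a non-decaying fit (slope `>= 0`, in
#' which case `d_i` is right-censored at the largest lag), are flagged
#' unreliable rather than failing silently.
#'
#' @param curve An [mi_decay_curve()].
#' @param epsilon_bits Information floor `eps` in bits.
#' @param noise_floor Estimation noise floor in bits (see
#'   [mi_noise_floor()]); lags at or below it are excluded from the fit.
#' @param max_extrapolation Crossings further than this multiple of the
#'   largest observed lag are right-censored at the cap and flagged
#'   unreliable (a near-zero slope on a near-frozen unit would otherwise
#'   extrapolate to astronomically large, meaningless times).
#' @return Object of class `idt_estimate`: `d_i` (sweeps), `reliable`,
#'   `slope`, `intercept`, `n_points`.
#' @export
estimate_idt <- function(curve, epsilon_bits, noise_floor = 0,
                         max_extrapolation = 10) {
  stopifnot(inherits(curve, "mi_decay_curve"))
  if (!(epsilon_bits > 0)) stop("epsilon_bits must be > 0")
  info <- curve$info_bits
  lags <- curve$lags
  if (!any(info > epsilon_bits))
    return(structure(list(d_i = 0, reliable = TRUE, slope = NA_real_,
                          intercept = NA_real_, n_points = 0L),
                     class = "idt_estimate"))
  usable <- which(info > max(noise_floor, 0))
  if (length(usable) < 2L) {
    d <- max(lags[info > epsilon_bits])
    return(structure(list(d_i = d, reliable = FALSE, slope = NA_real_,
                          intercept = NA_real_,
                          n_points = length(usable)),
                     class = "idt_estimate"))
  }
  fit <- stats::lsfit(lags[usable], log2(info[usable]))
  intercept <- fit$coefficients[[1]]
  slope <- fit$coefficients[[2]]
  if (!is.finite(slope) || slope >= 0) {
    return(structure(list(d_i = max(lags), reliable = FALSE, slope = slope,
                          intercept = intercept,
                          n_points = length(usable)),
                     class = "idt_estimate"))
  }
  d <- (log2(epsilon_bits) - intercept) / slope
  cap <- max_extrapolation * max(lags)
  if (d > cap)
    return(structure(list(d_i = cap, reliable = FALSE, slope = slope,
                          intercept = intercept, n_points = length(usable)),
                     class = "idt_estimate"))
  structure(list(d_i = max(0, d), reliable = length(usable) >= 3L,
                 slope = slope, intercept = intercept,
                 n_points = length(usable)),
            class = "idt_estimate")
}

#' Degree-binned aggregation of per-unit IDTs
#'
#' Bins units by degree (exact degrees up to `exact_max`, logarithmically
#' spaced bins above, where the heavy tail is sparse) and reports the mean
#' IDT, its standard error and the unit count per bin. The SEM is suppressed
#' (NA) for bins with a single unit.
#'
#' @param d_i Numeric vector of per-unit IDTs (sweeps).
#' @param degrees Integer vector of matching unit degrees.
#' @param reliable Optional logical vector of reliability flags (carried
#'   into the per-unit table; all units enter the bins).
#' @param exact_max Largest degree binned exactly (default 20).
#' @param n_log_bins Number of logarithmic bins above `exact_max`.
#' @return Object of class `empirical_idt`: `units` data frame
#'   (`unit_id`, `degree`, `d_i_sweeps`, `reliable_flag`) and `bins` data
#'   frame (`degree_bin_low`, `degree_bin_high`, `mean_d`, `sem_d`,
#'   `n_units`).
#' @export
aggregate_by_degree <- function(d_i, degrees, reliable = NULL,
                                exact_max = 20L, n_log_bins = 6L) {
  if (length(d_i) == 0L) stop("no per-unit results to aggregate")
  if (length(degrees) != length(d_i))
    stop("degrees and d_i must have equal length")
  if (is.null(reliable)) reliable <- rep(TRUE, length(d_i))
  lo_edges <- seq_len(min(exact_max, max(degrees)))
  edges_low <- lo_edges
  edges_high <- lo_edges
  if (max(degrees) > exact_max) {
    br <- unique(round(exp(seq(log(exact_max + 1), log(max(degrees) + 1),
                               length.out = n_log_bins + 1L))))
    lo <- br[-length(br)]
    hi <- c(br[-1] - 1L, max(degrees))
    hi <- pmax(lo, hi[seq_along(lo)])
    edges_low <- c(edges_low, lo)
    edges_high <- c(edges_high, hi)
  }
  bins <- lapply(seq_along(edges_low), function(b) {
    sel <- degrees >= edges_low[b] & degrees <= edges_high[b]
    if (!any(sel)) return(NULL)
    v <- d_i[sel]
    data.frame(degree_bin_low = edges_low[b], degree_bin_high = edges_high[b],
               mean_d = mean(v),
               sem_d = if (length(v) >= 2L)
                 stats::sd(v) / sqrt(length(v)) else NA_real_,
               n_units = length(v))
  })
  bins <- do.call(rbind, bins)
  units <- data.frame(unit_id = seq_along(d_i), degree = degrees,
                      d_i_sweeps = d_i, reliable_flag = reliable)
  structure(list(units = units, bins = bins), class = "empirical_idt")
}

#' @export
print.empirical_idt <- function(x, ...) {
  cat(sprintf("<empirical_idt> %d units in %d degree bins, mean IDT %.2f sweeps\n",
              nrow(x$units), nrow(x$bins), mean(x$units$d_i_sweeps)))
  invisible(x)
}

#' @export
plot.empirical_idt <- function(x, ...) {
  mid <- (x$bins$degree_bin_low + x$bins$degree_bin_high) / 2
  plot(mid, x$bins$mean_d, log = "x", pch = 16, xlab = "degree k",
       ylab = "mean IDT [sweeps]", ...)
  ok <- !is.na(x$bins$sem_d)
  arrows(mid[ok], x$bins$mean_d[ok] - 2 * x$bins$sem_d[ok],
         mid[ok], x$bins$mean_d[ok] + 2 * x$bins$sem_d[ok],
         angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Full empirical IDT experiment on configuration-model ensembles
#'
#' Runs the complete empirical pipeline: for each realization, draw a
#' power-law degree sequence, build a configuration-model network,
#' equilibrate, fix a random reference state, collect a conditioned
#' trajectory ensemble and unconditioned prior samples, estimate each
#' unit's information-decay curve and its IDT by regression; finally pool
#' all units over realizations and aggregate by degree.
#'
#' @param n_units Units per realization.
#' @param gamma Power-law exponent of the degree distribution.
#' @param dynamics A [dynamics_params()].
#' @param n_realizations Number of independent network + reference-state
#'   realizations pooled together.
#' @param n_series Conditioned trajectories per realization.
#' @param tau_max Largest lag in sweeps.
#' @param burn_in_sweeps Equilibration before the reference state is drawn.
#' @param n_prior_sweeps Unconditioned per-sweep samples for the prior.
#' @param epsilon_bits Information floor for the IDT regression.
#' @param k_min,k_max Degree bounds (defaults 1 and `floor(sqrt(n_units))`).
#' @param schedule Update schedule, see [run_chain()].
#' @return An `empirical_idt` object (see [aggregate_by_degree()]) with the
#'   run parameters attached as the `"run_params"` attribute.
#' @export
empirical_idt <- function(n_units, gamma, dynamics, n_realizations = 6L,
                          n_series = 5000L, tau_max = 15L,
                          burn_in_sweeps = 1000L, n_prior_sweeps = 2000L,
                          epsilon_bits = 0.01, k_min = 1L, k_max = NULL,
                          schedule = "random-site") {
  if (!is.null(dynamics$seed)) set.seed(dynamics$seed)
  all_d <- numeric(0); all_deg <- integer(0); all_rel <- logical(0)
  for (real in seq_len(n_realizations)) {
    degs <- sample_power_law_degrees(n_units, gamma, k_min, k_max)
    net <- build_configuration_graph(degs)
    ens <- conditioned_ensemble(net, dynamics, n_series = n_series,
                                tau_max = tau_max,
                                burn_in_sweeps = burn_in_sweeps,
                                schedule = schedule)
    prior <- equilibrium_samples(net, dynamics, n_samples = n_prior_sweeps,
                                 burn_in_sweeps = burn_in_sweeps)
    for (u in seq_len(n_units)) {
      curve <- mi_decay_curve(ens, u, prior)
      floor_u <- mi_noise_floor(prior, u, n_series)
      est <- estimate_idt(curve, epsilon_bits, noise_floor = floor_u)
      all_d <- c(all_d, est$d_i)
      all_deg <- c(all_deg, net$degrees[u])
      all_rel <- c(all_rel, est$reliable)
    }
  }
  res <- aggregate_by_degree(all_d, all_deg, all_rel)
  attr(res, "run_params") <- list(
    n_units = n_units, gamma = gamma, k_min = k_min,
    k_max = k_max %||% floor(sqrt(n_units)),
    temperature = dynamics$temperature, coupling = dynamics$coupling,
    rule = dynamics$rule, seed = dynamics$seed,
    n_realizations = n_realizations, n_series = n_series,
    tau_max = tau_max, burn_in_sweeps = burn_in_sweeps,
    n_prior_sweeps = n_prior_sweeps, epsilon_bits = epsilon_bits,
    schedule = schedule)
  res
}

#' Hub versus intermediate-degree IDT comparison
#'
#' Pools the units in the top quantile of the degree distribution (the
#' hubs) and compares their mean IDT with the best-performing degree bin
#' entirely below the hub cut. The separation is reported in units of the
#' joint standard error `sqrt(sem_hub^2 + sem_bin^2)`.
#'
#' @param result An `empirical_idt` object.
#' @param hub_quantile Degree quantile defining the hub set (default 0.9).
#' @return List: `hub_cut`, `hub_mean`, `hub_sem`, `hub_n`,
#'   `intermediate_max_mean`, `intermediate_sem`, `intermediate_bin`
#'   (`c(low, high)`), `separation_sems` (positive when hubs dissipate
#'   faster than the best intermediate bin).
#' @export
hub_vs_intermediate <- function(result, hub_quantile = 0.9) {
  stopifnot(inherits(result, "empirical_idt"))
  u <- result$units
  cut <- stats::quantile(u$degree, hub_quantile, names = FALSE)
  hubs <- u$degree >= cut
  if (!any(hubs) || all(hubs)) stop("degenerate hub cut")
  hv <- u$d_i_sweeps[hubs]
  inter <- result$bins[result$bins$degree_bin_high < cut &
                         result$bins$n_units >= 2L, , drop = FALSE]
  if (nrow(inter) == 0L) stop("no intermediate bins below the hub cut")
  b <- inter[which.max(inter$mean_d), ]
  hub_mean <- mean(hv)
  hub_sem <- stats::sd(hv) / sqrt(length(hv))
  list(hub_cut = cut, hub_mean = hub_mean, hub_sem = hub_sem,
       hub_n = length(hv),
       intermediate_max_mean = b$mean_d, intermediate_sem = b$sem_d,
       intermediate_bin = c(b$degree_bin_low, b$degree_bin_high),
       separation_sems = (b$mean_d - hub_mean) /
         sqrt(hub_sem^2 + b$sem_d^2))
}

#' Write empirical IDT results plus parameter sidecar
#'
#' Writes the per-unit table (`unit_id`, `degree`, `d_i_sweeps`,
#' `reliable_flag`; ids 0-based in the file), the per-bin table and a JSON
#' sidecar of all run parameters.
#'
#' @param result An `empirical_idt` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_empirical_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  units <- result$units
  units$unit_id <- units$unit_id - 1L
  utils::write.csv(units, file.path(dir, "idt_per_unit.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$bins, file.path(dir, "idt_per_degree_bin.csv"),
                   row.names = FALSE, quote = FALSE)
  rp <- attr(result, "run_params")
  if (!is.null(rp))
    jsonlite::write_json(rp, file.path(dir, "run_params.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
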