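# build a noiseless mi_decay_curve object directly for estimator tests
synthetic_curve <- function(info, prior = 1, n_series = 1e4) {
  structure(list(unit_id = 1L, lags = seq_along(info) - 1L,
                 info_bits = info, prior_entropy_bits = prior,
                 n_series = n_series, n_floored = 0L),
            class = "mi_decay_curve")
}

test_that("the conditioned ensemble anchors at the reference state and is reproducible", {
  net <- make_path_network(4)
  dp <- dynamics_params(3, rule = "glauber", seed = 31L)
  ens <- conditioned_ensemble(net, dp, n_series = 200, tau_max = 5)
  # lag 0: every sample equals the reference state exactly
  expect_identical(ens$plus_counts[, 1],
                   ifelse(ens$reference_state == 1L, 200L, 0L))
  ens2 <- conditioned_ensemble(net, dp, n_series = 200, tau_max = 5)
  expect_identical(ens$plus_counts, ens2$plus_counts)
  expect_identical(ens$reference_state, ens2$reference_state)
  expect_error(conditioned_ensemble(net, dp, n_series = 10, tau_max = 5),
               "n_series")
  expect_error(conditioned_ensemble(net, dp, n_series = 200, tau_max = 0),
               "tau_max")
})

test_that("lag-tau conditionals match exact transition-matrix powers on a tiny chain", {
  net <- make_path_network(2)
  dp <- dynamics_params(2, rule = "glauber", seed = 8L)
  ens <- conditioned_ensemble(net, dp, n_series = 20000, tau_max = 6,
                              count_states = TRUE)
  P_sweep <- matrix_power(update_transition_matrix(net, dp), net$n_units)
  a <- state_index(ens$reference_state)
  row <- diag(4)[a, ]
  for (tau in 1:6) {
    row <- row %*% P_sweep
    emp <- ens$state_counts[, tau + 1] / ens$n_series
    expect_lt(tv_distance(as.numeric(row), emp), 0.03)
  }
})

test_that("decay curves start at the prior entropy and vanish under fast mixing", {
  net <- make_path_network(4)
  dp <- dynamics_params(30, rule = "metropolis", seed = 5L)
  ens <- conditioned_ensemble(net, dp, n_series = 4000, tau_max = 8)
  prior <- equilibrium_samples(net, dp, n_samples = 4000,
                               burn_in_sweeps = 200)
  cv <- mi_decay_curve(ens, 2L, prior)
  expect_true(all(cv$info_bits >= 0))
  expect_equal(cv$info_bits[1], cv$prior_entropy_bits, tolerance = 1e-12)
  # at T = 30 the chain mixes within a sweep or two
  expect_lt(max(cv$info_bits[5:9]), 0.02)
  expect_error(mi_decay_curve(ens, 2L, NULL), "prior")
})

test_that("the regression recovers exact exponential crossings", {
  # info(tau) = 2^-tau, eps = 2^-5  ->  d = 5
  cv <- synthetic_curve(2^-(0:8))
  est <- estimate_idt(cv, 2^-5)
  expect_equal(est$d_i, 5, tolerance = 1e-10)
  expect_true(est$reliable)
  # scale equivariance: multiplying the curve by c shifts d by log2(c)/(-slope)
  cv4 <- synthetic_curve(4 * 2^-(0:8))
  expect_equal(estimate_idt(cv4, 2^-5)$d_i, 7, tolerance = 1e-10)
  # a curve entirely below eps has already dissipated
  low <- synthetic_curve(rep(1e-4, 6))
  expect_equal(estimate_idt(low, 0.01)$d_i, 0)
  expect_true(estimate_idt(low, 0.01)$reliable)
  # fewer than 3 usable lags is flagged, not silently trusted
  sparse <- synthetic_curve(c(0.5, 0.001, 0.001, 0.001))
  est_sparse <- estimate_idt(sparse, 0.01, noise_floor = 0.002)
  expect_false(est_sparse$reliable)
  # a non-decaying curve is right-censored at the window, flagged
  flat <- synthetic_curve(rep(0.4, 6))
  est_flat <- estimate_idt(flat, 0.01)
  expect_false(est_flat$reliable)
  expect_lte(est_flat$d_i, 10 * 5)
})

test_that("noisy exponential curves are recovered within a few percent", {
  set.seed(21)
  errs <- replicate(300, {
    decay <- 0.5          # bits of log-decay per sweep
    d_true <- stats::runif(1, 4, 12)
    lags <- 0:15
    info <- 2^(-decay * (lags - d_true) + log2(0.01)) *
      exp(stats::rnorm(length(lags), 0, 0.1))
    est <- estimate_idt(synthetic_curve(info), 0.01)
    abs(est$d_i - d_true) / d_true
  })
  expect_lt(stats::median(errs), 0.05)
})

test_that("degree aggregation reports means, SEMs and counts per bin", {
  expect_error(aggregate_by_degree(numeric(0), integer(0)), "no per-unit")
  # identical d everywhere: SEM 0 in every multi-unit bin
  res <- aggregate_by_degree(rep(2, 10), rep(c(1L, 3L), 5))
  expect_true(all(res$bins$sem_d == 0))
  expect_equal(res$bins$n_units, c(5L, 5L))
  # single unit in a bin: mean reported, SEM suppressed
  res1 <- aggregate_by_degree(c(1, 2, 3), c(1L, 1L, 4L))
  row4 <- res1$bins[res1$bins$degree_bin_low == 4L, ]
  expect_equal(row4$mean_d, 3)
  expect_true(is.na(row4$sem_d))
  # heavy tail: log-spaced bins above the exact range cover max degree
  set.seed(2)
  degs <- sample_power_law_degrees(400, 1.6, 1, 150)
  res2 <- aggregate_by_degree(stats::runif(400), as.integer(degs))
  expect_gte(max(res2$bins$degree_bin_high), max(degs))
  expect_equal(sum(res2$bins$n_units), 400L)
})

test_that("the noise floor scales down with sample size", {
  set.seed(3)
  prior <- matrix(sample(c(-1L, 1L), 4000, TRUE), ncol = 2)
  f_small <- mi_noise_floor(prior, 1L, 500)
  f_large <- mi_noise_floor(prior, 1L, 50000)
  expect_gt(f_small, f_large)
  expect_gt(f_small, 0)
})

test_that("results files carry per-unit and per-bin tables plus parameters", {
  res <- aggregate_by_degree(c(1, 2, 2, 5), c(1L, 1L, 2L, 3L),
                             reliable = c(TRUE, TRUE, FALSE, TRUE))
  attr(res, "run_params") <- list(seed = 1L, epsilon_bits = 0.01)
  d <- withr::local_tempdir()
  write_empirical_results(res, d)
  per_unit <- read.csv(file.path(d, "idt_per_unit.csv"))
  expect_identical(names(per_unit),
                   c("unit_id", "degree", "d_i_sweeps", "reliable_flag"))
  expect_identical(per_unit$unit_id, 0:3)
  side <- jsonlite::read_json(file.path(d, "run_params.json"))
  expect_equal(side$epsilon_bits, 0.01)
})
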