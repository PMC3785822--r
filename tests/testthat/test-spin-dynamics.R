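test_that("local energy follows the ferromagnetic form", {
  expect_identical(local_energy(1, c(1, 1), 1), -2)
  expect_identical(local_energy(-1, c(1, -1), 1), 0)
  expect_identical(local_energy(1, integer(0)), 0)   # no neighbours
  # exchange symmetry: only the neighbour-state distribution matters
  nb <- c(1, -1, -1, 1, 1)
  expect_identical(local_energy(-1, nb, 2), local_energy(-1, rev(nb), 2))
  expect_error(local_energy(0, c(1)), "state")
})

test_that("Gibbs transition probabilities are the two-state Boltzmann ratio", {
  p_hot <- gibbs_transition_probs(c(1, 1, 1), dynamics_params(1e9))
  expect_equal(unname(p_hot), c(0.5, 0.5), tolerance = 1e-8)
  p_iso <- gibbs_transition_probs(integer(0), dynamics_params(2))
  expect_equal(unname(p_iso), c(0.5, 0.5))
  # neighbours {+1,+1}, J=1, T=2 -> P(+1) = e^1 / (e^1 + e^-1)
  p <- gibbs_transition_probs(c(1, 1), dynamics_params(2))
  expect_equal(p[["+1"]], exp(1) / (exp(1) + exp(-1)), tolerance = 1e-14)
  expect_error(dynamics_params(0), "temperature")
})

test_that("single-step updates respect limits and preconditions", {
  net <- make_star_network(3)
  dp_cold <- dynamics_params(1e-6)
  cfg <- spin_configuration(c(-1, 1, 1, 1))
  set.seed(5)
  # T -> 0 with a positive local field: hub aligns almost surely
  for (i in 1:20) {
    out <- glauber_step(cfg, 1L, net, dp_cold)
    expect_identical(out[1], 1L)
    expect_identical(out[-1], cfg[-1])  # single-site update
  }
  expect_error(glauber_step(cfg, 9L, net, dp_cold), "site")
  expect_error(metropolis_step(cfg[-1], 1L, net, dp_cold), "length")
  # Metropolis accepts any non-increasing-energy flip with probability 1
  out <- metropolis_step(spin_configuration(c(-1, 1, 1, 1)), 1L, net, dp_cold)
  expect_identical(out[1], 1L)   # dE < 0
  net2 <- make_path_network(3)
  out2 <- metropolis_step(spin_configuration(c(1, 1, -1)), 2L, net2, dp_cold)
  expect_identical(out2[2], -1L) # dE = 0: still always accepted
})

test_that("detailed balance holds analytically for every local field", {
  # pi(a) P(a->b) = pi(b) P(b->a) for single flips, per field value h
  for (Tt in c(0.7, 2, 9)) {
    dp <- dynamics_params(Tt)
    for (h in -6:6) {
      # ratio of Gibbs weights of (s=+1) vs (s=-1) given field h: exp(2Jh/T)
      w_ratio <- exp(2 * h / Tt)
      # Glauber: pi(+) P(+ -> -) = pi(-) P(- -> +)
      pr <- gibbs_transition_probs(rep(1L, abs(h)) * sign(h), dp)
      expect_equal(w_ratio * pr[["-1"]], pr[["+1"]], tolerance = 1e-12)
      # Metropolis: flip prob from +1 has dE = 2h, from -1 has dE = -2h
      f_from_plus <- min(1, exp(-2 * h / Tt))
      f_from_minus <- min(1, exp(2 * h / Tt))
      expect_equal(w_ratio * f_from_plus, f_from_minus, tolerance = 1e-12)
    }
  }
})

test_that("chains are reproducible and obey the run contract", {
  net <- make_path_network(6)
  dp <- dynamics_params(2, rule = "metropolis", seed = 77L)
  t1 <- run_chain(net, dp, 50)
  t2 <- run_chain(net, dp, 50)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_error(run_chain(net, dp, 0), "n_steps")
  expect_error(run_chain(net, dp, 10, init = rep(1L, 3)), "length")
  # consecutive snapshots at stride 1 differ in at most n_units sites (sweep)
  expect_true(all(t1$snapshots %in% c(-1L, 1L)))
})

test_that("negating the start state yields the bit-exact negated trajectory", {
  net <- make_star_network(5)
  init <- spin_configuration(c(1, -1, 1, 1, -1, 1))
  for (rule in c("glauber", "metropolis")) {
    dp <- dynamics_params(1.5, rule = rule)
    set.seed(42); a <- run_chain(net, dp, 40, init = init)
    set.seed(42); b <- run_chain(net, dp, 40,
                                 init = spin_configuration(-as.integer(init)))
    expect_identical(b$snapshots, -a$snapshots)
  }
})

test_that("magnetization vanishes at high temperature", {
  set.seed(9)
  degs <- sample_power_law_degrees(200, 1.6)
  net <- build_configuration_graph(degs)
  dp <- dynamics_params(14, rule = "metropolis")
  traj <- run_chain(net, dp, 600)
  m <- rowMeans(traj$snapshots[101:600, ])
  sem <- stats::sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m)), 3 * max(sem, 0.02))
})

test_that("long-run frequencies match the exact Gibbs distribution on a tiny chain", {
  net <- make_path_network(2)
  dp <- dynamics_params(2, rule = "glauber", seed = 4L)
  freq <- state_frequencies(net, dp, 1e5, burn_in_sweeps = 200)
  expect_lt(tv_distance(freq, boltzmann_probs(net, 2)), 0.02)
})

test_that("trajectory files are written in both layouts", {
  net <- make_triangle_network()
  dp <- dynamics_params(3, seed = 2L)
  traj <- run_chain(net, dp, 10)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, f1, "long")
  write_trajectory(traj, f2, "matrix")
  long <- read.csv(f1)
  expect_identical(names(long), c("sweep", "unit_id", "state"))
  expect_identical(nrow(long), 30L)
  wide <- read.csv(f2)
  expect_identical(nrow(wide), 10L)
  expect_identical(ncol(wide), 4L)
})
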