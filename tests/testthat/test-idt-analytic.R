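params_for <- function(Tt, m = 0, dist = power_law_distribution(1.6, 1, 30),
                       eps = 1e-3, c_eff = 1) {
  analytic_idt_params(dist, dynamics_params(Tt), epsilon_bits = eps,
                      c_eff = c_eff, neighbor_magnetization = m)
}

test_that("T(k) equals brute-force enumeration and decreases in k", {
  for (Tt in c(2, 2.5, 9)) for (m in c(0, 0.6)) {
    ap <- params_for(Tt, m)
    ks <- 1:10
    fast <- neighbor_transmission_info(ks, ap)
    slow <- neighbor_transmission_info_bruteforce(ks, ap)
    expect_lt(max(abs(fast - slow)), 1e-12)
    expect_true(all(diff(fast) < 0))           # strictly decreasing
    expect_true(all(fast >= 0 & fast <= 1))    # at most the unit entropy
  }
})

test_that("T(k) has sane limits", {
  hot <- params_for(1e8)
  expect_lt(max(neighbor_transmission_info(1:10, hot)), 1e-12)
  # k = 1, J = 1, T = 2: MI of the 2x2 joint built from the logistic
  # transition probability, enumerated by hand
  ap <- params_for(2)
  p <- stats::plogis(2 * 1 / 2)   # P(next = +1 | source = +1)
  joint <- 0.5 * rbind(c(p, 1 - p), c(1 - p, p))
  expect_equal(neighbor_transmission_info(1, ap), mutual_information(joint),
               tolerance = 1e-13)
  expect_error(neighbor_transmission_info(0, ap), "k_neighbor")
})

test_that("expected transmission is the excess-degree average", {
  reg <- analytic_idt_params(degree_distribution(4L, 1), dynamics_params(2),
                             neighbor_magnetization = 0)
  expect_equal(expected_transmission(reg),
               neighbor_transmission_info(4, reg), tolerance = 1e-14)
  two <- analytic_idt_params(degree_distribution(c(1L, 3L), c(0.5, 0.5)),
                             dynamics_params(2), neighbor_magnetization = 0)
  tv <- neighbor_transmission_info(c(1L, 3L), two)
  expect_equal(expected_transmission(two), 0.25 * tv[1] + 0.75 * tv[2],
               tolerance = 1e-14)
})

test_that("initial information scales with k and is capped by the unit entropy", {
  ap <- params_for(2)
  tbar <- expected_transmission(ap)
  i1 <- initial_information(1, ap)
  expect_equal(as.numeric(i1), tbar, tolerance = 1e-14)
  i10 <- initial_information(10, ap)
  if (!attr(i10, "capped"))
    expect_equal(as.numeric(i10) / as.numeric(i1), 10, tolerance = 1e-12)
  for (k in c(1, 5, 20, 30))
    expect_lte(as.numeric(initial_information(k, ap)), 1 + 1e-12)
  # symmetric environment: cap is exactly 1 bit at every degree
  expect_equal(unit_state_entropy(c(1, 7, 30), ap), rep(1, 3))
  # magnetized environment: the unit entropy shrinks with degree
  apm <- params_for(2, m = 0.8)
  ents <- unit_state_entropy(c(1, 5, 15, 30), apm)
  expect_true(all(diff(ents) < 0))
})

test_that("dissipation ratio composes the verified pieces and flags degeneracy", {
  dist <- degree_distribution(c(1L, 3L), c(0.5, 0.5))
  ap <- analytic_idt_params(dist, dynamics_params(2), c_eff = 0.5,
                            neighbor_magnetization = 0)
  tv <- neighbor_transmission_info(c(1L, 3L), ap)
  # q(0) = 1/4 contributes m = 0; q(2) = 3/4 contributes 2 T(3); H(s) = 1 bit
  expect_equal(dissipation_ratio(ap),
               0.5 * min(1, 0.75 * 2 * tv[2]), tolerance = 1e-13)
  expect_error(dissipation_ratio(params_for(Inf)), "degenerate")
  # deterministic-copying limit: the relay sum (m+1 - 1) * T(m+1) saturates
  # because each extra neighbour dilutes the per-edge channel, so r plateaus
  # strictly below 1 even at T -> 0
  plateau <- vapply(c(16L, 64L, 150L), function(deg) {
    cold <- analytic_idt_params(degree_distribution(deg, 1),
                                dynamics_params(0.05),
                                neighbor_magnetization = 0)
    dissipation_ratio(cold)
  }, numeric(1))
  expect_true(all(plateau > 0.4 & plateau < 0.5))
  expect_true(all(diff(plateau) > 0))   # converges upward to the plateau
})

test_that("the IDT curve is the affine-log transform of the initial information", {
  ap <- params_for(2.5, m = "equilibrium")
  cv <- idt_curve(1:30, ap)
  r <- attr(cv, "dissipation_ratio")
  # order preserved between I_k(1) and D(k) (weakly, since D is clamped at 0
  # once I_k(1) falls below epsilon)
  expect_false(is.unsorted(cv$D_k_steps[order(cv$I_k1_bits)]))
  # doubling epsilon lowers every positive D by exactly log2(2)/(-log2 r)
  ap2 <- analytic_idt_params(ap$degree_distribution, ap$dynamics,
                             epsilon_bits = 2e-3,
                             neighbor_magnetization = ap$neighbor_magnetization)
  cv2 <- idt_curve(1:30, ap2)
  pos <- cv$D_k_steps > 0 & cv2$D_k_steps > 0
  shift <- 1 / (-log2(r))
  expect_equal(cv$D_k_steps[pos] - cv2$D_k_steps[pos],
               rep(shift, sum(pos)), tolerance = 1e-10)
  # epsilon equal to I_k(1) at some degree puts that degree exactly at D = 0
  ap0 <- analytic_idt_params(ap$degree_distribution, ap$dynamics,
                             epsilon_bits = cv$I_k1_bits[3],
                             neighbor_magnetization = ap$neighbor_magnetization)
  cv0 <- idt_curve(1:30, ap0)
  expect_equal(cv0$D_k_steps[3], 0)
  # epsilon above every I_k(1): error listing the feasible range
  expect_error(idt_curve(1:30, analytic_idt_params(
    ap$degree_distribution, ap$dynamics, epsilon_bits = 2,
    neighbor_magnetization = 0)), "feasible")
})

test_that("the analytic curve peaks at an intermediate degree", {
  dist <- power_law_distribution(1.6, 1, 77)
  ap <- analytic_idt_params(dist, dynamics_params(2.5), epsilon_bits = 1e-3)
  cv <- idt_curve(1:77, ap)
  am <- which.max(cv$D_k_steps)
  expect_gt(am, 1)
  expect_lt(am, 77)
  expect_lt(cv$D_k_steps[77], cv$D_k_steps[am])
})

test_that("transmission decay converges downward, matching brute force", {
  for (Tt in c(2, 9)) {
    ap <- params_for(Tt)
    prof <- transmission_decay_profile(1:15, ap)
    expect_true(all(prof$decrement >= 0))
    expect_true(all(diff(prof$decrement) <= 0))
    expect_lt(max(abs(prof$T_bits -
                        neighbor_transmission_info_bruteforce(1:15, ap))),
              1e-12)
  }
  hot <- transmission_decay_profile(1:5, params_for(1e8))
  expect_lt(max(abs(hot$decrement)), 1e-12)
  expect_error(transmission_decay_profile(1:2, params_for(2)), "3 points")
})

test_that("the cavity magnetization solver finds the ordered and disordered phases", {
  dist <- power_law_distribution(1.6, 1, 77)
  th_cold <- solve_neighbor_magnetization(dist, dynamics_params(2))
  th_hot <- solve_neighbor_magnetization(dist, dynamics_params(50))
  expect_gt(th_cold, 0.5)
  expect_equal(th_hot, 0)
  # regular lattice-like ensemble: known mean-field ordering around T ~ q J
  reg <- degree_distribution(4L, 1)
  expect_gt(solve_neighbor_magnetization(reg, dynamics_params(1)), 0.8)
  expect_equal(solve_neighbor_magnetization(reg, dynamics_params(10)), 0)
})

test_that("IDT curve files carry the parameter sidecar", {
  ap <- params_for(2.5)
  cv <- idt_curve(1:20, ap)
  f <- withr::local_tempfile(fileext = ".csv")
  write_idt_curve(cv, f)
  back <- read.csv(f)
  expect_identical(names(back), c("k", "I_k1_bits", "D_k_steps"))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$epsilon_bits, 1e-3)
  expect_equal(side$temperature, 2.5)
})
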