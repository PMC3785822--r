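#' Parameters of the analytic IDT pipeline
#'
#' Bundles everything the analytic information-dissipation-time (IDT)
#' calculation needs: the degree distribution of the ensemble, the spin
#' dynamics, the information floor, the relay efficiency, the uniqueness
#' discount and the assumed marginal of neighbour states.
#'
#' The neighbour-state marginal matters: every transmission term treats the
#' other neighbour states as i.i.d. `{-1, +1}` variables with mean
#' `neighbor_magnetization`. The default `"equilibrium"` solves the
#' heterogeneous mean-field (cavity) fixed point of the ensemble at the given
#' temperature, so that the marginal fed into the transmission terms is the
#' one the dynamics itself would produce; passing `0` instead uses the
#' maximum-entropy symmetric marginal.
#'
#' @param degree_distribution A [degree_distribution()] of kind `"degree"`.
#' @param dynamics A [dynamics_params()].
#' @param epsilon_bits Information floor `eps` in bits, `0 < eps < 1`.
#' @param c_eff Relay efficiency factor in `(0, 1]`: the fraction of
#'   already-relayed information passed on per hop beyond the first.
#' @param uniqueness `"upper-bound-1"` (no overlap between neighbours,
#'   `U(k) = 1`) or a function `k -> U(k)` with values in `[0, 1]`.
#' @param neighbor_magnetization `"equilibrium"` (default) or a number in
#'   `[-1, 1]`.
#' @return Object of class `analytic_idt_params`; the resolved magnetization
#'   is stored in `$neighbor_magnetization`.
#' @export
analytic_idt_params <- function(degree_distribution, dynamics,
                                epsilon_bits = 1e-3, c_eff = 1,
                                uniqueness = "upper-bound-1",
                                neighbor_magnetization = "equilibrium") {
  stopifnot(inherits(degree_distribution, "degree_distribution"),
            inherits(dynamics, "dynamics_params"))
  if (!(epsilon_bits > 0)) stop("epsilon_bits must be > 0")
  if (!(c_eff > 0 && c_eff <= 1)) stop("c_eff must be in (0, 1]")
  if (identical(uniqueness, "upper-bound-1")) {
    u_fun <- function(k) rep(1, length(k))
  } else if (is.function(uniqueness)) {
    u_fun <- uniqueness
  } else stop("uniqueness must be \"upper-bound-1\" or a function of k")
  if (identical(neighbor_magnetization, "equilibrium")) {
    m <- solve_neighbor_magnetization(degree_distribution, dynamics)
  } else {
    m <- neighbor_magnetization
    if (!is.numeric(m) || length(m) != 1L || abs(m) > 1)
      stop("neighbor_magnetization must be \"equilibrium\" or in [-1, 1]")
  }
  structure(list(degree_distribution = degree_distribution,
                 dynamics = dynamics, epsilon_bits = epsilon_bits,
                 c_eff = c_eff, uniqueness = u_fun,
                 uniqueness_mode = if (is.function(uniqueness))
                   "user" else "upper-bound-1",
                 neighbor_magnetization = m),
            class = "analytic_idt_params")
}

#' Self-consistent neighbour magnetization
#'
#' Fixed point of the cavity (heterogeneous mean-field) recursion on the
#' excess degree distribution: the mean state `theta` of a unit reached by a
#' random edge solves
#' `theta = sum_m q(m) E[tanh(J * h / T)]` with `h` the sum of `m` i.i.d.
#' `{-1, +1}` neighbour states of mean `theta`. On a locally tree-like
#' network this is the equilibrium edge magnetization under the same
#' independence assumption the transmission terms use. Returns 0 in the
#' disordered phase.
#'
#' @param degree_distribution A [degree_distribution()] of kind `"degree"`.
#' @param dynamics A [dynamics_params()].
#' @param tol Fixed-point tolerance.
#' @param max_iter Iteration cap.
#' @return Magnetization in `[0, 1]`.
#' @export
solve_neighbor_magnetization <- function(degree_distribution, dynamics,
                                         tol = 1e-12, max_iter = 10000L) {
  q <- excess_degree_distribution(degree_distribution)
  J <- dynamics$coupling; Temp <- dynamics$temperature
  step <- function(theta) {
    p_up <- (1 + theta) / 2
    sum(vapply(seq_along(q$support), function(i) {
      m <- q$support[i]
      if (m == 0L) return(0)
      a <- 0:m
      sum(stats::dbinom(a, m, p_up) * tanh(J * (2 * a - m) / Temp)) * q$probs[i]
    }, numeric(1)))
  }
  theta <- 1
  for (it in seq_len(max_iter)) {
    new <- step(theta)
    if (abs(new - theta) < tol) break
    theta <- new
  }
  if (theta < 1e-8) 0 else theta
}

# P(next state = +1) of a unit under the Gibbs update given summed field h
.p_plus_given_field <- function(h, J, Temp) stats::plogis(2 * J * h / Temp)

# guard against 1e-16-scale overshoot when summing binomial weights
.clamp01 <- function(p) pmin(1, pmax(0, p))

#' Per-edge transmission information T(k)
#'
#' Mutual information (bits) between a unit's current state and the next
#' state of a neighbour of degree `k_neighbor`: the unit's state has a
#' uniform prior, the neighbour's other `k_neighbor - 1` neighbour states are
#' i.i.d. with mean `neighbor_magnetization`, and the neighbour updates by
#' the Gibbs rule. Computed exactly by summing the binomial distribution of
#' the remaining field, so the cost is linear in `k_neighbor` rather than
#' `2^k`.
#'
#' @param k_neighbor Neighbour degree, integer `>= 1` (vectorized).
#' @param params An [analytic_idt_params()].
#' @return Transmission information in bits.
#' @export
neighbor_transmission_info <- function(k_neighbor, params) {
  stopifnot(inherits(params, "analytic_idt_params"))
  if (any(k_neighbor < 1) || any(k_neighbor != round(k_neighbor)))
    stop("k_neighbor must be an integer >= 1")
  J <- params$dynamics$coupling
  Temp <- params$dynamics$temperature
  p_up <- (1 + params$neighbor_magnetization) / 2
  vapply(as.integer(k_neighbor), function(k) {
    a <- 0:(k - 1L)
    w <- stats::dbinom(a, k - 1L, p_up)
    rest <- 2 * a - (k - 1L)
    p_plus_given <- function(s)
      .clamp01(sum(w * .p_plus_given_field(s + rest, J, Temp)))
    joint <- 0.5 * rbind(c(1 - p_plus_given(-1), p_plus_given(-1)),
                         c(1 - p_plus_given(+1), p_plus_given(+1)))
    max(0, mutual_information(joint))
  }, numeric(1))
}

#' Brute-force transmission information
#'
#' Same quantity as [neighbor_transmission_info()] but by exhaustive
#' enumeration of all `2^(k-1)` configurations of the neighbour's other
#' neighbours; independent oracle for the binomial-sum evaluation
#' (`k <= 20`).
#'
#' @inheritParams neighbor_transmission_info
#' @return Transmission information in bits.
#' @export
neighbor_transmission_info_bruteforce <- function(k_neighbor, params) {
  stopifnot(inherits(params, "analytic_idt_params"))
  J <- params$dynamics$coupling
  Temp <- params$dynamics$temperature
  p_up <- (1 + params$neighbor_magnetization) / 2
  vapply(as.integer(k_neighbor), function(k) {
    if (k > 20L) stop("brute force limited to k <= 20")
    others <- if (k == 1L) matrix(0, 1, 0) else
      as.matrix(expand.grid(rep(list(c(-1, 1)), k - 1L)))
    w <- apply(others, 1, function(r)
      prod(ifelse(r == 1, p_up, 1 - p_up)))
    if (k == 1L) w <- 1
    p_plus_given <- function(s)
      .clamp01(sum(w * .p_plus_given_field(s + rowSums(others), J, Temp)))
    joint <- 0.5 * rbind(c(1 - p_plus_given(-1), p_plus_given(-1)),
                         c(1 - p_plus_given(+1), p_plus_given(+1)))
    max(0, mutual_information(joint))
  }, numeric(1))
}

#' Excess-degree-averaged transmission
#'
#' `sum_m q(m) T(m + 1)`: the expected per-edge transmission information
#' into a random neighbour, with neighbour degrees weighted by the excess
#' degree distribution `q` (neighbour degrees are size-biased and do not
#' depend on the unit's own degree).
#'
#' @param params An [analytic_idt_params()].
#' @return Expected transmission in bits.
#' @export
expected_transmission <- function(params) {
  stopifnot(inherits(params, "analytic_idt_params"))
  q <- excess_degree_distribution(params$degree_distribution)
  sum(q$probs * neighbor_transmission_info(q$support + 1L, params))
}

#' Equilibrium entropy of a degree-k unit
#'
#' Entropy (bits) of the state of a unit with `k` neighbours whose states
#' are i.i.d. with mean `neighbor_magnetization`, after a Gibbs update to
#' that neighbourhood. Equals 1 bit for all `k` in the symmetric
#' (zero-magnetization) case and shrinks with `k` in a magnetized
#' environment, where a hub's state is slaved to its large aligned field.
#'
#' @param k Unit degree, integer `>= 0` (vectorized; `k = 0` gives 1 bit).
#' @param params An [analytic_idt_params()].
#' @return Entropy in bits.
#' @export
unit_state_entropy <- function(k, params) {
  stopifnot(inherits(params, "analytic_idt_params"))
  J <- params$dynamics$coupling
  Temp <- params$dynamics$temperature
  p_up <- (1 + params$neighbor_magnetization) / 2
  vapply(as.integer(k), function(kk) {
    if (kk == 0L) return(1)
    a <- 0:kk
    w <- stats::dbinom(a, kk, p_up)
    .h2(.clamp01(sum(w * .p_plus_given_field(2 * a - kk, J, Temp))))
  }, numeric(1))
}

#' Initial information of a degree-k unit, I_k(1)
#'
#' The information about a unit's current state held one step later by the
#' next states of its `k` neighbours. By conditional independence of the
#' neighbour next-states given the unit's state, it is bounded by the sum of
#' the per-edge transmissions, giving
#' `I_k(1) = U(k) * k * expected_transmission`, and it can never exceed the
#' unit's own state entropy, at which the value is capped (1 bit for
#' symmetric binary units).
#'
#' @param k Unit degree, integer `>= 1` (vectorized).
#' @param params An [analytic_idt_params()].
#' @return Information in bits, with attribute `"capped"` flagging degrees
#'   where the entropy cap binds.
#' @export
initial_information <- function(k, params) {
  stopifnot(inherits(params, "analytic_idt_params"))
  if (any(k < 1) || any(k != round(k))) stop("k must be an integer >= 1")
  tbar <- expected_transmission(params)
  raw <- params$uniqueness(k) * k * tbar
  cap <- unit_state_entropy(k, params)
  structure(pmin(raw, cap), capped = raw > cap)
}

#' Per-step dissipation ratio
#'
#' Fraction of the information about a unit that the network retains per
#' time step once the information has left the unit's direct neighbourhood:
#' `r = c_eff * min(1, <m T(m+1)>_q / H(s))`, where `<.>_q` averages over the
#' excess degree distribution (a relay node reached by an edge passes the
#' information on through its `m` remaining edges) and `H(s)` is the
#' ensemble-averaged unit entropy. Strictly in `(0, 1]`.
#'
#' @param params An [analytic_idt_params()].
#' @return Retained fraction per step.
#' @export
dissipation_ratio <- function(params) {
  stopifnot(inherits(params, "analytic_idt_params"))
  q <- excess_degree_distribution(params$degree_distribution)
  relay <- sum(q$probs * q$support *
                 neighbor_transmission_info(q$support + 1L, params))
  p <- params$degree_distribution
  h_unit <- sum(p$probs * unit_state_entropy(p$support, params))
  if (relay <= 1e-14 || h_unit <= 0)  # below double-precision MI resolution
    stop("degenerate dynamics: dissipation ratio is 0 (no information is transmitted)")
  params$c_eff * min(1, relay / h_unit)
}

#' Analytic IDT curve over degree
#'
#' Information dissipation time of a degree-k unit: the number of time steps
#' for the information about its instantaneous state to decay from the
#' initial amount `I_k(1)` to the floor `eps` at the constant per-step
#' retention ratio `r`,
#' `D(k) = (log I_k(1) - log eps) / (-log r)`.
#' `D` is an increasing affine transform of `log I_k(1)`, so orderings of
#' degrees by initial information and by dissipation time agree. Degrees
#' whose initial information is already at or below `eps` get `D(k) = 0`.
#'
#' @param degrees Strictly increasing integer degree grid.
#' @param params An [analytic_idt_params()]; `epsilon_bits` must lie below
#'   the largest `I_k(1)` on the grid and the dissipation ratio must be
#'   strictly below 1.
#' @return Object of class `idt_curve`: data frame columns `k`, `I_k1_bits`,
#'   `D_k_steps` plus parameter metadata in attributes.
#' @export
idt_curve <- function(degrees, params) {
  stopifnot(inherits(params, "analytic_idt_params"))
  degrees <- as.integer(degrees)
  if (any(diff(degrees) <= 0)) stop("degrees must be strictly increasing")
  r <- dissipation_ratio(params)
  if (r >= 1)
    stop("dissipation ratio is 1: information is never dissipated and the IDT diverges")
  info <- initial_information(degrees, params)
  eps <- params$epsilon_bits
  if (all(info <= eps))
    stop(sprintf(
      "epsilon_bits = %g is not below any I_k(1); feasible range is (0, %g)",
      eps, max(info)))
  D <- pmax(0, (log2(as.numeric(info)) - log2(eps)) / (-log2(r)))
  out <- data.frame(k = degrees, I_k1_bits = as.numeric(info), D_k_steps = D)
  structure(out, class = c("idt_curve", "data.frame"),
            dissipation_ratio = r, epsilon_bits = eps,
            neighbor_magnetization = params$neighbor_magnetization,
            temperature = params$dynamics$temperature,
            coupling = params$dynamics$coupling,
            c_eff = params$c_eff, uniqueness_mode = params$uniqueness_mode,
            capped = attr(info, "capped"))
}

#' @export
print.idt_curve <- function(x, ...) {
  cat(sprintf(
    "<idt_curve> %d degrees, T = %g, eps = %g bits, r = %.4g, peak D = %.3f at k = %d\n",
    nrow(x), attr(x, "temperature"), attr(x, "epsilon_bits"),
    attr(x, "dissipation_ratio"), max(x$D_k_steps),
    x$k[which.max(x$D_k_steps)]))
  invisible(x)
}

#' @export
plot.idt_curve <- function(x, ...) {
  plot(x$k, x$D_k_steps, type = "b", pch = 16, xlab = "degree k",
       ylab = "D(k) [time steps]", ...)
  invisible(x)
}

#' Downward convergence profile of T(k)
#'
#' Successive decrements of the transmission information towards its
#' large-degree limit, with the limit taken as the value at the largest
#' requested degree (no asymptotic form is assumed). The decrements are
#' nonnegative and non-increasing: T(k) converges downward, never upward.
#'
#' @param k_range Increasing integer degree grid with at least 3 points.
#' @param params An [analytic_idt_params()].
#' @return Data frame with columns `k`, `T_bits`, `decrement`
#'   (`T(k) - T(k_last)`).
#' @export
transmission_decay_profile <- function(k_range, params) {
  k_range <- as.integer(k_range)
  if (length(k_range) < 3L) stop("k_range must have at least 3 points")
  if (any(diff(k_range) <= 0)) stop("k_range must be strictly increasing")
  Tv <- neighbor_transmission_info(k_range, params)
  data.frame(k = k_range, T_bits = Tv, decrement = Tv - Tv[length(Tv)])
}

#' Write an IDT curve plus parameter sidecar
#'
#' CSV columns `(k, I_k1_bits, D_k_steps)` and a JSON sidecar
#' (`<path>.json`) with every parameter that produced the curve.
#'
#' @param curve An [idt_curve()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_idt_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("k", "I_k1_bits", "D_k_steps")],
                   path, row.names = FALSE, quote = FALSE)
  side <- list(epsilon_bits = attr(curve, "epsilon_bits"),
               dissipation_ratio = attr(curve, "dissipation_ratio"),
               neighbor_magnetization = attr(curve, "neighbor_magnetization"),
               temperature = attr(curve, "temperature"),
               coupling = attr(curve, "coupling"),
               c_eff = attr(curve, "c_eff"),
               uniqueness_mode = attr(curve, "uniqueness_mode"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
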