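# Shared helpers: independent oracles and small generators used across files.

# random strictly-positive joint distribution over nx x ny outcomes
random_joint <- function(nx, ny) {
  m <- matrix(stats::rexp(nx * ny) + 1e-3, nx, ny)
  m / sum(m)
}

# closed-form binary entropy
h_b <- function(p) ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))

# joint of a binary symmetric channel with given input bias and flip prob
bsc_joint <- function(p_input = 0.5, flip = 0.25) {
  rbind(c(p_input * (1 - flip), p_input * flip),
        c((1 - p_input) * flip, (1 - p_input) * (1 - flip)))
}

# exact Gibbs distribution by direct Boltzmann summation, written
# independently of gibbs_distribution() (edge loop instead of total_energy)
boltzmann_probs <- function(net, temperature, coupling = 1) {
  st <- enumerate_spin_states(net$n_units)
  w <- apply(st, 1, function(s) {
    e <- 0
    for (r in seq_len(nrow(net$edges)))
      e <- e - coupling * s[net$edges[r, 1]] * s[net$edges[r, 2]]
    exp(-e / temperature)
  })
  w / sum(w)
}

# deterministic small degree distributions for property loops
example_distributions <- function() {
  list(two_point = degree_distribution(c(1L, 3L), c(0.5, 0.5)),
       regular4 = degree_distribution(4L, 1),
       powlaw = power_law_distribution(1.6, 1, 30),
       powlaw_steep = power_law_distribution(2.5, 2, 50))
}
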