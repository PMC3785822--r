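# idtnet — information dissipation time of units in Markov networks

Which units drive the dynamics of a networked system? `idtnet` answers with
an information-theoretic measure: the **information dissipation time (IDT)**
of a unit — the time it takes for the mutual information between the unit's
instantaneous state and the evolving system state to fall below a small
floor ε. Units whose states are quickly forgotten cannot explain the
system's short-term behaviour, however well connected they are. For
Gibbs-measure dynamics on heavy-tailed random networks the IDT turns out to
be non-monotone in degree: it peaks at intermediate connectivity and
*declines for hubs*.

The package is aimed at researchers in systems biology, neuroscience and
network science who study discrete-time Markov networks — binary units
`s_i ∈ {−1,+1}` on an undirected graph, each updating by the Gibbs measure
of its local interaction energy `E(r | ∂i) = −J r Σ_{j∈∂i} s_j` at heat-bath
temperature `T` (the local-thermodynamic-equilibrium picture, with
ferromagnetic Ising spins as the canonical instance).

## What it computes

**Analytic IDT curve.** With `p(k)` the degree distribution and
`q(m) = (m+1)p(m+1)/⟨k⟩` its excess distribution, the per-edge transmission
`T(k)` (mutual information between a unit's state and a degree-`k`
neighbour's next state, computed exactly via the binomial field sum), the
initial information `I_k(1) = U(k)·k·⟨T(m+1)⟩_q` capped at the unit's own
entropy, and the per-step retention
`r = c_eff · min(1, ⟨m·T(m+1)⟩_q / H(s))` combine into

    D(k) = [log I_k(1) − log ε] / [−log r].

**Empirical IDT.** A compiled Glauber / Metropolis–Hastings simulator
generates ensembles of trajectories conditioned on a common reference state
(sampled by time reversal of the stationary chain); per-unit
information-decay curves are regressed on log scale to the ε-crossing `d_i`,
then aggregated by degree with standard errors.

**Infrastructure.** Power-law degree sequences, exact-degree
configuration-model graphs (stub matching + double-edge-swap repair),
exact 2^N Gibbs enumeration oracles for small systems, plug-in (and
Miller–Madow-corrected) entropy/MI estimators, YAML-configured command-line
pipelines.

## Worked example

```r
library(idtnet)
set.seed(7)

## degree law of the reference ensemble: p(k) ~ k^-1.6 on 1..77
dist <- power_law_distribution(1.6, k_min = 1, k_max = 77)
q <- excess_degree_distribution(dist)
cat(sprintf("mean degree %.2f, mean excess degree %.2f\n",
            mean_degree(dist), sum(q$support * q$probs)))
#> mean degree 5.68, mean excess degree 24.64

## analytic IDT curve at T = 2.5 (J = 1)
ap <- analytic_idt_params(dist, dynamics_params(temperature = 2.5),
                          epsilon_bits = 1e-3)
curve <- idt_curve(1:77, ap)
print(curve)
#> <idt_curve> 77 degrees, T = 2.5, eps = 0.001 bits, r = 0.04021, peak D = 1.532 at k = 7
```

The mean excess degree (24.6 ≫ 5.7) shows how strongly neighbour sampling
is size-biased. The curve summary already contains the headline: at
`T = 2.5` the dissipation time peaks at degree 7 — information about a
leaf's state is lost quickly because a leaf imprints on only one neighbour,
and information about a hub's state is lost quickly because a hub, slaved to
its large aligned neighbourhood, has very little state entropy to imprint in
the first place. `D(k)` rises from 0.93 sweeps at `k = 1` to 1.53 at
`k = 7` and falls back below the `k = 1` value by `k = 12`.

```r
## a 500-unit configuration-model realization and a conditioned ensemble
degs <- sample_power_law_degrees(500, gamma = 1.6)
net <- build_configuration_graph(degs)
print(net)
#> <interaction_network> 500 units, 808 edges, degrees 1..22

dp <- dynamics_params(9, rule = "metropolis")
ens <- conditioned_ensemble(net, dp, n_series = 1000, tau_max = 10,
                            burn_in_sweeps = 500)
prior <- equilibrium_samples(net, dp, n_samples = 1000, burn_in_sweeps = 500)
hub <- which.max(net$degrees)
cv <- mi_decay_curve(ens, hub, prior)
est <- estimate_idt(cv, epsilon_bits = 0.01,
                    noise_floor = mi_noise_floor(prior, hub, 1000))
cat(sprintf("hub unit %d (degree %d): d_i = %.2f sweeps (reliable: %s)\n",
            hub, net$degrees[hub], est$d_i, est$reliable))
#> hub unit 23 (degree 22): d_i = 2.28 sweeps (reliable: TRUE)
```

`empirical_idt()` wraps the whole experiment (several network realizations,
noise floors, regression, degree-binned aggregation); `hub_vs_intermediate()`
compares the top-degree-quantile units against the best intermediate degree
bin in units of the joint standard error.

## Command line

A thin front-end over the same functions lives at `inst/cli/idtnet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","idtnet.R",package="idtnet"))')" \
    generate-network --config run.yaml --seed 3 --out out/
```

Subcommands: `generate-network`, `analytic-curve`, `empirical-idt`,
`make-fixtures`. Every run writes its resolved YAML configuration, a JSON
log of seeds and repair counts, and CSV outputs in the documented formats
(0-based edge lists, `k,probability` degree tables, per-unit and per-bin IDT
tables with JSON parameter sidecars).

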