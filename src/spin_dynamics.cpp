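#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-site Markov-network dynamics on a fixed undirected simple graph.
// Adjacency is CSR: adj holds 0-based neighbour ids, offsets has length n+1.
// All randomness comes from R's RNG (RNGScope via Rcpp attributes), so
// set.seed() on the R side makes every run bit-reproducible.

static inline int field_sum(const std::vector<int>& states,
                            const IntegerVector& adj,
                            const IntegerVector& offsets,
                            int site) {
  int h = 0;
  for (int j = offsets[site]; j < offsets[site + 1]; ++j) h += states[adj[j]];
  return h;
}

// Glauber in keep/flip form: P(keep current state) = 1 / (1 + exp(-2 J h s / T)).
// Equivalent to drawing the new state from the local Gibbs conditional, and
// bit-exactly symmetric under a global spin flip (h*s is flip-invariant).
// Metropolis: flip always if dE <= 0, else with prob exp(-dE / T); the uniform
// is only consumed when dE > 0 (dE is flip-invariant, preserving the symmetry).
static inline void update_site(std::vector<int>& states,
                               const IntegerVector& adj,
                               const IntegerVector& offsets,
                               int site, double J, double T, bool metropolis) {
  int h = field_sum(states, adj, offsets, site);
  int s = states[site];
  if (metropolis) {
    double dE = 2.0 * J * s * h;
    if (dE <= 0.0 || R::runif(0.0, 1.0) < std::exp(-dE / T))
      states[site] = -s;
  } else {
    double pkeep = 1.0 / (1.0 + std::exp(-2.0 * J * h * s / T));
    if (R::runif(0.0, 1.0) >= pkeep)
      states[site] = -s;
  }
}

static inline int random_site(int n) {
  int site = (int)(R::unif_rand() * n);
  if (site >= n) site = n - 1;
  return site;
}

// One sweep = n single-site updates. schedule: 0 = random-site (iid uniform
// site choices), 1 = sweep (fresh random permutation of all sites).
static void one_sweep(std::vector<int>& states,
                      const IntegerVector& adj,
                      const IntegerVector& offsets,
                      int n, double J, double T, bool metropolis,
                      int schedule, std::vector<int>& perm) {
  if (schedule == 0) {
    for (int u = 0; u < n; ++u)
      update_site(states, adj, offsets, random_site(n), J, T, metropolis);
  } else {
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates
      int j = (int)(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    for (int u = 0; u < n; ++u)
      update_site(states, adj, offsets, perm[u], J, T, metropolis);
  }
}

// [[Rcpp::export]]
List cpp_run_chain(IntegerVector adj, IntegerVector offsets, IntegerVector init,
                   int n_sweeps, double temperature, double coupling,
                   bool metropolis, int schedule, int record_stride) {
  int n = offsets.size() - 1;
  std::vector<int> states(init.begin(), init.end());
  std::vector<int> perm(n);
  int n_rec = record_stride > 0 ? n_sweeps / record_stride : 0;
  IntegerMatrix snaps(n_rec, n);
  int rec = 0;
  for (int sw = 1; sw <= n_sweeps; ++sw) {
    one_sweep(states, adj, offsets, n, coupling, temperature, metropolis,
              schedule, perm);
    if (record_stride > 0 && sw % record_stride == 0) {
      for (int i = 0; i < n; ++i) snaps(rec, i) = states[i];
      ++rec;
    }
  }
  IntegerVector fin(states.begin(), states.end());
  return List::create(_["snapshots"] = snaps, _["final"] = fin);
}

// Long-run visit counts over all 2^n system states (n <= 25), sampling the
// state once per sweep after burn-in. Used for stationarity checks against
// exact enumeration of the Gibbs distribution.
// [[Rcpp::export]]
NumericVector cpp_state_counts(IntegerVector adj, IntegerVector offsets,
                               IntegerVector init, int n_samples,
                               int burn_in_sweeps, double temperature,
                               double coupling, bool metropolis, int schedule) {
  int n = offsets.size() - 1;
  if (n > 25) stop("state counting only supported for n <= 25 units");
  std::vector<int> states(init.begin(), init.end());
  std::vector<int> perm(n);
  NumericVector counts((R_xlen_t)1 << n);
  for (int sw = 0; sw < burn_in_sweeps; ++sw)
    one_sweep(states, adj, offsets, n, coupling, temperature, metropolis,
              schedule, perm);
  for (int smp = 0; smp < n_samples; ++smp) {
    one_sweep(states, adj, offsets, n, coupling, temperature, metropolis,
              schedule, perm);
    int idx = 0;
    for (int i = 0; i < n; ++i) if (states[i] == 1) idx |= (1 << i);
    counts[idx] += 1.0;
  }
  return counts;
}

// Conditioned trajectory ensemble: n_series independent forward runs started
// at the reference state; the lag-tau snapshot (tau sweeps after the start)
// is the sample of the system state tau sweeps away from the reference.
// Returns per-unit counts of +1 at each lag, and optionally (n <= 20) counts
// over full system states per lag for oracle comparisons on tiny chains.
// [[Rcpp::export]]
List cpp_conditioned_ensemble(IntegerVector adj, IntegerVector offsets,
                              IntegerVector ref, int n_series, int tau_max,
                              double temperature, double coupling,
                              bool metropolis, int schedule,
                              bool count_states) {
  int n = offsets.size() - 1;
  if (count_states && n > 20) stop("state counting only supported for n <= 20");
  IntegerMatrix plus_counts(n, tau_max + 1);
  NumericMatrix state_counts;
  if (count_states) state_counts = NumericMatrix((R_xlen_t)1 << n, tau_max + 1);
  std::vector<int> states(n), perm(n);
  for (int i = 0; i < n; ++i)
    if (ref[i] == 1) plus_counts(i, 0) = n_series;
  if (count_states) {
    int idx0 = 0;
    for (int i = 0; i < n; ++i) if (ref[i] == 1) idx0 |= (1 << i);
    state_counts(idx0, 0) = n_series;
  }
  for (int ser = 0; ser < n_series; ++ser) {
    for (int i = 0; i < n; ++i) states[i] = ref[i];
    for (int tau = 1; tau <= tau_max; ++tau) {
      one_sweep(states, adj, offsets, n, coupling, temperature, metropolis,
                schedule, perm);
      for (int i = 0; i < n; ++i)
        if (states[i] == 1) plus_counts(i, tau) += 1;
      if (count_states) {
        int idx = 0;
        for (int i = 0; i < n; ++i) if (states[i] == 1) idx |= (1 << i);
        state_counts(idx, tau) += 1.0;
      }
    }
    if (ser % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["plus_counts"] = plus_counts,
                      _["state_counts"] = count_states
                          ? (SEXP)state_counts : R_NilValue);
}
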