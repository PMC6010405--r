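#include <Rcpp.h>
using namespace Rcpp;

// Search machinery for weighted bipartite (Barber-type) modularity.
//
// B is the precomputed modularity matrix B_ij = A_ij/F - k_i d_j / F^2
// (plants on rows, visitors on columns); for a partition g of all species,
// Q(g) = sum_{ij : g(plant_i) == g(visitor_j)} B_ij.
//
// Each restart: random initial assignment into K = min(np, nv) labels,
// simulated annealing over single-species relabel moves with geometric
// cooling, then greedy label-switching sweeps to the nearest local optimum.
// Uses R's RNG throughout so results are reproducible under set.seed().

static double full_q(const NumericMatrix &B, const IntegerVector &pm,
                     const IntegerVector &vm) {
  double q = 0.0;
  for (int i = 0; i < B.nrow(); ++i)
    for (int j = 0; j < B.ncol(); ++j)
      if (pm[i] == vm[j]) q += B(i, j);
  return q;
}

// [[Rcpp::export]]
List sa_search(NumericMatrix B, int n_runs, int n_sweeps, double t0,
               double cooling, int max_polish) {
  const int np = B.nrow(), nv = B.ncol(), n = np + nv;
  const int K = std::max(1, std::min(np, nv));

  NumericVector run_scores(n_runs);
  IntegerMatrix run_assign(n_runs, n);

  // per-run working state: module-summed B rows/cols
  NumericMatrix Sp(np, K); // Sp(i,g) = sum_j in module g of B(i,j)
  NumericMatrix Sv(nv, K); // Sv(j,g) = sum_i in module g of B(i,j)
  IntegerVector pm(np), vm(nv);

  for (int run = 0; run < n_runs; ++run) {
    for (int i = 0; i < np; ++i) pm[i] = (int)(unif_rand() * K) % K;
    for (int j = 0; j < nv; ++j) vm[j] = (int)(unif_rand() * K) % K;
    std::fill(Sp.begin(), Sp.end(), 0.0);
    std::fill(Sv.begin(), Sv.end(), 0.0);
    for (int i = 0; i < np; ++i)
      for (int j = 0; j < nv; ++j) {
        Sp(i, vm[j]) += B(i, j);
        Sv(j, pm[i]) += B(i, j);
      }
    double q = 0.0;
    for (int i = 0; i < np; ++i) q += Sp(i, pm[i]);

    // annealing stage
    double T = t0;
    for (int sweep = 0; sweep < n_sweeps; ++sweep) {
      int proposals = 2 * n;
      for (int it = 0; it < proposals; ++it) {
        int s = (int)(unif_rand() * n) % n;
        int g = (int)(unif_rand() * K) % K;
        if (s < np) {
          int old = pm[s];
          if (g == old) continue;
          double d = Sp(s, g) - Sp(s, old);
          if (d > 0 || unif_rand() < std::exp(d / T)) {
            for (int j = 0; j < nv; ++j) {
              Sv(j, old) -= B(s, j);
              Sv(j, g) += B(s, j);
            }
            pm[s] = g;
            q += d;
          }
        } else {
          int jj = s - np;
          int old = vm[jj];
          if (g == old) continue;
          double d = Sv(jj, g) - Sv(jj, old);
          if (d > 0 || unif_rand() < std::exp(d / T)) {
            for (int i = 0; i < np; ++i) {
              Sp(i, old) -= B(i, jj);
              Sp(i, g) += B(i, jj);
            }
            vm[jj] = g;
            q += d;
          }
        }
      }
      T *= cooling;
    }

    // greedy polish: move each species to its best module until stable
    bool moved = true;
    int polish = 0;
    while (moved && polish++ < max_polish) {
      moved = false;
      for (int i = 0; i < np; ++i) {
        int best = pm[i];
        double bv = Sp(i, best);
        for (int g = 0; g < K; ++g)
          if (Sp(i, g) > bv + 1e-13) { bv = Sp(i, g); best = g; }
        if (best != pm[i]) {
          int old = pm[i];
          for (int j = 0; j < nv; ++j) {
            Sv(j, old) -= B(i, j);
            Sv(j, best) += B(i, j);
          }
          q += bv - Sp(i, old);
          pm[i] = best;
          moved = true;
        }
      }
      for (int j = 0; j < nv; ++j) {
        int best = vm[j];
        double bv = Sv(j, best);
        for (int g = 0; g < K; ++g)
          if (Sv(j, g) > bv + 1e-13) { bv = Sv(j, g); best = g; }
        if (best != vm[j]) {
          int old = vm[j];
          for (int i = 0; i < np; ++i) {
            Sp(i, old) -= B(i, j);
            Sp(i, best) += B(i, j);
          }
          q += bv - Sv(j, old);
          vm[j] = best;
          moved = true;
        }
      }
    }

    run_scores[run] = full_q(B, pm, vm); // recompute: avoids drift
    for (int i = 0; i < np; ++i) run_assign(run, i) = pm[i];
    for (int j = 0; j < nv; ++j) run_assign(run, np + j) = vm[j];
  }

  return List::create(_["run_scores"] = run_scores,
                      _["assignments"] = run_assign);
}
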