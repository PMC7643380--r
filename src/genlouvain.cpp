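#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Greedy agglomerative maximization of a (multilayer) modularity quality
// function given its supra-modularity matrix B: Q * 2mu = sum_{ij} B_ij
// delta(g_i, g_j). Standard two-phase Louvain on the supra-node graph:
// phase 1 sweeps nodes in random order taking strictly improving community
// moves; phase 2 aggregates communities into super-nodes and repeats.
//
// move_rule: 0 = "move"    (best strictly improving move, RNG tie-break)
//            1 = "moverandw" (random improving move, probability ~ gain)
//
// Uses R's RNG so set.seed() on the R side makes runs reproducible.

static int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// [[Rcpp::export]]
List genlouvain_cpp(NumericMatrix B, int move_rule, int max_sweeps) {
  const int n0 = B.nrow();
  const double eps = 1e-12;

  std::vector<double> B0(B.begin(), B.end());
  std::vector<double> Bc = B0;
  int ncur = n0;

  std::vector<int> node2cur(n0);
  for (int v = 0; v < n0; ++v) node2cur[v] = v;

  int total_sweeps = 0;
  bool merged = true;

  while (merged) {
    std::vector<int> comm(ncur);
    for (int i = 0; i < ncur; ++i) comm[i] = i;

    std::vector<double> S(ncur);
    std::vector<int> order(ncur);
    bool any_move_this_level = false;
    int moved = 1;
    int sweeps = 0;

    while (moved > 0) {
      if (++sweeps > max_sweeps) {
        stop("genlouvain did not converge within %d sweeps at graph size %d",
             max_sweeps, ncur);
      }
      ++total_sweeps;
      moved = 0;

      for (int i = 0; i < ncur; ++i) order[i] = i;
      for (int i = ncur - 1; i > 0; --i)
        std::swap(order[i], order[rand_below(i + 1)]);

      for (int oi = 0; oi < ncur; ++oi) {
        const int i = order[oi];
        std::fill(S.begin(), S.end(), 0.0);
        const double* rowi = &Bc[(size_t)i * ncur];
        for (int j = 0; j < ncur; ++j)
          if (j != i) S[comm[j]] += rowi[j];
        const double base = S[comm[i]];

        int target = -1;
        if (move_rule == 0) {
          double best = base + eps;
          int nties = 0;
          for (int c = 0; c < ncur; ++c) {
            if (c == comm[i]) continue;
            if (S[c] > best + 1e-14) {
              best = S[c];
              target = c;
              nties = 1;
            } else if (target >= 0 && std::abs(S[c] - best) <= 1e-14) {
              // reservoir tie-break with the run's RNG
              ++nties;
              if (unif_rand() < 1.0 / nties) target = c;
            }
          }
        } else {
          double tot = 0.0;
          for (int c = 0; c < ncur; ++c)
            if (c != comm[i] && S[c] - base > eps) tot += S[c] - base;
          if (tot > 0) {
            double u = unif_rand() * tot, acc = 0.0;
            for (int c = 0; c < ncur; ++c) {
              if (c == comm[i] || S[c] - base <= eps) continue;
              acc += S[c] - base;
              if (u <= acc) { target = c; break; }
            }
            if (target < 0) {  // numerical fallthrough
              for (int c = ncur - 1; c >= 0; --c)
                if (c != comm[i] && S[c] - base > eps) { target = c; break; }
            }
          }
        }

        if (target >= 0) {
          comm[i] = target;
          ++moved;
          any_move_this_level = true;
        }
      }
    }

    // relabel communities 0..K-1
    std::vector<int> relab(ncur, -1);
    int K = 0;
    for (int i = 0; i < ncur; ++i)
      if (relab[comm[i]] < 0) relab[comm[i]] = K++;
    for (int i = 0; i < ncur; ++i) comm[i] = relab[comm[i]];

    for (int v = 0; v < n0; ++v) node2cur[v] = comm[node2cur[v]];

    merged = any_move_this_level && K < ncur;
    if (merged) {
      std::vector<double> Bn((size_t)K * K, 0.0);
      for (int i = 0; i < ncur; ++i)
        for (int j = 0; j < ncur; ++j)
          Bn[(size_t)comm[i] * K + comm[j]] += Bc[(size_t)i * ncur + j];
      Bc.swap(Bn);
      ncur = K;
    }
  }

  // Q numerator recomputed from the original matrix and final assignment
  double qnum = 0.0;
  for (int i = 0; i < n0; ++i) {
    const double* rowi = &B0[(size_t)i * n0];
    for (int j = 0; j < n0; ++j)
      if (node2cur[i] == node2cur[j]) qnum += rowi[j];
  }

  IntegerVector membership(n0);
  for (int v = 0; v < n0; ++v) membership[v] = node2cur[v] + 1;

  return List::create(_["membership"] = membership,
                      _["q_num"] = qnum,
                      _["n_sweeps"] = total_sweeps);
}
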