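#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Louvain-style maximization of the generalized modularity
//   Q = (1/2m) sum_{i != j} (A_ij - gamma * P_ij) delta(g_i, g_j)
// on dense A with a dense, precomputed null matrix P. The null matrix is
// aggregated alongside A between levels (community-pair sums), so the
// objective is preserved exactly across levels; genomic distances never
// have to be re-derived for super-nodes. Node sweep order is a seeded
// shuffle each pass (R's RNG); ties in gain go to the lowest community id.

static void local_move(std::vector<double>& A, std::vector<double>& P,
                       int n, double gamma, std::vector<int>& lab) {
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> w(n);

  // a move of node i changes Q by (w_new - w_old) / m; the pass loop stops
  // once the summed Delta-Q drops below 1e-10
  double m = 0.0;
  for (size_t q = 0; q < A.size(); ++q) m += A[q];
  m /= 2.0;
  if (m <= 0.0) m = 1.0;

  for (;;) {
    // Fisher-Yates with R's RNG for per-seed determinism
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1)) % (i + 1);
      std::swap(order[i], order[j]);
    }
    double total_gain = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = order[t];
      std::fill(w.begin(), w.end(), 0.0);
      const double* Ai = &A[(size_t)i * n];
      const double* Pi = &P[(size_t)i * n];
      for (int j = 0; j < n; ++j)
        if (j != i) w[lab[j]] += Ai[j] - gamma * Pi[j];
      const int ci = lab[i];
      double best_w = w[ci];
      int best_c = ci;
      for (int c = 0; c < n; ++c) {
        if (w[c] > best_w + 1e-12 ||
            (w[c] > best_w - 1e-12 && c < best_c)) {
          best_w = w[c];
          best_c = c;
        }
      }
      if (best_c != ci && best_w - w[ci] > 0) {
        total_gain += best_w - w[ci];
        lab[i] = best_c;
      }
    }
    if (total_gain / m < 1e-10) break;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_louvain(NumericMatrix Ain, NumericMatrix Pin, double gamma) {
  const int n0 = Ain.nrow();
  if (n0 == 0) stop("empty graph");
  std::vector<double> A(Ain.begin(), Ain.end());
  std::vector<double> P(Pin.begin(), Pin.end());
  int n = n0;

  std::vector<int> assign(n0);  // original node -> current super-node
  for (int i = 0; i < n0; ++i) assign[i] = i;

  for (;;) {
    std::vector<int> lab(n);
    for (int i = 0; i < n; ++i) lab[i] = i;
    local_move(A, P, n, gamma, lab);

    // compact community ids
    std::vector<int> remap(n, -1);
    int nc = 0;
    for (int i = 0; i < n; ++i)
      if (remap[lab[i]] < 0) remap[lab[i]] = nc++;
    for (int i = 0; i < n; ++i) lab[i] = remap[lab[i]];
    if (nc == n) break;  // no merge anywhere: done

    for (int i = 0; i < n0; ++i) assign[i] = lab[assign[i]];

    // aggregate A and P over community pairs (diagonal keeps the
    // within-community weight; the fine-level diagonal was zero, so the
    // i != j exclusion stays exact)
    std::vector<double> A2((size_t)nc * nc, 0.0), P2((size_t)nc * nc, 0.0);
    for (int i = 0; i < n; ++i) {
      const int ci = lab[i];
      const double* Ai = &A[(size_t)i * n];
      const double* Pi = &P[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        A2[(size_t)ci * nc + lab[j]] += Ai[j];
        P2[(size_t)ci * nc + lab[j]] += Pi[j];
      }
    }
    A.swap(A2);
    P.swap(P2);
    n = nc;
  }

  IntegerVector out(n0);
  for (int i = 0; i < n0; ++i) out[i] = assign[i];
  return out;
}
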