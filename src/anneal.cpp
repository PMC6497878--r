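#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Off-lattice randomization of a chain under two hard constraints: every
// bond keeps its fixed length (moves are projected onto the feasible circle
// or sphere), and no two monomers approach closer than ev_diam (checked
// against a linked-cell grid). Interior monomers whose neighbours are
// collinear have a degenerate feasible set and are skipped.

struct CellGrid {
  double cell;
  std::unordered_map<long long, std::vector<int> > cells;

  explicit CellGrid(double c) : cell(c) {}

  long long key(double x, double y, double z) const {
    const long long OFF = 1LL << 20;
    long long ix = (long long)std::floor(x / cell) + OFF;
    long long iy = (long long)std::floor(y / cell) + OFF;
    long long iz = (long long)std::floor(z / cell) + OFF;
    return (ix << 42) | (iy << 21) | iz;
  }
  void insert(int i, double x, double y, double z) {
    cells[key(x, y, z)].push_back(i);
  }
  void remove(int i, double x, double y, double z) {
    std::vector<int>& v = cells[key(x, y, z)];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == i) { v[k] = v.back(); v.pop_back(); return; }
  }
};

static bool ev_clear(const CellGrid& g, const std::vector<double>& X,
                     const std::vector<double>& Y, const std::vector<double>& Z,
                     int i, double px, double py, double pz, double ev2) {
  const long long OFF = 1LL << 20;
  const long long cx = (long long)std::floor(px / g.cell) + OFF;
  const long long cy = (long long)std::floor(py / g.cell) + OFF;
  const long long cz = (long long)std::floor(pz / g.cell) + OFF;
  for (long long ax = cx - 1; ax <= cx + 1; ++ax)
    for (long long ay = cy - 1; ay <= cy + 1; ++ay)
      for (long long az = cz - 1; az <= cz + 1; ++az) {
        const long long k = (ax << 42) | (ay << 21) | az;
        std::unordered_map<long long, std::vector<int> >::const_iterator it =
            g.cells.find(k);
        if (it == g.cells.end()) continue;
        const std::vector<int>& v = it->second;
        for (size_t q = 0; q < v.size(); ++q) {
          const int j = v[q];
          if (j == i) continue;
          const double dx = X[j] - px, dy = Y[j] - py, dz = Z[j] - pz;
          if (dx * dx + dy * dy + dz * dz < ev2) return false;
        }
      }
  return true;
}

// [[Rcpp::export]]
List cpp_anneal(NumericMatrix coords, int n_snapshots, double n_moves,
                double disp, double bond, double ev_diam) {
  const int N = coords.nrow();
  std::vector<double> X(N), Y(N), Z(N);
  for (int i = 0; i < N; ++i) {
    X[i] = coords(i, 0);
    Y[i] = coords(i, 1);
    Z[i] = coords(i, 2);
  }
  // ev_diam < bond, so bonded neighbours always satisfy the clearance;
  // only non-bonded pairs can collide, but the grid check covers all pairs
  // anyway because bonded ones sit exactly at `bond`.
  const double ev2 = ev_diam * ev_diam;
  CellGrid grid(std::max(ev_diam, 1e-6));
  for (int i = 0; i < N; ++i) grid.insert(i, X[i], Y[i], Z[i]);

  List out(n_snapshots);
  const long long M = (long long)n_moves;

  for (int snap = 0; snap < n_snapshots; ++snap) {
    for (long long step = 0; step < M; ++step) {
      const int i = (int)(unif_rand() * N) % N;
      // uniform proposal in a ball of radius disp
      double ux, uy, uz;
      do {
        ux = 2.0 * unif_rand() - 1.0;
        uy = 2.0 * unif_rand() - 1.0;
        uz = 2.0 * unif_rand() - 1.0;
      } while (ux * ux + uy * uy + uz * uz > 1.0);
      double px = X[i] + disp * ux, py = Y[i] + disp * uy, pz = Z[i] + disp * uz;

      if (i > 0 && i < N - 1) {
        const double ax = X[i - 1], ay = Y[i - 1], az = Z[i - 1];
        const double bx = X[i + 1], by = Y[i + 1], bz = Z[i + 1];
        double nx = bx - ax, ny = by - ay, nz = bz - az;
        const double d = std::sqrt(nx * nx + ny * ny + nz * nz);
        if (d >= 2.0 * bond - 1e-9 || d < 1e-12) continue;  // degenerate
        nx /= d; ny /= d; nz /= d;
        const double c0x = 0.5 * (ax + bx), c0y = 0.5 * (ay + by),
                     c0z = 0.5 * (az + bz);
        const double rho = std::sqrt(bond * bond - 0.25 * d * d);
        double vx = px - c0x, vy = py - c0y, vz = pz - c0z;
        const double dot = vx * nx + vy * ny + vz * nz;
        vx -= dot * nx; vy -= dot * ny; vz -= dot * nz;
        const double vn = std::sqrt(vx * vx + vy * vy + vz * vz);
        if (vn < 1e-12) continue;
        px = c0x + rho * vx / vn;
        py = c0y + rho * vy / vn;
        pz = c0z + rho * vz / vn;
      } else {
        const int a = (i == 0) ? 1 : N - 2;
        double vx = px - X[a], vy = py - Y[a], vz = pz - Z[a];
        const double vn = std::sqrt(vx * vx + vy * vy + vz * vz);
        if (vn < 1e-12) continue;
        px = X[a] + bond * vx / vn;
        py = Y[a] + bond * vy / vn;
        pz = Z[a] + bond * vz / vn;
      }

      if (!ev_clear(grid, X, Y, Z, i, px, py, pz, ev2)) continue;
      grid.remove(i, X[i], Y[i], Z[i]);
      X[i] = px; Y[i] = py; Z[i] = pz;
      grid.insert(i, px, py, pz);
    }

    NumericMatrix m(N, 3);
    for (int i = 0; i < N; ++i) {
      m(i, 0) = X[i];
      m(i, 1) = Y[i];
      m(i, 2) = Z[i];
    }
    out[snap] = m;
  }
  return out;
}

// Count, over snapshots, the pairs (i, j), i != j, with Euclidean distance
// strictly below `threshold`. Returns a dense symmetric count matrix with a
// zero diagonal. Pair search uses a dense linked-cell grid rebuilt per
// snapshot (cell size = threshold, 27-cell stencil).
// [[Rcpp::export]]
NumericMatrix cpp_contact_counts(List snapshots, double threshold) {
  const int S = snapshots.size();
  if (S == 0) stop("no snapshots");
  NumericMatrix first = snapshots[0];
  const int N = first.nrow();
  NumericMatrix counts(N, N);
  double* C = counts.begin();
  const double t2 = threshold * threshold;
  std::vector<int> head, nxt(N), cell_of(N);
  std::vector<double> x(N), y(N), z(N);

  for (int s = 0; s < S; ++s) {
    NumericMatrix m = snapshots[s];
    if (m.nrow() != N)
      stop("snapshot %d has %d monomers, expected %d", s + 1, m.nrow(), N);
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
    for (int i = 0; i < N; ++i) {
      x[i] = m(i, 0); y[i] = m(i, 1); z[i] = m(i, 2);
      if (x[i] < lo[0]) lo[0] = x[i];
      if (y[i] < lo[1]) lo[1] = y[i];
      if (z[i] < lo[2]) lo[2] = z[i];
    }
    int gx = 1, gy = 1, gz = 1;
    for (int i = 0; i < N; ++i) {
      int cx = (int)((x[i] - lo[0]) / threshold) + 1;
      int cy = (int)((y[i] - lo[1]) / threshold) + 1;
      int cz = (int)((z[i] - lo[2]) / threshold) + 1;
      if (cx + 2 > gx) gx = cx + 2;
      if (cy + 2 > gy) gy = cy + 2;
      if (cz + 2 > gz) gz = cz + 2;
    }
    head.assign((size_t)gx * gy * gz, -1);
    for (int i = 0; i < N; ++i) {
      const int cx = (int)((x[i] - lo[0]) / threshold) + 1;
      const int cy = (int)((y[i] - lo[1]) / threshold) + 1;
      const int cz = (int)((z[i] - lo[2]) / threshold) + 1;
      const int c = (cx * gy + cy) * gz + cz;
      cell_of[i] = c;
      nxt[i] = head[c];
      head[c] = i;
    }
    for (int i = 0; i < N; ++i) {
      const int c = cell_of[i];
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int j = head[c + (dx * gy + dy) * gz + dz];
            for (; j >= 0; j = nxt[j]) {
              if (j <= i) continue;
              const double ax = x[j] - x[i], ay = y[j] - y[i],
                           az = z[j] - z[i];
              if (ax * ax + ay * ay + az * az < t2) {
                C[(size_t)j * N + i] += 1.0;
                C[(size_t)i * N + j] += 1.0;
              }
            }
          }
    }
  }
  return counts;
}

// Mean (and second moment) of the end-to-end distance over all (i, i+s)
// pairs of one conformation, per contour separation s = 1 .. N-1.
// [[Rcpp::export]]
List cpp_ee_curve(NumericMatrix coords) {
  const int N = coords.nrow();
  NumericVector sum(N - 1), sumsq(N - 1), cnt(N - 1);
  for (int s = 1; s < N; ++s) {
    double a = 0.0, b = 0.0;
    for (int i = 0; i + s < N; ++i) {
      const double dx = coords(i + s, 0) - coords(i, 0);
      const double dy = coords(i + s, 1) - coords(i, 1);
      const double dz = coords(i + s, 2) - coords(i, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      a += r; b += r * r;
    }
    sum[s - 1] = a;
    sumsq[s - 1] = b;
    cnt[s - 1] = N - s;
  }
  return List::create(_["s"] = seq_len(N - 1), _["sum"] = sum,
                      _["sumsq"] = sumsq, _["count"] = cnt);
}

// Minimum pairwise distance below `cutoff`, or +Inf if no pair is that
// close; grid-accelerated, used by conformation validation.
// [[Rcpp::export]]
double cpp_min_pairdist(NumericMatrix coords, double cutoff) {
  const int N = coords.nrow();
  CellGrid grid(cutoff);
  for (int i = 0; i < N; ++i) grid.insert(i, coords(i, 0), coords(i, 1), coords(i, 2));
  double best = R_PosInf;
  const double c2 = cutoff * cutoff;
  const long long OFF = 1LL << 20;
  for (int i = 0; i < N; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const long long cx = (long long)std::floor(xi / cutoff) + OFF;
    const long long cy = (long long)std::floor(yi / cutoff) + OFF;
    const long long cz = (long long)std::floor(zi / cutoff) + OFF;
    for (long long ax = cx - 1; ax <= cx + 1; ++ax)
      for (long long ay = cy - 1; ay <= cy + 1; ++ay)
        for (long long az = cz - 1; az <= cz + 1; ++az) {
          const long long k = (ax << 42) | (ay << 21) | az;
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
              grid.cells.find(k);
          if (it == grid.cells.end()) continue;
          const std::vector<int>& v = it->second;
          for (size_t q = 0; q < v.size(); ++q) {
            const int j = v[q];
            if (j <= i) continue;
            const double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
                         dz = coords(j, 2) - zi;
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < c2 && std::sqrt(d2) < best) best = std::sqrt(d2);
          }
        }
  }
  return best;
}
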