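#include <Rcpp.h>
#include <unordered_set>
#include <deque>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Lattice sites are packed into a single 64-bit key; OFF keeps coordinates
// positive (walks never stray further than ~N sites from the origin).
static const long long OFF = 1LL << 20;

static inline long long site_key(int x, int y, int z) {
  return ((x + OFF) << 42) | ((y + OFF) << 21) | (z + OFF);
}

static const int DX[6] = {1, -1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, 1, -1, 0, 0};
static const int DZ[6] = {0, 0, 0, 0, 1, -1};

struct Tri { int x, y, z; };

static inline bool in_box(int x, int y, int z, int L) {
  if (L <= 0) return true;  // unbounded lattice
  return x >= 0 && x < L && y >= 0 && y < L && z >= 0 && z < L;
}

// Conformation-dependent polymerization: a growing self-avoiding walk in
// which an unoccupied candidate site is weighted 1 + A * n, n being the
// number of occupied lattice neighbours of the candidate (the current head
// counts), and occupied candidates carry weight eps; drawing an occupied
// candidate is a rejected step and is redrawn. Trapped heads backtrack up
// to `backtrack` monomers; a walk whose backtracking budget is exhausted
// restarts from scratch, up to `max_restarts` times.
// [[Rcpp::export]]
IntegerMatrix cpp_cdp_grow(int N, double A, double eps, int L,
                           int backtrack, int max_restarts) {
  if (N < 2) stop("N must be at least 2");
  std::vector<Tri> walk;
  std::unordered_set<long long> occ;
  int restarts = 0;
  const int start = (L > 0) ? L / 2 : 0;
  long long bt_budget;

  for (;;) {
    walk.clear();
    occ.clear();
    walk.push_back({start, start, start});
    occ.insert(site_key(start, start, start));
    bt_budget = std::max(10000LL, 4LL * N);
    bool failed = false;

    while ((int)walk.size() < N) {
      const Tri h = walk.back();
      double w[6];
      bool occ_flag[6], valid[6];
      double tot = 0.0, tot_free = 0.0;
      for (int d = 0; d < 6; ++d) {
        const int cx = h.x + DX[d], cy = h.y + DY[d], cz = h.z + DZ[d];
        valid[d] = in_box(cx, cy, cz, L);
        if (!valid[d]) { w[d] = 0.0; occ_flag[d] = false; continue; }
        if (occ.count(site_key(cx, cy, cz))) {
          occ_flag[d] = true;
          w[d] = eps;
        } else {
          occ_flag[d] = false;
          // n counts occupied neighbours of the candidate other than the
          // head (the bond being formed): contacts with the rest of the
          // chain. n = 0 means stepping into open space (weight 1), so a
          // large A glues growth to the existing globule surface.
          int n = 0;
          for (int e = 0; e < 6; ++e) {
            const int nx = cx + DX[e], ny = cy + DY[e], nz = cz + DZ[e];
            if (nx == h.x && ny == h.y && nz == h.z) continue;
            if (occ.count(site_key(nx, ny, nz))) ++n;
          }
          w[d] = 1.0 + A * n;
          tot_free += w[d];
        }
        tot += w[d];
      }

      if (tot_free <= 0.0) {
        // trapped: backtrack, then restart once the budget runs out
        int nb = std::min(backtrack, (int)walk.size() - 1);
        if (nb <= 0 || bt_budget <= 0) { failed = true; break; }
        for (int b = 0; b < nb; ++b) {
          const Tri t = walk.back();
          occ.erase(site_key(t.x, t.y, t.z));
          walk.pop_back();
        }
        bt_budget -= nb;
        continue;
      }

      int pick = -1;
      for (int tries = 0; tries < 10000; ++tries) {
        double u = unif_rand() * tot, acc = 0.0;
        int d = 5;
        for (int k = 0; k < 6; ++k) {
          acc += w[k];
          if (u <= acc) { d = k; break; }
        }
        if (!valid[d] || w[d] <= 0.0) continue;
        if (occ_flag[d]) continue;  // rejected step: resample
        pick = d;
        break;
      }
      if (pick < 0) {
        // eps draws kept winning (pathological); take the best free site
        double best = -1.0;
        for (int d = 0; d < 6; ++d)
          if (valid[d] && !occ_flag[d] && w[d] > best) { best = w[d]; pick = d; }
      }
      const Tri nxt = {h.x + DX[pick], h.y + DY[pick], h.z + DZ[pick]};
      walk.push_back(nxt);
      occ.insert(site_key(nxt.x, nxt.y, nxt.z));
    }

    if (!failed) break;
    if (++restarts > max_restarts)
      stop("CDP growth failed after %d restarts (N = %d)", max_restarts, N);
  }

  IntegerMatrix out(N, 3);
  for (int i = 0; i < N; ++i) {
    out(i, 0) = walk[i].x;
    out(i, 1) = walk[i].y;
    out(i, 2) = walk[i].z;
  }
  out.attr("restarts") = restarts;
  return out;
}

// [[Rcpp::export]]
long long cpp_sphere_capacity(double radius) {
  const int R = (int)std::floor(radius);
  long long n = 0;
  const double r2 = radius * radius;
  for (int x = -R; x <= R; ++x)
    for (int y = -R; y <= R; ++y)
      for (int z = -R; z <= R; ++z)
        if ((double)x * x + (double)y * y + (double)z * z <= r2) ++n;
  return n;
}

static inline bool in_sphere(int x, int y, int z, double r2) {
  return (double)x * x + (double)y * y + (double)z * z <= r2;
}

// Equilibrium globule: a self-avoiding lattice chain confined to a sphere,
// grown with backtracking and then equilibrated by a mix of slithering-snake
// (reptation) and kink-jump moves.
// [[Rcpp::export]]
IntegerMatrix cpp_eg_generate(int N, double radius, double n_moves,
                              int max_restarts) {
  if (N < 2) stop("N must be at least 2");
  const double r2 = radius * radius;

  // initial self-avoiding chain inside the sphere
  std::vector<Tri> walk;
  std::unordered_set<long long> occ;
  int restarts = 0;
  for (;;) {
    walk.clear();
    occ.clear();
    walk.push_back({0, 0, 0});
    occ.insert(site_key(0, 0, 0));
    long long bt_budget = std::max(20000LL, 8LL * N);
    bool failed = false;
    while ((int)walk.size() < N) {
      const Tri h = walk.back();
      int cand[6], nc = 0;
      for (int d = 0; d < 6; ++d) {
        const int cx = h.x + DX[d], cy = h.y + DY[d], cz = h.z + DZ[d];
        if (in_sphere(cx, cy, cz, r2) && !occ.count(site_key(cx, cy, cz)))
          cand[nc++] = d;
      }
      if (nc == 0) {
        int nb = std::min(10, (int)walk.size() - 1);
        if (nb <= 0 || bt_budget <= 0) { failed = true; break; }
        for (int b = 0; b < nb; ++b) {
          const Tri t = walk.back();
          occ.erase(site_key(t.x, t.y, t.z));
          walk.pop_back();
        }
        bt_budget -= nb;
        continue;
      }
      const int d = cand[(int)(unif_rand() * nc) % nc];
      const Tri nxt = {h.x + DX[d], h.y + DY[d], h.z + DZ[d]};
      walk.push_back(nxt);
      occ.insert(site_key(nxt.x, nxt.y, nxt.z));
    }
    if (!failed) break;
    if (++restarts > max_restarts)
      stop("could not place a %d-monomer chain in a sphere of radius %.2f",
           N, radius);
  }

  // equilibration: 80% reptation, 20% kink-jump
  std::deque<Tri> chain(walk.begin(), walk.end());
  const long long M = (long long)n_moves;
  for (long long step = 0; step < M; ++step) {
    if (unif_rand() < 0.8 || N < 3) {
      const bool head = unif_rand() < 0.5;
      const Tri h = head ? chain.back() : chain.front();
      const Tri tail = head ? chain.front() : chain.back();
      int cand[6], nc = 0;
      for (int d = 0; d < 6; ++d) {
        const int cx = h.x + DX[d], cy = h.y + DY[d], cz = h.z + DZ[d];
        const long long k = site_key(cx, cy, cz);
        if (!in_sphere(cx, cy, cz, r2)) continue;
        if (occ.count(k) && !(cx == tail.x && cy == tail.y && cz == tail.z))
          continue;
        cand[nc++] = d;
      }
      if (nc == 0) continue;
      const int d = cand[(int)(unif_rand() * nc) % nc];
      const Tri nxt = {h.x + DX[d], h.y + DY[d], h.z + DZ[d]};
      occ.erase(site_key(tail.x, tail.y, tail.z));
      if (head) { chain.pop_front(); chain.push_back(nxt); }
      else      { chain.pop_back();  chain.push_front(nxt); }
      occ.insert(site_key(nxt.x, nxt.y, nxt.z));
    } else {
      const int i = 1 + (int)(unif_rand() * (N - 2)) % (N - 2);
      const Tri a = chain[i - 1], b = chain[i + 1], r = chain[i];
      const int mx = std::abs(a.x - b.x), my = std::abs(a.y - b.y),
                mz = std::abs(a.z - b.z);
      if (mx + my + mz != 2) continue;  // straight segment: no kink
      const Tri c = {a.x + b.x - r.x, a.y + b.y - r.y, a.z + b.z - r.z};
      const long long k = site_key(c.x, c.y, c.z);
      if (!in_sphere(c.x, c.y, c.z, r2) || occ.count(k)) continue;
      occ.erase(site_key(r.x, r.y, r.z));
      chain[i] = c;
      occ.insert(k);
    }
  }

  IntegerMatrix out(N, 3);
  for (int i = 0; i < N; ++i) {
    out(i, 0) = chain[i].x;
    out(i, 1) = chain[i].y;
    out(i, 2) = chain[i].z;
  }
  out.attr("restarts") = restarts;
  return out;
}
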