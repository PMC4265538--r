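#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Neighbourhood offsets.  Order is fixed so that every traversal below is
// deterministic given the same inputs and random stream.
static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 0, 0, 1};
static const int DC4[4] = {0, -1, 1, 0};

// ---------------------------------------------------------------------------
// Connected-component labelling (BFS), 4- or 8-connectivity.
// Labels are assigned in raster scan order (rows within columns follow the
// R column-major layout; the R wrapper re-orders components by bbox).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix m, int connectivity) {
  int h = m.nrow(), w = m.ncol();
  const int *dr = connectivity == 4 ? DR4 : DR8;
  const int *dc = connectivity == 4 ? DC4 : DC8;
  int nn = connectivity == 4 ? 4 : 8;
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (!m(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * h);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % h, pc = p / h;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= h || qc < 0 || qc >= w) continue;
          if (m(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * h);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Seeded region growing with a running region mean and FIFO frontier.
// A pixel is enqueued at most once (when first reached) and tested once
// against the mean current at dequeue time; the seed is always admitted.
// [[Rcpp::export(name = ".region_grow_cpp")]]
LogicalMatrix region_grow_cpp(NumericMatrix img, int sr, int sc, double tol) {
  int h = img.nrow(), w = img.ncol();
  LogicalMatrix region(h, w);
  std::vector<char> queued((size_t)h * w, 0);
  std::queue<int> frontier;
  frontier.push(sr + sc * h);
  queued[(size_t)(sr + sc * h)] = 1;
  double sum = 0.0;
  long  cnt = 0;
  while (!frontier.empty()) {
    int p = frontier.front();
    frontier.pop();
    int pr = p % h, pc = p / h;
    double v = img(pr, pc);
    if (cnt > 0) {
      double mean = sum / cnt;
      if (std::fabs(v - mean) > tol) continue;
    }
    region(pr, pc) = true;
    sum += v;
    ++cnt;
    for (int k = 0; k < 4; ++k) {
      int qr = pr + DR4[k], qc = pc + DC4[k];
      if (qr < 0 || qr >= h || qc < 0 || qc >= w) continue;
      size_t q = (size_t)(qr + qc * h);
      if (!queued[q]) {
        queued[q] = 1;
        frontier.push(qr + qc * h);
      }
    }
  }
  return region;
}

// ---------------------------------------------------------------------------
// Watershed by immersion (Meyer-style ordered flooding) of a topographic
// surface.  Regional minima (8-connected equal-value plateaus with no lower
// neighbour) seed the basins; flooding proceeds through 4-neighbours via a
// priority queue ordered by (height, insertion order).  A pixel reached by
// two distinct basins becomes a dam (label 0 in the output).  Basins are
// labelled 1..n.  4-connectivity for flooding guarantees that dam pixels
// 4-separate distinct basins.

struct FloodNode {
  double value;
  long   seq;
  int    idx;
};
struct FloodCmp {
  bool operator()(const FloodNode &a, const FloodNode &b) const {
    if (a.value != b.value) return a.value > b.value; // min-heap on height
    return a.seq > b.seq;                             // FIFO among equals
  }
};

// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerMatrix watershed_cpp(NumericMatrix g) {
  int h = g.nrow(), w = g.ncol();
  size_t n = (size_t)h * w;
  IntegerMatrix lab(h, w); // 0 = unlabelled during flood; dams become -1
  std::vector<char> seen(n, 0);
  std::vector<int> plateau;
  int next = 0;

  // 1. regional minima: 8-connected plateaus with no strictly lower neighbour
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      size_t p0 = (size_t)(r + c * h);
      if (seen[p0]) continue;
      double v = g(r, c);
      plateau.clear();
      plateau.push_back(r + c * h);
      seen[p0] = 1;
      bool is_min = true;
      for (size_t i = 0; i < plateau.size(); ++i) {
        int pr = plateau[i] % h, pc = plateau[i] / h;
        for (int k = 0; k < 8; ++k) {
          int qr = pr + DR8[k], qc = pc + DC8[k];
          if (qr < 0 || qr >= h || qc < 0 || qc >= w) continue;
          double qv = g(qr, qc);
          if (qv < v) {
            is_min = false;
          } else if (qv == v) {
            size_t q = (size_t)(qr + qc * h);
            if (!seen[q]) {
              seen[q] = 1;
              plateau.push_back(qr + qc * h);
            }
          }
        }
      }
      if (is_min) {
        ++next;
        for (size_t i = 0; i < plateau.size(); ++i) {
          lab(plateau[i] % h, plateau[i] / h) = next;
        }
      }
    }
  }

  // 2. ordered flooding from the minima
  std::priority_queue<FloodNode, std::vector<FloodNode>, FloodCmp> pq;
  std::vector<char> queued(n, 0);
  long seq = 0;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (lab(r, c) == 0) continue;
      for (int k = 0; k < 4; ++k) {
        int qr = r + DR4[k], qc = c + DC4[k];
        if (qr < 0 || qr >= h || qc < 0 || qc >= w) continue;
        size_t q = (size_t)(qr + qc * h);
        if (lab(qr, qc) == 0 && !queued[q]) {
          queued[q] = 1;
          pq.push(FloodNode{g(qr, qc), seq++, qr + qc * h});
        }
      }
    }
  }
  while (!pq.empty()) {
    FloodNode nd = pq.top();
    pq.pop();
    int pr = nd.idx % h, pc = nd.idx / h;
    if (lab(pr, pc) != 0) continue;
    int found = 0;
    bool conflict = false;
    for (int k = 0; k < 4; ++k) {
      int qr = pr + DR4[k], qc = pc + DC4[k];
      if (qr < 0 || qr >= h || qc < 0 || qc >= w) continue;
      int l = lab(qr, qc);
      if (l > 0) {
        if (found == 0) found = l;
        else if (found != l) conflict = true;
      }
    }
    if (conflict || found == 0) {
      lab(pr, pc) = -1; // dam (or isolated pocket walled in by dams)
    } else {
      lab(pr, pc) = found;
      for (int k = 0; k < 4; ++k) {
        int qr = pr + DR4[k], qc = pc + DC4[k];
        if (qr < 0 || qr >= h || qc < 0 || qc >= w) continue;
        size_t q = (size_t)(qr + qc * h);
        if (lab(qr, qc) == 0 && !queued[q]) {
          queued[q] = 1;
          pq.push(FloodNode{g(qr, qc), seq++, qr + qc * h});
        }
      }
    }
  }
  // pockets never reached (fully walled in): label each as its own basin
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (lab(r, c) == 0) lab(r, c) = ++next;
      else if (lab(r, c) == -1) lab(r, c) = 0; // dams reported as 0
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// ACO edge-detection walk.  Ants move on the pixel lattice; from pixel i the
// move to an 8-neighbour j has probability proportional to tau(j)^alpha *
// eta(j)^beta over the admissible (in-bounds, not yet visited by this ant)
// neighbours, uniform among them when all weights vanish.  Visited pixels are
// tabu per ant; a blocked ant respawns at a fresh random pixel.  After each
// iteration tau <- (1 - rho) * tau, then every recorded visit at pixel j
// deposits rho * eta(j).  All randomness comes from R's RNG so a set.seed()
// on the R side fixes the full move sequence: iterations outermost, ants in
// index order, moves in step order, one uniform draw per placement or move.
// [[Rcpp::export(name = ".aco_walk_cpp")]]
NumericMatrix aco_walk_cpp(NumericMatrix eta, int n_ants, int n_iterations,
                           int steps_per_ant, double alpha, double beta,
                           double rho, double tau0) {
  int h = eta.nrow(), w = eta.ncol();
  size_t n = (size_t)h * w;
  NumericMatrix tau(h, w);
  std::fill(tau.begin(), tau.end(), tau0);
  std::vector<int> stamp(n, -1); // id of the last ant that visited the pixel
  std::vector<int> visits;
  visits.reserve((size_t)n_ants * (steps_per_ant + 1));
  int adm[8];
  double wt[8];

  for (int iter = 0; iter < n_iterations; ++iter) {
    visits.clear();
    for (int a = 0; a < n_ants; ++a) {
      int id = iter * n_ants + a;
      int cur = (int)std::floor(unif_rand() * n);
      if (cur >= (int)n) cur = (int)n - 1;
      stamp[(size_t)cur] = id;
      visits.push_back(cur);
      for (int s = 0; s < steps_per_ant; ++s) {
        int pr = cur % h, pc = cur / h;
        int na = 0;
        for (int k = 0; k < 8; ++k) {
          int qr = pr + DR8[k], qc = pc + DC8[k];
          if (qr < 0 || qr >= h || qc < 0 || qc >= w) continue;
          int q = qr + qc * h;
          if (stamp[(size_t)q] != id) adm[na++] = q;
        }
        int nxt;
        if (na == 0) {
          // dead end: respawn at a fresh random pixel for the remaining steps
          nxt = (int)std::floor(unif_rand() * n);
          if (nxt >= (int)n) nxt = (int)n - 1;
        } else {
          double total = 0.0;
          for (int k = 0; k < na; ++k) {
            double e = eta[(size_t)adm[k]];
            double t = tau[(size_t)adm[k]];
            double wk = std::pow(t, alpha) * std::pow(e, beta);
            wt[k] = wk;
            total += wk;
          }
          double u = unif_rand();
          if (total <= 0.0) {
            int pick = (int)std::floor(u * na);
            if (pick >= na) pick = na - 1;
            nxt = adm[pick];
          } else {
            double acc = 0.0, target = u * total;
            int pick = na - 1;
            for (int k = 0; k < na; ++k) {
              acc += wt[k];
              if (target <= acc) { pick = k; break; }
            }
            nxt = adm[pick];
          }
        }
        cur = nxt;
        stamp[(size_t)cur] = id;
        visits.push_back(cur);
      }
    }
    for (size_t p = 0; p < n; ++p) tau[p] *= (1.0 - rho);
    for (size_t i = 0; i < visits.size(); ++i) {
      size_t p = (size_t)visits[i];
      tau[p] += rho * eta[p];
    }
  }
  return tau;
}
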