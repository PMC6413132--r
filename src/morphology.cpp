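#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pixel-level primitives for binary-mask morphology. All matrices are
// column-major (R layout); connectivity is 4 or 8.

static inline int idx2(int r, int c, int nr) { return c * nr + r; }

// [[Rcpp::export]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  const int nn = connectivity;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(idx2(r, c, nr));
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(idx2(qr, qc, nr));
          }
        }
      }
    }
  }
  return lab;
}

// Fill interior holes: background regions (4-connected) not reachable from
// the matrix border become foreground.
// [[Rcpp::export]]
LogicalMatrix fill_holes_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> outside(static_cast<size_t>(nr) * nc, 0);
  std::vector<int> stack;
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      bool border = (r == 0 || r == nr - 1 || c == 0 || c == nc - 1);
      if (!border || mask(r, c) || outside[idx2(r, c, nr)]) continue;
      outside[idx2(r, c, nr)] = 1;
      stack.clear();
      stack.push_back(idx2(r, c, nr));
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < 4; ++k) {
          int qr = pr + dr4[k], qc = pc + dc4[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          int q = idx2(qr, qc, nr);
          if (!mask(qr, qc) && !outside[q]) {
            outside[q] = 1;
            stack.push_back(q);
          }
        }
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = mask(r, c) || !outside[idx2(r, c, nr)];
  return out;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (pixels^2) from each foreground pixel to the
// nearest background pixel; the mask border counts as adjacent to
// background (a virtual background frame surrounds the matrix).
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  // pad by one pixel of background on all sides
  const int pr = nr + 2, pc = nc + 2;
  std::vector<double> g(static_cast<size_t>(pr) * pc);
  const double INF = 1e20;
  for (int c = 0; c < pc; ++c)
    for (int r = 0; r < pr; ++r) {
      bool fg = (r > 0 && r <= nr && c > 0 && c <= nc) && mask(r - 1, c - 1);
      g[static_cast<size_t>(c) * pr + r] = fg ? INF : 0.0;
    }
  std::vector<double> f(std::max(pr, pc)), d(std::max(pr, pc));
  // columns
  for (int c = 0; c < pc; ++c) {
    for (int r = 0; r < pr; ++r) f[r] = g[static_cast<size_t>(c) * pr + r];
    dt1d(f, d, pr);
    for (int r = 0; r < pr; ++r) g[static_cast<size_t>(c) * pr + r] = d[r];
  }
  // rows
  NumericMatrix out(nr, nc);
  std::vector<double> row(pc), drow(pc);
  for (int r = 0; r < pr; ++r) {
    for (int c = 0; c < pc; ++c) row[c] = g[static_cast<size_t>(c) * pr + r];
    dt1d(row, drow, pc);
    if (r > 0 && r <= nr)
      for (int c = 1; c <= nc; ++c) out(r - 1, c - 1) = drow[c];
  }
  return out;
}

struct WsNode {
  double h;
  int idx;
  int lab;
  long order;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.h != b.h) return a.h < b.h;  // max-heap on height
    return a.order > b.order;          // FIFO tie-break for determinism
  }
};

// Seeded watershed by priority flooding on a height map (descending),
// restricted to mask; seeds carry labels > 0.
// [[Rcpp::export]]
IntegerMatrix watershed_seeded_cpp(const NumericMatrix& height,
                                   const IntegerMatrix& seeds,
                                   const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) {
        out(r, c) = seeds(r, c);
        pq.push({height(r, c), idx2(r, c, nr), seeds(r, c), order++});
      }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int pr = nd.idx % nr, pc = nd.idx / nr;
    for (int k = 0; k < 8; ++k) {
      int qr = pr + dr8[k], qc = pc + dc8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (mask(qr, qc) && out(qr, qc) == 0) {
        out(qr, qc) = nd.lab;
        pq.push({height(qr, qc), idx2(qr, qc, nr), nd.lab, order++});
      }
    }
  }
  return out;
}
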