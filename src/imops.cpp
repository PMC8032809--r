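#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Feature maps are stored as (H*W) x C matrices, pixel p = i + j*H with
// i = row, j = col, both 0-based (column-major flattening of an H x W plane).

// im2col for a k x k kernel, symmetric zero padding `pad`, stride `stride`.
// Output: (k*k*C) x (Ho*Wo); patch row index = di + k*dj + k*k*c;
// output pixel q = io + jo*Ho (same flattening convention as input).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(k * k * C, Ho * Wo);
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const int q = io + jo * Ho;
      for (int c = 0; c < C; ++c) {
        for (int dj = 0; dj < k; ++dj) {
          const int j = jo * stride - pad + dj;
          for (int di = 0; di < k; ++di) {
            const int i = io * stride - pad + di;
            const int r = di + k * dj + k * k * c;
            if (i >= 0 && i < H && j >= 0 && j < W)
              out(r, q) = x(i + j * H, c);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add patch columns back onto an H x W x C map.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(H * W, C);
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const int q = io + jo * Ho;
      for (int c = 0; c < C; ++c) {
        for (int dj = 0; dj < k; ++dj) {
          const int j = jo * stride - pad + dj;
          for (int di = 0; di < k; ++di) {
            const int i = io * stride - pad + di;
            if (i >= 0 && i < H && j >= 0 && j < W)
              out(i + j * H, c) += cols(di + k * dj + k * k * c, q);
          }
        }
      }
    }
  }
  return out;
}

// Connected-component labeling of a logical matrix by BFS. Components are
// numbered 1..n in order of first encounter in a row-major raster scan, so
// the labeling is deterministic. connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[] = {-1, 0, 0, 1};
  const int dc4[] = {0, -1, 1, 0};
  const int n_nb = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < H; ++i) {      // row-major scan for label order
    for (int j = 0; j < W; ++j) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int t = 0; t < n_nb; ++t) {
          const int r = p.first + dr[t], c = p.second + dc[t];
          if (r >= 0 && r < H && c >= 0 && c < W && mask(r, c) && !lab(r, c)) {
            lab(r, c) = next;
            q.push(std::make_pair(r, c));
          }
        }
      }
    }
  }
  return lab;
}

// Minimum-cost perfect assignment on an n x n cost matrix (Hungarian
// algorithm with potentials, O(n^3)). Returns, for each row, the assigned
// column (1-based).
// [[Rcpp::export]]
IntegerVector cpp_hungarian(const NumericMatrix& cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      double delta = INF;
      int j1 = 0;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { const int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}

// In-place Adam update: p, m, v are modified directly (callers must own
// unshared copies). b1t/b2t are beta1^t / beta2^t for bias correction.
// [[Rcpp::export]]
void cpp_adam_step(NumericVector p, const NumericVector& g,
                   NumericVector m, NumericVector v,
                   double lr, double b1, double b2,
                   double b1t, double b2t, double eps) {
  const R_xlen_t n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("adam: length mismatch");
  const double c1 = 1.0 - b1, c2 = 1.0 - b2;
  const double d1 = 1.0 - b1t, d2 = 1.0 - b2t;
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + c1 * g[i];
    v[i] = b2 * v[i] + c2 * g[i] * g[i];
    p[i] -= lr * (m[i] / d1) / (std::sqrt(v[i] / d2) + eps);
  }
}

// Perimeter of a connected pixel component as the length of the closed
// Moore-neighbor boundary trace through pixel centers. A single pixel has
// perimeter 0 by convention; a 1 x n line yields 2*(n-1).
// [[Rcpp::export]]
double cpp_trace_perimeter(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  int si = -1, sj = -1;
  for (int i = 0; i < H && si < 0; ++i)
    for (int j = 0; j < W; ++j)
      if (mask(i, j)) { si = i; sj = j; break; }
  if (si < 0) return NA_REAL;
  // clockwise neighbor order starting at W
  const int dr[] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[] = {-1, -1, 0, 1, 1, 1, 0, -1};
  bool any_nb = false;
  for (int t = 0; t < 8; ++t) {
    const int r = si + dr[t], c = sj + dc[t];
    if (r >= 0 && r < H && c >= 0 && c < W && mask(r, c)) { any_nb = true; break; }
  }
  if (!any_nb) return 0.0;   // isolated pixel
  // Walk the Moore boundary; the walk state is (pixel, backtrack direction).
  // The walk enters a cycle whose edge length is the boundary polygon
  // perimeter; detect the first repeated state and return the cycle length.
  std::vector<long> seen(8L * H * W, -1);   // state -> step of first visit
  std::vector<double> cum;                  // length walked when state visited
  int ci = si, cj = sj;
  int bdir = 0;              // direction from current pixel to backtrack (W)
  double per = 0.0;
  const long maxit = 8L * H * W + 8;
  for (long it = 0; it < maxit; ++it) {
    const long state = ((long)(ci * W + cj)) * 8 + bdir;
    if (seen[state] >= 0) return per - cum[seen[state]];
    seen[state] = it;
    cum.push_back(per);
    int ni = ci, nj = cj, ndir = bdir;
    for (int t = 1; t <= 8; ++t) {
      const int d = (bdir + t) % 8;
      const int r = ci + dr[d], c = cj + dc[d];
      if (r >= 0 && r < H && c >= 0 && c < W && mask(r, c)) {
        ni = r; nj = c;
        // backtrack of the new pixel = previously examined (background)
        // neighbor, expressed as a direction from the new pixel
        const int pd = (bdir + t - 1) % 8;
        const int br = ci + dr[pd], bc = cj + dc[pd];
        for (int s = 0; s < 8; ++s)
          if (ni + dr[s] == br && nj + dc[s] == bc) { ndir = s; break; }
        break;
      }
    }
    per += std::sqrt((double)((ni - ci) * (ni - ci) + (nj - cj) * (nj - cj)));
    ci = ni; cj = nj; bdir = ndir;
  }
  return per;   // unreachable for connected components
}
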