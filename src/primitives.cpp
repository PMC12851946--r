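#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Connected-component labeling (binary matrix, 4- or 8-connectivity).
// Returns integer matrix of labels (0 = background), labels 1..K.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * H);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % H, pc = p / H;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr8[k], qc = pc + dc8[k];
          if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * H);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher).
// Distance from each TRUE pixel to the nearest FALSE pixel (in pixels).
// ---------------------------------------------------------------------------
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

// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double INF = 1e20;
  NumericMatrix sq(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) sq(r, c) = mask(r, c) ? INF : 0.0;
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  // columns
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) f[r] = sq(r, c);
    dt1d(f, d, H);
    for (int r = 0; r < H; ++r) sq(r, c) = d[r];
  }
  // rows
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) f[c] = sq(r, c);
    dt1d(f, d, W);
    for (int c = 0; c < W; ++c) sq(r, c) = d[c];
  }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) sq(r, c) = std::sqrt(sq(r, c));
  return sq;
}

// ---------------------------------------------------------------------------
// Zhang-Suen thinning: reduce a binary mask to a 1-px skeleton.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalMatrix cpp_skeletonize(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<unsigned char> img(H * W);
  for (int i = 0; i < H * W; ++i) img[i] = mask[i] ? 1 : 0;
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return img[r + c * H];
  };
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (!img[r + c * H]) continue;
          int p2 = at(r - 1, c), p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
              p5 = at(r + 1, c + 1), p6 = at(r + 1, c), p7 = at(r + 1, c - 1),
              p8 = at(r, c - 1), p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(r + c * H);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i) img[kill[i]] = 0;
    }
  }
  LogicalMatrix out(H, W);
  for (int i = 0; i < H * W; ++i) out[i] = img[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Marker-based watershed by priority flooding (ascending elevation).
// markers: integer matrix, >0 = seed labels, 0 elsewhere; flooding is
// restricted to mask==TRUE. Returns label matrix.
// ---------------------------------------------------------------------------
struct WsNode {
  double elev;
  long order;
  int idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& elev,
                            const IntegerMatrix& markers,
                            const LogicalMatrix& mask) {
  const int H = elev.nrow(), W = elev.ncol();
  IntegerMatrix lab(H, W);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int i = 0; i < H * W; ++i) {
    lab[i] = markers[i];
    if (markers[i] > 0) pq.push({elev[i], order++, i});
  }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int r = nd.idx % H, c = nd.idx / H;
    for (int k = 0; k < 4; ++k) {
      int qr = r + dr[k], qc = c + dc[k];
      if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
      int qi = qr + qc * H;
      if (!mask[qi] || lab[qi] != 0) continue;
      lab[qi] = lab[nd.idx];
      pq.push({elev[qi], order++, qi});
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// 2D convolution with zero padding, same-size output (small kernels).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_conv2(const NumericMatrix& img, const NumericMatrix& kern) {
  const int H = img.nrow(), W = img.ncol();
  const int kh = kern.nrow(), kw = kern.ncol();
  const int oh = kh / 2, ow = kw / 2;
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int kc = 0; kc < kw; ++kc) {
        int sc = c + kc - ow;
        if (sc < 0 || sc >= W) continue;
        for (int kr = 0; kr < kh; ++kr) {
          int sr = r + kr - oh;
          if (sr < 0 || sr >= H) continue;
          acc += img(sr, sc) * kern(kr, kc);
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact per-tree Shapley values (and optional interaction values) for an
// ensemble of binary decision trees, by enumeration over each tree's used
// feature subsets. For a tree using feature set F, the coalition value
//   v(S) = expected leaf value when features in S follow the decision path
//          of x (missing values follow the default branch) and features not
//          in S average both children weighted by training cover.
// Shapley values over F are exact; efficiency gives sum(phi) + base = margin.
// Trees are lists with 0-based integer vectors: feat (-1 = leaf), left,
// right, miss, and numeric split, value, cover.
// ---------------------------------------------------------------------------
static double eval_subset(int node, unsigned int S,
                          const std::vector<int>& feat,
                          const std::vector<int>& left,
                          const std::vector<int>& right,
                          const std::vector<int>& miss,
                          const std::vector<double>& split,
                          const std::vector<double>& value,
                          const std::vector<double>& cover,
                          const std::vector<int>& fpos,
                          const double* x) {
  int f = feat[node];
  if (f < 0) return value[node];
  int bit = fpos[f];
  if (S & (1u << bit)) {
    double xv = x[f];
    int child;
    if (ISNAN(xv)) child = miss[node];
    else child = (xv < split[node]) ? left[node] : right[node];
    return eval_subset(child, S, feat, left, right, miss, split, value, cover,
                       fpos, x);
  }
  double cl = cover[left[node]], cr = cover[right[node]];
  double tot = cl + cr;
  if (tot <= 0) { cl = cr = 1.0; tot = 2.0; }
  double vl = eval_subset(left[node], S, feat, left, right, miss, split, value,
                          cover, fpos, x);
  double vr = eval_subset(right[node], S, feat, left, right, miss, split,
                          value, cover, fpos, x);
  return (cl * vl + cr * vr) / tot;
}

// [[Rcpp::export]]
List cpp_tree_shap(List trees, const NumericMatrix& X, int n_features,
                   bool interactions) {
  const int n = X.nrow();
  NumericMatrix phi(n, n_features);
  NumericVector base(n);
  NumericVector inter;
  if (interactions)
    inter = NumericVector(Dimension(n_features, n_features, n));
  // factorial table
  std::vector<double> fact(32);
  fact[0] = 1.0;
  for (int i = 1; i < 32; ++i) fact[i] = fact[i - 1] * i;

  const int T = trees.size();
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    std::vector<int> feat = as<std::vector<int>>(tr["feat"]);
    std::vector<int> left = as<std::vector<int>>(tr["left"]);
    std::vector<int> right = as<std::vector<int>>(tr["right"]);
    std::vector<int> miss = as<std::vector<int>>(tr["miss"]);
    std::vector<double> split = as<std::vector<double>>(tr["split"]);
    std::vector<double> value = as<std::vector<double>>(tr["value"]);
    std::vector<double> cover = as<std::vector<double>>(tr["cover"]);
    // used features
    std::vector<int> used;
    std::vector<int> fpos(n_features, -1);
    for (size_t i = 0; i < feat.size(); ++i) {
      int f = feat[i];
      if (f >= 0 && fpos[f] < 0) {
        fpos[f] = used.size();
        used.push_back(f);
      }
    }
    const int m = used.size();
    if (m > 20) stop("tree uses too many distinct features for exact SHAP");
    const unsigned int NS = 1u << m;
    std::vector<double> v(NS);
    std::vector<double> xrow(n_features);
    for (int i = 0; i < n; ++i) {
      for (int f = 0; f < n_features; ++f) xrow[f] = X(i, f);
      for (unsigned int S = 0; S < NS; ++S)
        v[S] = eval_subset(0, S, feat, left, right, miss, split, value, cover,
                           fpos, xrow.data());
      base[i] += v[0];
      if (m == 0) continue;
      // Shapley values
      std::vector<double> phi_t(m, 0.0);
      for (unsigned int S = 0; S < NS; ++S) {
        int s = __builtin_popcount(S);
        for (int j = 0; j < m; ++j) {
          if (S & (1u << j)) continue;
          double w = fact[s] * fact[m - s - 1] / fact[m];
          phi_t[j] += w * (v[S | (1u << j)] - v[S]);
        }
      }
      for (int j = 0; j < m; ++j) phi(i, used[j]) += phi_t[j];
      if (interactions) {
        // off-diagonal Shapley interaction values (half-split, symmetric)
        std::vector<double> psi(m * m, 0.0);
        if (m >= 2) {
          for (unsigned int S = 0; S < NS; ++S) {
            int s = __builtin_popcount(S);
            for (int j = 0; j < m; ++j) {
              if (S & (1u << j)) continue;
              for (int k = j + 1; k < m; ++k) {
                if (S & (1u << k)) continue;
                double w =
                    fact[s] * fact[m - s - 2] / (2.0 * fact[m - 1]);
                double d = v[S | (1u << j) | (1u << k)] - v[S | (1u << j)] -
                           v[S | (1u << k)] + v[S];
                psi[j * m + k] += w * d;
              }
            }
          }
        }
        double* ip = REAL(inter) + (R_xlen_t)i * n_features * n_features;
        for (int j = 0; j < m; ++j) {
          double off = 0.0;
          for (int k = 0; k < m; ++k) {
            if (k == j) continue;
            double val = (j < k) ? psi[j * m + k] : psi[k * m + j];
            ip[used[j] + used[k] * n_features] += val;
            off += val;
          }
          // main effect keeps row sums equal to phi
          ip[used[j] + used[j] * n_features] += phi_t[j] - off;
        }
      }
    }
  }
  List out = List::create(_["phi"] = phi, _["base"] = base);
  if (interactions) out["interactions"] = inter;
  return out;
}
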