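// Contour-distance kernels and connected-component labeling.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sqd(const double* a, const double* b, int na, int nb,
                         int i, int j) {
  double dx = a[i] - b[j];
  double dy = a[i + na] - b[j + nb];
  return dx * dx + dy * dy;
}

// Directed max-min distance with early break on the inner loop.
static double directedHaus(const double* a, int na, const double* b, int nb) {
  double best = 0.0;
  for (int i = 0; i < na; ++i) {
    double mn = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double d = sqd(a, b, na, nb, i, j);
      if (d < mn) {
        mn = d;
        if (mn <= best) break;  // cannot raise the running maximum
      }
    }
    if (mn > best) best = mn;
  }
  return best;
}

// [[Rcpp::export(name = ".hausdorffCpp")]]
double hausdorffCpp(NumericMatrix A, NumericMatrix B) {
  double h = std::max(directedHaus(A.begin(), A.nrow(), B.begin(), B.nrow()),
                      directedHaus(B.begin(), B.nrow(), A.begin(), A.nrow()));
  return std::sqrt(h);
}

// Discrete Frechet distance on two open polylines via the standard
// dynamic-programming coupling recurrence, with rolling rows.
// [[Rcpp::export(name = ".frechetCpp")]]
double frechetCpp(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  std::vector<double> prev(nb), cur(nb);
  const double* a = A.begin();
  const double* b = B.begin();
  for (int j = 0; j < nb; ++j) {
    double d = sqd(a, b, na, nb, 0, j);
    prev[j] = (j == 0) ? d : std::max(prev[j - 1], d);
  }
  for (int i = 1; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double d = sqd(a, b, na, nb, i, j);
      double reach;
      if (j == 0) reach = prev[0];
      else reach = std::min(std::min(prev[j], prev[j - 1]), cur[j - 1]);
      cur[j] = std::max(reach, d);
    }
    std::swap(prev, cur);
  }
  return std::sqrt(prev[nb - 1]);
}

// Connected-component labeling, breadth-first, labels assigned in
// column-major scan order (so label 1 is the first component encountered).
// conn: 4 or 8 for 2D inputs, 6 or 26 for 3D.
// [[Rcpp::export(name = ".labelComponents")]]
IntegerVector labelComponents(LogicalVector mask, IntegerVector dims, int conn) {
  int H = dims[0], W = dims[1], D = dims.size() > 2 ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)H * W * D;
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  std::vector<int> offs_i, offs_j, offs_k;
  bool diag = (conn == 8 || conn == 26);
  bool use3d = (D > 1) && (conn == 6 || conn == 26);
  for (int dk = -1; dk <= 1; ++dk) {
    if (!use3d && dk != 0) continue;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int nz = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (!diag && nz > 1) continue;
        offs_i.push_back(di); offs_j.push_back(dj); offs_k.push_back(dk);
      }
  }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int i = p % H, j = (p / H) % W, k = (int)(p / ((R_xlen_t)H * W));
      for (size_t q = 0; q < offs_i.size(); ++q) {
        int ii = i + offs_i[q], jj = j + offs_j[q], kk = k + offs_k[q];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W || kk < 0 || kk >= D) continue;
        R_xlen_t pp = ii + (R_xlen_t)H * jj + (R_xlen_t)H * W * kk;
        if (mask[pp] && !lab[pp]) { lab[pp] = next; stack.push_back(pp); }
      }
    }
  }
  lab.attr("ncomp") = next;
  return lab;
}
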