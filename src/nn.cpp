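#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Brute-force exact nearest neighbours. Clouds at desk scale (< 10k points)
// make an O(N*M) scan cheaper and more predictable than building a tree.

// [[Rcpp::export]]
List cpp_nn(NumericMatrix query, NumericMatrix ref) {
  const int n = query.nrow(), m = ref.nrow(), d = query.ncol();
  if (ref.ncol() != d) stop("dimension mismatch between query and reference");
  IntegerVector idx(n);
  NumericVector dist(n);
  const double *q = REAL(query), *r = REAL(ref);
  if (d == 3) {
    const double *qx = q, *qy = q + n, *qz = q + 2 * n;
    const double *rx = r, *ry = r + m, *rz = r + 2 * m;
    for (int i = 0; i < n; ++i) {
      const double xi = qx[i], yi = qy[i], zi = qz[i];
      double best = R_PosInf;
      int bj = 0;
      for (int j = 0; j < m; ++j) {
        const double dx = xi - rx[j], dy = yi - ry[j], dz = zi - rz[j];
        const double s = dx * dx + dy * dy + dz * dz;
        if (s < best) { best = s; bj = j; }
      }
      idx[i] = bj + 1;
      dist[i] = std::sqrt(best);
    }
  } else {
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      int bj = 0;
      for (int j = 0; j < m; ++j) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          double diff = q[i + (R_xlen_t)k * n] - r[j + (R_xlen_t)k * m];
          s += diff * diff;
        }
        if (s < best) { best = s; bj = j; }
      }
      idx[i] = bj + 1;
      dist[i] = std::sqrt(best);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// k nearest neighbours per query row (k <= nrow(ref)).
// [[Rcpp::export]]
List cpp_knn(NumericMatrix query, NumericMatrix ref, int k) {
  const int n = query.nrow(), m = ref.nrow(), d = query.ncol();
  if (ref.ncol() != d) stop("dimension mismatch between query and reference");
  if (k < 1 || k > m) stop("k out of range");
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<double> ds(m);
  std::vector<int> ord(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int kk = 0; kk < d; ++kk) {
        double diff = query(i, kk) - ref(j, kk);
        s += diff * diff;
      }
      ds[j] = s;
      ord[j] = j;
    }
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                      [&](int a, int b) { return ds[a] < ds[b]; });
    for (int j = 0; j < k; ++j) {
      idx(i, j) = ord[j] + 1;
      dist(i, j) = std::sqrt(ds[ord[j]]);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Rotation from a 3x3 cross-covariance via Horn's quaternion method: the
// optimal rotation is the dominant eigenvector of a symmetric 4x4 built from
// H, found here by shifted power iteration (always converges for symmetric
// matrices after a positive diagonal shift).
static void rotation_from_H(const double H[3][3], double Rout[3][3]) {
  double N[4][4];
  N[0][0] = H[0][0] + H[1][1] + H[2][2];
  N[0][1] = H[1][2] - H[2][1];
  N[0][2] = H[2][0] - H[0][2];
  N[0][3] = H[0][1] - H[1][0];
  N[1][1] = H[0][0] - H[1][1] - H[2][2];
  N[1][2] = H[0][1] + H[1][0];
  N[1][3] = H[2][0] + H[0][2];
  N[2][2] = -H[0][0] + H[1][1] - H[2][2];
  N[2][3] = H[1][2] + H[2][1];
  N[3][3] = -H[0][0] - H[1][1] + H[2][2];
  for (int i = 1; i < 4; ++i)
    for (int j = 0; j < i; ++j) N[i][j] = N[j][i];
  double shift = 0.0;
  for (int i = 0; i < 4; ++i) {
    double row = 0.0;
    for (int j = 0; j < 4; ++j) row += std::fabs(N[i][j]);
    if (row > shift) shift = row;
  }
  for (int i = 0; i < 4; ++i) N[i][i] += shift;
  double q[4] = {1.0, 0.0, 0.0, 0.0};
  for (int it = 0; it < 60; ++it) {
    double v[4] = {0, 0, 0, 0};
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) v[i] += N[i][j] * q[j];
    double nrm = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2] + v[3] * v[3]);
    if (nrm < 1e-300) break;
    for (int i = 0; i < 4; ++i) q[i] = v[i] / nrm;
  }
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  Rout[0][0] = 1 - 2 * (y * y + z * z);
  Rout[0][1] = 2 * (x * y - w * z);
  Rout[0][2] = 2 * (x * z + w * y);
  Rout[1][0] = 2 * (x * y + w * z);
  Rout[1][1] = 1 - 2 * (x * x + z * z);
  Rout[1][2] = 2 * (y * z - w * x);
  Rout[2][0] = 2 * (x * z - w * y);
  Rout[2][1] = 2 * (y * z + w * x);
  Rout[2][2] = 1 - 2 * (x * x + y * y);
}

// RANSAC over putative matches: minimal 3-point rigid fits, inliers counted
// under `thresh` (mm). Uses R's RNG so set.seed() on the R side makes runs
// reproducible. Returns the best rotation/translation and the inlier mask.
// [[Rcpp::export]]
List cpp_ransac_rigid(NumericMatrix src, NumericMatrix dst, int iters, double thresh) {
  const int n = src.nrow();
  if (n < 3) stop("need at least 3 putative matches");
  if (dst.nrow() != n || src.ncol() != 3 || dst.ncol() != 3)
    stop("src and dst must be equally sized Nx3 matrices");
  RNGScope scope;
  const double t2 = thresh * thresh;
  int best_count = -1;
  double bestR[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  double bestT[3] = {0, 0, 0};
  for (int it = 0; it < iters; ++it) {
    int a = (int)(unif_rand() * n), b, c;
    do { b = (int)(unif_rand() * n); } while (b == a);
    do { c = (int)(unif_rand() * n); } while (c == a || c == b);
    if (a >= n) a = n - 1;
    if (b >= n) b = n - 1;
    if (c >= n) c = n - 1;
    int pick[3] = {a, b, c};
    double cs[3] = {0, 0, 0}, cd[3] = {0, 0, 0};
    for (int p = 0; p < 3; ++p)
      for (int k = 0; k < 3; ++k) {
        cs[k] += src(pick[p], k) / 3.0;
        cd[k] += dst(pick[p], k) / 3.0;
      }
    double H[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int p = 0; p < 3; ++p)
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          H[i][j] += (src(pick[p], i) - cs[i]) * (dst(pick[p], j) - cd[j]);
    double R[3][3];
    rotation_from_H(H, R);
    double T[3];
    for (int i = 0; i < 3; ++i) {
      double v = 0.0;
      for (int j = 0; j < 3; ++j) v += R[i][j] * cs[j];
      T[i] = cd[i] - v;
    }
    int count = 0;
    for (int p = 0; p < n; ++p) {
      double e = 0.0;
      for (int i = 0; i < 3; ++i) {
        double v = T[i];
        for (int j = 0; j < 3; ++j) v += R[i][j] * src(p, j);
        double diff = v - dst(p, i);
        e += diff * diff;
      }
      if (e <= t2) ++count;
    }
    if (count > best_count) {
      best_count = count;
      for (int i = 0; i < 3; ++i) {
        bestT[i] = T[i];
        for (int j = 0; j < 3; ++j) bestR[i][j] = R[i][j];
      }
    }
  }
  LogicalVector inl(n);
  NumericMatrix Rm(3, 3);
  NumericVector Tv(3);
  for (int i = 0; i < 3; ++i) {
    Tv[i] = bestT[i];
    for (int j = 0; j < 3; ++j) Rm(i, j) = bestR[i][j];
  }
  for (int p = 0; p < n; ++p) {
    double e = 0.0;
    for (int i = 0; i < 3; ++i) {
      double v = bestT[i];
      for (int j = 0; j < 3; ++j) v += bestR[i][j] * src(p, j);
      double diff = v - dst(p, i);
      e += diff * diff;
    }
    inl[p] = e <= t2;
  }
  return List::create(_["rotation"] = Rm, _["translation"] = Tv,
                      _["inliers"] = inl, _["n_inliers"] = best_count);
}
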