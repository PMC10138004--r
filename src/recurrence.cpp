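#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// copy an N x d matrix into point-major contiguous storage: p[i*d + k]
static std::vector<double> point_major(const NumericMatrix& m) {
  const int n = m.nrow(), d = m.ncol();
  std::vector<double> p((size_t)n * d);
  for (int k = 0; k < d; ++k) {
    const double* col = &m(0, k);
    for (int i = 0; i < n; ++i) p[(size_t)i * d + k] = col[i];
  }
  return p;
}

static inline double dist_pts(const double* a, const double* b, int d,
                              bool maxnorm) {
  if (maxnorm) {
    double m = 0.0;
    for (int k = 0; k < d; ++k) {
      double e = std::fabs(a[k] - b[k]);
      if (e > m) m = e;
    }
    return m;
  }
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    double e = a[k] - b[k];
    s += e * e;
  }
  return std::sqrt(s);
}

// [[Rcpp::export(name = ".cpp_cross_recurrence")]]
IntegerMatrix cpp_cross_recurrence(NumericMatrix a, NumericMatrix b,
                                   double eps, bool maxnorm) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  std::vector<double> pa = point_major(a), pb = point_major(b);
  IntegerMatrix out(n, m);
  if (maxnorm) {
    for (int j = 0; j < m; ++j) {
      const double* q = &pb[(size_t)j * d];
      int* col = &out(0, j);
      for (int i = 0; i < n; ++i) {
        const double* p = &pa[(size_t)i * d];
        int rec = 1;
        for (int k = 0; k < d; ++k) {
          if (std::fabs(p[k] - q[k]) > eps) { rec = 0; break; }
        }
        col[i] = rec;
      }
    }
  } else {
    const double eps2 = eps * eps;
    for (int j = 0; j < m; ++j) {
      const double* q = &pb[(size_t)j * d];
      int* col = &out(0, j);
      for (int i = 0; i < n; ++i) {
        const double* p = &pa[(size_t)i * d];
        double s = 0.0;
        int rec = 1;
        for (int k = 0; k < d; ++k) {
          double e = p[k] - q[k];
          s += e * e;
          if (s > eps2) { rec = 0; break; }
        }
        col[i] = rec;
      }
    }
  }
  return out;
}

// Exact maximum pairwise distance. Points are sorted by distance from the
// centroid; since dist(i, j) <= r_i + r_j (triangle inequality, any norm),
// pairs are examined in decreasing r order and the scan stops as soon as
// r_i + r_j cannot beat the incumbent, which prunes almost everything on
// compact clouds while remaining exact.
// [[Rcpp::export(name = ".cpp_max_pairwise_dist")]]
double cpp_max_pairwise_dist(NumericMatrix pts, bool maxnorm) {
  const int n = pts.nrow(), d = pts.ncol();
  if (n < 2) return 0.0;
  std::vector<double> p = point_major(pts);

  std::vector<double> centroid(d, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) centroid[k] += p[(size_t)i * d + k];
  for (int k = 0; k < d; ++k) centroid[k] /= n;

  std::vector<double> r(n);
  for (int i = 0; i < n; ++i)
    r[i] = dist_pts(&p[(size_t)i * d], centroid.data(), d, maxnorm);

  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&r](int a, int b) { return r[a] > r[b]; });

  // warm start: farthest point from centroid against everything
  double best = 0.0;
  const double* far0 = &p[(size_t)ord[0] * d];
  for (int i = 0; i < n; ++i) {
    double dd = dist_pts(far0, &p[(size_t)i * d], d, maxnorm);
    if (dd > best) best = dd;
  }

  for (int a = 0; a < n - 1; ++a) {
    int i = ord[a];
    if (2.0 * r[i] <= best) break;
    const double* pi = &p[(size_t)i * d];
    for (int b = a + 1; b < n; ++b) {
      int j = ord[b];
      if (r[i] + r[j] <= best) break;
      double dd = dist_pts(pi, &p[(size_t)j * d], d, maxnorm);
      if (dd > best) best = dd;
    }
  }
  return best;
}

// Histograms of maximal runs of 1s along (i+1, j+1) diagonals and down
// columns. Cells outside the matrix count as 0, so border-touching runs are
// maximal runs. Element k of each result = number of maximal runs of length k.
// [[Rcpp::export(name = ".cpp_line_histograms")]]
List cpp_line_histograms(IntegerMatrix m) {
  const int n = m.nrow(), mm = m.ncol();
  const int lmax = std::min(n, mm);
  std::vector<double> diag_h(lmax + 1, 0.0);
  std::vector<double> vert_h(n + 1, 0.0);

  // diagonals: start cells on first row and first column
  for (int s = -(n - 1); s <= mm - 1; ++s) {
    int i = (s < 0) ? -s : 0;
    int j = (s < 0) ? 0 : s;
    int run = 0;
    while (i < n && j < mm) {
      if (m(i, j) == 1) {
        ++run;
      } else if (run > 0) {
        diag_h[run] += 1.0;
        run = 0;
      }
      ++i; ++j;
    }
    if (run > 0) diag_h[run] += 1.0;
  }

  for (int j = 0; j < mm; ++j) {
    const int* col = &m(0, j);
    int run = 0;
    for (int i = 0; i < n; ++i) {
      if (col[i] == 1) {
        ++run;
      } else if (run > 0) {
        vert_h[run] += 1.0;
        run = 0;
      }
    }
    if (run > 0) vert_h[run] += 1.0;
  }

  NumericVector dh(diag_h.begin() + 1, diag_h.end());
  NumericVector vh(vert_h.begin() + 1, vert_h.end());
  return List::create(_["diagonal"] = dh, _["vertical"] = vh);
}

// Kennel false-nearest-neighbour fractions for dimensions 1..max_dim.
// x is the scalar series; embedding at dimension d uses delay t. For each
// reference point, the nearest neighbour in d dimensions is tested: a
// neighbour is false if |x[i+d*t] - x[nn+d*t]| / Rd > rtol, or if the
// (d+1)-dim distance exceeds atol times the attractor size (sd of x).
// stop_below: once a fraction drops below it, later dimensions are skipped
// (returned as NA). n_ref: number of evenly spaced reference points tested
// per dimension (neighbours are searched over all points); 0 = all points.
// [[Rcpp::export(name = ".cpp_fnn_fractions")]]
NumericVector cpp_fnn_fractions(NumericVector x, int t, int max_dim,
                                double rtol, double atol, double stop_below,
                                int n_ref) {
  const int len = x.size();
  double mu = 0.0;
  for (int i = 0; i < len; ++i) mu += x[i];
  mu /= len;
  double sd = 0.0;
  for (int i = 0; i < len; ++i) sd += (x[i] - mu) * (x[i] - mu);
  sd = std::sqrt(sd / (len - 1));

  NumericVector frac(max_dim, NA_REAL);
  for (int d = 1; d <= max_dim; ++d) {
    // need the (d+1)-th coordinate to test, so restrict to points with
    // index + d*t < len
    int npts = len - d * t;
    if (npts < 2) break;
    int nfalse = 0, ntested = 0;
    int nr = (n_ref > 0 && n_ref < npts) ? n_ref : npts;
    double step = (double)npts / nr;
    for (int r = 0; r < nr; ++r) {
      int i = (int)(r * step);
      if (i >= npts) break;
      // nearest neighbour of point i in d-dim embedding (brute force)
      double bestd2 = R_PosInf;
      int best = -1;
      for (int j = 0; j < npts; ++j) {
        if (j == i) continue;
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          double e = x[i + k * t] - x[j + k * t];
          s += e * e;
          if (s >= bestd2) break;
        }
        if (s < bestd2) { bestd2 = s; best = j; }
      }
      if (best < 0) continue;
      double rd = std::sqrt(bestd2);
      double extra = std::fabs(x[i + d * t] - x[best + d * t]);
      bool false_nb;
      if (rd > 0) {
        double rd1 = std::sqrt(bestd2 + extra * extra);
        false_nb = (extra / rd > rtol) || (rd1 / sd > atol);
      } else {
        false_nb = (extra / sd > atol);
      }
      ++ntested;
      if (false_nb) ++nfalse;
    }
    if (ntested == 0) break;
    frac[d - 1] = (double)nfalse / ntested;
    if (frac[d - 1] < stop_below) break;
  }
  return frac;
}
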