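#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fibers are stored row-wise as flat vectors of length 3*np with layout
// [x_0..x_{np-1} | y_0..y_{np-1} | z_0..z_{np-1}] after equal-arclength
// resampling to np points.  Distances are in the same units as the
// coordinates (millimetres throughout the package).

static inline double sqdist_pt(const double *a, const double *b, int np, int i, int j,
                               double bsign) {
  double dx = a[i] - bsign * b[j];
  double dy = a[np + i] - b[np + j];
  double dz = a[2 * np + i] - b[2 * np + j];
  return dx * dx + dy * dy + dz * dz;
}

// mean corresponding-point distance, forward or reversed ordering of b;
// bsign = -1 mirrors b across the x=0 plane
static double mean_corr(const double *a, const double *b, int np, bool rev, double bsign) {
  double s = 0.0;
  for (int i = 0; i < np; ++i) {
    int j = rev ? (np - 1 - i) : i;
    s += std::sqrt(sqdist_pt(a, b, np, i, j, bsign));
  }
  return s / np;
}

// symmetrised mean closest-point distance (orientation invariant)
static double mean_closest(const double *a, const double *b, int np, double bsign) {
  double sab = 0.0, sba = 0.0;
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < np; ++j) {
      double d = sqdist_pt(a, b, np, i, j, bsign);
      if (d < best) best = d;
    }
    sab += std::sqrt(best);
  }
  for (int j = 0; j < np; ++j) {
    double best = R_PosInf;
    for (int i = 0; i < np; ++i) {
      double d = sqdist_pt(a, b, np, i, j, bsign);
      if (d < best) best = d;
    }
    sba += std::sqrt(best);
  }
  return 0.5 * (sab + sba) / np;
}

static double pair_dist(const double *a, const double *b, int np, bool bilateral, int mode) {
  double d;
  if (mode == 0) {
    d = std::min(mean_corr(a, b, np, false, 1.0), mean_corr(a, b, np, true, 1.0));
    if (bilateral) {
      double dm = std::min(mean_corr(a, b, np, false, -1.0), mean_corr(a, b, np, true, -1.0));
      if (dm < d) d = dm;
    }
  } else {
    d = mean_closest(a, b, np, 1.0);
    if (bilateral) {
      double dm = mean_closest(a, b, np, -1.0);
      if (dm < d) d = dm;
    }
  }
  return d;
}

// [[Rcpp::export(name = ".pairwise_fiber_dist")]]
NumericMatrix pairwise_fiber_dist_cpp(NumericMatrix A, NumericMatrix B,
                                      bool bilateral, int mode) {
  const int ma = A.nrow(), mb = B.nrow();
  if (A.ncol() != B.ncol()) stop("fiber point counts differ between sets");
  if (A.ncol() % 3 != 0) stop("flat fiber matrix width must be a multiple of 3");
  const int np = A.ncol() / 3;
  NumericMatrix D(ma, mb);
  std::vector<double> arow(3 * np), brow(3 * np);
  for (int i = 0; i < ma; ++i) {
    for (int c = 0; c < 3 * np; ++c) arow[c] = A(i, c);
    for (int j = 0; j < mb; ++j) {
      for (int c = 0; c < 3 * np; ++c) brow[c] = B(j, c);
      D(i, j) = pair_dist(arow.data(), brow.data(), np, bilateral, mode);
    }
  }
  return D;
}
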