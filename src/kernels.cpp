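#include <Rcpp.h>
using namespace Rcpp;

// Segment arrays are kept in topological order: parent[i] < i (1-based,
// 0 marks the trunk).  All kernels rely on this invariant.

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Sum a quantity over each segment's subtree (self included).
// [[Rcpp::export]]
NumericMatrix cpp_acc_to_root(IntegerVector parent, NumericMatrix x) {
  int n = parent.size(), k = x.ncol();
  NumericMatrix s = clone(x);
  for (int i = n - 1; i >= 0; --i) {
    int p = parent[i] - 1;
    if (p >= 0)
      for (int j = 0; j < k; ++j) s(p, j) += s(i, j);
  }
  return s;
}

// Cumulative sum along the path from the root down to each segment.
// [[Rcpp::export]]
NumericMatrix cpp_cum_from_root(IntegerVector parent, NumericMatrix x) {
  int n = parent.size(), k = x.ncol();
  NumericMatrix s = clone(x);
  for (int i = 0; i < n; ++i) {
    int p = parent[i] - 1;
    if (p >= 0)
      for (int j = 0; j < k; ++j) s(i, j) += s(p, j);
  }
  return s;
}

// Strahler ranks: twigs are rank 1; a parent of two equal-rank-r children
// has rank r + 1, otherwise the maximum child rank.
// [[Rcpp::export]]
IntegerVector cpp_strahler(IntegerVector parent) {
  int n = parent.size();
  IntegerVector rank(n), cmax(n, 0), ctie(n, 0);
  for (int i = n - 1; i >= 0; --i) {
    rank[i] = (cmax[i] == 0) ? 1 : (ctie[i] >= 2 ? cmax[i] + 1 : cmax[i]);
    int p = parent[i] - 1;
    if (p >= 0) {
      if (rank[i] > cmax[p]) { cmax[p] = rank[i]; ctie[p] = 1; }
      else if (rank[i] == cmax[p]) ctie[p]++;
    }
  }
  return rank;
}

// Wind loads on one tree for a uniform horizontal wind U*u.
// Foliage drag 0.5*CY*U^2*Sfol*u acts at twig distal ends; segment drag
// 0.5*CY*U^2*d*L*|t x u|^2 (n x t), n = t x u / |t x u|, at midpoints.
// Forces and moments are folded from the leaves to the root; sigma is the
// maximal surface bending stress (32/pi)*|M_base x t|/d^3 in units of the
// material strength.
// [[Rcpp::export]]
List cpp_tree_loads(IntegerVector parent, NumericMatrix tmat,
                    NumericVector d, LogicalVector twig,
                    double U, NumericVector u,
                    double CY, double Sfol, double L) {
  int n = parent.size();
  NumericMatrix Fb(n, 3), Mb(n, 3);
  NumericVector sigma(n);
  std::vector<double> Ftop(3 * n, 0.0), Mtop(3 * n, 0.0);
  double q = 0.5 * CY * U * U;
  double ffol[3] = {q * Sfol * u[0], q * Sfol * u[1], q * Sfol * u[2]};
  double t[3], tcu[3], nv[3], fseg[3], mseg[3], fb[3], mb[3], tmp[3];
  for (int i = n - 1; i >= 0; --i) {
    t[0] = tmat(i, 0); t[1] = tmat(i, 1); t[2] = tmat(i, 2);
    cross3(t, &u[0], tcu);
    double s2 = tcu[0] * tcu[0] + tcu[1] * tcu[1] + tcu[2] * tcu[2];
    if (s2 > 1e-24) {
      double s = std::sqrt(s2);
      nv[0] = tcu[0] / s; nv[1] = tcu[1] / s; nv[2] = tcu[2] / s;
      cross3(nv, t, tmp);
      double mag = q * d[i] * L * s2;
      fseg[0] = mag * tmp[0]; fseg[1] = mag * tmp[1]; fseg[2] = mag * tmp[2];
    } else {
      fseg[0] = fseg[1] = fseg[2] = 0.0;
    }
    cross3(t, fseg, mseg);
    mseg[0] *= 0.5 * L; mseg[1] *= 0.5 * L; mseg[2] *= 0.5 * L;
    double* ft = &Ftop[3 * i];
    double* mt = &Mtop[3 * i];
    if (twig[i]) { ft[0] += ffol[0]; ft[1] += ffol[1]; ft[2] += ffol[2]; }
    cross3(t, ft, tmp);
    for (int j = 0; j < 3; ++j) {
      fb[j] = fseg[j] + ft[j];
      mb[j] = mseg[j] + mt[j] + L * tmp[j];
      Fb(i, j) = fb[j]; Mb(i, j) = mb[j];
    }
    cross3(mb, t, tmp);
    double bend = std::sqrt(tmp[0] * tmp[0] + tmp[1] * tmp[1] +
                            tmp[2] * tmp[2]);
    sigma[i] = (32.0 / M_PI) * bend / (d[i] * d[i] * d[i]);
    int p = parent[i] - 1;
    if (p >= 0) {
      double* fp = &Ftop[3 * p];
      double* mp = &Mtop[3 * p];
      for (int j = 0; j < 3; ++j) { fp[j] += fb[j]; mp[j] += mb[j]; }
    }
  }
  return List::create(_["F_base"] = Fb, _["M_base"] = Mb,
                      _["sigma"] = sigma);
}

// Maximum of the bending stress over n_az wind azimuths at U = 1, and the
// norm of the bending moment at the worst azimuth (used for the fracture
// target volume).
// [[Rcpp::export]]
List cpp_max_stress(IntegerVector parent, NumericMatrix tmat,
                    NumericVector d, LogicalVector twig,
                    double CY, double Sfol, double L, int n_az) {
  int n = parent.size();
  NumericVector smax(n, 0.0), mmax(n, 0.0);
  NumericVector u(3);
  for (int a = 0; a < n_az; ++a) {
    double phi = 2.0 * M_PI * a / n_az;
    u[0] = std::cos(phi); u[1] = std::sin(phi); u[2] = 0.0;
    List lo = cpp_tree_loads(parent, tmat, d, twig, 1.0, u, CY, Sfol, L);
    NumericVector sig = lo["sigma"];
    for (int i = 0; i < n; ++i) {
      if (sig[i] > smax[i]) {
        smax[i] = sig[i];
        mmax[i] = sig[i] * M_PI * d[i] * d[i] * d[i] / 32.0;
      }
    }
  }
  return List::create(_["sigma_max"] = smax, _["m_bend"] = mmax);
}
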