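#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

// Convex-hull volume in arbitrary (small) dimension by enumeration of
// supporting hyperplanes.  Every d-subset of points that spans a hyperplane
// with all points on one side is a supporting hyperplane; unique hyperplanes
// are collected, the (d-1)-volume of each facet is obtained recursively after
// projecting the on-plane points into an orthonormal in-plane basis, and the
// d-volume is the sum of cone volumes h * facetVol / d from an interior point.
// No point perturbation ("joggling") is applied: affinely degenerate inputs
// yield volume 0, which the R wrapper reports as undefined.
//
// Cost is O(C(n,d) * n) per level, intended for assemblage-sized point sets
// (n up to a few hundred) in d <= 4 standardized trait dimensions.

namespace {

typedef std::vector<double> Vec;
typedef std::vector<Vec> Mat;

double detSmall(Mat a) {
  // LU with partial pivoting; a is square, destroyed
  int n = a.size();
  double det = 1.0;
  for (int c = 0; c < n; ++c) {
    int piv = c;
    for (int r = c + 1; r < n; ++r)
      if (std::fabs(a[r][c]) > std::fabs(a[piv][c])) piv = r;
    if (a[piv][c] == 0.0) return 0.0;
    if (piv != c) { std::swap(a[piv], a[c]); det = -det; }
    det *= a[c][c];
    for (int r = c + 1; r < n; ++r) {
      double f = a[r][c] / a[c][c];
      for (int k = c; k < n; ++k) a[r][k] -= f * a[c][k];
    }
  }
  return det;
}

// normal of the hyperplane through d points (rows of P indexed by idx),
// via the generalized cross product (cofactor expansion)
Vec hyperplaneNormal(const Mat &P, const std::vector<int> &idx, int d) {
  Vec nrm(d, 0.0);
  // rows: p[idx[j]] - p[idx[0]], j = 1..d-1  -> (d-1) x d matrix
  Mat A(d - 1, Vec(d));
  for (int j = 1; j < d; ++j)
    for (int k = 0; k < d; ++k)
      A[j - 1][k] = P[idx[j]][k] - P[idx[0]][k];
  int sgn = 1;
  for (int k = 0; k < d; ++k) {
    Mat sub(d - 1, Vec(d - 1));
    for (int r = 0; r < d - 1; ++r) {
      int cc = 0;
      for (int c = 0; c < d; ++c)
        if (c != k) sub[r][cc++] = A[r][c];
    }
    nrm[k] = sgn * detSmall(sub);
    sgn = -sgn;
  }
  return nrm;
}

double hullVolRec(const Mat &P, int d);

// polygon/segment/facet volume of on-plane points: project into an
// orthonormal basis of the hyperplane and recurse one dimension down
double facetVolume(const Mat &P, const std::vector<int> &facetPts, int d) {
  int m = facetPts.size();
  if (m < d) return 0.0;  // cannot span a (d-1)-dim facet
  const Vec &origin = P[facetPts[0]];
  // Gram-Schmidt an orthonormal basis of dimension d-1 from point differences
  Mat basis;
  for (int i = 1; i < m && (int)basis.size() < d - 1; ++i) {
    Vec v(d);
    for (int k = 0; k < d; ++k) v[k] = P[facetPts[i]][k] - origin[k];
    for (size_t b = 0; b < basis.size(); ++b) {
      double dot = 0.0;
      for (int k = 0; k < d; ++k) dot += v[k] * basis[b][k];
      for (int k = 0; k < d; ++k) v[k] -= dot * basis[b][k];
    }
    double nv = 0.0;
    for (int k = 0; k < d; ++k) nv += v[k] * v[k];
    nv = std::sqrt(nv);
    if (nv > 1e-10) {
      for (int k = 0; k < d; ++k) v[k] /= nv;
      basis.push_back(v);
    }
  }
  if ((int)basis.size() < d - 1) return 0.0;  // degenerate facet
  Mat proj(m, Vec(d - 1));
  for (int i = 0; i < m; ++i)
    for (int b = 0; b < d - 1; ++b) {
      double dot = 0.0;
      for (int k = 0; k < d; ++k)
        dot += (P[facetPts[i]][k] - origin[k]) * basis[b][k];
      proj[i][b] = dot;
    }
  return hullVolRec(proj, d - 1);
}

double hullVolRec(const Mat &P, int d) {
  int n = P.size();
  if (d == 1) {
    double lo = P[0][0], hi = P[0][0];
    for (int i = 1; i < n; ++i) {
      lo = std::min(lo, P[i][0]);
      hi = std::max(hi, P[i][0]);
    }
    return hi - lo;
  }
  if (n < d + 1) return 0.0;

  double scale = 1.0;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) scale = std::max(scale, std::fabs(P[i][k]));
  const double epsSide = 1e-9 * scale;   // one-sidedness / on-plane tolerance
  const double epsDup = 1e-7;            // hyperplane dedup (unit normal + offset)

  Vec centroid(d, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) centroid[k] += P[i][k] / n;

  std::vector<Vec> seenN;   // unit outward normals of accepted facets
  Vec seenOff;              // their offsets
  double vol = 0.0;

  std::vector<int> idx(d);
  for (int i = 0; i < d; ++i) idx[i] = i;
  bool more = (n >= d);
  while (more) {
    Vec nrm = hyperplaneNormal(P, idx, d);
    double nn = 0.0;
    for (int k = 0; k < d; ++k) nn += nrm[k] * nrm[k];
    nn = std::sqrt(nn);
    if (nn > 1e-12 * std::pow(scale, d - 1)) {
      for (int k = 0; k < d; ++k) nrm[k] /= nn;
      double off = 0.0;
      for (int k = 0; k < d; ++k) off += nrm[k] * P[idx[0]][k];
      double smin = 0.0, smax = 0.0;
      for (int i = 0; i < n; ++i) {
        double s = -off;
        for (int k = 0; k < d; ++k) s += nrm[k] * P[i][k];
        smin = std::min(smin, s);
        smax = std::max(smax, s);
        if (smin < -epsSide && smax > epsSide) break;  // not supporting
      }
      bool supporting = (smin >= -epsSide) || (smax <= epsSide);
      if (supporting) {
        if (smin >= -epsSide) {  // flip so hull is on the negative side
          for (int k = 0; k < d; ++k) nrm[k] = -nrm[k];
          off = -off;
        }
        bool dup = false;
        for (size_t f = 0; f < seenN.size() && !dup; ++f) {
          double dot = 0.0;
          for (int k = 0; k < d; ++k) dot += nrm[k] * seenN[f][k];
          if (std::fabs(dot - 1.0) < epsDup &&
              std::fabs(off - seenOff[f]) < epsDup * scale)
            dup = true;
        }
        if (!dup) {
          seenN.push_back(nrm);
          seenOff.push_back(off);
          std::vector<int> facetPts;
          for (int i = 0; i < n; ++i) {
            double s = -off;
            for (int k = 0; k < d; ++k) s += nrm[k] * P[i][k];
            if (std::fabs(s) <= epsSide) facetPts.push_back(i);
          }
          double s = 0.0;  // distance of the interior centroid to the plane
          for (int k = 0; k < d; ++k) s += nrm[k] * centroid[k];
          double h = std::fabs(s - off);
          vol += h * facetVolume(P, facetPts, d) / d;
        }
      }
    }
    // next combination
    int pos = d - 1;
    while (pos >= 0 && idx[pos] == n - d + pos) --pos;
    if (pos < 0) more = false;
    else {
      ++idx[pos];
      for (int j = pos + 1; j < d; ++j) idx[j] = idx[j - 1] + 1;
    }
  }
  return vol;
}

}  // namespace

// [[Rcpp::export(name = ".hull_volume_cpp")]]
double hull_volume_cpp(Rcpp::NumericMatrix pts) {
  int n = pts.nrow(), d = pts.ncol();
  if (d < 1) Rcpp::stop("points must have at least one column");
  if (n < d + 1) return NA_REAL;
  Mat P(n, Vec(d));
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) {
      P[i][k] = pts(i, k);
      if (!R_finite(P[i][k])) Rcpp::stop("non-finite trait coordinate");
    }
  double v = hullVolRec(P, d);
  double scale = 1.0;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) scale = std::max(scale, std::fabs(P[i][k]));
  if (v <= 1e-12 * std::pow(scale, d)) return NA_REAL;  // affinely degenerate
  return v;
}
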