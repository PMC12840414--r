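// Voxel-column volume integration: the volume of a closed mesh is measured
// by casting vertical (z-direction) lines on a regular xy grid, collecting
// triangle crossings, pairing them by parity into inside intervals, and
// summing interval lengths times the column footprint. Serves as the
// independent oracle for the exact signed-tetrahedron and CSG volumes.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tri2 {
  double x1, y1, x2, y2, x3, y3;   // xy projection
  double z1, z2, z3;
  double d;                        // projected double-area (signed)
  double xmin, xmax, ymin, ymax;
};

std::vector<Tri2> project(const NumericMatrix& V, const IntegerMatrix& F) {
  std::vector<Tri2> tris;
  tris.reserve(F.nrow());
  for (int i = 0; i < F.nrow(); ++i) {
    Tri2 t;
    int a = F(i, 0) - 1, b = F(i, 1) - 1, c = F(i, 2) - 1;
    t.x1 = V(a, 0); t.y1 = V(a, 1); t.z1 = V(a, 2);
    t.x2 = V(b, 0); t.y2 = V(b, 1); t.z2 = V(b, 2);
    t.x3 = V(c, 0); t.y3 = V(c, 1); t.z3 = V(c, 2);
    t.d = (t.x2 - t.x1) * (t.y3 - t.y1) - (t.x3 - t.x1) * (t.y2 - t.y1);
    if (std::fabs(t.d) < 1e-14) continue;  // vertical triangle: no z-crossing
    t.xmin = std::min({t.x1, t.x2, t.x3}); t.xmax = std::max({t.x1, t.x2, t.x3});
    t.ymin = std::min({t.y1, t.y2, t.y3}); t.ymax = std::max({t.y1, t.y2, t.y3});
    tris.push_back(t);
  }
  return tris;
}

// crossing z-values of the vertical line at (x, y); false if the line grazes
// an edge or vertex (caller jitters and retries)
bool crossings(const std::vector<Tri2>& tris, double x, double y,
               std::vector<double>& zs) {
  zs.clear();
  for (const auto& t : tris) {
    if (x < t.xmin || x > t.xmax || y < t.ymin || y > t.ymax) continue;
    double l1 = ((t.y2 - t.y3) * (x - t.x3) + (t.x3 - t.x2) * (y - t.y3)) / t.d;
    double l2 = ((t.y3 - t.y1) * (x - t.x3) + (t.x1 - t.x3) * (y - t.y3)) / t.d;
    double l3 = 1.0 - l1 - l2;
    const double edge_eps = 1e-12;
    if (l1 < -edge_eps || l2 < -edge_eps || l3 < -edge_eps) continue;
    if (l1 < edge_eps || l2 < edge_eps || l3 < edge_eps) return false; // grazing
    zs.push_back(l1 * t.z1 + l2 * t.z2 + l3 * t.z3);
  }
  std::sort(zs.begin(), zs.end());
  return (zs.size() % 2) == 0;
}

// inside intervals for a column, with grazing handled by deterministic jitter
bool column_intervals(const std::vector<Tri2>& tris, double x, double y,
                      double pitch, std::vector<double>& zs) {
  for (int attempt = 0; attempt < 5; ++attempt) {
    double jx = x + attempt * 1.31e-4 * pitch;
    double jy = y + attempt * 0.97e-4 * pitch;
    if (crossings(tris, jx, jy, zs)) return true;
  }
  return false;
}

double overlap_length(const std::vector<double>& a, const std::vector<double>& b) {
  double len = 0;
  for (size_t i = 0; i + 1 < a.size(); i += 2) {
    for (size_t j = 0; j + 1 < b.size(); j += 2) {
      double lo = std::max(a[i], b[j]);
      double hi = std::min(a[i + 1], b[j + 1]);
      if (hi > lo) len += hi - lo;
    }
  }
  return len;
}

} // namespace

// [[Rcpp::export]]
double column_volume_cpp(NumericMatrix V, IntegerMatrix F, double pitch) {
  std::vector<Tri2> tris = project(V, F);
  if (tris.empty()) return 0.0;
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (const auto& t : tris) {
    xmin = std::min(xmin, t.xmin); xmax = std::max(xmax, t.xmax);
    ymin = std::min(ymin, t.ymin); ymax = std::max(ymax, t.ymax);
  }
  int nx = (int)std::ceil((xmax - xmin) / pitch);
  int ny = (int)std::ceil((ymax - ymin) / pitch);
  double vol = 0;
  std::vector<double> zs;
  for (int i = 0; i < nx; ++i) {
    double x = xmin + (i + 0.5) * pitch;
    for (int j = 0; j < ny; ++j) {
      double y = ymin + (j + 0.5) * pitch;
      if (!column_intervals(tris, x, y, pitch, zs)) continue;
      for (size_t k = 0; k + 1 < zs.size(); k += 2) vol += zs[k + 1] - zs[k];
    }
  }
  return vol * pitch * pitch;
}

// [[Rcpp::export]]
NumericVector surface_z_max_cpp(NumericMatrix V, IntegerMatrix F,
                                NumericVector xs, NumericVector ys) {
  // topmost z of the surface above each (x, y); NA where the vertical line
  // misses the mesh
  std::vector<Tri2> tris = project(V, F);
  int n = xs.size();
  NumericVector out(n, NA_REAL);
  std::vector<double> zs;
  for (int i = 0; i < n; ++i) {
    bool ok = false;
    for (int attempt = 0; attempt < 5 && !ok; ++attempt) {
      double jx = xs[i] + attempt * 1.7e-7;
      double jy = ys[i] + attempt * 1.3e-7;
      zs.clear();
      ok = true;
      for (const auto& t : tris) {
        if (jx < t.xmin || jx > t.xmax || jy < t.ymin || jy > t.ymax) continue;
        double l1 = ((t.y2 - t.y3) * (jx - t.x3) + (t.x3 - t.x2) * (jy - t.y3)) / t.d;
        double l2 = ((t.y3 - t.y1) * (jx - t.x3) + (t.x1 - t.x3) * (jy - t.y3)) / t.d;
        double l3 = 1.0 - l1 - l2;
        const double edge_eps = 1e-12;
        if (l1 < -edge_eps || l2 < -edge_eps || l3 < -edge_eps) continue;
        if (l1 < edge_eps || l2 < edge_eps || l3 < edge_eps) { ok = false; break; }
        zs.push_back(l1 * t.z1 + l2 * t.z2 + l3 * t.z3);
      }
    }
    if (!zs.empty())
      out[i] = *std::max_element(zs.begin(), zs.end());
  }
  return out;
}

// [[Rcpp::export]]
double column_intersect_volume_cpp(NumericMatrix Va, IntegerMatrix Fa,
                                   NumericMatrix Vb, IntegerMatrix Fb,
                                   double pitch) {
  std::vector<Tri2> ta = project(Va, Fa);
  std::vector<Tri2> tb = project(Vb, Fb);
  if (ta.empty() || tb.empty()) return 0.0;
  double axmin = R_PosInf, axmax = R_NegInf, aymin = R_PosInf, aymax = R_NegInf;
  for (const auto& t : ta) {
    axmin = std::min(axmin, t.xmin); axmax = std::max(axmax, t.xmax);
    aymin = std::min(aymin, t.ymin); aymax = std::max(aymax, t.ymax);
  }
  double bxmin = R_PosInf, bxmax = R_NegInf, bymin = R_PosInf, bymax = R_NegInf;
  for (const auto& t : tb) {
    bxmin = std::min(bxmin, t.xmin); bxmax = std::max(bxmax, t.xmax);
    bymin = std::min(bymin, t.ymin); bymax = std::max(bymax, t.ymax);
  }
  double xmin = std::max(axmin, bxmin), xmax = std::min(axmax, bxmax);
  double ymin = std::max(aymin, bymin), ymax = std::min(aymax, bymax);
  if (xmax <= xmin || ymax <= ymin) return 0.0;
  int nx = (int)std::ceil((xmax - xmin) / pitch);
  int ny = (int)std::ceil((ymax - ymin) / pitch);
  double vol = 0;
  std::vector<double> za, zb;
  for (int i = 0; i < nx; ++i) {
    double x = xmin + (i + 0.5) * pitch;
    for (int j = 0; j < ny; ++j) {
      double y = ymin + (j + 0.5) * pitch;
      if (!column_intervals(ta, x, y, pitch, za)) continue;
      if (za.empty()) continue;
      if (!column_intervals(tb, x, y, pitch, zb)) continue;
      vol += overlap_length(za, zb);
    }
  }
  return vol * pitch * pitch;
}
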