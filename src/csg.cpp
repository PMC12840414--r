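// Boolean intersection of closed triangle meshes via BSP-tree CSG
// (constructive solid geometry by mutual clipping of polygon sets).
// Polygons produced by plane splits stay convex because the inputs are
// triangles, so fan triangulation of the output is valid.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double EPS = 1e-5; // plane-side classification tolerance (mm)

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};
inline V3 operator-(const V3& a, const V3& b) { return V3(a.x-b.x, a.y-b.y, a.z-b.z); }
inline V3 operator+(const V3& a, const V3& b) { return V3(a.x+b.x, a.y+b.y, a.z+b.z); }
inline V3 operator*(const V3& a, double s) { return V3(a.x*s, a.y*s, a.z*s); }
inline double dot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
inline V3 lerp(const V3& a, const V3& b, double t) { return a + (b - a) * t; }

struct Plane {
  V3 n; double w; bool ok;
  Plane() : w(0), ok(false) {}
  Plane(const V3& a, const V3& b, const V3& c) {
    V3 cr = cross(b - a, c - a);
    double len = std::sqrt(dot(cr, cr));
    if (len < 1e-30) { ok = false; w = 0; return; }
    n = cr * (1.0 / len); w = dot(n, a); ok = true;
  }
  void flip() { n = n * (-1.0); w = -w; }
};

struct Poly {
  std::vector<V3> v;
  Plane p;
  void flip() {
    std::reverse(v.begin(), v.end());
    p.flip();
  }
};

enum { COPLANAR = 0, FRONT = 1, BACK = 2, SPANNING = 3 };

void split_polygon(const Plane& plane, const Poly& poly,
                   std::vector<Poly>& coFront, std::vector<Poly>& coBack,
                   std::vector<Poly>& front, std::vector<Poly>& back) {
  int polyType = 0;
  std::vector<int> types(poly.v.size());
  for (size_t i = 0; i < poly.v.size(); ++i) {
    double t = dot(plane.n, poly.v[i]) - plane.w;
    int ty = (t < -EPS) ? BACK : (t > EPS) ? FRONT : COPLANAR;
    polyType |= ty;
    types[i] = ty;
  }
  switch (polyType) {
  case COPLANAR:
    (dot(plane.n, poly.p.n) > 0 ? coFront : coBack).push_back(poly);
    break;
  case FRONT: front.push_back(poly); break;
  case BACK:  back.push_back(poly);  break;
  case SPANNING: {
    std::vector<V3> f, b;
    size_t n = poly.v.size();
    for (size_t i = 0; i < n; ++i) {
      size_t j = (i + 1) % n;
      int ti = types[i], tj = types[j];
      const V3 &vi = poly.v[i], &vj = poly.v[j];
      if (ti != BACK) f.push_back(vi);
      if (ti != FRONT) b.push_back(vi);
      if ((ti | tj) == SPANNING) {
        double t = (plane.w - dot(plane.n, vi)) / dot(plane.n, vj - vi);
        V3 vv = lerp(vi, vj, t);
        f.push_back(vv);
        b.push_back(vv);
      }
    }
    if (f.size() >= 3) { Poly pf; pf.v = f; pf.p = poly.p; front.push_back(pf); }
    if (b.size() >= 3) { Poly pb; pb.v = b; pb.p = poly.p; back.push_back(pb); }
    break;
  }
  }
}

struct Node {
  Plane plane;
  bool hasPlane;
  Node *front, *back;
  std::vector<Poly> polys;
  Node() : hasPlane(false), front(nullptr), back(nullptr) {}
  ~Node() { delete front; delete back; }

  void invert() {
    for (auto& p : polys) p.flip();
    if (hasPlane) plane.flip();
    if (front) front->invert();
    if (back) back->invert();
    std::swap(front, back);
  }

  std::vector<Poly> clip_polygons(const std::vector<Poly>& list) const {
    if (!hasPlane) return list;
    std::vector<Poly> f, b;
    for (const auto& p : list) split_polygon(plane, p, f, b, f, b);
    if (front) f = front->clip_polygons(f);
    if (back) b = back->clip_polygons(b); else b.clear();
    f.insert(f.end(), b.begin(), b.end());
    return f;
  }

  void clip_to(const Node* bsp) {
    polys = bsp->clip_polygons(polys);
    if (front) front->clip_to(bsp);
    if (back) back->clip_to(bsp);
  }

  void all_polygons(std::vector<Poly>& out) const {
    out.insert(out.end(), polys.begin(), polys.end());
    if (front) front->all_polygons(out);
    if (back) back->all_polygons(out);
  }

  void build(const std::vector<Poly>& list) {
    if (list.empty()) return;
    size_t start = 0;
    if (!hasPlane) {
      plane = list[0].p;
      hasPlane = true;
      polys.push_back(list[0]);
      start = 1;
    }
    std::vector<Poly> f, b;
    for (size_t i = start; i < list.size(); ++i)
      split_polygon(plane, list[i], polys, polys, f, b);
    if (!f.empty()) { if (!front) front = new Node(); front->build(f); }
    if (!b.empty()) { if (!back) back = new Node(); back->build(b); }
  }
};

// Deterministic Fisher-Yates shuffle (fixed LCG). Structured scan meshes
// list triangles in grid order, which degenerates the BSP tree; a shuffled
// insertion order keeps it balanced without affecting the result.
void shuffle_polys(std::vector<Poly>& v) {
  unsigned long long s = 88172645463325252ULL;
  for (size_t i = v.size(); i > 1; --i) {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    std::swap(v[i - 1], v[s % i]);
  }
}

std::vector<Poly> to_polys(const NumericMatrix& V, const IntegerMatrix& F) {
  std::vector<Poly> out;
  out.reserve(F.nrow());
  for (int i = 0; i < F.nrow(); ++i) {
    Poly p;
    for (int k = 0; k < 3; ++k) {
      int vi = F(i, k) - 1;
      p.v.push_back(V3(V(vi, 0), V(vi, 1), V(vi, 2)));
    }
    p.p = Plane(p.v[0], p.v[1], p.v[2]);
    if (p.p.ok) out.push_back(p);
  }
  return out;
}

double polys_volume(const std::vector<Poly>& polys) {
  // divergence-theorem sum of signed tetrahedra against the origin,
  // fanning each convex polygon from its first vertex
  double vol = 0;
  for (const auto& p : polys) {
    for (size_t k = 1; k + 1 < p.v.size(); ++k) {
      vol += dot(p.v[0], cross(p.v[k], p.v[k + 1]));
    }
  }
  return vol / 6.0;
}

} // namespace

// [[Rcpp::export]]
List csg_intersect_cpp(NumericMatrix Va, IntegerMatrix Fa,
                       NumericMatrix Vb, IntegerMatrix Fb) {
  std::vector<Poly> pa = to_polys(Va, Fa);
  std::vector<Poly> pb = to_polys(Vb, Fb);
  shuffle_polys(pa);
  shuffle_polys(pb);

  // intersection = ~(~A u ~B)
  Node a, b;
  a.build(pa);
  b.build(pb);
  a.invert();
  b.clip_to(&a);
  b.invert();
  a.clip_to(&b);
  b.clip_to(&a);
  std::vector<Poly> bAll;
  b.all_polygons(bAll);
  a.build(bAll);
  a.invert();

  std::vector<Poly> res;
  a.all_polygons(res);

  double vol = polys_volume(res);

  // triangulate by fanning; drop degenerate slivers
  std::vector<double> vx, vy, vz;
  std::vector<int> f1, f2, f3;
  for (const auto& p : res) {
    for (size_t k = 1; k + 1 < p.v.size(); ++k) {
      const V3 &A = p.v[0], &B = p.v[k], &C = p.v[k + 1];
      V3 cr = cross(B - A, C - A);
      if (std::sqrt(dot(cr, cr)) < 1e-14) continue;
      int base = (int)vx.size();
      vx.push_back(A.x); vy.push_back(A.y); vz.push_back(A.z);
      vx.push_back(B.x); vy.push_back(B.y); vz.push_back(B.z);
      vx.push_back(C.x); vy.push_back(C.y); vz.push_back(C.z);
      f1.push_back(base + 1); f2.push_back(base + 2); f3.push_back(base + 3);
    }
  }
  NumericMatrix V((int)vx.size(), 3);
  for (size_t i = 0; i < vx.size(); ++i) {
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
  }
  IntegerMatrix F((int)f1.size(), 3);
  for (size_t i = 0; i < f1.size(); ++i) {
    F(i, 0) = f1[i]; F(i, 1) = f2[i]; F(i, 2) = f3[i];
  }
  return List::create(_["vertices"] = V, _["faces"] = F, _["volume"] = vol);
}
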