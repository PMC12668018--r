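// Quadric-error-metric mesh decimation (Garland-Heckbert edge collapse).
//
// Collapses the cheapest edges first, where the cost of moving the merged
// vertex to position v is v' (Qa + Qb) v with Q the accumulated plane
// quadrics of each endpoint. Boundary edges contribute a large penalty
// quadric for the plane through the edge perpendicular to the incident
// face, which keeps open rims in place. Collapses that would break local
// manifoldness (link condition) or flip a surviving face normal are
// rejected. The loop stops when exactly `target` faces remain.

#include <Rcpp.h>
#include <queue>
#include <set>
#include <map>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Quad {
  double q[10]; // xx xy xz xw yy yz yw zz zw ww
  Quad() { std::fill(q, q + 10, 0.0); }
  void add_plane(double a, double b, double c, double d, double w) {
    q[0] += w * a * a; q[1] += w * a * b; q[2] += w * a * c; q[3] += w * a * d;
    q[4] += w * b * b; q[5] += w * b * c; q[6] += w * b * d;
    q[7] += w * c * c; q[8] += w * c * d; q[9] += w * d * d;
  }
  void add(const Quad &o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(const double *v) const {
    const double x = v[0], y = v[1], z = v[2];
    return q[0] * x * x + 2 * q[1] * x * y + 2 * q[2] * x * z + 2 * q[3] * x
         + q[4] * y * y + 2 * q[5] * y * z + 2 * q[6] * y
         + q[7] * z * z + 2 * q[8] * z + q[9];
  }
  // Minimizer of the quadric form, if the 3x3 system is well conditioned.
  bool optimal(double *out) const {
    const double a11 = q[0], a12 = q[1], a13 = q[2];
    const double a22 = q[4], a23 = q[5], a33 = q[7];
    const double b1 = -q[3], b2 = -q[6], b3 = -q[8];
    const double det = a11 * (a22 * a33 - a23 * a23)
                     - a12 * (a12 * a33 - a23 * a13)
                     + a13 * (a12 * a23 - a22 * a13);
    const double s = (std::fabs(a11) + std::fabs(a22) + std::fabs(a33)) / 3.0;
    if (s <= 0.0 || std::fabs(det) < 1e-9 * s * s * s) return false;
    out[0] = (b1 * (a22 * a33 - a23 * a23)
            - a12 * (b2 * a33 - a23 * b3)
            + a13 * (b2 * a23 - a22 * b3)) / det;
    out[1] = (a11 * (b2 * a33 - a23 * b3)
            - b1 * (a12 * a33 - a23 * a13)
            + a13 * (a12 * b3 - b2 * a13)) / det;
    out[2] = (a11 * (a22 * b3 - b2 * a23)
            - a12 * (a12 * b3 - b2 * a13)
            + b1 * (a12 * a23 - a22 * a13)) / det;
    return std::isfinite(out[0]) && std::isfinite(out[1]) &&
           std::isfinite(out[2]);
  }
};

struct Entry {
  double cost;
  int u, v, vu, vv;      // endpoints and their version stamps at push time
  double px, py, pz;     // chosen collapse position
};
struct EntryCmp {
  bool operator()(const Entry &a, const Entry &b) const {
    return a.cost > b.cost;
  }
};

inline void sub3(const double *a, const double *b, double *out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
inline void cross3(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline double norm3(const double *a) { return std::sqrt(dot3(a, a)); }

class Decimator {
public:
  std::vector<std::array<double, 3>> pos;
  std::vector<std::array<int, 3>> face;
  std::vector<char> falive, valive;
  std::vector<Quad> quad;
  std::vector<std::set<int>> vadj, vface;
  std::vector<int> ver;
  std::priority_queue<Entry, std::vector<Entry>, EntryCmp> heap;
  int faces_alive;

  Decimator(const NumericMatrix &V, const IntegerMatrix &F) {
    const int n = V.nrow(), m = F.nrow();
    pos.resize(n);
    for (int i = 0; i < n; ++i)
      pos[i] = { V(i, 0), V(i, 1), V(i, 2) };
    face.resize(m);
    falive.assign(m, 1);
    valive.assign(n, 1);
    quad.assign(n, Quad());
    vadj.resize(n);
    vface.resize(n);
    ver.assign(n, 0);
    faces_alive = m;
    for (int f = 0; f < m; ++f) {
      face[f] = { F(f, 0), F(f, 1), F(f, 2) };
      for (int c = 0; c < 3; ++c) {
        vface[face[f][c]].insert(f);
        vadj[face[f][c]].insert(face[f][(c + 1) % 3]);
        vadj[face[f][c]].insert(face[f][(c + 2) % 3]);
      }
    }
  }

  void face_normal(int f, double *nrm, double *area2) const {
    double e1[3], e2[3];
    sub3(pos[face[f][1]].data(), pos[face[f][0]].data(), e1);
    sub3(pos[face[f][2]].data(), pos[face[f][0]].data(), e2);
    cross3(e1, e2, nrm);
    *area2 = norm3(nrm);
    if (*area2 > 0) { nrm[0] /= *area2; nrm[1] /= *area2; nrm[2] /= *area2; }
  }

  void init_quadrics(double boundary_weight) {
    const int m = (int)face.size();
    for (int f = 0; f < m; ++f) {
      double nrm[3], a2;
      face_normal(f, nrm, &a2);
      if (a2 <= 0) continue;
      const double d = -dot3(nrm, pos[face[f][0]].data());
      for (int c = 0; c < 3; ++c)
        quad[face[f][c]].add_plane(nrm[0], nrm[1], nrm[2], d, a2 / 2.0);
    }
    // boundary constraint planes: edge borders exactly one face
    std::map<std::pair<int, int>, std::pair<int, int>> ecount; // edge -> (count, face)
    for (int f = 0; f < m; ++f)
      for (int c = 0; c < 3; ++c) {
        int a = face[f][c], b = face[f][(c + 1) % 3];
        auto key = std::make_pair(std::min(a, b), std::max(a, b));
        auto it = ecount.find(key);
        if (it == ecount.end()) ecount[key] = { 1, f };
        else it->second.first++;
      }
    for (auto &kv : ecount) {
      if (kv.second.first != 1) continue;
      const int a = kv.first.first, b = kv.first.second, f = kv.second.second;
      double nrm[3], a2, ed[3], cp[3];
      face_normal(f, nrm, &a2);
      sub3(pos[b].data(), pos[a].data(), ed);
      cross3(ed, nrm, cp);
      const double l = norm3(cp);
      if (l <= 0) continue;
      cp[0] /= l; cp[1] /= l; cp[2] /= l;
      const double d = -dot3(cp, pos[a].data());
      const double w = boundary_weight * dot3(ed, ed);
      quad[a].add_plane(cp[0], cp[1], cp[2], d, w);
      quad[b].add_plane(cp[0], cp[1], cp[2], d, w);
    }
  }

  Entry make_entry(int u, int v) const {
    Quad Q = quad[u];
    Q.add(quad[v]);
    double best[3], cand[3];
    double best_cost = R_PosInf;
    if (Q.optimal(cand)) {
      best_cost = Q.eval(cand);
      std::copy(cand, cand + 3, best);
    }
    const double mid[3] = { (pos[u][0] + pos[v][0]) / 2,
                            (pos[u][1] + pos[v][1]) / 2,
                            (pos[u][2] + pos[v][2]) / 2 };
    const double *cands[3] = { mid, pos[u].data(), pos[v].data() };
    for (int k = 0; k < 3; ++k) {
      const double c = Q.eval(cands[k]);
      if (c < best_cost) {
        best_cost = c;
        std::copy(cands[k], cands[k] + 3, best);
      }
    }
    return { best_cost, u, v, ver[u], ver[v], best[0], best[1], best[2] };
  }

  void push_all_edges() {
    for (int u = 0; u < (int)vadj.size(); ++u) {
      if (!valive[u]) continue;
      for (int v : vadj[u])
        if (u < v) heap.push(make_entry(u, v));
    }
  }

  bool face_has(int f, int v) const {
    return face[f][0] == v || face[f][1] == v || face[f][2] == v;
  }

  // would replacing vertex `mv` by `np` flip or squash any surviving face?
  bool flips(int mv, const double *np,
             const std::vector<int> &dying) const {
    for (int f : vface[mv]) {
      if (!falive[f]) continue;
      if (std::find(dying.begin(), dying.end(), f) != dying.end()) continue;
      double oldn[3], a2;
      face_normal(f, oldn, &a2);
      const double *p[3];
      for (int c = 0; c < 3; ++c)
        p[c] = (face[f][c] == mv) ? np : pos[face[f][c]].data();
      double e1[3], e2[3], newn[3];
      sub3(p[1], p[0], e1);
      sub3(p[2], p[0], e2);
      cross3(e1, e2, newn);
      const double l = norm3(newn);
      if (l < 1e-14 || a2 <= 0) return true;
      if (dot3(oldn, newn) / l < 1e-10) return true;
    }
    return false;
  }

  // returns number of collapses applied
  int run(int target) {
    int rebuilds = 0;
    while (faces_alive > target) {
      if (heap.empty()) {
        // retry edges rejected earlier whose neighborhoods have changed
        if (++rebuilds > 64) break;
        push_all_edges();
        if (heap.empty()) break;
        // if a full rebuild makes no progress we bail out below
      }
      const Entry e = heap.top();
      heap.pop();
      const int u = e.u, v = e.v;
      if (!valive[u] || !valive[v]) continue;
      if (ver[u] != e.vu || ver[v] != e.vv) continue;
      if (!vadj[u].count(v)) continue;

      std::vector<int> shared;
      for (int f : vface[u])
        if (falive[f] && face_has(f, v)) shared.push_back(f);
      if (shared.empty()) continue;
      if (faces_alive - (int)shared.size() < target) continue;

      // link condition: common neighbors must all be opposite a shared face
      int common = 0;
      for (int w : vadj[u])
        if (w != v && vadj[v].count(w)) ++common;
      if (common != (int)shared.size()) continue;

      const double np[3] = { e.px, e.py, e.pz };
      if (flips(u, np, shared) || flips(v, np, shared)) continue;

      // ---- apply collapse: v merges into u at np
      ++ver[u];
      ++ver[v];
      pos[u] = { np[0], np[1], np[2] };
      quad[u].add(quad[v]);
      for (int f : shared) {
        falive[f] = 0;
        --faces_alive;
        for (int c = 0; c < 3; ++c) vface[face[f][c]].erase(f);
      }
      for (int f : std::vector<int>(vface[v].begin(), vface[v].end())) {
        if (!falive[f]) { vface[v].erase(f); continue; }
        for (int c = 0; c < 3; ++c)
          if (face[f][c] == v) face[f][c] = u;
        vface[u].insert(f);
      }
      vface[v].clear();
      vadj[u].erase(v);
      for (int w : vadj[v]) {
        if (w == u) continue;
        vadj[w].erase(v);
        vadj[w].insert(u);
        vadj[u].insert(w);
      }
      vadj[v].clear();
      valive[v] = 0;
      rebuilds = 0; // progress made
      for (int w : vadj[u]) heap.push(make_entry(u, w));
    }
    return faces_alive;
  }
};

} // namespace

// [[Rcpp::export]]
List qem_decimate_cpp(NumericMatrix V, IntegerMatrix F, int target,
                      double boundary_weight) {
  Decimator d(V, F);
  d.init_quadrics(boundary_weight);
  d.push_all_edges();
  const int left = d.run(target);

  // compact surviving vertices/faces
  const int n = (int)d.pos.size();
  std::vector<int> remap(n, -1);
  int nv = 0;
  for (int f = 0; f < (int)d.face.size(); ++f) {
    if (!d.falive[f]) continue;
    for (int c = 0; c < 3; ++c)
      if (remap[d.face[f][c]] < 0) remap[d.face[f][c]] = nv++;
  }
  NumericMatrix Vout(nv, 3);
  for (int i = 0; i < n; ++i)
    if (remap[i] >= 0)
      for (int c = 0; c < 3; ++c) Vout(remap[i], c) = d.pos[i][c];
  IntegerMatrix Fout(left, 3);
  int fi = 0;
  for (int f = 0; f < (int)d.face.size(); ++f) {
    if (!d.falive[f]) continue;
    for (int c = 0; c < 3; ++c) Fout(fi, c) = remap[d.face[f][c]];
    ++fi;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout,
                      _["faces_left"] = left);
}
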