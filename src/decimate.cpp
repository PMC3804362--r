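#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <set>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Quadric-error-metric edge collapse (Garland & Heckbert) on a closed
// manifold triangle mesh, down to an exact target vertex count.
// Collapses that would break the manifold (link condition) or flip
// triangle normals are skipped.

namespace {

struct Quadric {
  // symmetric 4x4: a11 a12 a13 a14 a22 a23 a24 a33 a34 a44
  double q[10];
  Quadric() { std::fill(q, q + 10, 0.0); }
  void addPlane(double a, double b, double c, double d) {
    q[0] += a * a; q[1] += a * b; q[2] += a * c; q[3] += a * d;
    q[4] += b * b; q[5] += b * c; q[6] += b * d;
    q[7] += c * c; q[8] += c * d; q[9] += d * d;
  }
  Quadric operator+(const Quadric& o) const {
    Quadric r;
    for (int i = 0; i < 10; ++i) r.q[i] = q[i] + o.q[i];
    return r;
  }
  double eval(const double* v) const {
    double x = v[0], y = v[1], z = v[2];
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
         + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
         + q[7]*z*z + 2*q[8]*z + q[9];
  }
  // minimize v'Qv: solve the 3x3 system; false if near-singular
  bool optimal(double* v) const {
    double A[3][3] = {{q[0], q[1], q[2]}, {q[1], q[4], q[5]}, {q[2], q[5], q[7]}};
    double b[3] = {-q[3], -q[6], -q[8]};
    double det = A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
               - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
               + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
    double scale = std::fabs(A[0][0]) + std::fabs(A[1][1]) + std::fabs(A[2][2]);
    if (std::fabs(det) < 1e-10 * std::max(1.0, scale * scale * scale)) return false;
    // Cramer
    for (int c = 0; c < 3; ++c) {
      double M[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) M[i][j] = (j == c) ? b[i] : A[i][j];
      double dc = M[0][0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
                - M[0][1]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
                + M[0][2]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]);
      v[c] = dc / det;
    }
    return true;
  }
};

struct HeapEdge {
  double cost;
  int u, v;           // u < v
  long su, sv;        // vertex stamps at push time
  bool operator<(const HeapEdge& o) const {
    if (cost != o.cost) return cost > o.cost;      // min-heap
    if (u != o.u) return u > o.u;                  // deterministic ties
    return v > o.v;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_decimate_qem(NumericMatrix verts, IntegerMatrix facesIn, int target) {
  int nv = verts.nrow(), nf = facesIn.nrow();
  std::vector<std::array<double, 3>> P(nv);
  for (int i = 0; i < nv; ++i)
    P[i] = {verts(i, 0), verts(i, 1), verts(i, 2)};
  std::vector<std::array<int, 3>> F(nf);
  for (int f = 0; f < nf; ++f)
    F[f] = {facesIn(f, 0) - 1, facesIn(f, 1) - 1, facesIn(f, 2) - 1};

  std::vector<char> vAlive(nv, 1), fAlive(nf, 1);
  std::vector<long> stamp(nv, 0);
  std::vector<std::vector<int>> vFaces(nv);
  for (int f = 0; f < nf; ++f)
    for (int s = 0; s < 3; ++s) vFaces[F[f][s]].push_back(f);

  std::vector<Quadric> Q(nv);
  auto faceNormal = [&](int f, double* n, double* area2) {
    const auto& a = P[F[f][0]];
    const auto& b = P[F[f][1]];
    const auto& c = P[F[f][2]];
    double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    double w[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
    n[0] = u[1]*w[2] - u[2]*w[1];
    n[1] = u[2]*w[0] - u[0]*w[2];
    n[2] = u[0]*w[1] - u[1]*w[0];
    *area2 = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
  };
  for (int f = 0; f < nf; ++f) {
    double n[3], a2;
    faceNormal(f, n, &a2);
    if (a2 < 1e-30) continue;
    double inv = 1.0 / a2;
    double a = n[0]*inv, b = n[1]*inv, c = n[2]*inv;
    const auto& p = P[F[f][0]];
    double d = -(a*p[0] + b*p[1] + c*p[2]);
    for (int s = 0; s < 3; ++s) Q[F[f][s]].addPlane(a, b, c, d);
  }

  auto neighbours = [&](int v) {
    std::set<int> out;
    for (int f : vFaces[v]) {
      if (!fAlive[f]) continue;
      for (int s = 0; s < 3; ++s)
        if (F[f][s] != v) out.insert(F[f][s]);
    }
    return out;
  };

  auto edgeCost = [&](int u, int v, double* pos) -> double {
    Quadric Qe = Q[u] + Q[v];
    double best[3];
    double bestCost;
    if (Qe.optimal(best)) {
      bestCost = Qe.eval(best);
    } else {
      double mid[3] = {(P[u][0]+P[v][0])/2, (P[u][1]+P[v][1])/2, (P[u][2]+P[v][2])/2};
      const double* cands[3] = {mid, P[u].data(), P[v].data()};
      bestCost = R_PosInf;
      for (int c = 0; c < 3; ++c) {
        double e = Qe.eval(cands[c]);
        if (e < bestCost) { bestCost = e; best[0]=cands[c][0]; best[1]=cands[c][1]; best[2]=cands[c][2]; }
      }
    }
    pos[0] = best[0]; pos[1] = best[1]; pos[2] = best[2];
    return bestCost;
  };

  std::priority_queue<HeapEdge> heap;
  auto pushEdge = [&](int u, int v) {
    if (u > v) std::swap(u, v);
    double pos[3];
    double c = edgeCost(u, v, pos);
    heap.push({c, u, v, stamp[u], stamp[v]});
  };
  {
    std::set<std::pair<int, int>> seen;
    for (int f = 0; f < nf; ++f)
      for (int s = 0; s < 3; ++s) {
        int u = F[f][s], v = F[f][(s + 1) % 3];
        if (u > v) std::swap(u, v);
        if (seen.insert({u, v}).second) pushEdge(u, v);
      }
  }

  int alive = nv;
  while (alive > target && !heap.empty()) {
    HeapEdge e = heap.top();
    heap.pop();
    if (!vAlive[e.u] || !vAlive[e.v]) continue;
    if (stamp[e.u] != e.su || stamp[e.v] != e.sv) continue;
    int u = e.u, v = e.v;

    // edge must still exist and be manifold: exactly two shared alive faces
    std::vector<int> shared;
    for (int f : vFaces[u]) {
      if (!fAlive[f]) continue;
      for (int s = 0; s < 3; ++s)
        if (F[f][s] == v) { shared.push_back(f); break; }
    }
    if (shared.size() != 2) continue;

    // link condition: common neighbours must be exactly the two apices
    std::set<int> nu = neighbours(u), nvb = neighbours(v), common;
    std::set_intersection(nu.begin(), nu.end(), nvb.begin(), nvb.end(),
                          std::inserter(common, common.begin()));
    if (common.size() != 2) continue;
    if (alive - 1 < 4) break; // keep a tetrahedron at minimum

    double pos[3];
    edgeCost(u, v, pos);

    // normal-flip guard on surviving faces of u and v
    bool flip = false;
    for (int pass = 0; pass < 2 && !flip; ++pass) {
      int w = pass == 0 ? u : v;
      for (int f : vFaces[w]) {
        if (!fAlive[f]) continue;
        if (f == shared[0] || f == shared[1]) continue;
        double n0[3], a0;
        faceNormal(f, n0, &a0);
        std::array<double, 3> savedU = P[u], savedV = P[v];
        P[u] = {pos[0], pos[1], pos[2]};
        P[v] = {pos[0], pos[1], pos[2]};
        double n1[3], a1;
        faceNormal(f, n1, &a1);
        P[u] = savedU; P[v] = savedV;
        double dot = n0[0]*n1[0] + n0[1]*n1[1] + n0[2]*n1[2];
        if (a1 < 1e-30 || dot <= 0) { flip = true; break; }
      }
    }
    if (flip) continue;

    // collapse v into u at pos
    P[u] = {pos[0], pos[1], pos[2]};
    Q[u] = Q[u] + Q[v];
    fAlive[shared[0]] = 0;
    fAlive[shared[1]] = 0;
    for (int f : vFaces[v]) {
      if (!fAlive[f]) continue;
      for (int s = 0; s < 3; ++s)
        if (F[f][s] == v) F[f][s] = u;
      vFaces[u].push_back(f);
    }
    vAlive[v] = 0;
    --alive;
    // only edges incident to u change cost (Q[u] is the only updated quadric)
    ++stamp[u];
    std::set<int> nb = neighbours(u);
    for (int w : nb) pushEdge(u, w);
  }

  // compact
  std::vector<int> remap(nv, -1);
  int outN = 0;
  for (int i = 0; i < nv; ++i)
    if (vAlive[i]) remap[i] = outN++;
  NumericMatrix outV(outN, 3);
  for (int i = 0; i < nv; ++i)
    if (vAlive[i])
      for (int a = 0; a < 3; ++a) outV(remap[i], a) = P[i][a];
  int outF = 0;
  for (int f = 0; f < nf; ++f) if (fAlive[f]) ++outF;
  IntegerMatrix outFm(outF, 3);
  int r = 0;
  for (int f = 0; f < nf; ++f) {
    if (!fAlive[f]) continue;
    for (int a = 0; a < 3; ++a) outFm(r, a) = remap[F[f][a]] + 1;
    ++r;
  }
  return List::create(_["vertices"] = outV, _["faces"] = outFm,
                      _["reached"] = (alive == target));
}
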