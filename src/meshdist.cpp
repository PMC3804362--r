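#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// closest point on triangle (a,b,c) to p — Ericson, Real-Time Collision
// Detection, ch. 5
static double pointTriDist2(const double* p, const double* a,
                            const double* b, const double* c) {
  double ab[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double ac[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double ap[3] = {p[0]-a[0], p[1]-a[1], p[2]-a[2]};
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  auto dist2 = [&](double qx, double qy, double qz) {
    double dx = p[0]-qx, dy = p[1]-qy, dz = p[2]-qz;
    return dx*dx + dy*dy + dz*dz;
  };
  if (d1 <= 0 && d2 <= 0) return dist2(a[0], a[1], a[2]);
  double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) return dist2(b[0], b[1], b[2]);
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return dist2(a[0]+v*ab[0], a[1]+v*ab[1], a[2]+v*ab[2]);
  }
  double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) return dist2(c[0], c[1], c[2]);
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return dist2(a[0]+w*ac[0], a[1]+w*ac[1], a[2]+w*ac[2]);
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist2(b[0]+w*(c[0]-b[0]), b[1]+w*(c[1]-b[1]), b[2]+w*(c[2]-b[2]));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return dist2(a[0]+ab[0]*v+ac[0]*w, a[1]+ab[1]*v+ac[1]*w, a[2]+ab[2]*v+ac[2]*w);
}

// min distance from each point to a triangulated surface
// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix points, NumericMatrix verts,
                                  IntegerMatrix faces) {
  int np = points.nrow(), nf = faces.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double a[3] = {verts(faces(f,0)-1, 0), verts(faces(f,0)-1, 1), verts(faces(f,0)-1, 2)};
      double b[3] = {verts(faces(f,1)-1, 0), verts(faces(f,1)-1, 1), verts(faces(f,1)-1, 2)};
      double c[3] = {verts(faces(f,2)-1, 0), verts(faces(f,2)-1, 1), verts(faces(f,2)-1, 2)};
      double d2 = pointTriDist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// index (1-based) of nearest row of B for each row of A, plus the distance;
// ties go to the smaller index
// [[Rcpp::export]]
List cpp_nn_index(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  IntegerVector idx(na);
  NumericVector dist(na);
  for (int i = 0; i < na; ++i) {
    double ax = A(i,0), ay = A(i,1), az = A(i,2);
    double best = R_PosInf;
    int bi = 0;
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j,0), dy = ay - B(j,1), dz = az - B(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; bi = j; }
    }
    idx[i] = bi + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// closest point ON triangle (a,b,c) to p (returns the point, not just the
// distance): clamped-barycentric version of the routine above
static void closestOnTri(const double* p, const double* a, const double* b,
                         const double* c, double* out) {
  double ab[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double ac[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double ap[3] = {p[0]-a[0], p[1]-a[1], p[2]-a[2]};
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }
  double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
}

// closest point on a triangulated surface for each query point
// [[Rcpp::export]]
NumericMatrix cpp_closest_point_on_mesh(NumericMatrix points,
                                        NumericMatrix verts,
                                        IntegerMatrix faces) {
  int np = points.nrow(), nf = faces.nrow();
  NumericMatrix out(np, 3);
  for (int i = 0; i < np; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double best = R_PosInf, bestPt[3] = {p[0], p[1], p[2]};
    for (int f = 0; f < nf; ++f) {
      double a[3] = {verts(faces(f,0)-1, 0), verts(faces(f,0)-1, 1), verts(faces(f,0)-1, 2)};
      double b[3] = {verts(faces(f,1)-1, 0), verts(faces(f,1)-1, 1), verts(faces(f,1)-1, 2)};
      double c[3] = {verts(faces(f,2)-1, 0), verts(faces(f,2)-1, 1), verts(faces(f,2)-1, 2)};
      double q[3];
      closestOnTri(p, a, b, c, q);
      double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; bestPt[0]=q[0]; bestPt[1]=q[1]; bestPt[2]=q[2]; }
    }
    out(i, 0) = bestPt[0]; out(i, 1) = bestPt[1]; out(i, 2) = bestPt[2];
  }
  return out;
}
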