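#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Kuhn subdivision of the unit cube into 6 tetrahedra around the 0-7
// diagonal. Corner c has offsets (c&1, (c>>1)&1, (c>>2)&1). Face diagonals
// always join the min-index to the max-index corner of the face, so the
// subdivision is consistent across neighbouring cubes.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

// Separable Gaussian smoothing of a 3-D grid, zero padding outside.
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector grid, IntegerVector dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int rad = (int)std::ceil(3.0 * sigma);
  if (rad < 1) rad = 1;
  std::vector<double> w(2 * rad + 1);
  double s = 0.0;
  for (int k = -rad; k <= rad; ++k) {
    w[k + rad] = std::exp(-0.5 * k * k / (sigma * sigma));
    s += w[k + rad];
  }
  for (double& x : w) x /= s;

  std::vector<double> a(grid.begin(), grid.end()), b(n);
  auto at = [&](std::vector<double>& v, int i, int j, int k) -> double& {
    return v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
  };
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int d = -rad; d <= rad; ++d) {
          int ii = i + d;
          if (ii >= 0 && ii < nx) acc += w[d + rad] * at(a, ii, j, k);
        }
        at(b, i, j, k) = acc;
      }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int d = -rad; d <= rad; ++d) {
          int jj = j + d;
          if (jj >= 0 && jj < ny) acc += w[d + rad] * at(b, i, jj, k);
        }
        at(a, i, j, k) = acc;
      }
  // z pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int d = -rad; d <= rad; ++d) {
          int kk = k + d;
          if (kk >= 0 && kk < nz) acc += w[d + rad] * at(a, i, j, kk);
        }
        at(b, i, j, k) = acc;
      }
  NumericVector out(n);
  std::copy(b.begin(), b.end(), out.begin());
  return out;
}

// Marching tetrahedra on a scalar grid. Inside = value > iso (strict).
// Returns welded vertices (physical coords) and outward-oriented faces.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims,
                       NumericVector spacing, NumericVector origin,
                       double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto gid = [&](int i, int j, int k) -> int {
    return i + nx * (j + ny * k);
  };
  std::unordered_map<uint64_t, int> edgeVert;
  std::vector<double> V;   // xyz interleaved
  std::vector<int> F;      // 0-based triples

  auto coordOf = [&](int g, double* p) {
    int k = g / (nx * ny);
    int rem = g % (nx * ny);
    int j = rem / nx;
    int i = rem % nx;
    p[0] = i; p[1] = j; p[2] = k;
  };

  auto edgeVertex = [&](int g0, int g1, double v0, double v1) -> int {
    uint64_t key = (g0 < g1)
      ? (((uint64_t)(uint32_t)g0 << 32) | (uint32_t)g1)
      : (((uint64_t)(uint32_t)g1 << 32) | (uint32_t)g0);
    auto it = edgeVert.find(key);
    if (it != edgeVert.end()) return it->second;
    double t = (iso - v0) / (v1 - v0);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    double p0[3], p1[3];
    coordOf(g0, p0); coordOf(g1, p1);
    int id = (int)(V.size() / 3);
    for (int a = 0; a < 3; ++a) {
      double idxc = p0[a] + t * (p1[a] - p0[a]);
      V.push_back(origin[a] + idxc * spacing[a]);
    }
    edgeVert[key] = id;
    return id;
  };

  auto pushTri = [&](int a, int b, int c, const double* inPt) {
    // orient so the normal points away from the inside reference point
    const double* pa = &V[3 * (size_t)a];
    const double* pb = &V[3 * (size_t)b];
    const double* pc = &V[3 * (size_t)c];
    double u[3] = {pb[0] - pa[0], pb[1] - pa[1], pb[2] - pa[2]};
    double v[3] = {pc[0] - pa[0], pc[1] - pa[1], pc[2] - pa[2]};
    double n[3] = {u[1] * v[2] - u[2] * v[1],
                   u[2] * v[0] - u[0] * v[2],
                   u[0] * v[1] - u[1] * v[0]};
    double cx = (pa[0] + pb[0] + pc[0]) / 3.0;
    double cy = (pa[1] + pb[1] + pc[1]) / 3.0;
    double cz = (pa[2] + pb[2] + pc[2]) / 3.0;
    double d = n[0] * (cx - inPt[0]) + n[1] * (cy - inPt[1]) + n[2] * (cz - inPt[2]);
    if (d >= 0) { F.push_back(a); F.push_back(b); F.push_back(c); }
    else        { F.push_back(a); F.push_back(c); F.push_back(b); }
  };

  int cg[8];
  double cv[8];
  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      for (int i = 0; i < nx - 1; ++i) {
        for (int c = 0; c < 8; ++c) {
          cg[c] = gid(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
          cv[c] = field[cg[c]];
        }
        for (int t = 0; t < 6; ++t) {
          int tg[4]; double tv[4]; bool in[4];
          int nin = 0;
          for (int s = 0; s < 4; ++s) {
            tg[s] = cg[TETS[t][s]];
            tv[s] = cv[TETS[t][s]];
            in[s] = tv[s] > iso;
            if (in[s]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            // apex = the lone inside (or outside) vertex
            bool lookFor = (nin == 1);
            int apex = -1, oth[3], no = 0;
            for (int s = 0; s < 4; ++s) {
              if (in[s] == lookFor) apex = s; else oth[no++] = s;
            }
            int e0 = edgeVertex(tg[apex], tg[oth[0]], tv[apex], tv[oth[0]]);
            int e1 = edgeVertex(tg[apex], tg[oth[1]], tv[apex], tv[oth[1]]);
            int e2 = edgeVertex(tg[apex], tg[oth[2]], tv[apex], tv[oth[2]]);
            // inside reference point: an inside corner of the tet
            int inIdx = (nin == 1) ? apex : oth[0];
            double ip[3]; coordOf(tg[inIdx], ip);
            for (int a = 0; a < 3; ++a) ip[a] = origin[a] + ip[a] * spacing[a];
            pushTri(e0, e1, e2, ip);
          } else { // nin == 2 -> quad split into two triangles
            int A[2], B[2], na = 0, nb = 0;
            for (int s = 0; s < 4; ++s) {
              if (in[s]) A[na++] = s; else B[nb++] = s;
            }
            int q1 = edgeVertex(tg[A[0]], tg[B[0]], tv[A[0]], tv[B[0]]);
            int q2 = edgeVertex(tg[A[0]], tg[B[1]], tv[A[0]], tv[B[1]]);
            int q3 = edgeVertex(tg[A[1]], tg[B[1]], tv[A[1]], tv[B[1]]);
            int q4 = edgeVertex(tg[A[1]], tg[B[0]], tv[A[1]], tv[B[0]]);
            double ip[3]; coordOf(tg[A[0]], ip);
            for (int a = 0; a < 3; ++a) ip[a] = origin[a] + ip[a] * spacing[a];
            pushTri(q1, q2, q3, ip);
            pushTri(q1, q3, q4, ip);
          }
        }
      }
    }
  }

  int nv = (int)(V.size() / 3), nf = (int)(F.size() / 3);
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; ++v)
    for (int a = 0; a < 3; ++a) verts(v, a) = V[3 * (size_t)v + a];
  IntegerMatrix faces(nf, 3);
  for (int f = 0; f < nf; ++f)
    for (int a = 0; a < 3; ++a) faces(f, a) = F[3 * (size_t)f + a] + 1;
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// Even-odd scanline voxelization of a closed mesh: casts +x rays through
// voxel centres and fills between crossing pairs.
// [[Rcpp::export]]
IntegerVector cpp_voxelize(NumericMatrix verts, IntegerMatrix faces,
                           IntegerVector dims, NumericVector spacing,
                           NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector grid((R_xlen_t)nx * ny * nz);
  const double eps = 1e-7;
  std::vector<std::vector<double>> rows((size_t)ny * nz);
  for (int f = 0; f < faces.nrow(); ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    double ax = verts(a, 0), ay = verts(a, 1), az = verts(a, 2);
    double bx = verts(b, 0), by = verts(b, 1), bz = verts(b, 2);
    double cx = verts(c, 0), cy = verts(c, 1), cz = verts(c, 2);
    double ylo = std::min({ay, by, cy}), yhi = std::max({ay, by, cy});
    double zlo = std::min({az, bz, cz}), zhi = std::max({az, bz, cz});
    int jlo = std::max(0, (int)std::ceil((ylo - origin[1]) / spacing[1] - eps));
    int jhi = std::min(ny - 1, (int)std::floor((yhi - origin[1]) / spacing[1] + eps));
    int klo = std::max(0, (int)std::ceil((zlo - origin[2]) / spacing[2] - eps));
    int khi = std::min(nz - 1, (int)std::floor((zhi - origin[2]) / spacing[2] + eps));
    for (int k = klo; k <= khi; ++k) {
      double z = origin[2] + k * spacing[2] + eps * spacing[2];
      for (int j = jlo; j <= jhi; ++j) {
        double y = origin[1] + j * spacing[1] + eps * spacing[1];
        // 2-D point-in-triangle in the (y,z) projection via barycentric
        double d00y = by - ay, d00z = bz - az;
        double d01y = cy - ay, d01z = cz - az;
        double det = d00y * d01z - d00z * d01y;
        if (std::fabs(det) < 1e-14) continue; // edge-on: neighbours cover it
        double py = y - ay, pz = z - az;
        double u = (py * d01z - pz * d01y) / det;
        double v = (d00y * pz - d00z * py) / det;
        if (u < 0 || v < 0 || u + v > 1) continue;
        double x = ax + u * (bx - ax) + v * (cx - ax);
        rows[(size_t)j + (size_t)ny * k].push_back(x);
      }
    }
  }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      std::vector<double>& xs = rows[(size_t)j + (size_t)ny * k];
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      size_t m = xs.size() - (xs.size() % 2); // drop unpaired degenerate crossing
      for (size_t p = 0; p + 1 < m + 1 && p + 1 < xs.size() + 1; p += 2) {
        if (p + 1 >= m) break;
        int ilo = std::max(0, (int)std::ceil((xs[p] - origin[0]) / spacing[0]));
        int ihi = std::min(nx - 1, (int)std::floor((xs[p + 1] - origin[0]) / spacing[0]));
        for (int i = ilo; i <= ihi; ++i)
          grid[(R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k)] = 1;
      }
    }
  return grid;
}
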