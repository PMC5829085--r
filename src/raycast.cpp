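#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Voxelize a closed triangle mesh by casting a +z ray through every
// (x, y) voxel column and filling between paired surface crossings.
// A voxel is foreground iff its center lies inside the surface. Ray
// origins are offset by a tiny fixed fraction of the spacing so rays
// do not pass exactly through mesh edges or vertices of meshes in
// general position.
// verts: M x 3, faces: F x 3 (0-based), dim/origin/spacing length 3.
// [[Rcpp::export(name = ".raycastVoxelize")]]
LogicalVector raycastVoxelize(NumericMatrix verts, IntegerMatrix faces,
                              NumericVector origin, NumericVector spacing,
                              IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nf = faces.nrow();
  LogicalVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  const double ex = 1e-4 * spacing[0], ey = 1e-4 * spacing[1];

  // triangle data
  std::vector<double> x1(nf), y1(nf), z1(nf), x2(nf), y2(nf), z2(nf),
      x3(nf), y3(nf), z3(nf), xmin(nf), xmax(nf), ymin(nf), ymax(nf);
  for (int f = 0; f < nf; ++f) {
    int a = faces(f, 0), b = faces(f, 1), c = faces(f, 2);
    x1[f] = verts(a, 0); y1[f] = verts(a, 1); z1[f] = verts(a, 2);
    x2[f] = verts(b, 0); y2[f] = verts(b, 1); z2[f] = verts(b, 2);
    x3[f] = verts(c, 0); y3[f] = verts(c, 1); z3[f] = verts(c, 2);
    xmin[f] = std::min({x1[f], x2[f], x3[f]});
    xmax[f] = std::max({x1[f], x2[f], x3[f]});
    ymin[f] = std::min({y1[f], y2[f], y3[f]});
    ymax[f] = std::max({y1[f], y2[f], y3[f]});
  }

  int oddColumns = 0;
  std::vector<double> zs;
  for (int iy = 0; iy < ny; ++iy) {
    const double py = origin[1] + iy * spacing[1] + ey;
    for (int ix = 0; ix < nx; ++ix) {
      const double px = origin[0] + ix * spacing[0] + ex;
      zs.clear();
      for (int f = 0; f < nf; ++f) {
        if (px < xmin[f] || px > xmax[f] || py < ymin[f] || py > ymax[f])
          continue;
        // 2D barycentric test in the xy projection
        const double d1x = x2[f] - x1[f], d1y = y2[f] - y1[f];
        const double d2x = x3[f] - x1[f], d2y = y3[f] - y1[f];
        const double det = d1x * d2y - d2x * d1y;
        if (det == 0.0) continue;  // triangle vertical in z: no crossing
        const double qx = px - x1[f], qy = py - y1[f];
        const double u = (qx * d2y - d2x * qy) / det;
        const double v = (d1x * qy - qx * d1y) / det;
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        zs.push_back(z1[f] + u * (z2[f] - z1[f]) + v * (z3[f] - z1[f]));
      }
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      // collapse duplicate crossings (shared-edge grazing)
      std::vector<double> zu;
      for (double z : zs)
        if (zu.empty() || z - zu.back() > 1e-9) zu.push_back(z);
      if (zu.size() % 2 == 1) { ++oddColumns; zu.pop_back(); }
      for (size_t p = 0; p + 1 < zu.size(); p += 2) {
        // voxel centers strictly between entry and exit
        int k0 = (int)std::ceil((zu[p] - origin[2]) / spacing[2]);
        int k1 = (int)std::floor((zu[p + 1] - origin[2]) / spacing[2]);
        if (k0 < 0) k0 = 0;
        if (k1 > nz - 1) k1 = nz - 1;
        for (int k = k0; k <= k1; ++k)
          out[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  out.attr("oddColumns") = oddColumns;
  out.attr("dim") = dim;
  return out;
}

// directed squared Hausdorff h(A, B)^2 with the classic early break:
// once a candidate distance drops below the running maximum, this
// source point cannot raise the maximum and the inner scan stops.
static double directedH2(const NumericMatrix& A, const NumericMatrix& B) {
  const int p = A.nrow(), q = B.nrow();
  double h = 0.0;
  for (int i = 0; i < p; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < q; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < h) { best = -1.0; break; }
      if (d2 < best) best = d2;
    }
    if (best > h) h = best;
  }
  return h;
}

// Exact symmetric Hausdorff distance between two point sets (mm).
// [[Rcpp::export(name = ".hausdorffCpp")]]
double hausdorffCpp(NumericMatrix A, NumericMatrix B) {
  return std::sqrt(std::max(directedH2(A, B), directedH2(B, A)));
}
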