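#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sampling of a 3D array at continuous 0-based voxel coordinates.
// Out-of-bounds samples return `fill` (air/background by convention).
// [[Rcpp::export(name = ".c_sample_trilinear")]]
NumericVector c_sample_trilinear(NumericVector data, IntegerVector dim,
                                 NumericMatrix vox, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = vox.nrow();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double x = vox(k, 0), y = vox(k, 1), z = vox(k, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x < 0.0 || y < 0.0 || z < 0.0 ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
      out[k] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
    const double *d = data.begin();
    const R_xlen_t sxy = (R_xlen_t)nx * ny;
    double c000 = d[x0 + (R_xlen_t)nx * y0 + sxy * z0];
    double c100 = d[x1 + (R_xlen_t)nx * y0 + sxy * z0];
    double c010 = d[x0 + (R_xlen_t)nx * y1 + sxy * z0];
    double c110 = d[x1 + (R_xlen_t)nx * y1 + sxy * z0];
    double c001 = d[x0 + (R_xlen_t)nx * y0 + sxy * z1];
    double c101 = d[x1 + (R_xlen_t)nx * y0 + sxy * z1];
    double c011 = d[x0 + (R_xlen_t)nx * y1 + sxy * z1];
    double c111 = d[x1 + (R_xlen_t)nx * y1 + sxy * z1];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[k] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Fused affine transform + trilinear sampling: for each world point p,
// sample the volume at voxel coordinates M * (p, 1). Avoids materializing
// the transformed point set in R on the registration hot path.
// [[Rcpp::export(name = ".c_sample_affine")]]
NumericVector c_sample_affine(NumericVector data, IntegerVector dim,
                              NumericMatrix pts, NumericMatrix M,
                              double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  double m[12];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) m[4 * r + c] = M(r, c);
  const double *d = data.begin();
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int k = 0; k < n; ++k) {
    double px = pts(k, 0), py = pts(k, 1), pz = pts(k, 2);
    double x = m[0] * px + m[1] * py + m[2] * pz + m[3];
    double y = m[4] * px + m[5] * py + m[6] * pz + m[7];
    double z = m[8] * px + m[9] * py + m[10] * pz + m[11];
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x < 0.0 || y < 0.0 || z < 0.0 ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
      out[k] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
    double c000 = d[x0 + (R_xlen_t)nx * y0 + sxy * z0];
    double c100 = d[x1 + (R_xlen_t)nx * y0 + sxy * z0];
    double c010 = d[x0 + (R_xlen_t)nx * y1 + sxy * z0];
    double c110 = d[x1 + (R_xlen_t)nx * y1 + sxy * z0];
    double c001 = d[x0 + (R_xlen_t)nx * y0 + sxy * z1];
    double c101 = d[x1 + (R_xlen_t)nx * y0 + sxy * z1];
    double c011 = d[x0 + (R_xlen_t)nx * y1 + sxy * z1];
    double c111 = d[x1 + (R_xlen_t)nx * y1 + sxy * z1];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[k] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling at continuous 0-based voxel coordinates.
// [[Rcpp::export(name = ".c_sample_nearest")]]
NumericVector c_sample_nearest(NumericVector data, IntegerVector dim,
                               NumericMatrix vox, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = vox.nrow();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double x = vox(k, 0), y = vox(k, 1), z = vox(k, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z)) { out[k] = fill; continue; }
    int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
    if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz) {
      out[k] = fill;
    } else {
      out[k] = data[xi + (R_xlen_t)nx * yi + (R_xlen_t)nx * ny * zi];
    }
  }
  return out;
}

static inline void closest_on_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *q) {
  // Ericson, Real-Time Collision Detection, 5.1.5
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) q[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) q[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) q[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) q[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) q[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) q[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Exact closest point on a triangulated surface for each query point.
// verts: V x 3 (mm); tris: T x 3 (1-based vertex indices); pts: N x 3.
// Ties in squared distance (within 1e-12 relative) resolve to the lower
// triangle id so the result is deterministic.
// [[Rcpp::export(name = ".c_closest_on_mesh")]]
List c_closest_on_mesh(NumericMatrix verts, IntegerMatrix tris, NumericMatrix pts) {
  const int T = tris.nrow(), N = pts.nrow();
  NumericMatrix qout(N, 3);
  IntegerVector tid(N);
  NumericVector dist(N);
  for (int k = 0; k < N; ++k) {
    double p[3] = { pts(k, 0), pts(k, 1), pts(k, 2) };
    double best = R_PosInf, bq[3] = {0, 0, 0};
    int bt = NA_INTEGER;
    for (int t = 0; t < T; ++t) {
      int ia = tris(t, 0) - 1, ib = tris(t, 1) - 1, ic = tris(t, 2) - 1;
      double a[3] = { verts(ia, 0), verts(ia, 1), verts(ia, 2) };
      double b[3] = { verts(ib, 0), verts(ib, 1), verts(ib, 2) };
      double c[3] = { verts(ic, 0), verts(ic, 1), verts(ic, 2) };
      double q[3];
      closest_on_triangle(p, a, b, c, q);
      double d2 = (p[0]-q[0])*(p[0]-q[0]) + (p[1]-q[1])*(p[1]-q[1]) +
                  (p[2]-q[2])*(p[2]-q[2]);
      if (bt == NA_INTEGER || d2 < best - 1e-12 * (1.0 + best)) {
        best = d2; bt = t + 1;
        bq[0] = q[0]; bq[1] = q[1]; bq[2] = q[2];
      }
    }
    qout(k, 0) = bq[0]; qout(k, 1) = bq[1]; qout(k, 2) = bq[2];
    tid[k] = bt;
    dist[k] = std::sqrt(best);
  }
  return List::create(_["point"] = qout, _["triangle"] = tid, _["distance"] = dist);
}
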