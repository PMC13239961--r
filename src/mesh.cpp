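#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Iso-surface area and enclosed volume by marching tetrahedra.
// Each grid cell is split into six tetrahedra around the main diagonal;
// triangle vertices are placed by linear interpolation at `iso`.
// Triangles are oriented outward (checked against the inside corners), so
// the divergence-theorem volume is signed-consistent; |V| is returned.
// The field is assumed zero-padded so the surface is closed.

struct V3 {
  double x, y, z;
};
static inline V3 sub(const V3& a, const V3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline V3 cross(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline double dot(const V3& a, const V3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// cube corner order by bit pattern (dx, dy, dz)
static const int CUBE[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                               {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
// six tetrahedra sharing the v0-v6 diagonal
static const int TETS[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                               {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

// [[Rcpp::export]]
NumericVector mesh_area_volume_cpp(const NumericVector& f,
                                   const IntegerVector& dims,
                                   const NumericVector& spacing, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double area = 0.0, vol6 = 0.0;

  V3 pos[8];
  double val[8];
  auto interp = [&](int a, int b) -> V3 {
    const double t = (iso - val[a]) / (val[b] - val[a]);
    return {pos[a].x + t * (pos[b].x - pos[a].x),
            pos[a].y + t * (pos[b].y - pos[a].y),
            pos[a].z + t * (pos[b].z - pos[a].z)};
  };
  auto add_tri = [&](const V3& a, const V3& b, const V3& c, const V3& in) {
    V3 n = cross(sub(b, a), sub(c, a));
    const V3 cen = {(a.x + b.x + c.x) / 3 - in.x, (a.y + b.y + c.y) / 3 - in.y,
                    (a.z + b.z + c.z) / 3 - in.z};
    V3 p0 = a, p1 = b, p2 = c;
    if (dot(n, cen) < 0) {  // flip to point away from the inside corner
      std::swap(p1, p2);
      n = cross(sub(p1, p0), sub(p2, p0));
    }
    area += 0.5 * std::sqrt(dot(n, n));
    vol6 += dot(p0, cross(p1, p2));
  };

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          const int ci = i + CUBE[c][0], cj = j + CUBE[c][1],
                    ck = k + CUBE[c][2];
          val[c] = f[(R_xlen_t)ci + (R_xlen_t)nx * cj + (R_xlen_t)nx * ny * ck];
          pos[c] = {ci * sx, cj * sy, ck * sz};
          (val[c] > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int in_idx[4], out_idx[4];
          int ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (val[T[c]] > iso)
              in_idx[ni++] = T[c];
            else
              out_idx[no++] = T[c];
          }
          if (ni == 0 || ni == 4) continue;
          if (ni == 1) {
            const int a = in_idx[0];
            add_tri(interp(a, out_idx[0]), interp(a, out_idx[1]),
                    interp(a, out_idx[2]), pos[a]);
          } else if (ni == 3) {
            const int d = out_idx[0];
            const V3 in_cen = {
                (pos[in_idx[0]].x + pos[in_idx[1]].x + pos[in_idx[2]].x) / 3,
                (pos[in_idx[0]].y + pos[in_idx[1]].y + pos[in_idx[2]].y) / 3,
                (pos[in_idx[0]].z + pos[in_idx[1]].z + pos[in_idx[2]].z) / 3};
            add_tri(interp(in_idx[0], d), interp(in_idx[1], d),
                    interp(in_idx[2], d), in_cen);
          } else {  // 2 in / 2 out: quad split into two triangles
            const int a = in_idx[0], b = in_idx[1];
            const int c = out_idx[0], d = out_idx[1];
            const V3 pac = interp(a, c), pad = interp(a, d);
            const V3 pbd = interp(b, d), pbc = interp(b, c);
            const V3 in_cen = {(pos[a].x + pos[b].x) / 2,
                               (pos[a].y + pos[b].y) / 2,
                               (pos[a].z + pos[b].z) / 2};
            add_tri(pac, pad, pbd, in_cen);
            add_tri(pac, pbd, pbc, in_cen);
          }
        }
      }
  return NumericVector::create(area, std::fabs(vol6) / 6.0);
}
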