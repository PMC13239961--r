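#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Texture-matrix construction on a discretized volume.
// `lev` holds integer gray levels 1..ng for in-mask voxels and 0 outside.
// All matrices use the 26-neighbourhood; pairwise descriptors use the 13
// unique 3D directions at distance 1 (angle-aggregated downstream).

static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline R_xlen_t vox(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * j + (R_xlen_t)nx * ny * k;
}

// Co-occurrence counts, one ng x ng slab per direction (not symmetrized).
// [[Rcpp::export]]
NumericVector glcm_counts_cpp(const IntegerVector& lev,
                              const IntegerVector& dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    const R_xlen_t base = (R_xlen_t)ng * ng * d;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int li = lev[vox(i, j, k, nx, ny)];
          if (li == 0) continue;
          const int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny || k2 >= nz)
            continue;
          const int lj = lev[vox(i2, j2, k2, nx, ny)];
          if (lj == 0) continue;
          out[base + (li - 1) + (R_xlen_t)ng * (lj - 1)] += 1.0;
        }
  }
  return out;
}

// Run-length counts, one ng x maxlen slab per direction.
// [[Rcpp::export]]
NumericVector glrlm_counts_cpp(const IntegerVector& lev,
                               const IntegerVector& dims, int ng, int maxlen) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)ng * maxlen * 13);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    const R_xlen_t base = (R_xlen_t)ng * maxlen * d;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int li = lev[vox(i, j, k, nx, ny)];
          if (li == 0) continue;
          // run starts where the backward neighbour differs or is absent
          const int ip = i - dx, jp = j - dy, kp = k - dz;
          if (ip >= 0 && jp >= 0 && kp >= 0 && ip < nx && jp < ny && kp < nz &&
              lev[vox(ip, jp, kp, nx, ny)] == li)
            continue;
          int len = 1;
          int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          while (i2 >= 0 && j2 >= 0 && k2 >= 0 && i2 < nx && j2 < ny &&
                 k2 < nz && lev[vox(i2, j2, k2, nx, ny)] == li) {
            ++len;
            i2 += dx; j2 += dy; k2 += dz;
          }
          if (len > maxlen) len = maxlen;
          out[base + (li - 1) + (R_xlen_t)ng * (len - 1)] += 1.0;
        }
  }
  return out;
}

// Size zones: 26-connected components of constant gray level.
// Returns a two-column matrix (level, zone size).
// [[Rcpp::export]]
IntegerMatrix glszm_zones_cpp(const IntegerVector& lev,
                              const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (seen[s] || lev[s] == 0) continue;
    const int g = lev[s];
    int size = 0;
    seen[s] = 1;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      ++size;
      const int i = (int)(cur % nx);
      const int j = (int)((cur / nx) % ny);
      const int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const int i2 = i + di, j2 = j + dj, k2 = k + dk;
            if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny || k2 >= nz)
              continue;
            const R_xlen_t v = vox(i2, j2, k2, nx, ny);
            if (!seen[v] && lev[v] == g) {
              seen[v] = 1;
              stack.push_back(v);
            }
          }
    }
    zl.push_back(g);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t r = 0; r < zl.size(); ++r) {
    out(r, 0) = zl[r];
    out(r, 1) = zs[r];
  }
  return out;
}

// Dependence counts: for each voxel, the number of 26-neighbours whose
// level differs by at most `alpha`. Returns ng x 27 counts (dependence 0..26).
// [[Rcpp::export]]
NumericMatrix gldm_counts_cpp(const IntegerVector& lev,
                              const IntegerVector& dims, int ng, int alpha) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 27);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int li = lev[vox(i, j, k, nx, ny)];
        if (li == 0) continue;
        int dep = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              const int i2 = i + di, j2 = j + dj, k2 = k + dk;
              if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny ||
                  k2 >= nz)
                continue;
              const int lj = lev[vox(i2, j2, k2, nx, ny)];
              if (lj != 0 && std::abs(lj - li) <= alpha) ++dep;
            }
        out(li - 1, dep) += 1.0;
      }
  return out;
}

// Neighbourhood gray-tone difference: per level, the voxel count n_i and
// the accumulated |level - mean(neighbour levels)| term s_i.
// [[Rcpp::export]]
NumericMatrix ngtdm_table_cpp(const IntegerVector& lev,
                              const IntegerVector& dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 2);  // columns: n_i, s_i
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int li = lev[vox(i, j, k, nx, ny)];
        if (li == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              const int i2 = i + di, j2 = j + dj, k2 = k + dk;
              if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny ||
                  k2 >= nz)
                continue;
              const int lj = lev[vox(i2, j2, k2, nx, ny)];
              if (lj != 0) {
                sum += lj;
                ++cnt;
              }
            }
        out(li - 1, 0) += 1.0;
        if (cnt > 0) out(li - 1, 1) += std::abs(li - sum / cnt);
      }
  return out;
}
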