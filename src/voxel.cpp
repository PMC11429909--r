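#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Grid conventions shared with the R side:
//   voxel (i, j, k) is 1-based; its centre is origin + (i - 1, j - 1, k - 1) * spacing.
//   Linear index (0-based) = (i-1) + nx*((j-1) + ny*(k-1)).

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Mark voxels whose centre lies within radius[a] of atom a. Also records, per
// marked voxel, the index (1-based) of the nearest covering atom.
// [[Rcpp::export(name = ".cppOccupancy")]]
List cppOccupancy(NumericMatrix xyz, NumericVector radius,
                  NumericVector origin, double spacing, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  LogicalVector mask(nvox, false);
  IntegerVector atom(nvox, 0);
  std::vector<double> best(nvox, R_PosInf);

  for (int a = 0; a < xyz.nrow(); ++a) {
    const double r = radius[a], r2 = r * r;
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    int i0 = (int)std::ceil((ax - r - origin[0]) / spacing);
    int i1 = (int)std::floor((ax + r - origin[0]) / spacing);
    int j0 = (int)std::ceil((ay - r - origin[1]) / spacing);
    int j1 = (int)std::floor((ay + r - origin[1]) / spacing);
    int k0 = (int)std::ceil((az - r - origin[2]) / spacing);
    int k1 = (int)std::floor((az + r - origin[2]) / spacing);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * spacing - az, dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * spacing - ay, d2yz = dy * dy + dz2;
        if (d2yz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * spacing - ax;
          const double d2 = dx * dx + d2yz;
          if (d2 <= r2) {
            const R_xlen_t v = lin(i, j, k, nx, ny);
            mask[v] = true;
            if (d2 < best[v]) { best[v] = d2; atom[v] = a + 1; }
          }
        }
      }
    }
  }
  return List::create(_["mask"] = mask, _["atom"] = atom);
}

// Binary dilation of `mask` by a ball of radius r (in Angstrom, spacing given).
// [[Rcpp::export(name = ".cppDilate")]]
LogicalVector cppDilate(LogicalVector mask, IntegerVector dims,
                        double spacing, double r) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  LogicalVector out(nvox, false);
  const int w = (int)std::floor(r / spacing);
  const double r2 = (r / spacing) * (r / spacing);
  // precompute ball offsets
  std::vector<int> di, dj, dk;
  for (int c = -w; c <= w; ++c)
    for (int b = -w; b <= w; ++b)
      for (int a = -w; a <= w; ++a)
        if ((double)a * a + b * b + c * c <= r2) {
          di.push_back(a); dj.push_back(b); dk.push_back(c);
        }
  const int noff = (int)di.size();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask[lin(i, j, k, nx, ny)]) continue;
        for (int o = 0; o < noff; ++o) {
          const int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          out[lin(ii, jj, kk, nx, ny)] = true;
        }
      }
  return out;
}

// Flood fill of `open` voxels starting from every open voxel on the box
// boundary; 26-connectivity. Returns reachability mask.
// [[Rcpp::export(name = ".cppFloodBoundary")]]
LogicalVector cppFloodBoundary(LogicalVector open, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  LogicalVector seen(nvox, false);
  std::queue<int> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && j != 0 && k != 0 && i != nx - 1 && j != ny - 1 &&
            k != nz - 1)
          continue;
        const int v = lin(i, j, k, nx, ny);
        if (open[v] && !seen[v]) { seen[v] = true; q.push(v); }
      }
  while (!q.empty()) {
    const int v = q.front(); q.pop();
    const int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          const int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          const int u = lin(ii, jj, kk, nx, ny);
          if (open[u] && !seen[u]) { seen[u] = true; q.push(u); }
        }
  }
  return seen;
}

// Ray enclosure: for each candidate voxel, count how many of 26 grid ray
// directions (6 axial, 12 face-diagonal, 8 body-diagonal) hit a protein
// voxel before leaving the grid. The count approximates the fraction of the
// sky occluded by protein; a strict majority marks a concave location.
// [[Rcpp::export(name = ".cppEnclosure")]]
IntegerVector cppEnclosure(LogicalVector protein, LogicalVector candidate,
                           IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  static const int dirs[13][3] = {
    {1,0,0},{0,1,0},{0,0,1},
    {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
    {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
  IntegerVector out(nvox, 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v = lin(i, j, k, nx, ny);
        if (!candidate[v]) continue;
        int count = 0;
        for (int d = 0; d < 13; ++d) {
          for (int s = -1; s <= 1; s += 2) {
            int ii = i, jj = j, kk = k;
            for (;;) {
              ii += s * dirs[d][0]; jj += s * dirs[d][1]; kk += s * dirs[d][2];
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                  kk >= nz)
                break;
              if (protein[lin(ii, jj, kk, nx, ny)]) { ++count; break; }
            }
          }
        }
        out[v] = count;
      }
  return out;
}

// Label connected components of `mask` (26- or 6-connectivity). Labels are
// 1..n in order of first (lowest) linear voxel index encountered.
// [[Rcpp::export(name = ".cppLabel")]]
IntegerVector cppLabel(LogicalVector mask, IntegerVector dims, int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(nvox, 0);
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t start = 0; start < nvox; ++start) {
    if (!mask[start] || lab[start]) continue;
    lab[start] = ++next;
    q.push((int)start);
    while (!q.empty()) {
      const int v = q.front(); q.pop();
      const int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            if (conn == 6 && (std::abs(di) + std::abs(dj) + std::abs(dk)) != 1)
              continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                kk >= nz)
              continue;
            const int u = lin(ii, jj, kk, nx, ny);
            if (mask[u] && !lab[u]) { lab[u] = lab[v]; q.push(u); }
          }
    }
  }
  return lab;
}

// For one labelled component: count boundary faces (6-adjacency faces to
// voxels outside the component or outside the grid), and list protein voxels
// face-adjacent to the component (for lining atoms) and component voxels
// face-adjacent to `bulk` (for mouths).
// [[Rcpp::export(name = ".cppComponentSurface")]]
List cppComponentSurface(IntegerVector lab, int id, LogicalVector protein,
                         LogicalVector bulk, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  int faces = 0;
  std::vector<int> liningVox, mouthVox;
  static const int f[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (R_xlen_t v = 0; v < nvox; ++v) {
    if (lab[v] != id) continue;
    const int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    bool touches_bulk = false;
    for (int d = 0; d < 6; ++d) {
      const int ii = i + f[d][0], jj = j + f[d][1], kk = k + f[d][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) {
        ++faces;
        continue;
      }
      const int u = lin(ii, jj, kk, nx, ny);
      if (lab[u] != id) {
        ++faces;
        if (protein[u]) liningVox.push_back(u + 1);
        if (bulk[u]) touches_bulk = true;
      }
    }
    if (touches_bulk) mouthVox.push_back((int)v + 1);
  }
  return List::create(_["faces"] = faces,
                      _["lining"] = IntegerVector(liningVox.begin(), liningVox.end()),
                      _["mouth"] = IntegerVector(mouthVox.begin(), mouthVox.end()));
}
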