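#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// Binary voxel topology: sequential 6-subiteration thinning to a unit-width
// curve skeleton, and 26-connected component labelling. Volumes are column
// major (x fastest), out-of-bounds treated as background.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Number of 26-connected components of object voxels in the 3x3x3
// neighbourhood, centre excluded. All cells are 26-adjacent to the centre,
// so every component counts.
static int object_components26(const int nb[27]) {
  bool visited[27] = {false};
  int ncomp = 0, stack[27];
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || visited[i]) continue;
    ++ncomp;
    int sp = 0;
    stack[sp++] = i;
    visited[i] = true;
    while (sp) {
      int c = stack[--sp];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || visited[j] || !nb[j]) continue;
        int jx = j % 3, jy = (j / 3) % 3, jz = j / 9;
        if (std::abs(jx - cx) <= 1 && std::abs(jy - cy) <= 1 &&
            std::abs(jz - cz) <= 1) {
          visited[j] = true;
          stack[sp++] = j;
        }
      }
    }
  }
  return ncomp;
}

// Number of 6-connected components of background voxels within the
// 18-neighbourhood that contain a face neighbour of the centre.
static int background_components6(const int nb[27]) {
  bool in18[27], visited[27] = {false};
  for (int i = 0; i < 27; ++i) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    int nzc = (x != 0) + (y != 0) + (z != 0);
    in18[i] = (nzc >= 1 && nzc <= 2);
  }
  int ncomp = 0, stack[27];
  for (int i = 0; i < 27; ++i) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    bool face = (std::abs(x) + std::abs(y) + std::abs(z) == 1);
    if (!face || nb[i] || visited[i]) continue;
    ++ncomp;
    int sp = 0;
    stack[sp++] = i;
    visited[i] = true;
    while (sp) {
      int c = stack[--sp];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int j = 0; j < 27; ++j) {
        if (visited[j] || !in18[j] || nb[j]) continue;
        int jx = j % 3, jy = (j / 3) % 3, jz = j / 9;
        if (std::abs(jx - cx) + std::abs(jy - cy) + std::abs(jz - cz) == 1) {
          visited[j] = true;
          stack[sp++] = j;
        }
      }
    }
  }
  return ncomp;
}

// A border voxel is deletable when it is a simple point (deletion preserves
// both object and background topology) and not a curve endpoint.
// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n) stop("volume size does not match dim");
  std::vector<char> v(n);
  for (R_xlen_t i = 0; i < n; ++i) v[i] = (vol[i] == TRUE) ? 1 : 0;

  const int dirs[6][3] = {{0, 0, -1}, {0, 0, 1},  {0, -1, 0},
                          {0, 1, 0},  {-1, 0, 0}, {1, 0, 0}};

  auto get = [&](int x, int y, int z) -> int {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
    return v[idx3(x, y, z, nx, ny)];
  };

  int nb[27];
  auto fill_nb = [&](int x, int y, int z) -> int {
    int cnt = 0, k = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx, ++k) {
          nb[k] = get(x + dx, y + dy, z + dz);
          if (k != 13) cnt += nb[k];
        }
    return cnt;
  };

  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      const int dx = dirs[d][0], dy = dirs[d][1], dz = dirs[d][2];
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int id = idx3(x, y, z, nx, ny);
            if (v[id] && !get(x + dx, y + dy, z + dz)) cand.push_back(id);
          }
      // sequential re-check so each deletion sees the current object
      for (size_t c = 0; c < cand.size(); ++c) {
        int id = cand[c];
        if (!v[id]) continue;
        int x = id % nx, y = (id / nx) % ny, z = id / (nx * ny);
        if (get(x + dx, y + dy, z + dz)) continue;
        int cnt = fill_nb(x, y, z);
        if (cnt <= 1) continue;  // endpoint: keep curve extremities
        if (object_components26(nb) != 1) continue;
        if (background_components6(nb) != 1) continue;
        v[id] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = v[i] ? TRUE : FALSE;
  out.attr("dim") = dim;
  return out;
}

// 26-connected component labels, 0 = background, components numbered by
// decreasing size (label 1 is the largest).
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n) stop("volume size does not match dim");
  std::vector<int> lab(n, 0);
  std::vector<R_xlen_t> queue, sizes;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (vol[i] != TRUE || lab[i]) continue;
    ++next;
    R_xlen_t sz = 0;
    queue.clear();
    queue.push_back(i);
    lab[i] = next;
    while (!queue.empty()) {
      R_xlen_t c = queue.back();
      queue.pop_back();
      ++sz;
      int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            R_xlen_t j = idx3(xx, yy, zz, nx, ny);
            if (vol[j] == TRUE && !lab[j]) {
              lab[j] = next;
              queue.push_back(j);
            }
          }
    }
    sizes.push_back(sz);
  }
  // relabel by decreasing size
  std::vector<int> order(next);
  for (int k = 0; k < next; ++k) order[k] = k;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> remap(next + 1, 0);
  for (int r = 0; r < next; ++r) remap[order[r] + 1] = r + 1;
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = remap[lab[i]];
  out.attr("dim") = dim;
  return out;
}
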