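// Lattice-combinatorial core: 3x3x3 neighbourhood predicates, topology-
// preserving thinning, connected-component labelling and separable
// convolution on 3D arrays.
//
// Array layout matches R: dim = c(nz, ny, nx), column-major, so the
// 0-based linear index of voxel (iz, iy, ix) is iz + nz*(iy + ny*ix).
// Inside a 3x3x3 neighbourhood the same convention holds with nz = ny = 3:
// index = iz + 3*iy + 9*ix, the centre voxel sits at index 13.
// Out-of-bounds voxels are treated as background everywhere.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 3x3x3 neighbourhood helpers
// ---------------------------------------------------------------------------

static inline int nb_index(int iz, int iy, int ix) {
  return iz + 3 * iy + 9 * ix;
}

// Euler characteristic of the voxels marked in a 3x3x3 block, computed on
// the cubical complex of closed unit cubes: chi = V - E + F - C. Cells of
// the complex live on a 7x7x7 half-integer grid; a cell's dimension is the
// number of odd coordinates, and it contributes (-1)^dim.
static int chi_block27(const bool nb[27]) {
  bool cell[343];
  std::memset(cell, 0, sizeof(cell));
  for (int ix = 0; ix < 3; ++ix)
    for (int iy = 0; iy < 3; ++iy)
      for (int iz = 0; iz < 3; ++iz) {
        if (!nb[nb_index(iz, iy, ix)]) continue;
        for (int az = 0; az <= 2; ++az)
          for (int ay = 0; ay <= 2; ++ay)
            for (int ax = 0; ax <= 2; ++ax)
              cell[(2 * iz + az) + 7 * (2 * iy + ay) + 49 * (2 * ix + ax)] = true;
      }
  int chi = 0;
  for (int cx = 0; cx < 7; ++cx)
    for (int cy = 0; cy < 7; ++cy)
      for (int cz = 0; cz < 7; ++cz) {
        if (!cell[cz + 7 * cy + 49 * cx]) continue;
        int odd = (cx & 1) + (cy & 1) + (cz & 1);
        chi += (odd & 1) ? -1 : 1;
      }
  return chi;
}

static inline int nb_count(const bool nb[27]) {
  int n = 0;
  for (int i = 0; i < 27; ++i) n += nb[i];
  return n;
}

static bool end_point(const bool nb[27]) {
  return nb[13] && nb_count(nb) == 2;
}

static bool euler_invariant(const bool nb[27]) {
  bool without[27];
  std::memcpy(without, nb, sizeof(without));
  without[13] = false;
  return chi_block27(nb) == chi_block27(without);
}

// Number of 26-connected components of the foreground restricted to the 26
// neighbours (centre excluded both as a member and as a connecting cell).
static int t26(const bool nb[27]) {
  int label[27];
  for (int i = 0; i < 27; ++i) label[i] = 0;
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || label[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    label[s] = ncomp;
    while (top > 0) {
      int v = stack[--top];
      int vz = v % 3, vy = (v / 3) % 3, vx = v / 9;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int wx = vx + dx, wy = vy + dy, wz = vz + dz;
            if (wx < 0 || wx > 2 || wy < 0 || wy > 2 || wz < 0 || wz > 2)
              continue;
            int w = nb_index(wz, wy, wx);
            if (w == 13 || w == v || !nb[w] || label[w]) continue;
            label[w] = ncomp;
            stack[top++] = w;
          }
    }
  }
  return ncomp;
}

// Number of 6-connected components of the background restricted to the 18
// face-and-edge neighbours that are 6-adjacent to the centre.
static int t6(const bool nb[27]) {
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int iz = i % 3, iy = (i / 3) % 3, ix = i / 9;
    int adx = ix == 1 ? 0 : 1, ady = iy == 1 ? 0 : 1, adz = iz == 1 ? 0 : 1;
    int nonzero = adx + ady + adz;
    in18[i] = (nonzero >= 1 && nonzero <= 2);
  }
  int label[27];
  for (int i = 0; i < 27; ++i) label[i] = 0;
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || label[s]) continue;
    // only seed from face neighbours (6-adjacent to the centre)
    int sz = s % 3, sy = (s / 3) % 3, sx = s / 9;
    int nz0 = (sx != 1) + (sy != 1) + (sz != 1);
    if (nz0 != 1) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    label[s] = ncomp;
    while (top > 0) {
      int v = stack[--top];
      int vz = v % 3, vy = (v / 3) % 3, vx = v / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int wx = vx + d6[k][0], wy = vy + d6[k][1], wz = vz + d6[k][2];
        if (wx < 0 || wx > 2 || wy < 0 || wy > 2 || wz < 0 || wz > 2) continue;
        int w = nb_index(wz, wy, wx);
        if (!in18[w] || nb[w] || label[w]) continue;
        label[w] = ncomp;
        stack[top++] = w;
      }
    }
  }
  // components already counted only when seeded from a face neighbour, but a
  // component might contain face neighbours while first visited from an edge
  // cell; seeding exclusively at face neighbours and growing outwards covers
  // every component 6-adjacent to the centre because any such component
  // contains a face neighbour by definition.
  return ncomp;
}

static bool simple_point(const bool nb[27]) {
  return t26(nb) == 1 && t6(nb) == 1;
}

// ---------------------------------------------------------------------------
// Whole-volume helpers
// ---------------------------------------------------------------------------

struct Vol {
  const int *data;
  int nz, ny, nx;
  inline bool at(int iz, int iy, int ix) const {
    if (iz < 0 || iz >= nz || iy < 0 || iy >= ny || ix < 0 || ix >= nx)
      return false;
    return data[iz + nz * (iy + (long long)ny * ix)] != 0;
  }
};

static void fill_nb(const Vol &v, int iz, int iy, int ix, bool nb[27]) {
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz)
        nb[nb_index(dz + 1, dy + 1, dx + 1)] = v.at(iz + dz, iy + dy, ix + dx);
}

static bool check27(LogicalVector nb27, bool nb[27]) {
  if (nb27.size() != 27)
    stop("neighbourhood must have exactly 27 entries");
  for (int i = 0; i < 27; ++i) nb[i] = nb27[i] == TRUE;
  if (!nb[13]) stop("centre voxel of the neighbourhood must be material");
  return true;
}

// [[Rcpp::export]]
bool cpp_is_end_point(LogicalVector nb27) {
  bool nb[27];
  check27(nb27, nb);
  return end_point(nb);
}

// [[Rcpp::export]]
bool cpp_is_euler_invariant(LogicalVector nb27) {
  bool nb[27];
  check27(nb27, nb);
  return euler_invariant(nb);
}

// [[Rcpp::export]]
bool cpp_is_simple_point(LogicalVector nb27) {
  bool nb[27];
  check27(nb27, nb);
  return simple_point(nb);
}

// [[Rcpp::export]]
int cpp_chi_block27(LogicalVector nb27) {
  bool nb[27];
  if (nb27.size() != 27) stop("need 27 entries");
  for (int i = 0; i < 27; ++i) nb[i] = nb27[i] == TRUE;
  return chi_block27(nb);
}

// ---------------------------------------------------------------------------
// Thinning
// ---------------------------------------------------------------------------

// Directed border test: the 6-neighbour in direction d is background.
// Direction order (fixed): -z, +z, -y, +y, -x, +x.
static const int DIRS[6][3] = {
  {-1, 0, 0}, {1, 0, 0}, {0, -1, 0}, {0, 1, 0}, {0, 0, -1}, {0, 0, 1}
}; // entries are (dz, dy, dx)

static bool removable(const Vol &v, int iz, int iy, int ix) {
  bool nb[27];
  fill_nb(v, iz, iy, ix, nb);
  if (end_point(nb)) return false;
  if (!euler_invariant(nb)) return false;
  if (!simple_point(nb)) return false;
  return true;
}

// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector vol, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long long n = (long long)nz * ny * nx;
  std::vector<int> work(n);
  for (long long i = 0; i < n; ++i) work[i] = vol[i] == TRUE ? 1 : 0;
  Vol v;
  v.data = work.data();
  v.nz = nz; v.ny = ny; v.nx = nx;

  std::vector<long long> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      // collection pass in linear scan order (z fastest, then y, then x)
      for (int ix = 0; ix < nx; ++ix)
        for (int iy = 0; iy < ny; ++iy)
          for (int iz = 0; iz < nz; ++iz) {
            long long idx = iz + (long long)nz * (iy + (long long)ny * ix);
            if (!work[idx]) continue;
            if (v.at(iz + DIRS[d][0], iy + DIRS[d][1], ix + DIRS[d][2]))
              continue; // not a border voxel for this direction
            if (removable(v, iz, iy, ix)) cand.push_back(idx);
          }
      // sequential re-check: earlier removals can invalidate later candidates
      for (size_t k = 0; k < cand.size(); ++k) {
        long long idx = cand[k];
        int iz = (int)(idx % nz);
        int iy = (int)((idx / nz) % ny);
        int ix = (int)(idx / ((long long)nz * ny));
        if (removable(v, iz, iy, ix)) {
          work[idx] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (long long i = 0; i < n; ++i) out[i] = work[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (26- or 6-connectivity)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector vol, IntegerVector dims,
                                   int connectivity) {
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long long n = (long long)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<long long> stack;
  int next = 0;

  std::vector<std::array<int, 3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dz, dy, dx});
      }

  for (long long s = 0; s < n; ++s) {
    if (vol[s] != TRUE || labels[s]) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    labels[s] = next;
    while (!stack.empty()) {
      long long v = stack.back();
      stack.pop_back();
      int iz = (int)(v % nz);
      int iy = (int)((v / nz) % ny);
      int ix = (int)(v / ((long long)nz * ny));
      for (size_t k = 0; k < offs.size(); ++k) {
        int wz = iz + offs[k][0], wy = iy + offs[k][1], wx = ix + offs[k][2];
        if (wz < 0 || wz >= nz || wy < 0 || wy >= ny || wx < 0 || wx >= nx)
          continue;
        long long w = wz + (long long)nz * (wy + (long long)ny * wx);
        if (vol[w] != TRUE || labels[w]) continue;
        labels[w] = next;
        stack.push_back(w);
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// ---------------------------------------------------------------------------
// Neighbourhood material counts (centre included), for voxel classification
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_neighbor_count(LogicalVector vol, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long long n = (long long)nz * ny * nx;
  std::vector<int> work(n);
  for (long long i = 0; i < n; ++i) work[i] = vol[i] == TRUE ? 1 : 0;
  Vol v;
  v.data = work.data();
  v.nz = nz; v.ny = ny; v.nx = nx;
  IntegerVector out(n, 0);
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        long long idx = iz + (long long)nz * (iy + (long long)ny * ix);
        if (!work[idx]) continue;
        int c = 0;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz)
              c += v.at(iz + dz, iy + dy, ix + dx);
        out[idx] = c;
      }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Separable 1D convolution along one axis with reflected boundaries
// ---------------------------------------------------------------------------

// axis: 1 = z (first index), 2 = y, 3 = x. Kernel length must be odd.
// Reflection is half-sample: ... c b a | a b c ...
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector vol, IntegerVector dims,
                                NumericVector kernel, int axis) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long long n = (long long)nz * ny * nx;
  int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  int kh = klen / 2;
  NumericVector out(n);
  int len = axis == 1 ? nz : (axis == 2 ? ny : nx);
  long long stride = axis == 1 ? 1 : (axis == 2 ? nz : (long long)nz * ny);

  // iterate over all lines along the chosen axis
  long long nlines = n / len;
  std::vector<double> line(len);
  for (long long l = 0; l < nlines; ++l) {
    // compute the base index of this line
    long long base;
    if (axis == 1) {
      long long iy = l % ny, ix = l / ny;
      base = (long long)nz * (iy + (long long)ny * ix);
    } else if (axis == 2) {
      long long iz = l % nz, ix = l / nz;
      base = iz + (long long)nz * ny * ix;
    } else {
      base = l; // l = iz + nz*iy
    }
    for (int i = 0; i < len; ++i) line[i] = vol[base + stride * i];
    for (int i = 0; i < len; ++i) {
      double acc = 0.0;
      for (int k = -kh; k <= kh; ++k) {
        int j = i + k;
        if (j < 0) j = -j - 1;           // reflect
        if (j >= len) j = 2 * len - j - 1;
        if (j < 0) j = 0;                // very short lines
        if (j >= len) j = len - 1;
        acc += line[j] * kernel[k + kh];
      }
      out[base + stride * i] = acc;
    }
  }
  out.attr("dim") = dims;
  return out;
}
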