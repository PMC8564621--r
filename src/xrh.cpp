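#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear index helpers for arrays stored [y, x, z] (column-major).
static inline int idx3(int y, int x, int z, int ny, int nx) {
  return y + ny * (x + nx * z);
}

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int n = ny * nx * nz;
  IntegerVector labels(n, 0);
  std::vector<int> offy, offx, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int manh = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offy.push_back(dy); offx.push_back(dx); offz.push_back(dz);
      }
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || labels[i]) continue;
    ++next;
    labels[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int z = cur / (ny * nx);
      int rem = cur - z * ny * nx;
      int x = rem / ny;
      int y = rem - x * ny;
      for (size_t k = 0; k < offy.size(); ++k) {
        int yy = y + offy[k], xx = x + offx[k], zz = z + offz[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        int j = idx3(yy, xx, zz, ny, nx);
        if (mask[j] && !labels[j]) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}

// Ball structuring element of radius rho (Euclidean), used by the
// curvature-smoothing step: one morphological opening per iteration.
// Opening is anti-extensive (it never adds voxels, so it cannot cross the
// speed barrier), preserves flat fronts and any blob that contains the ball,
// and removes protrusions/channels narrower than the ball -- the discrete
// realization of resistance to entering narrow objects.
struct BallSE {
  std::vector<int> dy, dx, dz;
  explicit BallSE(int rho) {
    for (int a = -rho; a <= rho; ++a)
      for (int b = -rho; b <= rho; ++b)
        for (int c = -rho; c <= rho; ++c)
          if (a * a + b * b + c * c <= rho * rho) {
            dy.push_back(a); dx.push_back(b); dz.push_back(c);
          }
  }
};

// Opening of u by the ball, restricted to the bounding box (expanded by the
// ball radius).  Out-of-volume voxels count as foreground for the erosion so
// structures touching the grid border are not eroded from outside.
static void open_pass(std::vector<unsigned char> &u,
                      int ny, int nx, int nz,
                      int lo[3], int hi[3], const BallSE &se, int rho) {
  int blo[3], bhi[3];
  blo[0] = std::max(0, lo[0] - rho); bhi[0] = std::min(ny - 1, hi[0] + rho);
  blo[1] = std::max(0, lo[1] - rho); bhi[1] = std::min(nx - 1, hi[1] + rho);
  blo[2] = std::max(0, lo[2] - rho); bhi[2] = std::min(nz - 1, hi[2] + rho);
  std::vector<int> core;
  for (int z = blo[2]; z <= bhi[2]; ++z)
    for (int x = blo[1]; x <= bhi[1]; ++x)
      for (int y = blo[0]; y <= bhi[0]; ++y) {
        int i = idx3(y, x, z, ny, nx);
        if (!u[i]) continue;
        bool all = true;
        for (size_t k = 0; k < se.dy.size() && all; ++k) {
          int yy = y + se.dy[k], xx = x + se.dx[k], zz = z + se.dz[k];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
            continue;  // outside the grid counts as foreground
          if (!u[idx3(yy, xx, zz, ny, nx)]) all = false;
        }
        if (all) core.push_back(i);
      }
  // clear the box, then dilate the eroded core back out
  for (int z = blo[2]; z <= bhi[2]; ++z)
    for (int x = blo[1]; x <= bhi[1]; ++x)
      for (int y = blo[0]; y <= bhi[0]; ++y)
        u[idx3(y, x, z, ny, nx)] = 0;
  for (size_t k = 0; k < core.size(); ++k) {
    int i = core[k];
    int z = i / (ny * nx);
    int rem = i - z * ny * nx;
    int x = rem / ny;
    int y = rem - x * ny;
    for (size_t m = 0; m < se.dy.size(); ++m) {
      int yy = y + se.dy[m], xx = x + se.dx[m], zz = z + se.dz[m];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
        continue;
      u[idx3(yy, xx, zz, ny, nx)] = 1;
    }
  }
}

// [[Rcpp::export(name = ".active_contour_cpp")]]
List active_contour_cpp(NumericVector speed, IntegerVector dims,
                        IntegerMatrix seeds, double smoothing_force,
                        int max_iterations, double convergence_tol,
                        int init_radius) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int n = ny * nx * nz;
  std::vector<unsigned char> u(n, 0);
  int lo[3] = {ny, nx, nz}, hi[3] = {-1, -1, -1};

  // initialize small balls at the seeds, clipped to positive speed
  for (int s = 0; s < seeds.nrow(); ++s) {
    int sx = seeds(s, 0), sy = seeds(s, 1), sz = seeds(s, 2);
    for (int dz = -init_radius; dz <= init_radius; ++dz)
      for (int dx = -init_radius; dx <= init_radius; ++dx)
        for (int dy = -init_radius; dy <= init_radius; ++dy) {
          if (dx * dx + dy * dy + dz * dz > init_radius * init_radius) continue;
          int y = sy + dy, x = sx + dx, z = sz + dz;
          if (y < 0 || y >= ny || x < 0 || x >= nx || z < 0 || z >= nz) continue;
          int i = idx3(y, x, z, ny, nx);
          if (speed[i] > 0) {
            u[i] = 1;
            if (y < lo[0]) lo[0] = y; if (y > hi[0]) hi[0] = y;
            if (x < lo[1]) lo[1] = x; if (x > hi[1]) hi[1] = x;
            if (z < lo[2]) lo[2] = z; if (z > hi[2]) hi[2] = z;
          }
        }
  }
  if (hi[0] < 0)
    return List::create(_["mask"] = LogicalVector(n, false),
                        _["iterations"] = 0, _["converged"] = true);

  int rho = (int) std::lround(smoothing_force / 0.2);
  BallSE se(rho);
  int iter = 0;
  bool converged = false;
  std::vector<unsigned char> uprev;
  for (iter = 1; iter <= max_iterations; ++iter) {
    uprev = u;
    // expand the working box by one voxel for the balloon step
    int blo[3], bhi[3];
    blo[0] = std::max(0, lo[0] - 1); bhi[0] = std::min(ny - 1, hi[0] + 1);
    blo[1] = std::max(0, lo[1] - 1); bhi[1] = std::min(nx - 1, hi[1] + 1);
    blo[2] = std::max(0, lo[2] - 1); bhi[2] = std::min(nz - 1, hi[2] + 1);

    // balloon: grow one voxel (6-connected) into positive-speed territory
    std::vector<int> added;
    for (int z = blo[2]; z <= bhi[2]; ++z)
      for (int x = blo[1]; x <= bhi[1]; ++x)
        for (int y = blo[0]; y <= bhi[0]; ++y) {
          int i = idx3(y, x, z, ny, nx);
          if (u[i] || speed[i] <= 0) continue;
          bool nb = (y > 0 && u[i - 1]) || (y < ny - 1 && u[i + 1]) ||
                    (x > 0 && u[i - ny]) || (x < nx - 1 && u[i + ny]) ||
                    (z > 0 && u[i - ny * nx]) || (z < nz - 1 && u[i + ny * nx]);
          if (nb) added.push_back(i);
        }
    for (size_t k = 0; k < added.size(); ++k) u[added[k]] = 1;

    // update the bounding box
    for (int a = 0; a < 3; ++a) { lo[a] = blo[a]; hi[a] = bhi[a]; }

    // curvature smoothing: one opening by the force-scaled ball
    if (rho > 0) open_pass(u, ny, nx, nz, lo, hi, se, rho);

    // net change over the iteration (balloon additions may be undone by the
    // smoothing passes, e.g. at a narrow neck: that counts as no change)
    size_t changed = 0;
    for (int z = lo[2]; z <= hi[2]; ++z)
      for (int x = lo[1]; x <= hi[1]; ++x)
        for (int y = lo[0]; y <= hi[0]; ++y) {
          int i = idx3(y, x, z, ny, nx);
          if (u[i] != uprev[i]) ++changed;
        }
    double frac = (double) changed / (double) n;
    if (frac < convergence_tol) { converged = true; break; }
  }

  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = u[i] != 0;
  return List::create(_["mask"] = out, _["iterations"] = iter,
                      _["converged"] = converged);
}
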