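#include <Rcpp.h>
#include <queue>
#include <map>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// 3D grid helpers: arrays arrive as R column-major vectors with dims (nx, ny, nz).

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Connected components on a logical mask, 6-connectivity.
// Returns integer labels 0 (background) / 1..C, plus component sizes.
// [[Rcpp::export(name = ".cc6")]]
IntegerVector cc6(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<int> stack;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    stack.clear();
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int z = v / (nx * ny);
      int rem = v - z * nx * ny;
      int y = rem / nx;
      int x = rem - y * nx;
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        int w = lin(xx, yy, zz, nx, ny);
        if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// SLIC-style supervoxel oversegmentation restricted to a mask.
// vox: intensities in [0,1]; spacing in mm. Distance
//   D^2 = (dI)^2 + compactness^2 * (ds_mm / step_mm)^2
// with step_mm the expected supervoxel pitch. After convergence every
// connected component becomes its own supervoxel; components are then merged
// into their most-contacted neighbour until at most n_segments remain (tiny
// fragments first), so labels partition the mask into connected regions.
// [[Rcpp::export(name = ".slic3d")]]
IntegerVector slic3d(NumericVector vox, LogicalVector mask, IntegerVector dims,
                     NumericVector spacing, int n_segments, double compactness,
                     int max_iter) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  std::vector<int> inmask;
  inmask.reserve(n);
  for (int i = 0; i < n; ++i) if (mask[i]) inmask.push_back(i);
  int V = (int)inmask.size();
  if (V == 0) stop("mask is empty");
  if (n_segments < 1) stop("n_segments must be >= 1");

  double voxvol = sx * sy * sz;
  double step_mm = std::cbrt((double)V * voxvol / (double)n_segments);
  if (step_mm <= 0) step_mm = 1.0;

  // bounding box of the mask
  int x0 = nx, x1 = -1, y0 = ny, y1 = -1, z0 = nz, z1 = -1;
  for (int t = 0; t < V; ++t) {
    int v = inmask[t];
    int z = v / (nx * ny), rem = v - z * nx * ny, y = rem / nx, x = rem - y * nx;
    if (x < x0) x0 = x; if (x > x1) x1 = x;
    if (y < y0) y0 = y; if (y > y1) y1 = y;
    if (z < z0) z0 = z; if (z > z1) z1 = z;
  }

  // seed centers on a regular grid (voxel pitch per axis from step_mm)
  int gx = std::max(1, (int)std::lround(step_mm / sx));
  int gy = std::max(1, (int)std::lround(step_mm / sy));
  int gz = std::max(1, (int)std::lround(step_mm / sz));
  std::vector<double> cX, cY, cZ, cI;  // center position (voxel units) + intensity
  for (int z = z0 + gz / 2; z <= z1; z += gz)
    for (int y = y0 + gy / 2; y <= y1; y += gy)
      for (int x = x0 + gx / 2; x <= x1; x += gx) {
        int v = lin(x, y, z, nx, ny);
        if (!mask[v]) continue;
        cX.push_back(x); cY.push_back(y); cZ.push_back(z); cI.push_back(vox[v]);
      }
  if ((int)cX.size() == 0) {
    // fall back to the first in-mask voxel
    int v = inmask[0];
    int z = v / (nx * ny), rem = v - z * nx * ny, y = rem / nx, x = rem - y * nx;
    cX.push_back(x); cY.push_back(y); cZ.push_back(z); cI.push_back(vox[v]);
  }
  // cap at n_segments by even subsampling
  if ((int)cX.size() > n_segments) {
    std::vector<double> nX, nY, nZ, nI;
    double stride = (double)cX.size() / (double)n_segments;
    for (int k = 0; k < n_segments; ++k) {
      int idx = (int)std::floor(k * stride);
      nX.push_back(cX[idx]); nY.push_back(cY[idx]);
      nZ.push_back(cZ[idx]); nI.push_back(cI[idx]);
    }
    cX = nX; cY = nY; cZ = nZ; cI = nI;
  }
  int C = (int)cX.size();

  std::vector<int> assign(n, -1);
  std::vector<double> best(n, R_PosInf);
  double m2 = compactness * compactness;
  int wx = std::max(1, 2 * gx), wy = std::max(1, 2 * gy), wz = std::max(1, 2 * gz);

  for (int iter = 0; iter < max_iter; ++iter) {
    std::fill(best.begin(), best.end(), R_PosInf);
    std::fill(assign.begin(), assign.end(), -1);
    for (int c = 0; c < C; ++c) {
      int cx = (int)std::lround(cX[c]), cy = (int)std::lround(cY[c]),
          cz = (int)std::lround(cZ[c]);
      int ax0 = std::max(0, cx - wx), ax1 = std::min(nx - 1, cx + wx);
      int ay0 = std::max(0, cy - wy), ay1 = std::min(ny - 1, cy + wy);
      int az0 = std::max(0, cz - wz), az1 = std::min(nz - 1, cz + wz);
      for (int z = az0; z <= az1; ++z)
        for (int y = ay0; y <= ay1; ++y)
          for (int x = ax0; x <= ax1; ++x) {
            int v = lin(x, y, z, nx, ny);
            if (!mask[v]) continue;
            double dI = vox[v] - cI[c];
            double ddx = (x - cX[c]) * sx, ddy = (y - cY[c]) * sy,
                   ddz = (z - cZ[c]) * sz;
            double ds2 = (ddx * ddx + ddy * ddy + ddz * ddz) / (step_mm * step_mm);
            double D = dI * dI + m2 * ds2;
            if (D < best[v]) { best[v] = D; assign[v] = c; }
          }
    }
    // voxels outside every search window: nearest center by full scan
    for (int t = 0; t < V; ++t) {
      int v = inmask[t];
      if (assign[v] >= 0) continue;
      int z = v / (nx * ny), rem = v - z * nx * ny, y = rem / nx, x = rem - y * nx;
      double bd = R_PosInf; int bc = 0;
      for (int c = 0; c < C; ++c) {
        double ddx = (x - cX[c]) * sx, ddy = (y - cY[c]) * sy, ddz = (z - cZ[c]) * sz;
        double d = ddx * ddx + ddy * ddy + ddz * ddz;
        if (d < bd) { bd = d; bc = c; }
      }
      assign[v] = bc;
    }
    // update centers
    std::vector<double> sX(C, 0), sY(C, 0), sZ(C, 0), sI(C, 0);
    std::vector<int> cnt(C, 0);
    for (int t = 0; t < V; ++t) {
      int v = inmask[t], c = assign[v];
      int z = v / (nx * ny), rem = v - z * nx * ny, y = rem / nx, x = rem - y * nx;
      sX[c] += x; sY[c] += y; sZ[c] += z; sI[c] += vox[v]; ++cnt[c];
    }
    double shift = 0;
    int kept = 0;
    for (int c = 0; c < C; ++c) {
      if (cnt[c] == 0) continue;
      double nXc = sX[c] / cnt[c], nYc = sY[c] / cnt[c], nZc = sZ[c] / cnt[c];
      shift += std::abs(nXc - cX[c]) + std::abs(nYc - cY[c]) + std::abs(nZc - cZ[c]);
      cX[kept] = nXc; cY[kept] = nYc; cZ[kept] = nZc; cI[kept] = sI[c] / cnt[c];
      // remap assignments lazily below if centers were dropped
      if (kept != c)
        for (int t = 0; t < V; ++t) if (assign[inmask[t]] == c) assign[inmask[t]] = kept;
      ++kept;
    }
    C = kept;
    cX.resize(C); cY.resize(C); cZ.resize(C); cI.resize(C);
    if (shift < 1e-3) break;
  }

  // --- connectivity enforcement ---------------------------------------
  // components of equal-assignment regions (6-connectivity)
  std::vector<int> comp(n, -1);
  std::vector<std::vector<int> > members;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int t = 0; t < V; ++t) {
    int i = inmask[t];
    if (comp[i] != -1) continue;
    int id = (int)members.size();
    members.push_back(std::vector<int>());
    std::vector<int> stack(1, i);
    comp[i] = id;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      members[id].push_back(v);
      int z = v / (nx * ny), rem = v - z * nx * ny, y = rem / nx, x = rem - y * nx;
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        int w = lin(xx, yy, zz, nx, ny);
        if (mask[w] && comp[w] == -1 && assign[w] == assign[v]) {
          comp[w] = id; stack.push_back(w);
        }
      }
    }
  }
  int nc = (int)members.size();
  // union-find over components; merge smallest into most-contacted neighbour
  std::vector<int> parent(nc);
  for (int i = 0; i < nc; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  std::vector<long> csize(nc);
  for (int i = 0; i < nc; ++i) csize[i] = (long)members[i].size();

  typedef std::pair<long, int> SP;
  std::priority_queue<SP, std::vector<SP>, std::greater<SP> > pq;
  int alive = nc;
  for (int i = 0; i < nc; ++i) pq.push(SP(csize[i], i));
  while (alive > n_segments && !pq.empty()) {
    SP top = pq.top(); pq.pop();
    int c = find(top.second);
    if (c != top.second || csize[c] != top.first) continue;  // stale entry
    // contact counts with neighbouring (root) components
    std::map<int, int> contact;
    for (size_t t = 0; t < members[c].size(); ++t) {
      // members may have been merged in; iterate over all voxels of root set:
      ;
    }
    // gather all voxels belonging to root c
    // (walk every original component whose root is c)
    for (int oc = 0; oc < nc; ++oc) {
      if (find(oc) != c) continue;
      for (size_t t = 0; t < members[oc].size(); ++t) {
        int v = members[oc][t];
        int z = v / (nx * ny), rem = v - z * nx * ny, y = rem / nx, x = rem - y * nx;
        for (int d = 0; d < 6; ++d) {
          int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
          int w = lin(xx, yy, zz, nx, ny);
          if (!mask[w]) continue;
          int rc = find(comp[w]);
          if (rc != c) contact[rc] += 1;
        }
      }
    }
    if (contact.empty()) continue;  // isolated island (mask component) stays
    int bestc = -1; int bestn = -1;
    for (std::map<int, int>::iterator it = contact.begin(); it != contact.end(); ++it)
      if (it->second > bestn) { bestn = it->second; bestc = it->first; }
    parent[c] = bestc;
    csize[bestc] += csize[c];
    --alive;
    pq.push(SP(csize[bestc], bestc));
  }

  // final labels 1..S
  std::map<int, int> relab;
  IntegerVector out(n, 0);
  for (int t = 0; t < V; ++t) {
    int v = inmask[t];
    int r = find(comp[v]);
    std::map<int, int>::iterator it = relab.find(r);
    int l;
    if (it == relab.end()) { l = (int)relab.size() + 1; relab[r] = l; }
    else l = it->second;
    out[v] = l;
  }
  out.attr("n_supervoxels") = (int)relab.size();
  return out;
}
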