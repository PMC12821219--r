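// Voxel morphology, thinning, distance transforms, implicit capsule
// rasterization, iso-surfacing and mesh distance kernels.
//
// All 3D arrays are R arrays in column-major order: linear index
// i + nx*(j + ny*k), 0-based here. Voxel centers sit at (i + 0.5) * spacing.
#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (size_t)ny * k);
}

// ---------------------------------------------------------------------------
// Connected components (6- or 26-connectivity), BFS flood fill.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int nlab = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++nlab;
    lab[s] = nlab;
    stack.push_back((int)s);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (connectivity == 6 && man != 1) continue;
            int ii = i + dx, jj = j + dy, kk = k + dz;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            int u = idx3(ii, jj, kk, nx, ny);
            if (mask[u] && !lab[u]) { lab[u] = nlab; stack.push_back(u); }
          }
    }
  }
  lab.attr("n_components") = nlab;
  return lab;
}

// ---------------------------------------------------------------------------
// Fill enclosed background cavities: 6-connected background components that
// do not touch the array border become foreground.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalVector fill_holes(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<int> stack;
  // seed from all border background voxels
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        int v = idx3(i, j, k, nx, ny);
        if (!mask[v] && !outside[v]) { outside[v] = 1; stack.push_back(v); }
      }
  const int stepi[6] = {-1, 1, 0, 0, 0, 0};
  const int stepj[6] = {0, 0, -1, 1, 0, 0};
  const int stepk[6] = {0, 0, 0, 0, -1, 1};
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    for (int d = 0; d < 6; ++d) {
      int ii = i + stepi[d], jj = j + stepj[d], kk = k + stepk[d];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      int u = idx3(ii, jj, kk, nx, ny);
      if (!mask[u] && !outside[u]) { outside[u] = 1; stack.push_back(u); }
    }
  }
  LogicalVector out(n);
  for (size_t s = 0; s < n; ++s) out[s] = mask[s] || !outside[s];
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas), anisotropic spacing. Returns, for every voxel,
// the distance to the nearest background voxel center (0 on background).
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w) {
  const double INF = 1e30;
  int kk = 0;
  v[0] = 0;
  z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[kk];
      s = ((f[q] + w * w * q * q) - (f[p] + w * w * p * p)) /
          (2.0 * w * w * (q - p));
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s; z[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < w * q) ++kk;
    int p = v[kk];
    double dq = w * (q - p);
    d[q] = dq * dq + f[p];
  }
}

// [[Rcpp::export(name = ".edt")]]
NumericVector edt(LogicalVector fg, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  const double INF = 1e30;
  NumericVector D(n);
  for (size_t s = 0; s < n; ++s) D[s] = fg[s] ? INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = D[idx3(i, j, k, nx, ny)];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) D[idx3(i, j, k, nx, ny)] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = D[idx3(i, j, k, nx, ny)];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) D[idx3(i, j, k, nx, ny)] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = D[idx3(i, j, k, nx, ny)];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) D[idx3(i, j, k, nx, ny)] = d[k];
    }
  for (size_t s = 0; s < n; ++s) D[s] = std::sqrt(D[s]);
  return D;
}

// ---------------------------------------------------------------------------
// Simple-point test (Bertrand/Malandain characterization):
//   * foreground voxels of the 26-neighborhood form exactly one
//     26-connected component, and
//   * background voxels of the 18-neighborhood form exactly one 6-connected
//     component that is 6-adjacent to the center.
// nb: 27 booleans, center at index 13, index = (dx+1)+3*(dy+1)+9*(dz+1).
static inline int nb_index(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

static bool is_simple(const bool nb[27]) {
  // --- foreground 26-components in N26
  bool fg[27];
  int nfg = 0;
  for (int t = 0; t < 27; ++t) { fg[t] = nb[t]; }
  fg[13] = false;
  for (int t = 0; t < 27; ++t) if (fg[t]) ++nfg;
  if (nfg == 0) return false;
  {
    int seen[27] = {0};
    int stack[27], sp = 0, start = -1;
    for (int t = 0; t < 27; ++t) if (fg[t]) { start = t; break; }
    stack[sp++] = start; seen[start] = 1;
    int cnt = 1;
    while (sp) {
      int t = stack[--sp];
      int dx = t % 3 - 1, dy = (t / 3) % 3 - 1, dz = t / 9 - 1;
      for (int cz = -1; cz <= 1; ++cz)
        for (int cy = -1; cy <= 1; ++cy)
          for (int cx = -1; cx <= 1; ++cx) {
            int ex = dx + cx, ey = dy + cy, ez = dz + cz;
            if (ex < -1 || ex > 1 || ey < -1 || ey > 1 || ez < -1 || ez > 1)
              continue;
            int u = nb_index(ex, ey, ez);
            if (fg[u] && !seen[u]) { seen[u] = 1; stack[sp++] = u; ++cnt; }
          }
    }
    if (cnt != nfg) return false;  // more than one fg component
  }
  // --- background 6-components in N18 adjacent to center
  bool in18[27];
  for (int t = 0; t < 27; ++t) {
    int dx = t % 3 - 1, dy = (t / 3) % 3 - 1, dz = t / 9 - 1;
    int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
    in18[t] = (man == 1 || man == 2);
  }
  bool bg[27];
  for (int t = 0; t < 27; ++t) bg[t] = in18[t] && !nb[t];
  // seed from background face-neighbors of the center
  const int faces[6] = {nb_index(-1, 0, 0), nb_index(1, 0, 0),
                        nb_index(0, -1, 0), nb_index(0, 1, 0),
                        nb_index(0, 0, -1), nb_index(0, 0, 1)};
  bool any_face_bg = false;
  for (int d = 0; d < 6; ++d) if (bg[faces[d]]) any_face_bg = true;
  if (!any_face_bg) return false;
  int seen[27] = {0};
  int stack[27], sp = 0;
  // flood from first bg face neighbor
  for (int d = 0; d < 6; ++d)
    if (bg[faces[d]]) { stack[sp++] = faces[d]; seen[faces[d]] = 1; break; }
  while (sp) {
    int t = stack[--sp];
    int dx = t % 3 - 1, dy = (t / 3) % 3 - 1, dz = t / 9 - 1;
    const int sx[6] = {-1, 1, 0, 0, 0, 0};
    const int sy[6] = {0, 0, -1, 1, 0, 0};
    const int sz[6] = {0, 0, 0, 0, -1, 1};
    for (int d = 0; d < 6; ++d) {
      int ex = dx + sx[d], ey = dy + sy[d], ez = dz + sz[d];
      if (ex < -1 || ex > 1 || ey < -1 || ey > 1 || ez < -1 || ez > 1) continue;
      int u = nb_index(ex, ey, ez);
      if (bg[u] && !seen[u]) { seen[u] = 1; stack[sp++] = u; }
    }
  }
  // every bg face neighbor must be in this single component
  for (int d = 0; d < 6; ++d)
    if (bg[faces[d]] && !seen[faces[d]]) return false;
  return true;
}

// exported for testing: simple-point check on a 27-voxel neighborhood
// [[Rcpp::export(name = ".is_simple_point")]]
bool is_simple_point(LogicalVector nb27) {
  bool nb[27];
  for (int t = 0; t < 27; ++t) nb[t] = nb27[t];
  return is_simple(nb);
}

// ---------------------------------------------------------------------------
// Homotopic thinning to a one-voxel-wide curve skeleton: sequential removal
// of simple, non-endpoint border points in six directional subiterations
// until stable. Topology (component and loop counts) is preserved because
// only simple points are deleted, with re-checks at deletion time.
// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> cur(n);
  for (size_t s = 0; s < n; ++s) cur[s] = mask[s] ? 1 : 0;
  // distance transform of the original mask: deletions proceed outside-in so
  // the erosion front stays parallel to the boundary and the result medial
  NumericVector spacing_unit = NumericVector::create(1.0, 1.0, 1.0);
  NumericVector dist = edt(mask, dims, spacing_unit);
  const int sx[6] = {-1, 1, 0, 0, 0, 0};
  const int sy[6] = {0, 0, -1, 1, 0, 0};
  const int sz[6] = {0, 0, 0, 0, -1, 1};
  auto fg_at = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return cur[idx3(i, j, k, nx, ny)] != 0;
  };
  auto load_nb = [&](int i, int j, int k, bool nb[27]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[nb_index(dx, dy, dz)] = fg_at(i + dx, j + dy, k + dz);
  };
  auto n26 = [&](int i, int j, int k) -> int {
    int c = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          if (fg_at(i + dx, j + dy, k + dz)) ++c;
        }
    return c;
  };
  // Cleanup phase, run only when the directional passes are exhausted:
  // remove remaining simple non-endpoint voxels in distance order. The
  // directional passes have already peeled every straight multi-voxel-wide
  // run, so what is left are diagonal knots and duplicate voxels riding
  // beside the digital curve; eroding those outside-in tautens the skeleton
  // to one-voxel-wide curves without end-to-end cascades.
  auto knot_cleanup = [&]() {
    bool any = false;
    bool repeat_pass = true;
    std::vector<std::pair<double, int>> cc;
    while (repeat_pass) {
      repeat_pass = false;
      cc.clear();
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            int v = idx3(i, j, k, nx, ny);
            if (cur[v]) cc.push_back(std::make_pair(std::floor(dist[v]), v));
          }
      std::stable_sort(cc.begin(), cc.end(),
                       [](const std::pair<double, int>& a,
                          const std::pair<double, int>& b) {
                         return a.first < b.first;
                       });
      for (auto& cv : cc) {
        int v = cv.second;
        if (!cur[v]) continue;
        int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
        if (n26(i, j, k) <= 1) continue;
        bool nb[27];
        load_nb(i, j, k, nb);
        if (is_simple(nb)) {
          cur[v] = 0;
          any = true;
          repeat_pass = true;
        }
      }
    }
    return any;
  };
  bool changed = true;
  std::vector<std::pair<double, int>> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            int v = idx3(i, j, k, nx, ny);
            if (!cur[v]) continue;
            if (fg_at(i + sx[d], j + sy[d], k + sz[d])) continue;  // not border
            cand.push_back(std::make_pair(std::floor(dist[v]), v));
          }
      std::stable_sort(cand.begin(), cand.end(),
                       [](const std::pair<double, int>& a,
                          const std::pair<double, int>& b) {
                         return a.first < b.first;
                       });
      for (auto& cv : cand) {
        int v = cv.second;
        int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
        if (!cur[v]) continue;
        if (fg_at(i + sx[d], j + sy[d], k + sz[d])) continue;
        // only peel a layer: a voxel that is already one voxel wide along
        // the peel direction is medial along this axis, and deleting it
        // would let a whole 1-voxel-wide structure be consumed end-to-end
        // within one subiteration. Voxels with no face-connected neighbor
        // at all (diagonal debris of the erosion front) are exempt from
        // this protection, otherwise they accumulate into thinning-stable
        // diagonal lattices.
        if (!fg_at(i - sx[d], j - sy[d], k - sz[d])) {
          int n6 = 0;
          for (int dd = 0; dd < 6; ++dd)
            if (fg_at(i + sx[dd], j + sy[dd], k + sz[dd])) ++n6;
          if (n6 >= 1) continue;
        }
        if (n26(i, j, k) <= 1) continue;  // endpoint: preserve curve ends
        bool nb[27];
        load_nb(i, j, k, nb);
        if (is_simple(nb)) { cur[v] = 0; changed = true; }
      }
    }
    if (!changed && knot_cleanup()) changed = true;
  }
  LogicalVector out(n);
  for (size_t s = 0; s < n; ++s) out[s] = cur[s] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Skeleton voxel graph: cluster junction voxels (>= 3 neighbors) into branch
// nodes, endpoints (1 neighbor) and isolated voxels become terminal nodes,
// and trace degree-2 chains into links. Pure cycles get one anchor node and
// a self-loop link. Returns 1-based voxel indices.
// [[Rcpp::export(name = ".skel_graph")]]
List skel_graph(LogicalVector skel, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  auto fg_at = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return skel[idx3(i, j, k, nx, ny)] != 0;
  };
  std::vector<int> vox;             // skeleton voxels
  std::vector<int> deg(n, -1);
  for (size_t s = 0; s < n; ++s) if (skel[s]) vox.push_back((int)s);
  auto neighbors = [&](int v, std::vector<int>& out) {
    out.clear();
    int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          if (fg_at(i + dx, j + dy, k + dz))
            out.push_back(idx3(i + dx, j + dy, k + dz, nx, ny));
        }
  };
  std::vector<int> nbbuf;
  for (int v : vox) { neighbors(v, nbbuf); deg[v] = (int)nbbuf.size(); }

  std::vector<int> node_of(n, 0);   // node id (1-based), 0 = not a node voxel
  std::vector<std::vector<int>> node_members;
  // junction clusters (26-connected groups of deg>=3 voxels)
  for (int v : vox) {
    if (deg[v] < 3 || node_of[v]) continue;
    int id = (int)node_members.size() + 1;
    node_members.push_back({});
    std::vector<int> stack{v};
    node_of[v] = id;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      node_members[id - 1].push_back(u);
      neighbors(u, nbbuf);
      for (int w : nbbuf)
        if (deg[w] >= 3 && !node_of[w]) { node_of[w] = id; stack.push_back(w); }
    }
  }
  // endpoints and isolated voxels
  for (int v : vox) {
    if (deg[v] <= 1 && !node_of[v]) {
      node_of[v] = (int)node_members.size() + 1;
      node_members.push_back({v});
    }
  }
  std::vector<char> used(n, 0);     // chain voxels consumed by a link
  std::vector<int> link_a, link_b;
  std::vector<std::vector<int>> link_path;  // chain voxels, node ends excluded
  // direct node-node adjacencies (no chain voxels between)
  std::unordered_map<uint64_t, char> direct_seen;
  for (int v : vox) {
    if (!node_of[v]) continue;
    neighbors(v, nbbuf);
    std::vector<int> nb_local = nbbuf;
    for (int u : nb_local) {
      if (node_of[u] && node_of[u] != node_of[v]) {
        int a = std::min(node_of[v], node_of[u]);
        int b = std::max(node_of[v], node_of[u]);
        uint64_t key = ((uint64_t)a << 32) | (uint64_t)b;
        if (!direct_seen.count(key)) {
          direct_seen[key] = 1;
          link_a.push_back(a); link_b.push_back(b);
          link_path.push_back({v, u});
        }
      }
    }
  }
  // chains from node voxels
  std::vector<int> nb2;
  for (int v : vox) {
    if (!node_of[v]) continue;
    neighbors(v, nbbuf);
    std::vector<int> starts = nbbuf;
    for (int u : starts) {
      if (node_of[u] || used[u]) continue;
      // trace chain starting at u, came from node voxel v
      std::vector<int> path;
      int prev = v, curv = u;
      int end_node = 0;
      while (true) {
        path.push_back(curv);
        used[curv] = 1;
        neighbors(curv, nb2);
        int nxt = -1;
        // prefer an unvisited chain voxel, else a node voxel != prev
        for (int w : nb2) {
          if (w == prev) continue;
          if (!node_of[w] && !used[w]) { nxt = w; break; }
        }
        if (nxt < 0) {
          for (int w : nb2) {
            if (w == prev) continue;
            if (node_of[w]) { nxt = w; break; }
          }
          if (nxt >= 0) { end_node = node_of[nxt]; }
          break;
        }
        prev = curv; curv = nxt;
      }
      if (end_node == 0) {
        // dangling chain (shouldn't happen for clean skeletons): make the
        // last voxel a terminal node
        int last = path.back();
        node_of[last] = (int)node_members.size() + 1;
        node_members.push_back({last});
        end_node = node_of[last];
        path.pop_back();
      }
      link_a.push_back(node_of[v]);
      link_b.push_back(end_node);
      link_path.push_back(path);
    }
  }
  // pure cycles: remaining unused deg-2 voxels
  for (int v : vox) {
    if (node_of[v] || used[v] || deg[v] != 2) continue;
    int id = (int)node_members.size() + 1;
    node_members.push_back({v});
    node_of[v] = id;
    neighbors(v, nbbuf);
    int u = nbbuf[0];
    std::vector<int> path;
    int prev = v, curv = u;
    while (curv != v && !node_of[curv]) {
      path.push_back(curv);
      used[curv] = 1;
      neighbors(curv, nb2);
      int nxt = -1;
      for (int w : nb2) if (w != prev) { nxt = w; break; }
      if (nxt < 0) break;
      prev = curv; curv = nxt;
    }
    link_a.push_back(id); link_b.push_back(id);
    link_path.push_back(path);
  }
  List nodes(node_members.size()), paths(link_path.size());
  for (size_t t = 0; t < node_members.size(); ++t) {
    IntegerVector m(node_members[t].size());
    for (size_t q = 0; q < node_members[t].size(); ++q)
      m[q] = node_members[t][q] + 1;
    nodes[t] = m;
  }
  for (size_t t = 0; t < link_path.size(); ++t) {
    IntegerVector m(link_path[t].size());
    for (size_t q = 0; q < link_path[t].size(); ++q) m[q] = link_path[t][q] + 1;
    paths[t] = m;
  }
  return List::create(_["node_voxels"] = nodes,
                      _["link_a"] = wrap(link_a),
                      _["link_b"] = wrap(link_b),
                      _["link_paths"] = paths);
}

// ---------------------------------------------------------------------------
// Implicit capsule union: for each voxel center, the minimum over all
// segments of (distance to segment axis - local radius). Radii interpolate
// linearly along each segment, so a constant-radius polyline is an exact
// capsule chain (spheres at segment ends come for free). Also returns the
// 1-based id of the winning segment's link.
// segs columns: x1,y1,z1,x2,y2,z2,r1,r2,link_id (physical units).
// [[Rcpp::export(name = ".capsule_field")]]
List capsule_field(IntegerVector dims, NumericVector spacing,
                   NumericMatrix segs, double pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  NumericVector g(n, 1e30);
  IntegerVector id(n, 0);
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  for (int s = 0; s < segs.nrow(); ++s) {
    double ax = segs(s, 0), ay = segs(s, 1), az = segs(s, 2);
    double bx = segs(s, 3), by = segs(s, 4), bz = segs(s, 5);
    double r1 = segs(s, 6), r2 = segs(s, 7);
    int lid = (int)segs(s, 8);
    double rmax = std::max(r1, r2);
    double lox = std::min(ax, bx) - rmax - pad, hix = std::max(ax, bx) + rmax + pad;
    double loy = std::min(ay, by) - rmax - pad, hiy = std::max(ay, by) + rmax + pad;
    double loz = std::min(az, bz) - rmax - pad, hiz = std::max(az, bz) + rmax + pad;
    int i0 = std::max(0, (int)std::floor(lox / hx - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil(hix / hx - 0.5));
    int j0 = std::max(0, (int)std::floor(loy / hy - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil(hiy / hy - 0.5));
    int k0 = std::max(0, (int)std::floor(loz / hz - 0.5));
    int k1 = std::min(nz - 1, (int)std::ceil(hiz / hz - 0.5));
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double L2 = ux * ux + uy * uy + uz * uz;
    for (int k = k0; k <= k1; ++k) {
      double pz = (k + 0.5) * hz;
      for (int j = j0; j <= j1; ++j) {
        double py = (j + 0.5) * hy;
        for (int i = i0; i <= i1; ++i) {
          double px = (i + 0.5) * hx;
          double t = 0.0;
          if (L2 > 0)
            t = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / L2;
          if (t < 0) t = 0; else if (t > 1) t = 1;
          double cx = ax + t * ux - px, cy = ay + t * uy - py,
                 cz = az + t * uz - pz;
          double d = std::sqrt(cx * cx + cy * cy + cz * cz) - (r1 + t * (r2 - r1));
          int v = idx3(i, j, k, nx, ny);
          if (d < g[v]) { g[v] = d; id[v] = lid; }
        }
      }
    }
  }
  return List::create(_["g"] = g, _["link_id"] = id);
}

// ---------------------------------------------------------------------------
// Marching tetrahedra iso-surface at `iso` on a scalar volume sampled at
// voxel centers. Kuhn 6-tetrahedra cube split (translation-invariant, hence
// watertight across cube faces). Vertices welded on shared sample-grid edges.
// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector vol, IntegerVector dims, double iso,
                NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // Kuhn split: vertex bits (x=1, y=2, z=4)
  const int tets[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                          {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> V;
  std::vector<int> F;
  auto corner_id = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * k);
  };
  auto corner_pos = [&](int i, int j, int k, double* p) {
    p[0] = origin[0] + (i + 0.5) * spacing[0];
    p[1] = origin[1] + (j + 0.5) * spacing[1];
    p[2] = origin[2] + (k + 0.5) * spacing[2];
  };
  auto edge_vtx = [&](uint64_t ga, uint64_t gb, const double* pa,
                      const double* pb, double va, double vb) -> int {
    uint64_t lo = std::min(ga, gb), hi = std::max(ga, gb);
    // exact composite key (grid ids fit well below 2^32 here)
    uint64_t k2 = (lo << 32) ^ hi;
    auto it = edge_vertex.find(k2);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - va) / (vb - va);
    if (!std::isfinite(t)) t = 0.5;
    if (t < 0) t = 0; else if (t > 1) t = 1;
    // orient interpolation consistently from lower to higher grid id
    const double* p0 = (ga <= gb) ? pa : pb;
    const double* p1 = (ga <= gb) ? pb : pa;
    double t01 = (ga <= gb) ? t : 1.0 - t;
    int vid = (int)(V.size() / 3);
    V.push_back(p0[0] + t01 * (p1[0] - p0[0]));
    V.push_back(p0[1] + t01 * (p1[1] - p0[1]));
    V.push_back(p0[2] + t01 * (p1[2] - p0[2]));
    edge_vertex[k2] = vid;
    return vid;
  };
  double cpos[8][3];
  double cval[8];
  uint64_t cid[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_hi = false, any_lo = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
          cval[c] = vol[idx3(ii, jj, kk, nx, ny)];
          corner_pos(ii, jj, kk, cpos[c]);
          cid[c] = corner_id(ii, jj, kk);
          if (cval[c] > iso) any_hi = true; else any_lo = true;
        }
        if (!any_hi || !any_lo) continue;
        for (int t = 0; t < 6; ++t) {
          const int* tv = tets[t];
          int above[4], na = 0, nb = 0, below[4];
          for (int c = 0; c < 4; ++c) {
            if (cval[tv[c]] > iso) above[na++] = tv[c];
            else below[nb++] = tv[c];
          }
          if (na == 0 || na == 4) continue;
          if (na == 1 || na == 3) {
            int apex = (na == 1) ? above[0] : below[0];
            int base[3];
            int bi = 0;
            for (int c = 0; c < 4; ++c)
              if (tv[c] != apex) base[bi++] = tv[c];
            int v0 = edge_vtx(cid[apex], cid[base[0]], cpos[apex], cpos[base[0]],
                              cval[apex], cval[base[0]]);
            int v1 = edge_vtx(cid[apex], cid[base[1]], cpos[apex], cpos[base[1]],
                              cval[apex], cval[base[1]]);
            int v2 = edge_vtx(cid[apex], cid[base[2]], cpos[apex], cpos[base[2]],
                              cval[apex], cval[base[2]]);
            if (v0 != v1 && v1 != v2 && v0 != v2) {
              F.push_back(v0); F.push_back(v1); F.push_back(v2);
            }
          } else {
            // 2/2 split: quad between the four crossing edges
            int a0 = above[0], a1 = above[1], b0 = below[0], b1 = below[1];
            int q0 = edge_vtx(cid[a0], cid[b0], cpos[a0], cpos[b0], cval[a0], cval[b0]);
            int q1 = edge_vtx(cid[a0], cid[b1], cpos[a0], cpos[b1], cval[a0], cval[b1]);
            int q2 = edge_vtx(cid[a1], cid[b1], cpos[a1], cpos[b1], cval[a1], cval[b1]);
            int q3 = edge_vtx(cid[a1], cid[b0], cpos[a1], cpos[b0], cval[a1], cval[b0]);
            if (q0 != q1 && q1 != q2 && q0 != q2) {
              F.push_back(q0); F.push_back(q1); F.push_back(q2);
            }
            if (q0 != q2 && q2 != q3 && q0 != q3) {
              F.push_back(q0); F.push_back(q2); F.push_back(q3);
            }
          }
        }
      }
  int nv = (int)(V.size() / 3), nf = (int)(F.size() / 3);
  NumericMatrix Vm(nv, 3);
  IntegerMatrix Fm(nf, 3);
  for (int t = 0; t < nv; ++t) {
    Vm(t, 0) = V[3 * t]; Vm(t, 1) = V[3 * t + 1]; Vm(t, 2) = V[3 * t + 2];
  }
  for (int t = 0; t < nf; ++t) {
    Fm(t, 0) = F[3 * t] + 1; Fm(t, 1) = F[3 * t + 1] + 1; Fm(t, 2) = F[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}

// ---------------------------------------------------------------------------
// Exact point-to-triangle distance (Ericson, Real-Time Collision Detection).
static double pt_tri_d2(const double* p, const double* a, const double* b,
                        const double* c) {
  double ab[3], ac[3], ap[3], bp[3], cp[3];
  for (int t = 0; t < 3; ++t) {
    ab[t] = b[t] - a[t]; ac[t] = c[t] - a[t]; ap[t] = p[t] - a[t];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  auto d2pt = [&](const double* q) {
    double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
    return dx * dx + dy * dy + dz * dz;
  };
  if (d1 <= 0 && d2 <= 0) return d2pt(a);
  for (int t = 0; t < 3; ++t) bp[t] = p[t] - b[t];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) return d2pt(b);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    double q[3] = {a[0] + t * ab[0], a[1] + t * ab[1], a[2] + t * ab[2]};
    return d2pt(q);
  }
  for (int t = 0; t < 3; ++t) cp[t] = p[t] - c[t];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) return d2pt(c);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    double q[3] = {a[0] + t * ac[0], a[1] + t * ac[1], a[2] + t * ac[2]};
    return d2pt(q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3] = {b[0] + t * (c[0] - b[0]), b[1] + t * (c[1] - b[1]),
                   b[2] + t * (c[2] - b[2])};
    return d2pt(q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double q[3] = {a[0] + ab[0] * v + ac[0] * w, a[1] + ab[1] * v + ac[1] * w,
                 a[2] + ab[2] * v + ac[2] * w};
  return d2pt(q);
}

// Unsigned distance from each point to the nearest point on the mesh,
// accelerated with a uniform grid over triangle bounding boxes.
// [[Rcpp::export(name = ".point_mesh_dist")]]
NumericVector point_mesh_dist(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  if (nf == 0) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  double lo[3], hi[3];
  for (int t = 0; t < 3; ++t) { lo[t] = R_PosInf; hi[t] = R_NegInf; }
  for (int v = 0; v < V.nrow(); ++v)
    for (int t = 0; t < 3; ++t) {
      lo[t] = std::min(lo[t], V(v, t));
      hi[t] = std::max(hi[t], V(v, t));
    }
  double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  // target ~ nf cells
  double cell = ext / std::max(1.0, std::cbrt((double)nf));
  int gd[3];
  for (int t = 0; t < 3; ++t) {
    gd[t] = std::max(1, std::min(128, (int)std::ceil((hi[t] - lo[t]) / cell)));
  }
  double cs[3];
  for (int t = 0; t < 3; ++t)
    cs[t] = std::max((hi[t] - lo[t]) / gd[t], 1e-12);
  auto cell_of = [&](double x, int t) {
    int c = (int)std::floor((x - lo[t]) / cs[t]);
    if (c < 0) c = 0; if (c >= gd[t]) c = gd[t] - 1;
    return c;
  };
  std::vector<std::vector<int>> bins((size_t)gd[0] * gd[1] * gd[2]);
  for (int f = 0; f < nf; ++f) {
    double blo[3], bhi[3];
    for (int t = 0; t < 3; ++t) {
      blo[t] = std::min({V(F(f, 0) - 1, t), V(F(f, 1) - 1, t), V(F(f, 2) - 1, t)});
      bhi[t] = std::max({V(F(f, 0) - 1, t), V(F(f, 1) - 1, t), V(F(f, 2) - 1, t)});
    }
    int c0[3], c1[3];
    for (int t = 0; t < 3; ++t) { c0[t] = cell_of(blo[t], t); c1[t] = cell_of(bhi[t], t); }
    for (int ck = c0[2]; ck <= c1[2]; ++ck)
      for (int cj = c0[1]; cj <= c1[1]; ++cj)
        for (int ci = c0[0]; ci <= c1[0]; ++ci)
          bins[ci + (size_t)gd[0] * (cj + (size_t)gd[1] * ck)].push_back(f);
  }
  double a[3], b[3], c[3], p[3];
  double csmin = std::min({cs[0], cs[1], cs[2]});
  int rmax = gd[0] + gd[1] + gd[2];
  for (int q = 0; q < np; ++q) {
    for (int t = 0; t < 3; ++t) p[t] = P(q, t);
    int pc[3];
    for (int t = 0; t < 3; ++t) pc[t] = cell_of(p[t], t);
    double best = R_PosInf;
    for (int r = 0; r <= rmax; ++r) {
      // once a hit exists, stop when remaining shells cannot improve
      if (std::isfinite(best) && (r - 1) * csmin > std::sqrt(best)) break;
      bool any_cell = false;
      for (int ck = pc[2] - r; ck <= pc[2] + r; ++ck) {
        if (ck < 0 || ck >= gd[2]) continue;
        for (int cj = pc[1] - r; cj <= pc[1] + r; ++cj) {
          if (cj < 0 || cj >= gd[1]) continue;
          for (int ci = pc[0] - r; ci <= pc[0] + r; ++ci) {
            if (ci < 0 || ci >= gd[0]) continue;
            int rr = std::max({std::abs(ci - pc[0]), std::abs(cj - pc[1]),
                               std::abs(ck - pc[2])});
            if (rr != r) continue;  // shell only
            any_cell = true;
            const std::vector<int>& bin =
                bins[ci + (size_t)gd[0] * (cj + (size_t)gd[1] * ck)];
            for (int f : bin) {
              for (int t = 0; t < 3; ++t) {
                a[t] = V(F(f, 0) - 1, t);
                b[t] = V(F(f, 1) - 1, t);
                c[t] = V(F(f, 2) - 1, t);
              }
              double d2 = pt_tri_d2(p, a, b, c);
              if (d2 < best) best = d2;
            }
          }
        }
      }
      if (!any_cell && r > rmax) break;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Nearest-neighbor indices: for each row of A, the 1-based index of the
// closest row of B (uniform-grid accelerated; exact).
// [[Rcpp::export(name = ".nn_index")]]
IntegerVector nn_index(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  IntegerVector out(na);
  double lo[3], hi[3];
  for (int t = 0; t < 3; ++t) { lo[t] = R_PosInf; hi[t] = R_NegInf; }
  for (int v = 0; v < nb; ++v)
    for (int t = 0; t < 3; ++t) {
      lo[t] = std::min(lo[t], B(v, t));
      hi[t] = std::max(hi[t], B(v, t));
    }
  double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  double cell = ext / std::max(1.0, std::cbrt((double)nb));
  int gd[3];
  double cs[3];
  for (int t = 0; t < 3; ++t) {
    gd[t] = std::max(1, std::min(128, (int)std::ceil((hi[t] - lo[t]) / cell)));
    cs[t] = std::max((hi[t] - lo[t]) / gd[t], 1e-12);
  }
  auto cell_of = [&](double x, int t) {
    int c = (int)std::floor((x - lo[t]) / cs[t]);
    if (c < 0) c = 0; if (c >= gd[t]) c = gd[t] - 1;
    return c;
  };
  std::vector<std::vector<int>> bins((size_t)gd[0] * gd[1] * gd[2]);
  for (int v = 0; v < nb; ++v)
    bins[cell_of(B(v, 0), 0) +
         (size_t)gd[0] * (cell_of(B(v, 1), 1) +
                          (size_t)gd[1] * cell_of(B(v, 2), 2))].push_back(v);
  double csmin = std::min({cs[0], cs[1], cs[2]});
  int rmax = gd[0] + gd[1] + gd[2];
  for (int q = 0; q < na; ++q) {
    double p[3] = {A(q, 0), A(q, 1), A(q, 2)};
    int pc[3];
    for (int t = 0; t < 3; ++t) pc[t] = cell_of(p[t], t);
    double best = R_PosInf;
    int besti = -1;
    for (int r = 0; r <= rmax; ++r) {
      if (besti >= 0 && (r - 1) * csmin > std::sqrt(best)) break;
      for (int ck = pc[2] - r; ck <= pc[2] + r; ++ck) {
        if (ck < 0 || ck >= gd[2]) continue;
        for (int cj = pc[1] - r; cj <= pc[1] + r; ++cj) {
          if (cj < 0 || cj >= gd[1]) continue;
          for (int ci = pc[0] - r; ci <= pc[0] + r; ++ci) {
            if (ci < 0 || ci >= gd[0]) continue;
            int rr = std::max({std::abs(ci - pc[0]), std::abs(cj - pc[1]),
                               std::abs(ck - pc[2])});
            if (rr != r) continue;
            const std::vector<int>& bin =
                bins[ci + (size_t)gd[0] * (cj + (size_t)gd[1] * ck)];
            for (int v : bin) {
              double dx = p[0] - B(v, 0), dy = p[1] - B(v, 1), dz = p[2] - B(v, 2);
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best) { best = d2; besti = v; }
            }
          }
        }
      }
    }
    out[q] = besti + 1;
  }
  return out;
}
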