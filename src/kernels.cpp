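// Voxel / surface kernels used by the mesh repair pipeline.
// All grids are axis-aligned in their own frame; callers handle any
// OBB rotation in R. Coordinates are voxel-center based: node (i,j,k)
// (0-based) sits at origin + h * (i,j,k).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int lin3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// ---------------------------------------------------------------------------
// Ray-parity voxelization with 3-axis majority voting.
// V: n x 3 vertices (grid frame), F: m x 3 0-based faces.
// A voxel is inside along one axis if a ray through its (jittered) center
// crosses the surface an odd number of times below it; majority of the three
// axes decides, so a small hole only corrupts one vote.
// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           IntegerVector dims, NumericVector origin,
                           double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<unsigned char> votes(nvox, 0);
  const int nf = F.nrow();

  // axis = ray direction; (u, w) = the two transverse axes
  for (int axis = 0; axis < 3; ++axis) {
    const int u = (axis + 1) % 3, w = (axis + 2) % 3;
    const int nu = dims[u], nw = dims[w], na = dims[axis];
    const double ju = h * 1.2345e-4, jw = h * 2.6789e-4; // edge-hit jitter
    // crossing parameter lists per transverse column
    std::vector< std::vector<double> > cross_t((size_t)nu * nw);
    for (int f = 0; f < nf; ++f) {
      const int a = F(f, 0), b = F(f, 1), c = F(f, 2);
      double p0u = V(a, u), p0w = V(a, w), p0a = V(a, axis);
      double p1u = V(b, u), p1w = V(b, w), p1a = V(b, axis);
      double p2u = V(c, u), p2w = V(c, w), p2a = V(c, axis);
      double den = (p1u - p0u) * (p2w - p0w) - (p2u - p0u) * (p1w - p0w);
      if (std::fabs(den) < 1e-14) continue; // parallel to ray
      double minu = std::min(p0u, std::min(p1u, p2u));
      double maxu = std::max(p0u, std::max(p1u, p2u));
      double minw = std::min(p0w, std::min(p1w, p2w));
      double maxw = std::max(p0w, std::max(p1w, p2w));
      int iu0 = std::max(0, (int)std::ceil((minu - origin[u] - ju) / h));
      int iu1 = std::min(nu - 1, (int)std::floor((maxu - origin[u] - ju) / h));
      int iw0 = std::max(0, (int)std::ceil((minw - origin[w] - jw) / h));
      int iw1 = std::min(nw - 1, (int)std::floor((maxw - origin[w] - jw) / h));
      for (int iu = iu0; iu <= iu1; ++iu) {
        double su = origin[u] + h * iu + ju;
        for (int iw = iw0; iw <= iw1; ++iw) {
          double sw = origin[w] + h * iw + jw;
          // barycentric in the (u, w) projection
          double l1 = ((su - p0u) * (p2w - p0w) - (p2u - p0u) * (sw - p0w)) / den;
          double l2 = ((p1u - p0u) * (sw - p0w) - (su - p0u) * (p1w - p0w)) / den;
          if (l1 < 0.0 || l2 < 0.0 || l1 + l2 > 1.0) continue;
          double ta = p0a + l1 * (p1a - p0a) + l2 * (p2a - p0a);
          cross_t[(size_t)iu + (size_t)nu * iw].push_back(ta);
        }
      }
    }
    // parity fill along the ray axis
    for (int iu = 0; iu < nu; ++iu) {
      for (int iw = 0; iw < nw; ++iw) {
        std::vector<double>& ts = cross_t[(size_t)iu + (size_t)nu * iw];
        if (ts.empty()) continue;
        std::sort(ts.begin(), ts.end());
        size_t ci = 0;
        for (int ia = 0; ia < na; ++ia) {
          double ca = origin[axis] + h * ia;
          while (ci < ts.size() && ts[ci] < ca) ++ci;
          if (ci & 1) {
            int idx[3];
            idx[axis] = ia; idx[u] = iu; idx[w] = iw;
            votes[lin3(idx[0], idx[1], idx[2], nx, ny)]++;
          }
        }
        ci = 0; // reset for next column (ci is per-column)
      }
    }
  }

  LogicalVector occ(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) occ[i] = votes[i] >= 2;
  occ.attr("dim") = dims;
  return occ;
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1D passes. Distances in voxel units to the nearest TRUE voxel.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    if (!R_FINITE(f[q]) && f[q] > 0) {
      // +Inf sites never become minima unless everything is Inf; handle via
      // the standard formula below (works with Inf thanks to guard)
    }
    double s;
    while (true) {
      double fq = f[q], fv = f[v[k]];
      s = ((fq + (double)q * q) - (fv + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(nvox);
  const double INF = 1e30;
  for (R_xlen_t i = 0; i < nvox; ++i) g[i] = occ[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = g[lin3(i, j, k, nx, ny)];
      dt1d(f, d, nx);
      for (int i = 0; i < nx; ++i) g[lin3(i, j, k, nx, ny)] = d[i];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[lin3(i, j, k, nx, ny)];
      dt1d(f, d, ny);
      for (int j = 0; j < ny; ++j) g[lin3(i, j, k, nx, ny)] = d[j];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[lin3(i, j, k, nx, ny)];
      dt1d(f, d, nz);
      for (int k = 0; k < nz; ++k) g[lin3(i, j, k, nx, ny)] = d[k];
    }

  NumericVector out(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) out[i] = g[i];
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian filter of a 3D field (sigma in voxel units).
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector field, IntegerVector dims,
                         double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out = clone(field);
  if (sigma <= 0) { out.attr("dim") = dims; return out; }
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + r];
  }
  for (auto& k : ker) k /= s;

  std::vector<double> a(nvox), b(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) a[i] = out[i];
  const int strides[3] = {1, nx, nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    const int n = dims[axis], stride = strides[axis];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int idx3[3] = {i, j, k};
          if (idx3[axis] != 0) continue; // start of each line only
          int base = lin3(i, j, k, nx, ny);
          for (int p = 0; p < n; ++p) {
            double acc = 0;
            for (int q = -r; q <= r; ++q) {
              int pp = p + q;
              if (pp < 0) pp = 0;
              if (pp >= n) pp = n - 1;
              acc += ker[q + r] * a[base + (R_xlen_t)pp * stride];
            }
            b[base + (R_xlen_t)p * stride] = acc;
          }
        }
    std::swap(a, b);
  }
  for (R_xlen_t i = 0; i < nvox; ++i) out[i] = a[i];
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Isosurface extraction by tetrahedral decomposition of the voxel lattice
// (6 tetrahedra per cell sharing the main diagonal, so shared cell faces are
// triangulated identically and the surface is watertight). Field values sit
// on lattice nodes; triangles are oriented with normals pointing from
// field > iso toward field <= iso (outward for solid > iso).
struct MTState {
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  std::unordered_map<uint64_t, int> edge_vertex;
};

static int edge_point(MTState& st, const NumericVector& field,
                      const NumericVector& origin, double h,
                      int na, int nb, int nxa, int nya,
                      double va, double vb, double iso) {
  uint64_t key = na < nb
    ? ((uint64_t)na << 32) | (uint64_t)nb
    : ((uint64_t)nb << 32) | (uint64_t)na;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double t = (iso - va) / (vb - va);
  if (t < 0) t = 0; if (t > 1) t = 1;
  int ia = na % nxa, ja = (na / nxa) % nya, ka = na / (nxa * nya);
  int ib = nb % nxa, jb = (nb / nxa) % nya, kb = nb / (nxa * nya);
  double x = origin[0] + h * (ia + t * (ib - ia));
  double y = origin[1] + h * (ja + t * (jb - ja));
  double z = origin[2] + h * (ka + t * (kb - ka));
  int id = (int)st.vx.size();
  st.vx.push_back(x); st.vy.push_back(y); st.vz.push_back(z);
  st.edge_vertex[key] = id;
  return id;
}

static void emit_tri(MTState& st, int p, int q, int r,
                     double rx, double ry, double rz) {
  // orient so the normal has positive dot with the inside->outside reference
  double ux = st.vx[q] - st.vx[p], uy = st.vy[q] - st.vy[p],
         uz = st.vz[q] - st.vz[p];
  double wx = st.vx[r] - st.vx[p], wy = st.vy[r] - st.vy[p],
         wz = st.vz[r] - st.vz[p];
  double nxn = uy * wz - uz * wy, nyn = uz * wx - ux * wz,
         nzn = ux * wy - uy * wx;
  double a2 = nxn * nxn + nyn * nyn + nzn * nzn;
  if (a2 < 1e-30) return; // degenerate sliver
  if (nxn * rx + nyn * ry + nzn * rz < 0) std::swap(q, r);
  st.tri.push_back(p); st.tri.push_back(q); st.tri.push_back(r);
}

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dims,
                    NumericVector origin, double h, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  MTState st;
  // cube corner offsets, standard labeling (0..7)
  const int cdx[8] = {0, 1, 1, 0, 0, 1, 1, 0};
  const int cdy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int cdz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  // six tetrahedra sharing the 0-6 diagonal
  const int tets[6][4] = {
    {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
    {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        int node[8];
        double val[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          node[c] = lin3(i + cdx[c], j + cdy[c], k + cdz[c], nx, ny);
          val[c] = field[node[c]];
          if (val[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int tv[4];
          double fv[4];
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            tv[c] = node[tets[t][c]];
            fv[c] = val[tets[t][c]];
            in[c] = fv[c] > iso;
            if (in[c]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          // inside->outside reference direction from node centroids
          double cix = 0, ciy = 0, ciz = 0, cox = 0, coy = 0, coz = 0;
          for (int c = 0; c < 4; ++c) {
            int ii = tv[c] % nx, jj = (tv[c] / nx) % ny, kk = tv[c] / (nx * ny);
            double px = origin[0] + h * ii, py = origin[1] + h * jj,
                   pz = origin[2] + h * kk;
            if (in[c]) { cix += px; ciy += py; ciz += pz; }
            else { cox += px; coy += py; coz += pz; }
          }
          int nout = 4 - nin;
          double rx = cox / nout - cix / nin, ry = coy / nout - ciy / nin,
                 rz = coz / nout - ciz / nin;
          int A = -1, B = -1, C = -1, D = -1;
          if (nin == 1 || nin == 3) {
            bool lone_in = (nin == 1);
            int lone = -1, oth[3], no = 0;
            for (int c = 0; c < 4; ++c) {
              if (in[c] == lone_in) lone = c; else oth[no++] = c;
            }
            int p = edge_point(st, field, origin, h, tv[lone], tv[oth[0]],
                               nx, ny, fv[lone], fv[oth[0]], iso);
            int q = edge_point(st, field, origin, h, tv[lone], tv[oth[1]],
                               nx, ny, fv[lone], fv[oth[1]], iso);
            int r = edge_point(st, field, origin, h, tv[lone], tv[oth[2]],
                               nx, ny, fv[lone], fv[oth[2]], iso);
            emit_tri(st, p, q, r, rx, ry, rz);
          } else {
            int ins[2], outs[2], ni = 0, no2 = 0;
            for (int c = 0; c < 4; ++c) {
              if (in[c]) ins[ni++] = c; else outs[no2++] = c;
            }
            A = ins[0]; B = ins[1]; C = outs[0]; D = outs[1];
            int pac = edge_point(st, field, origin, h, tv[A], tv[C], nx, ny,
                                 fv[A], fv[C], iso);
            int pad = edge_point(st, field, origin, h, tv[A], tv[D], nx, ny,
                                 fv[A], fv[D], iso);
            int pbc = edge_point(st, field, origin, h, tv[B], tv[C], nx, ny,
                                 fv[B], fv[C], iso);
            int pbd = edge_point(st, field, origin, h, tv[B], tv[D], nx, ny,
                                 fv[B], fv[D], iso);
            emit_tri(st, pac, pad, pbd, rx, ry, rz);
            emit_tri(st, pac, pbd, pbc, rx, ry, rz);
          }
        }
      }

  int nv = (int)st.vx.size();
  int nf = (int)st.tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i];
  }
  IntegerMatrix Fm(nf, 3);
  for (int f = 0; f < nf; ++f) {
    Fm(f, 0) = st.tri[3 * f] + 1;     // 1-based for R
    Fm(f, 1) = st.tri[3 * f + 1] + 1;
    Fm(f, 2) = st.tri[3 * f + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// ---------------------------------------------------------------------------
// Minimum distance from each query point to a triangle mesh surface
// (true point-to-triangle, Ericson's closest-point construction).
static double pt_tri_d2(double px, double py, double pz,
                        const double* a, const double* b, const double* c) {
  double abx = b[0] - a[0], aby = b[1] - a[1], abz = b[2] - a[2];
  double acx = c[0] - a[0], acy = c[1] - a[1], acz = c[2] - a[2];
  double apx = px - a[0], apy = py - a[1], apz = pz - a[2];
  double d1 = abx * apx + aby * apy + abz * apz;
  double d2 = acx * apx + acy * apy + acz * apz;
  double qx, qy, qz;
  if (d1 <= 0 && d2 <= 0) { qx = a[0]; qy = a[1]; qz = a[2]; }
  else {
    double bpx = px - b[0], bpy = py - b[1], bpz = pz - b[2];
    double d3 = abx * bpx + aby * bpy + abz * bpz;
    double d4 = acx * bpx + acy * bpy + acz * bpz;
    if (d3 >= 0 && d4 <= d3) { qx = b[0]; qy = b[1]; qz = b[2]; }
    else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = d1 / (d1 - d3);
        qx = a[0] + v * abx; qy = a[1] + v * aby; qz = a[2] + v * abz;
      } else {
        double cpx = px - c[0], cpy = py - c[1], cpz = pz - c[2];
        double d5 = abx * cpx + aby * cpy + abz * cpz;
        double d6 = acx * cpx + acy * cpy + acz * cpz;
        if (d6 >= 0 && d5 <= d6) { qx = c[0]; qy = c[1]; qz = c[2]; }
        else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double w = d2 / (d2 - d6);
            qx = a[0] + w * acx; qy = a[1] + w * acy; qz = a[2] + w * acz;
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              qx = b[0] + w * (c[0] - b[0]);
              qy = b[1] + w * (c[1] - b[1]);
              qz = b[2] + w * (c[2] - b[2]);
            } else {
              double den = 1.0 / (va + vb + vc);
              double v = vb * den, w = vc * den;
              qx = a[0] + abx * v + acx * w;
              qy = a[1] + aby * v + acy * w;
              qz = a[2] + abz * v + acz * w;
            }
          }
        }
      }
    }
  }
  double dx = px - qx, dy = py - qy, dz = pz - qz;
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix P, NumericMatrix V,
                                  IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  // triangle data + centroids/radii for pruning
  std::vector<double> tri(9 * nf), cx(nf), cy(nf), cz(nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    for (int c = 0; c < 3; ++c) {
      int v = F(f, c) - 1;
      tri[9 * f + 3 * c] = V(v, 0);
      tri[9 * f + 3 * c + 1] = V(v, 1);
      tri[9 * f + 3 * c + 2] = V(v, 2);
    }
    cx[f] = (tri[9 * f] + tri[9 * f + 3] + tri[9 * f + 6]) / 3.0;
    cy[f] = (tri[9 * f + 1] + tri[9 * f + 4] + tri[9 * f + 7]) / 3.0;
    cz[f] = (tri[9 * f + 2] + tri[9 * f + 5] + tri[9 * f + 8]) / 3.0;
    double r2 = 0;
    for (int c = 0; c < 3; ++c) {
      double dx = tri[9 * f + 3 * c] - cx[f];
      double dy = tri[9 * f + 3 * c + 1] - cy[f];
      double dz = tri[9 * f + 3 * c + 2] - cz[f];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }
  for (int p = 0; p < np; ++p) {
    double px = P(p, 0), py = P(p, 1), pz = P(p, 2);
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double dx = px - cx[f], dy = py - cy[f], dz = pz - cz[f];
      double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - rad[f];
      if (dc > 0 && dc * dc >= best) continue;
      double d2 = pt_tri_d2(px, py, pz, &tri[9 * f], &tri[9 * f + 3],
                            &tri[9 * f + 6]);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
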