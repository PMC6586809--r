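#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Implicit lumen field of a vessel tree: union of tapered capsules (one per
// centerline piece) clipped flat at declared cap planes (root inlet, distal
// outlets).  Negative values are inside the lumen.  The field is sampled on a
// regular grid; per-sample nearest-piece bookkeeping supports wall normals,
// arclength lookup and face labelling downstream.

static inline double seg_point_dist(const double *p, const double *a,
                                    const double *b, double &tout,
                                    double *q) {
  double v0 = b[0] - a[0], v1 = b[1] - a[1], v2 = b[2] - a[2];
  double w0 = p[0] - a[0], w1 = p[1] - a[1], w2 = p[2] - a[2];
  double vv = v0 * v0 + v1 * v1 + v2 * v2;
  double t = vv > 0 ? (w0 * v0 + w1 * v1 + w2 * v2) / vv : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  q[0] = a[0] + t * v0; q[1] = a[1] + t * v1; q[2] = a[2] + t * v2;
  double d0 = p[0] - q[0], d1 = p[1] - q[1], d2 = p[2] - q[2];
  tout = t;
  return std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
}

// [[Rcpp::export]]
List cpp_voxel_field(IntegerVector dims, NumericVector origin, double h,
                     NumericMatrix A, NumericMatrix B, NumericVector ra,
                     NumericVector rb, IntegerVector piece_seg,
                     NumericMatrix capC, NumericMatrix capN,
                     NumericVector capR, double cap_ball = 2.0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector f(ntot, 1e30);
  IntegerVector piece(ntot, -1);
  NumericVector tpar(ntot);
  const int np = A.nrow();
  for (int ip = 0; ip < np; ++ip) {
    double a[3] = {A(ip, 0), A(ip, 1), A(ip, 2)};
    double b[3] = {B(ip, 0), B(ip, 1), B(ip, 2)};
    double rmax = std::max(ra[ip], rb[ip]);
    double margin = rmax + 2.5 * h;
    int lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      double mn = std::min(a[d], b[d]) - margin;
      double mx = std::max(a[d], b[d]) + margin;
      lo[d] = std::max(0, (int)std::floor((mn - origin[d]) / h));
      hi[d] = std::min(dims[d] - 1, (int)std::ceil((mx - origin[d]) / h));
    }
    for (int k = lo[2]; k <= hi[2]; ++k)
      for (int j = lo[1]; j <= hi[1]; ++j) {
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        double p[3];
        p[1] = origin[1] + h * j;
        p[2] = origin[2] + h * k;
        for (int i = lo[0]; i <= hi[0]; ++i) {
          p[0] = origin[0] + h * i;
          double t, q[3];
          double d = seg_point_dist(p, a, b, t, q);
          double val = d - (ra[ip] + (rb[ip] - ra[ip]) * t);
          R_xlen_t idx = base + i;
          if (val < f[idx]) {
            f[idx] = val;
            piece[idx] = ip;
            tpar[idx] = t;
          }
        }
      }
  }
  // flat caps: cut the rounded capsule ends with a localized half-space
  const int nc = capC.nrow();
  for (int ic = 0; ic < nc; ++ic) {
    double c[3] = {capC(ic, 0), capC(ic, 1), capC(ic, 2)};
    double n[3] = {capN(ic, 0), capN(ic, 1), capN(ic, 2)};
    double ball = cap_ball * capR[ic] + 2.0 * h;
    int lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::max(0, (int)std::floor((c[d] - ball - origin[d]) / h));
      hi[d] = std::min(dims[d] - 1, (int)std::ceil((c[d] + ball - origin[d]) / h));
    }
    for (int k = lo[2]; k <= hi[2]; ++k)
      for (int j = lo[1]; j <= hi[1]; ++j)
        for (int i = lo[0]; i <= hi[0]; ++i) {
          R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
          double p0 = origin[0] + h * i - c[0];
          double p1 = origin[1] + h * j - c[1];
          double p2 = origin[2] + h * k - c[2];
          double s = p0 * n[0] + p1 * n[1] + p2 * n[2];
          double rr = std::sqrt(p0 * p0 + p1 * p1 + p2 * p2);
          double cut = std::min(s, ball - rr);
          if (cut > f[idx]) f[idx] = cut;
        }
  }
  return List::create(_["f"] = f, _["piece"] = piece, _["t"] = tpar);
}

// Nearest centerline piece for arbitrary query points (full scan; used for
// small point sets: wall samples, face centroids, landmarks).
// [[Rcpp::export]]
List cpp_tree_nearest(NumericMatrix P, NumericMatrix A, NumericMatrix B,
                      NumericVector ra, NumericVector rb) {
  const int n = P.nrow(), np = A.nrow();
  IntegerVector piece(n);
  NumericVector tpar(n), daxis(n), rad(n);
  NumericMatrix Q(n, 3);
  for (int i = 0; i < n; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = 1e30; int bip = -1; double bt = 0, bq[3] = {0, 0, 0}, br = 0;
    for (int ip = 0; ip < np; ++ip) {
      double a[3] = {A(ip, 0), A(ip, 1), A(ip, 2)};
      double b[3] = {B(ip, 0), B(ip, 1), B(ip, 2)};
      double t, q[3];
      double d = seg_point_dist(p, a, b, t, q);
      double r = ra[ip] + (rb[ip] - ra[ip]) * t;
      if (d - r < best) {
        best = d - r; bip = ip; bt = t; br = r;
        bq[0] = q[0]; bq[1] = q[1]; bq[2] = q[2];
        daxis[i] = d;
      }
    }
    piece[i] = bip; tpar[i] = bt; rad[i] = br;
    Q(i, 0) = bq[0]; Q(i, 1) = bq[1]; Q(i, 2) = bq[2];
  }
  return List::create(_["piece"] = piece, _["t"] = tpar, _["d_axis"] = daxis,
                      _["radius"] = rad, _["q"] = Q);
}

// Marching tetrahedra over a node grid of field values.  Each cube is split
// into six tetrahedra sharing the main diagonal; shared cube faces carry the
// same diagonal in adjacent cubes, so the extracted isosurface is watertight
// by construction whenever it closes inside the grid.

struct VKey {
  int64_t k;
  bool operator==(const VKey &o) const { return k == o.k; }
};
struct VKeyHash {
  size_t operator()(const VKey &v) const { return std::hash<int64_t>()(v.k); }
};

// [[Rcpp::export]]
List cpp_march_tets(NumericVector f, IntegerVector dims, NumericVector origin,
                    double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto nid = [&](int i, int j, int k) -> int64_t {
    return (int64_t)k * nx * ny + (int64_t)j * nx + i;
  };
  std::vector<double> V;
  std::vector<int> F;
  std::unordered_map<VKey, int, VKeyHash> vmap;
  const int tets[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                          {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  const int cx[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  const int cy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int cz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  auto fval = [&](int64_t id) {
    double v = f[id];
    if (std::fabs(v) < 1e-9) v = 1e-9;  // nudge off the isosurface
    return v;
  };
  auto edge_vertex = [&](int64_t n1, int64_t n2, double f1, double f2) -> int {
    if (n1 > n2) { std::swap(n1, n2); std::swap(f1, f2); }
    VKey key{n1 * ((int64_t)nx * ny * nz + 1) + n2};
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = f1 / (f1 - f2);
    int i1 = (int)(n1 % nx), j1 = (int)((n1 / nx) % ny), k1 = (int)(n1 / ((int64_t)nx * ny));
    int i2 = (int)(n2 % nx), j2 = (int)((n2 / nx) % ny), k2 = (int)(n2 / ((int64_t)nx * ny));
    double x = origin[0] + h * (i1 + t * (i2 - i1));
    double y = origin[1] + h * (j1 + t * (j2 - j1));
    double z = origin[2] + h * (k1 + t * (k2 - k1));
    int id = (int)(V.size() / 3);
    V.push_back(x); V.push_back(y); V.push_back(z);
    vmap.emplace(key, id);
    return id;
  };
  auto emit = [&](int a, int b, int c, const double *outdir) {
    // orient so the normal points towards the outside (f > 0)
    double ux = V[3 * b] - V[3 * a], uy = V[3 * b + 1] - V[3 * a + 1],
           uz = V[3 * b + 2] - V[3 * a + 2];
    double vx = V[3 * c] - V[3 * a], vy = V[3 * c + 1] - V[3 * a + 1],
           vz = V[3 * c + 2] - V[3 * a + 2];
    double nxv = uy * vz - uz * vy, nyv = uz * vx - ux * vz,
           nzv = ux * vy - uy * vx;
    double d = nxv * outdir[0] + nyv * outdir[1] + nzv * outdir[2];
    if (d >= 0) { F.push_back(a); F.push_back(b); F.push_back(c); }
    else        { F.push_back(a); F.push_back(c); F.push_back(b); }
  };
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        int64_t cid[8];
        double cf[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          cid[c] = nid(i + cx[c], j + cy[c], k + cz[c]);
          cf[c] = fval(cid[c]);
          (cf[c] < 0 ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int tt = 0; tt < 6; ++tt) {
          const int *T = tets[tt];
          int ins[4], nin = 0, outs[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (cf[T[c]] < 0) ins[nin++] = T[c]; else outs[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          // direction from inside centroid to outside centroid
          // (grid index space is fine for orientation)
          double ci[3] = {0, 0, 0}, co[3] = {0, 0, 0};
          auto ncoord = [&](int corner, double *out) {
            out[0] = (double)(i + cx[corner]);
            out[1] = (double)(j + cy[corner]);
            out[2] = (double)(k + cz[corner]);
          };
          for (int c = 0; c < nin; ++c) {
            double pc[3]; ncoord(ins[c], pc);
            ci[0] += pc[0] / nin; ci[1] += pc[1] / nin; ci[2] += pc[2] / nin;
          }
          for (int c = 0; c < nout; ++c) {
            double pc[3]; ncoord(outs[c], pc);
            co[0] += pc[0] / nout; co[1] += pc[1] / nout; co[2] += pc[2] / nout;
          }
          double outdir[3] = {co[0] - ci[0], co[1] - ci[1], co[2] - ci[2]};
          if (nin == 1) {
            int v0 = edge_vertex(cid[ins[0]], cid[outs[0]], cf[ins[0]], cf[outs[0]]);
            int v1 = edge_vertex(cid[ins[0]], cid[outs[1]], cf[ins[0]], cf[outs[1]]);
            int v2 = edge_vertex(cid[ins[0]], cid[outs[2]], cf[ins[0]], cf[outs[2]]);
            emit(v0, v1, v2, outdir);
          } else if (nin == 3) {
            int v0 = edge_vertex(cid[ins[0]], cid[outs[0]], cf[ins[0]], cf[outs[0]]);
            int v1 = edge_vertex(cid[ins[1]], cid[outs[0]], cf[ins[1]], cf[outs[0]]);
            int v2 = edge_vertex(cid[ins[2]], cid[outs[0]], cf[ins[2]], cf[outs[0]]);
            emit(v0, v1, v2, outdir);
          } else {  // nin == 2: quad split into two triangles
            int vac = edge_vertex(cid[ins[0]], cid[outs[0]], cf[ins[0]], cf[outs[0]]);
            int vad = edge_vertex(cid[ins[0]], cid[outs[1]], cf[ins[0]], cf[outs[1]]);
            int vbd = edge_vertex(cid[ins[1]], cid[outs[1]], cf[ins[1]], cf[outs[1]]);
            int vbc = edge_vertex(cid[ins[1]], cid[outs[0]], cf[ins[1]], cf[outs[0]]);
            emit(vac, vad, vbd, outdir);
            emit(vac, vbd, vbc, outdir);
          }
        }
      }
  int nv = (int)(V.size() / 3), nf = (int)(F.size() / 3);
  NumericMatrix Vm(nv, 3);
  IntegerMatrix Fm(nf, 3);
  for (int v = 0; v < nv; ++v)
    for (int d = 0; d < 3; ++d) Vm(v, d) = V[3 * v + d];
  for (int t = 0; t < nf; ++t)
    for (int d = 0; d < 3; ++d) Fm(t, d) = F[3 * t + d] + 1;  // 1-based
  return List::create(_["vertices"] = Vm, _["triangles"] = Fm);
}

// Exact point-to-triangle distance (Ericson, Real-Time Collision Detection)
static double point_tri_dist2(const double *p, const double *a,
                              const double *b, const double *c) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  auto dist2 = [&](double qx, double qy, double qz) {
    double dx = p[0] - qx, dy = p[1] - qy, dz = p[2] - qz;
    return dx * dx + dy * dy + dz * dz;
  };
  if (d1 <= 0 && d2 <= 0) return dist2(a[0], a[1], a[2]);
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) return dist2(b[0], b[1], b[2]);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return dist2(a[0] + v * ab[0], a[1] + v * ab[1], a[2] + v * ab[2]);
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) return dist2(c[0], c[1], c[2]);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return dist2(a[0] + w * ac[0], a[1] + w * ac[1], a[2] + w * ac[2]);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist2(b[0] + w * (c[0] - b[0]), b[1] + w * (c[1] - b[1]),
                 b[2] + w * (c[2] - b[2]));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return dist2(a[0] + ab[0] * v + ac[0] * w, a[1] + ab[1] * v + ac[1] * w,
               a[2] + ab[2] * v + ac[2] * w);
}

// Distances from points to a triangle mesh, accelerated by a uniform grid
// over triangle bounding boxes with expanding ring search.
// [[Rcpp::export]]
NumericVector cpp_points_to_mesh(NumericMatrix P, NumericMatrix V,
                                 IntegerMatrix Fm) {
  const int n = P.nrow(), nt = Fm.nrow();
  NumericVector out(n);
  // mesh bbox
  double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
  for (int v = 0; v < V.nrow(); ++v)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], V(v, d));
      hi[d] = std::max(hi[d], V(v, d));
    }
  double ext[3] = {hi[0] - lo[0] + 1e-9, hi[1] - lo[1] + 1e-9,
                   hi[2] - lo[2] + 1e-9};
  double vol = ext[0] * ext[1] * ext[2];
  double cell = std::cbrt(vol / std::max(1, nt)) * 2.0;
  int gd[3];
  for (int d = 0; d < 3; ++d)
    gd[d] = std::max(1, std::min(96, (int)std::ceil(ext[d] / cell)));
  double cs[3];
  for (int d = 0; d < 3; ++d) cs[d] = ext[d] / gd[d];
  double csmin = std::min(cs[0], std::min(cs[1], cs[2]));
  std::vector<std::vector<int>> cells((size_t)gd[0] * gd[1] * gd[2]);
  auto cidx = [&](int i, int j, int k) {
    return (size_t)k * gd[0] * gd[1] + (size_t)j * gd[0] + i;
  };
  for (int t = 0; t < nt; ++t) {
    double tlo[3] = {1e30, 1e30, 1e30}, thi[3] = {-1e30, -1e30, -1e30};
    for (int c = 0; c < 3; ++c) {
      int v = Fm(t, c) - 1;
      for (int d = 0; d < 3; ++d) {
        tlo[d] = std::min(tlo[d], V(v, d));
        thi[d] = std::max(thi[d], V(v, d));
      }
    }
    int il[3], ih[3];
    for (int d = 0; d < 3; ++d) {
      il[d] = std::max(0, std::min(gd[d] - 1, (int)((tlo[d] - lo[d]) / cs[d])));
      ih[d] = std::max(0, std::min(gd[d] - 1, (int)((thi[d] - lo[d]) / cs[d])));
    }
    for (int k = il[2]; k <= ih[2]; ++k)
      for (int j = il[1]; j <= ih[1]; ++j)
        for (int i = il[0]; i <= ih[0]; ++i) cells[cidx(i, j, k)].push_back(t);
  }
  int maxring = gd[0] + gd[1] + gd[2];
  for (int ip = 0; ip < n; ++ip) {
    double p[3] = {P(ip, 0), P(ip, 1), P(ip, 2)};
    // distance from p to grid bbox
    double dbox = 0;
    int pc[3];
    for (int d = 0; d < 3; ++d) {
      double e = std::max(std::max(lo[d] - p[d], 0.0), p[d] - hi[d]);
      dbox += e * e;
      pc[d] = std::max(0, std::min(gd[d] - 1, (int)((p[d] - lo[d]) / cs[d])));
    }
    dbox = std::sqrt(dbox);
    double best2 = 1e60;
    for (int r = 0; r <= maxring; ++r) {
      double bound = dbox + std::max(0, r - 1) * csmin;
      if (bound * bound > best2) break;
      bool any = false;
      int i0 = std::max(0, pc[0] - r), i1 = std::min(gd[0] - 1, pc[0] + r);
      int j0 = std::max(0, pc[1] - r), j1 = std::min(gd[1] - 1, pc[1] + r);
      int k0 = std::max(0, pc[2] - r), k1 = std::min(gd[2] - 1, pc[2] + r);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            int cheb = std::max(std::abs(i - pc[0]),
                        std::max(std::abs(j - pc[1]), std::abs(k - pc[2])));
            if (cheb != r) continue;
            any = true;
            for (int t : cells[cidx(i, j, k)]) {
              double a[3], b[3], c[3];
              for (int d = 0; d < 3; ++d) {
                a[d] = V(Fm(t, 0) - 1, d);
                b[d] = V(Fm(t, 1) - 1, d);
                c[d] = V(Fm(t, 2) - 1, d);
              }
              double d2 = point_tri_dist2(p, a, b, c);
              if (d2 < best2) best2 = d2;
            }
          }
      if (!any && r > 0 && i0 == 0 && j0 == 0 && k0 == 0 &&
          i1 == gd[0] - 1 && j1 == gd[1] - 1 && k1 == gd[2] - 1)
        break;  // searched the whole grid
    }
    out[ip] = std::sqrt(best2);
  }
  return out;
}

// Wall-adjacent fluid voxels: fluid voxels with at least one solid (or
// outside-grid) face/edge neighbour among the 18 nearest.
// [[Rcpp::export]]
IntegerVector cpp_wall_adjacent(IntegerVector cls, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> out;
  const int off[18][3] = {
      {1, 0, 0},  {-1, 0, 0}, {0, 1, 0},  {0, -1, 0}, {0, 0, 1},  {0, 0, -1},
      {1, 1, 0},  {1, -1, 0}, {-1, 1, 0}, {-1, -1, 0}, {1, 0, 1}, {1, 0, -1},
      {-1, 0, 1}, {-1, 0, -1}, {0, 1, 1}, {0, 1, -1}, {0, -1, 1}, {0, -1, -1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        if (cls[idx] != 1) continue;  // plain fluid only (not inlet/outlet)
        bool wall = false;
        for (int q = 0; q < 18 && !wall; ++q) {
          int ii = i + off[q][0], jj = j + off[q][1], kk = k + off[q][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            wall = true;
          else if (cls[(R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii] == 0)
            wall = true;
        }
        if (wall) out.push_back((int)idx);
      }
  return wrap(out);
}

// 26-connected flood fill from a seed voxel over fluid classes (>0);
// returns component labels (0 = not fluid, 1 = seed component, 2.. others).
// [[Rcpp::export]]
IntegerVector cpp_flood_components(IntegerVector cls, IntegerVector dims,
                                   int seed_idx) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 1;
  auto fill = [&](R_xlen_t start, int label) {
    stack.clear();
    stack.push_back(start);
    lab[start] = label;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t nidx = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
            if (cls[nidx] > 0 && lab[nidx] == 0) {
              lab[nidx] = label;
              stack.push_back(nidx);
            }
          }
    }
  };
  if (seed_idx >= 0 && cls[seed_idx] > 0) fill(seed_idx, next_label++);
  else next_label = 2;  // no valid seed: label everything 2+
  for (R_xlen_t idx = 0; idx < ntot; ++idx)
    if (cls[idx] > 0 && lab[idx] == 0) fill(idx, next_label++);
  return lab;
}
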