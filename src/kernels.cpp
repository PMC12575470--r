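// Ray-marching kernels shared by the multi-pass renderer, the one-pass
// reference renderer, and the depth-only shadow pass.
//
// The per-sample primitives (ray generation, world->local transform,
// trilinear/nearest sampling, transfer-function classification,
// front-to-back compositing step) are single inline functions used by
// every rendering path, so that a sample taken at the same (pixel, t)
// classifies bit-identically regardless of which renderer took it.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct CamK {
  double eye[3], right[3], up[3], fwd[3];
  double tanv, aspect;
  int W, H;
  double nearc, farc;
};

struct ShadowK {
  bool has;
  const double* map;  // H x W distances to the light (column-major)
  CamK cam;
  double bias;
  ShadowK() : has(false), map(nullptr), bias(0.0) {}
};

struct LightK {
  bool has;
  double pos[3];
  double ambient, diffuse;
  ShadowK shadow;
  LightK() : has(false), ambient(0.3), diffuse(0.7) {}
};

struct ParamsK {
  double step;
  double thr;
  bool aligned;
  bool shading;
  LightK light;
};

struct NodeK {
  const double* data;
  int nx, ny, nz;
  double sx, sy, sz;
  double inv[12];    // world -> local-mm affine, rows (3 x 4)
  double nrm[9];     // local-mm gradient -> world normal matrix, rows
  const int* mask;
  bool hasMask;
  const double* tfx;  // control intensities (ntf)
  const double* tfc;  // control colors, column-major ntf x 4 (r,g,b,a)
  int ntf;
  int interp;         // 0 = linear, 1 = left-constant (step)
  double segop[256];
  double refstep;
  double lo[3], hi[3];  // local-mm sampling box
  bool hasSkip;
  int bs, bx, by, bz;
  const int* skip;  // per block: 1 = provably transparent
};

inline double clampd(double v, double a, double b) {
  return v < a ? a : (v > b ? b : v);
}

void camFromList(const List& L, CamK& c) {
  NumericVector eye = L["eye"], right = L["right"], up = L["up"], fwd = L["forward"];
  for (int i = 0; i < 3; i++) {
    c.eye[i] = eye[i]; c.right[i] = right[i]; c.up[i] = up[i]; c.fwd[i] = fwd[i];
  }
  c.tanv = as<double>(L["tanv"]);
  c.aspect = as<double>(L["aspect"]);
  c.W = as<int>(L["width"]);
  c.H = as<int>(L["height"]);
  c.nearc = as<double>(L["near"]);
  c.farc = as<double>(L["far"]);
}

void paramsFromList(const List& L, ParamsK& p) {
  p.step = as<double>(L["step"]);
  p.thr = as<double>(L["alpha_threshold"]);
  p.aligned = as<bool>(L["align_global_grid"]);
  p.shading = as<bool>(L["shading"]);
  p.light.has = false;
  if (L.containsElementNamed("light") && !Rf_isNull(L["light"])) {
    List lt = L["light"];
    p.light.has = true;
    NumericVector pos = lt["position"];
    for (int i = 0; i < 3; i++) p.light.pos[i] = pos[i];
    p.light.ambient = as<double>(lt["ambient"]);
    p.light.diffuse = as<double>(lt["diffuse"]);
    if (lt.containsElementNamed("shadow") && !Rf_isNull(lt["shadow"])) {
      List sh = lt["shadow"];
      p.light.shadow.has = true;
      NumericMatrix m = sh["depth"];
      p.light.shadow.map = REAL(m);
      camFromList(sh["camera"], p.light.shadow.cam);
      p.light.shadow.bias = as<double>(sh["bias"]);
    }
  }
}

void nodeFromList(const List& L, NodeK& n) {
  NumericVector data = L["data"];
  n.data = REAL(data);
  IntegerVector dims = L["dims"];
  n.nx = dims[0]; n.ny = dims[1]; n.nz = dims[2];
  NumericVector sp = L["spacing"];
  n.sx = sp[0]; n.sy = sp[1]; n.sz = sp[2];
  NumericMatrix inv = L["inv"];
  for (int r = 0; r < 3; r++)
    for (int c = 0; c < 4; c++) n.inv[r * 4 + c] = inv(r, c);
  NumericMatrix nrm = L["nrm"];
  for (int r = 0; r < 3; r++)
    for (int c = 0; c < 3; c++) n.nrm[r * 3 + c] = nrm(r, c);
  n.hasMask = !Rf_isNull(L["mask"]);
  n.mask = n.hasMask ? INTEGER(as<IntegerVector>(L["mask"])) : nullptr;
  NumericVector tfx = L["tf_x"];
  n.tfx = REAL(tfx);
  n.ntf = tfx.size();
  NumericMatrix tfc = L["tf_rgba"];
  n.tfc = REAL(tfc);
  n.interp = as<int>(L["tf_interp"]);
  NumericVector so = L["segop"];
  for (int i = 0; i < 256; i++) n.segop[i] = so[i];
  n.refstep = as<double>(L["reference_step"]);
  NumericVector lo = L["box_lo"], hi = L["box_hi"];
  for (int i = 0; i < 3; i++) { n.lo[i] = lo[i]; n.hi[i] = hi[i]; }
  n.hasSkip = !Rf_isNull(L["skip"]);
  n.skip = nullptr;
  if (n.hasSkip) {
    List sk = L["skip"];
    n.bs = as<int>(sk["block_size"]);
    IntegerVector nb = sk["nblocks"];
    n.bx = nb[0]; n.by = nb[1]; n.bz = nb[2];
    n.skip = INTEGER(as<IntegerVector>(sk["skippable"]));
  }
}

// Camera ray through the center of pixel (ix, iy), 0-based, (0,0) top-left.
inline void pixelRay(const CamK& c, int ix, int iy, double d[3]) {
  double xn = (2.0 * (ix + 0.5) / c.W - 1.0) * c.aspect * c.tanv;
  double yn = (1.0 - 2.0 * (iy + 0.5) / c.H) * c.tanv;
  double dx = xn * c.right[0] + yn * c.up[0] + c.fwd[0];
  double dy = xn * c.right[1] + yn * c.up[1] + c.fwd[1];
  double dz = xn * c.right[2] + yn * c.up[2] + c.fwd[2];
  double nr = std::sqrt(dx * dx + dy * dy + dz * dz);
  d[0] = dx / nr; d[1] = dy / nr; d[2] = dz / nr;
}

inline void worldToLocal(const NodeK& n, double px, double py, double pz, double l[3]) {
  l[0] = n.inv[0] * px + n.inv[1] * py + n.inv[2] * pz + n.inv[3];
  l[1] = n.inv[4] * px + n.inv[5] * py + n.inv[6] * pz + n.inv[7];
  l[2] = n.inv[8] * px + n.inv[9] * py + n.inv[10] * pz + n.inv[11];
}

// Trilinear sample at continuous voxel coordinates (centers at integers),
// coordinates clamped into [0, dim-1] (boundary-voxel clamping policy).
inline double triSample(const NodeK& n, double vx, double vy, double vz) {
  vx = clampd(vx, 0.0, n.nx - 1.0);
  vy = clampd(vy, 0.0, n.ny - 1.0);
  vz = clampd(vz, 0.0, n.nz - 1.0);
  int x0 = (int)std::floor(vx), y0 = (int)std::floor(vy), z0 = (int)std::floor(vz);
  if (x0 > n.nx - 2) x0 = n.nx > 1 ? n.nx - 2 : 0;
  if (y0 > n.ny - 2) y0 = n.ny > 1 ? n.ny - 2 : 0;
  if (z0 > n.nz - 2) z0 = n.nz > 1 ? n.nz - 2 : 0;
  int x1 = x0 + 1 < n.nx ? x0 + 1 : x0;
  int y1 = y0 + 1 < n.ny ? y0 + 1 : y0;
  int z1 = z0 + 1 < n.nz ? z0 + 1 : z0;
  double fx = vx - x0, fy = vy - y0, fz = vz - z0;
  const double* D = n.data;
  R_xlen_t sy = n.nx, sz = (R_xlen_t)n.nx * n.ny;
  double c000 = D[x0 + sy * y0 + sz * z0], c100 = D[x1 + sy * y0 + sz * z0];
  double c010 = D[x0 + sy * y1 + sz * z0], c110 = D[x1 + sy * y1 + sz * z0];
  double c001 = D[x0 + sy * y0 + sz * z1], c101 = D[x1 + sy * y0 + sz * z1];
  double c011 = D[x0 + sy * y1 + sz * z1], c111 = D[x1 + sy * y1 + sz * z1];
  double c00 = c000 + fx * (c100 - c000), c10 = c010 + fx * (c110 - c010);
  double c01 = c001 + fx * (c101 - c001), c11 = c011 + fx * (c111 - c011);
  double c0 = c00 + fy * (c10 - c00), c1 = c01 + fy * (c11 - c01);
  return c0 + fz * (c1 - c0);
}

// Nearest-neighbor label lookup; outside the grid -> 0 (unassigned).
inline int labelSample(const NodeK& n, double vx, double vy, double vz) {
  if (!n.hasMask) return 0;
  long ix = std::lround(vx), iy = std::lround(vy), iz = std::lround(vz);
  if (ix < 0 || iy < 0 || iz < 0 || ix >= n.nx || iy >= n.ny || iz >= n.nz) return 0;
  return n.mask[ix + (R_xlen_t)n.nx * iy + (R_xlen_t)n.nx * n.ny * iz];
}

// Piecewise evaluation of the transfer function at intensity I,
// clamped to the end control points outside the domain.
inline void tfEval(const NodeK& n, double I, double rgba[4]) {
  const double* x = n.tfx;
  int m = n.ntf;
  const double* R = n.tfc;
  const double* G = R + m;
  const double* B = G + m;
  const double* A = B + m;
  if (I <= x[0]) {
    rgba[0] = R[0]; rgba[1] = G[0]; rgba[2] = B[0]; rgba[3] = A[0];
    return;
  }
  if (I >= x[m - 1]) {
    rgba[0] = R[m - 1]; rgba[1] = G[m - 1]; rgba[2] = B[m - 1]; rgba[3] = A[m - 1];
    return;
  }
  int i = 0;
  while (I >= x[i + 1]) i++;
  if (n.interp == 1) {
    rgba[0] = R[i]; rgba[1] = G[i]; rgba[2] = B[i]; rgba[3] = A[i];
  } else {
    double w = (I - x[i]) / (x[i + 1] - x[i]);
    rgba[0] = R[i] + w * (R[i + 1] - R[i]);
    rgba[1] = G[i] + w * (G[i + 1] - G[i]);
    rgba[2] = B[i] + w * (B[i + 1] - B[i]);
    rgba[3] = A[i] + w * (A[i + 1] - A[i]);
  }
}

// Shadow-map visibility of world point p: 1 if lit, 0 if occluded.
inline double shadowVisibility(const LightK& lt, const double p[3]) {
  if (!lt.shadow.has) return 1.0;
  const CamK& c = lt.shadow.cam;
  double rx = p[0] - c.eye[0], ry = p[1] - c.eye[1], rz = p[2] - c.eye[2];
  double dist = std::sqrt(rx * rx + ry * ry + rz * rz);
  double cx = rx * c.right[0] + ry * c.right[1] + rz * c.right[2];
  double cy = rx * c.up[0] + ry * c.up[1] + rz * c.up[2];
  double cz = rx * c.fwd[0] + ry * c.fwd[1] + rz * c.fwd[2];
  if (cz <= c.nearc) return 1.0;
  double px = (cx / (cz * c.tanv * c.aspect) + 1.0) / 2.0 * c.W - 0.5;
  double py = (1.0 - cy / (cz * c.tanv)) / 2.0 * c.H - 0.5;
  long ix = std::lround(px), iy = std::lround(py);
  if (ix < 0 || iy < 0 || ix >= c.W || iy >= c.H) return 1.0;
  double occ = lt.shadow.map[iy + (R_xlen_t)c.H * ix];
  return dist <= occ + lt.shadow.bias ? 1.0 : 0.0;
}

// Lambert shading with a fixed ambient term. Zero-gradient regions are
// treated as fully lit (diffuse factor 1) since they have no surface.
inline void shadeSample(const NodeK& n, const ParamsK& P, const double pw[3],
                        double vx, double vy, double vz, double rgb[3]) {
  if (!P.light.has) return;
  double gx = (triSample(n, vx + 1.0, vy, vz) - triSample(n, vx - 1.0, vy, vz)) / (2.0 * n.sx);
  double gy = (triSample(n, vx, vy + 1.0, vz) - triSample(n, vx, vy - 1.0, vz)) / (2.0 * n.sy);
  double gz = (triSample(n, vx, vy, vz + 1.0) - triSample(n, vx, vy, vz - 1.0)) / (2.0 * n.sz);
  double wx = n.nrm[0] * gx + n.nrm[1] * gy + n.nrm[2] * gz;
  double wy = n.nrm[3] * gx + n.nrm[4] * gy + n.nrm[5] * gz;
  double wz = n.nrm[6] * gx + n.nrm[7] * gy + n.nrm[8] * gz;
  double gl = std::sqrt(wx * wx + wy * wy + wz * wz);
  double vis = shadowVisibility(P.light, pw);
  double diff;
  if (gl < 1e-12) {
    diff = 1.0;
  } else {
    double lx = P.light.pos[0] - pw[0], ly = P.light.pos[1] - pw[1], lz = P.light.pos[2] - pw[2];
    double ll = std::sqrt(lx * lx + ly * ly + lz * lz);
    if (ll < 1e-12) { diff = 1.0; }
    else {
      // normal = -normalized gradient
      double ndl = -(wx * lx + wy * ly + wz * lz) / (gl * ll);
      diff = ndl > 0.0 ? ndl : 0.0;
    }
  }
  double f = P.light.ambient + P.light.diffuse * diff * vis;
  rgb[0] *= f; rgb[1] *= f; rgb[2] *= f;
}

// Classify the world point pw for node n: color and opacity-corrected
// alpha. When checkInside, points outside the node's local sampling box
// contribute nothing (used by the one-pass renderer).
inline bool classifyWorld(const NodeK& n, const ParamsK& P, const double pw[3],
                          double out[4], bool checkInside) {
  double l[3];
  worldToLocal(n, pw[0], pw[1], pw[2], l);
  if (checkInside) {
    if (l[0] < n.lo[0] || l[0] > n.hi[0] || l[1] < n.lo[1] || l[1] > n.hi[1] ||
        l[2] < n.lo[2] || l[2] > n.hi[2])
      return false;
  }
  double vx = l[0] / n.sx, vy = l[1] / n.sy, vz = l[2] / n.sz;
  if (n.hasSkip) {
    int bi = (int)clampd(vx, 0.0, n.nx - 1.0) / n.bs;
    int bj = (int)clampd(vy, 0.0, n.ny - 1.0) / n.bs;
    int bk = (int)clampd(vz, 0.0, n.nz - 1.0) / n.bs;
    if (n.skip[bi + (R_xlen_t)n.bx * bj + (R_xlen_t)n.bx * n.by * bk]) {
      out[0] = out[1] = out[2] = out[3] = 0.0;
      return true;
    }
  }
  double I = triSample(n, vx, vy, vz);
  int label = labelSample(n, vx, vy, vz);
  double rgba[4];
  tfEval(n, I, rgba);
  double a = rgba[3] * n.segop[label & 255];
  double ac = 1.0 - std::pow(1.0 - a, P.step / n.refstep);
  out[0] = rgba[0]; out[1] = rgba[1]; out[2] = rgba[2]; out[3] = ac;
  if (ac > 0.0 && P.shading) {
    shadeSample(n, P, pw, vx, vy, vz, out);
  }
  return true;
}

struct MarchOut {
  double C[3];
  double A;
  double hit;  // < 0 if the alpha threshold was never reached
};

// Front-to-back march of one ray through one node over [t0, t1).
inline void marchRay(const NodeK& n, const ParamsK& P, const double o[3],
                     const double d[3], double t0, double t1, MarchOut& out) {
  out.C[0] = out.C[1] = out.C[2] = 0.0;
  out.A = 0.0;
  out.hit = -1.0;
  // slab intersection in the node's local frame
  double ol[3];
  worldToLocal(n, o[0], o[1], o[2], ol);
  double dl[3];
  dl[0] = n.inv[0] * d[0] + n.inv[1] * d[1] + n.inv[2] * d[2];
  dl[1] = n.inv[4] * d[0] + n.inv[5] * d[1] + n.inv[6] * d[2];
  dl[2] = n.inv[8] * d[0] + n.inv[9] * d[1] + n.inv[10] * d[2];
  double tE = t0, tX = t1;
  for (int a = 0; a < 3; a++) {
    if (dl[a] != 0.0) {
      double ta = (n.lo[a] - ol[a]) / dl[a];
      double tb = (n.hi[a] - ol[a]) / dl[a];
      if (ta > tb) { double tmp = ta; ta = tb; tb = tmp; }
      if (ta > tE) tE = ta;
      if (tb < tX) tX = tb;
    } else if (ol[a] < n.lo[a] || ol[a] > n.hi[a]) {
      return;
    }
  }
  if (tE >= tX) return;
  double C0 = 0.0, C1 = 0.0, C2 = 0.0, A = 0.0;
  long long k = 0;
  if (P.aligned) {
    k = (long long)std::ceil(tE / P.step);
    if ((double)k * P.step < tE) k++;
  }
  for (;; k++) {
    double t = P.aligned ? (double)k * P.step : tE + (k + 0.5) * P.step;
    if (t >= tX) break;
    double pw[3] = { o[0] + t * d[0], o[1] + t * d[1], o[2] + t * d[2] };
    double s[4];
    classifyWorld(n, P, pw, s, false);
    double a = s[3];
    if (a > 0.0) {
      double w = (1.0 - A) * a;
      C0 += w * s[0];
      C1 += w * s[1];
      C2 += w * s[2];
      A += w;
      if (A >= P.thr) {
        out.hit = t;
        break;
      }
    }
  }
  out.C[0] = C0; out.C[1] = C1; out.C[2] = C2; out.A = A;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_pixel_rays(List cam, IntegerVector ix, IntegerVector iy) {
  CamK c;
  camFromList(cam, c);
  int n = ix.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) {
    double d[3];
    pixelRay(c, ix[i], iy[i], d);
    out(i, 0) = d[0]; out(i, 1) = d[1]; out(i, 2) = d[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector data, IntegerVector dims,
                                   NumericMatrix pts) {
  NodeK n = {};
  n.data = REAL(data);
  n.nx = dims[0]; n.ny = dims[1]; n.nz = dims[2];
  int m = pts.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; i++)
    out[i] = triSample(n, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_sample_label(IntegerVector labels, IntegerVector dims,
                               NumericMatrix pts) {
  NodeK n = {};
  n.mask = INTEGER(labels);
  n.hasMask = true;
  n.nx = dims[0]; n.ny = dims[1]; n.nz = dims[2];
  int m = pts.nrow();
  IntegerVector out(m);
  for (int i = 0; i < m; i++)
    out[i] = labelSample(n, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// [[Rcpp::export]]
List cpp_march_ray(List node, List params, NumericVector origin,
                   NumericVector dir, double t0, double t1) {
  NodeK n;
  nodeFromList(node, n);
  ParamsK P;
  paramsFromList(params, P);
  double o[3] = { origin[0], origin[1], origin[2] };
  double d[3] = { dir[0], dir[1], dir[2] };
  MarchOut out;
  marchRay(n, P, o, d, t0, t1, out);
  return List::create(
      _["rgba"] = NumericVector::create(out.C[0], out.C[1], out.C[2], out.A),
      _["hit"] = out.hit);
}

// One render pass for a single node over the pixels of rect
// (x0, x1, y0, y1; half-open, 0-based), rays clamped per pixel at
// clampDepth. Returns the pass's premultiplied RGBA and hit-distance
// depth image (far where the alpha threshold was not reached).
// [[Rcpp::export]]
List cpp_render_pass(List node, List cam, List params, IntegerVector rect,
                     NumericMatrix clampDepth, bool depthOnly) {
  NodeK n;
  nodeFromList(node, n);
  CamK c;
  camFromList(cam, c);
  ParamsK P;
  paramsFromList(params, P);
  int H = c.H, W = c.W;
  NumericVector color(depthOnly ? 0 : (R_xlen_t)H * W * 4);
  NumericMatrix pdepth(H, W);
  std::fill(pdepth.begin(), pdepth.end(), c.farc);
  R_xlen_t plane = (R_xlen_t)H * W;
  long long hits = 0, marched = 0;
  for (int iy = rect[2]; iy < rect[3]; iy++) {
    for (int ix = rect[0]; ix < rect[1]; ix++) {
      double d[3];
      pixelRay(c, ix, iy, d);
      double t1 = clampDepth(iy, ix);
      if (t1 > c.farc) t1 = c.farc;
      MarchOut out;
      marchRay(n, P, c.eye, d, c.nearc, t1, out);
      marched++;
      if (!depthOnly) {
        R_xlen_t px = iy + (R_xlen_t)H * ix;
        color[px] = out.C[0];
        color[px + plane] = out.C[1];
        color[px + 2 * plane] = out.C[2];
        color[px + 3 * plane] = out.A;
      }
      if (out.hit >= 0.0) {
        pdepth(iy, ix) = out.hit;
        hits++;
      }
    }
  }
  if (!depthOnly) color.attr("dim") = IntegerVector::create(H, W, 4);
  return List::create(_["color"] = color, _["depth"] = pdepth,
                      _["pixels"] = (double)marched, _["hits"] = (double)hits);
}

// One-pass reference renderer: for every pixel, march t = k * step over
// [near, min(far, clamp)); at each step classify the sample of every
// node whose box contains the point and composite the contributions
// front-to-back in node-list order before advancing.
// [[Rcpp::export]]
List cpp_render_onepass(List nodes, List cam, List params,
                        NumericMatrix clampDepth) {
  int nn = nodes.size();
  std::vector<NodeK> nk(nn);
  for (int i = 0; i < nn; i++) nodeFromList(nodes[i], nk[i]);
  CamK c;
  camFromList(cam, c);
  ParamsK P;
  paramsFromList(params, P);
  int H = c.H, W = c.W;
  NumericVector color((R_xlen_t)H * W * 4);
  NumericMatrix depth(H, W);
  std::fill(depth.begin(), depth.end(), c.farc);
  R_xlen_t plane = (R_xlen_t)H * W;
  for (int iy = 0; iy < H; iy++) {
    for (int ix = 0; ix < W; ix++) {
      double d[3];
      pixelRay(c, ix, iy, d);
      double t1 = clampDepth(iy, ix);
      if (t1 > c.farc) t1 = c.farc;
      double C0 = 0.0, C1 = 0.0, C2 = 0.0, A = 0.0, hit = -1.0;
      long long k = (long long)std::ceil(c.nearc / P.step);
      if ((double)k * P.step < c.nearc) k++;
      for (;; k++) {
        double t = (double)k * P.step;
        if (t >= t1) break;
        double pw[3] = { c.eye[0] + t * d[0], c.eye[1] + t * d[1],
                         c.eye[2] + t * d[2] };
        bool done = false;
        for (int i = 0; i < nn; i++) {
          double s[4];
          if (!classifyWorld(nk[i], P, pw, s, true)) continue;
          double a = s[3];
          if (a > 0.0) {
            double w = (1.0 - A) * a;
            C0 += w * s[0];
            C1 += w * s[1];
            C2 += w * s[2];
            A += w;
            if (A >= P.thr) {
              hit = t;
              done = true;
              break;
            }
          }
        }
        if (done) break;
      }
      R_xlen_t px = iy + (R_xlen_t)H * ix;
      color[px] = C0;
      color[px + plane] = C1;
      color[px + 2 * plane] = C2;
      color[px + 3 * plane] = A;
      if (hit >= 0.0) depth(iy, ix) = hit;
    }
  }
  color.attr("dim") = IntegerVector::create(H, W, 4);
  return List::create(_["color"] = color, _["depth"] = depth);
}

// Per-block min/max intensity over each block dilated by one voxel
// (trilinear support), and whether the dilated block touches any
// labeled voxel.
// [[Rcpp::export]]
List cpp_block_minmax(NumericVector data, IntegerVector dims,
                      Nullable<IntegerVector> mask, int block) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int bx = (nx + block - 1) / block;
  int by = (ny + block - 1) / block;
  int bz = (nz + block - 1) / block;
  R_xlen_t nb = (R_xlen_t)bx * by * bz;
  NumericVector bmin(nb), bmax(nb);
  LogicalVector blab(nb);
  const double* D = REAL(data);
  const int* M = mask.isNotNull() ? INTEGER(as<IntegerVector>(mask)) : nullptr;
  R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int bk = 0; bk < bz; bk++) {
    for (int bj = 0; bj < by; bj++) {
      for (int bi = 0; bi < bx; bi++) {
        int x0 = bi * block - 1, x1 = (bi + 1) * block;  // dilated, inclusive
        int y0 = bj * block - 1, y1 = (bj + 1) * block;
        int z0 = bk * block - 1, z1 = (bk + 1) * block;
        if (x0 < 0) x0 = 0;
        if (y0 < 0) y0 = 0;
        if (z0 < 0) z0 = 0;
        if (x1 > nx - 1) x1 = nx - 1;
        if (y1 > ny - 1) y1 = ny - 1;
        if (z1 > nz - 1) z1 = nz - 1;
        double mn = R_PosInf, mx = R_NegInf;
        bool lab = false;
        for (int z = z0; z <= z1; z++)
          for (int y = y0; y <= y1; y++) {
            R_xlen_t base = sy * y + sz * z;
            for (int x = x0; x <= x1; x++) {
              double v = D[x + base];
              if (v < mn) mn = v;
              if (v > mx) mx = v;
              if (M && M[x + base] != 0) lab = true;
            }
          }
        R_xlen_t idx = bi + (R_xlen_t)bx * bj + (R_xlen_t)bx * by * bk;
        bmin[idx] = mn;
        bmax[idx] = mx;
        blab[idx] = lab;
      }
    }
  }
  bmin.attr("dim") = IntegerVector::create(bx, by, bz);
  bmax.attr("dim") = IntegerVector::create(bx, by, bz);
  blab.attr("dim") = IntegerVector::create(bx, by, bz);
  return List::create(_["min"] = bmin, _["max"] = bmax, _["has_label"] = blab,
                      _["nblocks"] = IntegerVector::create(bx, by, bz));
}
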