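// Monte Carlo direct volume renderer for non-scalar (intensity, mask)
// volumes: null-scattering path tracing under a macrocell majorant grid with
// 3D-DDA traversal, hybrid volumetric (Henyey-Greenstein) / surface
// (cosine-power lobe) shading, next-event estimation with ratio-tracked
// shadow transmittance, and a deterministic emission-absorption ray-march
// oracle. Counter-based RNG streams keyed by (seed, pixel, sample) make
// progressive accumulation order-independent and bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  static uint64_t mix(uint64_t z) {
    z += 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  uint64_t next_u64() { s += 0x9E3779B97F4A7C15ULL; uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31); }
  double u() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
};

static Rng stream_rng(uint64_t seed, uint64_t pixel, uint64_t sample) {
  uint64_t h = Rng::mix(seed ^ 0x5851F42D4C957F2DULL);
  h = Rng::mix(h ^ (pixel * 0x9E3779B97F4A7C15ULL));
  h = Rng::mix(h ^ (sample * 0xD1342543DE82EF95ULL));
  return Rng(h);
}

// ------------------------------------------------------------- vectors ---

struct V3 { double x, y, z; };
static inline V3 operator+(V3 a, V3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline V3 operator-(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 operator*(V3 a, double s) { return {a.x * s, a.y * s, a.z * s}; }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm3(V3 a) { return std::sqrt(dot(a, a)); }
static inline V3 normalize(V3 a) { double n = norm3(a); return {a.x / n, a.y / n, a.z / n}; }

// build an orthonormal basis around w and return a direction with polar
// angle (ct = cos theta) about w
static V3 rotate_about(V3 w, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  V3 a = std::fabs(w.x) < 0.9 ? V3{1, 0, 0} : V3{0, 1, 0};
  V3 u = normalize(cross(a, w));
  V3 v = cross(w, u);
  return normalize(w * ct + u * (st * std::cos(phi)) + v * (st * std::sin(phi)));
}

// ------------------------------------------------------------- volume ----

struct Volume {
  const double* inten;   // H x W x D
  const double* mask;    // g in [0,1], same shape
  int H, W, D;
  V3 sp;                 // spacing (mm)
  V3 extent() const { return {H * sp.x, W * sp.y, D * sp.z}; }
  long idx(int h, int w, int d) const { return h + (long)H * (w + (long)W * d); }

  double inten_at(V3 p) const {   // trilinear, voxel centers at (i+0.5)*sp
    double u = p.x / sp.x - 0.5, v = p.y / sp.y - 0.5, t = p.z / sp.z - 0.5;
    u = std::min(std::max(u, 0.0), H - 1.0);
    v = std::min(std::max(v, 0.0), W - 1.0);
    t = std::min(std::max(t, 0.0), D - 1.0);
    int i0 = (int)u, j0 = (int)v, k0 = (int)t;
    int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1), k1 = std::min(k0 + 1, D - 1);
    double fu = u - i0, fv = v - j0, ft = t - k0;
    double c00 = inten[idx(i0, j0, k0)] * (1 - fu) + inten[idx(i1, j0, k0)] * fu;
    double c10 = inten[idx(i0, j1, k0)] * (1 - fu) + inten[idx(i1, j1, k0)] * fu;
    double c01 = inten[idx(i0, j0, k1)] * (1 - fu) + inten[idx(i1, j0, k1)] * fu;
    double c11 = inten[idx(i0, j1, k1)] * (1 - fu) + inten[idx(i1, j1, k1)] * fu;
    double c0 = c00 * (1 - fv) + c10 * fv, c1 = c01 * (1 - fv) + c11 * fv;
    return c0 * (1 - ft) + c1 * ft;
  }
  double mask_at(V3 p) const {    // nearest neighbour (labels must not blend)
    int i = (int)std::floor(p.x / sp.x), j = (int)std::floor(p.y / sp.y),
        k = (int)std::floor(p.z / sp.z);
    i = std::min(std::max(i, 0), H - 1);
    j = std::min(std::max(j, 0), W - 1);
    k = std::min(std::max(k, 0), D - 1);
    return mask[idx(i, j, k)];
  }
  V3 gradient(V3 p) const {       // central differences, one voxel step
    V3 g;
    g.x = (inten_at({p.x + sp.x, p.y, p.z}) - inten_at({p.x - sp.x, p.y, p.z})) / (2 * sp.x);
    g.y = (inten_at({p.x, p.y + sp.y, p.z}) - inten_at({p.x, p.y - sp.y, p.z})) / (2 * sp.y);
    g.z = (inten_at({p.x, p.y, p.z + sp.z}) - inten_at({p.x, p.y, p.z - sp.z})) / (2 * sp.z);
    return g;
  }
};

// ------------------------------------------------- transfer function -----

struct TF {
  std::vector<double> xi, op, r, g, b, sm, pg;   // sorted control points
  double imp_a, density_scale;

  static double lerp(double a, double b, double f) { return a + (b - a) * f; }
  int seg(double x) const {
    int n = xi.size();
    if (x <= xi[0]) return -1;
    if (x >= xi[n - 1]) return n - 1;
    int i = 0;
    while (i + 1 < n && xi[i + 1] < x) ++i;
    return i;
  }
  void base_at(double x, double* out) const {   // opacity,r,g,b,smooth,phase
    int n = xi.size();
    double xc = std::min(std::max(x, xi[0]), xi[n - 1]);
    int i = 0;
    while (i + 1 < n - 1 && xi[i + 1] < xc) ++i;
    double f = (xi[i + 1] == xi[i]) ? 0 : (xc - xi[i]) / (xi[i + 1] - xi[i]);
    out[0] = lerp(op[i], op[i + 1], f); out[1] = lerp(r[i], r[i + 1], f);
    out[2] = lerp(g[i], g[i + 1], f);   out[3] = lerp(b[i], b[i + 1], f);
    out[4] = lerp(sm[i], sm[i + 1], f); out[5] = lerp(pg[i], pg[i + 1], f);
  }
  double importance(double gm) const {
    return (1 - std::exp(-imp_a * gm)) * (1 + std::exp(-imp_a)) /
           ((1 + std::exp(-imp_a * gm)) * (1 - std::exp(-imp_a)));
  }
  // conservative max opacity over an intensity interval: endpoints plus any
  // interior control points (piecewise-linear extrema sit at control points)
  double max_opacity(double lo, double hi) const {
    double m = 0; int n = xi.size();
    double a, tmp[6];
    base_at(lo, tmp); m = tmp[0];
    base_at(hi, tmp); a = tmp[0]; if (a > m) m = a;
    for (int i = 0; i < n; ++i)
      if (xi[i] > lo && xi[i] < hi && op[i] > m) m = op[i];
    return m;
  }
  double sigma_t(const Volume& vol, V3 p) const {
    double tmp[6];
    base_at(vol.inten_at(p), tmp);
    return tmp[0] * importance(vol.mask_at(p)) * density_scale;
  }
};

static TF make_tf(const NumericMatrix& pts, double imp_a, double density_scale) {
  TF tf;
  int n = pts.nrow();
  for (int i = 0; i < n; ++i) {
    tf.xi.push_back(pts(i, 0)); tf.op.push_back(pts(i, 1));
    tf.r.push_back(pts(i, 2)); tf.g.push_back(pts(i, 3)); tf.b.push_back(pts(i, 4));
    tf.sm.push_back(pts(i, 5)); tf.pg.push_back(pts(i, 6));
  }
  tf.imp_a = imp_a; tf.density_scale = density_scale;
  return tf;
}

// ----------------------------------------------------- macrocell grid ----

struct Macro {
  std::vector<double> maj;   // per-cell majorant extinction
  int nx, ny, nz, cs;        // cells per axis, cell size (voxels)
  V3 cell_mm;                // cell extent in mm
  double global;
  long cidx(int i, int j, int k) const { return i + (long)nx * (j + (long)ny * k); }
};

static Macro build_macro(const Volume& vol, const TF& tf, int cs) {
  Macro mc;
  mc.cs = cs;
  mc.nx = (vol.H + cs - 1) / cs; mc.ny = (vol.W + cs - 1) / cs; mc.nz = (vol.D + cs - 1) / cs;
  mc.cell_mm = {cs * vol.sp.x, cs * vol.sp.y, cs * vol.sp.z};
  mc.maj.assign((long)mc.nx * mc.ny * mc.nz, 0.0);
  mc.global = 0;
  for (int k = 0; k < mc.nz; ++k)
    for (int j = 0; j < mc.ny; ++j)
      for (int i = 0; i < mc.nx; ++i) {
        // expand by one voxel: trilinear samples inside the cell touch
        // neighbouring voxels
        int h0 = std::max(0, i * cs - 1), h1 = std::min(vol.H - 1, (i + 1) * cs);
        int w0 = std::max(0, j * cs - 1), w1 = std::min(vol.W - 1, (j + 1) * cs);
        int d0 = std::max(0, k * cs - 1), d1 = std::min(vol.D - 1, (k + 1) * cs);
        double lo = R_PosInf, hi = R_NegInf, gmax = 0;
        for (int d = d0; d <= d1; ++d)
          for (int w = w0; w <= w1; ++w)
            for (int h = h0; h <= h1; ++h) {
              double v = vol.inten[vol.idx(h, w, d)];
              if (v < lo) lo = v;
              if (v > hi) hi = v;
              double g = vol.mask[vol.idx(h, w, d)];
              if (g > gmax) gmax = g;
            }
        double m = tf.max_opacity(lo, hi) * tf.importance(gmax) * tf.density_scale;
        mc.maj[mc.cidx(i, j, k)] = m;
        if (m > mc.global) mc.global = m;
      }
  return mc;
}

// ----------------------------------------------------------- geometry ----

static bool ray_box(V3 o, V3 d, V3 lo, V3 hi, double& t0, double& t1) {
  t0 = 0; t1 = R_PosInf;
  const double* ov = &o.x; const double* dv = &d.x;
  const double* lv = &lo.x; const double* hv = &hi.x;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dv[a]) < 1e-300) {
      if (ov[a] < lv[a] || ov[a] > hv[a]) return false;
    } else {
      double ta = (lv[a] - ov[a]) / dv[a], tb = (hv[a] - ov[a]) / dv[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
      if (t0 > t1) return false;
    }
  }
  return true;
}

// 3D-DDA over macrocells; calls visit(cell_linear_index, t_enter, t_exit);
// stops early if visit returns false.
template <class F>
static void dda(const Macro& mc, V3 o, V3 d, double t0, double t1, F visit) {
  const double eps = 1e-12;
  V3 p = o + d * (t0 + 1e-9);
  int ix = std::min(std::max((int)std::floor(p.x / mc.cell_mm.x), 0), mc.nx - 1);
  int iy = std::min(std::max((int)std::floor(p.y / mc.cell_mm.y), 0), mc.ny - 1);
  int iz = std::min(std::max((int)std::floor(p.z / mc.cell_mm.z), 0), mc.nz - 1);
  int sx = d.x > eps ? 1 : (d.x < -eps ? -1 : 0);
  int sy = d.y > eps ? 1 : (d.y < -eps ? -1 : 0);
  int sz = d.z > eps ? 1 : (d.z < -eps ? -1 : 0);
  double tx = sx != 0 ? ((ix + (sx > 0 ? 1 : 0)) * mc.cell_mm.x - o.x) / d.x : R_PosInf;
  double ty = sy != 0 ? ((iy + (sy > 0 ? 1 : 0)) * mc.cell_mm.y - o.y) / d.y : R_PosInf;
  double tz = sz != 0 ? ((iz + (sz > 0 ? 1 : 0)) * mc.cell_mm.z - o.z) / d.z : R_PosInf;
  double dtx = sx != 0 ? mc.cell_mm.x / std::fabs(d.x) : R_PosInf;
  double dty = sy != 0 ? mc.cell_mm.y / std::fabs(d.y) : R_PosInf;
  double dtz = sz != 0 ? mc.cell_mm.z / std::fabs(d.z) : R_PosInf;
  double tcur = t0;
  while (tcur < t1 - 1e-12) {
    double tnext = std::min(std::min(tx, ty), std::min(tz, t1));
    if (!visit(mc.cidx(ix, iy, iz), tcur, tnext)) return;
    tcur = tnext;
    if (tnext >= t1 - 1e-12) break;
    if (tx <= ty && tx <= tz) { ix += sx; tx += dtx; if (ix < 0 || ix >= mc.nx) break; }
    else if (ty <= tz)        { iy += sy; ty += dty; if (iy < 0 || iy >= mc.ny) break; }
    else                      { iz += sz; tz += dtz; if (iz < 0 || iz >= mc.nz) break; }
  }
}

// -------------------------------------------------- transport kernels ----

struct Hit { bool real; double t; };

// null-scattering free flight from o along d within [t0, t1]
static Hit free_flight(const Volume& vol, const TF& tf, const Macro& mc,
                       V3 o, V3 d, double t0, double t1, Rng& rng, bool* err) {
  Hit hit{false, t1};
  dda(mc, o, d, t0, t1, [&](long ci, double ta, double tb) {
    double sbar = mc.maj[ci];
    if (sbar <= 0) return true;
    double t = ta;
    while (true) {
      t += -std::log(1 - rng.u()) / sbar;
      if (t >= tb) return true;
      double st = tf.sigma_t(vol, o + d * t);
      if (st > sbar * (1 + 1e-9)) { *err = true; return false; }
      if (rng.u() < st / sbar) { hit.real = true; hit.t = t; return false; }
    }
  });
  return hit;
}

// ratio-tracked transmittance from o along d within [t0, t1]
static double transmittance(const Volume& vol, const TF& tf, const Macro& mc,
                            V3 o, V3 d, double t0, double t1, Rng& rng) {
  double T = 1;
  dda(mc, o, d, t0, t1, [&](long ci, double ta, double tb) {
    double sbar = mc.maj[ci];
    if (sbar <= 0) return true;
    double t = ta;
    while (true) {
      t += -std::log(1 - rng.u()) / sbar;
      if (t >= tb) return true;
      double st = tf.sigma_t(vol, o + d * t);
      T *= std::max(0.0, 1.0 - st / sbar);
      if (T < 1e-5) return false;
    }
  });
  return T;
}

static double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-6) return 1 - 2 * u;
  double sq = (1 - g * g) / (1 - g + 2 * g * u);
  return (1 + g * g - sq * sq) / (2 * g);
}

static double hg_pdf(double g, double ct) {
  double denom = 1 + g * g - 2 * g * ct;
  return (1 - g * g) / (4 * M_PI * denom * std::sqrt(denom));
}

struct Scene {
  Volume vol; TF tf; Macro mc;
  V3 light_dir;          // direction TOWARD the light (normalized)
  V3 light_rad, ambient; // RGB
  double grad_thresh;    // gradient magnitude where surfaceness saturates
  int max_bounces;
};

// sample one scattering event at x for incoming direction d: picks the
// surface or volumetric branch from the local gradient, samples the
// outgoing direction, and reports the single-scattering albedo throughput.
static void scatter_sample(const Scene& sc, V3 x, V3 d, Rng& rng,
                           V3& nd, double alb[3], int& branch) {
  double mat[6];
  sc.tf.base_at(sc.vol.inten_at(x), mat);
  double I = sc.tf.importance(sc.vol.mask_at(x));
  alb[0] = mat[1] * I; alb[1] = mat[2] * I; alb[2] = mat[3] * I;
  double smooth = mat[4] * I, phg = std::min(std::max(mat[5], -0.99), 0.99);
  V3 grad = sc.vol.gradient(x);
  double gm = norm3(grad);
  double s = std::min(gm / std::max(sc.grad_thresh, 1e-12), 1.0);
  bool surface = rng.u() < s && gm > 1e-12;
  if (surface) {
    V3 n = normalize(grad);
    if (dot(n, d) > 0) n = n * -1.0;
    double pw = 2.0 / ((1 - smooth + 1e-3) * (1 - smooth + 1e-3)) - 2.0;
    double ct = std::pow(rng.u(), 1.0 / (pw + 1));
    nd = rotate_about(n, ct, 2 * M_PI * rng.u());
    branch = 1;
  } else {
    nd = rotate_about(d, hg_cos(phg, rng.u()), 2 * M_PI * rng.u());
    branch = 0;
  }
}

// one path; returns RGB radiance
static void trace_path(const Scene& sc, V3 o, V3 d, Rng& rng, double* rgb, bool* err) {
  double tput[3] = {1, 1, 1};
  rgb[0] = rgb[1] = rgb[2] = 0;
  V3 lo{0, 0, 0}, hi = sc.vol.extent();
  for (int bounce = 0; bounce < sc.max_bounces; ++bounce) {
    double t0, t1;
    if (!ray_box(o, d, lo, hi, t0, t1)) {
      rgb[0] += tput[0] * sc.ambient.x; rgb[1] += tput[1] * sc.ambient.y;
      rgb[2] += tput[2] * sc.ambient.z;
      return;
    }
    Hit h = free_flight(sc.vol, sc.tf, sc.mc, o, d, t0, t1, rng, err);
    if (*err) return;
    if (!h.real) {
      rgb[0] += tput[0] * sc.ambient.x; rgb[1] += tput[1] * sc.ambient.y;
      rgb[2] += tput[2] * sc.ambient.z;
      return;
    }
    V3 x = o + d * h.t;
    double mat[6];
    sc.tf.base_at(sc.vol.inten_at(x), mat);
    double I = sc.tf.importance(sc.vol.mask_at(x));
    double alb[3] = {mat[1] * I, mat[2] * I, mat[3] * I};
    double smooth = mat[4] * I, phg = std::min(std::max(mat[5], -0.99), 0.99);

    V3 grad = sc.vol.gradient(x);
    double gm = norm3(grad);
    double s = std::min(gm / std::max(sc.grad_thresh, 1e-12), 1.0);
    bool surface = rng.u() < s && gm > 1e-12;

    // next-event estimation toward the directional light
    {
      double lt0, lt1, f;
      if (surface) {
        V3 n = normalize(grad);
        if (dot(n, d) > 0) n = n * -1.0;
        double p = 2.0 / ((1 - smooth + 1e-3) * (1 - smooth + 1e-3)) - 2.0;
        double cl = dot(n, sc.light_dir);
        f = cl > 0 ? (p + 1) / (2 * M_PI) * std::pow(cl, p) : 0.0;
      } else {
        f = hg_pdf(phg, dot(d, sc.light_dir));
      }
      if (f > 0) {
        bool inb = ray_box(x, sc.light_dir, lo, hi, lt0, lt1);
        double T = inb ? transmittance(sc.vol, sc.tf, sc.mc, x, sc.light_dir,
                                       std::max(lt0, 1e-9), lt1, rng) : 1.0;
        rgb[0] += tput[0] * alb[0] * f * T * sc.light_rad.x;
        rgb[1] += tput[1] * alb[1] * f * T * sc.light_rad.y;
        rgb[2] += tput[2] * alb[2] * f * T * sc.light_rad.z;
      }
    }

    // continue the path (importance-sampled lobe; pdf cancels)
    tput[0] *= alb[0]; tput[1] *= alb[1]; tput[2] *= alb[2];
    if (tput[0] <= 0 && tput[1] <= 0 && tput[2] <= 0) return;
    V3 nd;
    if (surface) {
      V3 n = normalize(grad);
      if (dot(n, d) > 0) n = n * -1.0;
      double p = 2.0 / ((1 - smooth + 1e-3) * (1 - smooth + 1e-3)) - 2.0;
      double ct = std::pow(rng.u(), 1.0 / (p + 1));
      nd = rotate_about(n, ct, 2 * M_PI * rng.u());
    } else {
      nd = rotate_about(d, hg_cos(phg, rng.u()), 2 * M_PI * rng.u());
    }
    o = x; d = nd;

    if (bounce >= 3) {   // Russian roulette
      double q = std::min(std::max(std::max(tput[0], std::max(tput[1], tput[2])), 0.05), 0.95);
      if (rng.u() >= q) return;
      tput[0] /= q; tput[1] /= q; tput[2] /= q;
    }
  }
}

// ------------------------------------------------------------ exports ----

static Volume make_volume(const NumericVector& inten, const NumericVector& mask,
                          const IntegerVector& dims, const NumericVector& spacing) {
  Volume v;
  v.inten = inten.begin(); v.mask = mask.begin();
  v.H = dims[0]; v.W = dims[1]; v.D = dims[2];
  v.sp = {spacing[0], spacing[1], spacing[2]};
  return v;
}

// [[Rcpp::export]]
List build_macrocell_cpp(NumericVector inten, NumericVector mask, IntegerVector dims,
                         NumericVector spacing, NumericMatrix tf_points,
                         double imp_a, double density_scale, int cell_size) {
  Volume vol = make_volume(inten, mask, dims, spacing);
  TF tf = make_tf(tf_points, imp_a, density_scale);
  Macro mc = build_macro(vol, tf, cell_size);
  NumericVector maj(mc.maj.begin(), mc.maj.end());
  maj.attr("dim") = IntegerVector::create(mc.nx, mc.ny, mc.nz);
  return List::create(Named("majorants") = maj,
                      Named("n_cells") = IntegerVector::create(mc.nx, mc.ny, mc.nz),
                      Named("cell_size") = cell_size,
                      Named("cell_mm") = NumericVector::create(mc.cell_mm.x, mc.cell_mm.y,
                                                               mc.cell_mm.z),
                      Named("global_majorant") = mc.global);
}

// [[Rcpp::export]]
NumericMatrix dda_traverse_cpp(NumericVector origin, NumericVector dir,
                               IntegerVector n_cells, NumericVector cell_mm) {
  Macro mc;
  mc.nx = n_cells[0]; mc.ny = n_cells[1]; mc.nz = n_cells[2];
  mc.cell_mm = {cell_mm[0], cell_mm[1], cell_mm[2]};
  V3 o{origin[0], origin[1], origin[2]}, d{dir[0], dir[1], dir[2]};
  if (norm3(d) == 0) stop("ray direction must be nonzero");
  d = normalize(d);
  V3 lo{0, 0, 0}, hi{mc.nx * mc.cell_mm.x, mc.ny * mc.cell_mm.y, mc.nz * mc.cell_mm.z};
  double t0, t1;
  std::vector<std::array<double, 5>> rows;
  if (ray_box(o, d, lo, hi, t0, t1) && t1 > t0 + 1e-12) {
    dda(mc, o, d, t0, t1, [&](long ci, double ta, double tb) {
      int ix = ci % mc.nx, iy = (ci / mc.nx) % mc.ny, iz = ci / ((long)mc.nx * mc.ny);
      rows.push_back({(double)ix, (double)iy, (double)iz, ta, tb});
      return true;
    });
  }
  NumericMatrix out(rows.size(), 5);
  for (size_t i = 0; i < rows.size(); ++i)
    for (int j = 0; j < 5; ++j) out(i, j) = rows[i][j];
  colnames(out) = CharacterVector::create("ix", "iy", "iz", "t_enter", "t_exit");
  return out;
}

// Free-flight sampling experiment: n rays from `origin` along `dir`; returns
// collision distance or Inf (escape) per ray.
// [[Rcpp::export]]
NumericVector free_flight_cpp(NumericVector inten, NumericVector mask, IntegerVector dims,
                              NumericVector spacing, NumericMatrix tf_points,
                              double imp_a, double density_scale, int cell_size,
                              NumericVector origin, NumericVector dir, int n, int seed) {
  Volume vol = make_volume(inten, mask, dims, spacing);
  TF tf = make_tf(tf_points, imp_a, density_scale);
  Macro mc = build_macro(vol, tf, cell_size);
  V3 o{origin[0], origin[1], origin[2]}, d = normalize(V3{dir[0], dir[1], dir[2]});
  V3 lo{0, 0, 0}, hi = vol.extent();
  NumericVector out(n);
  bool err = false;
  for (int i = 0; i < n; ++i) {
    Rng rng = stream_rng(seed, i, 0);
    double t0, t1;
    if (!ray_box(o, d, lo, hi, t0, t1)) { out[i] = R_PosInf; continue; }
    Hit h = free_flight(vol, tf, mc, o, d, t0, t1, rng, &err);
    if (err) stop("majorant violated during free-flight sampling");
    out[i] = h.real ? h.t : R_PosInf;
  }
  return out;
}

// HG direction sampling experiment: cosines relative to the incoming axis.
// [[Rcpp::export]]
NumericVector hg_sample_cpp(double g, int n, int seed) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    Rng rng = stream_rng(seed, i, 1);
    V3 d = rotate_about(V3{0, 0, 1}, hg_cos(g, rng.u()), 2 * M_PI * rng.u());
    out[i] = d.z;
  }
  return out;
}

// Ratio-tracked transmittance estimates along one ray (for unbiasedness tests).
// [[Rcpp::export]]
NumericVector transmittance_cpp(NumericVector inten, NumericVector mask, IntegerVector dims,
                                NumericVector spacing, NumericMatrix tf_points,
                                double imp_a, double density_scale, int cell_size,
                                NumericVector origin, NumericVector dir, int n, int seed) {
  Volume vol = make_volume(inten, mask, dims, spacing);
  TF tf = make_tf(tf_points, imp_a, density_scale);
  Macro mc = build_macro(vol, tf, cell_size);
  V3 o{origin[0], origin[1], origin[2]}, d = normalize(V3{dir[0], dir[1], dir[2]});
  V3 lo{0, 0, 0}, hi = vol.extent();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    Rng rng = stream_rng(seed, i, 2);
    double t0, t1;
    out[i] = ray_box(o, d, lo, hi, t0, t1)
      ? transmittance(vol, tf, mc, o, d, t0, t1, rng) : 1.0;
  }
  return out;
}

struct Cam {
  V3 pos, f, r, u;
  double tanv, aspect;
  int width, height;
  V3 ray_dir(double px, double py) const {   // px in [0,w), py in [0,h)
    double x = (2 * (px + 0.5) / width - 1) * tanv * aspect;
    double y = (1 - 2 * (py + 0.5) / height) * tanv;
    return normalize(f + r * x + u * y);
  }
};

static Cam make_cam(NumericVector position, NumericVector look_at, NumericVector up,
                    double fov_deg, int width, int height) {
  Cam c;
  c.pos = {position[0], position[1], position[2]};
  V3 la{look_at[0], look_at[1], look_at[2]}, upv{up[0], up[1], up[2]};
  c.f = normalize(la - c.pos);
  c.r = normalize(cross(c.f, upv));
  c.u = cross(c.r, c.f);
  c.tanv = std::tan(fov_deg * M_PI / 360.0);
  c.aspect = (double)width / height;
  c.width = width; c.height = height;
  return c;
}

// Progressive Monte Carlo render: accumulates samples [spp_start,
// spp_start + spp) into per-pixel radiance sums. Streams are keyed by
// (seed, pixel, sample), so two passes of n/2 equal one pass of n.
// [[Rcpp::export]]
NumericVector render_pt_cpp(NumericVector inten, NumericVector mask, IntegerVector dims,
                            NumericVector spacing, NumericMatrix tf_points,
                            double imp_a, double density_scale, int cell_size,
                            NumericVector cam_pos, NumericVector cam_look, NumericVector cam_up,
                            double fov_deg, int width, int height,
                            NumericVector light_dir, NumericVector light_rad,
                            NumericVector ambient, double grad_thresh, int max_bounces,
                            int spp, int spp_start, int seed) {
  Scene sc;
  sc.vol = make_volume(inten, mask, dims, spacing);
  sc.tf = make_tf(tf_points, imp_a, density_scale);
  sc.mc = build_macro(sc.vol, sc.tf, cell_size);
  sc.light_dir = normalize(V3{light_dir[0], light_dir[1], light_dir[2]});
  sc.light_rad = {light_rad[0], light_rad[1], light_rad[2]};
  sc.ambient = {ambient[0], ambient[1], ambient[2]};
  sc.grad_thresh = grad_thresh;
  sc.max_bounces = max_bounces;
  Cam cam = make_cam(cam_pos, cam_look, cam_up, fov_deg, width, height);
  NumericVector out((long)width * height * 3);
  bool err = false;
  for (int py = 0; py < height; ++py)
    for (int px = 0; px < width; ++px) {
      long pix = px + (long)width * py;          // RNG stream key
      long pr = py + (long)height * px;          // column-major (h, w, 3) output
      double acc[3] = {0, 0, 0};
      for (int sdx = 0; sdx < spp; ++sdx) {
        Rng rng = stream_rng(seed, pix, spp_start + sdx);
        double jx = rng.u() - 0.5, jy = rng.u() - 0.5;
        V3 d = cam.ray_dir(px + jx, py + jy);
        double rgb[3];
        trace_path(sc, cam.pos, d, rng, rgb, &err);
        if (err) stop("majorant violated during path tracing");
        acc[0] += rgb[0]; acc[1] += rgb[1]; acc[2] += rgb[2];
      }
      out[pr] = acc[0];
      out[pr + (long)width * height] = acc[1];
      out[pr + 2L * (long)width * height] = acc[2];
    }
  out.attr("dim") = IntegerVector::create(height, width, 3);
  return out;
}

// Deterministic emission-absorption ray-march oracle with headlight-free
// lambertian shading against the directional light plus ambient.
// [[Rcpp::export]]
NumericVector render_rm_cpp(NumericVector inten, NumericVector mask, IntegerVector dims,
                            NumericVector spacing, NumericMatrix tf_points,
                            double imp_a, double density_scale,
                            NumericVector cam_pos, NumericVector cam_look, NumericVector cam_up,
                            double fov_deg, int width, int height,
                            NumericVector light_dir, NumericVector light_rad,
                            NumericVector ambient, double step) {
  Volume vol = make_volume(inten, mask, dims, spacing);
  TF tf = make_tf(tf_points, imp_a, density_scale);
  V3 ld = normalize(V3{light_dir[0], light_dir[1], light_dir[2]});
  V3 lrad{light_rad[0], light_rad[1], light_rad[2]};
  V3 amb{ambient[0], ambient[1], ambient[2]};
  Cam cam = make_cam(cam_pos, cam_look, cam_up, fov_deg, width, height);
  V3 lo{0, 0, 0}, hi = vol.extent();
  NumericVector out((long)width * height * 3);
  for (int py = 0; py < height; ++py)
    for (int px = 0; px < width; ++px) {
      long pr = py + (long)height * px;
      V3 d = cam.ray_dir(px, py);
      double T = 1, rgb[3] = {0, 0, 0};
      double t0, t1;
      if (ray_box(cam.pos, d, lo, hi, t0, t1)) {
        for (double t = t0 + step / 2; t < t1; t += step) {
          V3 x = cam.pos + d * t;
          double matv[6];
          tf.base_at(vol.inten_at(x), matv);
          double I = tf.importance(vol.mask_at(x));
          double st = matv[0] * I * tf.density_scale;
          if (st <= 0) continue;
          double alpha = 1 - std::exp(-st * step);
          V3 grad = vol.gradient(x);
          double lam = 0.3;       // ambient floor of the local shading
          double gn = norm3(grad);
          if (gn > 1e-12) {
            double c = dot(normalize(grad), ld);
            lam += 0.7 * std::fabs(c);
          } else lam += 0.35;
          double sh[3] = {lam * lrad.x + amb.x, lam * lrad.y + amb.y, lam * lrad.z + amb.z};
          rgb[0] += T * alpha * matv[1] * I * sh[0];
          rgb[1] += T * alpha * matv[2] * I * sh[1];
          rgb[2] += T * alpha * matv[3] * I * sh[2];
          T *= 1 - alpha;
          if (T < 1e-4) break;
        }
      }
      rgb[0] += T * amb.x; rgb[1] += T * amb.y; rgb[2] += T * amb.z;
      out[pr] = rgb[0];
      out[pr + (long)width * height] = rgb[1];
      out[pr + 2L * (long)width * height] = rgb[2];
    }
  out.attr("dim") = IntegerVector::create(height, width, 3);
  return out;
}

// Scattering-event sampling experiment: draws n events at world position
// `x` for incoming direction `dir`; returns outgoing directions, RGB
// throughput (single-scattering albedo), and the branch taken
// (0 volumetric, 1 surface).
// [[Rcpp::export]]
List shade_event_cpp(NumericVector inten, NumericVector mask, IntegerVector dims,
                     NumericVector spacing, NumericMatrix tf_points,
                     double imp_a, double density_scale,
                     NumericVector x, NumericVector dir, double grad_thresh,
                     int n, int seed) {
  Scene sc;
  sc.vol = make_volume(inten, mask, dims, spacing);
  sc.tf = make_tf(tf_points, imp_a, density_scale);
  sc.grad_thresh = grad_thresh;
  V3 xp{x[0], x[1], x[2]}, d = normalize(V3{dir[0], dir[1], dir[2]});
  NumericMatrix dirs(n, 3), tput(n, 3);
  IntegerVector branch(n);
  for (int i = 0; i < n; ++i) {
    Rng rng = stream_rng(seed, i, 3);
    V3 nd; double alb[3]; int br;
    scatter_sample(sc, xp, d, rng, nd, alb, br);
    dirs(i, 0) = nd.x; dirs(i, 1) = nd.y; dirs(i, 2) = nd.z;
    tput(i, 0) = alb[0]; tput(i, 1) = alb[1]; tput(i, 2) = alb[2];
    branch[i] = br;
  }
  return List::create(Named("dir") = dirs, Named("throughput") = tput,
                      Named("branch") = branch);
}
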