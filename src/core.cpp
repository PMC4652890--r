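// Ray-casting scene core and the per-tick EMD simulation loop.
//
// The scene is a set of axis-aligned textured surfaces: an optional outer box
// (6 faces) plus axis-aligned box obstacles. Obstacle lookups are accelerated
// by a uniform 2-D grid over the ground plane (obstacles are vertical prisms).
// All heavy per-tick work of the closed loop (panoramic rendering, temporal
// filtering, correlator responses, squared-flow accumulation) lives here; the
// control law stays in R.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double EPS_T = 1e-9;

struct Texture {
  // brightness quantized to 8 bits (the package's PNG export precision);
  // the summed-area table is exact in integers
  std::vector<unsigned char> v;      // row-major, 0..255
  std::vector<unsigned int> sat;     // summed-area table, (nrow+1) x (ncol+1)
  int nrow, ncol;
  double texel;            // texel edge length (m)
  double at(double u, double vv) const {
    // (u, v) are face-local coordinates in metres; nearest-texel, tiled
    long j = (long)std::floor(u / texel) % ncol; if (j < 0) j += ncol;
    long i = (long)std::floor(vv / texel) % nrow; if (i < 0) i += nrow;
    return v[(size_t)i * ncol + j] / 255.0;
  }
  void build_sat() {
    sat.assign((size_t)(nrow + 1) * (ncol + 1), 0u);
    for (int i = 0; i < nrow; ++i) {
      unsigned int row = 0;
      for (int j = 0; j < ncol; ++j) {
        row += v[(size_t)i * ncol + j];
        sat[(size_t)(i + 1) * (ncol + 1) + (j + 1)] =
          sat[(size_t)i * (ncol + 1) + (j + 1)] + row;
      }
    }
  }
  // mean brightness over the texel-snapped box [u-su, u+su] x [v-sv, v+sv]
  // (metres, clamped to the texture); approximates the optics washing out
  // sub-resolution texture with distance
  double box_avg(double u, double vv, double su, double sv) const {
    long j0 = (long)std::floor((u - su) / texel);
    long j1 = (long)std::floor((u + su) / texel) + 1;
    long i0 = (long)std::floor((vv - sv) / texel);
    long i1 = (long)std::floor((vv + sv) / texel) + 1;
    if (j1 - j0 <= 1 && i1 - i0 <= 1) return at(u, vv);
    if (j0 < 0) j0 = 0; if (i0 < 0) i0 = 0;
    if (j1 > ncol) j1 = ncol; if (i1 > nrow) i1 = nrow;
    if (j1 <= j0 || i1 <= i0) return at(u, vv);
    double sum = (double)sat[(size_t)i1 * (ncol + 1) + j1] -
                 (double)sat[(size_t)i0 * (ncol + 1) + j1] -
                 (double)sat[(size_t)i1 * (ncol + 1) + j0] +
                 (double)sat[(size_t)i0 * (ncol + 1) + j0];
    return sum / (255.0 * (double)(i1 - i0) * (double)(j1 - j0));
  }
};

struct BoxObs {
  double lo[3], hi[3];
  int tex;
};

struct Scene {
  bool has_walls;
  double footprint;        // per-sub-ray half-angle (rad) of texture filtering
  double lo[3], hi[3];     // outer box bounds (also grid bounds)
  int wall_tex[6];         // faces: x-, x+, y-, y+, z- (floor), z+ (ceiling)
  std::vector<BoxObs> boxes;
  std::vector<Texture> textures;
  double background;       // brightness returned for rays escaping open scenes
  // uniform grid over (x, y)
  int nx, ny;
  double cx, cy;           // cell sizes
  std::vector<std::vector<int>> cells;
  mutable std::vector<int> mailbox;
  mutable int stamp;

  void build_grid() {
    nx = std::max(1, (int)std::ceil((hi[0] - lo[0]) / 0.10));
    ny = std::max(1, (int)std::ceil((hi[1] - lo[1]) / 0.10));
    cx = (hi[0] - lo[0]) / nx;
    cy = (hi[1] - lo[1]) / ny;
    cells.assign((size_t)nx * ny, {});
    for (int b = 0; b < (int)boxes.size(); ++b) {
      int i0 = std::max(0, (int)std::floor((boxes[b].lo[0] - lo[0]) / cx));
      int i1 = std::min(nx - 1, (int)std::floor((boxes[b].hi[0] - lo[0]) / cx));
      int j0 = std::max(0, (int)std::floor((boxes[b].lo[1] - lo[1]) / cy));
      int j1 = std::min(ny - 1, (int)std::floor((boxes[b].hi[1] - lo[1]) / cy));
      for (int i = i0; i <= i1; ++i)
        for (int j = j0; j <= j1; ++j)
          cells[(size_t)j * nx + i].push_back(b);
    }
    mailbox.assign(boxes.size(), -1);
    stamp = 0;
  }
};

// slab test against an AABB; returns entry t (> EPS_T) and entry axis, or -1
static inline double box_hit(const double* lo, const double* hi,
                             const double* o, const double* d, int& axis) {
  double tmin = -std::numeric_limits<double>::infinity();
  double tmax = std::numeric_limits<double>::infinity();
  int amin = -1;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-14) {
      if (o[a] < lo[a] || o[a] > hi[a]) return -1.0;
    } else {
      double inv = 1.0 / d[a];
      double t1 = (lo[a] - o[a]) * inv, t2 = (hi[a] - o[a]) * inv;
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) { tmin = t1; amin = a; }
      if (t2 < tmax) tmax = t2;
      if (tmin > tmax) return -1.0;
    }
  }
  if (tmax < EPS_T) return -1.0;
  if (tmin > EPS_T) { axis = amin; return tmin; }
  axis = -1;                      // origin inside the box: return exit
  return tmax;
}

struct Hit { double t; double bright; };

// filtered brightness of a surface point: the angular footprint projects to
// an ellipse on the surface, elongated at grazing incidence; approximated by
// an axis-aligned box with per-axis elongation (capped), like anisotropic
// mipmapped texture filtering
static inline double tex_bright(const Scene& sc, const Texture& tx,
                                double u, double v, double t, double dn,
                                double du, double dv) {
  if (sc.footprint <= 0) return tx.at(u, v);
  double an = std::max(std::fabs(dn), 1.0 / 32.0);
  double s0 = t * sc.footprint;
  double su = s0 * std::sqrt(1.0 + (du * du) / (an * an));
  double sv = s0 * std::sqrt(1.0 + (dv * dv) / (an * an));
  return tx.box_avg(u, v, su, sv);
}

static inline double obs_bright(const Scene& sc, const BoxObs& b,
                                const double* p, int axis, double t,
                                const double* d) {
  if (axis < 0) axis = 0;
  int ua = (axis + 1) % 3, va = (axis + 2) % 3;
  const Texture& tx = sc.textures[b.tex];
  return tex_bright(sc, tx, p[ua] - b.lo[ua], p[va] - b.lo[va], t, d[axis],
                    d[ua], d[va]);
}

static Hit cast_one(const Scene& sc, const double* o, const double* d) {
  Hit h; h.t = std::numeric_limits<double>::infinity(); h.bright = sc.background;
  // outer walls
  if (sc.has_walls) {
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-14) continue;
      for (int s = 0; s < 2; ++s) {
        double c = s ? sc.hi[a] : sc.lo[a];
        double t = (c - o[a]) / d[a];
        if (t < EPS_T || t >= h.t) continue;
        double p[3] = { o[0] + t * d[0], o[1] + t * d[1], o[2] + t * d[2] };
        int ua = (a + 1) % 3, va = (a + 2) % 3;
        if (p[ua] < sc.lo[ua] - 1e-9 || p[ua] > sc.hi[ua] + 1e-9) continue;
        if (p[va] < sc.lo[va] - 1e-9 || p[va] > sc.hi[va] + 1e-9) continue;
        h.t = t;
        const Texture& tx = sc.textures[sc.wall_tex[2 * a + s]];
        h.bright = tex_bright(sc, tx, p[ua] - sc.lo[ua], p[va] - sc.lo[va],
                              t, d[a], d[ua], d[va]);
      }
    }
  }
  size_t nb = sc.boxes.size();
  if (nb == 0) return h;
  if (nb <= 8 || sc.cells.empty()) {            // brute force
    for (size_t b = 0; b < nb; ++b) {
      int axis; double t = box_hit(sc.boxes[b].lo, sc.boxes[b].hi, o, d, axis);
      if (t > 0 && t < h.t) {
        double p[3] = { o[0] + t * d[0], o[1] + t * d[1], o[2] + t * d[2] };
        h.t = t;
        h.bright = obs_bright(sc, sc.boxes[b], p, axis, t, d);
      }
    }
    return h;
  }
  // 2-D DDA over the ground-plane grid
  sc.stamp++;
  double gx0 = sc.lo[0], gy0 = sc.lo[1];
  double t0 = 0.0;
  // clip to grid bounds in xy (origin is inside for walled scenes)
  double txy_hi = h.t;
  for (int a = 0; a < 2; ++a) {
    if (std::fabs(d[a]) < 1e-14) {
      if (o[a] < sc.lo[a] || o[a] > sc.hi[a]) return h;
    } else {
      double inv = 1.0 / d[a];
      double t1 = (sc.lo[a] - o[a]) * inv, t2 = (sc.hi[a] - o[a]) * inv;
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > t0) t0 = t1;
      if (t2 < txy_hi) txy_hi = t2;
    }
  }
  if (t0 > txy_hi) return h;
  double sx = o[0] + t0 * d[0], sy = o[1] + t0 * d[1];
  int ix = std::min(sc.nx - 1, std::max(0, (int)std::floor((sx - gx0) / sc.cx)));
  int iy = std::min(sc.ny - 1, std::max(0, (int)std::floor((sy - gy0) / sc.cy)));
  int stepx = d[0] > 0 ? 1 : -1, stepy = d[1] > 0 ? 1 : -1;
  double tMaxX, tMaxY, tDx, tDy;
  if (std::fabs(d[0]) < 1e-14) { tMaxX = std::numeric_limits<double>::infinity(); tDx = tMaxX; }
  else {
    double nxt = gx0 + (ix + (stepx > 0 ? 1 : 0)) * sc.cx;
    tMaxX = (nxt - o[0]) / d[0]; tDx = sc.cx / std::fabs(d[0]);
  }
  if (std::fabs(d[1]) < 1e-14) { tMaxY = std::numeric_limits<double>::infinity(); tDy = tMaxY; }
  else {
    double nyt = gy0 + (iy + (stepy > 0 ? 1 : 0)) * sc.cy;
    tMaxY = (nyt - o[1]) / d[1]; tDy = sc.cy / std::fabs(d[1]);
  }
  double tcell = t0;
  while (true) {
    if (tcell > h.t) break;
    const std::vector<int>& cell = sc.cells[(size_t)iy * sc.nx + ix];
    for (int b : cell) {
      if (sc.mailbox[b] == sc.stamp) continue;
      sc.mailbox[b] = sc.stamp;
      int axis; double t = box_hit(sc.boxes[b].lo, sc.boxes[b].hi, o, d, axis);
      if (t > 0 && t < h.t) {
        double p[3] = { o[0] + t * d[0], o[1] + t * d[1], o[2] + t * d[2] };
        h.t = t;
        h.bright = obs_bright(sc, sc.boxes[b], p, axis, t, d);
      }
    }
    if (tMaxX < tMaxY) {
      tcell = tMaxX; tMaxX += tDx; ix += stepx;
      if (ix < 0 || ix >= sc.nx) break;
    } else {
      tcell = tMaxY; tMaxY += tDy; iy += stepy;
      if (iy < 0 || iy >= sc.ny) break;
    }
    if (tcell > txy_hi + 1e-12) break;
  }
  return h;
}

static Scene* make_scene(List desc) {
  Scene* sc = new Scene();
  List tex = desc["textures"];
  for (int i = 0; i < tex.size(); ++i) {
    List t = tex[i];
    NumericMatrix g = t["grid"];
    Texture T;
    T.nrow = g.nrow(); T.ncol = g.ncol();
    T.texel = as<double>(t["texel"]);
    T.v.resize((size_t)T.nrow * T.ncol);
    for (int r = 0; r < T.nrow; ++r)
      for (int c = 0; c < T.ncol; ++c)
        T.v[(size_t)r * T.ncol + c] =
          (unsigned char)std::lround(g(r, c) * 255.0);
    T.build_sat();
    sc->textures.push_back(std::move(T));
  }
  sc->has_walls = as<bool>(desc["has_walls"]);
  NumericVector lo = desc["lo"], hi = desc["hi"];
  for (int a = 0; a < 3; ++a) { sc->lo[a] = lo[a]; sc->hi[a] = hi[a]; }
  IntegerVector wt = desc["wall_tex"];
  for (int f = 0; f < 6; ++f) sc->wall_tex[f] = wt[f];
  List bx = desc["boxes"];
  for (int b = 0; b < bx.size(); ++b) {
    List bb = bx[b];
    NumericVector blo = bb["lo"], bhi = bb["hi"];
    BoxObs o;
    for (int a = 0; a < 3; ++a) { o.lo[a] = blo[a]; o.hi[a] = bhi[a]; }
    o.tex = as<int>(bb["tex"]);
    sc->boxes.push_back(o);
  }
  sc->background = as<double>(desc["background"]);
  sc->footprint = as<double>(desc["footprint"]) * M_PI / 180.0;
  sc->build_grid();
  return sc;
}

// [[Rcpp::export]]
SEXP cpp_scene_build(List desc) {
  XPtr<Scene> p(make_scene(desc), true);
  return p;
}

// [[Rcpp::export]]
List cpp_cast_rays(SEXP scene, NumericVector origin, NumericMatrix dirs) {
  XPtr<Scene> sc(scene);
  int n = dirs.nrow();
  NumericVector dist(n), bright(n);
  double o[3] = { origin[0], origin[1], origin[2] };
  for (int i = 0; i < n; ++i) {
    double d[3] = { dirs(i, 0), dirs(i, 1), dirs(i, 2) };
    Hit h = cast_one(*sc, o, d);
    dist[i] = h.t;
    bright[i] = h.bright;
  }
  return List::create(_["distance"] = dist, _["brightness"] = bright);
}

// minimal distance from an interior point to any scene surface
static double scene_dist(const Scene& sc, const double* p) {
  double dmin = std::numeric_limits<double>::infinity();
  if (sc.has_walls)
    for (int a = 0; a < 3; ++a) {
      dmin = std::min(dmin, p[a] - sc.lo[a]);
      dmin = std::min(dmin, sc.hi[a] - p[a]);
    }
  for (const BoxObs& b : sc.boxes) {
    double s = 0.0; bool inside = true;
    for (int a = 0; a < 3; ++a) {
      double e = std::max(b.lo[a] - p[a], p[a] - b.hi[a]);
      if (e > 0) { s += e * e; inside = false; }
    }
    dmin = std::min(dmin, inside ? 0.0 : std::sqrt(s));
  }
  return dmin;
}

// [[Rcpp::export]]
double cpp_scene_distance(SEXP scene, NumericVector point) {
  XPtr<Scene> sc(scene);
  double p[3] = { point[0], point[1], point[2] };
  return scene_dist(*sc, p);
}

// render one panoramic brightness image; stencil is 3 x (nrec * ns),
// receptor-major columns (receptors in R column-major grid order), ns
// sub-rays per receptor with Gaussian weights
static void render_into(const Scene& sc, const double* pos, double heading,
                        const double* stencil, const double* w,
                        int nrec, int ns, double* out) {
  double ch = std::cos(heading), sh = std::sin(heading);
  for (int r = 0; r < nrec; ++r) {
    double acc = 0.0;
    for (int s = 0; s < ns; ++s) {
      const double* b = stencil + 3 * ((size_t)r * ns + s);
      double d[3] = { ch * b[0] - sh * b[1], sh * b[0] + ch * b[1], b[2] };
      Hit h = cast_one(sc, pos, d);
      acc += w[s] * h.bright;
    }
    out[r] = acc;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_render(SEXP scene, NumericVector pos, double heading,
                         NumericMatrix stencil, NumericVector weights,
                         int nrow, int ncol) {
  XPtr<Scene> sc(scene);
  int ns = weights.size();
  int nrec = nrow * ncol;
  NumericMatrix out(nrow, ncol);
  // stencil rows are receptor-major in column-major (eps-fastest) order to
  // match R matrix layout
  std::vector<double> buf((size_t)nrec);
  double p[3] = { pos[0], pos[1], pos[2] };
  render_into(*sc, p, heading, REAL(stencil), REAL(weights), nrec, ns, buf.data());
  std::copy(buf.begin(), buf.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_distances(SEXP scene, NumericVector pos, double heading,
                            NumericMatrix dirs, int nrow, int ncol) {
  XPtr<Scene> sc(scene);
  NumericMatrix out(nrow, ncol);
  double ch = std::cos(heading), sh = std::sin(heading);
  double o[3] = { pos[0], pos[1], pos[2] };
  int n = nrow * ncol;
  for (int i = 0; i < n; ++i) {
    double d[3] = { ch * dirs(i, 0) - sh * dirs(i, 1),
                    sh * dirs(i, 0) + ch * dirs(i, 1), dirs(i, 2) };
    Hit h = cast_one(*sc, o, d);
    out[i] = h.t;
  }
  return out;
}

// One flight phase of the EMD-based closed loop: per 1-ms tick, translate,
// yaw, render, run the photoreceptor / high-pass / correlator cascade, and
// (on flagged ticks) accumulate squared correlator responses re-gridded to
// receptor positions. Filter states keep running across phases so saccadic
// motion history contaminates the following intersaccade, as it should.
// [[Rcpp::export]]
List cpp_emd_phase(SEXP scene, NumericVector pose, double speed, double dt,
                   NumericVector dir_off_deg, NumericVector yaw_dps,
                   LogicalVector accumulate, List state,
                   NumericMatrix stencil, NumericVector weights,
                   List params, double collision_radius) {
  XPtr<Scene> sc(scene);
  int nr = as<int>(params["nrow"]), nc = as<int>(params["ncol"]);
  int nrec = nr * nc, ns = weights.size();
  double a_pr = std::exp(-dt / as<double>(params["tau_pr"]));
  double a_hp = std::exp(-dt / as<double>(params["tau_hp"]));
  double a_lp = std::exp(-dt / as<double>(params["tau_lp"]));
  NumericMatrix pr = clone(as<NumericMatrix>(state["pr"]));
  NumericMatrix hp_lp = clone(as<NumericMatrix>(state["hp_lp"]));
  NumericMatrix dly = clone(as<NumericMatrix>(state["lp"]));
  double* PR = REAL(pr); double* HPLP = REAL(hp_lp); double* D = REAL(dly);
  std::vector<double> img((size_t)nrec), H((size_t)nrec);
  std::vector<double> rh((size_t)nr * (nc - 1)), rv((size_t)(nr - 1) * nc);
  NumericMatrix hsq(nr, nc), vsq(nr, nc);
  double* HS = REAL(hsq); double* VS = REAL(vsq);
  int n = dir_off_deg.size(), nacc = 0, crash = -1;
  double x = pose[0], y = pose[1], z = pose[2], heading = pose[3];
  NumericMatrix path(n, 3);
  const double d2r = M_PI / 180.0;
  const double dt_s = dt / 1000.0;    // dt is in ms (filter time constants)
  for (int t = 0; t < n; ++t) {
    double mdir = heading + dir_off_deg[t] * d2r;
    x += speed * dt_s * std::cos(mdir);
    y += speed * dt_s * std::sin(mdir);
    heading += yaw_dps[t] * d2r * dt_s;
    double p[3] = { x, y, z };
    if (scene_dist(*sc, p) < collision_radius) { crash = t + 1; }
    path(t, 0) = x; path(t, 1) = y; path(t, 2) = heading / d2r;
    render_into(*sc, p, heading, REAL(stencil), REAL(weights), nrec, ns, img.data());
    for (int i = 0; i < nrec; ++i) {
      PR[i] = a_pr * PR[i] + (1 - a_pr) * img[i];
      HPLP[i] = a_hp * HPLP[i] + (1 - a_hp) * PR[i];
      H[i] = PR[i] - HPLP[i];
      D[i] = a_lp * D[i] + (1 - a_lp) * H[i];
    }
    if (crash > 0) break;
    if (!accumulate[t]) continue;
    nacc++;
    // column-major layout: element (i, j) at i + nr * j
    // horizontal correlators pair azimuth neighbours (columns j, j + 1);
    // positive response = motion toward increasing azimuth
    for (int j = 0; j < nc - 1; ++j)
      for (int i = 0; i < nr; ++i) {
        size_t a = (size_t)i + (size_t)nr * j, b = a + nr;
        rh[(size_t)i + (size_t)nr * j] = D[a] * H[b] - D[b] * H[a];
      }
    // vertical correlators pair elevation neighbours (rows i, i + 1)
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr - 1; ++i) {
        size_t a = (size_t)i + (size_t)nr * j, b = a + 1;
        rv[(size_t)i + (size_t)(nr - 1) * j] = D[a] * H[b] - D[b] * H[a];
      }
    // re-grid to receptor positions: signed mean of the flanking detectors,
    // then squared; azimuth wraps (column nc - 1 duplicates column 0)
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        int jl = j - 1, jr = j;
        if (jl < 0) jl = nc - 2;          // wrap across +-180
        if (jr > nc - 2) jr = 0;
        double h2 = 0.5 * (rh[(size_t)i + (size_t)nr * jl] +
                           rh[(size_t)i + (size_t)nr * jr]);
        double v2;
        if (i == 0)            v2 = rv[(size_t)0 + (size_t)(nr - 1) * j];
        else if (i == nr - 1)  v2 = rv[(size_t)(nr - 2) + (size_t)(nr - 1) * j];
        else v2 = 0.5 * (rv[(size_t)(i - 1) + (size_t)(nr - 1) * j] +
                         rv[(size_t)i + (size_t)(nr - 1) * j]);
        HS[(size_t)i + (size_t)nr * j] += h2 * h2;
        VS[(size_t)i + (size_t)nr * j] += v2 * v2;
      }
  }
  if (nacc > 0) {
    for (int i = 0; i < nrec; ++i) { HS[i] /= nacc; VS[i] /= nacc; }
  }
  return List::create(
    _["pose"] = NumericVector::create(x, y, z, heading),
    _["state"] = List::create(_["pr"] = pr, _["hp_lp"] = hp_lp, _["lp"] = dly),
    _["hsq"] = hsq, _["vsq"] = vsq, _["n_accumulated"] = nacc,
    _["crash_tick"] = crash, _["path"] = path);
}
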