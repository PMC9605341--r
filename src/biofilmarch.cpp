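// Compiled core: spherocylinder contact geometry, pair/surface force laws,
// the overdamped colony-growth integrator, and a 3D convex hull.
//
// Cells are rod-shaped: a segment of length ell = len - w (the cell axis
// between the two cap centres) dilated by a sphere of diameter w.  Contact
// separation delta between two cells is the minimal axis-segment distance
// minus the mean width; delta < 0 means steric overlap.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1]*b[2] - a[2]*b[1];
  out[1] = a[2]*b[0] - a[0]*b[2];
  out[2] = a[0]*b[1] - a[1]*b[0];
}
static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// Closest points between segments [p1,q1] and [p2,q2] (Ericson, RTCD 5.1.9).
static void seg_closest_pts(const double* p1, const double* q1,
                            const double* p2, const double* q2,
                            double* c1, double* c2) {
  double d1[3], d2[3], r[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = q1[k] - p1[k];
    d2[k] = q2[k] - p2[k];
    r[k]  = p1[k] - p2[k];
  }
  const double EPS = 1e-14;
  double a = dot3(d1, d1), e = dot3(d2, d2), f = dot3(d2, r);
  double s = 0.0, t = 0.0;
  if (a <= EPS && e <= EPS) {
    s = t = 0.0;
  } else if (a <= EPS) {
    t = clamp01(f / e);
  } else {
    double c = dot3(d1, r);
    if (e <= EPS) {
      s = clamp01(-c / a);
    } else {
      double b = dot3(d1, d2);
      double denom = a * e - b * b;
      s = (denom > EPS) ? clamp01((b * f - c * e) / denom) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0)      { t = 0.0; s = clamp01(-c / a); }
      else if (t > 1.0) { t = 1.0; s = clamp01((b - c) / a); }
    }
  }
  for (int k = 0; k < 3; ++k) {
    c1[k] = p1[k] + s * d1[k];
    c2[k] = p2[k] + t * d2[k];
  }
}

static void cell_endpoints(const double* pos, const double* dir,
                           double len, double w, double* p, double* q) {
  double h = 0.5 * std::max(len - w, 0.0);
  for (int k = 0; k < 3; ++k) {
    p[k] = pos[k] - h * dir[k];
    q[k] = pos[k] + h * dir[k];
  }
}

//' @noRd
// [[Rcpp::export]]
List seg_closest_cpp(NumericVector posA, NumericVector dirA, double lenA, double wA,
                     NumericVector posB, NumericVector dirB, double lenB, double wB) {
  double p1[3], q1[3], p2[3], q2[3], c1[3], c2[3];
  cell_endpoints(REAL(posA), REAL(dirA), lenA, wA, p1, q1);
  cell_endpoints(REAL(posB), REAL(dirB), lenB, wB, p2, q2);
  seg_closest_pts(p1, q1, p2, q2, c1, c2);
  double d[3] = { c1[0] - c2[0], c1[1] - c2[1], c1[2] - c2[2] };
  double dist = norm3(d);
  return List::create(_["dist"] = dist,
                      _["cA"] = NumericVector::create(c1[0], c1[1], c1[2]),
                      _["cB"] = NumericVector::create(c2[0], c2[1], c2[2]));
}

// Axis-segment distances from one candidate cell to many cells.
//' @noRd
// [[Rcpp::export]]
NumericVector segdist_many_cpp(NumericVector pos, NumericVector dir, double len, double w,
                               NumericMatrix P, NumericMatrix D,
                               NumericVector lens, NumericVector ws) {
  int n = P.nrow();
  NumericVector out(n);
  double p1[3], q1[3], p2[3], q2[3], c1[3], c2[3];
  cell_endpoints(REAL(pos), REAL(dir), len, w, p1, q1);
  for (int i = 0; i < n; ++i) {
    double pp[3] = { P(i, 0), P(i, 1), P(i, 2) };
    double dd[3] = { D(i, 0), D(i, 1), D(i, 2) };
    cell_endpoints(pp, dd, lens[i], ws[i], p2, q2);
    seg_closest_pts(p1, q1, p2, q2, c1, c2);
    double d[3] = { c1[0] - c2[0], c1[1] - c2[1], c1[2] - c2[2] };
    out[i] = norm3(d);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Force laws.  Parameters are passed as a flat struct extracted from an R
// list once per call chain.

struct SimPar {
  double k_rep, r_rep, r_att, f_att;
  double f_surf, r_surf;
  double zeta_par, zeta_ratio, zeta_rot_factor;
  double gamma, L_div, width, dt, sigma_div, sigma_ori;
  int    n_target;
  double max_hours;
};

static SimPar par_from_list(List p) {
  SimPar s;
  s.k_rep      = as<double>(p["k_rep"]);
  s.r_rep      = as<double>(p["r_rep"]);
  s.r_att      = as<double>(p["r_att"]);
  s.f_att      = as<double>(p["f_att"]);
  s.f_surf     = as<double>(p["f_surf"]);
  s.r_surf     = as<double>(p["r_surf"]);
  s.zeta_par   = as<double>(p["zeta_par"]);
  s.zeta_ratio = as<double>(p["zeta_ratio"]);
  s.zeta_rot_factor = as<double>(p["zeta_rot_factor"]);
  s.gamma      = as<double>(p["gamma"]);
  s.L_div      = as<double>(p["L_div"]);
  s.width      = as<double>(p["width"]);
  s.dt         = as<double>(p["dt"]);
  s.sigma_div  = as<double>(p["sigma_div"]);
  s.sigma_ori  = as<double>(p["sigma_ori"]);
  s.n_target   = as<int>(p["n_target"]);
  s.max_hours  = as<double>(p["max_hours"]);
  return s;
}

// Scalar force magnitude on the separation coordinate; positive = repulsive.
// Repulsion: Hertzian k (r_rep - delta)^{3/2} inside the repulsion range.
// Attraction: linear ramp f (1 - (delta - r_rep)/r_att), clamped at full
// strength inside the repulsion zone so the total force is continuous.
static inline double contact_force_mag(double delta, double k, double rrep,
                                       double ratt, double fatt) {
  double fm = 0.0;
  if (delta < rrep) fm += k * std::pow(rrep - delta, 1.5);
  if (fatt > 0.0 && delta < rrep + ratt) {
    double u = (delta - rrep) / ratt;       // may be negative inside overlap
    double ramp = u < 0.0 ? 1.0 : 1.0 - u;
    fm -= fatt * ramp;
  }
  return fm;
}

// Matching potential, continuous, zero beyond r_rep + r_att.
static inline double contact_potential(double delta, double k, double rrep,
                                       double ratt, double fatt) {
  double U = 0.0;
  if (delta < rrep) U += 0.4 * k * std::pow(rrep - delta, 2.5);
  if (fatt > 0.0 && delta < rrep + ratt) {
    if (delta >= rrep) {
      double u = 1.0 - (delta - rrep) / ratt;
      U -= 0.5 * fatt * ratt * u * u;
    } else {
      U -= 0.5 * fatt * ratt + fatt * (rrep - delta);
    }
  }
  return U;
}

// Fallback contact normal for coincident axes: deterministic unit vector
// perpendicular to dA.
static void fallback_normal(const double* dA, double* n) {
  double ref[3] = { 0.0, 0.0, 1.0 };
  if (std::fabs(dA[2]) > 0.9) { ref[0] = 1.0; ref[1] = 0.0; ref[2] = 0.0; }
  cross3(dA, ref, n);
  double nn = norm3(n);
  if (nn < 1e-12) { n[0] = 1.0; n[1] = 0.0; n[2] = 0.0; return; }
  for (int k = 0; k < 3; ++k) n[k] /= nn;
}

// Full pair interaction.  Returns false when out of interaction range.
static bool pair_force_core(const double* pA, const double* dA, double lenA, double wA,
                            const double* pB, const double* dB, double lenB, double wB,
                            const SimPar& par,
                            double* FA, double* TA, double* FB, double* TB,
                            double* delta_out, double* n_out) {
  double p1[3], q1[3], p2[3], q2[3], c1[3], c2[3];
  cell_endpoints(pA, dA, lenA, wA, p1, q1);
  cell_endpoints(pB, dB, lenB, wB, p2, q2);
  seg_closest_pts(p1, q1, p2, q2, c1, c2);
  double dv[3] = { c1[0] - c2[0], c1[1] - c2[1], c1[2] - c2[2] };
  double dist = norm3(dv);
  double wbar = 0.5 * (wA + wB);
  double delta = dist - wbar;
  if (delta_out) *delta_out = delta;
  double n[3];
  if (dist > 1e-12) {
    for (int k = 0; k < 3; ++k) n[k] = dv[k] / dist;
  } else {
    fallback_normal(dA, n);
  }
  if (n_out) for (int k = 0; k < 3; ++k) n_out[k] = n[k];
  for (int k = 0; k < 3; ++k) { FA[k] = TA[k] = FB[k] = TB[k] = 0.0; }
  if (delta >= par.r_rep + par.r_att) return false;
  double fmag = contact_force_mag(delta, par.k_rep, par.r_rep, par.r_att, par.f_att);
  double rA[3], rB[3], f[3];
  for (int k = 0; k < 3; ++k) {
    f[k]  = fmag * n[k];     // force on A
    FA[k] = f[k];
    FB[k] = -f[k];
    rA[k] = c1[k] - pA[k];
    rB[k] = c2[k] - pB[k];
  }
  double tA[3], tB[3], fneg[3] = { -f[0], -f[1], -f[2] };
  cross3(rA, f, tA);
  cross3(rB, fneg, tB);
  for (int k = 0; k < 3; ++k) { TA[k] = tA[k]; TB[k] = tB[k]; }
  return true;
}

//' @noRd
// [[Rcpp::export]]
List pair_force_cpp(NumericVector posA, NumericVector dirA, double lenA, double wA,
                    NumericVector posB, NumericVector dirB, double lenB, double wB,
                    List params) {
  SimPar par = par_from_list(params);
  double FA[3], TA[3], FB[3], TB[3], delta, n[3];
  pair_force_core(REAL(posA), REAL(dirA), lenA, wA,
                  REAL(posB), REAL(dirB), lenB, wB,
                  par, FA, TA, FB, TB, &delta, n);
  return List::create(
    _["force_A"]  = NumericVector::create(FA[0], FA[1], FA[2]),
    _["torque_A"] = NumericVector::create(TA[0], TA[1], TA[2]),
    _["force_B"]  = NumericVector::create(FB[0], FB[1], FB[2]),
    _["torque_B"] = NumericVector::create(TB[0], TB[1], TB[2]),
    _["delta"]    = delta,
    _["normal"]   = NumericVector::create(n[0], n[1], n[2]));
}

//' @noRd
// [[Rcpp::export]]
double pair_potential_cpp(NumericVector posA, NumericVector dirA, double lenA, double wA,
                          NumericVector posB, NumericVector dirB, double lenB, double wB,
                          List params) {
  SimPar par = par_from_list(params);
  double p1[3], q1[3], p2[3], q2[3], c1[3], c2[3];
  cell_endpoints(REAL(posA), REAL(dirA), lenA, wA, p1, q1);
  cell_endpoints(REAL(posB), REAL(dirB), lenB, wB, p2, q2);
  seg_closest_pts(p1, q1, p2, q2, c1, c2);
  double dv[3] = { c1[0] - c2[0], c1[1] - c2[1], c1[2] - c2[2] };
  double delta = norm3(dv) - 0.5 * (wA + wB);
  return contact_potential(delta, par.k_rep, par.r_rep, par.r_att, par.f_att);
}

// Surface interaction: each cap-sphere centre (axis endpoint) at height h
// feels Hertzian repulsion below w/2 and a clamped linear adhesive ramp up
// to w/2 + r_surf; force is vertical and applied at the endpoint.
static void surface_force_core(const double* pos, const double* dir,
                               double len, double w, const SimPar& par,
                               double* F, double* T) {
  double p[3], q[3];
  cell_endpoints(pos, dir, len, w, p, q);
  const double* ends[2] = { p, q };
  for (int k = 0; k < 3; ++k) { F[k] = T[k] = 0.0; }
  for (int e = 0; e < 2; ++e) {
    double h = ends[e][2];
    double fz = 0.0;
    if (h < 0.5 * w) fz += par.k_rep * std::pow(0.5 * w - h, 1.5);
    if (par.f_surf > 0.0 && h < 0.5 * w + par.r_surf) {
      double u = (h - 0.5 * w) / par.r_surf;
      double ramp = u < 0.0 ? 1.0 : 1.0 - u;
      fz -= par.f_surf * ramp;
    }
    if (fz != 0.0) {
      double r[3] = { ends[e][0] - pos[0], ends[e][1] - pos[1], ends[e][2] - pos[2] };
      double f[3] = { 0.0, 0.0, fz };
      double t[3];
      cross3(r, f, t);
      F[2] += fz;
      for (int k = 0; k < 3; ++k) T[k] += t[k];
    }
  }
}

//' @noRd
// [[Rcpp::export]]
List surface_force_cpp(NumericVector pos, NumericVector dir, double len, double w,
                       List params) {
  SimPar par = par_from_list(params);
  double F[3], T[3];
  surface_force_core(REAL(pos), REAL(dir), len, w, par, F, T);
  return List::create(
    _["force"]  = NumericVector::create(F[0], F[1], F[2]),
    _["torque"] = NumericVector::create(T[0], T[1], T[2]));
}

//' @noRd
// [[Rcpp::export]]
double surface_potential_cpp(NumericVector pos, NumericVector dir, double len, double w,
                             List params) {
  SimPar par = par_from_list(params);
  double p[3], q[3];
  cell_endpoints(REAL(pos), REAL(dir), len, w, p, q);
  double U = 0.0;
  double hs[2] = { p[2], q[2] };
  for (int e = 0; e < 2; ++e) {
    double delta = hs[e] - 0.5 * w;   // height above contact
    U += contact_potential(delta, par.k_rep, 0.0, par.r_surf, par.f_surf);
  }
  return U;
}

// ---------------------------------------------------------------------------
// Colony state and integrator.

struct Colony {
  std::vector<double> px, py, pz, dx, dy, dz, len, wid, thr;
  double t = 0.0;
  size_t size() const { return px.size(); }
};

static Colony colony_from_list(List st) {
  Colony C;
  NumericMatrix pos = st["pos"], dir = st["dir"];
  NumericVector len = st["length"], wid = st["width"], thr = st["threshold"];
  int n = pos.nrow();
  C.px.resize(n); C.py.resize(n); C.pz.resize(n);
  C.dx.resize(n); C.dy.resize(n); C.dz.resize(n);
  C.len.resize(n); C.wid.resize(n); C.thr.resize(n);
  for (int i = 0; i < n; ++i) {
    C.px[i] = pos(i, 0); C.py[i] = pos(i, 1); C.pz[i] = pos(i, 2);
    C.dx[i] = dir(i, 0); C.dy[i] = dir(i, 1); C.dz[i] = dir(i, 2);
    C.len[i] = len[i]; C.wid[i] = wid[i]; C.thr[i] = thr[i];
  }
  C.t = as<double>(st["time"]);
  return C;
}

static List colony_to_list(const Colony& C) {
  int n = (int) C.size();
  NumericMatrix pos(n, 3), dir(n, 3);
  NumericVector len(n), wid(n), thr(n);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = C.px[i]; pos(i, 1) = C.py[i]; pos(i, 2) = C.pz[i];
    dir(i, 0) = C.dx[i]; dir(i, 1) = C.dy[i]; dir(i, 2) = C.dz[i];
    len[i] = C.len[i]; wid[i] = C.wid[i]; thr[i] = C.thr[i];
  }
  return List::create(_["pos"] = pos, _["dir"] = dir, _["length"] = len,
                      _["width"] = wid, _["threshold"] = thr, _["time"] = C.t);
}

struct BinKey {
  int64_t v;
  bool operator==(const BinKey& o) const { return v == o.v; }
};
struct BinHash {
  size_t operator()(const BinKey& k) const { return std::hash<int64_t>()(k.v); }
};
static inline BinKey make_key(int ix, int iy, int iz) {
  BinKey k;
  k.v = ((int64_t)(ix + 1048576) << 42) | ((int64_t)(iy + 1048576) << 21) |
        (int64_t)(iz + 1048576);
  return k;
}

// One force evaluation over the whole colony; fills F and T (length 3n) and
// returns the pair interaction count.  Grid-accelerated.
static void colony_forces(const Colony& C, const SimPar& par,
                          std::vector<double>& F, std::vector<double>& T) {
  size_t n = C.size();
  F.assign(3 * n, 0.0);
  T.assign(3 * n, 0.0);
  double maxlen = 0.0;
  for (size_t i = 0; i < n; ++i) maxlen = std::max(maxlen, C.len[i]);
  double reach = maxlen + par.r_rep + par.r_att;   // conservative centre reach
  double bin = std::max(reach, 1e-6);
  std::unordered_map<BinKey, std::vector<int>, BinHash> grid;
  grid.reserve(2 * n);
  for (size_t i = 0; i < n; ++i) {
    int ix = (int) std::floor(C.px[i] / bin);
    int iy = (int) std::floor(C.py[i] / bin);
    int iz = (int) std::floor(C.pz[i] / bin);
    grid[make_key(ix, iy, iz)].push_back((int) i);
  }
  double FA[3], TA[3], FB[3], TB[3];
  for (size_t i = 0; i < n; ++i) {
    double pA[3] = { C.px[i], C.py[i], C.pz[i] };
    double dA[3] = { C.dx[i], C.dy[i], C.dz[i] };
    int ix = (int) std::floor(C.px[i] / bin);
    int iy = (int) std::floor(C.py[i] / bin);
    int iz = (int) std::floor(C.pz[i] / bin);
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          auto it = grid.find(make_key(ix + ox, iy + oy, iz + oz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= (int) i) continue;
            double dx = C.px[j] - C.px[i];
            double dy = C.py[j] - C.py[i];
            double dz = C.pz[j] - C.pz[i];
            double lim = 0.5 * (C.len[i] + C.len[j]) + par.r_rep + par.r_att;
            if (dx * dx + dy * dy + dz * dz > lim * lim) continue;
            double pB[3] = { C.px[j], C.py[j], C.pz[j] };
            double dB[3] = { C.dx[j], C.dy[j], C.dz[j] };
            if (pair_force_core(pA, dA, C.len[i], C.wid[i],
                                pB, dB, C.len[j], C.wid[j], par,
                                FA, TA, FB, TB, nullptr, nullptr)) {
              for (int k = 0; k < 3; ++k) {
                F[3 * i + k] += FA[k];
                T[3 * i + k] += TA[k];
                F[3 * j + k] += FB[k];
                T[3 * j + k] += TB[k];
              }
            }
          }
        }
    double Fs[3], Ts[3];
    surface_force_core(pA, dA, C.len[i], C.wid[i], par, Fs, Ts);
    for (int k = 0; k < 3; ++k) {
      F[3 * i + k] += Fs[k];
      T[3 * i + k] += Ts[k];
    }
  }
  for (size_t i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      if (!std::isfinite(F[3 * i + k]) || !std::isfinite(T[3 * i + k]))
        stop("non-finite force on cell %d (parameter blow-up?)", (int) i + 1);
    }
  }
}

// Overdamped mechanics over dt with adaptive substepping: no cell moves more
// than width/10 per substep.
static void mechanics_step(Colony& C, const SimPar& par, double dt) {
  size_t n = C.size();
  std::vector<double> F, T;
  double remaining = dt;
  int guard = 0;
  while (remaining > 1e-15) {
    if (++guard > 100000) stop("mechanics substepping failed to converge");
    colony_forces(C, par, F, T);
    double vmax = 0.0;
    std::vector<double> vx(n), vy(n), vz(n), wx(n), wy(n), wz(n);
    for (size_t i = 0; i < n; ++i) {
      double d[3] = { C.dx[i], C.dy[i], C.dz[i] };
      double Fi[3] = { F[3 * i], F[3 * i + 1], F[3 * i + 2] };
      double L = std::max(C.len[i], 1e-9);
      double fpar = dot3(Fi, d);
      double zpar = par.zeta_par * L;
      double zperp = par.zeta_par * par.zeta_ratio * L;
      double v[3];
      for (int k = 0; k < 3; ++k) {
        double Fperp = Fi[k] - fpar * d[k];
        v[k] = fpar * d[k] / zpar + Fperp / zperp;
      }
      double Ti[3] = { T[3 * i], T[3 * i + 1], T[3 * i + 2] };
      double tpar = dot3(Ti, d);
      double zrot = par.zeta_rot_factor * par.zeta_par * par.zeta_ratio * L * L * L;
      double om[3];
      for (int k = 0; k < 3; ++k) om[k] = (Ti[k] - tpar * d[k]) / zrot;
      vx[i] = v[0]; vy[i] = v[1]; vz[i] = v[2];
      wx[i] = om[0]; wy[i] = om[1]; wz[i] = om[2];
      double speed = norm3(v) + norm3(om) * 0.5 * L;
      vmax = std::max(vmax, speed);
    }
    double cap = (vmax > 0.0) ? (0.1 * par.width / vmax) : remaining;
    double h = std::min(remaining, cap);
    for (size_t i = 0; i < n; ++i) {
      C.px[i] += vx[i] * h;
      C.py[i] += vy[i] * h;
      C.pz[i] += vz[i] * h;
      double d[3] = { C.dx[i], C.dy[i], C.dz[i] };
      double om[3] = { wx[i], wy[i], wz[i] };
      double dd[3];
      cross3(om, d, dd);
      for (int k = 0; k < 3; ++k) d[k] += dd[k] * h;
      double nn = norm3(d);
      if (nn < 1e-12) { d[0] = 1.0; d[1] = 0.0; d[2] = 0.0; nn = 1.0; }
      C.dx[i] = d[0] / nn; C.dy[i] = d[1] / nn; C.dz[i] = d[2] / nn;
    }
    remaining -= h;
  }
}

// Exponential elongation over dt, then division of all cells at or above
// their division threshold.  Consumes R RNG draws in cell-index order:
// per daughter (tilt angle, tilt azimuth, threshold factor).
static void grow_divide(Colony& C, const SimPar& par, double dt) {
  size_t n0 = C.size();
  double g = std::exp(par.gamma * dt);
  for (size_t i = 0; i < n0; ++i) C.len[i] *= g;
  for (size_t i = 0; i < n0; ++i) {
    if (C.len[i] < C.thr[i]) continue;
    double L = C.len[i], w = C.wid[i];
    // Daughters of half the mother length placed end-to-end: their
    // spherocylinders exactly tile the mother (sibling separation delta = 0)
    // and a newborn needs ln(2)/gamma to regrow to the division length, so
    // the population doubling time equals ln(2)/gamma.
    double newlen = std::max(0.5 * L, 1.01 * w);
    double d[3] = { C.dx[i], C.dy[i], C.dz[i] };
    double c[3] = { C.px[i], C.py[i], C.pz[i] };
    // orthonormal frame around the mother axis
    double u[3], v[3];
    fallback_normal(d, u);
    cross3(d, u, v);
    double off = 0.25 * L;
    for (int dgt = 0; dgt < 2; ++dgt) {
      double sgn = dgt == 0 ? -1.0 : 1.0;
      double theta = R::rnorm(0.0, par.sigma_ori);
      double phi = R::runif(0.0, 2.0 * M_PI);
      double nd[3];
      for (int k = 0; k < 3; ++k)
        nd[k] = std::cos(theta) * d[k] +
                std::sin(theta) * (std::cos(phi) * u[k] + std::sin(phi) * v[k]);
      double nn = norm3(nd);
      for (int k = 0; k < 3; ++k) nd[k] /= nn;
      double thr = par.L_div * std::exp(R::rnorm(0.0, par.sigma_div));
      thr = std::max(thr, 1.2 * newlen);
      double pos[3] = { c[0] + sgn * off * d[0], c[1] + sgn * off * d[1],
                        c[2] + sgn * off * d[2] };
      if (pos[2] < 0.0) pos[2] = 0.0;   // substrate floor for the centroid
      if (dgt == 0) {
        C.px[i] = pos[0]; C.py[i] = pos[1]; C.pz[i] = pos[2];
        C.dx[i] = nd[0]; C.dy[i] = nd[1]; C.dz[i] = nd[2];
        C.len[i] = newlen; C.thr[i] = thr;
      } else {
        C.px.push_back(pos[0]); C.py.push_back(pos[1]); C.pz.push_back(pos[2]);
        C.dx.push_back(nd[0]); C.dy.push_back(nd[1]); C.dz.push_back(nd[2]);
        C.len.push_back(newlen); C.wid.push_back(w); C.thr.push_back(thr);
      }
    }
  }
}

//' @noRd
// [[Rcpp::export]]
List advance_cpp(List state, List params, int nsteps) {
  SimPar par = par_from_list(params);
  Colony C = colony_from_list(state);
  for (int s = 0; s < nsteps; ++s) {
    mechanics_step(C, par, par.dt);
    C.t += par.dt;
  }
  return colony_to_list(C);
}

//' @noRd
// [[Rcpp::export]]
List grow_divide_cpp(List state, List params) {
  SimPar par = par_from_list(params);
  Colony C = colony_from_list(state);
  grow_divide(C, par, par.dt);
  return colony_to_list(C);
}

//' @noRd
// [[Rcpp::export]]
List simulate_colony_cpp(List params) {
  SimPar par = par_from_list(params);
  Colony C;
  double h0 = 0.5 * par.width;
  if (par.f_surf > 0.0)
    h0 = std::max(0.0, 0.5 * par.width - std::pow(par.f_surf / par.k_rep, 2.0 / 3.0));
  double phi = R::runif(0.0, 2.0 * M_PI);
  C.px.push_back(0.0); C.py.push_back(0.0); C.pz.push_back(h0);
  C.dx.push_back(std::cos(phi)); C.dy.push_back(std::sin(phi)); C.dz.push_back(0.0);
  C.len.push_back(std::max(0.6 * par.L_div, 1.01 * par.width));
  C.wid.push_back(par.width);
  C.thr.push_back(par.L_div * std::exp(R::rnorm(0.0, par.sigma_div)));
  std::vector<double> hist_t;
  std::vector<int> hist_n;
  hist_t.push_back(0.0);
  hist_n.push_back(1);
  while ((int) C.size() < par.n_target) {
    if (C.t > par.max_hours)
      stop("simulation did not reach n_target within max_hours");
    size_t before = C.size();
    mechanics_step(C, par, par.dt);
    grow_divide(C, par, par.dt);
    C.t += par.dt;
    if (C.size() != before) {
      hist_t.push_back(C.t);
      hist_n.push_back((int) C.size());
    }
    Rcpp::checkUserInterrupt();
  }
  List out = colony_to_list(C);
  out["history_time"] = wrap(hist_t);
  out["history_n"] = wrap(hist_n);
  return out;
}

// ---------------------------------------------------------------------------
// 3D convex hull (incremental), returning surface area and volume.

struct Face { int a, b, c; bool alive; };

//' @noRd
// [[Rcpp::export]]
List hull_area_volume_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("degenerate geometry: need at least 4 points");
  std::vector<std::array<double, 3>> P(n);
  double lo[3] = { R_PosInf, R_PosInf, R_PosInf };
  double hi[3] = { R_NegInf, R_NegInf, R_NegInf };
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      P[i][k] = pts(i, k);
      lo[k] = std::min(lo[k], P[i][k]);
      hi[k] = std::max(hi[k], P[i][k]);
    }
  }
  double scale = std::max({ hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-12 });
  double eps = 1e-9 * scale;

  // initial simplex: extreme in x, farthest point, farthest from line,
  // farthest from plane
  int i0 = 0;
  for (int i = 1; i < n; ++i) if (P[i][0] < P[i0][0]) i0 = i;
  int i1 = -1; double best = eps;
  for (int i = 0; i < n; ++i) {
    double d[3] = { P[i][0] - P[i0][0], P[i][1] - P[i0][1], P[i][2] - P[i0][2] };
    double dist = norm3(d);
    if (dist > best) { best = dist; i1 = i; }
  }
  if (i1 < 0) stop("degenerate geometry: all points coincide");
  int i2 = -1; best = eps * scale;
  double e0[3] = { P[i1][0] - P[i0][0], P[i1][1] - P[i0][1], P[i1][2] - P[i0][2] };
  for (int i = 0; i < n; ++i) {
    double d[3] = { P[i][0] - P[i0][0], P[i][1] - P[i0][1], P[i][2] - P[i0][2] };
    double cr[3];
    cross3(e0, d, cr);
    double a = norm3(cr);
    if (a > best) { best = a; i2 = i; }
  }
  if (i2 < 0) stop("degenerate geometry: points are collinear");
  int i3 = -1; best = eps * scale * scale;
  double e1[3] = { P[i2][0] - P[i0][0], P[i2][1] - P[i0][1], P[i2][2] - P[i0][2] };
  double nrm[3];
  cross3(e0, e1, nrm);
  for (int i = 0; i < n; ++i) {
    double d[3] = { P[i][0] - P[i0][0], P[i][1] - P[i0][1], P[i][2] - P[i0][2] };
    double v = std::fabs(dot3(nrm, d));
    if (v > best) { best = v; i3 = i; }
  }
  if (i3 < 0) stop("degenerate geometry: points are coplanar");

  // interior reference point
  double cen[3];
  for (int k = 0; k < 3; ++k)
    cen[k] = 0.25 * (P[i0][k] + P[i1][k] + P[i2][k] + P[i3][k]);

  std::vector<Face> faces;
  auto face_normal = [&](const Face& f, double* nn) {
    double u[3], v[3];
    for (int k = 0; k < 3; ++k) {
      u[k] = P[f.b][k] - P[f.a][k];
      v[k] = P[f.c][k] - P[f.a][k];
    }
    cross3(u, v, nn);
  };
  auto add_face = [&](int a, int b, int c) {
    Face f = { a, b, c, true };
    double nn[3];
    face_normal(f, nn);
    double d[3] = { cen[0] - P[a][0], cen[1] - P[a][1], cen[2] - P[a][2] };
    if (dot3(nn, d) > 0) std::swap(f.b, f.c);   // orient outward
    faces.push_back(f);
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    std::vector<int> visible;
    for (size_t fi = 0; fi < faces.size(); ++fi) {
      if (!faces[fi].alive) continue;
      double nn[3];
      face_normal(faces[fi], nn);
      double nl = norm3(nn);
      if (nl < 1e-300) continue;
      double d[3] = { P[i][0] - P[faces[fi].a][0], P[i][1] - P[faces[fi].a][1],
                      P[i][2] - P[faces[fi].a][2] };
      if (dot3(nn, d) / nl > eps) visible.push_back((int) fi);
    }
    if (visible.empty()) continue;
    // horizon = directed edges of visible faces whose reverse is not visible
    std::unordered_map<int64_t, int> edgecount;
    auto ekey = [](int a, int b) { return ((int64_t) a << 32) | (uint32_t) b; };
    for (int fi : visible) {
      const Face& f = faces[fi];
      int vs[3] = { f.a, f.b, f.c };
      for (int e = 0; e < 3; ++e) {
        int a = vs[e], b = vs[(e + 1) % 3];
        edgecount[ekey(std::min(a, b), std::max(a, b))] += 1;
      }
    }
    std::vector<std::pair<int, int>> horizon;
    for (int fi : visible) {
      const Face& f = faces[fi];
      int vs[3] = { f.a, f.b, f.c };
      for (int e = 0; e < 3; ++e) {
        int a = vs[e], b = vs[(e + 1) % 3];
        if (edgecount[ekey(std::min(a, b), std::max(a, b))] == 1)
          horizon.push_back({ a, b });
      }
    }
    for (int fi : visible) faces[fi].alive = false;
    for (auto& ed : horizon) {
      Face f = { ed.first, ed.second, i, true };
      faces.push_back(f);
    }
  }

  double area = 0.0, vol = 0.0;
  int nfaces = 0;
  for (const Face& f : faces) {
    if (!f.alive) continue;
    ++nfaces;
    double u[3], v[3], nn[3];
    for (int k = 0; k < 3; ++k) {
      u[k] = P[f.b][k] - P[f.a][k];
      v[k] = P[f.c][k] - P[f.a][k];
    }
    cross3(u, v, nn);
    area += 0.5 * norm3(nn);
    double a0[3] = { P[f.a][0] - cen[0], P[f.a][1] - cen[1], P[f.a][2] - cen[2] };
    double b0[3] = { P[f.b][0] - cen[0], P[f.b][1] - cen[1], P[f.b][2] - cen[2] };
    double c0[3] = { P[f.c][0] - cen[0], P[f.c][1] - cen[1], P[f.c][2] - cen[2] };
    double cr[3];
    cross3(b0, c0, cr);
    vol += dot3(a0, cr) / 6.0;
  }
  vol = std::fabs(vol);
  if (vol <= 0.0) stop("degenerate geometry: zero hull volume");
  return List::create(_["area"] = area, _["volume"] = vol,
                      _["n_faces"] = nfaces);
}
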