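// Fixed-step RK4 cores for the model families and the non-homogeneous
// FitzHugh-Nagumo reaction-diffusion system (method of lines).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// cubic variants: 0 = soft (-u^3/3 + u), 1 = steep (-u^3 + 3u)
static inline double fcub(double u, int var) {
  return var == 0 ? -u * u * u / 3.0 + u : -u * u * u + 3.0 * u;
}
static inline double fcubp(double u, int var) {
  return var == 0 ? 1.0 - u * u : 3.0 - 3.0 * u * u;
}

// Root of f(u) - u/b + w + I = 0 (fixed point of the frozen-w planar
// subsystem).  Safeguarded Newton with an expanding bracket; the map is
// strictly decreasing for the soft cubic when b < 1.
static double ustar_planar(double w, double I, double b, int var, double guess) {
  double lo = guess - 1.0, hi = guess + 1.0;
  auto F = [&](double u) { return fcub(u, var) - u / b + w + I; };
  for (int k = 0; k < 200 && F(lo) < 0.0; ++k) lo -= 1.0;
  for (int k = 0; k < 200 && F(hi) > 0.0; ++k) hi += 1.0;
  double u = guess;
  if (u < lo || u > hi) u = 0.5 * (lo + hi);
  for (int it = 0; it < 100; ++it) {
    double f = F(u);
    if (f > 0.0) lo = u; else hi = u;
    double fp = fcubp(u, var) - 1.0 / b;
    double un = u - f / fp;
    if (!(un > lo && un < hi)) un = 0.5 * (lo + hi);
    if (std::fabs(un - u) < 1e-14) { u = un; break; }
    u = un;
  }
  return u;
}

struct Ctx { double ustar_guess; };

// model codes: 1 fhr, 2 fhr_original, 3 fhn2d, 4 fold blow-up,
// 5 moving_focus, 6 transformed (exact focus frame)
static inline void model_rhs(int model, const double* p, const double* y,
                             double* dy, Ctx& ctx) {
  switch (model) {
  case 1: { // pars: I, b, c, eps, var
    double I = p[0], b = p[1], c = p[2], eps = p[3]; int var = (int)p[4];
    dy[0] = (fcub(y[0], var) - y[1] + y[2] + I) / eps;
    dy[1] = y[0] - b * y[1] - c;
    dy[2] = eps * (-y[0] - y[2]);
    break;
  }
  case 2: { // pars: I, a, b, c, d, phi, eps, literal
    double I = p[0], a = p[1], b = p[2], c = p[3], d = p[4], phi = p[5],
           eps = p[6];
    bool literal = p[7] != 0.0;
    double dv = fcub(y[0], 0) - y[1] + y[2] + I;
    dy[0] = literal ? dv / eps : dv;
    dy[1] = phi * (a + y[0] - b * y[1]);
    dy[2] = eps * (c - y[0] - d * y[2]);
    break;
  }
  case 3: { // pars: I, b, eps, var, drive_w
    double I = p[0], b = p[1], eps = p[2]; int var = (int)p[3];
    dy[0] = (fcub(y[0], var) - y[1] + I + p[4]) / eps;
    dy[1] = y[0] - b * y[1];
    break;
  }
  case 4: { // fold blow-up system: no pars, w carried as third (constant) state
    dy[0] = -3.0 * y[0] * y[0] - y[1] + y[2];
    dy[1] = y[0];
    dy[2] = 0.0;
    break;
  }
  case 5: { // pars: I, b, eps, var; state measured about the moving focus
    double I = p[0], b = p[1], eps = p[2]; int var = (int)p[3];
    double us = ustar_planar(y[2], I, b, var, ctx.ustar_guess);
    ctx.ustar_guess = us;
    dy[0] = (fcubp(us, var) * y[0] - y[1]) / eps;
    dy[1] = y[0] - b * y[1];
    dy[2] = -eps * (y[2] + us + y[0]);
    break;
  }
  case 6: { // pars: I, b, eps, var; exact focus-frame system
    double I = p[0], b = p[1], eps = p[2]; int var = (int)p[3];
    double us = ustar_planar(y[2], I, b, var, ctx.ustar_guess);
    ctx.ustar_guess = us;
    double g = fcub(us + y[0], var) - fcub(us, var);
    double k = 1.0 / (fcubp(us, var) - 1.0 / b);
    double s = us + y[0] + y[2];
    dy[0] = (g - y[1]) / eps - eps * k * s;
    dy[1] = y[0] - b * y[1] - eps * k * s / b;
    dy[2] = -eps * (y[2] + us + y[0]);
    break;
  }
  default:
    stop("unknown model code");
  }
}

static inline bool bad_state(const double* y, int d, double blowup) {
  for (int i = 0; i < d; ++i)
    if (!std::isfinite(y[i]) || std::fabs(y[i]) > blowup) return true;
  return false;
}

static void rk4_step(int model, const double* p, double* y, int d, double h,
                     Ctx& ctx, double* k1, double* k2, double* k3, double* k4,
                     double* tmp) {
  model_rhs(model, p, y, k1, ctx);
  for (int i = 0; i < d; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  model_rhs(model, p, tmp, k2, ctx);
  for (int i = 0; i < d; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  model_rhs(model, p, tmp, k3, ctx);
  for (int i = 0; i < d; ++i) tmp[i] = y[i] + h * k3[i];
  model_rhs(model, p, tmp, k4, ctx);
  for (int i = 0; i < d; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export]]
List rk4_model_cpp(int model, NumericVector pars, NumericVector y0, double t0,
                   double t1, double dt, int stride, double blowup) {
  if (dt <= 0.0 || t1 <= t0) stop("need dt > 0 and t1 > t0");
  if (stride < 1) stride = 1;
  int d = y0.size();
  long nsteps = (long)std::ceil((t1 - t0) / dt - 1e-12);
  long nrec_max = nsteps / stride + 3;
  NumericVector times(nrec_max);
  NumericMatrix states(nrec_max, d);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(d), k2(d), k3(d), k4(d), tmp(d);
  Ctx ctx; ctx.ustar_guess = (d >= 3) ? y[2] : 0.0;
  if (model == 5 || model == 6)
    ctx.ustar_guess = ustar_planar(y[2], pars[0], pars[1], (int)pars[3], 0.0);

  long nrec = 0;
  times[nrec] = t0;
  for (int i = 0; i < d; ++i) states(nrec, i) = y[i];
  ++nrec;
  bool blown = false;
  double t = t0;
  for (long s = 0; s < nsteps; ++s) {
    double h = std::min(dt, t1 - t);
    rk4_step(model, REAL(pars), y.data(), d, h, ctx, k1.data(), k2.data(),
             k3.data(), k4.data(), tmp.data());
    t = (s == nsteps - 1) ? t1 : t + h;
    if (bad_state(y.data(), d, blowup)) { blown = true; break; }
    if (((s + 1) % stride == 0) || s == nsteps - 1) {
      times[nrec] = t;
      for (int i = 0; i < d; ++i) states(nrec, i) = y[i];
      ++nrec;
    }
  }
  return List::create(_["times"] = times[Range(0, nrec - 1)],
                      _["states"] = states(Range(0, nrec - 1), _),
                      _["blown_up"] = blown, _["t_last"] = t);
}

// Integrate until the first crossing of y[comp] = level with the requested
// direction (+1 rising, -1 falling, 0 either), optionally requiring
// y[1] < 0 at the crossing (the Poincare section {u=0, v<0}).  The crossing
// is refined by bisection on the sub-step length, re-taking a single RK4
// step from the pre-crossing state, so its accuracy is that of the solver.
// [[Rcpp::export]]
List integrate_until_section_cpp(int model, NumericVector pars,
                                 NumericVector y0, double t0, double tmax,
                                 double dt, int comp, double level,
                                 int direction, double min_time,
                                 bool require_vneg, double blowup) {
  int d = y0.size();
  std::vector<double> y(y0.begin(), y0.end()), ypre(d);
  std::vector<double> k1(d), k2(d), k3(d), k4(d), tmp(d);
  Ctx ctx; ctx.ustar_guess = (d >= 3) ? y[2] : 0.0;
  double t = t0;
  bool blown = false;
  while (t < tmax) {
    double h = std::min(dt, tmax - t);
    std::copy(y.begin(), y.end(), ypre.begin());
    Ctx ctx_pre = ctx;
    rk4_step(model, REAL(pars), y.data(), d, h, ctx, k1.data(), k2.data(),
             k3.data(), k4.data(), tmp.data());
    double tn = t + h;
    if (bad_state(y.data(), d, blowup)) { blown = true; t = tn; break; }
    double g0 = ypre[comp] - level, g1 = y[comp] - level;
    bool dir_ok = direction == 0 || (direction > 0 ? g1 > g0 : g1 < g0);
    if (tn > min_time && g0 * g1 <= 0.0 && g0 != g1 && dir_ok &&
        !(g0 == 0.0 && t <= t0)) {
      // refine: bisection on sub-step length from the pre state
      double lo = 0.0, hi = h;
      std::vector<double> ymid(d);
      for (int it = 0; it < 60; ++it) {
        double hm = 0.5 * (lo + hi);
        std::copy(ypre.begin(), ypre.end(), ymid.begin());
        Ctx cm = ctx_pre;
        rk4_step(model, REAL(pars), ymid.data(), d, hm, cm, k1.data(),
                 k2.data(), k3.data(), k4.data(), tmp.data());
        double gm = ymid[comp] - level;
        if (gm * g0 <= 0.0 && gm != 0.0) hi = hm; else lo = hm;
        if (hi - lo < 1e-15 * std::max(1.0, h)) break;
      }
      double hc = 0.5 * (lo + hi);
      std::copy(ypre.begin(), ypre.end(), ymid.begin());
      Ctx cm = ctx_pre;
      rk4_step(model, REAL(pars), ymid.data(), d, hc, cm, k1.data(), k2.data(),
               k3.data(), k4.data(), tmp.data());
      if (!require_vneg || ymid[1] < 0.0) {
        return List::create(_["found"] = true, _["time"] = t + hc,
                            _["state"] = NumericVector(ymid.begin(), ymid.end()),
                            _["blown_up"] = false);
      }
    }
    t = tn;
  }
  return List::create(_["found"] = false, _["time"] = t,
                      _["state"] = NumericVector(y.begin(), y.end()),
                      _["blown_up"] = blown);
}

// ---------------- reaction-diffusion core ----------------

// 5-point (3-point in 1D) Laplacian with Neumann (reflecting ghost) BCs
static void lap_neumann(const double* f, double* out, int nx, int ny,
                        double dx) {
  double idx2 = 1.0 / (dx * dx);
  if (ny == 1) {
    for (int i = 0; i < nx; ++i) {
      double l = (i > 0) ? f[i - 1] : f[i];
      double r = (i < nx - 1) ? f[i + 1] : f[i];
      out[i] = (l - 2.0 * f[i] + r) * idx2;
    }
  } else {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int id = i + nx * j;
        double l = (i > 0) ? f[id - 1] : f[id];
        double r = (i < nx - 1) ? f[id + 1] : f[id];
        double dn = (j > 0) ? f[id - nx] : f[id];
        double up = (j < ny - 1) ? f[id + nx] : f[id];
        out[id] = (l + r + dn + up - 4.0 * f[id]) * idx2;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector laplacian_neumann_cpp(NumericVector f, int nx, int ny,
                                    double dx) {
  NumericVector out(f.size());
  lap_neumann(REAL(f), REAL(out), nx, ny, dx);
  return out;
}

struct RDsys {
  int nx, ny, N, var;
  double dx, eps, b, du, dv;
  const double* Ip;
  const double* cp;
  std::vector<double> lapu, lapv;
  void rhs(const double* u, const double* v, double* dudt, double* dvdt) {
    if (du != 0.0) lap_neumann(u, lapu.data(), nx, ny, dx);
    if (dv != 0.0) lap_neumann(v, lapv.data(), nx, ny, dx);
    for (int i = 0; i < N; ++i) {
      double diffu = du != 0.0 ? du * lapu[i] : 0.0;
      dudt[i] = (fcub(u[i], var) - v[i] + Ip[i] + diffu) / eps;
      dvdt[i] = u[i] - b * v[i] - cp[i] + (dv != 0.0 ? dv * lapv[i] : 0.0);
    }
  }
};

// [[Rcpp::export]]
List nhfhn_cpp(NumericVector u0, NumericVector v0, int nx, int ny, double dx,
               double eps, double b, double d_u, double d_v, int cubic,
               NumericVector Iprof, NumericVector cprof, double t0, double t1,
               double dt, int stride, IntegerVector probe_idx,
               int probe_stride, double blowup) {
  int N = nx * ny;
  if (u0.size() != N || v0.size() != N) stop("field size mismatch");
  RDsys sys;
  sys.nx = nx; sys.ny = ny; sys.N = N; sys.var = cubic; sys.dx = dx;
  sys.eps = eps; sys.b = b; sys.du = d_u; sys.dv = d_v;
  sys.Ip = REAL(Iprof); sys.cp = REAL(cprof);
  sys.lapu.assign(N, 0.0); sys.lapv.assign(N, 0.0);

  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> ku1(N), kv1(N), ku2(N), kv2(N), ku3(N), kv3(N), ku4(N),
      kv4(N), ut(N), vt(N);

  long nsteps = (long)std::ceil((t1 - t0) / dt - 1e-12);
  long nrec_max = nsteps / stride + 3;
  int nprobe = probe_idx.size();
  long nprec_max = nsteps / probe_stride + 3;

  NumericVector times(nrec_max);
  NumericMatrix U(nrec_max, N), V(nrec_max, N);
  NumericVector ptimes(nprobe > 0 ? nprec_max : 0);
  NumericMatrix PU(nprobe > 0 ? nprec_max : 0, nprobe),
      PV(nprobe > 0 ? nprec_max : 0, nprobe),
      PL(nprobe > 0 ? nprec_max : 0, nprobe);

  long nrec = 0, nprec = 0;
  auto record_fields = [&](double tt) {
    times[nrec] = tt;
    for (int i = 0; i < N; ++i) { U(nrec, i) = u[i]; V(nrec, i) = v[i]; }
    ++nrec;
  };
  auto record_probes = [&](double tt) {
    if (nprobe == 0) return;
    lap_neumann(u.data(), sys.lapu.data(), nx, ny, dx);
    ptimes[nprec] = tt;
    for (int q = 0; q < nprobe; ++q) {
      int id = probe_idx[q];
      PU(nprec, q) = u[id]; PV(nprec, q) = v[id];
      PL(nprec, q) = sys.lapu[id];
    }
    ++nprec;
  };
  record_fields(t0);
  record_probes(t0);

  bool blown = false;
  double t = t0;
  for (long s = 0; s < nsteps; ++s) {
    double h = std::min(dt, t1 - t);
    sys.rhs(u.data(), v.data(), ku1.data(), kv1.data());
    for (int i = 0; i < N; ++i) {
      ut[i] = u[i] + 0.5 * h * ku1[i]; vt[i] = v[i] + 0.5 * h * kv1[i];
    }
    sys.rhs(ut.data(), vt.data(), ku2.data(), kv2.data());
    for (int i = 0; i < N; ++i) {
      ut[i] = u[i] + 0.5 * h * ku2[i]; vt[i] = v[i] + 0.5 * h * kv2[i];
    }
    sys.rhs(ut.data(), vt.data(), ku3.data(), kv3.data());
    for (int i = 0; i < N; ++i) {
      ut[i] = u[i] + h * ku3[i]; vt[i] = v[i] + h * kv3[i];
    }
    sys.rhs(ut.data(), vt.data(), ku4.data(), kv4.data());
    for (int i = 0; i < N; ++i) {
      u[i] += h / 6.0 * (ku1[i] + 2.0 * ku2[i] + 2.0 * ku3[i] + ku4[i]);
      v[i] += h / 6.0 * (kv1[i] + 2.0 * kv2[i] + 2.0 * kv3[i] + kv4[i]);
    }
    t = (s == nsteps - 1) ? t1 : t + h;
    bool bad = false;
    for (int i = 0; i < N; ++i)
      if (!std::isfinite(u[i]) || std::fabs(u[i]) > blowup) { bad = true; break; }
    if (bad) { blown = true; break; }
    if (((s + 1) % stride == 0) || s == nsteps - 1) record_fields(t);
    if (nprobe > 0 && (((s + 1) % probe_stride == 0) || s == nsteps - 1))
      record_probes(t);
    if ((s & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  List probes = R_NilValue;
  if (nprobe > 0) {
    probes = List::create(_["times"] = ptimes[Range(0, std::max(nprec - 1, 0L))],
                          _["u"] = PU(Range(0, std::max(nprec - 1, 0L)), _),
                          _["v"] = PV(Range(0, std::max(nprec - 1, 0L)), _),
                          _["lap_u"] = PL(Range(0, std::max(nprec - 1, 0L)), _));
  }
  return List::create(_["times"] = times[Range(0, nrec - 1)],
                      _["u"] = U(Range(0, nrec - 1), _),
                      _["v"] = V(Range(0, nrec - 1), _),
                      _["blown_up"] = blown, _["probes"] = probes);
}
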