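// Core numerics: planar skeletal dynamics (recursive Newton-Euler), smooth
// sphere contact, Hill-type muscle-tendon units in implicit-tendon form, and
// the Hermite-Simpson collocation transcription with augmented-Lagrangian
// objective/gradient evaluators. All functions are C1-smooth in their inputs,
// which the gradient-based solver relies on.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NQ = 11;
static const int NM = 24;
static const int NSPH = 10;
static const int NX = 2 * NQ + 2 * NM;   // q, u, a, ftilde
static const int NU = 2 * NM;            // e, dftilde

// tendon force-length curve constants (exponential tendon)
static const double TC1 = 0.200, TC2 = 0.995, TC3 = 0.250, TKT = 35.0;

struct GaitModel {
  // bodies indexed like the coordinate that creates them
  arma::ivec parent;          // 11
  arma::ivec jtype;           // 0 prismatic, 1 revolute
  arma::vec axis_x, axis_y;   // prismatic axis in parent frame
  arma::vec axis_sign;        // revolute sign
  arma::vec anc_x, anc_y;     // joint anchor in parent frame
  arma::vec mass, com_x, com_y, izz;
  double gravity;
  double body_mass;
  // contact
  arma::ivec sph_body;        // 10
  arma::vec sph_x, sph_y, sph_r;
  double c_stiff, c_diss, c_mu, c_vt, c_epsd;
  int heel_r, heel_l;         // sphere indices of heel markers
  // muscles
  arma::vec fmax, lopt, lts, alpha0, vmax, tau_a, tau_d, damping, ftfrac, mmass;
  arma::mat arms;             // 24 x 11 signed constant moment arms
  arma::vec lmt_ref;          // muscle-tendon length at q = 0
  arma::vec h_fib;            // lopt * sin(alpha0), constant fiber height
  arma::vec jdamp, jstiff;    // passive joint damping / return stiffness
  arma::vec qcal;             // muscle length calibration pose
};

// ---------------------------------------------------------------- kinematics
struct BodyKin {
  double th, om, al;
  double px, py, vx, vy, ax, ay;
};

// outward pass: positions/velocities/accelerations of body frames
static void kin_pass(const GaitModel& M, const double* q, const double* u,
                     const double* ud, bool grav, BodyKin* B) {
  for (int i = 0; i < NQ; ++i) {
    double pth = 0, pom = 0, pal = 0, ppx = 0, ppy = 0, pvx = 0, pvy = 0,
           pax = 0, pay = grav ? M.gravity : 0.0;  // base accel trick
    int p = M.parent[i];
    if (p >= 0) {
      const BodyKin& P = B[p];
      pth = P.th; pom = P.om; pal = P.al;
      ppx = P.px; ppy = P.py; pvx = P.vx; pvy = P.vy; pax = P.ax; pay = P.ay;
    }
    double c = std::cos(pth), s = std::sin(pth);
    double rx = c * M.anc_x[i] - s * M.anc_y[i];
    double ry = s * M.anc_x[i] + c * M.anc_y[i];
    BodyKin& b = B[i];
    if (M.jtype[i] == 0) {  // prismatic
      double dx = c * M.axis_x[i] - s * M.axis_y[i];
      double dy = s * M.axis_x[i] + c * M.axis_y[i];
      double ox = rx + dx * q[i], oy = ry + dy * q[i];
      b.th = pth; b.om = pom; b.al = pal;
      b.px = ppx + ox; b.py = ppy + oy;
      b.vx = pvx - pom * oy + dx * u[i];
      b.vy = pvy + pom * ox + dy * u[i];
      b.ax = pax - pal * oy - pom * pom * ox + dx * ud[i] - 2.0 * pom * dy * u[i];
      b.ay = pay + pal * ox - pom * pom * oy + dy * ud[i] + 2.0 * pom * dx * u[i];
    } else {                // revolute
      double sg = M.axis_sign[i];
      b.th = pth + sg * q[i];
      b.om = pom + sg * u[i];
      b.al = pal + sg * ud[i];
      b.px = ppx + rx; b.py = ppy + ry;
      b.vx = pvx - pom * ry; b.vy = pvy + pom * rx;
      b.ax = pax - pal * ry - pom * pom * rx;
      b.ay = pay + pal * rx - pom * pom * ry;
    }
  }
}

// external point force applied to a body
struct ExtForce { int body; double px, py, fx, fy; };

// inverse dynamics: joint torques realizing ud given external forces.
// Gravity enters via the base-acceleration trick inside kin_pass.
static void rnea(const GaitModel& M, const double* q, const double* u,
                 const double* ud, bool grav,
                 const std::vector<ExtForce>& ext, double* tau) {
  BodyKin B[NQ];
  kin_pass(M, q, u, ud, grav, B);
  double Fx[NQ], Fy[NQ], Nz[NQ];
  for (int i = 0; i < NQ; ++i) { Fx[i] = Fy[i] = Nz[i] = 0.0; }
  // accumulate external forces (as moments about each body origin)
  for (size_t k = 0; k < ext.size(); ++k) {
    const ExtForce& e = ext[k];
    Fx[e.body] -= e.fx; Fy[e.body] -= e.fy;
    Nz[e.body] -= (e.px - B[e.body].px) * e.fy - (e.py - B[e.body].py) * e.fx;
  }
  // inward pass (children have larger indices than parents by construction)
  for (int i = NQ - 1; i >= 0; --i) {
    const BodyKin& b = B[i];
    double c = std::cos(b.th), s = std::sin(b.th);
    double rcx = c * M.com_x[i] - s * M.com_y[i];
    double rcy = s * M.com_x[i] + c * M.com_y[i];
    double acx = b.ax - b.al * rcy - b.om * b.om * rcx;
    double acy = b.ay + b.al * rcx - b.om * b.om * rcy;
    double fx = M.mass[i] * acx + Fx[i];
    double fy = M.mass[i] * acy + Fy[i];
    double nz = M.izz[i] * b.al + rcx * (M.mass[i] * acy) - rcy * (M.mass[i] * acx) + Nz[i];
    int p = M.parent[i];
    if (p >= 0) {
      Fx[p] += fx; Fy[p] += fy;
      Nz[p] += nz + (b.px - B[p].px) * fy - (b.py - B[p].py) * fx;
    }
    if (M.jtype[i] == 0) {
      double pth = (p >= 0) ? B[p].th : 0.0;
      double cp = std::cos(pth), sp = std::sin(pth);
      double dx = cp * M.axis_x[i] - sp * M.axis_y[i];
      double dy = sp * M.axis_x[i] + cp * M.axis_y[i];
      tau[i] = dx * fx + dy * fy;
    } else {
      tau[i] = M.axis_sign[i] * nz;
    }
  }
}

// ------------------------------------------------------------------ contact
// smooth positive part with width eps
static inline double spos(double x, double eps) {
  return 0.5 * (x + std::sqrt(x * x + eps * eps));
}

// softplus positive part: same smoothing width near zero, but an
// exponentially vanishing tail (no spurious force at clear clearance, yet a
// usable attraction gradient within a few widths of the ground)
static inline double spos_exp(double x, double eps) {
  double r = x / eps;
  if (r > 40.0) return x;
  if (r < -40.0) return 0.0;
  return eps * std::log1p(std::exp(r));
}

// per-sphere forces; also fills foot sums and heel positions
static void contact_eval(const GaitModel& M, const double* q, const double* u,
                         double* sfx, double* sfy,
                         double* grf, /* 4: fx_r, fy_r, fx_l, fy_l */
                         double* heelx, double* heely,
                         std::vector<ExtForce>* ext) {
  BodyKin B[NQ];
  double zero[NQ] = {0};
  kin_pass(M, q, u, zero, false, B);
  grf[0] = grf[1] = grf[2] = grf[3] = 0.0;
  for (int k = 0; k < NSPH; ++k) {
    int b = M.sph_body[k];
    double c = std::cos(B[b].th), s = std::sin(B[b].th);
    double rx = c * M.sph_x[k] - s * M.sph_y[k];
    double ry = s * M.sph_x[k] + c * M.sph_y[k];
    double px = B[b].px + rx, py = B[b].py + ry;
    double vx = B[b].vx - B[b].om * ry, vy = B[b].vy + B[b].om * rx;
    double depth = M.sph_r[k] - py;
    double ds = spos_exp(depth, M.c_epsd);
    double damp = spos(1.0 + 1.5 * M.c_diss * (-vy), 0.1);
    double fy = M.c_stiff * ds * std::sqrt(ds) * damp;
    double fx = -M.c_mu * fy * std::tanh(vx / M.c_vt);
    sfx[k] = fx; sfy[k] = fy;
    bool right = (k < NSPH / 2);
    grf[right ? 0 : 2] += fx;
    grf[right ? 1 : 3] += fy;
    if (k == M.heel_r) { heelx[0] = px; heely[0] = py; }
    if (k == M.heel_l) { heelx[1] = px; heely[1] = py; }
    if (ext) {
      ExtForce e; e.body = b; e.px = px; e.py = py; e.fx = fx; e.fy = fy;
      ext->push_back(e);
    }
  }
}

// ------------------------------------------------------------------ muscles
// characteristic curves (dimensionless, C1-smooth everywhere)
static inline double f_act_fl(double lm) {
  static const double b1[3] = {0.815, 0.433, 0.100};
  static const double b2[3] = {1.055, 0.717, 1.000};
  static const double b3[3] = {0.162, -0.030, 0.354};
  static const double b4[3] = {0.063, 0.200, 0.000};
  double f = 0.0;
  for (int i = 0; i < 3; ++i) {
    double den = b3[i] + b4[i] * lm;
    double z = (lm - b2[i]) / den;
    f += b1[i] * std::exp(-0.5 * z * z);
  }
  return f;
}
static inline double f_pas_fl(double lm) {
  static const double kpe = 4.0, e0 = 0.6;
  return (std::exp(kpe * (lm - 1.0) / e0) - 1.0) / (std::exp(kpe) - 1.0);
}
static inline double f_fv(double v) {
  static const double d1 = -0.318, d2 = -8.149, d3 = -0.374, d4 = 0.886;
  double z = d2 * v + d3;
  return d1 * std::log(z + std::sqrt(z * z + 1.0)) + d4;
}
static inline double f_tendon(double lt) {
  return TC1 * std::exp(TKT * (lt - TC2)) - TC3;
}

static inline double act_dyn_one(double e, double a, double ta, double td) {
  double f = 0.5 + 0.5 * std::tanh(10.0 * (e - a));
  return (e - a) * (f / ta + (1.0 - f) / td);
}

struct FiberState {
  double lm_tilde, vm_tilde, cos_alpha, f_fiber, power;
};

// fiber state implied by the tendon state (implicit-tendon parameterization)
static FiberState fiber_from_tendon(const GaitModel& M, int m, double ft,
                                    double dft, double lmt, double vmt) {
  FiberState S;
  double lt = M.lts[m] * (TC2 + std::log((ft + TC3) / TC1) / TKT);
  double vt = dft * M.lts[m] / (TKT * (ft + TC3));
  double lax = lmt - lt;                       // fiber projection on the line of action
  double h = M.h_fib[m];
  double lm = std::sqrt(lax * lax + h * h);
  double ca = lax / lm;
  double vm = (vmt - vt) * ca;                 // d(lm)/dt
  S.lm_tilde = lm / M.lopt[m];
  S.vm_tilde = vm / (M.vmax[m] * M.lopt[m]);
  S.cos_alpha = ca;
  S.f_fiber = ft * M.fmax[m] / std::max(ca, 0.1);  // force along the fiber
  S.power = -S.f_fiber * vm;                   // positive when shortening
  return S;
}

// equilibrium residual (dimensionless): fiber force balance minus tendon force
static double tendon_residual(const GaitModel& M, int m, double a, double ft,
                              double dft, double lmt, double vmt) {
  FiberState S = fiber_from_tendon(M, m, ft, dft, lmt, vmt);
  double ffl = f_act_fl(S.lm_tilde), fpe = f_pas_fl(S.lm_tilde),
         fv = f_fv(S.vm_tilde);
  return (a * ffl * fv + fpe + M.damping[m] * S.vm_tilde) * S.cos_alpha - ft;
}

static void muscle_geometry(const GaitModel& M, const double* q,
                            const double* u, double* lmt, double* vmt) {
  for (int m = 0; m < NM; ++m) {
    double l = M.lmt_ref[m], v = 0.0;
    for (int j = 0; j < NQ; ++j) {
      double r = M.arms(m, j);
      if (r != 0.0) { l -= r * q[j]; v -= r * u[j]; }
    }
    lmt[m] = l; vmt[m] = v;
  }
}

// ------------------------------------------------------- forward dynamics
static void mass_matrix(const GaitModel& M, const double* q, arma::mat& Mm) {
  Mm.set_size(NQ, NQ);
  std::vector<ExtForce> noext;
  double zero[NQ] = {0}, col[NQ], e[NQ];
  for (int j = 0; j < NQ; ++j) {
    for (int i = 0; i < NQ; ++i) e[i] = 0.0;
    e[j] = 1.0;
    rnea(M, q, zero, e, false, noext, col);
    for (int i = 0; i < NQ; ++i) Mm(i, j) = col[i];
  }
}

// right-hand side tau_muscle - bias(q, u, contact, gravity)
static void fd_rhs(const GaitModel& M, const double* q, const double* u,
                   const double* ft, arma::vec& rhs) {
  std::vector<ExtForce> ext;
  double sfx[NSPH], sfy[NSPH], grf[4], hx[2], hy[2];
  contact_eval(M, q, u, sfx, sfy, grf, hx, hy, &ext);
  double zero[NQ] = {0};
  arma::vec bias(NQ);
  rnea(M, q, u, zero, true, ext, bias.memptr());
  rhs.set_size(NQ);
  for (int j = 0; j < NQ; ++j) rhs[j] = -bias[j];
  for (int m = 0; m < NM; ++m) {
    double F = ft[m] * M.fmax[m];
    for (int j = 0; j < NQ; ++j) {
      double r = M.arms(m, j);
      if (r != 0.0) rhs[j] += r * F;
    }
  }
  // passive joint structures: light viscous damping and a return spring
  for (int j = 0; j < NQ; ++j)
    rhs[j] += -M.jdamp[j] * u[j] - M.jstiff[j] * q[j];
}

static void fwd_dyn(const GaitModel& M, const double* q, const double* u,
                    const double* ft, double* qdd, arma::mat* Mout = nullptr) {
  arma::mat Mm;
  mass_matrix(M, q, Mm);
  arma::vec rhs;
  fd_rhs(M, q, u, ft, rhs);
  arma::vec sol = arma::solve(Mm, rhs, arma::solve_opts::likely_sympd);
  for (int i = 0; i < NQ; ++i) qdd[i] = sol[i];
  if (Mout) *Mout = Mm;
}

// full state derivative f(x, c): x = (q, u, a, ftilde), c = (e, dftilde)
static void state_deriv(const GaitModel& M, const double* x, const double* c,
                        double* f) {
  const double* q = x;
  const double* u = x + NQ;
  const double* a = x + 2 * NQ;
  const double* ft = x + 2 * NQ + NM;
  const double* e = c;
  const double* dft = c + NM;
  for (int i = 0; i < NQ; ++i) f[i] = u[i];
  fwd_dyn(M, q, u, ft, f + NQ);
  for (int m = 0; m < NM; ++m)
    f[2 * NQ + m] = act_dyn_one(e[m], a[m], M.tau_a[m], M.tau_d[m]);
  for (int m = 0; m < NM; ++m) f[2 * NQ + NM + m] = dft[m];
}

// ------------------------------------------------------------ model builder
static GaitModel* model_from_list(List L) {
  GaitModel* M = new GaitModel();
  M->parent = as<arma::ivec>(L["parent"]);
  M->jtype = as<arma::ivec>(L["jtype"]);
  M->axis_x = as<arma::vec>(L["axis_x"]);
  M->axis_y = as<arma::vec>(L["axis_y"]);
  M->axis_sign = as<arma::vec>(L["axis_sign"]);
  M->anc_x = as<arma::vec>(L["anc_x"]);
  M->anc_y = as<arma::vec>(L["anc_y"]);
  M->mass = as<arma::vec>(L["mass"]);
  M->com_x = as<arma::vec>(L["com_x"]);
  M->com_y = as<arma::vec>(L["com_y"]);
  M->izz = as<arma::vec>(L["izz"]);
  M->gravity = as<double>(L["gravity"]);
  M->body_mass = arma::sum(M->mass);
  M->sph_body = as<arma::ivec>(L["sph_body"]);
  M->sph_x = as<arma::vec>(L["sph_x"]);
  M->sph_y = as<arma::vec>(L["sph_y"]);
  M->sph_r = as<arma::vec>(L["sph_r"]);
  M->c_stiff = as<double>(L["stiffness"]);
  M->c_diss = as<double>(L["dissipation"]);
  M->c_mu = as<double>(L["friction"]);
  M->c_vt = as<double>(L["velocity_smoothing"]);
  M->c_epsd = as<double>(L["depth_smoothing"]);
  M->heel_r = as<int>(L["heel_r"]);
  M->heel_l = as<int>(L["heel_l"]);
  M->fmax = as<arma::vec>(L["fmax"]);
  M->lopt = as<arma::vec>(L["lopt"]);
  M->lts = as<arma::vec>(L["lts"]);
  M->alpha0 = as<arma::vec>(L["alpha0"]);
  M->vmax = as<arma::vec>(L["vmax"]);
  M->tau_a = as<arma::vec>(L["tau_a"]);
  M->tau_d = as<arma::vec>(L["tau_d"]);
  M->damping = as<arma::vec>(L["damping"]);
  M->ftfrac = as<arma::vec>(L["ftfrac"]);
  M->mmass = as<arma::vec>(L["mmass"]);
  M->arms = as<arma::mat>(L["arms"]);
  M->jdamp = as<arma::vec>(L["jdamp"]);
  M->jstiff = as<arma::vec>(L["jstiff"]);
  M->qcal = as<arma::vec>(L["qcal"]);
  // fiber at optimal length and tendon at slack at the calibration pose
  M->lmt_ref = M->lts + M->lopt % arma::cos(M->alpha0) + M->arms * M->qcal;
  M->h_fib = M->lopt % arma::sin(M->alpha0);
  return M;
}

// [[Rcpp::export(name = ".model_build_cpp")]]
SEXP model_build_cpp(List L) {
  XPtr<GaitModel> p(model_from_list(L), true);
  return p;
}

// [[Rcpp::export(name = ".model_body_mass_cpp")]]
double model_body_mass_cpp(SEXP mp) {
  XPtr<GaitModel> M(mp);
  return M->body_mass;
}

// [[Rcpp::export(name = ".muscle_curves_cpp")]]
List muscle_curves_cpp(NumericVector lm, NumericVector vm, NumericVector lt) {
  int n = lm.size();
  NumericVector afl(n), pfl(n), fv(n), ften(lt.size());
  for (int i = 0; i < n; ++i) {
    afl[i] = f_act_fl(lm[i]);
    pfl[i] = f_pas_fl(lm[i]);
    fv[i] = f_fv(vm[i]);
  }
  for (int i = 0; i < lt.size(); ++i) ften[i] = f_tendon(lt[i]);
  return List::create(_["active_fl"] = afl, _["passive_fl"] = pfl,
                      _["fv"] = fv, _["tendon_fl"] = ften);
}

// [[Rcpp::export(name = ".act_dyn_cpp")]]
NumericVector act_dyn_cpp(NumericVector e, NumericVector a, double tau_a,
                          double tau_d) {
  int n = e.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = act_dyn_one(e[i], a[i], tau_a, tau_d);
  return out;
}

// [[Rcpp::export(name = ".tendon_residual_cpp")]]
NumericVector tendon_residual_cpp(SEXP mp, IntegerVector im, NumericVector a,
                                  NumericVector ft, NumericVector dft,
                                  NumericVector lmt, NumericVector vmt) {
  XPtr<GaitModel> M(mp);
  int n = im.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = tendon_residual(*M, im[i] - 1, a[i], ft[i], dft[i], lmt[i], vmt[i]);
  return out;
}

// [[Rcpp::export(name = ".muscle_geometry_cpp")]]
List muscle_geometry_cpp(SEXP mp, NumericVector q, NumericVector u) {
  XPtr<GaitModel> M(mp);
  NumericVector lmt(NM), vmt(NM);
  muscle_geometry(*M, q.begin(), u.begin(), lmt.begin(), vmt.begin());
  return List::create(_["lmt"] = lmt, _["vmt"] = vmt);
}

// [[Rcpp::export(name = ".contact_cpp")]]
List contact_cpp(SEXP mp, NumericVector q, NumericVector u) {
  XPtr<GaitModel> M(mp);
  double sfx[NSPH], sfy[NSPH], grf[4], hx[2], hy[2];
  contact_eval(*M, q.begin(), u.begin(), sfx, sfy, grf, hx, hy, nullptr);
  return List::create(
      _["sphere_fx"] = NumericVector(sfx, sfx + NSPH),
      _["sphere_fy"] = NumericVector(sfy, sfy + NSPH),
      _["grf"] = NumericVector(grf, grf + 4),
      _["heel_x"] = NumericVector(hx, hx + 2),
      _["heel_y"] = NumericVector(hy, hy + 2));
}

// [[Rcpp::export(name = ".fwd_dyn_cpp")]]
NumericVector fwd_dyn_cpp(SEXP mp, NumericVector q, NumericVector u,
                          NumericVector ft) {
  XPtr<GaitModel> M(mp);
  NumericVector qdd(NQ);
  fwd_dyn(*M, q.begin(), u.begin(), ft.begin(), qdd.begin());
  return qdd;
}

// [[Rcpp::export(name = ".inv_dyn_cpp")]]
NumericVector inv_dyn_cpp(SEXP mp, NumericVector q, NumericVector u,
                          NumericVector ud, bool use_contact, bool use_gravity) {
  XPtr<GaitModel> M(mp);
  std::vector<ExtForce> ext;
  if (use_contact) {
    double sfx[NSPH], sfy[NSPH], grf[4], hx[2], hy[2];
    contact_eval(*M, q.begin(), u.begin(), sfx, sfy, grf, hx, hy, &ext);
  }
  NumericVector tau(NQ);
  rnea(*M, q.begin(), u.begin(), ud.begin(), use_gravity, ext, tau.begin());
  return tau;
}

// [[Rcpp::export(name = ".state_deriv_cpp")]]
NumericVector state_deriv_cpp(SEXP mp, NumericVector x, NumericVector c) {
  XPtr<GaitModel> M(mp);
  NumericVector f(NX);
  state_deriv(*M, x.begin(), c.begin(), f.begin());
  return f;
}

// fiber states over a whole trajectory (for metabolics / work reporting)
// [[Rcpp::export(name = ".traj_fiber_cpp")]]
List traj_fiber_cpp(SEXP mp, NumericMatrix X, NumericMatrix C) {
  XPtr<GaitModel> M(mp);
  int n = X.ncol();
  NumericMatrix lm(NM, n), vm(NM, n), ff(NM, n), pw(NM, n), ca(NM, n);
  double lmt[NM], vmt[NM];
  for (int k = 0; k < n; ++k) {
    const double* x = &X(0, k);
    muscle_geometry(*M, x, x + NQ, lmt, vmt);
    const double* ft = x + 2 * NQ + NM;
    const double* dft = &C(NM, k);
    for (int m = 0; m < NM; ++m) {
      FiberState S = fiber_from_tendon(*M, m, ft[m], dft[m], lmt[m], vmt[m]);
      lm(m, k) = S.lm_tilde; vm(m, k) = S.vm_tilde;
      ff(m, k) = S.f_fiber; pw(m, k) = S.power; ca(m, k) = S.cos_alpha;
    }
  }
  return List::create(_["lm_tilde"] = lm, _["vm_tilde"] = vm,
                      _["fiber_force"] = ff, _["fiber_power"] = pw,
                      _["cos_alpha"] = ca);
}

// world positions of all contact spheres at a pose (guess construction)
// [[Rcpp::export(name = ".sphere_pos_cpp")]]
List sphere_pos_cpp(SEXP mp, NumericVector q) {
  XPtr<GaitModel> M(mp);
  BodyKin B[NQ];
  double zero[NQ] = {0};
  kin_pass(*M, q.begin(), zero, zero, false, B);
  NumericVector px(NSPH), py(NSPH), r(NSPH);
  for (int k = 0; k < NSPH; ++k) {
    int b = M->sph_body[k];
    double c = std::cos(B[b].th), s = std::sin(B[b].th);
    px[k] = B[b].px + c * M->sph_x[k] - s * M->sph_y[k];
    py[k] = B[b].py + s * M->sph_x[k] + c * M->sph_y[k];
    r[k] = M->sph_r[k];
  }
  return List::create(_["x"] = px, _["y"] = py, _["radius"] = r);
}

// contact summary over a whole trajectory (GRFs and heel positions per node)
// [[Rcpp::export(name = ".traj_contact_cpp")]]
List traj_contact_cpp(SEXP mp, NumericMatrix X) {
  XPtr<GaitModel> M(mp);
  int n = X.ncol();
  NumericMatrix grf(4, n), heelx(2, n), heely(2, n);
  double sfx[NSPH], sfy[NSPH], g4[4], hx[2], hy[2];
  for (int k = 0; k < n; ++k) {
    const double* x = &X(0, k);
    contact_eval(*M, x, x + NQ, sfx, sfy, g4, hx, hy, nullptr);
    for (int j = 0; j < 4; ++j) grf(j, k) = g4[j];
    heelx(0, k) = hx[0]; heelx(1, k) = hx[1];
    heely(0, k) = hy[0]; heely(1, k) = hy[1];
  }
  return List::create(_["grf"] = grf, _["heel_x"] = heelx, _["heel_y"] = heely);
}

// ===================================================================== OCP
// Decision vector layout (all scaled):
//   z = [x_0, ..., x_{n-1} (NX each), c_0, ..., c_{n-1} (NU each), tf]
// Constraints:
//   defects  (n-1) * NX   (Hermite-Simpson, compressed form, scaled by 1/(sx*h))
//   tendon   n * NM       (implicit equilibrium residual at nodes)
//   periodic NX + NU      (all states and controls; pelvis_tx offset v*tf)
struct OCP {
  GaitModel M;
  int n;
  double v;                   // target average speed
  arma::vec sx, su;           // per-channel scales
  arma::vec sd;               // defect row scales (characteristic rates)
  double stf;
  arma::vec lb, ub;           // scaled bounds on z
  // objective
  int obj_mode;               // 0 effort, 1 tracking, 2 effort + symmetry goals
  // tracking data (at node phases)
  arma::mat qref, uref, grfref;   // 11 x n, 11 x n, 4 x n
  arma::vec sigq, sigu, siggrf;
  double w_track_kin, w_track_grf;
  // symmetry goal settings
  double w_sl, w_st, target_step, sharp_sl, f_thresh, sharp_contact, sharp_lead;
  int nz() const { return n * (NX + NU) + 1; }
  int ncon() const { return (n - 1) * NX + n * NM + NX + NU; }
};

static void unpack(const OCP& O, const double* z, arma::mat& X, arma::mat& C,
                   double& tf) {
  X.set_size(NX, O.n); C.set_size(NU, O.n);
  for (int k = 0; k < O.n; ++k)
    for (int i = 0; i < NX; ++i) X(i, k) = z[k * NX + i] * O.sx[i];
  int off = O.n * NX;
  for (int k = 0; k < O.n; ++k)
    for (int i = 0; i < NU; ++i) C(i, k) = z[off + k * NU + i] * O.su[i];
  tf = z[O.nz() - 1] * O.stf;
}

// Simpson node weights (n odd), times h
static arma::vec simpson_weights(int n, double h) {
  arma::vec w(n);
  w[0] = w[n - 1] = h / 3.0;
  for (int k = 1; k < n - 1; ++k) w[k] = (k % 2 == 1) ? 4.0 * h / 3.0 : 2.0 * h / 3.0;
  return w;
}

// constraint evaluation; node derivatives optionally returned for reuse
static void ocp_constraints_impl(const OCP& O, const arma::mat& X,
                                 const arma::mat& C, double tf, arma::vec& con) {
  const int n = O.n;
  double h = tf / (n - 1);
  con.set_size(O.ncon());
  arma::mat F(NX, n);
  for (int k = 0; k < n; ++k)
    state_deriv(O.M, X.colptr(k), C.colptr(k), F.colptr(k));
  arma::vec xm(NX), cm(NU), fm(NX);
  int ic = 0;
  for (int k = 0; k < n - 1; ++k) {
    for (int i = 0; i < NX; ++i) {
      xm[i] = 0.5 * (X(i, k) + X(i, k + 1)) + h / 8.0 * (F(i, k) - F(i, k + 1));
    }
    for (int i = 0; i < NU; ++i) cm[i] = 0.5 * (C(i, k) + C(i, k + 1));
    state_deriv(O.M, xm.memptr(), cm.memptr(), fm.memptr());
    for (int i = 0; i < NX; ++i) {
      double d = X(i, k + 1) - X(i, k) -
                 h / 6.0 * (F(i, k) + 4.0 * fm[i] + F(i, k + 1));
      con[ic++] = d / (O.sd[i] * h);
    }
  }
  // tendon equilibrium at nodes
  double lmt[NM], vmt[NM];
  for (int k = 0; k < n; ++k) {
    muscle_geometry(O.M, X.colptr(k), X.colptr(k) + NQ, lmt, vmt);
    const double* a = X.colptr(k) + 2 * NQ;
    const double* ft = X.colptr(k) + 2 * NQ + NM;
    const double* dft = C.colptr(k) + NM;
    for (int m = 0; m < NM; ++m)
      con[ic++] = tendon_residual(O.M, m, a[m], ft[m], dft[m], lmt[m], vmt[m]);
  }
  // periodicity: states
  for (int i = 0; i < NX; ++i) {
    double d = X(i, n - 1) - X(i, 0);
    if (i == 0) d -= O.v * tf;  // pelvis_tx advances by v * tf
    con[ic++] = d / O.sx[i];
  }
  // periodicity: controls (excitations and tendon-force derivatives)
  for (int m = 0; m < NU; ++m)
    con[ic++] = (C(m, n - 1) - C(m, 0)) / O.su[m];
}

// ------------------------------------------------ objective (value + parts)
struct ObjParts { double effort, track, sls, sts, total; };

// smooth step-length overshoot penalty and step-time node-count surrogate
static void symmetry_terms(const OCP& O, const arma::mat& X, double& sls,
                           double& sts, arma::mat* dq = nullptr,
                           arma::mat* du = nullptr) {
  const int n = O.n;
  // phase-weighted Simpson (no tf factor -> decoupled from final time)
  arma::vec w = simpson_weights(n, 1.0 / (n - 1));
  double sfx[NSPH], sfy[NSPH], g4[4], hx[2], hy[2];
  arma::vec IR(n), IL(n), LR(n), sepR(n);
  double acc = 0.0;
  for (int k = 0; k < n; ++k) {
    contact_eval(O.M, X.colptr(k), X.colptr(k) + NQ, sfx, sfy, g4, hx, hy, nullptr);
    double s = hx[0] - hx[1];  // fore-aft heel separation, right minus left
    sepR[k] = s;
    IR[k] = 1.0 / (1.0 + std::exp(-O.sharp_contact * (g4[1] - O.f_thresh) / O.f_thresh));
    IL[k] = 1.0 / (1.0 + std::exp(-O.sharp_contact * (g4[3] - O.f_thresh) / O.f_thresh));
    LR[k] = 1.0 / (1.0 + std::exp(-O.sharp_lead * s));
    double oR = std::log1p(std::exp(O.sharp_sl * (s - O.target_step))) / O.sharp_sl;
    double oL = std::log1p(std::exp(O.sharp_sl * (-s - O.target_step))) / O.sharp_sl;
    acc += w[k] * (oR * oR + oL * oL);
  }
  sls = acc / (O.target_step * O.target_step);
  // node-count step-time surrogate; double-support nodes go to the leading foot
  double nR = 0.0, nL = 0.0;
  for (int k = 0; k < n - 1; ++k) {  // last node duplicates the first (periodic)
    double both = IR[k] * IL[k];
    nR += IR[k] * (1.0 - IL[k]) + both * LR[k];
    nL += IL[k] * (1.0 - IR[k]) + both * (1.0 - LR[k]);
  }
  double S = nR + nL + 1e-9;
  double A = (nR - nL) / S;
  sts = A * A;
  if (dq) {
    // gradients via node-local finite differences of (sep, grf, lead)
    dq->zeros(NQ, n); du->zeros(NQ, n);
    double eps = 1e-6;
    double dnR_dIR, dnR_dIL, dnL_dIR, dnL_dIL, dnR_dLR, dnL_dLR;
    for (int k = 0; k < n; ++k) {
      arma::vec qk = X.col(k).head(NQ), uk = X.col(k).subvec(NQ, 2 * NQ - 1);
      bool counted = (k < n - 1);
      for (int j = 0; j < 2 * NQ; ++j) {
        arma::vec qp = qk, up = uk;
        if (j < NQ) qp[j] += eps; else up[j - NQ] += eps;
        contact_eval(O.M, qp.memptr(), up.memptr(), sfx, sfy, g4, hx, hy, nullptr);
        double s = hx[0] - hx[1];
        double iR = 1.0 / (1.0 + std::exp(-O.sharp_contact * (g4[1] - O.f_thresh) / O.f_thresh));
        double iL = 1.0 / (1.0 + std::exp(-O.sharp_contact * (g4[3] - O.f_thresh) / O.f_thresh));
        double lR = 1.0 / (1.0 + std::exp(-O.sharp_lead * s));
        double oR = std::log1p(std::exp(O.sharp_sl * (s - O.target_step))) / O.sharp_sl;
        double oL = std::log1p(std::exp(O.sharp_sl * (-s - O.target_step))) / O.sharp_sl;
        double oR0 = std::log1p(std::exp(O.sharp_sl * (sepR[k] - O.target_step))) / O.sharp_sl;
        double oL0 = std::log1p(std::exp(O.sharp_sl * (-sepR[k] - O.target_step))) / O.sharp_sl;
        double dsls = w[k] * ((oR * oR + oL * oL) - (oR0 * oR0 + oL0 * oL0)) / eps /
                      (O.target_step * O.target_step);
        double dsts = 0.0;
        if (counted) {
          double both0 = IR[k] * IL[k];
          double nR0k = IR[k] * (1.0 - IL[k]) + both0 * LR[k];
          double nL0k = IL[k] * (1.0 - IR[k]) + both0 * (1.0 - LR[k]);
          double both = iR * iL;
          double nRk = iR * (1.0 - iL) + both * lR;
          double nLk = iL * (1.0 - iR) + both * (1.0 - lR);
          double dnR = (nRk - nR0k) / eps, dnL = (nLk - nL0k) / eps;
          // d(A^2)/dnR = 2A * 2nL/S^2 ; d(A^2)/dnL = -2A * 2nR/S^2
          dsts = 2.0 * A * (2.0 * nL * dnR - 2.0 * nR * dnL) / (S * S);
        }
        double g = O.w_sl * dsls + O.w_st * dsts;
        if (j < NQ) (*dq)(j, k) += g; else (*du)(j - NQ, k) += g;
      }
    }
    (void)dnR_dIR; (void)dnR_dIL; (void)dnL_dIR; (void)dnL_dIL;
    (void)dnR_dLR; (void)dnL_dLR;
  }
}

static ObjParts objective_impl(const OCP& O, const arma::mat& X,
                               const arma::mat& C, double tf,
                               arma::vec* grad /* scaled, or null */) {
  const int n = O.n;
  double h = tf / (n - 1);
  arma::vec w = simpson_weights(n, h);
  ObjParts P; P.effort = P.track = P.sls = P.sts = 0.0;
  double disp = X(0, n - 1) - X(0, 0);
  // effort: integral of summed cubed excitations over displacement, with
  // the interval-consistent Hermite-Simpson quadrature (midpoint controls
  // interpolated), which leaves no node-aliasing loophole for the optimizer
  double eint = 0.0;
  int offc = n * NX;
  if (grad) grad->zeros(O.nz());
  for (int k = 0; k < n - 1; ++k) {
    for (int m = 0; m < NM; ++m) {
      double e0 = C(m, k), e1 = C(m, k + 1), em = 0.5 * (e0 + e1);
      eint += h / 6.0 * (e0 * e0 * e0 + 4.0 * em * em * em + e1 * e1 * e1);
      if (grad) {
        double g0 = h / 6.0 * (3.0 * e0 * e0 + 6.0 * em * em);
        double g1 = h / 6.0 * (3.0 * e1 * e1 + 6.0 * em * em);
        (*grad)[offc + k * NU + m] += g0 / disp * O.su[m];
        (*grad)[offc + (k + 1) * NU + m] += g1 / disp * O.su[m];
      }
    }
  }
  P.effort = eint / disp;
  if (grad) {
    (*grad)[O.nz() - 1] += (eint / tf) / disp * O.stf;
    (*grad)[(n - 1) * NX + 0] += -eint / (disp * disp) * O.sx[0];
    (*grad)[0] += eint / (disp * disp) * O.sx[0];
  }
  if (O.obj_mode == 1) {
    // tracking: SD-normalized squared deviations of q, u, and 4 GRF channels
    double sfx[NSPH], sfy[NSPH], g4[4], hx[2], hy[2];
    double acc = 0.0;
    for (int k = 0; k < n; ++k) {
      double dev = 0.0;
      for (int i = 0; i < NQ; ++i) {
        if (i == 0) continue;  // pelvis forward position is not tracked
        double dq = (X(i, k) - O.qref(i, k)) / O.sigq[i];
        double duv = (X(NQ + i, k) - O.uref(i, k)) / O.sigu[i];
        dev += O.w_track_kin * (dq * dq + duv * duv);
        if (grad) {
          (*grad)[k * NX + i] += w[k] * O.w_track_kin * 2.0 * dq / O.sigq[i] * O.sx[i];
          (*grad)[k * NX + NQ + i] +=
              w[k] * O.w_track_kin * 2.0 * duv / O.sigu[i] * O.sx[NQ + i];
        }
      }
      contact_eval(O.M, X.colptr(k), X.colptr(k) + NQ, sfx, sfy, g4, hx, hy, nullptr);
      double gdev = 0.0;
      for (int j = 0; j < 4; ++j) {
        double d = (g4[j] - O.grfref(j, k)) / O.siggrf[j];
        gdev += d * d;
      }
      dev += O.w_track_grf * gdev;
      if (grad) {
        // GRF part: node-local finite differences on (q, u)
        double eps = 1e-6;
        for (int j = 0; j < 2 * NQ; ++j) {
          arma::vec qk = X.col(k).head(NQ), uk = X.col(k).subvec(NQ, 2 * NQ - 1);
          if (j < NQ) qk[j] += eps; else uk[j - NQ] += eps;
          contact_eval(O.M, qk.memptr(), uk.memptr(), sfx, sfy, g4, hx, hy, nullptr);
          double gp = 0.0;
          for (int jj = 0; jj < 4; ++jj) {
            double d = (g4[jj] - O.grfref(jj, k)) / O.siggrf[jj];
            gp += d * d;
          }
          (*grad)[k * NX + j] += w[k] * O.w_track_grf * (gp - gdev) / eps * O.sx[j];
        }
      }
      acc += w[k] * dev;
    }
    P.track = acc;
    if (grad) (*grad)[O.nz() - 1] += (acc / tf) * O.stf;
  }
  if (O.obj_mode == 2 && (O.w_sl > 0.0 || O.w_st > 0.0)) {
    arma::mat dq, du;
    symmetry_terms(O, X, P.sls, P.sts, grad ? &dq : nullptr, grad ? &du : nullptr);
    if (grad) {
      for (int k = 0; k < n; ++k)
        for (int i = 0; i < NQ; ++i) {
          (*grad)[k * NX + i] += dq(i, k) * O.sx[i];
          (*grad)[k * NX + NQ + i] += du(i, k) * O.sx[NQ + i];
        }
    }
  }
  P.total = P.effort + P.track + O.w_sl * P.sls + O.w_st * P.sts;
  return P;
}

// -------------------------------------------------- constraint Jacobian
// Per-node state-derivative Jacobians A = df/dx, B = df/dc, computed with the
// structure of f exploited: the q-block of f is trivially u, the ftilde block
// is trivially dft, activation rows are diagonal in (e, a), and accelerations
// depend on (q, u, ftilde) only -- with the ftilde columns available in closed
// form through the factorized mass matrix.
static void node_jacobians(const GaitModel& M, const double* x, const double* c,
                           arma::mat& A, arma::mat& B) {
  A.zeros(NX, NX); B.zeros(NX, NU);
  const double* q = x;
  const double* u = x + NQ;
  const double* a = x + 2 * NQ;
  const double* ft = x + 2 * NQ + NM;
  const double* e = c;
  for (int i = 0; i < NQ; ++i) A(i, NQ + i) = 1.0;          // qdot = u
  for (int m = 0; m < NM; ++m) B(2 * NQ + NM + m, NM + m) = 1.0;  // d(ft)/dt = dft
  // acceleration block; the mass matrix depends on q only, so velocity and
  // tendon-force perturbations reuse one Cholesky factorization
  arma::mat Mm;
  mass_matrix(M, q, Mm);
  arma::mat L = arma::chol(Mm, "lower");
  arma::vec rhs0;
  fd_rhs(M, q, u, ft, rhs0);
  arma::vec qdd0 = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), rhs0));
  {
    arma::mat rhs(NQ, NM);
    for (int m = 0; m < NM; ++m)
      for (int j = 0; j < NQ; ++j) rhs(j, m) = M.arms(m, j) * M.fmax[m];
    arma::mat Minv_arms = arma::solve(arma::trimatu(L.t()),
                                      arma::solve(arma::trimatl(L), rhs));
    for (int m = 0; m < NM; ++m)
      for (int i = 0; i < NQ; ++i) A(NQ + i, 2 * NQ + NM + m) = Minv_arms(i, m);
  }
  double eps = 1e-6, qp[NQ], up[NQ], qddp[NQ];
  for (int j = 0; j < NQ; ++j) {
    std::copy(q, q + NQ, qp);
    qp[j] += eps;
    fwd_dyn(M, qp, u, ft, qddp);
    for (int i = 0; i < NQ; ++i) A(NQ + i, j) = (qddp[i] - qdd0[i]) / eps;
  }
  arma::vec rhsp;
  for (int j = 0; j < NQ; ++j) {
    std::copy(u, u + NQ, up);
    up[j] += eps;
    fd_rhs(M, q, up, ft, rhsp);
    arma::vec qp2 = arma::solve(arma::trimatu(L.t()),
                                arma::solve(arma::trimatl(L), rhsp));
    for (int i = 0; i < NQ; ++i) A(NQ + i, NQ + j) = (qp2[i] - qdd0[i]) / eps;
  }
  // activation rows: diagonal in a and e
  for (int m = 0; m < NM; ++m) {
    double f0 = act_dyn_one(e[m], a[m], M.tau_a[m], M.tau_d[m]);
    A(2 * NQ + m, 2 * NQ + m) =
        (act_dyn_one(e[m], a[m] + eps, M.tau_a[m], M.tau_d[m]) - f0) / eps;
    B(2 * NQ + m, m) =
        (act_dyn_one(e[m] + eps, a[m], M.tau_a[m], M.tau_d[m]) - f0) / eps;
  }
}

// tendon residual partials at a node: rows NM, cols (x: q,u,a,ft | c: dft)
static void tendon_jacobian(const GaitModel& M, const double* x,
                            const double* c, arma::mat& Jx, arma::vec& Jdft) {
  Jx.zeros(NM, NX); Jdft.zeros(NM);
  const double* q = x;
  const double* u = x + NQ;
  const double* a = x + 2 * NQ;
  const double* ft = x + 2 * NQ + NM;
  const double* dft = c + NM;
  double lmt[NM], vmt[NM];
  muscle_geometry(M, q, u, lmt, vmt);
  double eps = 1e-7;
  for (int m = 0; m < NM; ++m) {
    double r0 = tendon_residual(M, m, a[m], ft[m], dft[m], lmt[m], vmt[m]);
    double dr_dlmt =
        (tendon_residual(M, m, a[m], ft[m], dft[m], lmt[m] + eps, vmt[m]) - r0) / eps;
    double dr_dvmt =
        (tendon_residual(M, m, a[m], ft[m], dft[m], lmt[m], vmt[m] + eps) - r0) / eps;
    double dr_da =
        (tendon_residual(M, m, a[m] + eps, ft[m], dft[m], lmt[m], vmt[m]) - r0) / eps;
    double dr_dft =
        (tendon_residual(M, m, a[m], ft[m] + eps, dft[m], lmt[m], vmt[m]) - r0) / eps;
    Jdft[m] =
        (tendon_residual(M, m, a[m], ft[m], dft[m] + eps, lmt[m], vmt[m]) - r0) / eps;
    for (int j = 0; j < NQ; ++j) {
      double r = M.arms(m, j);
      if (r != 0.0) {
        Jx(m, j) = dr_dlmt * (-r);
        Jx(m, NQ + j) = dr_dvmt * (-r);
      }
    }
    Jx(m, 2 * NQ + m) = dr_da;
    Jx(m, 2 * NQ + NM + m) = dr_dft;
  }
}

// [[Rcpp::export(name = ".ocp_build_cpp")]]
SEXP ocp_build_cpp(SEXP mp, List opts) {
  XPtr<GaitModel> M(mp);
  OCP* O = new OCP();
  O->M = *M;
  O->n = as<int>(opts["n_nodes"]);
  O->v = as<double>(opts["speed"]);
  O->sx = as<arma::vec>(opts["sx"]);
  O->su = as<arma::vec>(opts["su"]);
  O->sd = as<arma::vec>(opts["sd"]);
  O->stf = as<double>(opts["stf"]);
  O->lb = as<arma::vec>(opts["lb"]);
  O->ub = as<arma::vec>(opts["ub"]);
  O->obj_mode = as<int>(opts["obj_mode"]);
  if (O->obj_mode == 1) {
    O->qref = as<arma::mat>(opts["qref"]);
    O->uref = as<arma::mat>(opts["uref"]);
    O->grfref = as<arma::mat>(opts["grfref"]);
    O->sigq = as<arma::vec>(opts["sigq"]);
    O->sigu = as<arma::vec>(opts["sigu"]);
    O->siggrf = as<arma::vec>(opts["siggrf"]);
    O->w_track_kin = as<double>(opts["w_track_kin"]);
    O->w_track_grf = as<double>(opts["w_track_grf"]);
  } else {
    O->w_track_kin = O->w_track_grf = 0.0;
  }
  if (O->obj_mode == 2) {
    O->w_sl = as<double>(opts["w_sl"]);
    O->w_st = as<double>(opts["w_st"]);
    O->target_step = as<double>(opts["target_step"]);
    O->sharp_sl = as<double>(opts["sharp_sl"]);
    O->f_thresh = as<double>(opts["f_thresh"]);
    O->sharp_contact = as<double>(opts["sharp_contact"]);
    O->sharp_lead = as<double>(opts["sharp_lead"]);
  } else {
    O->w_sl = O->w_st = 0.0; O->target_step = 1.0;
    O->sharp_sl = 30.0; O->f_thresh = 20.0; O->sharp_contact = 4.0;
    O->sharp_lead = 30.0;
  }
  XPtr<OCP> p(O, true);
  return p;
}

// [[Rcpp::export(name = ".ocp_dims_cpp")]]
List ocp_dims_cpp(SEXP op) {
  XPtr<OCP> O(op);
  return List::create(_["nz"] = O->nz(), _["ncon"] = O->ncon(),
                      _["n_nodes"] = O->n, _["nx"] = NX, _["nu"] = NU,
                      _["lb"] = NumericVector(O->lb.begin(), O->lb.end()),
                      _["ub"] = NumericVector(O->ub.begin(), O->ub.end()));
}

// [[Rcpp::export(name = ".ocp_constraints_cpp")]]
NumericVector ocp_constraints_cpp(SEXP op, NumericVector z) {
  XPtr<OCP> O(op);
  arma::mat X, C; double tf;
  unpack(*O, z.begin(), X, C, tf);
  arma::vec con;
  ocp_constraints_impl(*O, X, C, tf, con);
  return NumericVector(con.begin(), con.end());
}

// [[Rcpp::export(name = ".ocp_objective_cpp")]]
List ocp_objective_cpp(SEXP op, NumericVector z) {
  XPtr<OCP> O(op);
  arma::mat X, C; double tf;
  unpack(*O, z.begin(), X, C, tf);
  ObjParts P = objective_impl(*O, X, C, tf, nullptr);
  return List::create(_["total"] = P.total, _["effort"] = P.effort,
                      _["track"] = P.track, _["sls"] = P.sls, _["sts"] = P.sts);
}

// augmented-Lagrangian value and gradient:
//   phi(z) = J(z) + lambda' c(z) + (mu/2) ||c(z)||^2
// The gradient uses per-interval defect Jacobian blocks assembled from the
// nodal A, B matrices (chain rule through the Hermite midpoint state).
// [[Rcpp::export(name = ".ocp_al_cpp")]]
List ocp_al_cpp(SEXP op, NumericVector zin, NumericVector lambda, double mu,
                bool want_grad) {
  XPtr<OCP> Optr(op);
  const OCP& O = *Optr;
  const int n = O.n;
  arma::mat X, C; double tf;
  unpack(O, zin.begin(), X, C, tf);
  double h = tf / (n - 1);
  arma::vec con;
  ocp_constraints_impl(O, X, C, tf, con);
  arma::vec grad;
  ObjParts P = objective_impl(O, X, C, tf, want_grad ? &grad : nullptr);
  arma::vec lam(lambda.begin(), lambda.size());
  double phi = P.total + arma::dot(lam, con) + 0.5 * mu * arma::dot(con, con);
  if (!want_grad) {
    return List::create(_["value"] = phi, _["objective"] = P.total,
                        _["max_violation"] = arma::abs(con).max(),
                        _["effort"] = P.effort);
  }
  arma::vec y = lam + mu * con;
  // nodal Jacobians at nodes
  std::vector<arma::mat> A(n), B(n);
  for (int k = 0; k < n; ++k) node_jacobians(O.M, X.colptr(k), C.colptr(k), A[k], B[k]);
  // defect blocks
  arma::mat F(NX, n);
  for (int k = 0; k < n; ++k) state_deriv(O.M, X.colptr(k), C.colptr(k), F.colptr(k));
  arma::vec xm(NX), cm(NU), fm(NX);
  arma::mat Am(NX, NX), Bm(NX, NU);
  int offc = n * NX;
  for (int k = 0; k < n - 1; ++k) {
    for (int i = 0; i < NX; ++i)
      xm[i] = 0.5 * (X(i, k) + X(i, k + 1)) + h / 8.0 * (F(i, k) - F(i, k + 1));
    for (int i = 0; i < NU; ++i) cm[i] = 0.5 * (C(i, k) + C(i, k + 1));
    state_deriv(O.M, xm.memptr(), cm.memptr(), fm.memptr());
    node_jacobians(O.M, xm.memptr(), cm.memptr(), Am, Bm);
    // scaled defect: d = (x1 - x0 - h/6 (f0 + 4 fm + f1)) / (sx * h)
    // dd/dx0 = (-I - h/6 (A0 + 4 Am (I/2 + h/8 A0))) / (sx h)
    arma::mat M0 = 0.5 * arma::eye(NX, NX) + (h / 8.0) * A[k];
    arma::mat M1 = 0.5 * arma::eye(NX, NX) - (h / 8.0) * A[k + 1];
    arma::mat AmM0 = Am * M0, AmM1 = Am * M1;
    arma::mat D0 = -arma::eye(NX, NX) - (h / 6.0) * (A[k] + 4.0 * AmM0);
    arma::mat D1 = arma::eye(NX, NX) - (h / 6.0) * (A[k + 1] + 4.0 * AmM1);
    // controls: fm depends on cm = (c0 + c1)/2 and (via xm) on f0, f1
    arma::mat E0 = -(h / 6.0) * (B[k] + 4.0 * ((h / 8.0) * (Am * B[k]) + 0.5 * Bm));
    arma::mat E1 = -(h / 6.0) * (B[k + 1] + 4.0 * (-(h / 8.0) * (Am * B[k + 1]) + 0.5 * Bm));
    arma::vec yk = y.subvec(k * NX, (k + 1) * NX - 1);
    // row scaling 1/(sd h)
    arma::vec ys = yk / (O.sd * h);
    arma::vec g0 = D0.t() * ys, g1 = D1.t() * ys;
    arma::vec gc0 = E0.t() * ys, gc1 = E1.t() * ys;
    for (int i = 0; i < NX; ++i) {
      grad[k * NX + i] += g0[i] * O.sx[i];
      grad[(k + 1) * NX + i] += g1[i] * O.sx[i];
    }
    for (int i = 0; i < NU; ++i) {
      grad[offc + k * NU + i] += gc0[i] * O.su[i];
      grad[offc + (k + 1) * NU + i] += gc1[i] * O.su[i];
    }
    // tf-derivative of this defect block by finite difference on h
    {
      double epsh = 1e-7;
      double h2 = h + epsh;
      arma::vec xm2(NX), fm2(NX);
      for (int i = 0; i < NX; ++i)
        xm2[i] = 0.5 * (X(i, k) + X(i, k + 1)) + h2 / 8.0 * (F(i, k) - F(i, k + 1));
      state_deriv(O.M, xm2.memptr(), cm.memptr(), fm2.memptr());
      double acc = 0.0;
      for (int i = 0; i < NX; ++i) {
        double d1v = (X(i, k + 1) - X(i, k) -
                      h2 / 6.0 * (F(i, k) + 4.0 * fm2[i] + F(i, k + 1))) / (O.sd[i] * h2);
        double d0v = con[k * NX + i];
        acc += yk[i] * (d1v - d0v) / epsh;
      }
      grad[O.nz() - 1] += acc / (n - 1) * O.stf;
    }
  }
  // tendon residual blocks
  int ic0 = (n - 1) * NX;
  arma::mat Jx(NM, NX); arma::vec Jdft(NM);
  for (int k = 0; k < n; ++k) {
    tendon_jacobian(O.M, X.colptr(k), C.colptr(k), Jx, Jdft);
    arma::vec yk = y.subvec(ic0 + k * NM, ic0 + (k + 1) * NM - 1);
    arma::vec gx = Jx.t() * yk;
    for (int i = 0; i < NX; ++i) grad[k * NX + i] += gx[i] * O.sx[i];
    for (int m = 0; m < NM; ++m)
      grad[offc + k * NU + NM + m] += Jdft[m] * yk[m] * O.su[NM + m];
  }
  // periodicity blocks (linear)
  int ip0 = (n - 1) * NX + n * NM;
  for (int i = 0; i < NX; ++i) {
    double yi = y[ip0 + i] / O.sx[i];
    grad[(n - 1) * NX + i] += yi * O.sx[i];
    grad[i] += -yi * O.sx[i];
    if (i == 0) grad[O.nz() - 1] += -O.v * y[ip0] / O.sx[0] * O.stf;
  }
  for (int m = 0; m < NU; ++m) {
    double yi = y[ip0 + NX + m] / O.su[m];
    grad[offc + (n - 1) * NU + m] += yi * O.su[m];
    grad[offc + m] += -yi * O.su[m];
  }
  return List::create(_["value"] = phi, _["objective"] = P.total,
                      _["gradient"] = NumericVector(grad.begin(), grad.end()),
                      _["max_violation"] = arma::abs(con).max(),
                      _["effort"] = P.effort);
}

// Full scaled constraint Jacobian (sparse triplets), constraint values, and
// objective gradient -- consumed by the damped Gauss-Newton phase of the
// solver. Shares the block formulas of the augmented-Lagrangian gradient
// (their consistency, J' y + grad J == AL gradient, is asserted in tests).
// [[Rcpp::export(name = ".ocp_kkt_cpp")]]
List ocp_kkt_cpp(SEXP op, NumericVector zin) {
  XPtr<OCP> Optr(op);
  const OCP& O = *Optr;
  const int n = O.n;
  arma::mat X, C; double tf;
  unpack(O, zin.begin(), X, C, tf);
  double h = tf / (n - 1);
  arma::vec con;
  ocp_constraints_impl(O, X, C, tf, con);
  arma::vec gobj;
  ObjParts P = objective_impl(O, X, C, tf, &gobj);
  std::vector<int> ti, tj;
  std::vector<double> tv;
  ti.reserve(1200000); tj.reserve(1200000); tv.reserve(1200000);
  const double prune = 1e-12;
  int offc = n * NX, itf = O.nz() - 1;
  std::vector<arma::mat> A(n), B(n);
  for (int k = 0; k < n; ++k)
    node_jacobians(O.M, X.colptr(k), C.colptr(k), A[k], B[k]);
  arma::mat F(NX, n);
  for (int k = 0; k < n; ++k)
    state_deriv(O.M, X.colptr(k), C.colptr(k), F.colptr(k));
  arma::vec xm(NX), cm(NU), fm(NX);
  arma::mat Am(NX, NX), Bm(NX, NU);
  for (int k = 0; k < n - 1; ++k) {
    for (int i = 0; i < NX; ++i)
      xm[i] = 0.5 * (X(i, k) + X(i, k + 1)) + h / 8.0 * (F(i, k) - F(i, k + 1));
    for (int i = 0; i < NU; ++i) cm[i] = 0.5 * (C(i, k) + C(i, k + 1));
    state_deriv(O.M, xm.memptr(), cm.memptr(), fm.memptr());
    node_jacobians(O.M, xm.memptr(), cm.memptr(), Am, Bm);
    arma::mat M0 = 0.5 * arma::eye(NX, NX) + (h / 8.0) * A[k];
    arma::mat M1 = 0.5 * arma::eye(NX, NX) - (h / 8.0) * A[k + 1];
    arma::mat D0 = -arma::eye(NX, NX) - (h / 6.0) * (A[k] + 4.0 * (Am * M0));
    arma::mat D1 = arma::eye(NX, NX) - (h / 6.0) * (A[k + 1] + 4.0 * (Am * M1));
    arma::mat E0 = -(h / 6.0) * (B[k] + 4.0 * ((h / 8.0) * (Am * B[k]) + 0.5 * Bm));
    arma::mat E1 = -(h / 6.0) * (B[k + 1] + 4.0 * (-(h / 8.0) * (Am * B[k + 1]) + 0.5 * Bm));
    for (int i = 0; i < NX; ++i) {
      int r = k * NX + i;
      double si = 1.0 / (O.sd[i] * h);
      for (int j = 0; j < NX; ++j) {
        double v0 = D0(i, j) * O.sx[j] * si;
        if (std::abs(v0) > prune) { ti.push_back(r); tj.push_back(k * NX + j); tv.push_back(v0); }
        double v1 = D1(i, j) * O.sx[j] * si;
        if (std::abs(v1) > prune) { ti.push_back(r); tj.push_back((k + 1) * NX + j); tv.push_back(v1); }
      }
      for (int j = 0; j < NU; ++j) {
        double v0 = E0(i, j) * O.su[j] * si;
        if (std::abs(v0) > prune) { ti.push_back(r); tj.push_back(offc + k * NU + j); tv.push_back(v0); }
        double v1 = E1(i, j) * O.su[j] * si;
        if (std::abs(v1) > prune) { ti.push_back(r); tj.push_back(offc + (k + 1) * NU + j); tv.push_back(v1); }
      }
    }
    // tf column by finite difference on h
    {
      double epsh = 1e-7, h2 = h + epsh;
      arma::vec xm2(NX), fm2(NX);
      for (int i = 0; i < NX; ++i)
        xm2[i] = 0.5 * (X(i, k) + X(i, k + 1)) + h2 / 8.0 * (F(i, k) - F(i, k + 1));
      state_deriv(O.M, xm2.memptr(), cm.memptr(), fm2.memptr());
      for (int i = 0; i < NX; ++i) {
        double d1v = (X(i, k + 1) - X(i, k) -
                      h2 / 6.0 * (F(i, k) + 4.0 * fm2[i] + F(i, k + 1))) /
                     (O.sd[i] * h2);
        double v = (d1v - con[k * NX + i]) / epsh / (n - 1) * O.stf;
        if (std::abs(v) > prune) { ti.push_back(k * NX + i); tj.push_back(itf); tv.push_back(v); }
      }
    }
  }
  int ic0 = (n - 1) * NX;
  arma::mat Jx(NM, NX); arma::vec Jdft(NM);
  for (int k = 0; k < n; ++k) {
    tendon_jacobian(O.M, X.colptr(k), C.colptr(k), Jx, Jdft);
    for (int m = 0; m < NM; ++m) {
      int r = ic0 + k * NM + m;
      for (int i = 0; i < NX; ++i) {
        double v = Jx(m, i) * O.sx[i];
        if (std::abs(v) > prune) { ti.push_back(r); tj.push_back(k * NX + i); tv.push_back(v); }
      }
      double v = Jdft[m] * O.su[NM + m];
      if (std::abs(v) > prune) {
        ti.push_back(r); tj.push_back(offc + k * NU + NM + m); tv.push_back(v);
      }
    }
  }
  int ip0 = (n - 1) * NX + n * NM;
  for (int i = 0; i < NX; ++i) {
    ti.push_back(ip0 + i); tj.push_back((n - 1) * NX + i); tv.push_back(1.0);
    ti.push_back(ip0 + i); tj.push_back(i); tv.push_back(-1.0);
  }
  { ti.push_back(ip0); tj.push_back(itf); tv.push_back(-O.v * O.stf / O.sx[0]); }
  for (int m = 0; m < NU; ++m) {
    ti.push_back(ip0 + NX + m); tj.push_back(offc + (n - 1) * NU + m); tv.push_back(1.0);
    ti.push_back(ip0 + NX + m); tj.push_back(offc + m); tv.push_back(-1.0);
  }
  return List::create(_["con"] = NumericVector(con.begin(), con.end()),
                      _["grad_obj"] = NumericVector(gobj.begin(), gobj.end()),
                      _["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["x"] = NumericVector(tv.begin(), tv.end()),
                      _["objective"] = P.total, _["effort"] = P.effort);
}

// symmetry goal values on a given trajectory (post-hoc / testing)
// [[Rcpp::export(name = ".symmetry_terms_cpp")]]
List symmetry_terms_cpp(SEXP mp, NumericMatrix X, double target_step,
                        double sharp_sl, double f_thresh, double sharp_contact,
                        double sharp_lead) {
  XPtr<GaitModel> M(mp);
  OCP O;
  O.M = *M;
  O.n = X.ncol();
  O.target_step = target_step; O.sharp_sl = sharp_sl; O.f_thresh = f_thresh;
  O.sharp_contact = sharp_contact; O.sharp_lead = sharp_lead;
  O.w_sl = 1.0; O.w_st = 1.0;
  arma::mat Xa(X.begin(), X.nrow(), X.ncol());
  double sls, sts;
  symmetry_terms(O, Xa, sls, sts);
  return List::create(_["sls"] = sls, _["sts"] = sts);
}
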