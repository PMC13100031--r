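// Planar neuromusculoskeletal simulation core.
//
// Rigid-body dynamics of a planar kinematic tree (floating, planar-translation,
// revolute and prismatic joints) via recursive Newton-Euler inverse dynamics:
// the joint-space mass matrix is assembled column-wise from unit-acceleration
// inverse-dynamics calls and the equations of motion are solved each step.
// Muscles are Hill-type musculotendon units with series-elastic tendon,
// Gaussian force-length, hyperbolic force-velocity and first-order activation
// dynamics; they act on joint coordinates through constant moment arms.
// Ground contact is a smooth viscoelastic (Hunt-Crossley style) normal force
// with regularized Coulomb friction at designated body-fixed points.
// The reflex controller computes per-muscle stimulation from delayed
// normalized CE length and tendon force through a fixed connection list.
//
// Integration: fixed-step semi-implicit (symplectic) Euler.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Vec2 {
  double x, y;
  Vec2(double x_ = 0.0, double y_ = 0.0) : x(x_), y(y_) {}
  Vec2 operator+(const Vec2& o) const { return Vec2(x + o.x, y + o.y); }
  Vec2 operator-(const Vec2& o) const { return Vec2(x - o.x, y - o.y); }
  Vec2 operator*(double s) const { return Vec2(x * s, y * s); }
};
inline double cross2(const Vec2& a, const Vec2& b) { return a.x * b.y - a.y * b.x; }
inline Vec2 zcross(double w, const Vec2& r) { return Vec2(-w * r.y, w * r.x); }
inline double dot2(const Vec2& a, const Vec2& b) { return a.x * b.x + a.y * b.y; }

enum JointType { JT_FLOATING = 0, JT_REVOLUTE = 1, JT_PRISMATIC = 2, JT_PLANAR_XY = 3 };

struct Body {
  int parent;       // -1 = world
  int jtype;
  Vec2 anchor;      // joint anchor in parent frame
  Vec2 axis;        // prismatic axis in parent frame (unit)
  double mass;
  double inertia;   // about CoM
  Vec2 com;         // CoM in body frame
  int dof0;         // first generalized coordinate index
  int ndof;
};

struct BodyKin {
  double th;          // world orientation
  double c, s;        // cos/sin of th
  Vec2 o;             // world position of body frame origin
  double w;           // angular velocity
  Vec2 v;             // velocity of body origin (as material point)
  double al;          // angular acceleration
  Vec2 a;             // acceleration of body origin
  Vec2 comw;          // world CoM
  Vec2 uw;            // world prismatic axis (prismatic joints)
};

struct Muscle {
  double fmax, lopt, lslack, vmax; // vmax in lopt/s
  double tau_act, tau_deact;
  int delay_steps;
  double lref;        // MTU path length at q = 0
  double flw;         // force-length Gaussian width
  double fv_k;        // shortening curvature (Hill a/F0)
  double fv_ml;       // eccentric force plateau
  double eps_ref;     // tendon strain at fmax
  std::vector<double> marm; // moment arm per dof (torque = marm * F)
};

struct ContactPt {
  int body;
  Vec2 pt;            // in body frame
};

struct ContactPar {
  double k_n, exp_n, c_hc, mu, v_reg;
};

struct Model {
  std::vector<Body> bodies;
  int ndof;
  std::vector<double> damping;                 // per dof
  std::vector<double> lim_lo, lim_hi, lim_k, lim_d; // per dof (NaN = none)
  double gravity;                              // positive magnitude, acts in -y
  std::vector<ContactPt> contacts;
  ContactPar cpar;
  std::vector<Muscle> muscles;
  std::vector<int> conn_tgt, conn_src;         // controller connections (muscle idx)
  double u_min, u_max;
};

Model parse_model(const List& ml) {
  Model m;
  List bl = ml["bodies"];
  IntegerVector parent = bl["parent"];
  IntegerVector jtype = bl["jtype"];
  NumericMatrix anchor = bl["anchor"];
  NumericMatrix axis = bl["axis"];
  NumericVector mass = bl["mass"];
  NumericVector inertia = bl["inertia"];
  NumericMatrix com = bl["com"];
  int nb = parent.size();
  int dof = 0;
  for (int i = 0; i < nb; ++i) {
    Body b;
    b.parent = parent[i];
    b.jtype = jtype[i];
    b.anchor = Vec2(anchor(i, 0), anchor(i, 1));
    b.axis = Vec2(axis(i, 0), axis(i, 1));
    b.mass = mass[i];
    b.inertia = inertia[i];
    b.com = Vec2(com(i, 0), com(i, 1));
    b.dof0 = dof;
    b.ndof = (b.jtype == JT_FLOATING) ? 3 : (b.jtype == JT_PLANAR_XY ? 2 : 1);
    dof += b.ndof;
    if (b.parent >= i) stop("bodies must be ordered parents-first");
    m.bodies.push_back(b);
  }
  m.ndof = dof;
  NumericVector damp = ml["damping"];
  m.damping.assign(damp.begin(), damp.end());
  NumericMatrix lim = ml["limits"]; // ndof x 4: lo hi k d
  for (int d = 0; d < dof; ++d) {
    m.lim_lo.push_back(lim(d, 0));
    m.lim_hi.push_back(lim(d, 1));
    m.lim_k.push_back(lim(d, 2));
    m.lim_d.push_back(lim(d, 3));
  }
  m.gravity = as<double>(ml["gravity"]);
  List cl = ml["contacts"];
  IntegerVector cbody = cl["body"];
  NumericMatrix cpt = cl["point"];
  for (int i = 0; i < cbody.size(); ++i) {
    ContactPt c;
    c.body = cbody[i];
    c.pt = Vec2(cpt(i, 0), cpt(i, 1));
    m.contacts.push_back(c);
  }
  List cp = ml["contact_params"];
  m.cpar.k_n = as<double>(cp["k_n"]);
  m.cpar.exp_n = as<double>(cp["exp_n"]);
  m.cpar.c_hc = as<double>(cp["c_hc"]);
  m.cpar.mu = as<double>(cp["mu"]);
  m.cpar.v_reg = as<double>(cp["v_reg"]);
  List mus = ml["muscles"];
  NumericVector fmax = mus["fmax"], lopt = mus["lopt"], lslack = mus["lslack"],
                vmax = mus["vmax"], ta = mus["tau_act"], td = mus["tau_deact"],
                lref = mus["lref"], flw = mus["flw"], fvk = mus["fv_k"],
                fvml = mus["fv_ml"], epsr = mus["eps_ref"];
  IntegerVector dsteps = mus["delay_steps"];
  NumericMatrix marm = mus["marm"]; // nm x ndof
  for (int i = 0; i < fmax.size(); ++i) {
    Muscle mu;
    mu.fmax = fmax[i]; mu.lopt = lopt[i]; mu.lslack = lslack[i]; mu.vmax = vmax[i];
    mu.tau_act = ta[i]; mu.tau_deact = td[i]; mu.delay_steps = dsteps[i];
    mu.lref = lref[i]; mu.flw = flw[i]; mu.fv_k = fvk[i]; mu.fv_ml = fvml[i];
    mu.eps_ref = epsr[i];
    mu.marm.resize(dof);
    for (int d = 0; d < dof; ++d) mu.marm[d] = marm(i, d);
    m.muscles.push_back(mu);
  }
  List ctrl = ml["controller"];
  IntegerVector ct = ctrl["conn_tgt"], cs = ctrl["conn_src"];
  m.conn_tgt.assign(ct.begin(), ct.end());
  m.conn_src.assign(cs.begin(), cs.end());
  m.u_min = as<double>(ctrl["u_min"]);
  m.u_max = as<double>(ctrl["u_max"]);
  return m;
}

// Forward kinematics (positions/velocities/accelerations).
// a0y: fictitious upward world acceleration (gravity trick); pass 0 for none.
void fk(const Model& m, const double* q, const double* qd, const double* qdd,
        double a0y, std::vector<BodyKin>& K) {
  int nb = (int)m.bodies.size();
  K.resize(nb);
  for (int i = 0; i < nb; ++i) {
    const Body& b = m.bodies[i];
    BodyKin pk; // parent kinematics (world if parent < 0)
    if (b.parent >= 0) pk = K[b.parent];
    else {
      pk.th = 0; pk.c = 1; pk.s = 0; pk.o = Vec2(0, 0); pk.w = 0;
      pk.v = Vec2(0, 0); pk.al = 0; pk.a = Vec2(0, a0y);
    }
    BodyKin k;
    Vec2 aw(pk.c * b.anchor.x - pk.s * b.anchor.y,
            pk.s * b.anchor.x + pk.c * b.anchor.y); // anchor in world axes
    Vec2 ap = pk.o + aw;                            // anchor world position
    Vec2 v_ap = pk.v + zcross(pk.w, aw);
    Vec2 a_ap = pk.a + zcross(pk.al, aw) + zcross(pk.w, zcross(pk.w, aw));
    switch (b.jtype) {
      case JT_FLOATING: {
        k.th = q[b.dof0 + 2];
        k.o = Vec2(q[b.dof0], q[b.dof0 + 1]);
        k.w = qd[b.dof0 + 2];
        k.v = Vec2(qd[b.dof0], qd[b.dof0 + 1]);
        k.al = qdd[b.dof0 + 2];
        k.a = Vec2(qdd[b.dof0], qdd[b.dof0 + 1]) + Vec2(0, a0y);
        break;
      }
      case JT_PLANAR_XY: {
        k.th = 0;
        k.o = Vec2(q[b.dof0], q[b.dof0 + 1]);
        k.w = 0;
        k.v = Vec2(qd[b.dof0], qd[b.dof0 + 1]);
        k.al = 0;
        k.a = Vec2(qdd[b.dof0], qdd[b.dof0 + 1]) + Vec2(0, a0y);
        break;
      }
      case JT_REVOLUTE: {
        k.th = pk.th + q[b.dof0];
        k.o = ap;
        k.w = pk.w + qd[b.dof0];
        k.v = v_ap;
        k.al = pk.al + qdd[b.dof0];
        k.a = a_ap;
        break;
      }
      case JT_PRISMATIC: {
        double s = q[b.dof0], sd = qd[b.dof0], sdd = qdd[b.dof0];
        Vec2 uw(pk.c * b.axis.x - pk.s * b.axis.y,
                pk.s * b.axis.x + pk.c * b.axis.y);
        k.th = pk.th;
        k.o = ap + uw * s;
        k.w = pk.w;
        k.v = v_ap + uw * sd + zcross(pk.w, uw * s);
        k.al = pk.al;
        k.a = a_ap + uw * sdd + zcross(pk.w, uw * sd) * 2.0 +
              zcross(pk.al, uw * s) + zcross(pk.w, zcross(pk.w, uw * s));
        k.uw = uw;
        break;
      }
      default: stop("unknown joint type");
    }
    k.c = std::cos(k.th);
    k.s = std::sin(k.th);
    Vec2 cw(k.c * b.com.x - k.s * b.com.y, k.s * b.com.x + k.c * b.com.y);
    k.comw = k.o + cw;
    K[i] = k;
  }
}

// Inverse dynamics: generalized forces realizing qdd at (q, qd) under gravity
// (if gravity_on). Backward Newton-Euler over the tree.
void inverse_dynamics(const Model& m, const double* q, const double* qd,
                      const double* qdd, bool gravity_on, double* tau,
                      std::vector<BodyKin>& K) {
  int nb = (int)m.bodies.size();
  fk(m, q, qd, qdd, gravity_on ? m.gravity : 0.0, K);
  std::vector<Vec2> f(nb);
  std::vector<double> n(nb); // moment about body origin
  for (int i = 0; i < nb; ++i) {
    const Body& b = m.bodies[i];
    const BodyKin& k = K[i];
    Vec2 rc = k.comw - k.o;
    Vec2 acom = k.a + zcross(k.al, rc) + zcross(k.w, zcross(k.w, rc));
    f[i] = acom * b.mass;
    n[i] = b.inertia * k.al + cross2(rc, f[i]);
  }
  for (int i = nb - 1; i >= 0; --i) {
    int p = m.bodies[i].parent;
    if (p >= 0) {
      f[p] = f[p] + f[i];
      n[p] += n[i] + cross2(K[i].o - K[p].o, f[i]);
    }
  }
  for (int i = 0; i < nb; ++i) {
    const Body& b = m.bodies[i];
    switch (b.jtype) {
      case JT_FLOATING:
        tau[b.dof0] = f[i].x; tau[b.dof0 + 1] = f[i].y; tau[b.dof0 + 2] = n[i];
        break;
      case JT_PLANAR_XY:
        tau[b.dof0] = f[i].x; tau[b.dof0 + 1] = f[i].y;
        break;
      case JT_REVOLUTE:
        tau[b.dof0] = n[i];
        break;
      case JT_PRISMATIC:
        tau[b.dof0] = dot2(f[i], K[i].uw);
        break;
    }
  }
}

// World position/velocity of a point fixed on a body (kinematics precomputed).
inline void point_state(const Model& m, const std::vector<BodyKin>& K, int body,
                        const Vec2& pt, Vec2& pw, Vec2& vw) {
  const BodyKin& k = K[body];
  Vec2 rw(k.c * pt.x - k.s * pt.y, k.s * pt.x + k.c * pt.y);
  pw = k.o + rw;
  vw = k.v + zcross(k.w, rw);
}

// tau += J^T f for a force f applied at world point pw on `body`.
void apply_point_force(const Model& m, const std::vector<BodyKin>& K, int body,
                       const Vec2& pw, const Vec2& f, double* tau) {
  int i = body;
  while (i >= 0) {
    const Body& b = m.bodies[i];
    const BodyKin& k = K[i];
    switch (b.jtype) {
      case JT_FLOATING: {
        tau[b.dof0] += f.x;
        tau[b.dof0 + 1] += f.y;
        Vec2 r = pw - k.o;
        tau[b.dof0 + 2] += cross2(r, f);
        break;
      }
      case JT_PLANAR_XY:
        tau[b.dof0] += f.x;
        tau[b.dof0 + 1] += f.y;
        break;
      case JT_REVOLUTE: {
        Vec2 r = pw - k.o;
        tau[b.dof0] += cross2(r, f);
        break;
      }
      case JT_PRISMATIC:
        tau[b.dof0] += dot2(f, k.uw);
        break;
    }
    i = b.parent;
  }
}

struct ContactForce { double fn, ft; };

// Viscoelastic normal force + regularized Coulomb friction; adds into tau.
void contact_forces(const Model& m, const std::vector<BodyKin>& K, double* tau,
                    std::vector<ContactForce>& out) {
  const ContactPar& cp = m.cpar;
  out.resize(m.contacts.size());
  for (size_t ci = 0; ci < m.contacts.size(); ++ci) {
    Vec2 pw, vw;
    point_state(m, K, m.contacts[ci].body, m.contacts[ci].pt, pw, vw);
    double fn = 0.0, ft = 0.0;
    if (pw.y < 0.0) {
      double d = -pw.y;      // penetration depth
      double ddot = -vw.y;   // penetration rate
      fn = cp.k_n * std::pow(d, cp.exp_n) * (1.0 + cp.c_hc * ddot);
      if (fn < 0.0) fn = 0.0;
      double s = vw.x / cp.v_reg;
      if (s > 1.0) s = 1.0;
      if (s < -1.0) s = -1.0;
      ft = -cp.mu * fn * s;
      Vec2 f(ft, fn);
      if (tau) apply_point_force(m, K, m.contacts[ci].body, pw, f, tau);
    }
    out[ci].fn = fn;
    out[ci].ft = ft;
  }
}

// --- Hill-type MTU ------------------------------------------------------

inline double tendon_force(const Muscle& mu, double lt) {
  double eps = (lt - mu.lslack) / mu.lslack;
  if (eps <= 0.0) return 0.0;
  if (eps <= mu.eps_ref) {
    double r = eps / mu.eps_ref;
    return mu.fmax * r * r;
  }
  // linear continuation beyond reference strain (stiffness continuity)
  return mu.fmax * (1.0 + 2.0 / mu.eps_ref * (eps - mu.eps_ref));
}

inline double force_length(const Muscle& mu, double lce_n) {
  double z = (lce_n - 1.0) / mu.flw;
  return std::exp(-z * z);
}

inline double parallel_force(const Muscle& mu, double lce_n) {
  if (lce_n <= 1.0) return 0.0;
  double z = (lce_n - 1.0) / 0.56;
  return z * z; // normalized by fmax
}

// Invert the force-velocity relation: given required normalized CE force
// factor fv (= F_ce / (a * fl * fmax)), return CE velocity in lopt/s
// (negative = shortening).
inline double invert_fv(const Muscle& mu, double fv) {
  double lo = 0.0, hi = mu.fv_ml - 1e-3;
  if (fv < lo) fv = lo;
  if (fv > hi) fv = hi;
  double ik = 1.0 / mu.fv_k;
  if (fv <= 1.0) return mu.vmax * (fv - 1.0) / (1.0 + ik * fv);
  // eccentric branch, slope-continuous at fv = 1
  double c = (mu.fv_ml - 1.0) / (1.0 + ik);
  return mu.vmax * c * (fv - 1.0) / (mu.fv_ml - fv);
}

struct MuscleState {
  double act;
  double lce;
};

// One MTU update: activation dynamics + CE advance. Returns tendon force
// computed at the *incoming* state (used both as the applied force and the
// force sensor sample of this step).
double mtu_advance(const Muscle& mu, MuscleState& st, double stim, double lmt,
                   double dt) {
  double lt = lmt - st.lce;
  double fse = tendon_force(mu, lt);
  // activation dynamics (first order, asymmetric time constants)
  double tau = (stim > st.act) ? mu.tau_act : mu.tau_deact;
  st.act += dt * (stim - st.act) / tau;
  if (st.act < 0.0) st.act = 0.0;
  if (st.act > 1.0) st.act = 1.0;
  // CE velocity from force equilibrium F_se = fmax*(a*fl*fv + fpe)
  double lce_n = st.lce / mu.lopt;
  double fl = force_length(mu, lce_n);
  double fpe = parallel_force(mu, lce_n);
  double af = st.act * fl;
  if (af < 1e-4) af = 1e-4;
  double fv = (fse / mu.fmax - fpe) / af;
  double vce_n = invert_fv(mu, fv); // lopt/s
  st.lce += vce_n * mu.lopt * dt;
  double lo = 0.3 * mu.lopt, hi = 1.8 * mu.lopt;
  if (st.lce < lo) st.lce = lo;
  if (st.lce > hi) st.lce = hi;
  return fse;
}

inline double mtu_path_length(const Model& m, int mi, const double* q) {
  const Muscle& mu = m.muscles[mi];
  double l = mu.lref;
  for (int d = 0; d < m.ndof; ++d) l -= mu.marm[d] * q[d];
  return l;
}

void total_com(const Model& m, const std::vector<BodyKin>& K, double& cx,
               double& cy, double& mass) {
  cx = cy = mass = 0.0;
  for (size_t i = 0; i < m.bodies.size(); ++i) {
    cx += m.bodies[i].mass * K[i].comw.x;
    cy += m.bodies[i].mass * K[i].comw.y;
    mass += m.bodies[i].mass;
  }
  cx /= mass;
  cy /= mass;
}

} // namespace

// [[Rcpp::export]]
List cpp_fk(List model, NumericVector q) {
  Model m = parse_model(model);
  std::vector<double> z(m.ndof, 0.0);
  std::vector<BodyKin> K;
  fk(m, REAL(q), z.data(), z.data(), 0.0, K);
  int nb = (int)m.bodies.size();
  NumericMatrix com(nb, 2), origin(nb, 2);
  NumericVector th(nb);
  for (int i = 0; i < nb; ++i) {
    com(i, 0) = K[i].comw.x; com(i, 1) = K[i].comw.y;
    origin(i, 0) = K[i].o.x; origin(i, 1) = K[i].o.y;
    th[i] = K[i].th;
  }
  double cx, cy, mass;
  total_com(m, K, cx, cy, mass);
  int nc = (int)m.contacts.size();
  NumericMatrix cpts(nc, 2);
  for (int i = 0; i < nc; ++i) {
    Vec2 pw, vw;
    point_state(m, K, m.contacts[i].body, m.contacts[i].pt, pw, vw);
    cpts(i, 0) = pw.x; cpts(i, 1) = pw.y;
  }
  return List::create(_["com"] = com, _["origin"] = origin, _["theta"] = th,
                      _["total_com"] = NumericVector::create(cx, cy),
                      _["total_mass"] = mass, _["contact_points"] = cpts);
}

// [[Rcpp::export]]
NumericVector cpp_mtu_lengths(List model, NumericVector q) {
  Model m = parse_model(model);
  NumericVector out(m.muscles.size());
  for (size_t i = 0; i < m.muscles.size(); ++i)
    out[i] = mtu_path_length(m, (int)i, REAL(q));
  return out;
}

// [[Rcpp::export]]
List cpp_contact_wrench(List model, NumericVector q, NumericVector qd) {
  Model m = parse_model(model);
  std::vector<double> z(m.ndof, 0.0);
  std::vector<BodyKin> K;
  fk(m, REAL(q), REAL(qd), z.data(), 0.0, K);
  std::vector<double> tau(m.ndof, 0.0);
  std::vector<ContactForce> cf;
  contact_forces(m, K, tau.data(), cf);
  int nc = (int)cf.size();
  NumericVector fn(nc), ft(nc);
  for (int i = 0; i < nc; ++i) { fn[i] = cf[i].fn; ft[i] = cf[i].ft; }
  return List::create(_["normal"] = fn, _["tangential"] = ft,
                      _["tau"] = NumericVector(tau.begin(), tau.end()));
}

// [[Rcpp::export]]
List cpp_mtu_step(List mus, double act, double lce, double stim, double lmt,
                  double dt) {
  if (!std::isfinite(stim) || !std::isfinite(lmt) || !std::isfinite(lce) ||
      !std::isfinite(act))
    stop("non-finite MTU input");
  Muscle mu;
  mu.fmax = as<double>(mus["fmax"]); mu.lopt = as<double>(mus["lopt"]);
  mu.lslack = as<double>(mus["lslack"]); mu.vmax = as<double>(mus["vmax"]);
  mu.tau_act = as<double>(mus["tau_act"]); mu.tau_deact = as<double>(mus["tau_deact"]);
  mu.flw = as<double>(mus["flw"]); mu.fv_k = as<double>(mus["fv_k"]);
  mu.fv_ml = as<double>(mus["fv_ml"]); mu.eps_ref = as<double>(mus["eps_ref"]);
  MuscleState st; st.act = act; st.lce = lce;
  double f = mtu_advance(mu, st, stim, lmt, dt);
  return List::create(_["act"] = st.act, _["lce"] = st.lce, _["force"] = f);
}

// [[Rcpp::export]]
List cpp_step_dynamics(List model, NumericVector q, NumericVector qd,
                       NumericVector muscle_force, double dt, bool use_contact,
                       bool use_gravity, bool use_passive) {
  Model m = parse_model(model);
  int nd = m.ndof;
  for (int i = 0; i < nd; ++i)
    if (!std::isfinite(q[i]) || !std::isfinite(qd[i]))
      stop("non-finite state");
  std::vector<double> z(nd, 0.0), tau(nd, 0.0), bias(nd);
  std::vector<BodyKin> K;
  // applied generalized forces
  fk(m, REAL(q), REAL(qd), z.data(), 0.0, K);
  for (size_t mi = 0; mi < m.muscles.size(); ++mi)
    for (int d = 0; d < nd; ++d)
      tau[d] += m.muscles[mi].marm[d] * muscle_force[mi];
  if (use_passive) {
    for (int d = 0; d < nd; ++d) {
      tau[d] -= m.damping[d] * qd[d];
      if (!std::isnan(m.lim_lo[d]) && q[d] < m.lim_lo[d])
        tau[d] += m.lim_k[d] * (m.lim_lo[d] - q[d]) - m.lim_d[d] * qd[d];
      if (!std::isnan(m.lim_hi[d]) && q[d] > m.lim_hi[d])
        tau[d] += m.lim_k[d] * (m.lim_hi[d] - q[d]) - m.lim_d[d] * qd[d];
    }
  }
  std::vector<ContactForce> cf;
  if (use_contact) contact_forces(m, K, tau.data(), cf);
  inverse_dynamics(m, REAL(q), REAL(qd), z.data(), use_gravity, bias.data(), K);
  arma::mat M(nd, nd);
  std::vector<double> e(nd, 0.0), col(nd);
  for (int j = 0; j < nd; ++j) {
    e[j] = 1.0;
    inverse_dynamics(m, REAL(q), z.data(), e.data(), false, col.data(), K);
    for (int i = 0; i < nd; ++i) M(i, j) = col[i];
    e[j] = 0.0;
  }
  arma::vec rhs(nd);
  for (int i = 0; i < nd; ++i) rhs[i] = tau[i] - bias[i];
  arma::vec qdd = arma::solve(M, rhs, arma::solve_opts::fast);
  NumericVector qn(nd), qdn(nd);
  for (int i = 0; i < nd; ++i) {
    qdn[i] = qd[i] + dt * qdd[i];
    qn[i] = q[i] + dt * qdn[i];
    if (!std::isfinite(qn[i]) || !std::isfinite(qdn[i]))
      stop("integration diverged (non-finite state)");
  }
  return List::create(_["q"] = qn, _["qd"] = qdn);
}

// Full episode with piecewise-constant controller gains.
//
// segments: list(t = start times (first 0), KL = nseg x nconn, KF = nseg x
// nconn, C = nseg x nmusc). cfg: dt, t_max, fall_y (NaN disables), record_dt,
// q0, qd0, act0, lce0 (NaN = auto from slack tendon at q0).
// [[Rcpp::export]]
List cpp_simulate(List model, List segments, List cfg) {
  Model m = parse_model(model);
  int nd = m.ndof, nm = (int)m.muscles.size(), nc = (int)m.contacts.size();
  int nconn = (int)m.conn_tgt.size();

  double dt = as<double>(cfg["dt"]);
  double t_max = as<double>(cfg["t_max"]);
  double fall_y = as<double>(cfg["fall_y"]);
  double record_dt = as<double>(cfg["record_dt"]);
  NumericVector q0 = cfg["q0"], qd0 = cfg["qd0"], act0 = cfg["act0"],
                lce0 = cfg["lce0"];

  NumericVector seg_t = segments["t"];
  NumericMatrix seg_KL = segments["KL"], seg_KF = segments["KF"],
                seg_C = segments["C"];
  int nseg = seg_t.size();

  std::vector<double> q(q0.begin(), q0.end()), qd(qd0.begin(), qd0.end());
  std::vector<MuscleState> ms(nm);
  for (int i = 0; i < nm; ++i) {
    ms[i].act = act0[i];
    double lmt0 = mtu_path_length(m, i, q.data());
    ms[i].lce = std::isnan(lce0[i])
                    ? std::min(std::max(lmt0 - m.muscles[i].lslack,
                                        0.3 * m.muscles[i].lopt),
                               1.8 * m.muscles[i].lopt)
                    : lce0[i];
  }

  // delayed-sensor ring buffers, initialized with the first sample
  int maxdel = 1;
  for (int i = 0; i < nm; ++i)
    maxdel = std::max(maxdel, m.muscles[i].delay_steps + 1);
  std::vector<std::vector<double>> bufL(nm), bufF(nm);

  long nsteps = (long)std::llround(t_max / dt);
  int rec_every = std::max(1, (int)std::llround(record_dt / dt));
  int nrec_cap = (int)(nsteps / rec_every) + 2;

  NumericVector rt(nrec_cap);
  NumericMatrix rq(nrec_cap, nd), rqd(nrec_cap, nd), rcom(nrec_cap, 2),
      rscx(nrec_cap, (int)m.bodies.size()), rscy(nrec_cap, (int)m.bodies.size()),
      ract(nrec_cap, nm), rfor(nrec_cap, nm), rlce(nrec_cap, nm),
      rstim(nrec_cap, nm), rcn(nrec_cap, std::max(nc, 1)),
      rct(nrec_cap, std::max(nc, 1)), rLd(nrec_cap, nm), rFd(nrec_cap, nm);
  int nrec = 0;

  std::vector<double> zero(nd, 0.0), tau(nd), bias(nd), lmt(nm), stim(nm),
      fmus(nm), Ld(nm), Fd(nm);
  std::vector<BodyKin> K;
  std::vector<ContactForce> cf;
  arma::mat M(nd, nd);
  arma::vec rhs(nd), qdd(nd);
  std::vector<double> e(nd, 0.0), col(nd);

  int status = 0; // 0 completed, 1 fell, 2 non-finite
  double t = 0.0, t_sim = t_max;
  int seg = 0;
  long bufpos = 0;

  for (long step = 0; step <= nsteps; ++step) {
    t = step * dt;
    // advance active gain segment
    while (seg + 1 < nseg && t >= seg_t[seg + 1] - 1e-12) ++seg;

    fk(m, q.data(), qd.data(), zero.data(), 0.0, K);

    // sensor samples at the current state
    for (int i = 0; i < nm; ++i) {
      lmt[i] = mtu_path_length(m, i, q.data());
      double Lnow = ms[i].lce / m.muscles[i].lopt;
      double Fnow = tendon_force(m.muscles[i], lmt[i] - ms[i].lce) /
                    m.muscles[i].fmax;
      if (step == 0) {
        bufL[i].assign(m.muscles[i].delay_steps + 1, Lnow);
        bufF[i].assign(m.muscles[i].delay_steps + 1, Fnow);
      } else {
        int len = (int)bufL[i].size();
        bufL[i][bufpos % len] = Lnow;
        bufF[i][bufpos % len] = Fnow;
      }
      int len = (int)bufL[i].size();
      long idx = (bufpos - m.muscles[i].delay_steps);
      if (idx < 0) idx = 0;
      Ld[i] = bufL[i][idx % len];
      Fd[i] = bufF[i][idx % len];
    }

    // reflex controller
    for (int i = 0; i < nm; ++i) stim[i] = seg_C(seg, i);
    for (int ci = 0; ci < nconn; ++ci) {
      int tgt = m.conn_tgt[ci], src = m.conn_src[ci];
      stim[tgt] += seg_KL(seg, ci) * Ld[src] + seg_KF(seg, ci) * Fd[src];
    }
    for (int i = 0; i < nm; ++i) {
      if (stim[i] < m.u_min) stim[i] = m.u_min;
      if (stim[i] > m.u_max) stim[i] = m.u_max;
    }

    // MTU forces and state advance
    for (int i = 0; i < nm; ++i)
      fmus[i] = mtu_advance(m.muscles[i], ms[i], stim[i], lmt[i], dt);

    // applied generalized forces
    std::fill(tau.begin(), tau.end(), 0.0);
    for (int i = 0; i < nm; ++i)
      for (int d = 0; d < nd; ++d) tau[d] += m.muscles[i].marm[d] * fmus[i];
    for (int d = 0; d < nd; ++d) {
      tau[d] -= m.damping[d] * qd[d];
      if (!std::isnan(m.lim_lo[d]) && q[d] < m.lim_lo[d])
        tau[d] += m.lim_k[d] * (m.lim_lo[d] - q[d]) - m.lim_d[d] * qd[d];
      if (!std::isnan(m.lim_hi[d]) && q[d] > m.lim_hi[d])
        tau[d] += m.lim_k[d] * (m.lim_hi[d] - q[d]) - m.lim_d[d] * qd[d];
    }
    contact_forces(m, K, tau.data(), cf);

    // record (pre-step state)
    double cx, cy, mass;
    total_com(m, K, cx, cy, mass);
    bool fell = !std::isnan(fall_y) && cy < fall_y;
    bool last = (step == nsteps) || fell;
    if (step % rec_every == 0 || last) {
      rt[nrec] = t;
      for (int d = 0; d < nd; ++d) { rq(nrec, d) = q[d]; rqd(nrec, d) = qd[d]; }
      rcom(nrec, 0) = cx; rcom(nrec, 1) = cy;
      for (size_t b = 0; b < m.bodies.size(); ++b) {
        rscx(nrec, (int)b) = K[b].comw.x;
        rscy(nrec, (int)b) = K[b].comw.y;
      }
      for (int i = 0; i < nm; ++i) {
        ract(nrec, i) = ms[i].act; rfor(nrec, i) = fmus[i];
        rlce(nrec, i) = ms[i].lce; rstim(nrec, i) = stim[i];
        rLd(nrec, i) = Ld[i]; rFd(nrec, i) = Fd[i];
      }
      for (int i = 0; i < nc; ++i) {
        rcn(nrec, i) = cf[i].fn; rct(nrec, i) = cf[i].ft;
      }
      ++nrec;
    }

    if (fell) { status = 1; t_sim = t; break; }
    if (last) { t_sim = t_max; break; }

    // dynamics solve + semi-implicit Euler
    inverse_dynamics(m, q.data(), qd.data(), zero.data(), true, bias.data(), K);
    for (int j = 0; j < nd; ++j) {
      e[j] = 1.0;
      inverse_dynamics(m, q.data(), zero.data(), e.data(), false, col.data(), K);
      for (int i = 0; i < nd; ++i) M(i, j) = col[i];
      e[j] = 0.0;
    }
    for (int i = 0; i < nd; ++i) rhs[i] = tau[i] - bias[i];
    bool ok = arma::solve(qdd, M, rhs, arma::solve_opts::fast);
    if (!ok) { status = 2; t_sim = t; break; }
    bool finite = true;
    for (int i = 0; i < nd; ++i) {
      qd[i] += dt * qdd[i];
      q[i] += dt * qd[i];
      if (!std::isfinite(q[i]) || !std::isfinite(qd[i])) finite = false;
    }
    if (!finite) { status = 2; t_sim = t; break; }
    ++bufpos;
  }

  auto trim = [&](NumericMatrix& M2) {
    NumericMatrix out(nrec, M2.ncol());
    for (int i = 0; i < nrec; ++i)
      for (int j = 0; j < M2.ncol(); ++j) out(i, j) = M2(i, j);
    return out;
  };
  NumericVector rt2(nrec);
  for (int i = 0; i < nrec; ++i) rt2[i] = rt[i];

  return List::create(
      _["status"] = status, _["t_sim"] = t_sim, _["t"] = rt2,
      _["q"] = trim(rq), _["qd"] = trim(rqd), _["com"] = trim(rcom),
      _["seg_com_x"] = trim(rscx), _["seg_com_y"] = trim(rscy),
      _["act"] = trim(ract), _["force"] = trim(rfor), _["lce"] = trim(rlce),
      _["stim"] = trim(rstim), _["contact_normal"] = trim(rcn),
      _["contact_tangential"] = trim(rct), _["L_delayed"] = trim(rLd),
      _["F_delayed"] = trim(rFd));
}
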