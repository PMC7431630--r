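// Core numerics: 2D corotational Euler-Bernoulli beam, Hill-type line
// actuators, per-muscle adaptive fuzzy controllers, implicit Newmark time
// stepping.  All quantities SI (m, N, s) except where noted; controller
// error signals are in mm / mm/s to match the published gain magnitudes.
#include <RcppArmadillo.h>
#include <algorithm>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// ---------------------------------------------------------------------------
// Corotational beam element
// ---------------------------------------------------------------------------

struct ElemState {
  double N;   // axial force, tension positive
  double V;   // local shear (M1+M2)/L, positive toward local +normal
  double M1, M2;
  double L;
};

// internal force (6-vector) and consistent tangent (6x6) of one element.
// p1, p2: current node positions; th1, th2: current rotations;
// L0, beta0: reference length and angle.
static void elem_ft(const vec2& p1, const vec2& p2, double th1, double th2,
                    double L0, double beta0, double EA, double EI,
                    vec::fixed<6>& f, mat::fixed<6, 6>& K, ElemState& es,
                    bool want_K) {
  const double dx = p2(0) - p1(0), dz = p2(1) - p1(1);
  const double L = std::sqrt(dx * dx + dz * dz);
  const double c = dx / L, s = dz / L;
  double br = std::atan2(dz, dx) - beta0;
  br -= 2.0 * M_PI * std::round(br / (2.0 * M_PI));
  const double ub = L - L0;
  const double t1 = th1 - br, t2 = th2 - br;
  const double N = EA * ub / L0;
  const double M1 = (EI / L0) * (4.0 * t1 + 2.0 * t2);
  const double M2 = (EI / L0) * (2.0 * t1 + 4.0 * t2);

  vec::fixed<6> r = {-c, -s, 0.0, c, s, 0.0};
  vec::fixed<6> z = {s, -c, 0.0, -s, c, 0.0};

  f = N * r - ((M1 + M2) / L) * z;
  f(2) += M1;
  f(5) += M2;

  es.N = N;
  es.V = (M1 + M2) / L;
  es.M1 = M1;
  es.M2 = M2;
  es.L = L;

  if (!want_K) return;
  // B rows: d(ubar)/dd, d(t1)/dd, d(t2)/dd
  mat::fixed<3, 6> B;
  B.row(0) = r.t();
  rowvec::fixed<6> zl = (-z / L).t();
  B.row(1) = zl;
  B.row(2) = zl;
  B(1, 2) += 1.0;
  B(2, 5) += 1.0;
  mat::fixed<3, 3> Kl(fill::zeros);
  Kl(0, 0) = EA / L0;
  Kl(1, 1) = 4.0 * EI / L0;
  Kl(2, 2) = 4.0 * EI / L0;
  Kl(1, 2) = Kl(2, 1) = 2.0 * EI / L0;
  K = B.t() * Kl * B + (N / L) * (z * z.t()) +
      ((M1 + M2) / (L * L)) * (r * z.t() + z * r.t());
}

// assemble internal force vector + tangent for a chain of elements
static void assemble_chain(const mat& coords0, const vec& u, double EA,
                           double EI, vec& fint, mat& K, mat& ends,
                           bool want_K) {
  const uword nn = coords0.n_rows, ne = nn - 1;
  fint.zeros(3 * nn);
  if (want_K) K.zeros(3 * nn, 3 * nn);
  ends.set_size(ne, 2);
  vec::fixed<6> fe;
  mat::fixed<6, 6> Ke;
  ElemState es;
  for (uword e = 0; e < ne; ++e) {
    const uword i = e, j = e + 1;
    vec2 p1 = {coords0(i, 0) + u(3 * i), coords0(i, 1) + u(3 * i + 1)};
    vec2 p2 = {coords0(j, 0) + u(3 * j), coords0(j, 1) + u(3 * j + 1)};
    const double dx0 = coords0(j, 0) - coords0(i, 0);
    const double dz0 = coords0(j, 1) - coords0(i, 1);
    const double L0 = std::sqrt(dx0 * dx0 + dz0 * dz0);
    const double beta0 = std::atan2(dz0, dx0);
    elem_ft(p1, p2, u(3 * i + 2), u(3 * j + 2), L0, beta0, EA, EI, fe, Ke, es,
            want_K);
    uvec idx = {3 * i, 3 * i + 1, 3 * i + 2, 3 * j, 3 * j + 1, 3 * j + 2};
    fint(idx) += fe;
    if (want_K) K(idx, idx) += Ke;
    ends(e, 0) = es.N;
    ends(e, 1) = es.V;
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_assemble(const arma::mat& coords0, const arma::vec& u,
                        double EA, double EI) {
  vec f;
  mat K, ends;
  assemble_chain(coords0, u, EA, EI, f, K, ends, true);
  return Rcpp::List::create(Rcpp::Named("f") = f, Rcpp::Named("K") = K,
                            Rcpp::Named("ends") = ends);
}

// ---------------------------------------------------------------------------
// Hill muscle
// ---------------------------------------------------------------------------

static inline double hill_fl(double ratio) {
  double v = 5.1 + ratio * (-29.0 + ratio * (56.0 + ratio * (-41.0 + ratio * 10.0)));
  return v > 0.0 ? v : 0.0;
}
static inline double hill_fl_d(double ratio) {
  // derivative of the unclamped quartic (0 in the clamped region)
  double v = 5.1 + ratio * (-29.0 + ratio * (56.0 + ratio * (-41.0 + ratio * 10.0)));
  if (v <= 0.0) return 0.0;
  return -29.0 + ratio * (112.0 + ratio * (-123.0 + ratio * 40.0));
}
static inline double hill_fv(double x) {  // x = ldot / ldot_max
  return 0.1433 / (0.1074 + std::exp(-1.409 * std::sinh(3.2 * x + 1.6)));
}
static inline double hill_fv_d(double x) {
  const double sh = std::sinh(3.2 * x + 1.6);
  const double ch = std::cosh(3.2 * x + 1.6);
  const double ex = std::exp(-1.409 * sh);
  const double den = 0.1074 + ex;
  return 0.1433 * 1.409 * 3.2 * ch * ex / (den * den);
}
static inline double hill_fp(double ratio) {
  return std::exp(-10.671 + 7.675 * ratio);
}

// [[Rcpp::export]]
double cpp_muscle_force(double l, double ldot, double alpha, double l0,
                        double ldot_max, double f_max, bool passive) {
  alpha = std::min(1.0, std::max(0.0, alpha));
  double F = alpha * hill_fl(l / l0) * hill_fv(ldot / ldot_max);
  if (passive) F += hill_fp(l / l0);
  return f_max * F;
}

// ---------------------------------------------------------------------------
// Fuzzy controller (zero-order Takagi-Sugeno, Gaussian grid over (e, edot))
// ---------------------------------------------------------------------------

struct FuzzyNet {
  vec centers;  // grid centers on [-1, 1], one axis
  double sigma;
  double norm_e, norm_edot;  // mm, mm/s
};

// normalized firing strengths mu_i / sum(mu); e, edot in mm, mm/s
static vec fuzzy_mu(const FuzzyNet& net, double e, double edot) {
  const uword n = net.centers.n_elem;
  double en = std::clamp(e / net.norm_e, -1.0, 1.0);
  double rn = std::clamp(edot / net.norm_edot, -1.0, 1.0);
  vec me(n), mr(n);
  for (uword i = 0; i < n; ++i) {
    double de = (en - net.centers(i)) / net.sigma;
    double dr = (rn - net.centers(i)) / net.sigma;
    me(i) = std::exp(-0.5 * de * de);
    mr(i) = std::exp(-0.5 * dr * dr);
  }
  vec mu(n * n);
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < n; ++j) mu(i * n + j) = me(i) * mr(j);
  double s = accu(mu);
  if (s <= 0.0) Rcpp::stop("fuzzy membership family does not cover the input");
  return mu / s;
}

// [[Rcpp::export]]
Rcpp::List cpp_fuzzy_eval(const arma::vec& w, double e, double edot,
                          const arma::vec& centers, double sigma,
                          double norm_e, double norm_edot) {
  FuzzyNet net{centers, sigma, norm_e, norm_edot};
  vec mu = fuzzy_mu(net, e, edot);
  double a_raw = dot(mu, w);
  return Rcpp::List::create(Rcpp::Named("alpha_raw") = a_raw,
                            Rcpp::Named("alpha") =
                                std::clamp(a_raw, 0.0, 1.0),
                            Rcpp::Named("mu_norm") = mu);
}

// ---------------------------------------------------------------------------
// Coupled time integration (Newmark average acceleration + Newton)
// ---------------------------------------------------------------------------

struct Muscle {
  vec2 origin;
  uword node;     // 0-based node index of insertion
  double f_max, l0, ldot_max;
  int jsign;
  double ke;
  bool passive;
};

// applied nodal force of one muscle + its position/velocity Jacobians (2x2)
static void muscle_force_jac(const Muscle& mu, const vec2& ins,
                             const vec2& vins, double alpha, double& Fout,
                             vec2& g, mat22& dg_du, mat22& dg_dv,
                             double& l_out, double& ldot_out) {
  vec2 w = mu.origin - ins;
  double l = std::sqrt(dot(w, w));
  vec2 uhat = w / l;
  double ldot = -dot(uhat, vins);
  double ratio = l / mu.l0;
  double x = ldot / mu.ldot_max;
  double fl = hill_fl(ratio), fv = hill_fv(x);
  double F = alpha * fl * fv;
  if (mu.passive) F += hill_fp(ratio);
  F *= mu.f_max;
  Fout = F;
  g = F * uhat;
  l_out = l;
  ldot_out = ldot;
  // dF/dl and dF/dldot
  double dF_dl = mu.f_max * alpha * (hill_fl_d(ratio) / mu.l0) * fv;
  if (mu.passive) dF_dl += mu.f_max * 7.675 / mu.l0 * hill_fp(ratio);
  double dF_dld = mu.f_max * alpha * fl * hill_fv_d(x) / mu.ldot_max;
  // du/dins = (-I + u u^T)/l ; dl/dins = -u^T ; dldot/dv = -u^T
  mat22 uuT = uhat * uhat.t();
  mat22 I2(fill::eye);
  dg_du = -dF_dl * uuT + (F / l) * (uuT - I2);
  dg_dv = -dF_dld * uuT;
}

// [[Rcpp::export]]
Rcpp::List cpp_simulate(const arma::mat& coords0, double EA, double EI,
                        const arma::mat& m_origin, const arma::uvec& m_node,
                        const arma::vec& m_fmax, const arma::vec& m_l0,
                        const arma::vec& m_ldotmax,
                        const arma::ivec& m_jsign, const arma::vec& m_ke,
                        const arma::uvec& m_passive,
                        const arma::vec& ctrl_target_z,  // per muscle, m
                        double h1, double h2, double h3, double kalpha,
                        double eta, const arma::vec& centers, double sigma,
                        double norm_e, double norm_edot, double windup,
                        const arma::vec& P_node,  // -X load per node, N
                        double ramp_time, const arma::mat& pulses,
                        double dt, int nsteps, double node_mass,
                        double rot_inertia, double rayleigh_beta,
                        bool control_on, bool muscles_on,
                        double diverge_z, int record_every,
                        int control_every) {
  const uword nn = coords0.n_rows, ndof = 3 * nn;
  const uword nm = muscles_on ? m_node.n_elem : 0;
  FuzzyNet net{centers, sigma, norm_e, norm_edot};

  std::vector<Muscle> mus(nm);
  for (uword m = 0; m < nm; ++m)
    mus[m] = Muscle{vec2{m_origin(m, 0), m_origin(m, 1)}, m_node(m),
                    m_fmax(m), m_l0(m), m_ldotmax(m), (int)m_jsign(m),
                    m_ke(m), m_passive(m) != 0};

  // controller state
  mat W(centers.n_elem * centers.n_elem, nm, fill::zeros);
  vec Ie(nm, fill::zeros), alpha(nm, fill::zeros);

  // mass matrix (diagonal), clamped base handled via free-dof set
  vec Md(ndof);
  for (uword i = 0; i < nn; ++i) {
    Md(3 * i) = Md(3 * i + 1) = node_mass;
    Md(3 * i + 2) = rot_inertia;
  }
  uvec freed = regspace<uvec>(3, ndof - 1);

  // Rayleigh damping from the reference-configuration tangent
  vec f0;
  mat K0, ends;
  assemble_chain(coords0, zeros<vec>(ndof), EA, EI, f0, K0, ends, true);
  mat C = rayleigh_beta * K0;

  vec u(ndof, fill::zeros), v(ndof, fill::zeros), a(ndof, fill::zeros);

  const int nrec = nsteps / record_every + 1;
  mat recU(nrec, ndof), recAlpha(nrec, nm), recF(nrec, nm);
  mat recN(nrec, nn - 1), recVl(nrec, nn - 1), recVel(nrec, ndof);
  vec recT(nrec);
  int irec = 0;
  bool unstable = false;
  double t_unstable = NA_REAL;

  // external load at time t
  auto fext_at = [&](double t) {
    vec fe(ndof, fill::zeros);
    double ramp = ramp_time > 0 ? std::min(t / ramp_time, 1.0) : 1.0;
    for (uword i = 0; i < nn; ++i) fe(3 * i) -= ramp * P_node(i);
    for (uword p = 0; p < pulses.n_rows; ++p)
      if (t >= pulses(p, 0) && t < pulses(p, 1))
        fe(3 * (uword)pulses(p, 2)) -= pulses(p, 3);
    return fe;
  };

  auto record = [&](double t) {
    recT(irec) = t;
    recU.row(irec) = u.t();
    recVel.row(irec) = v.t();
    for (uword m = 0; m < nm; ++m) {
      recAlpha(irec, m) = alpha(m);
      vec2 ins = {coords0(mus[m].node, 0) + u(3 * mus[m].node),
                  coords0(mus[m].node, 1) + u(3 * mus[m].node + 1)};
      vec2 vins = {v(3 * mus[m].node), v(3 * mus[m].node + 1)};
      double F, l, ld;
      vec2 g;
      mat22 d1, d2;
      muscle_force_jac(mus[m], ins, vins, alpha(m), F, g, d1, d2, l, ld);
      recF(irec, m) = F;
    }
    vec fint_;
    mat Kd_, ends_;
    assemble_chain(coords0, u, EA, EI, fint_, Kd_, ends_, false);
    recN.row(irec) = ends_.col(0).t();
    recVl.row(irec) = ends_.col(1).t();
    ++irec;
  };
  record(0.0);

  const double beta = 0.25, gamma = 0.5;
  // one implicit substep of size h starting at time t (state u,v,a updated)
  std::function<bool(double, double, int)> substep = [&](double t, double h,
                                                         int depth) -> bool {
    const double c0 = 1.0 / (beta * h * h), c2 = 1.0 / (beta * h),
                 c3 = 1.0 / (2.0 * beta) - 1.0, cg = gamma / (beta * h);
    vec un = u, vn = v, an = a;
    vec fe = fext_at(t + h);
    vec ut = un + h * vn + 0.5 * h * h * an;  // predictor
    bool ok = false;
    for (int it = 0; it < 30; ++it) {
      vec at = c0 * (ut - un) - c2 * vn - c3 * an;
      vec vt = vn + h * ((1.0 - gamma) * an) + gamma * h * at;
      vec fint;
      mat Kt, ends_;
      assemble_chain(coords0, ut, EA, EI, fint, Kt, ends_, true);
      vec r = Md % at + C * vt + fint - fe;
      mat Keff = Kt + cg * C;
      Keff.diag() += c0 * Md;
      for (uword m = 0; m < nm; ++m) {
        const uword nd = mus[m].node;
        vec2 ins = {coords0(nd, 0) + ut(3 * nd), coords0(nd, 1) + ut(3 * nd + 1)};
        vec2 vins = {vt(3 * nd), vt(3 * nd + 1)};
        double F, l, ld;
        vec2 g;
        mat22 dgu, dgv;
        muscle_force_jac(mus[m], ins, vins, alpha(m), F, g, dgu, dgv, l, ld);
        r(3 * nd) -= g(0);
        r(3 * nd + 1) -= g(1);
        uvec id = {3 * nd, 3 * nd + 1};
        Keff(id, id) -= dgu + cg * dgv;
      }
      double rn = norm(r(freed));
      if (rn < 1e-7 * std::max(1.0, norm(fe))) {
        ok = true;
        u = ut;
        a = c0 * (ut - un) - c2 * vn - c3 * an;
        v = vn + h * ((1.0 - gamma) * an + gamma * a);
        break;
      }
      vec du;
      bool solved = solve(du, Keff(freed, freed), -r(freed),
                          solve_opts::no_approx);
      if (!solved) break;
      ut(freed) += du;
    }
    if (!ok) {
      if (depth >= 12) return false;
      // restore and take two half steps
      u = un;
      v = vn;
      a = an;
      if (!substep(t, h / 2.0, depth + 1)) return false;
      return substep(t + h / 2.0, h / 2.0, depth + 1);
    }
    return true;
  };

  // controller runs on its own clock: one cycle every `control_every`
  // integration steps (1 ms by default), so refining the integration step
  // does not change the learning trajectory
  const double dt_ctrl = control_every * dt;
  std::vector<vec> mu_used(nm);
  bool have_mu = false;
  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    if (control_on && step % control_every == 0) {
      for (uword m = 0; m < nm; ++m) {
        const uword nd = mus[m].node;
        double e_mm = (ctrl_target_z(m) - (coords0(nd, 1) + u(3 * nd + 1))) * 1e3;
        double ed_mm = -v(3 * nd + 1) * 1e3;
        // critics + steepest-descent weight update for the completed cycle
        if (have_mu) {
          Ie(m) = std::clamp(Ie(m) + e_mm * dt_ctrl, -windup, windup);
          double re = h1 * e_mm + h2 * ed_mm + h3 * Ie(m);
          double grad = eta * (mus[m].ke * h1 * re * mus[m].jsign -
                               kalpha * std::abs(alpha(m)));
          W.col(m) += grad * mu_used[m];
        }
        // fresh activation for the next cycle
        vec mu_n = fuzzy_mu(net, e_mm, ed_mm);
        alpha(m) = std::clamp(dot(mu_n, W.col(m)), 0.0, 1.0);
        mu_used[m] = mu_n;
      }
      have_mu = true;
    }
    // ---- advance plant ----
    if (!substep(t, dt, 0)) {
      unstable = true;
      t_unstable = t;
      break;
    }
    // ---- divergence check ----
    for (uword i = 1; i < nn; ++i)
      if (std::abs(u(3 * i + 1)) > diverge_z) {
        unstable = true;
        t_unstable = t + dt;
        break;
      }
    if ((step + 1) % record_every == 0 && irec < nrec) record((step + 1) * dt);
    if (unstable) break;
  }

  return Rcpp::List::create(
      Rcpp::Named("time") = recT.head(irec),
      Rcpp::Named("U") = recU.head_rows(irec),
      Rcpp::Named("V") = recVel.head_rows(irec),
      Rcpp::Named("alpha") = recAlpha.head_rows(irec),
      Rcpp::Named("force") = recF.head_rows(irec),
      Rcpp::Named("axial") = recN.head_rows(irec),
      Rcpp::Named("shear_local") = recVl.head_rows(irec),
      Rcpp::Named("weights") = W, Rcpp::Named("int_err") = Ie,
      Rcpp::Named("unstable") = unstable,
      Rcpp::Named("t_unstable") = t_unstable);
}
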