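#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Period-2 minimum image for the path-progress coordinate s.
static inline double wrap2(double x) {
  double y = 0.5 * (x + 1.0);
  return 2.0 * (y - std::floor(y)) - 1.0;
}

// Wrap an angle to [-pi, pi).
static inline double wrap2pi(double x) {
  const double twopi = 2.0 * M_PI;
  double y = (x + M_PI) / twopi;
  return twopi * (y - std::floor(y)) - M_PI;
}

// ---------------------------------------------------------------------------
// Piecewise-linear path projection
// ---------------------------------------------------------------------------

static void cumulative_lengths(const NumericMatrix& nodes,
                               std::vector<double>& cumlen) {
  const int n = nodes.nrow(), d = nodes.ncol();
  cumlen.assign(n, 0.0);
  for (int i = 1; i < n; ++i) {
    double l2 = 0.0;
    for (int k = 0; k < d; ++k) {
      double e = nodes(i, k) - nodes(i - 1, k);
      l2 += e * e;
    }
    cumlen[i] = cumlen[i - 1] + std::sqrt(l2);
  }
}

// Nearest point on the open polyline; frac is arc-length position in [0,1],
// z the Euclidean distance. Exact ties go to the lower segment index.
static void project_polyline(const double* p, const NumericMatrix& nodes,
                             const std::vector<double>& cumlen,
                             double& frac, double& z) {
  const int n = nodes.nrow(), d = nodes.ncol();
  double best_d2 = R_PosInf, best_arc = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    double ab2 = 0.0, apab = 0.0;
    for (int k = 0; k < d; ++k) {
      double a = nodes(i, k);
      double e = nodes(i + 1, k) - a;
      ab2 += e * e;
      apab += (p[k] - a) * e;
    }
    double t = ab2 > 0.0 ? apab / ab2 : 0.0;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    double d2 = 0.0;
    for (int k = 0; k < d; ++k) {
      double a = nodes(i, k);
      double q = a + t * (nodes(i + 1, k) - a);
      double diff = p[k] - q;
      d2 += diff * diff;
    }
    if (d2 < best_d2) {
      best_d2 = d2;
      best_arc = cumlen[i] + t * (cumlen[i + 1] - cumlen[i]);
    }
  }
  const double L = cumlen[n - 1];
  frac = L > 0.0 ? best_arc / L : 0.0;
  z = std::sqrt(best_d2);
}

// [[Rcpp::export]]
NumericMatrix cpp_project_batch(NumericMatrix pts, NumericMatrix nodes) {
  const int m = pts.nrow(), d = pts.ncol();
  if (d != nodes.ncol()) stop("point/path dimensionality mismatch");
  std::vector<double> cumlen;
  cumulative_lengths(nodes, cumlen);
  NumericMatrix out(m, 2);
  std::vector<double> p(d);
  for (int i = 0; i < m; ++i) {
    for (int k = 0; k < d; ++k) p[k] = pts(i, k);
    double frac, z;
    project_polyline(p.data(), nodes, cumlen, frac, z);
    out(i, 0) = frac;
    out(i, 1) = z;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Analytic model potentials
// ---------------------------------------------------------------------------
// pot_id: 1 = rotor_flip (2D: chi', theta), 2 = harmonic (par = spring per
// axis), 3 = flat. Energies in kcal/mol, angles in rad.

// rotor_flip parameter order:
// 0 chi_wcf, 1 chi_hg, 2 b_in_3p, 3 b_in_5p, 4 b_out_3p, 5 b_out_5p,
// 6 theta_out, 7 sigma_theta, 8 k_open, 9 df_hg, 10 gate_exp
//
// The outside-channel gate is centered on theta_out * w(chi) with
// w = [sin(chi - chi_wcf) sin(chi - chi_hg)]^2 (optionally raised to
// gate_exp): the channel sits at theta_out at mid-rotation and descends
// into the closed-helix basins (theta -> 0) along a gentle diagonal as
// either stable state is approached, like a base that flips out only
// while it is rotating.
static void rotor_flip_eg(double chi, double theta, const double* q,
                          double& E, double& dchi, double& dtheta) {
  const double u = 0.5 * (1.0 + std::cos(chi));
  const double du = -0.5 * std::sin(chi);
  const double Bin = q[2] * u + q[3] * (1.0 - u);
  const double dBin = (q[2] - q[3]) * du;
  const double Bout = q[4] * u + q[5] * (1.0 - u);
  const double dBout = (q[4] - q[5]) * du;
  const double c1 = 1.0 - std::cos(chi - q[0]);
  const double s1 = std::sin(chi - q[0]);
  const double c2 = 1.0 - std::cos(chi - q[1]);
  const double sb = std::sin(chi - q[1]);
  const double r = c1 * c2;
  const double dr = s1 * c2 + c1 * sb;
  const double h = std::sin(chi - q[0]) * std::sin(chi - q[1]);
  const double dh = std::sin(2.0 * chi - q[0] - q[1]);
  const double p = q[10];
  const double h2 = h * h;
  const double w = (p == 1.0) ? h2 : std::pow(h2, p);
  const double dw = (p == 1.0) ? 2.0 * h * dh
                               : (h2 > 0.0 ? p * std::pow(h2, p - 1.0) *
                                                 2.0 * h * dh
                                           : 0.0);
  const double thc = q[6] * w;
  const double td = theta - thc;
  const double s2 = q[7] * q[7];
  const double g = std::exp(-0.5 * td * td / s2);
  const double dg_theta = -(td / s2) * g;
  const double dg_chi = (td / s2) * g * q[6] * dw;
  const double Bg = Bin - (Bin - Bout) * g;
  const double dBg_chi = dBin - (dBin - dBout) * g - (Bin - Bout) * dg_chi;
  const double dBg_theta = -(Bin - Bout) * dg_theta;
  const double tn = 1.0 - std::cos(q[1] - q[0]);
  const double tilt = q[9] * c1 / tn;
  const double dtilt = q[9] * s1 / tn;
  E = Bg * r + q[8] * theta * theta + tilt;
  dchi = dBg_chi * r + Bg * dr + dtilt;
  dtheta = dBg_theta * r + 2.0 * q[8] * theta;
}

static void pot_eg(int pot_id, const double* par, int npar, const double* x,
                   int d, double& E, double* grad) {
  if (pot_id == 1) {
    if (d != 2) stop("rotor_flip potential is two-dimensional");
    rotor_flip_eg(x[0], x[1], par, E, grad[0], grad[1]);
  } else if (pot_id == 2) {
    if (npar < d) stop("harmonic potential needs one spring constant per axis");
    E = 0.0;
    for (int k = 0; k < d; ++k) {
      E += 0.5 * par[k] * x[k] * x[k];
      grad[k] = par[k] * x[k];
    }
  } else if (pot_id == 3) {
    E = 0.0;
    for (int k = 0; k < d; ++k) grad[k] = 0.0;
  } else {
    stop("unknown potential id");
  }
}

// [[Rcpp::export]]
List cpp_rotor_flip(NumericVector chi, NumericVector theta, NumericVector par) {
  const int n = chi.size();
  if (theta.size() != n) stop("chi and theta lengths differ");
  if (par.size() < 11) stop("rotor_flip needs 11 parameters");
  NumericVector E(n), dchi(n), dtheta(n);
  for (int i = 0; i < n; ++i) {
    double e, dc, dt;
    rotor_flip_eg(chi[i], theta[i], par.begin(), e, dc, dt);
    E[i] = e;
    dchi[i] = dc;
    dtheta[i] = dt;
  }
  return List::create(_["energy"] = E, _["dchi"] = dchi, _["dtheta"] = dtheta);
}

// ---------------------------------------------------------------------------
// Metadynamics bias on the periodic s axis
// ---------------------------------------------------------------------------

static void hills_eg(double s, const double* c, const double* w,
                     const double* h, int nh, double& E, double& dEds) {
  E = 0.0;
  dEds = 0.0;
  for (int i = 0; i < nh; ++i) {
    const double d = wrap2(s - c[i]);
    const double s2 = w[i] * w[i];
    const double e = h[i] * std::exp(-0.5 * d * d / s2);
    E += e;
    dEds += -(d / s2) * e;
  }
}

// [[Rcpp::export]]
List cpp_hills_energy(NumericVector s, NumericVector center,
                      NumericVector width, NumericVector height) {
  const int n = s.size(), nh = center.size();
  NumericVector E(n), dEds(n);
  for (int i = 0; i < n; ++i) {
    double e, de;
    hills_eg(s[i], center.begin(), width.begin(), height.begin(), nh, e, de);
    E[i] = e;
    dEds[i] = de;
  }
  return List::create(_["energy"] = E, _["dEds"] = dEds);
}

// ---------------------------------------------------------------------------
// Overdamped Langevin propagation
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_run_langevin(NumericVector x0, int pot_id, NumericVector par,
                               int n_steps, double dt, double gamma, double kT,
                               int record_every, LogicalVector wrap_axis) {
  const int d = x0.size();
  if ((int)wrap_axis.size() != d) stop("wrap_axis length must match dimension");
  std::vector<double> x(x0.begin(), x0.end()), grad(d);
  const int n_rec = n_steps / record_every;
  NumericMatrix rec(n_rec, d);
  const double mob = dt / gamma;
  const double sig = std::sqrt(2.0 * kT * dt / gamma);
  int ir = 0;
  for (int i = 1; i <= n_steps; ++i) {
    double E;
    pot_eg(pot_id, par.begin(), par.size(), x.data(), d, E, grad.data());
    for (int k = 0; k < d; ++k) {
      if (!R_finite(grad[k])) stop("non-finite potential gradient");
      x[k] += -grad[k] * mob + sig * norm_rand();
      if (wrap_axis[k]) x[k] = wrap2pi(x[k]);
    }
    if (i % record_every == 0 && ir < n_rec) {
      for (int k = 0; k < d; ++k) rec(ir, k) = x[k];
      ++ir;
    }
  }
  return rec;
}

// ---------------------------------------------------------------------------
// Multiple-walker segment propagator
// ---------------------------------------------------------------------------
// Walkers live in (chi', theta); the path lives in [cos chi', sin chi',
// theta]. Gradients of s and z with respect to (chi', theta) are central
// finite differences with step fd_step, composed with the embedding.
//
// role: 0 = standard (feels hills, deposits outside this function),
//       1 = intermediate attractor (theta restraint + steered s restraint),
//       2 = state attractor (harmonic restraint at a (chi, theta) point).
// restr columns: 0 k_theta, 1 theta0, 2 k_s, 3 s_target, 4 s_start,
//                5 steer_window, 6 k_point, 7 chi_ref, 8 theta_ref
//
// Steered walkers are restrained on a winding-aware continuous progress
// coordinate (s unwrapped along the walker's own history, passed in and
// out via s_cont): the nearest-segment s is discontinuous across the
// path's cut locus near the shared endpoint, and a minimum-image
// difference there would let a walker flap between the two sides of the
// anchor instead of following the moving center around the cycle.

struct ProjCache {
  const NumericMatrix* nodes;
  const std::vector<double>* cumlen;
};

static inline void project_state(double chi, double theta, const ProjCache& pc,
                                 double& s, double& z) {
  double p[3] = {std::cos(chi), std::sin(chi), theta};
  double frac;
  project_polyline(p, *pc.nodes, *pc.cumlen, frac, z);
  s = -1.0 + 2.0 * frac;
}

// [[Rcpp::export]]
List cpp_propagate_segment(NumericMatrix pos, IntegerVector role,
                           NumericMatrix restr, NumericMatrix nodes,
                           NumericVector hc, NumericVector hw, NumericVector hh,
                           double tube_k, int pot_id, NumericVector pot_par,
                           double dt, double gamma, double kT, double t0,
                           int n_steps, IntegerVector substeps,
                           double fd_step, NumericVector s_cont_in) {
  const int nw = pos.nrow();
  if (pos.ncol() != 2) stop("walker positions must be (chi, theta)");
  std::vector<double> cumlen;
  cumulative_lengths(nodes, cumlen);
  ProjCache pc = {&nodes, &cumlen};
  const int nh = hc.size();

  NumericMatrix chi_rec(n_steps, nw), theta_rec(n_steps, nw),
      s_rec(n_steps, nw), z_rec(n_steps, nw), eb_rec(n_steps, nw);
  NumericVector t_rec(n_steps);
  NumericMatrix out_pos(clone(pos));
  NumericVector s_cont(clone(s_cont_in));

  for (int step = 0; step < n_steps; ++step) {
    for (int w = 0; w < nw; ++w) {
      const int ns = substeps[w] > 0 ? substeps[w] : 1;
      const double h = dt / ns;
      const double mob = h / gamma;
      const double sig = std::sqrt(2.0 * kT * h / gamma);
      double chi = out_pos(w, 0), theta = out_pos(w, 1);
      for (int sub = 0; sub < ns; ++sub) {
        const double t_cur = t0 + step * dt + sub * h;
        double E, dVchi, dVtheta;
        double x[2] = {chi, theta};
        double grad[2];
        pot_eg(pot_id, pot_par.begin(), pot_par.size(), x, 2, E, grad);
        dVchi = grad[0];
        dVtheta = grad[1];

        double s, z;
        project_state(chi, theta, pc, s, z);
        double sp, sm, zp, zm;
        project_state(chi + fd_step, theta, pc, sp, zp);
        project_state(chi - fd_step, theta, pc, sm, zm);
        double ds_dchi = wrap2(sp - sm) / (2.0 * fd_step);
        double dz_dchi = (zp - zm) / (2.0 * fd_step);
        project_state(chi, theta + fd_step, pc, sp, zp);
        project_state(chi, theta - fd_step, pc, sm, zm);
        double ds_dtheta = wrap2(sp - sm) / (2.0 * fd_step);
        double dz_dtheta = (zp - zm) / (2.0 * fd_step);
        // the nearest-segment s is discontinuous on the path's cut locus;
        // clip the finite-difference gradient there (|grad s| is ~2/L on
        // the path's tube) so a walker swept by the cut gets no
        // unphysical kick
        const double GMAX = 3.0;
        if (ds_dchi > GMAX) ds_dchi = GMAX;
        if (ds_dchi < -GMAX) ds_dchi = -GMAX;
        if (ds_dtheta > GMAX) ds_dtheta = GMAX;
        if (ds_dtheta < -GMAX) ds_dtheta = -GMAX;
        if (dz_dchi > GMAX) dz_dchi = GMAX;
        if (dz_dchi < -GMAX) dz_dchi = -GMAX;
        if (dz_dtheta > GMAX) dz_dtheta = GMAX;
        if (dz_dtheta < -GMAX) dz_dtheta = -GMAX;

        double fchi = -dVchi, ftheta = -dVtheta;
        // tube: upper harmonic wall at z = 0
        fchi += -tube_k * z * dz_dchi;
        ftheta += -tube_k * z * dz_dtheta;

        if (role[w] == 0 && nh > 0) {
          double Eb, dEds;
          hills_eg(s, hc.begin(), hw.begin(), hh.begin(), nh, Eb, dEds);
          fchi += -dEds * ds_dchi;
          ftheta += -dEds * ds_dtheta;
        } else if (role[w] == 1) {
          ftheta += -restr(w, 0) * (theta - restr(w, 1));
          const double win = restr(w, 5);
          const double s0 = restr(w, 4);
          const double dtot = wrap2(restr(w, 3) - s0);
          const double a = (win > 0.0 && t_cur < win) ? t_cur / win : 1.0;
          const double cen = s0 + a * dtot;  // continuous (unwrapped) center
          s_cont[w] += wrap2(s - wrap2(s_cont[w]));
          const double dsr = s_cont[w] - cen;
          fchi += -restr(w, 2) * dsr * ds_dchi;
          ftheta += -restr(w, 2) * dsr * ds_dtheta;
        } else if (role[w] == 2) {
          fchi += -restr(w, 6) * wrap2pi(chi - restr(w, 7));
          ftheta += -restr(w, 6) * (theta - restr(w, 8));
        }

        if (!R_finite(fchi) || !R_finite(ftheta))
          stop("non-finite force on walker %d at t = %f", w + 1, t_cur);
        // trust region: cap the deterministic drift per substep
        const double DMAX = 0.25;
        double dchi_drift = fchi * mob, dtheta_drift = ftheta * mob;
        if (dchi_drift > DMAX) dchi_drift = DMAX;
        if (dchi_drift < -DMAX) dchi_drift = -DMAX;
        if (dtheta_drift > DMAX) dtheta_drift = DMAX;
        if (dtheta_drift < -DMAX) dtheta_drift = -DMAX;
        chi += dchi_drift + sig * norm_rand();
        theta += dtheta_drift + sig * norm_rand();
        chi = wrap2pi(chi);
      }
      out_pos(w, 0) = chi;
      out_pos(w, 1) = theta;

      double s, z;
      project_state(chi, theta, pc, s, z);
      chi_rec(step, w) = chi;
      theta_rec(step, w) = theta;
      s_rec(step, w) = s;
      z_rec(step, w) = z;
      double eb = 0.0;
      if (role[w] == 0 && nh > 0) {
        double de;
        hills_eg(s, hc.begin(), hw.begin(), hh.begin(), nh, eb, de);
      }
      eb_rec(step, w) = eb;
    }
    t_rec[step] = t0 + (step + 1) * dt;
  }

  return List::create(_["pos"] = out_pos, _["time"] = t_rec,
                      _["chi"] = chi_rec, _["theta"] = theta_rec,
                      _["s"] = s_rec, _["z"] = z_rec, _["ebias"] = eb_rec,
                      _["s_cont"] = s_cont);
}
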