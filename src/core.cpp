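// Core numerics for the rigid polarizable 4-site (Dang-Chang type) water
// potential: site expansion from angle-axis rigid-body coordinates, energy
// terms (LJ, Coulomb, self-consistent induced-dipole polarization with a
// hard O-O cutoff on the polarization term only), analytic rigid-body
// gradients, an L-BFGS quench and the basin-hopping loop.
//
// Units: kcal/mol, Angstrom, electron charges, radians.  Fields and dipole
// tensors are computed in Gaussian-style units (charge/A^2); the Coulomb
// conversion constant kc multiplies energies and gradients once.
//
// Energy and gradient are evaluated in one fused pass over 3xN
// column-contiguous site arrays: the quench dominates the basin-hopping
// cost, so this path is written for speed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat33 skew3(const arma::vec3& v) {
  arma::mat33 S(arma::fill::zeros);
  S(0, 1) = -v(2); S(0, 2) =  v(1);
  S(1, 0) =  v(2); S(1, 2) = -v(0);
  S(2, 0) = -v(1); S(2, 1) =  v(0);
  return S;
}

// Rodrigues rotation from a rotation vector p (angle = |p|, axis = p/|p|).
static arma::mat33 rot_aa(const arma::vec3& p) {
  const double th2 = arma::dot(p, p);
  arma::mat33 I(arma::fill::eye);
  if (th2 < 1e-24) {
    arma::mat33 K = skew3(p);
    return I + K + 0.5 * (K * K);
  }
  const double th = std::sqrt(th2);
  arma::mat33 K = skew3(p / th);
  return I + std::sin(th) * K + (1.0 - std::cos(th)) * (K * K);
}

// dR/dp_i (Gallego & Yezzi closed form); series fallback near |p| = 0.
static void rot_derivs(const arma::vec3& p, const arma::mat33& R,
                       arma::mat33 dR[3]) {
  const double th2 = arma::dot(p, p);
  if (th2 < 1e-16) {
    for (int i = 0; i < 3; ++i) {
      arma::vec3 e(arma::fill::zeros); e(i) = 1.0;
      dR[i] = skew3(e);
    }
    return;
  }
  arma::mat33 I(arma::fill::eye);
  arma::mat33 ImR = I - R;
  arma::mat33 Pk = skew3(p);
  for (int i = 0; i < 3; ++i) {
    arma::vec3 e(arma::fill::zeros); e(i) = 1.0;
    arma::vec3 v = arma::cross(p, arma::vec3(ImR * e));
    dR[i] = ((p(i) * Pk + skew3(v)) / th2) * R;
  }
}

struct Params {
  double eps, sig, qh, qm, alpha, kc;
  double cutoff;          // polarization O-O cutoff radius (A)
  double scf_tol;
  int    scf_maxit;
  bool   mutual;          // include dipole-dipole coupling in the SCF
  double overlap_floor;   // hard O-O floor for LJ (degenerate configs)
  arma::vec3 body[4];     // body-frame offsets: O, H1, H2, M (O at origin)
};

static Params parse_params(const List& par) {
  Params P;
  P.eps = as<double>(par["epsilon"]);
  P.sig = as<double>(par["sigma"]);
  P.qh = as<double>(par["q_h"]);
  P.qm = as<double>(par["q_m"]);
  P.alpha = as<double>(par["alpha"]);
  P.kc = as<double>(par["coulomb_k"]);
  P.cutoff = as<double>(par["cutoff"]);
  P.scf_tol = as<double>(par["scf_tol"]);
  P.scf_maxit = as<int>(par["scf_maxit"]);
  P.mutual = as<bool>(par["mutual"]);
  P.overlap_floor = as<double>(par["overlap_floor"]);
  List g = par["geom"];
  const double roh = as<double>(g["r_oh"]);
  const double rom = as<double>(g["r_om"]);
  const double half = 0.5 * as<double>(g["theta_hoh"]) * M_PI / 180.0;
  // Body frame: O at origin, HOH bisector along +z (toward the hydrogens),
  // molecule in the xz-plane.
  P.body[0] = { 0.0, 0.0, 0.0 };
  P.body[1] = { roh * std::sin(half), 0.0, roh * std::cos(half) };
  P.body[2] = {-roh * std::sin(half), 0.0, roh * std::cos(half) };
  P.body[3] = { 0.0, 0.0, rom };
  return P;
}

struct EOut {
  double lj = 0.0, coul = 0.0, pol = 0.0;
  bool ok = true;        // no degenerate geometry / solver failure
  bool conv = true;      // dipole solution obtained
  int iters = 0;
  double resid = 0.0;
  arma::mat mu, e0;      // N x 3 (Gaussian units: mu in e*A, e0 in e/A^2)
  std::string err;
  double total() const { return lj + coul + pol; }
};

// Fused energy (+ optional gradient) evaluation.
// x: N x 6 pose matrix.  method: 0 direct solve, 1 fixed-point (energy
// only; the gradient path always uses the direct solve).
// If want_grad, g is filled N x 6.
static EOut eval_all(const arma::mat& x, const Params& P, int method,
                     bool want_grad, arma::mat* g) {
  const int N = x.n_rows;
  EOut E;

  // site positions, 3 x N column-contiguous; s[a] holds site a of all
  // molecules (0 = O, 1 = H1, 2 = H2, 3 = M)
  arma::mat s[4];
  std::vector<arma::mat33> Rm(want_grad ? N : 0);
  for (int a = 0; a < 4; ++a) s[a].set_size(3, N);
  for (int i = 0; i < N; ++i) {
    arma::vec3 pos = { x(i, 0), x(i, 1), x(i, 2) };
    arma::vec3 aa  = { x(i, 3), x(i, 4), x(i, 5) };
    arma::mat33 R = rot_aa(aa);
    if (want_grad) Rm[i] = R;
    for (int a = 0; a < 4; ++a) s[a].col(i) = pos + R * P.body[a];
  }

  // site gradients (3 x N per site type), filled only when want_grad
  arma::mat gs[4];
  if (want_grad) for (int a = 0; a < 4; ++a) gs[a].zeros(3, N);

  const double sig2 = P.sig * P.sig;
  const double q[4] = { 0.0, P.qh, P.qh, P.qm };

  // O-O distances once; collect polarization neighbors
  arma::mat doo(N, N, arma::fill::zeros);
  std::vector<std::pair<int,int>> nbr;
  nbr.reserve(N * (N - 1) / 2);
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      arma::vec3 r = s[0].col(i) - s[0].col(j);
      const double d = std::sqrt(arma::dot(r, r));
      doo(i, j) = doo(j, i) = d;
      if (d < P.overlap_floor) {
        E.ok = false; E.err = "degenerate configuration: O-O overlap";
        return E;
      }
      if (d <= P.cutoff) nbr.push_back({i, j});

      // Lennard-Jones (O-O, never truncated)
      const double ir2 = sig2 / (d * d);
      const double ir6 = ir2 * ir2 * ir2;
      E.lj += 4.0 * P.eps * ir6 * (ir6 - 1.0);
      if (want_grad) {
        const double dEdd_over_d = 4.0 * P.eps * (-12.0 * ir6 * ir6 + 6.0 * ir6) / (d * d);
        arma::vec3 f = dEdd_over_d * r;
        gs[0].col(i) += f;
        gs[0].col(j) -= f;
      }

      // Coulomb (intermolecular charged sites, never truncated)
      for (int a = 1; a < 4; ++a)
        for (int b = 1; b < 4; ++b) {
          arma::vec3 rc = s[a].col(i) - s[b].col(j);
          const double d2 = arma::dot(rc, rc);
          // hard floor on intermolecular charged-site contacts: the
          // undamped point-charge/point-dipole model is meaningless below
          // ~0.7 A (shortest physical H..M contact is ~1.5 A)
          if (d2 < 0.49) {
            E.ok = false;
            E.err = "degenerate configuration: near-coincident charge sites";
            return E;
          }
          const double dd = std::sqrt(d2);
          const double e = P.kc * q[a] * q[b] / dd;
          E.coul += e;
          if (want_grad) {
            arma::vec3 f = (-e / d2) * rc;
            gs[a].col(i) += f;
            gs[b].col(j) -= f;
          }
        }
    }

  E.e0.zeros(N, 3);
  E.mu.zeros(N, 3);

  auto fold = [&]() {
    if (!want_grad) return;
    g->zeros(N, 6);
    for (int i = 0; i < N; ++i) {
      arma::vec3 aa = { x(i, 3), x(i, 4), x(i, 5) };
      arma::mat33 dR[3];
      rot_derivs(aa, Rm[i], dR);
      arma::vec3 gpos = gs[0].col(i) + gs[1].col(i) + gs[2].col(i) + gs[3].col(i);
      (*g)(i, 0) = gpos(0); (*g)(i, 1) = gpos(1); (*g)(i, 2) = gpos(2);
      for (int k = 0; k < 3; ++k)
        (*g)(i, 3 + k) = arma::dot(gs[1].col(i), dR[k] * P.body[1])
                       + arma::dot(gs[2].col(i), dR[k] * P.body[2])
                       + arma::dot(gs[3].col(i), dR[k] * P.body[3]);
    }
  };

  if (nbr.empty() || P.alpha <= 0.0) { E.pol = 0.0; fold(); return E; }

  // static field at the M sites from the fixed charges of polarization
  // neighbors (Gaussian units, no kc)
  arma::mat e0t(3, N, arma::fill::zeros);  // 3 x N working copy
  for (auto& pr : nbr) {
    const int i = pr.first, j = pr.second;
    for (int a = 1; a < 4; ++a) {
      arma::vec3 r1 = s[3].col(i) - s[a].col(j);
      double d2 = arma::dot(r1, r1);
      if (d2 < 0.49) { E.ok = false; E.err = "degenerate configuration: site on M site"; return E; }
      e0t.col(i) += q[a] / (d2 * std::sqrt(d2)) * r1;
      arma::vec3 r2 = s[3].col(j) - s[a].col(i);
      d2 = arma::dot(r2, r2);
      if (d2 < 0.49) { E.ok = false; E.err = "degenerate configuration: site on M site"; return E; }
      e0t.col(j) += q[a] / (d2 * std::sqrt(d2)) * r2;
    }
  }
  E.e0 = e0t.t();

  // dipole interaction tensors between M sites for the masked pairs
  std::vector<arma::mat33> Ts(nbr.size());
  for (size_t k = 0; k < nbr.size(); ++k) {
    arma::vec3 r = s[3].col(nbr[k].first) - s[3].col(nbr[k].second);
    const double d2 = arma::dot(r, r);
    const double d = std::sqrt(d2), d3 = d2 * d;
    arma::mat33 T = (3.0 / d2) * (r * r.t());
    T.diag() -= 1.0;
    Ts[k] = T / d3;
  }

  arma::mat mut(3, N);  // dipoles, 3 x N
  if (!P.mutual) {
    mut = P.alpha * e0t;
  } else if (method == 0 || want_grad) {
    arma::mat A(3 * N, 3 * N, arma::fill::eye);
    for (size_t k = 0; k < nbr.size(); ++k) {
      const int i = nbr[k].first, j = nbr[k].second;
      for (int c = 0; c < 3; ++c)
        for (int rr = 0; rr < 3; ++rr) {
          A(3 * i + rr, 3 * j + c) -= P.alpha * Ts[k](rr, c);
          A(3 * j + rr, 3 * i + c) -= P.alpha * Ts[k](rr, c);
        }
    }
    arma::vec b = P.alpha * arma::vectorise(e0t);
    // A is symmetric and must be positive definite for the linear-response
    // solution to exist (the energy functional is bounded below only
    // there); a failed Cholesky factorization is the polarization
    // catastrophe
    arma::mat U;
    if (!arma::chol(U, A)) {
      E.ok = false; E.conv = false;
      E.err = "induced-dipole system not positive definite (polarization catastrophe)";
      return E;
    }
    arma::vec m = arma::solve(arma::trimatu(U),
                              arma::solve(arma::trimatl(U.t()), b));
    if (!m.is_finite()) {
      E.ok = false; E.conv = false;
      E.err = "induced-dipole linear solve failed (polarization catastrophe)";
      return E;
    }
    mut = arma::reshape(m, 3, N);
  } else {
    // fixed-point: mu_i <- alpha (e0_i + sum_j T_ij mu_j)
    arma::mat mu0 = P.alpha * e0t, mun(3, N);
    double resid = 1e9;
    int it = 0;
    for (; it < P.scf_maxit; ++it) {
      mun = P.alpha * e0t;
      for (size_t k = 0; k < nbr.size(); ++k) {
        const int i = nbr[k].first, j = nbr[k].second;
        mun.col(i) += P.alpha * (Ts[k] * mu0.col(j));
        mun.col(j) += P.alpha * (Ts[k] * mu0.col(i));
      }
      resid = arma::abs(mun - mu0).max();
      mu0 = mun;
      if (resid < P.scf_tol) break;
      if (!std::isfinite(resid) || resid > 1e8) break;
    }
    mut = mu0; E.iters = it + 1; E.resid = resid;
    if (!(resid < P.scf_tol)) {
      E.ok = false; E.conv = false;
      E.err = "induced-dipole iteration did not converge (polarization catastrophe)";
      return E;
    }
  }

  if (!mut.is_finite() || arma::abs(mut).max() > 2.0) {
    E.ok = false; E.conv = false;
    E.err = "induced dipoles diverged (polarization catastrophe)";
    return E;
  }
  E.mu = mut.t();
  E.pol = -0.5 * P.kc * arma::accu(mut % e0t);

  if (want_grad) {
    // variational gradient: converged dipoles held fixed
    for (auto& pr : nbr) {
      const int i = pr.first, j = pr.second;
      const arma::vec3 mi = mut.col(i), mj = mut.col(j);
      // -kc * mu . (field from neighbor charges), both directions
      for (int a = 1; a < 4; ++a) {
        {
          arma::vec3 r = s[3].col(i) - s[a].col(j);
          const double d2 = arma::dot(r, r);
          const double d3 = d2 * std::sqrt(d2);
          arma::vec3 dgr = mi / d3 - (3.0 * arma::dot(mi, r) / (d3 * d2)) * r;
          arma::vec3 f = -P.kc * q[a] * dgr;
          gs[3].col(i) += f;
          gs[a].col(j) -= f;
        }
        {
          arma::vec3 r = s[3].col(j) - s[a].col(i);
          const double d2 = arma::dot(r, r);
          const double d3 = d2 * std::sqrt(d2);
          arma::vec3 dgr = mj / d3 - (3.0 * arma::dot(mj, r) / (d3 * d2)) * r;
          arma::vec3 f = -P.kc * q[a] * dgr;
          gs[3].col(j) += f;
          gs[a].col(i) -= f;
        }
      }
      if (P.mutual) {
        // -kc * mu_i^T T_ij mu_j
        arma::vec3 r = s[3].col(i) - s[3].col(j);
        const double d2 = arma::dot(r, r);
        const double d5 = d2 * d2 * std::sqrt(d2), d7 = d5 * d2;
        const double mir = arma::dot(mi, r), mjr = arma::dot(mj, r);
        arma::vec3 gradT = (3.0 / d5) * (mir * mj + mjr * mi + arma::dot(mi, mj) * r)
                         - (15.0 * mir * mjr / d7) * r;
        arma::vec3 f = -P.kc * gradT;
        gs[3].col(i) += f;
        gs[3].col(j) -= f;
      }
    }
  }
  fold();
  return E;
}

static EOut eval_energy(const arma::mat& x, const Params& P, int method) {
  return eval_all(x, P, method, false, nullptr);
}

// ---------- L-BFGS quench over the 6N rigid-body coordinates ----------

struct MinOut {
  arma::mat x;
  EOut E;
  double gmax = NA_REAL;
  int iters = 0, nev = 0;
  bool conv = false;
};

static MinOut lbfgs_min(const arma::mat& x0, const Params& P,
                        double gtol, int maxit) {
  const int N = x0.n_rows, m = 6;
  MinOut out; out.x = x0;
  arma::mat X = x0, G;
  EOut E = eval_all(X, P, 0, true, &G);
  if (!E.ok) { out.E = E; return out; }
  out.nev = 1;
  double f = E.total();
  arma::vec xv = arma::vectorise(X.t());
  arma::vec gv = arma::vectorise(G.t());

  std::vector<arma::vec> S, Y;
  std::vector<double> rho;

  for (int it = 0; it < maxit; ++it) {
    out.iters = it;
    out.gmax = arma::abs(gv).max();
    if (out.gmax <= gtol) { out.conv = true; break; }

    // two-loop recursion
    arma::vec qv = gv;
    const int k = S.size();
    std::vector<double> a(k);
    for (int i = k - 1; i >= 0; --i) {
      a[i] = rho[i] * arma::dot(S[i], qv);
      qv -= a[i] * Y[i];
    }
    double gamma = 1.0;
    if (k > 0) gamma = arma::dot(S[k-1], Y[k-1]) / arma::dot(Y[k-1], Y[k-1]);
    arma::vec d = gamma * qv;
    for (int i = 0; i < k; ++i) {
      double b = rho[i] * arma::dot(Y[i], d);
      d += (a[i] - b) * S[i];
    }
    d = -d;
    double dg = arma::dot(d, gv);
    if (!(dg < 0.0)) { d = -gv; dg = -arma::dot(gv, gv); }

    // Armijo backtracking; trial step capped so no coordinate moves more
    // than 0.5 (A or rad) at once -- uncapped first steps from
    // high-overlap starts can scatter the cluster
    double t = std::min(1.0, 0.5 / (arma::abs(d).max() + 1e-300));
    const double c1 = 1e-4;
    arma::vec xn; double fn = 0.0;
    arma::mat Xn, Gn; EOut En;
    bool ls_ok = false;
    for (int bt = 0; bt < 50; ++bt) {
      xn = xv + t * d;
      Xn = arma::reshape(xn, 6, N).t();
      En = eval_all(Xn, P, 0, true, &Gn);
      ++out.nev;
      if (En.ok) {
        fn = En.total();
        // Armijo, with a non-increase fallback once the predicted decrease
        // falls below the floating-point noise of the energy
        if (std::isfinite(fn) &&
            (fn <= f + c1 * t * dg ||
             (fn <= f && t * std::abs(dg) < 1e-11 * (1.0 + std::abs(f))))) {
          ls_ok = true; break;
        }
      }
      t *= 0.5;
    }
    if (!ls_ok) break;  // line-search breakdown: return best so far

    arma::vec gn = arma::vectorise(Gn.t());
    arma::vec sv = xn - xv, yv = gn - gv;
    const double sy = arma::dot(sv, yv);
    if (sy > 1e-10) {
      S.push_back(sv); Y.push_back(yv); rho.push_back(1.0 / sy);
      if ((int)S.size() > m) { S.erase(S.begin()); Y.erase(Y.begin()); rho.erase(rho.begin()); }
    }
    xv = xn; gv = gn; f = fn; X = Xn; G = Gn; E = En;
  }
  out.x = X; out.E = E;
  if (std::isfinite(out.gmax) && out.gmax <= gtol) out.conv = true;
  return out;
}

// connectivity of the O-O graph at radius guard_r
static bool oo_connected(const arma::mat& x, double guard_r) {
  const int N = x.n_rows;
  if (N <= 1) return true;
  std::vector<int> stack = {0};
  std::vector<bool> seen(N, false);
  seen[0] = true;
  int nseen = 1;
  while (!stack.empty()) {
    int i = stack.back(); stack.pop_back();
    for (int j = 0; j < N; ++j) {
      if (seen[j]) continue;
      double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
      if (std::sqrt(dx*dx+dy*dy+dz*dz) <= guard_r) {
        seen[j] = true; ++nseen; stack.push_back(j);
      }
    }
  }
  return nseen == N;
}

// ---------- exported interface ----------

// [[Rcpp::export]]
arma::mat cpp_rotation(const arma::vec& p) {
  return rot_aa(arma::vec3(p));
}

// [[Rcpp::export]]
arma::mat cpp_sites(const arma::mat& x, const List& par) {
  Params P = parse_params(par);
  const int N = x.n_rows;
  arma::mat out(4 * N, 3);
  for (int i = 0; i < N; ++i) {
    arma::vec3 pos = { x(i, 0), x(i, 1), x(i, 2) };
    arma::vec3 aa  = { x(i, 3), x(i, 4), x(i, 5) };
    arma::mat33 R = rot_aa(aa);
    for (int a = 0; a < 4; ++a)
      out.row(4 * i + a) = (pos + R * P.body[a]).t();
  }
  return out;
}

static List eout_to_list(const EOut& E) {
  return List::create(
    _["e_lj"] = E.lj, _["e_coulomb"] = E.coul, _["e_pol"] = E.pol,
    _["e_total"] = E.total(), _["ok"] = E.ok, _["converged"] = E.conv,
    _["iterations"] = E.iters, _["residual"] = E.resid,
    _["mu"] = E.mu, _["e0"] = E.e0, _["error"] = E.err);
}

// [[Rcpp::export]]
List cpp_energy(const arma::mat& x, const List& par, int method) {
  Params P = parse_params(par);
  return eout_to_list(eval_energy(x, P, method));
}

// [[Rcpp::export]]
List cpp_gradient(const arma::mat& x, const List& par) {
  Params P = parse_params(par);
  arma::mat g;
  EOut E = eval_all(x, P, 0, true, &g);
  return List::create(_["gradient"] = g, _["ok"] = E.ok, _["error"] = E.err,
                      _["breakdown"] = eout_to_list(E));
}

// [[Rcpp::export]]
List cpp_minimize(const arma::mat& x, const List& par, double gtol, int maxit) {
  Params P = parse_params(par);
  MinOut m = lbfgs_min(x, P, gtol, maxit);
  return List::create(_["x"] = m.x, _["breakdown"] = eout_to_list(m.E),
                      _["gmax"] = m.gmax, _["iterations"] = m.iters,
                      _["n_evaluations"] = m.nev, _["converged"] = m.conv);
}

// One basin-hopping trajectory.  Uses R's RNG stream (seedable with
// set.seed from R).  Moves perturb ALL molecules; blocks of translational
// then angular moves with step-size adaptation toward target_acc.
// [[Rcpp::export]]
List cpp_basin_hopping(const arma::mat& x0, const List& par, int n_steps,
                       double kT, int trans_block, int ang_block,
                       double target_acc, double s_trans, double s_rot,
                       double gtol, int maxit, double guard_r) {
  Params P = parse_params(par);
  const int N = x0.n_rows;

  MinOut cur = lbfgs_min(x0, P, gtol, maxit);
  int n_min = 1;
  // if the random start fails to quench (or quenches into a dissociated
  // configuration), nudge it until it does
  int tries = 0;
  while ((!cur.E.ok || !oo_connected(cur.x, guard_r)) && tries < 50) {
    arma::mat xr = x0;
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 3; ++c) xr(i, c) += R::runif(-0.5, 0.5);
    cur = lbfgs_min(xr, P, gtol, maxit);
    ++n_min; ++tries;
  }
  if (!cur.E.ok) stop("basin hopping: could not quench the starting configuration");

  double e_cur = cur.E.total();
  arma::mat best_x = cur.x;
  EOut best_e = cur.E;
  int best_step = 0;

  std::vector<double> acc_hist, st_hist, sr_hist, best_hist;
  int step = 0;
  bool translational = true;
  while (step < n_steps) {
    const int blk = translational ? trans_block : ang_block;
    int n_acc = 0, n_try = 0;
    for (int b = 0; b < blk && step < n_steps; ++b, ++step) {
      arma::mat xp = cur.x;
      if (translational) {
        for (int i = 0; i < N; ++i)
          for (int c = 0; c < 3; ++c) xp(i, c) += R::runif(-s_trans, s_trans);
      } else {
        for (int i = 0; i < N; ++i)
          for (int c = 3; c < 6; ++c) xp(i, c) += R::runif(-s_rot, s_rot);
      }
      MinOut prop = lbfgs_min(xp, P, gtol, maxit);
      ++n_min; ++n_try;
      if (!prop.E.ok || !std::isfinite(prop.E.total())) continue;
      if (!oo_connected(prop.x, guard_r)) continue;  // evaporated molecule
      const double e_new = prop.E.total();
      bool accept = e_new <= e_cur ||
                    unif_rand() < std::exp(-(e_new - e_cur) / kT);
      if (accept) {
        cur = prop; e_cur = e_new; ++n_acc;
        if (e_new < best_e.total()) { best_x = cur.x; best_e = cur.E; best_step = step; }
      }
    }
    const double frac = n_try > 0 ? (double)n_acc / n_try : 0.0;
    acc_hist.push_back(frac);
    if (translational) {
      s_trans *= (frac > target_acc) ? 1.05 : 0.95;
      s_trans = std::min(2.0, std::max(1e-3, s_trans));
    } else {
      s_rot *= (frac > target_acc) ? 1.05 : 0.95;
      s_rot = std::min(M_PI, std::max(1e-3, s_rot));
    }
    st_hist.push_back(s_trans); sr_hist.push_back(s_rot);
    best_hist.push_back(best_e.total());
    translational = !translational;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["best_x"] = best_x, _["best"] = eout_to_list(best_e),
    _["best_step"] = best_step, _["n_minimizations"] = n_min,
    _["acceptance"] = acc_hist, _["step_trans"] = st_hist,
    _["step_rot"] = sr_hist, _["best_history"] = best_hist);
}
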