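#include <RcppArmadillo.h>
#include "substep_taylor.h"
// [[Rcpp::depends(RcppArmadillo)]]

// Compiled trajectory core for linear-vibronic-coupling models.
//
// Implements the same three-step integrator as the R-level operations
// (nuclear velocity Verlet on the active spin-adiabatic surface;
// diagonalization + gauge alignment at the new geometry; substepped unitary
// electronic propagation with linearly interpolated energies/couplings and
// fewest-switches hop decision), specialized to the LVC model family so
// long ensembles run at compiled speed. Hop rolls draw from R's RNG so
// trajectories are reproducible under set.seed().
//
// All quantities in Hartree atomic units.

namespace {

struct ModelAU {
  arma::vec omega, mass, q0, e0;
  arma::mat kappa;          // (nS+nT) x K
  arma::cube lamS, lamT;    // nS x nS x K, nT x nT x K
  arma::cx_mat soc;         // nS x 3nT (diabatic base)
  arma::mat mod;            // rows: [row col mode lin quad] (1-based idx)
  int nS, nT, K, d;
};

ModelAU unpack(const Rcpp::List& m) {
  ModelAU M;
  M.omega = Rcpp::as<arma::vec>(m["omega"]);
  M.mass = Rcpp::as<arma::vec>(m["mass"]);
  M.q0 = Rcpp::as<arma::vec>(m["q0"]);
  M.e0 = Rcpp::as<arma::vec>(m["e0"]);
  M.kappa = Rcpp::as<arma::mat>(m["kappa"]);
  M.lamS = Rcpp::as<arma::cube>(m["lamS"]);
  M.lamT = Rcpp::as<arma::cube>(m["lamT"]);
  M.soc = Rcpp::as<arma::cx_mat>(m["soc"]);
  M.mod = Rcpp::as<arma::mat>(m["mod"]);
  M.nS = Rcpp::as<int>(m["nS"]);
  M.nT = Rcpp::as<int>(m["nT"]);
  M.K = M.omega.n_elem;
  M.d = M.nS + 3 * M.nT;
  return M;
}

// diabatic SOC with magnitude modulation at coordinates q
arma::cx_mat soc_at(const ModelAU& M, const arma::vec& q) {
  arma::cx_mat soc = M.soc;
  for (arma::uword r = 0; r < M.mod.n_rows; ++r) {
    int i = int(M.mod(r, 0)) - 1, j = int(M.mod(r, 1)) - 1,
        k = int(M.mod(r, 2)) - 1;
    double dd = q(k) - M.q0(k);
    double add = M.mod(r, 3) * dd + M.mod(r, 4) * dd * dd;
    std::complex<double> base = M.soc(i, j);
    double mag = std::abs(base);
    soc(i, j) = mag > 0 ? base * ((mag + add) / mag)
                        : std::complex<double>(add, 0.0);
  }
  return soc;
}

struct Frame {
  arma::vec eS, eT, E;      // scalar energies; spin-adiabatic energies
  arma::mat RS, RT;         // scalar rotations
  arma::cx_mat U;           // spin-adiabatic vectors (scalar basis)
};

// scalar-layer evaluation + spin Hamiltonian diagonalization
Frame eval_frame(const ModelAU& M, const arma::vec& q, double alpha) {
  Frame F;
  arma::vec dq = q - M.q0;
  double vh = 0.5 * arma::accu(M.mass % arma::square(M.omega) % arma::square(dq));
  arma::vec diag_e = M.e0 + M.kappa * dq + vh;
  arma::mat VS = arma::diagmat(diag_e.head(M.nS));
  for (int k = 0; k < M.K; ++k) VS += M.lamS.slice(k) * dq(k);
  arma::eig_sym(F.eS, F.RS, VS);
  arma::cx_mat Hsp(M.d, M.d, arma::fill::zeros);
  if (M.nT > 0) {
    arma::mat VT = arma::diagmat(diag_e.tail(M.nT));
    for (int k = 0; k < M.K; ++k) VT += M.lamT.slice(k) * dq(k);
    arma::eig_sym(F.eT, F.RT, VT);
    arma::cx_mat socs = arma::conv_to<arma::cx_mat>::from(F.RS.t()) *
      soc_at(M, q) * arma::kron(arma::conv_to<arma::cx_mat>::from(F.RT),
                                arma::cx_mat(arma::eye(3, 3), arma::zeros(3, 3)));
    Hsp.submat(0, M.nS, M.nS - 1, M.d - 1) = alpha * socs;
    Hsp.submat(M.nS, 0, M.d - 1, M.nS - 1) = alpha * socs.t();
    for (int t = 0; t < M.nT; ++t)
      for (int c = 0; c < 3; ++c)
        Hsp(M.nS + 3 * t + c, M.nS + 3 * t + c) = F.eT(t);
  }
  for (int s = 0; s < M.nS; ++s) Hsp(s, s) = F.eS(s);
  arma::vec E;
  arma::cx_mat U;
  arma::eig_sym(E, U, Hsp);   // ascending
  F.E = E;
  F.U = U;
  return F;
}

// scalar-basis overlap between consecutive frames (block diagonal)
arma::mat scalar_overlap(const ModelAU& M, const Frame& A, const Frame& B) {
  arma::mat S(M.d, M.d, arma::fill::zeros);
  S.submat(0, 0, M.nS - 1, M.nS - 1) = A.RS.t() * B.RS;
  if (M.nT > 0)
    S.submat(M.nS, M.nS, M.d - 1, M.d - 1) =
      arma::kron(A.RT.t() * B.RT, arma::eye(3, 3));
  return S;
}

// gauge alignment: permutation by greedy max |overlap|, phase fix; returns
// the aligned overlap matrix and permutes U and E in place
arma::cx_mat align_in_place(const arma::cx_mat& U_prev, const arma::mat& S,
                            arma::cx_mat& U, arma::vec& E) {
  const int d = U.n_cols;
  arma::cx_mat O = U_prev.t() * (arma::conv_to<arma::cx_mat>::from(S) * U);
  arma::vec dO = arma::abs(O.diag());
  if (dO.min() <= 0.7071) {
    arma::mat absO = arma::abs(O);
    arma::uvec perm(d, arma::fill::zeros);
    std::vector<bool> taken(d, false);
    arma::vec rowmax = arma::max(absO, 1);
    arma::uvec order = arma::sort_index(rowmax, "descend");
    for (int s = 0; s < d; ++s) {
      int i = order(s);
      int bestj = -1; double best = -1.0;
      for (int j = 0; j < d; ++j)
        if (!taken[j] && absO(i, j) > best) { best = absO(i, j); bestj = j; }
      perm(i) = bestj; taken[bestj] = true;
    }
    U = U.cols(perm);
    E = E(perm);
    O = O.cols(perm);
  }
  for (int j = 0; j < d; ++j) {
    std::complex<double> o = O(j, j);
    double m = std::abs(o);
    if (m > 1e-14) {
      std::complex<double> ph = std::conj(o) / m;
      U.col(j) *= ph;
      O.col(j) *= ph;
    }
  }
  return O;
}

// Hellmann-Feynman force on the active spin-adiabatic surface
arma::vec active_force(const ModelAU& M, const arma::vec& q, const Frame& F,
                       int active, double alpha) {
  arma::cx_vec u = F.U.col(active);
  arma::cx_vec wS = arma::conv_to<arma::cx_mat>::from(F.RS) * u.head(M.nS);
  arma::cx_mat WT;
  arma::cx_vec wTv;
  if (M.nT > 0) {
    arma::cx_mat uT(u.memptr() + M.nS, 3, M.nT);  // copy view: 3 x nT
    WT = arma::cx_mat(uT) * arma::conv_to<arma::cx_mat>::from(F.RT.t());
    wTv = arma::vectorise(WT);
  }
  arma::vec dq = q - M.q0;
  arma::vec f(M.K, arma::fill::zeros);
  for (int k = 0; k < M.K; ++k) {
    double harm = M.mass(k) * M.omega(k) * M.omega(k) * dq(k);
    double g = harm;
    arma::mat AS = arma::diagmat(M.kappa.col(k).head(M.nS)) + M.lamS.slice(k);
    g += std::real(arma::cdot(wS, arma::conv_to<arma::cx_mat>::from(AS) * wS));
    if (M.nT > 0) {
      arma::mat AT = arma::diagmat(M.kappa.col(k).tail(M.nT)) + M.lamT.slice(k);
      g += std::real(arma::cdot(wTv,
             arma::vectorise(WT * arma::conv_to<arma::cx_mat>::from(AT.t()))));
      // SOC modulation derivative along mode k
      for (arma::uword r = 0; r < M.mod.n_rows; ++r) {
        if (int(M.mod(r, 2)) - 1 != k) continue;
        int i = int(M.mod(r, 0)) - 1, j = int(M.mod(r, 1)) - 1;
        double dd = dq(k);
        double dmag = M.mod(r, 3) + 2.0 * M.mod(r, 4) * dd;
        std::complex<double> base = M.soc(i, j);
        std::complex<double> ph = std::abs(base) > 0 ? base / std::abs(base)
                                                     : std::complex<double>(1, 0);
        std::complex<double> dsoc = ph * dmag;
        g += 2.0 * alpha * std::real(std::conj(wS(i)) * dsoc * wTv(j));
      }
    }
    f(k) = -g;
  }
  return f;
}

}  // namespace

// [[Rcpp::export(name = ".run_lvc_trajectory")]]
Rcpp::List run_lvc_trajectory(const Rcpp::List& model_au,
                              const arma::vec& q_init, const arma::vec& p_init,
                              int init_row, double alpha, double dt,
                              int n_sub, int n_steps) {
  ModelAU M = unpack(model_au);
  const int d = M.d, nscal = M.nS + M.nT;
  arma::vec q = q_init, p = p_init;

  Frame F = eval_frame(M, q, alpha);
  arma::uword active;
  arma::abs(F.U.row(init_row - 1)).eval().max(active);
  arma::cx_vec c(d, arma::fill::zeros);
  c(active) = 1.0;
  arma::mat Tc(d, d, arma::fill::zeros);

  const int n_rec = n_steps + 1;
  arma::vec times(n_rec), pot(n_rec), kin(n_rec);
  arma::mat Qs(n_rec, M.K), Ps(n_rec, M.K);
  arma::ivec act(n_rec);
  arma::mat popA(n_rec, d), popD(n_rec, nscal);
  std::vector<double> hop_t;
  std::vector<int> hop_from, hop_to, hop_acc;
  Rcpp::List hop_U;
  int n_renorm = 0;
  bool truncated = false;
  int n_done = 0;

  auto record = [&](int i, double t_fs_au_steps) {
    times(i) = t_fs_au_steps;
    Qs.row(i) = q.t();
    Ps.row(i) = p.t();
    act(i) = active + 1;
    arma::vec pa = arma::square(arma::abs(c));
    popA.row(i) = pa.t();
    arma::cx_vec b = F.U * c;
    arma::vec pb = arma::square(arma::abs(b));
    for (int s = 0; s < M.nS; ++s) popD(i, s) = pb(s);
    for (int t = 0; t < M.nT; ++t)
      popD(i, M.nS + t) = pb(M.nS + 3 * t) + pb(M.nS + 3 * t + 1) +
        pb(M.nS + 3 * t + 2);
    pot(i) = F.E(active);
    kin(i) = arma::accu(arma::square(p) / (2.0 * M.mass));
  };
  record(0, 0.0);
  n_done = 1;

  for (int step = 1; step <= n_steps; ++step) {
    arma::vec f = active_force(M, q, F, active, alpha);
    if (!f.is_finite()) { truncated = true; break; }
    arma::vec p_half = p + 0.5 * dt * f;
    arma::vec q_new = q + dt * (p_half / M.mass);
    Frame F2 = eval_frame(M, q_new, alpha);
    arma::mat S = scalar_overlap(M, F, F2);
    arma::cx_mat O = align_in_place(F.U, S, F2.U, F2.E);
    arma::mat Rr = arma::real(O);
    arma::mat T2 = (Rr - Rr.t()) / (2.0 * dt);
    arma::vec f2 = active_force(M, q_new, F2, active, alpha);
    arma::vec p_new = p_half + 0.5 * dt * f2;

    // substepped unitary propagation + fewest-switches flux accumulation
    arma::vec g(d, arma::fill::zeros);
    {
      const double h = dt / n_sub;
      for (int s = 0; s < n_sub; ++s) {
        const double fm = (s + 0.5) / n_sub;
        arma::vec Em = (1.0 - fm) * F.E + fm * F2.E;
        arma::mat Tm = (1.0 - fm) * Tc + fm * T2;
        const std::complex<double> ca = c(active);
        const double pa = std::norm(ca);
        if (pa > 1e-12) {
          for (int j = 0; j < d; ++j) {
            if (j == (int)active) continue;
            double flux = 2.0 * std::real(std::conj(c(j)) * ca *
                                          Tm(active, j)) * h / pa;
            if (flux > 0.0) g(j) += flux;
          }
        }
        substep_apply(c, Em, Tm, h);
      }
    }
    double nrm = std::sqrt(arma::accu(arma::square(arma::abs(c))));
    if (std::abs(nrm - 1.0) > 1e-8) { c /= nrm; ++n_renorm; }
    double tot = arma::accu(g);
    if (tot > 1.0) g /= tot;

    q = q_new; p = p_new; F = F2; Tc = T2;

    double xi = R::unif_rand();
    if (xi < std::min(tot, 1.0)) {
      double cum = 0.0;
      int target = -1;
      for (int j = 0; j < d; ++j) { cum += g(j); if (xi < cum) { target = j; break; } }
      if (target >= 0) {
        double ke = arma::accu(arma::square(p) / (2.0 * M.mass));
        double gap = F.E(target) - F.E(active);
        bool accepted = ke >= gap;
        int from = active;
        if (accepted) {
          p *= std::sqrt((ke - gap) / ke);
          active = target;
        }
        hop_t.push_back(step * dt);
        hop_from.push_back(from + 1);
        hop_to.push_back(target + 1);
        hop_acc.push_back(accepted ? 1 : 0);
        hop_U.push_back(Rcpp::wrap(F.U));
      }
    }
    if (!F.E.is_finite()) { truncated = true; break; }
    record(step, step * dt);
    n_done = step + 1;
  }

  arma::span keep(0, n_done - 1);
  return Rcpp::List::create(
    Rcpp::Named("times_au") = times(keep),
    Rcpp::Named("coords") = Qs.rows(0, n_done - 1),
    Rcpp::Named("momenta") = Ps.rows(0, n_done - 1),
    Rcpp::Named("active") = act(keep),
    Rcpp::Named("pop_adiabatic") = popA.rows(0, n_done - 1),
    Rcpp::Named("pop_diabatic") = popD.rows(0, n_done - 1),
    Rcpp::Named("potential") = pot(keep),
    Rcpp::Named("kinetic") = kin(keep),
    Rcpp::Named("hop_t") = hop_t,
    Rcpp::Named("hop_from") = hop_from,
    Rcpp::Named("hop_to") = hop_to,
    Rcpp::Named("hop_accepted") = hop_acc,
    Rcpp::Named("hop_U") = hop_U,
    Rcpp::Named("n_renorm") = n_renorm,
    Rcpp::Named("truncated") = truncated);
}
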