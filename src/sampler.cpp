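// Metropolis-within-Gibbs sampler for the data-augmented integrated SCR
// model (SCR captures + occupancy detection/nondetection + telemetry).
//
// Parameterisation notes:
//  * cloglog link: p = 1 - exp(-lambda) implies log(1 - p) = -lambda, so the
//    all-zero binomial mass of a latent individual is -sum_j K_j lambda_ij
//    and the per-camera union probability is 1 - exp(-Lambda_j) with
//    Lambda_j = lam0_cam * sum_{i: z_i = 1} E_ij.  Both are linear in the
//    baseline rates, which keeps most updates free of exp() calls.
//  * E matrices cache exp(-d^2 / (2 sigma^2)); squared distances are cached
//    separately so a sigma move only pays exp(), not distance arithmetic.
//  * Binomial normalising constants are dropped throughout (they cancel in
//    every Metropolis ratio); R-side likelihood functions keep them.

#include <Rcpp.h>
using namespace Rcpp;

static inline double lg1me(double lam) {
  // log(1 - exp(-lam)) for lam > 0
  if (lam <= 0.0) return R_NegInf;
  if (lam < 0.693) return std::log(-std::expm1(-lam));
  return std::log1p(-std::exp(-lam));
}

// per-camera occupancy log-mass (constant dropped): y*log(1-e^-L) - (K-y)*L
static inline double occ_term(double Lam, int y, int K) {
  if (y == 0) return -(double)K * Lam;
  return y * lg1me(Lam) - (double)(K - y) * Lam;
}

struct Model {
  // data
  IntegerMatrix yscr;      // n x Jt
  IntegerVector Kt, bait;  // Jt
  NumericMatrix trapxy;    // Jt x 2
  IntegerVector yocc, Kc;  // Jc
  NumericMatrix camxy;     // Jc x 2
  // telemetry summaries per tagged individual
  IntegerVector tel_slot;  // 0-based augmented slot
  NumericVector tel_mx, tel_my, tel_ss; // centroid + total squared dev
  IntegerVector tel_R;
  double tel_Rtot, tel_SStot;
  // config
  int M, n, Jt, Jc, m_tel;
  bool use_scr, use_occ, use_tel, use_cov;
  int cov_link; // 0 log, 1 logit
  double xmin, xmax, ymin, ymax;
  double sigma_max, lam0t_max, lam0c_max, beta_sd, rj_sd, rj_prior;

  // state
  std::vector<int> z;
  std::vector<double> sx, sy;
  double psi, sigma, beta0, beta1;
  int w;

  // caches
  std::vector<double> D2t, D2c;   // M x J squared distances (row-major)
  std::vector<double> Et, Ec;     // exp kernels
  std::vector<double> S0, S1;     // per-row K-weighted trap kernel sums by bait class
  std::vector<double> Socc;       // per-camera sum of Ec over z = 1 rows
  std::vector<int> tagged_of;     // slot -> tagged index or -1
  int Ninc;
  double lam0c;

  double lam00() const {
    return use_cov && cov_link == 1 ? 1.0 / (1.0 + std::exp(-beta0))
                                    : std::exp(beta0);
  }
  double lam01() const {
    double eta = beta0 + (w ? beta1 : 0.0);
    return use_cov && cov_link == 1 ? 1.0 / (1.0 + std::exp(-eta))
                                    : std::exp(eta);
  }

  void row_dist(int i) {
    for (int j = 0; j < Jt; ++j) {
      double dx = sx[i] - trapxy(j, 0), dy = sy[i] - trapxy(j, 1);
      D2t[(size_t)i * Jt + j] = dx * dx + dy * dy;
    }
    for (int j = 0; j < Jc; ++j) {
      double dx = sx[i] - camxy(j, 0), dy = sy[i] - camxy(j, 1);
      D2c[(size_t)i * Jc + j] = dx * dx + dy * dy;
    }
  }

  void row_kernel(int i) {
    double h = 1.0 / (2.0 * sigma * sigma);
    double s0 = 0.0, s1 = 0.0;
    for (int j = 0; j < Jt; ++j) {
      double e = std::exp(-D2t[(size_t)i * Jt + j] * h);
      Et[(size_t)i * Jt + j] = e;
      if (bait[j]) s1 += Kt[j] * e; else s0 += Kt[j] * e;
    }
    S0[i] = s0; S1[i] = s1;
    for (int j = 0; j < Jc; ++j)
      Ec[(size_t)i * Jc + j] = std::exp(-D2c[(size_t)i * Jc + j] * h);
  }

  void rebuild_all() {
    for (int i = 0; i < M; ++i) { row_dist(i); row_kernel(i); }
    rebuild_socc();
  }

  void rebuild_kernels() {
    for (int i = 0; i < M; ++i) row_kernel(i);
    rebuild_socc();
  }

  void rebuild_socc() {
    std::fill(Socc.begin(), Socc.end(), 0.0);
    Ninc = 0;
    for (int i = 0; i < M; ++i) if (z[i]) {
      ++Ninc;
      for (int j = 0; j < Jc; ++j) Socc[j] += Ec[(size_t)i * Jc + j];
    }
  }

  // observed-rows SCR log-likelihood (constants dropped) for given kernels
  double ll_scr_obs(const std::vector<double>& E, double l0, double l1) const {
    if (!use_scr) return 0.0;
    double ll = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < Jt; ++j) {
        double lam = (bait[j] ? l1 : l0) * E[(size_t)i * Jt + j];
        int y = yscr(i, j);
        if (y > 0) ll += y * lg1me(lam) - (double)(Kt[j] - y) * lam;
        else       ll += -(double)Kt[j] * lam;
      }
    return ll;
  }

  // all-zero SCR mass of latent included individuals
  double ll_scr_zero(const std::vector<double>& s0v,
                     const std::vector<double>& s1v,
                     double l0, double l1) const {
    if (!use_scr) return 0.0;
    double acc = 0.0;
    for (int i = n; i < M; ++i) if (z[i]) acc += l0 * s0v[i] + l1 * s1v[i];
    return -acc;
  }

  double ll_occ_all(const std::vector<double>& S, double l0c) const {
    if (!use_occ) return 0.0;
    double ll = 0.0;
    for (int j = 0; j < Jc; ++j) ll += occ_term(l0c * S[j], yocc[j], Kc[j]);
    return ll;
  }

  double ll_tel(double sig) const {
    if (!use_tel || m_tel == 0) return 0.0;
    double quad = tel_SStot;
    for (int t = 0; t < m_tel; ++t) {
      int i = tel_slot[t];
      double dx = sx[i] - tel_mx[t], dy = sy[i] - tel_my[t];
      quad += tel_R[t] * (dx * dx + dy * dy);
    }
    return -2.0 * tel_Rtot * std::log(sig) - quad / (2.0 * sig * sig);
  }
};

// [[Rcpp::export]]
List run_chain_cpp(IntegerMatrix yscr, IntegerVector Kt, IntegerVector bait,
                   NumericMatrix trapxy, IntegerVector yocc, IntegerVector Kc,
                   NumericMatrix camxy, IntegerVector tel_slot,
                   NumericVector tel_mx, NumericVector tel_my,
                   NumericVector tel_ss, IntegerVector tel_R,
                   int M, int n_pin, NumericVector bounds, List priors,
                   List init, List prop, List flags, int n_iter, int n_burn) {
  Model mod;
  mod.yscr = yscr; mod.Kt = Kt; mod.bait = bait; mod.trapxy = trapxy;
  mod.yocc = yocc; mod.Kc = Kc; mod.camxy = camxy;
  mod.tel_slot = tel_slot; mod.tel_mx = tel_mx; mod.tel_my = tel_my;
  mod.tel_ss = tel_ss; mod.tel_R = tel_R;
  mod.m_tel = tel_slot.size();
  mod.tel_Rtot = 0.0; mod.tel_SStot = 0.0;
  for (int t = 0; t < mod.m_tel; ++t) {
    mod.tel_Rtot += tel_R[t]; mod.tel_SStot += tel_ss[t];
  }
  mod.M = M; mod.n = yscr.nrow(); mod.Jt = Kt.size(); mod.Jc = Kc.size();
  mod.use_scr = flags["use_scr"]; mod.use_occ = flags["use_occ"];
  mod.use_tel = flags["use_tel"]; mod.use_cov = flags["use_cov"];
  mod.cov_link = flags["cov_link"];
  bool use_rj = flags["use_rj"];
  bool upd_z = flags["upd_z"], upd_s = flags["upd_s"],
       upd_sigma = flags["upd_sigma"], upd_lam0t = flags["upd_lam0t"],
       upd_lam0c = flags["upd_lam0c"], upd_psi = flags["upd_psi"];
  bool adapt = flags["adapt"];
  mod.xmin = bounds[0]; mod.xmax = bounds[1];
  mod.ymin = bounds[2]; mod.ymax = bounds[3];
  mod.sigma_max = priors["sigma_max"]; mod.lam0t_max = priors["lam0_trap_max"];
  mod.lam0c_max = priors["lam0_cam_max"]; mod.beta_sd = priors["beta_sd"];
  mod.rj_sd = priors["rj_sd"]; mod.rj_prior = priors["rj_prior"];
  double psi_a = priors["psi_a"], psi_b = priors["psi_b"];

  // state init
  IntegerVector z0 = init["z"]; NumericMatrix s0m = init["s"];
  mod.z.assign(z0.begin(), z0.end());
  mod.sx.resize(M); mod.sy.resize(M);
  for (int i = 0; i < M; ++i) { mod.sx[i] = s0m(i, 0); mod.sy[i] = s0m(i, 1); }
  mod.psi = init["psi"]; mod.sigma = init["sigma"];
  mod.beta0 = init["beta0"]; mod.beta1 = init["beta1"];
  mod.w = init["w"]; mod.lam0c = init["lam0_cam"];

  mod.D2t.assign((size_t)M * mod.Jt, 0.0);
  mod.D2c.assign((size_t)M * mod.Jc, 0.0);
  mod.Et.assign((size_t)M * mod.Jt, 0.0);
  mod.Ec.assign((size_t)M * mod.Jc, 0.0);
  mod.S0.assign(M, 0.0); mod.S1.assign(M, 0.0);
  mod.Socc.assign(mod.Jc, 0.0);
  mod.tagged_of.assign(M, -1);
  for (int t = 0; t < mod.m_tel; ++t) mod.tagged_of[tel_slot[t]] = t;
  mod.rebuild_all();

  double ps_s = prop["s"], ps_sig = prop["sigma"], ps_l0t = prop["lam0_trap"],
         ps_l0c = prop["lam0_cam"], ps_b1 = prop["beta1"];

  int n_keep = std::max(0, n_iter - n_burn);
  int n_par = 8 + 2 * n_pin;  // psi sigma lam0t lam0c beta1 w N + s_pinned
  NumericMatrix draws(n_keep, n_par);

  // acceptance bookkeeping: s, sigma, lam0t, lam0c, beta1
  double acc[5] = {0, 0, 0, 0, 0}, try_[5] = {0, 0, 0, 0, 0};
  double bacc[5] = {0, 0, 0, 0, 0}, btry[5] = {0, 0, 0, 0, 0};
  int batch = 0;

  std::vector<double> newEt(mod.Jt), newEc(mod.Jc);

  for (int it = 0; it < n_iter; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
    double l0 = mod.lam00(), l1 = mod.lam01();

    // ---- z: Gibbs full conditional for latent slots ----------------------
    if (upd_z) {
      double lodds_psi = std::log(mod.psi) - std::log1p(-mod.psi);
      for (int i = n_pin; i < M; ++i) {
        double d = lodds_psi;
        if (mod.use_scr) d -= l0 * mod.S0[i] + l1 * mod.S1[i];
        if (mod.use_occ) {
          for (int j = 0; j < mod.Jc; ++j) {
            double lamij = mod.lam0c * mod.Ec[(size_t)i * mod.Jc + j];
            double base = mod.lam0c * mod.Socc[j] -
                          (mod.z[i] ? lamij : 0.0);
            d += occ_term(base + lamij, mod.yocc[j], mod.Kc[j]) -
                 occ_term(base, mod.yocc[j], mod.Kc[j]);
          }
        }
        int znew = (R::unif_rand() < 1.0 / (1.0 + std::exp(-d))) ? 1 : 0;
        if (znew != mod.z[i]) {
          double sgn = znew ? 1.0 : -1.0;
          for (int j = 0; j < mod.Jc; ++j)
            mod.Socc[j] += sgn * mod.Ec[(size_t)i * mod.Jc + j];
          mod.Ninc += znew ? 1 : -1;
          mod.z[i] = znew;
        }
      }
    }

    // ---- s: per-individual moves -----------------------------------------
    if (upd_s) {
      double h = 1.0 / (2.0 * mod.sigma * mod.sigma);
      for (int i = 0; i < M; ++i) {
        if (mod.z[i] == 0 && i >= n_pin) {
          // no likelihood terms: redraw from the uniform prior
          mod.sx[i] = R::runif(mod.xmin, mod.xmax);
          mod.sy[i] = R::runif(mod.ymin, mod.ymax);
          mod.row_dist(i); mod.row_kernel(i);
          continue;
        }
        double px = mod.sx[i] + R::norm_rand() * ps_s;
        double py = mod.sy[i] + R::norm_rand() * ps_s;
        btry[0] += 1.0; try_[0] += 1.0;
        if (px < mod.xmin || px > mod.xmax || py < mod.ymin || py > mod.ymax)
          continue;
        double dll = 0.0, ns0 = 0.0, ns1 = 0.0;
        for (int j = 0; j < mod.Jt; ++j) {
          double dx = px - mod.trapxy(j, 0), dy = py - mod.trapxy(j, 1);
          double e = std::exp(-(dx * dx + dy * dy) * h);
          newEt[j] = e;
          if (mod.bait[j]) ns1 += mod.Kt[j] * e; else ns0 += mod.Kt[j] * e;
        }
        if (mod.use_scr) {
          if (i < mod.n) {
            for (int j = 0; j < mod.Jt; ++j) {
              double l0j = mod.bait[j] ? l1 : l0;
              double lamn = l0j * newEt[j];
              double lamo = l0j * mod.Et[(size_t)i * mod.Jt + j];
              int y = mod.yscr(i, j);
              if (y > 0)
                dll += y * (lg1me(lamn) - lg1me(lamo)) -
                       (double)(mod.Kt[j] - y) * (lamn - lamo);
              else
                dll += -(double)mod.Kt[j] * (lamn - lamo);
            }
          } else {
            dll += -(l0 * (ns0 - mod.S0[i]) + l1 * (ns1 - mod.S1[i]));
          }
        }
        if (mod.use_occ) {
          for (int j = 0; j < mod.Jc; ++j) {
            double dx = px - mod.camxy(j, 0), dy = py - mod.camxy(j, 1);
            newEc[j] = std::exp(-(dx * dx + dy * dy) * h);
            double old_lam = mod.lam0c * mod.Ec[(size_t)i * mod.Jc + j];
            double base = mod.lam0c * mod.Socc[j] - old_lam;
            dll += occ_term(base + mod.lam0c * newEc[j], mod.yocc[j], mod.Kc[j]) -
                   occ_term(base + old_lam, mod.yocc[j], mod.Kc[j]);
          }
        }
        int t = mod.tagged_of[i];
        if (mod.use_tel && t >= 0) {
          double dxn = px - mod.tel_mx[t], dyn = py - mod.tel_my[t];
          double dxo = mod.sx[i] - mod.tel_mx[t], dyo = mod.sy[i] - mod.tel_my[t];
          dll += -mod.tel_R[t] *
                 ((dxn * dxn + dyn * dyn) - (dxo * dxo + dyo * dyo)) *
                 h;  // h = 1/(2 sigma^2)
        }
        if (std::log(R::unif_rand()) < dll) {
          bacc[0] += 1.0; acc[0] += 1.0;
          mod.sx[i] = px; mod.sy[i] = py;
          for (int j = 0; j < mod.Jt; ++j) {
            double dx = px - mod.trapxy(j, 0), dy = py - mod.trapxy(j, 1);
            mod.D2t[(size_t)i * mod.Jt + j] = dx * dx + dy * dy;
            mod.Et[(size_t)i * mod.Jt + j] = newEt[j];
          }
          mod.S0[i] = ns0; mod.S1[i] = ns1;
          for (int j = 0; j < mod.Jc; ++j) {
            double dx = px - mod.camxy(j, 0), dy = py - mod.camxy(j, 1);
            mod.D2c[(size_t)i * mod.Jc + j] = dx * dx + dy * dy;
            if (!mod.use_occ)
              newEc[j] = std::exp(-mod.D2c[(size_t)i * mod.Jc + j] * h);
            if (mod.z[i])
              mod.Socc[j] += newEc[j] - mod.Ec[(size_t)i * mod.Jc + j];
            mod.Ec[(size_t)i * mod.Jc + j] = newEc[j];
          }
        }
      }
    }

    // ---- sigma: log-scale random walk ------------------------------------
    if (upd_sigma) {
      btry[1] += 1.0; try_[1] += 1.0;
      double signew = mod.sigma * std::exp(R::norm_rand() * ps_sig);
      if (signew < mod.sigma_max) {
        double hn = 1.0 / (2.0 * signew * signew);
        // candidate kernels for rows that matter (z = 1)
        double ll_new = 0.0, ll_old = 0.0;
        std::vector<double> candS(mod.Jc, 0.0);
        std::vector<double> candS0(mod.M, 0.0), candS1(mod.M, 0.0);
        // observed rows
        for (int i = 0; i < mod.M; ++i) {
          if (!mod.z[i]) continue;
          double s0n = 0.0, s1n = 0.0;
          if (mod.use_scr) {
            if (i < mod.n) {
              for (int j = 0; j < mod.Jt; ++j) {
                double l0j = mod.bait[j] ? l1 : l0;
                double en = std::exp(-mod.D2t[(size_t)i * mod.Jt + j] * hn);
                double lamn = l0j * en;
                double lamo = l0j * mod.Et[(size_t)i * mod.Jt + j];
                int y = mod.yscr(i, j);
                if (y > 0) {
                  ll_new += y * lg1me(lamn) - (double)(mod.Kt[j] - y) * lamn;
                  ll_old += y * lg1me(lamo) - (double)(mod.Kt[j] - y) * lamo;
                } else {
                  ll_new += -(double)mod.Kt[j] * lamn;
                  ll_old += -(double)mod.Kt[j] * lamo;
                }
              }
            } else {
              for (int j = 0; j < mod.Jt; ++j) {
                double en = std::exp(-mod.D2t[(size_t)i * mod.Jt + j] * hn);
                if (mod.bait[j]) s1n += mod.Kt[j] * en; else s0n += mod.Kt[j] * en;
              }
              ll_new += -(l0 * s0n + l1 * s1n);
              ll_old += -(l0 * mod.S0[i] + l1 * mod.S1[i]);
            }
          }
          if (mod.use_occ)
            for (int j = 0; j < mod.Jc; ++j)
              candS[j] += std::exp(-mod.D2c[(size_t)i * mod.Jc + j] * hn);
        }
        if (mod.use_occ) {
          ll_new += mod.ll_occ_all(candS, mod.lam0c);
          ll_old += mod.ll_occ_all(mod.Socc, mod.lam0c);
        }
        if (mod.use_tel) {
          ll_new += mod.ll_tel(signew);
          ll_old += mod.ll_tel(mod.sigma);
        }
        double lr = ll_new - ll_old + std::log(signew / mod.sigma);
        if (std::log(R::unif_rand()) < lr) {
          bacc[1] += 1.0; acc[1] += 1.0;
          mod.sigma = signew;
          mod.rebuild_kernels();
        }
      }
    }

    // ---- lam0_trap / beta0, beta1 ---------------------------------------
    if (upd_lam0t && mod.use_scr) {
      if (!mod.use_cov) {
        btry[2] += 1.0; try_[2] += 1.0;
        double cur = std::exp(mod.beta0);
        double candidate = cur * std::exp(R::norm_rand() * ps_l0t);
        if (candidate < mod.lam0t_max) {
          double lln = mod.ll_scr_obs(mod.Et, candidate, candidate) +
                       mod.ll_scr_zero(mod.S0, mod.S1, candidate, candidate);
          double llo = mod.ll_scr_obs(mod.Et, cur, cur) +
                       mod.ll_scr_zero(mod.S0, mod.S1, cur, cur);
          double lr = lln - llo + std::log(candidate / cur);
          if (std::log(R::unif_rand()) < lr) {
            bacc[2] += 1.0; acc[2] += 1.0;
            mod.beta0 = std::log(candidate);
          }
        }
      } else {
        // beta0 random walk, normal prior
        btry[2] += 1.0; try_[2] += 1.0;
        double b0n = mod.beta0 + R::norm_rand() * ps_l0t;
        double save = mod.beta0;
        double llo = mod.ll_scr_obs(mod.Et, mod.lam00(), mod.lam01()) +
                     mod.ll_scr_zero(mod.S0, mod.S1, mod.lam00(), mod.lam01());
        mod.beta0 = b0n;
        double lln = mod.ll_scr_obs(mod.Et, mod.lam00(), mod.lam01()) +
                     mod.ll_scr_zero(mod.S0, mod.S1, mod.lam00(), mod.lam01());
        double lr = lln - llo +
          R::dnorm(b0n, 0.0, mod.beta_sd, 1) - R::dnorm(save, 0.0, mod.beta_sd, 1);
        if (std::log(R::unif_rand()) < lr) { bacc[2] += 1.0; acc[2] += 1.0; }
        else mod.beta0 = save;
        // beta1 random walk only when in the model
        if (mod.w) {
          btry[4] += 1.0; try_[4] += 1.0;
          double b1n = mod.beta1 + R::norm_rand() * ps_b1;
          double saveb = mod.beta1;
          double llo1 = mod.ll_scr_obs(mod.Et, mod.lam00(), mod.lam01()) +
                        mod.ll_scr_zero(mod.S0, mod.S1, mod.lam00(), mod.lam01());
          mod.beta1 = b1n;
          double lln1 = mod.ll_scr_obs(mod.Et, mod.lam00(), mod.lam01()) +
                        mod.ll_scr_zero(mod.S0, mod.S1, mod.lam00(), mod.lam01());
          double lr1 = lln1 - llo1 +
            R::dnorm(b1n, 0.0, mod.beta_sd, 1) - R::dnorm(saveb, 0.0, mod.beta_sd, 1);
          if (std::log(R::unif_rand()) < lr1) { bacc[4] += 1.0; acc[4] += 1.0; }
          else mod.beta1 = saveb;
        }
      }
      l0 = mod.lam00(); l1 = mod.lam01();
    }

    // ---- reversible jump on the bait covariate ---------------------------
    if (use_rj && mod.use_cov && mod.use_scr) {
      double llo = mod.ll_scr_obs(mod.Et, mod.lam00(), mod.lam01()) +
                   mod.ll_scr_zero(mod.S0, mod.S1, mod.lam00(), mod.lam01());
      if (mod.w == 0) {
        double b1p = R::norm_rand() * mod.rj_sd;
        int savew = mod.w; double saveb = mod.beta1;
        mod.w = 1; mod.beta1 = b1p;
        double lln = mod.ll_scr_obs(mod.Et, mod.lam00(), mod.lam01()) +
                     mod.ll_scr_zero(mod.S0, mod.S1, mod.lam00(), mod.lam01());
        double lr = lln - llo +
          R::dnorm(b1p, 0.0, mod.beta_sd, 1) - R::dnorm(b1p, 0.0, mod.rj_sd, 1) +
          std::log(mod.rj_prior) - std::log1p(-mod.rj_prior);
        if (std::log(R::unif_rand()) >= lr) { mod.w = savew; mod.beta1 = saveb; }
      } else {
        int savew = mod.w; double saveb = mod.beta1;
        mod.w = 0;
        double lln = mod.ll_scr_obs(mod.Et, mod.lam00(), mod.lam01()) +
                     mod.ll_scr_zero(mod.S0, mod.S1, mod.lam00(), mod.lam01());
        double lr = lln - llo -
          (R::dnorm(saveb, 0.0, mod.beta_sd, 1) - R::dnorm(saveb, 0.0, mod.rj_sd, 1)) +
          std::log1p(-mod.rj_prior) - std::log(mod.rj_prior);
        if (std::log(R::unif_rand()) >= lr) { mod.w = savew; }
        else mod.beta1 = 0.0;
      }
      l0 = mod.lam00(); l1 = mod.lam01();
    }

    // ---- lam0_cam --------------------------------------------------------
    if (upd_lam0c && mod.use_occ) {
      btry[3] += 1.0; try_[3] += 1.0;
      double candidate = mod.lam0c * std::exp(R::norm_rand() * ps_l0c);
      if (candidate < mod.lam0c_max) {
        double lr = mod.ll_occ_all(mod.Socc, candidate) -
                    mod.ll_occ_all(mod.Socc, mod.lam0c) +
                    std::log(candidate / mod.lam0c);
        if (std::log(R::unif_rand()) < lr) {
          bacc[3] += 1.0; acc[3] += 1.0;
          mod.lam0c = candidate;
        }
      }
    }

    // ---- psi: conjugate Beta --------------------------------------------
    if (upd_psi)
      mod.psi = R::rbeta(psi_a + mod.Ninc, psi_b + mod.M - mod.Ninc);

    // ---- Robbins-Monro adaptation during burn-in ------------------------
    if (adapt && it < n_burn && ((it + 1) % 50 == 0)) {
      ++batch;
      double step = 1.0 / std::sqrt((double)batch);
      double* scales[5] = {&ps_s, &ps_sig, &ps_l0t, &ps_l0c, &ps_b1};
      for (int b = 0; b < 5; ++b) {
        if (btry[b] > 0) {
          double rate = bacc[b] / btry[b];
          *scales[b] *= std::exp(step * (rate - 0.35));
        }
        bacc[b] = 0.0; btry[b] = 0.0;
      }
    }

    // ---- store -----------------------------------------------------------
    if (it >= n_burn) {
      int r = it - n_burn;
      draws(r, 0) = mod.psi;
      draws(r, 1) = mod.sigma;
      draws(r, 2) = mod.lam00();
      draws(r, 3) = mod.use_occ ? mod.lam0c : NA_REAL;
      draws(r, 4) = mod.use_cov ? mod.beta1 : NA_REAL;
      draws(r, 5) = mod.use_cov ? (double)mod.w : NA_REAL;
      draws(r, 6) = (double)mod.Ninc;
      draws(r, 7) = mod.lam01();
      for (int i = 0; i < n_pin; ++i) {
        draws(r, 8 + i) = mod.sx[i];
        draws(r, 8 + n_pin + i) = mod.sy[i];
      }
    }
  }

  NumericVector accrate(5);
  const char* nm[5] = {"s", "sigma", "lam0_trap", "lam0_cam", "beta1"};
  CharacterVector accnm(5);
  for (int b = 0; b < 5; ++b) {
    accrate[b] = try_[b] > 0 ? acc[b] / try_[b] : NA_REAL;
    accnm[b] = nm[b];
  }
  accrate.names() = accnm;
  return List::create(_["draws"] = draws, _["acceptance"] = accrate,
                      _["prop_final"] = NumericVector::create(
                        _["s"] = ps_s, _["sigma"] = ps_sig,
                        _["lam0_trap"] = ps_l0t, _["lam0_cam"] = ps_l0c,
                        _["beta1"] = ps_b1));
}
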