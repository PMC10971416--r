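// Adaptive Metropolis-within-Gibbs samplers for the hierarchical models.
//
// All models share the same skeleton: scalar random-walk proposals with
// Robbins-Monro step adaptation during warmup (target acceptance 0.44,
// frozen afterwards so the kept draws form a valid Markov chain), full
// conditionals evaluated through cached block log likelihoods, and R's RNG
// throughout so set.seed() on the R side makes runs byte-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double ADAPT_TARGET = 0.44;

static inline double log_sigmoid(double x) {
  return x >= 0.0 ? -log1p(std::exp(-x)) : x - log1p(std::exp(x));
}

static inline double sigmoid(double x) {
  return x >= 0.0 ? 1.0 / (1.0 + std::exp(-x)) : std::exp(x) / (1.0 + std::exp(x));
}

// one adaptation step for a scalar proposal log-step
static inline void adapt_step(double &ls, bool accepted, int t) {
  double gamma = std::pow((double)t + 1.0, -0.6);
  ls += gamma * ((accepted ? 1.0 : 0.0) - ADAPT_TARGET);
  if (ls < -8.0) ls = -8.0;
  if (ls > 4.0) ls = 4.0;
}

static inline double half_normal_lp(double sigma, double scale) {
  // density of sigma > 0; normalising constant dropped
  return -0.5 * sigma * sigma / (scale * scale);
}

static inline double normal_lp(double x, double sd) {
  return -0.5 * x * x / (sd * sd);
}

// ---------------------------------------------------------------------------
// Graded response model block (shared by all samplers that see item data)
// ---------------------------------------------------------------------------

struct GRMData {
  int J = 0;                       // items
  int n_obs = 0;
  std::vector<int> subj, item, y;  // observations
  std::vector<int> K;              // categories per item
  std::vector<int> trait_of_item;  // trait index per item
  std::vector<std::vector<int>> obs_of_item;
  std::vector<std::vector<int>> obs_of_subj;  // only this trait's items matter per subject
};

struct GRMState {
  // unconstrained: la[j] = log discrimination; cut_u[j] = (kappa1, log diffs)
  std::vector<double> la;
  std::vector<std::vector<double>> cut_u;
  std::vector<std::vector<double>> kappa;  // constrained thresholds

  void refresh_kappa(int j) {
    int m = (int)cut_u[j].size();
    kappa[j][0] = cut_u[j][0];
    for (int k = 1; k < m; ++k) kappa[j][k] = kappa[j][k - 1] + std::exp(cut_u[j][k]);
  }

  double prior_lp(int j) const {
    // thresholds ~ N(0, 2) on the constrained scale, plus log-Jacobian of the
    // increasing transform; log discrimination ~ N(0, 1) (lognormal on a).
    double lp = normal_lp(la[j], 1.0);
    int m = (int)cut_u[j].size();
    for (int k = 0; k < m; ++k) lp += normal_lp(kappa[j][k], 2.0);
    for (int k = 1; k < m; ++k) lp += cut_u[j][k];
    return lp;
  }
};

static inline double grm_obs_ll(int y, int K, double a, const std::vector<double> &kappa,
                                double theta) {
  double eta = a * theta;
  double upper = (y == 0) ? 1.0 : sigmoid(eta - kappa[y - 1]);
  double lower = (y == K - 1) ? 0.0 : sigmoid(eta - kappa[y]);
  double p = upper - lower;
  if (p < 1e-300) p = 1e-300;
  return std::log(p);
}

// sum of item log likelihood over a set of observations, given per-subject traits
static double grm_ll_over(const std::vector<int> &idx, const GRMData &gd,
                          const GRMState &gs, const std::vector<double> &theta_flat,
                          int P) {
  double ll = 0.0;
  for (size_t ii = 0; ii < idx.size(); ++ii) {
    int o = idx[ii];
    int j = gd.item[o];
    int t = gd.trait_of_item[j];
    double th = theta_flat[t * P + gd.subj[o]];
    ll += grm_obs_ll(gd.y[o], gd.K[j], std::exp(gs.la[j]), gs.kappa[j], th);
  }
  return ll;
}

static void grm_build(const List &grm, int P, GRMData &gd) {
  IntegerVector s = grm["subj"], it = grm["item"], y = grm["y"];
  IntegerVector K = grm["K"], tr = grm["trait"];
  gd.n_obs = s.size();
  gd.J = K.size();
  gd.subj.assign(s.begin(), s.end());
  gd.item.assign(it.begin(), it.end());
  gd.y.assign(y.begin(), y.end());
  gd.K.assign(K.begin(), K.end());
  gd.trait_of_item.assign(tr.begin(), tr.end());
  gd.obs_of_item.assign(gd.J, {});
  gd.obs_of_subj.assign(P, {});
  for (int o = 0; o < gd.n_obs; ++o) {
    gd.obs_of_item[gd.item[o]].push_back(o);
    gd.obs_of_subj[gd.subj[o]].push_back(o);
  }
}

static void grm_init(const GRMData &gd, GRMState &gs) {
  gs.la.assign(gd.J, 0.0);
  gs.cut_u.assign(gd.J, {});
  gs.kappa.assign(gd.J, {});
  for (int j = 0; j < gd.J; ++j) {
    int m = gd.K[j] - 1;
    gs.cut_u[j].assign(m, 0.0);
    gs.kappa[j].assign(m, 0.0);
    // spread initial thresholds; first at -1, then log-increments
    gs.cut_u[j][0] = -1.0 + 0.1 * norm_rand();
    for (int k = 1; k < m; ++k) gs.cut_u[j][k] = std::log(2.0 / m) + 0.1 * norm_rand();
    gs.la[j] = 0.1 * norm_rand();
    gs.refresh_kappa(j);
  }
}

// update item parameters by scalar random walks; theta_flat holds traits (T x P)
static void grm_update_items(const GRMData &gd, GRMState &gs,
                             std::vector<double> &theta_flat, int P,
                             std::vector<double> &ls, int t, bool adapting) {
  int pos = 0;
  for (int j = 0; j < gd.J; ++j) {
    int m = gd.K[j] - 1;
    // discrimination
    {
      double cur = gs.la[j];
      double ll0 = grm_ll_over(gd.obs_of_item[j], gd, gs, theta_flat, P) + gs.prior_lp(j);
      gs.la[j] = cur + std::exp(ls[pos]) * norm_rand();
      double ll1 = grm_ll_over(gd.obs_of_item[j], gd, gs, theta_flat, P) + gs.prior_lp(j);
      bool acc = std::log(unif_rand()) < ll1 - ll0;
      if (!acc) gs.la[j] = cur;
      if (adapting) adapt_step(ls[pos], acc, t);
      ++pos;
    }
    // thresholds (unconstrained components)
    for (int k = 0; k < m; ++k) {
      double cur = gs.cut_u[j][k];
      double ll0 = grm_ll_over(gd.obs_of_item[j], gd, gs, theta_flat, P) + gs.prior_lp(j);
      gs.cut_u[j][k] = cur + std::exp(ls[pos]) * norm_rand();
      gs.refresh_kappa(j);
      double ll1 = grm_ll_over(gd.obs_of_item[j], gd, gs, theta_flat, P) + gs.prior_lp(j);
      bool acc = std::log(unif_rand()) < ll1 - ll0;
      if (!acc) { gs.cut_u[j][k] = cur; gs.refresh_kappa(j); }
      if (adapting) adapt_step(ls[pos], acc, t);
      ++pos;
    }
  }
}

static int grm_n_scalars(const GRMData &gd) {
  int n = 0;
  for (int j = 0; j < gd.J; ++j) n += gd.K[j];  // 1 discrimination + K-1 cuts
  return n;
}

// ---------------------------------------------------------------------------
// Reward-effort model (also covers reliability fits and the joint model)
// ---------------------------------------------------------------------------

struct REModel {
  int P = 0, n_obs = 0, T = 0, target = -1;
  bool intervention = false, has_grm = false;
  std::vector<int> subj, sess, y;
  std::vector<double> dr, de;
  std::vector<int> act;                       // per subject
  std::vector<std::vector<int>> obs_ps;       // (p * 2 + s) -> obs indices
  // priors
  double mu_scale[2], sd_scale[2], phi_scale, beta_scale;

  // state
  double mu[2][2], lsig[2][2], zr[2], phi[2];
  std::vector<double> bb, bi;       // per trait
  std::vector<double> z;            // p*4 + k*2 + s
  std::vector<double> theta;        // T x P (t * P + p)
  GRMData gd;
  GRMState gs;

  // caches
  std::vector<double> ll_ps;        // p*2 + s

  inline double mean_only(int p, int k, int s) const {
    double m = mu[k][s];
    if (k == target) {
      if (s == 0) {
        for (int t = 0; t < T; ++t) m += bb[t] * theta[t * P + p];
      } else if (act[p]) {
        for (int t = 0; t < T; ++t) m += bi[t] * theta[t * P + p];
      }
    }
    if (s == 1 && intervention && act[p]) m += phi[k];
    return m;
  }

  inline double xval(int p, int k, int s) const {
    double sig = std::exp(lsig[k][s]);
    double R = std::tanh(zr[k]);
    double z0 = z[p * 4 + k * 2 + 0], z1 = z[p * 4 + k * 2 + 1];
    double off = (s == 0) ? sig * z0 : sig * (R * z0 + std::sqrt(1.0 - R * R) * z1);
    return mean_only(p, k, s) + off;
  }

  // Gaussian log density of fixed subject values x for parameter k under the
  // current group state (used by the centered interweaving step)
  double gauss_lp_k(int k, const std::vector<double> &x) const {
    double s1 = std::exp(lsig[k][0]), s2 = std::exp(lsig[k][1]);
    double R = std::tanh(zr[k]);
    double c = std::sqrt(std::max(1.0 - R * R, 1e-12));
    double lp = -P * (lsig[k][0] + lsig[k][1] + std::log(c));
    for (int p = 0; p < P; ++p) {
      double z0 = (x[p * 4 + k * 2 + 0] - mean_only(p, k, 0)) / s1;
      double z1 = ((x[p * 4 + k * 2 + 1] - mean_only(p, k, 1)) / s2 - R * z0) / c;
      lp -= 0.5 * (z0 * z0 + z1 * z1);
    }
    return lp;
  }

  // back-transform offsets so that subject values stay at x
  void z_from_x(const std::vector<double> &x) {
    for (int k = 0; k < 2; ++k) {
      double s1 = std::exp(lsig[k][0]), s2 = std::exp(lsig[k][1]);
      double R = std::tanh(zr[k]);
      double c = std::sqrt(std::max(1.0 - R * R, 1e-12));
      for (int p = 0; p < P; ++p) {
        double z0 = (x[p * 4 + k * 2 + 0] - mean_only(p, k, 0)) / s1;
        double z1 = ((x[p * 4 + k * 2 + 1] - mean_only(p, k, 1)) / s2 - R * z0) / c;
        z[p * 4 + k * 2 + 0] = z0;
        z[p * 4 + k * 2 + 1] = z1;
      }
    }
  }

  double ll_subj_sess(int p, int s) const {
    double xr = xval(p, 0, s), xe = xval(p, 1, s);
    double ll = 0.0;
    const std::vector<int> &idx = obs_ps[p * 2 + s];
    for (size_t ii = 0; ii < idx.size(); ++ii) {
      int o = idx[ii];
      double logit = xr * dr[o] - xe * de[o];
      ll += y[o] ? log_sigmoid(logit) : log_sigmoid(-logit);
    }
    return ll;
  }

  void refresh_all_ll() {
    for (int p = 0; p < P; ++p)
      for (int s = 0; s < 2; ++s) ll_ps[p * 2 + s] = ll_subj_sess(p, s);
  }

  // total cached log likelihood over an affected set: sessions in mask
  // (bit 0 = session 1, bit 1 = session 2), optionally active subjects only
  double cached_ll(int smask, bool active_only) const {
    double ll = 0.0;
    for (int p = 0; p < P; ++p) {
      if (active_only && !act[p]) continue;
      if (smask & 1) ll += ll_ps[p * 2 + 0];
      if (smask & 2) ll += ll_ps[p * 2 + 1];
    }
    return ll;
  }

  double cached_ll_control_s2() const {
    double ll = 0.0;
    for (int p = 0; p < P; ++p) if (!act[p]) ll += ll_ps[p * 2 + 1];
    return ll;
  }

  double fresh_ll_control_s2(std::vector<double> &scratch) const {
    double ll = 0.0;
    for (int p = 0; p < P; ++p)
      if (!act[p]) { scratch[p * 2 + 1] = ll_subj_sess(p, 1); ll += scratch[p * 2 + 1]; }
    return ll;
  }

  void commit_control_s2(const std::vector<double> &scratch) {
    for (int p = 0; p < P; ++p) if (!act[p]) ll_ps[p * 2 + 1] = scratch[p * 2 + 1];
  }

  double fresh_ll(int smask, bool active_only, std::vector<double> &scratch) const {
    double ll = 0.0;
    for (int p = 0; p < P; ++p) {
      if (active_only && !act[p]) continue;
      if (smask & 1) { scratch[p * 2 + 0] = ll_subj_sess(p, 0); ll += scratch[p * 2 + 0]; }
      if (smask & 2) { scratch[p * 2 + 1] = ll_subj_sess(p, 1); ll += scratch[p * 2 + 1]; }
    }
    return ll;
  }

  void commit(int smask, bool active_only, const std::vector<double> &scratch) {
    for (int p = 0; p < P; ++p) {
      if (active_only && !act[p]) continue;
      if (smask & 1) ll_ps[p * 2 + 0] = scratch[p * 2 + 0];
      if (smask & 2) ll_ps[p * 2 + 1] = scratch[p * 2 + 1];
    }
  }
};

// generic scalar group update over the task likelihood
static void re_group_update(REModel &M, double &par, int smask,
                            bool active_only, double &ls, int t, bool adapting,
                            std::vector<double> &scratch, double (*prior_fn)(double, double),
                            double prior_scale) {
  double cur = par;
  double ll0 = M.cached_ll(smask, active_only) + prior_fn(cur, prior_scale);
  par = cur + std::exp(ls) * norm_rand();
  double ll1 = M.fresh_ll(smask, active_only, scratch) + prior_fn(par, prior_scale);
  bool acc = std::log(unif_rand()) < ll1 - ll0;
  if (acc) M.commit(smask, active_only, scratch);
  else par = cur;
  if (adapting) adapt_step(ls, acc, t);
}

static double prior_normal(double x, double sd) { return normal_lp(x, sd); }
static double prior_logsigma(double ls_, double scale) {
  // half-normal on sigma = exp(ls) with log Jacobian
  double sig = std::exp(ls_);
  return half_normal_lp(sig, scale) + ls_;
}
static double prior_atanh_corr(double zr, double) {
  // uniform correlation on [-1, 1]; Jacobian of tanh
  double R = std::tanh(zr);
  return log1p(-R * R);
}

// [[Rcpp::export]]
NumericMatrix sample_re_cpp(IntegerVector subj, IntegerVector sess,
                            NumericVector dr, NumericVector de, IntegerVector y,
                            IntegerVector active, bool intervention,
                            List grm, int target_param, int n_traits,
                            NumericVector prior, int warmup, int n_keep, int thin,
                            NumericVector theta_fixed) {
  REModel M;
  M.P = active.size();
  M.n_obs = subj.size();
  M.subj.assign(subj.begin(), subj.end());
  M.sess.assign(sess.begin(), sess.end());
  M.dr.assign(dr.begin(), dr.end());
  M.de.assign(de.begin(), de.end());
  M.y.assign(y.begin(), y.end());
  M.act.assign(active.begin(), active.end());
  M.intervention = intervention;
  M.target = target_param;
  M.T = n_traits;
  M.has_grm = grm.size() > 0;
  M.mu_scale[0] = prior[0]; M.mu_scale[1] = prior[1];
  M.sd_scale[0] = prior[2]; M.sd_scale[1] = prior[3];
  M.phi_scale = prior[4]; M.beta_scale = prior[5];

  M.obs_ps.assign(M.P * 2, {});
  for (int o = 0; o < M.n_obs; ++o) M.obs_ps[M.subj[o] * 2 + M.sess[o]].push_back(o);

  // init
  for (int k = 0; k < 2; ++k)
    for (int s = 0; s < 2; ++s) {
      M.mu[k][s] = 0.2 * norm_rand();
      M.lsig[k][s] = -0.5 + 0.2 * norm_rand();
    }
  M.zr[0] = 0.2 * norm_rand(); M.zr[1] = 0.2 * norm_rand();
  M.phi[0] = M.phi[1] = 0.0;
  if (intervention) { M.phi[0] = 0.2 * norm_rand(); M.phi[1] = 0.2 * norm_rand(); }
  M.bb.assign(std::max(M.T, 0), 0.0);
  M.bi.assign(std::max(M.T, 0), 0.0);
  M.z.assign(M.P * 4, 0.0);
  for (int i = 0; i < M.P * 4; ++i) M.z[i] = 0.3 * norm_rand();
  M.theta.assign(std::max(M.T, 1) * M.P, 0.0);
  bool theta_is_fixed = theta_fixed.size() == M.T * M.P && M.T > 0;
  if (theta_is_fixed)
    for (int i = 0; i < M.T * M.P; ++i) M.theta[i] = theta_fixed[i];
  if (M.has_grm) {
    for (int i = 0; i < M.T * M.P; ++i) M.theta[i] = 0.3 * norm_rand();
    grm_build(grm, M.P, M.gd);
    grm_init(M.gd, M.gs);
  }
  M.ll_ps.assign(M.P * 2, 0.0);
  M.refresh_all_ll();

  // step sizes
  int n_group = 8 + 2 + (intervention ? 2 : 0) + (M.target >= 0 ? 2 * M.T : 0);
  std::vector<double> ls_group(n_group, std::log(0.2));
  std::vector<double> ls_z(M.P * 4, std::log(0.5));
  std::vector<double> ls_theta(M.has_grm ? M.T * M.P : 0, std::log(0.5));
  std::vector<double> ls_items(M.has_grm ? grm_n_scalars(M.gd) : 0, std::log(0.3));
  std::vector<double> ls_asis(n_group, std::log(0.2));
  std::vector<double> ls_decouple(2, std::log(0.2));
  std::vector<double> ls_soft(M.P * 2, std::log(0.5));
  std::vector<double> scratch(M.P * 2, 0.0);
  double dr_bar = 0.0, de_bar = 0.0;
  if (M.n_obs > 0) {
    for (int o = 0; o < M.n_obs; ++o) { dr_bar += M.dr[o]; de_bar += M.de[o]; }
    dr_bar /= M.n_obs; de_bar /= M.n_obs;
  } else { dr_bar = 1.0; de_bar = 1.0; }

  // output layout
  int n_item_cols = 0;
  if (M.has_grm) n_item_cols = grm_n_scalars(M.gd);
  int ncol = 10 + (intervention ? 2 : 0) + (M.target >= 0 ? 2 * M.T : 0) +
             n_item_cols + (M.has_grm ? M.T * M.P : 0) + M.P * 4;
  NumericMatrix out(n_keep, ncol);

  int total_iter = warmup + n_keep * thin;
  int kept = 0;
  for (int t = 0; t < total_iter; ++t) {
    bool adapting = t < warmup;
    int g = 0;
    // group means: mu[k][s] affects session s only
    for (int k = 0; k < 2; ++k)
      for (int s = 0; s < 2; ++s) {
        re_group_update(M, M.mu[k][s], s == 0 ? 1 : 2, false, ls_group[g], t,
                        adapting, scratch, prior_normal, M.mu_scale[k]);
        ++g;
      }
    // sds
    for (int k = 0; k < 2; ++k)
      for (int s = 0; s < 2; ++s) {
        re_group_update(M, M.lsig[k][s], s == 0 ? 1 : 2, false, ls_group[g], t,
                        adapting, scratch, prior_logsigma, M.sd_scale[k]);
        ++g;
      }
    // cross-session correlations affect session-2 values only
    for (int k = 0; k < 2; ++k) {
      re_group_update(M, M.zr[k], 2, false, ls_group[g], t, adapting, scratch,
                      prior_atanh_corr, 0.0);
      ++g;
    }
    if (intervention)
      for (int k = 0; k < 2; ++k) {
        re_group_update(M, M.phi[k], 2, true, ls_group[g], t, adapting, scratch,
                        prior_normal, M.phi_scale);
        ++g;
        // arm-decoupling move: shift mu[k][1] and phi[k] oppositely, which
        // moves the control-arm mean while leaving the active arm fixed;
        // breaks the strong posterior coupling of the two parameters
        {
          double d = std::exp(ls_decouple[k]) * norm_rand();
          double mu0 = M.mu[k][1], phi0 = M.phi[k];
          double lp0 = M.cached_ll_control_s2() + normal_lp(mu0, M.mu_scale[k]) +
                       normal_lp(phi0, M.phi_scale);
          M.mu[k][1] = mu0 + d;
          M.phi[k] = phi0 - d;
          double lp1 = M.fresh_ll_control_s2(scratch) +
                       normal_lp(M.mu[k][1], M.mu_scale[k]) +
                       normal_lp(M.phi[k], M.phi_scale);
          bool acc = std::log(unif_rand()) < lp1 - lp0;
          if (acc) M.commit_control_s2(scratch);
          else { M.mu[k][1] = mu0; M.phi[k] = phi0; }
          if (adapting) adapt_step(ls_decouple[k], acc, t);
        }
      }
    if (M.target >= 0)
      for (int tr = 0; tr < M.T; ++tr) {
        re_group_update(M, M.bb[tr], 1, false, ls_group[g], t, adapting, scratch,
                        prior_normal, M.beta_scale);
        ++g;
        re_group_update(M, M.bi[tr], 2, true, ls_group[g], t, adapting, scratch,
                        prior_normal, M.beta_scale);
        ++g;
      }

    // subject offsets
    for (int p = 0; p < M.P; ++p)
      for (int k = 0; k < 2; ++k)
        for (int s = 0; s < 2; ++s) {
          int zi = p * 4 + k * 2 + s;
          double cur = M.z[zi];
          double ll0 = normal_lp(cur, 1.0);
          double ll1n;
          if (s == 0) ll0 += M.ll_ps[p * 2 + 0] + M.ll_ps[p * 2 + 1];
          else ll0 += M.ll_ps[p * 2 + 1];
          M.z[zi] = cur + std::exp(ls_z[zi]) * norm_rand();
          double a0 = 0, a1 = 0;
          if (s == 0) { a0 = M.ll_subj_sess(p, 0); a1 = M.ll_subj_sess(p, 1); ll1n = a0 + a1; }
          else { a1 = M.ll_subj_sess(p, 1); ll1n = a1; }
          ll1n += normal_lp(M.z[zi], 1.0);
          bool acc = std::log(unif_rand()) < ll1n - ll0;
          if (acc) {
            if (s == 0) { M.ll_ps[p * 2 + 0] = a0; M.ll_ps[p * 2 + 1] = a1; }
            else M.ll_ps[p * 2 + 1] = a1;
          } else M.z[zi] = cur;
          if (adapting) adapt_step(ls_z[zi], acc, t);
        }

    // soft-mode moves: the offer structure makes each subject's (rewSens,
    // effSens) posterior a narrow ridge along (mean_dr, mean_de)-conjugate
    // directions; translate both offsets jointly along that ridge
    for (int p = 0; p < M.P; ++p) {
      // session-1 components (propagate to session 2 through R)
      {
        double d = std::exp(ls_soft[p * 2 + 0]) * norm_rand();
        int zr_i = p * 4 + 0 * 2 + 0, ze_i = p * 4 + 1 * 2 + 0;
        double zr0 = M.z[zr_i], ze0 = M.z[ze_i];
        double sr = std::exp(M.lsig[0][0]), se = std::exp(M.lsig[1][0]);
        double ll0 = normal_lp(zr0, 1.0) + normal_lp(ze0, 1.0) +
                     M.ll_ps[p * 2 + 0] + M.ll_ps[p * 2 + 1];
        M.z[zr_i] = zr0 + d * de_bar / sr;
        M.z[ze_i] = ze0 + d * dr_bar / se;
        double a0 = M.ll_subj_sess(p, 0), a1 = M.ll_subj_sess(p, 1);
        double ll1 = normal_lp(M.z[zr_i], 1.0) + normal_lp(M.z[ze_i], 1.0) + a0 + a1;
        bool acc = std::log(unif_rand()) < ll1 - ll0;
        if (acc) { M.ll_ps[p * 2 + 0] = a0; M.ll_ps[p * 2 + 1] = a1; }
        else { M.z[zr_i] = zr0; M.z[ze_i] = ze0; }
        if (adapting) adapt_step(ls_soft[p * 2 + 0], acc, t);
      }
      // session-2 specific components
      {
        double d = std::exp(ls_soft[p * 2 + 1]) * norm_rand();
        int zr_i = p * 4 + 0 * 2 + 1, ze_i = p * 4 + 1 * 2 + 1;
        double zr0 = M.z[zr_i], ze0 = M.z[ze_i];
        double Rr = std::tanh(M.zr[0]), Re = std::tanh(M.zr[1]);
        double cr = std::sqrt(std::max(1.0 - Rr * Rr, 1e-12));
        double ce = std::sqrt(std::max(1.0 - Re * Re, 1e-12));
        double sr = std::exp(M.lsig[0][1]) * cr, se = std::exp(M.lsig[1][1]) * ce;
        double ll0 = normal_lp(zr0, 1.0) + normal_lp(ze0, 1.0) + M.ll_ps[p * 2 + 1];
        M.z[zr_i] = zr0 + d * de_bar / sr;
        M.z[ze_i] = ze0 + d * dr_bar / se;
        double a1 = M.ll_subj_sess(p, 1);
        double ll1 = normal_lp(M.z[zr_i], 1.0) + normal_lp(M.z[ze_i], 1.0) + a1;
        bool acc = std::log(unif_rand()) < ll1 - ll0;
        if (acc) M.ll_ps[p * 2 + 1] = a1;
        else { M.z[zr_i] = zr0; M.z[ze_i] = ze0; }
        if (adapting) adapt_step(ls_soft[p * 2 + 1], acc, t);
      }
    }

    // joint part: traits and item parameters
    if (M.has_grm) {
      for (int tr = 0; tr < M.T; ++tr)
        for (int p = 0; p < M.P; ++p) {
          int ti = tr * M.P + p;
          double cur = M.theta[ti];
          bool affects_task = M.target >= 0;
          double ll0 = normal_lp(cur, 1.0) +
                       grm_ll_over(M.gd.obs_of_subj[p], M.gd, M.gs, M.theta, M.P);
          if (affects_task) ll0 += M.ll_ps[p * 2 + 0] + M.ll_ps[p * 2 + 1];
          M.theta[ti] = cur + std::exp(ls_theta[ti]) * norm_rand();
          double a0 = 0, a1 = 0;
          double ll1 = normal_lp(M.theta[ti], 1.0) +
                       grm_ll_over(M.gd.obs_of_subj[p], M.gd, M.gs, M.theta, M.P);
          if (affects_task) {
            a0 = M.ll_subj_sess(p, 0); a1 = M.ll_subj_sess(p, 1);
            ll1 += a0 + a1;
          }
          bool acc = std::log(unif_rand()) < ll1 - ll0;
          if (acc) {
            if (affects_task) { M.ll_ps[p * 2 + 0] = a0; M.ll_ps[p * 2 + 1] = a1; }
          } else M.theta[ti] = cur;
          if (adapting) adapt_step(ls_theta[ti], acc, t);
        }
      grm_update_items(M.gd, M.gs, M.theta, M.P, ls_items, t, adapting);
    }

    // centered interweaving: with subject values held fixed, group-level
    // parameters see a cheap Gaussian target; this breaks the strong
    // mean/offset and scale/offset coupling of the non-centered form
    {
      std::vector<double> xfix(M.P * 4);
      for (int p = 0; p < M.P; ++p)
        for (int k = 0; k < 2; ++k)
          for (int s = 0; s < 2; ++s) xfix[p * 4 + k * 2 + s] = M.xval(p, k, s);
      int a = 0;
      for (int k = 0; k < 2; ++k) {
        struct Slot { double *par; double (*pf)(double, double); double sc; };
        std::vector<Slot> slots = {
          {&M.mu[k][0], prior_normal, M.mu_scale[k]},
          {&M.mu[k][1], prior_normal, M.mu_scale[k]},
          {&M.lsig[k][0], prior_logsigma, M.sd_scale[k]},
          {&M.lsig[k][1], prior_logsigma, M.sd_scale[k]},
          {&M.zr[k], prior_atanh_corr, 0.0}};
        if (intervention) slots.push_back({&M.phi[k], prior_normal, M.phi_scale});
        if (k == M.target)
          for (int tr = 0; tr < M.T; ++tr) {
            slots.push_back({&M.bb[tr], prior_normal, M.beta_scale});
            slots.push_back({&M.bi[tr], prior_normal, M.beta_scale});
          }
        for (size_t si = 0; si < slots.size(); ++si) {
          double cur = *slots[si].par;
          double lp0 = M.gauss_lp_k(k, xfix) + slots[si].pf(cur, slots[si].sc);
          *slots[si].par = cur + std::exp(ls_asis[a]) * norm_rand();
          double lp1 = M.gauss_lp_k(k, xfix) + slots[si].pf(*slots[si].par, slots[si].sc);
          bool acc = std::log(unif_rand()) < lp1 - lp0;
          if (!acc) *slots[si].par = cur;
          if (adapting) adapt_step(ls_asis[a], acc, t);
          ++a;
        }
      }
      M.z_from_x(xfix);
    }

    if (!adapting && ((t - warmup + 1) % thin == 0)) {
      int c = 0;
      for (int k = 0; k < 2; ++k)
        for (int s = 0; s < 2; ++s) out(kept, c++) = M.mu[k][s];
      for (int k = 0; k < 2; ++k)
        for (int s = 0; s < 2; ++s) out(kept, c++) = std::exp(M.lsig[k][s]);
      for (int k = 0; k < 2; ++k) out(kept, c++) = std::tanh(M.zr[k]);
      if (intervention)
        for (int k = 0; k < 2; ++k) out(kept, c++) = M.phi[k];
      if (M.target >= 0)
        for (int tr = 0; tr < M.T; ++tr) { out(kept, c++) = M.bb[tr]; out(kept, c++) = M.bi[tr]; }
      if (M.has_grm) {
        for (int j = 0; j < M.gd.J; ++j) {
          out(kept, c++) = std::exp(M.gs.la[j]);
          for (int k = 0; k < M.gd.K[j] - 1; ++k) out(kept, c++) = M.gs.kappa[j][k];
        }
        for (int tr = 0; tr < M.T; ++tr)
          for (int p = 0; p < M.P; ++p) out(kept, c++) = M.theta[tr * M.P + p];
      }
      for (int p = 0; p < M.P; ++p)
        for (int k = 0; k < 2; ++k)
          for (int s = 0; s < 2; ++s) out(kept, c++) = M.xval(p, k, s);
      ++kept;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Attribution model: two binary codes per trial, 4-dimensional MVN per valence
// ---------------------------------------------------------------------------

// build lower Cholesky of a 4x4 correlation matrix from canonical partial
// correlations (atanh scale), vine ordering; LKJ(1) corresponds to
// cpc ~ 2*Beta(b,b)-1 with b = 1 + (K - 1 - lag)/2
static void cpc_to_chol(const double *cz, double L[4][4]) {
  double zc[4][4] = {{0}};
  int pos = 0;
  for (int i = 0; i < 4; ++i)
    for (int j = i + 1; j < 4; ++j) zc[i][j] = std::tanh(cz[pos++]);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) L[i][j] = 0.0;
  L[0][0] = 1.0;
  for (int i = 1; i < 4; ++i) {
    double sum = 0.0;
    for (int j = 0; j < i; ++j) {
      L[i][j] = zc[j][i] * std::sqrt(1.0 - sum);
      sum += L[i][j] * L[i][j];
    }
    L[i][i] = std::sqrt(1.0 - sum);
  }
}

static double cpc_prior_lp(const double *cz) {
  // LKJ(1) through the vine: (b-1)*log(1-r^2) plus tanh Jacobian log(1-r^2)
  static const double b_of_lag[4] = {0.0, 2.0, 1.5, 1.0};
  double lp = 0.0;
  int pos = 0;
  for (int i = 0; i < 4; ++i)
    for (int j = i + 1; j < 4; ++j) {
      double r = std::tanh(cz[pos++]);
      lp += b_of_lag[j - i] * log1p(-r * r);
    }
  return lp;
}

struct AttModel {
  int P = 0, T = 0;
  bool intervention = false, has_grm = false;
  int target_v = -1, target_d = -1;          // joint moderation target cell
  std::vector<int> act;
  // counts: idx = ((p * 2 + v) * 4 + c), c = 2*s + d
  std::vector<int> n_cell, k_cell;
  double mu_scale, sd_scale, phi_scale, beta_scale;

  double mu[2][4], lsig[2][4], cz[2][6], phi[2][2];
  double Lr[2][4][4];
  std::vector<double> z;       // ((p*2+v)*4+i)
  std::vector<double> bb, bi;  // per trait
  std::vector<double> theta;   // T x P
  GRMData gd;
  GRMState gs;
  std::vector<double> ll_cell; // per (p, v, c)

  void refresh_L(int v) { cpc_to_chol(cz[v], Lr[v]); }

  inline double mean_cell(int p, int v, int c) const {
    int d = c % 2, s = c / 2;
    double th = mu[v][c];
    if (s == 1 && intervention && act[p]) th += phi[v][d];
    if (v == target_v && d == target_d) {
      if (s == 0) for (int t = 0; t < T; ++t) th += bb[t] * theta[t * P + p];
      else if (act[p]) for (int t = 0; t < T; ++t) th += bi[t] * theta[t * P + p];
    }
    return th;
  }

  inline double cell_lin(int p, int v, int c) const {
    double w = 0.0;
    for (int j = 0; j <= c; ++j) w += Lr[v][c][j] * z[(p * 2 + v) * 4 + j];
    return mean_cell(p, v, c) + std::exp(lsig[v][c]) * w;
  }

  // Gaussian log density of fixed cell values under the current group state
  // for one valence (centered interweaving step)
  double gauss_lp_v(int v, const std::vector<double> &xfix) const {
    double ld = 0.0;
    for (int i = 0; i < 4; ++i)
      ld += lsig[v][i] + std::log(std::max(Lr[v][i][i], 1e-12));
    double lp = -P * ld;
    for (int p = 0; p < P; ++p) {
      double zz[4];
      for (int i = 0; i < 4; ++i) {
        double r = (xfix[(p * 2 + v) * 4 + i] - mean_cell(p, v, i)) /
                   std::exp(lsig[v][i]);
        for (int j = 0; j < i; ++j) r -= Lr[v][i][j] * zz[j];
        zz[i] = r / std::max(Lr[v][i][i], 1e-12);
        lp -= 0.5 * zz[i] * zz[i];
      }
    }
    return lp;
  }

  void z_from_x_v(int v, const std::vector<double> &xfix) {
    for (int p = 0; p < P; ++p) {
      double zz[4];
      for (int i = 0; i < 4; ++i) {
        double r = (xfix[(p * 2 + v) * 4 + i] - mean_cell(p, v, i)) /
                   std::exp(lsig[v][i]);
        for (int j = 0; j < i; ++j) r -= Lr[v][i][j] * zz[j];
        zz[i] = r / std::max(Lr[v][i][i], 1e-12);
        z[(p * 2 + v) * 4 + i] = zz[i];
      }
    }
  }

  inline double ll_one(int p, int v, int c) const {
    int i = (p * 2 + v) * 4 + c;
    if (n_cell[i] == 0) return 0.0;
    double th = cell_lin(p, v, c);
    return k_cell[i] * log_sigmoid(th) + (n_cell[i] - k_cell[i]) * log_sigmoid(-th);
  }

  void refresh_all_ll() {
    for (int p = 0; p < P; ++p)
      for (int v = 0; v < 2; ++v)
        for (int c = 0; c < 4; ++c) ll_cell[(p * 2 + v) * 4 + c] = ll_one(p, v, c);
  }
};

// update one group scalar of the attribution model; affected set: valence v,
// cells with bit set in cmask, optionally active subjects only
static void att_group_update(AttModel &M, double &par, int v, int cmask,
                             bool active_only, double &ls, int t, bool adapting,
                             double (*prior_fn)(double, double), double prior_scale,
                             bool refresh_L) {
  double cur = par;
  double lp0 = prior_fn(cur, prior_scale);
  double ll0 = 0.0;
  for (int p = 0; p < M.P; ++p) {
    if (active_only && !M.act[p]) continue;
    for (int c = 0; c < 4; ++c)
      if (cmask & (1 << c)) ll0 += M.ll_cell[(p * 2 + v) * 4 + c];
  }
  par = cur + std::exp(ls) * norm_rand();
  if (refresh_L) M.refresh_L(v);
  double lp1 = prior_fn(par, prior_scale);
  double ll1 = 0.0;
  std::vector<double> scratch;
  scratch.reserve(64);
  std::vector<int> which;
  which.reserve(64);
  for (int p = 0; p < M.P; ++p) {
    if (active_only && !M.act[p]) continue;
    for (int c = 0; c < 4; ++c)
      if (cmask & (1 << c)) {
        double l = M.ll_one(p, v, c);
        scratch.push_back(l);
        which.push_back((p * 2 + v) * 4 + c);
        ll1 += l;
      }
  }
  bool acc = std::log(unif_rand()) < (ll1 + lp1) - (ll0 + lp0);
  if (acc) {
    for (size_t i = 0; i < which.size(); ++i) M.ll_cell[which[i]] = scratch[i];
  } else {
    par = cur;
    if (refresh_L) M.refresh_L(v);
  }
  if (adapting) adapt_step(ls, acc, t);
}

// [[Rcpp::export]]
NumericMatrix sample_att_cpp(IntegerVector n_cell, IntegerVector k_cell,
                             IntegerVector active, bool intervention,
                             List grm, int target_v, int target_d, int n_traits,
                             NumericVector prior, int warmup, int n_keep, int thin) {
  AttModel M;
  M.P = active.size();
  M.act.assign(active.begin(), active.end());
  M.n_cell.assign(n_cell.begin(), n_cell.end());
  M.k_cell.assign(k_cell.begin(), k_cell.end());
  M.intervention = intervention;
  M.T = n_traits;
  M.target_v = target_v;
  M.target_d = target_d;
  M.has_grm = grm.size() > 0;
  M.mu_scale = prior[0]; M.sd_scale = prior[1];
  M.phi_scale = prior[2]; M.beta_scale = prior[3];

  for (int v = 0; v < 2; ++v) {
    for (int c = 0; c < 4; ++c) {
      M.mu[v][c] = 0.2 * norm_rand();
      M.lsig[v][c] = -0.5 + 0.2 * norm_rand();
    }
    for (int i = 0; i < 6; ++i) M.cz[v][i] = 0.1 * norm_rand();
    M.phi[v][0] = M.phi[v][1] = 0.0;
    if (intervention) { M.phi[v][0] = 0.2 * norm_rand(); M.phi[v][1] = 0.2 * norm_rand(); }
    M.refresh_L(v);
  }
  M.z.assign(M.P * 8, 0.0);
  for (int i = 0; i < M.P * 8; ++i) M.z[i] = 0.3 * norm_rand();
  M.bb.assign(std::max(M.T, 0), 0.0);
  M.bi.assign(std::max(M.T, 0), 0.0);
  M.theta.assign(std::max(M.T, 1) * M.P, 0.0);
  if (M.has_grm) {
    for (int i = 0; i < M.T * M.P; ++i) M.theta[i] = 0.3 * norm_rand();
    grm_build(grm, M.P, M.gd);
    grm_init(M.gd, M.gs);
  }
  M.ll_cell.assign(M.P * 8, 0.0);
  M.refresh_all_ll();

  int n_group_v = 4 + 4 + 6 + (intervention ? 2 : 0);
  int n_group = 2 * n_group_v + (M.target_v >= 0 ? 2 * M.T : 0);
  std::vector<double> ls_group(n_group, std::log(0.2));
  std::vector<double> ls_z(M.P * 8, std::log(0.5));
  std::vector<double> ls_theta(M.has_grm ? M.T * M.P : 0, std::log(0.5));
  std::vector<double> ls_items(M.has_grm ? grm_n_scalars(M.gd) : 0, std::log(0.3));
  std::vector<double> ls_asis(n_group, std::log(0.2));
  std::vector<double> ls_decouple(4, std::log(0.2));

  int n_item_cols = M.has_grm ? grm_n_scalars(M.gd) : 0;
  // per valence: 4 mu, 4 sigma, 6 correlations, (2 phi); then betas, items,
  // traits, subject linear predictors (P x 8)
  int ncol = 2 * (14 + (intervention ? 2 : 0)) + (M.target_v >= 0 ? 2 * M.T : 0) +
             n_item_cols + (M.has_grm ? M.T * M.P : 0) + M.P * 8;
  NumericMatrix out(n_keep, ncol);

  int total_iter = warmup + n_keep * thin;
  int kept = 0;
  for (int t = 0; t < total_iter; ++t) {
    bool adapting = t < warmup;
    int g = 0;
    for (int v = 0; v < 2; ++v) {
      for (int c = 0; c < 4; ++c)
        att_group_update(M, M.mu[v][c], v, 1 << c, false, ls_group[g++], t, adapting,
                         prior_normal, M.mu_scale, false);
      for (int c = 0; c < 4; ++c)
        att_group_update(M, M.lsig[v][c], v, 1 << c, false, ls_group[g++], t, adapting,
                         prior_logsigma, M.sd_scale, false);
      for (int i = 0; i < 6; ++i) {
        // joint prior over the 6 CPCs evaluated around the proposal
        double lp0 = cpc_prior_lp(M.cz[v]);
        double cur = M.cz[v][i];
        double ll0 = 0.0;
        for (int p = 0; p < M.P; ++p)
          for (int c = 0; c < 4; ++c) ll0 += M.ll_cell[(p * 2 + v) * 4 + c];
        M.cz[v][i] = cur + std::exp(ls_group[g]) * norm_rand();
        M.refresh_L(v);
        double lp1 = cpc_prior_lp(M.cz[v]);
        double ll1 = 0.0;
        std::vector<double> scratch(M.P * 4);
        for (int p = 0; p < M.P; ++p)
          for (int c = 0; c < 4; ++c) {
            scratch[p * 4 + c] = M.ll_one(p, v, c);
            ll1 += scratch[p * 4 + c];
          }
        bool acc = std::log(unif_rand()) < (ll1 + lp1) - (ll0 + lp0);
        if (acc) {
          for (int p = 0; p < M.P; ++p)
            for (int c = 0; c < 4; ++c) M.ll_cell[(p * 2 + v) * 4 + c] = scratch[p * 4 + c];
        } else {
          M.cz[v][i] = cur;
          M.refresh_L(v);
        }
        if (adapting) adapt_step(ls_group[g], acc, t);
        ++g;
      }
      if (intervention)
        for (int d = 0; d < 2; ++d) {
          att_group_update(M, M.phi[v][d], v, 1 << (2 + d), true, ls_group[g++], t,
                           adapting, prior_normal, M.phi_scale, false);
          // arm-decoupling move (see reward-effort sampler)
          int cc = 2 + d;
          double dlt = std::exp(ls_decouple[v * 2 + d]) * norm_rand();
          double mu0 = M.mu[v][cc], phi0 = M.phi[v][d];
          double lp0 = normal_lp(mu0, M.mu_scale) + normal_lp(phi0, M.phi_scale);
          double ll0 = 0.0;
          for (int p = 0; p < M.P; ++p)
            if (!M.act[p]) ll0 += M.ll_cell[(p * 2 + v) * 4 + cc];
          M.mu[v][cc] = mu0 + dlt;
          M.phi[v][d] = phi0 - dlt;
          double lp1 = normal_lp(M.mu[v][cc], M.mu_scale) +
                       normal_lp(M.phi[v][d], M.phi_scale);
          double ll1 = 0.0;
          std::vector<double> sc(M.P, 0.0);
          for (int p = 0; p < M.P; ++p)
            if (!M.act[p]) { sc[p] = M.ll_one(p, v, cc); ll1 += sc[p]; }
          bool acc = std::log(unif_rand()) < (ll1 + lp1) - (ll0 + lp0);
          if (acc) {
            for (int p = 0; p < M.P; ++p)
              if (!M.act[p]) M.ll_cell[(p * 2 + v) * 4 + cc] = sc[p];
          } else { M.mu[v][cc] = mu0; M.phi[v][d] = phi0; }
          if (adapting) adapt_step(ls_decouple[v * 2 + d], acc, t);
        }
    }
    if (M.target_v >= 0)
      for (int tr = 0; tr < M.T; ++tr) {
        att_group_update(M, M.bb[tr], M.target_v, 1 << (0 + M.target_d), false,
                         ls_group[g++], t, adapting, prior_normal, M.beta_scale, false);
        att_group_update(M, M.bi[tr], M.target_v, 1 << (2 + M.target_d), true,
                         ls_group[g++], t, adapting, prior_normal, M.beta_scale, false);
      }

    // subject offsets: z[p][v][i] affects cells i..3 of valence v
    for (int p = 0; p < M.P; ++p)
      for (int v = 0; v < 2; ++v)
        for (int i = 0; i < 4; ++i) {
          int zi = (p * 2 + v) * 4 + i;
          double cur = M.z[zi];
          double ll0 = normal_lp(cur, 1.0);
          for (int c = i; c < 4; ++c) ll0 += M.ll_cell[(p * 2 + v) * 4 + c];
          M.z[zi] = cur + std::exp(ls_z[zi]) * norm_rand();
          double ll1 = normal_lp(M.z[zi], 1.0);
          double scratch[4];
          for (int c = i; c < 4; ++c) { scratch[c] = M.ll_one(p, v, c); ll1 += scratch[c]; }
          bool acc = std::log(unif_rand()) < ll1 - ll0;
          if (acc) for (int c = i; c < 4; ++c) M.ll_cell[(p * 2 + v) * 4 + c] = scratch[c];
          else M.z[zi] = cur;
          if (adapting) adapt_step(ls_z[zi], acc, t);
        }

    if (M.has_grm) {
      for (int tr = 0; tr < M.T; ++tr)
        for (int p = 0; p < M.P; ++p) {
          int ti = tr * M.P + p;
          double cur = M.theta[ti];
          bool affects_task = M.target_v >= 0;
          int c1 = M.target_d, c2 = 2 + M.target_d;
          double ll0 = normal_lp(cur, 1.0) +
                       grm_ll_over(M.gd.obs_of_subj[p], M.gd, M.gs, M.theta, M.P);
          if (affects_task)
            ll0 += M.ll_cell[(p * 2 + M.target_v) * 4 + c1] +
                   M.ll_cell[(p * 2 + M.target_v) * 4 + c2];
          M.theta[ti] = cur + std::exp(ls_theta[ti]) * norm_rand();
          double ll1 = normal_lp(M.theta[ti], 1.0) +
                       grm_ll_over(M.gd.obs_of_subj[p], M.gd, M.gs, M.theta, M.P);
          double s1 = 0, s2 = 0;
          if (affects_task) {
            s1 = M.ll_one(p, M.target_v, c1);
            s2 = M.ll_one(p, M.target_v, c2);
            ll1 += s1 + s2;
          }
          bool acc = std::log(unif_rand()) < ll1 - ll0;
          if (acc) {
            if (affects_task) {
              M.ll_cell[(p * 2 + M.target_v) * 4 + c1] = s1;
              M.ll_cell[(p * 2 + M.target_v) * 4 + c2] = s2;
            }
          } else M.theta[ti] = cur;
          if (adapting) adapt_step(ls_theta[ti], acc, t);
        }
      grm_update_items(M.gd, M.gs, M.theta, M.P, ls_items, t, adapting);
    }

    // centered interweaving on the fixed subject cell values
    {
      std::vector<double> xfix(M.P * 8);
      for (int p = 0; p < M.P; ++p)
        for (int v = 0; v < 2; ++v)
          for (int cc = 0; cc < 4; ++cc)
            xfix[(p * 2 + v) * 4 + cc] = M.cell_lin(p, v, cc);
      int a = 0;
      for (int v = 0; v < 2; ++v) {
        // means, log-sds, intervention effects, moderation weights
        std::vector<double *> pars;
        std::vector<double (*)(double, double)> pfs;
        std::vector<double> scs;
        for (int i = 0; i < 4; ++i) {
          pars.push_back(&M.mu[v][i]); pfs.push_back(prior_normal); scs.push_back(M.mu_scale);
        }
        for (int i = 0; i < 4; ++i) {
          pars.push_back(&M.lsig[v][i]); pfs.push_back(prior_logsigma); scs.push_back(M.sd_scale);
        }
        if (intervention)
          for (int d = 0; d < 2; ++d) {
            pars.push_back(&M.phi[v][d]); pfs.push_back(prior_normal); scs.push_back(M.phi_scale);
          }
        if (v == M.target_v)
          for (int tr = 0; tr < M.T; ++tr) {
            pars.push_back(&M.bb[tr]); pfs.push_back(prior_normal); scs.push_back(M.beta_scale);
            pars.push_back(&M.bi[tr]); pfs.push_back(prior_normal); scs.push_back(M.beta_scale);
          }
        for (size_t si = 0; si < pars.size(); ++si) {
          double cur = *pars[si];
          double lp0 = M.gauss_lp_v(v, xfix) + pfs[si](cur, scs[si]);
          *pars[si] = cur + std::exp(ls_asis[a]) * norm_rand();
          double lp1 = M.gauss_lp_v(v, xfix) + pfs[si](*pars[si], scs[si]);
          bool acc = std::log(unif_rand()) < lp1 - lp0;
          if (!acc) *pars[si] = cur;
          if (adapting) adapt_step(ls_asis[a], acc, t);
          ++a;
        }
        // canonical partial correlations (joint LKJ prior)
        for (int i = 0; i < 6; ++i) {
          double cur = M.cz[v][i];
          double lp0 = M.gauss_lp_v(v, xfix) + cpc_prior_lp(M.cz[v]);
          M.cz[v][i] = cur + std::exp(ls_asis[a]) * norm_rand();
          M.refresh_L(v);
          double lp1 = M.gauss_lp_v(v, xfix) + cpc_prior_lp(M.cz[v]);
          bool acc = std::log(unif_rand()) < lp1 - lp0;
          if (!acc) { M.cz[v][i] = cur; M.refresh_L(v); }
          if (adapting) adapt_step(ls_asis[a], acc, t);
          ++a;
        }
        M.z_from_x_v(v, xfix);
      }
      M.refresh_all_ll();
    }

    if (!adapting && ((t - warmup + 1) % thin == 0)) {
      int c = 0;
      for (int v = 0; v < 2; ++v) {
        for (int i = 0; i < 4; ++i) out(kept, c++) = M.mu[v][i];
        for (int i = 0; i < 4; ++i) out(kept, c++) = std::exp(M.lsig[v][i]);
        // marginal correlations R = Lr Lr'
        for (int i = 0; i < 4; ++i)
          for (int j = i + 1; j < 4; ++j) {
            double r = 0.0;
            for (int m = 0; m <= i; ++m) r += M.Lr[v][i][m] * M.Lr[v][j][m];
            out(kept, c++) = r;
          }
        if (intervention) { out(kept, c++) = M.phi[v][0]; out(kept, c++) = M.phi[v][1]; }
      }
      if (M.target_v >= 0)
        for (int tr = 0; tr < M.T; ++tr) { out(kept, c++) = M.bb[tr]; out(kept, c++) = M.bi[tr]; }
      if (M.has_grm) {
        for (int j = 0; j < M.gd.J; ++j) {
          out(kept, c++) = std::exp(M.gs.la[j]);
          for (int k = 0; k < M.gd.K[j] - 1; ++k) out(kept, c++) = M.gs.kappa[j][k];
        }
        for (int tr = 0; tr < M.T; ++tr)
          for (int p = 0; p < M.P; ++p) out(kept, c++) = M.theta[tr * M.P + p];
      }
      for (int p = 0; p < M.P; ++p)
        for (int v = 0; v < 2; ++v)
          for (int cc = 0; cc < 4; ++cc) out(kept, c++) = M.cell_lin(p, v, cc);
      ++kept;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Stand-alone graded response model
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix sample_grm_cpp(List grm, int n_subjects, int warmup, int n_keep,
                             int thin) {
  GRMData gd;
  grm_build(grm, n_subjects, gd);
  GRMState gs;
  grm_init(gd, gs);
  int P = n_subjects;
  std::vector<double> theta(P, 0.0);
  for (int p = 0; p < P; ++p) theta[p] = 0.3 * norm_rand();

  std::vector<double> ls_theta(P, std::log(0.5));
  std::vector<double> ls_items(grm_n_scalars(gd), std::log(0.3));

  int ncol = grm_n_scalars(gd) + P;
  NumericMatrix out(n_keep, ncol);
  int total_iter = warmup + n_keep * thin;
  int kept = 0;
  for (int t = 0; t < total_iter; ++t) {
    bool adapting = t < warmup;
    for (int p = 0; p < P; ++p) {
      double cur = theta[p];
      double ll0 = normal_lp(cur, 1.0) + grm_ll_over(gd.obs_of_subj[p], gd, gs, theta, P);
      theta[p] = cur + std::exp(ls_theta[p]) * norm_rand();
      double ll1 = normal_lp(theta[p], 1.0) + grm_ll_over(gd.obs_of_subj[p], gd, gs, theta, P);
      bool acc = std::log(unif_rand()) < ll1 - ll0;
      if (!acc) theta[p] = cur;
      if (adapting) adapt_step(ls_theta[p], acc, t);
    }
    grm_update_items(gd, gs, theta, P, ls_items, t, adapting);
    if (!adapting && ((t - warmup + 1) % thin == 0)) {
      int c = 0;
      for (int j = 0; j < gd.J; ++j) {
        out(kept, c++) = std::exp(gs.la[j]);
        for (int k = 0; k < gd.K[j] - 1; ++k) out(kept, c++) = gs.kappa[j][k];
      }
      for (int p = 0; p < P; ++p) out(kept, c++) = theta[p];
      ++kept;
    }
  }
  return out;
}

// fast Bernoulli-logit log likelihood for a vector of trials (used by the
// R-level likelihood functions on large datasets)
// [[Rcpp::export]]
double bern_logit_ll_cpp(NumericVector logit, IntegerVector y) {
  double ll = 0.0;
  for (int i = 0; i < logit.size(); ++i)
    ll += y[i] ? log_sigmoid(logit[i]) : log_sigmoid(-logit[i]);
  return ll;
}
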