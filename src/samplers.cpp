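#include <Rcpp.h>
using namespace Rcpp;

// Componentwise adaptive random-walk Metropolis samplers for the two
// Bayesian models in this package:
//   * hierarchical zero-inflated beta regression of tributary contributions
//   * zero-and-one inflated Dirichlet regression of main-stem composition
// Proposal scales adapt by Robbins-Monro toward 0.44 acceptance.

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// log(1 + exp(x)) without overflow
static inline double rg_log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct Adapt {
  std::vector<double> ls;   // log proposal sd
  double target = 0.44;
  explicit Adapt(int n, double init = -1.0) : ls(n, init) {}
  double scale(int j) const { return std::exp(ls[j]); }
  void update(int j, double acc_prob, int iter) {
    ls[j] += (acc_prob - target) / std::sqrt(iter / 50.0 + 1.0);
    if (ls[j] < -8) ls[j] = -8;
    if (ls[j] > 4) ls[j] = 4;
  }
};

// ---------------------------------------------------------------------------
// Zero-inflated beta regression
//
// Observation i (all strata): z_i ~ Bernoulli(omega_i),
//   logit(omega) = X_om beta_om.
// Positive observation j: p_j ~ Beta(mu_j phi_j, (1-mu_j) phi_j),
//   logit(mu) = X_mu beta_mu + a_sec[sec_j] + a_unit[unit_j],
//   log(phi)  = X_ph beta_ph.
// Priors: betas ~ N(0, prior_sd); a_sec ~ N(0, sd_s); a_unit ~ N(0, sd_r);
// sd_s, sd_r ~ half-N(0, 2), sampled on the log scale with Jacobian.
// ---------------------------------------------------------------------------

struct ZibState {
  NumericVector beta_mu, a_sec, a_unit, beta_ph, beta_om;
  double log_sd_s, log_sd_r;
};

class ZibModel {
public:
  NumericMatrix Xmu, Xph, Xom;
  IntegerVector z, sec, unit;          // sec/unit are 0-based, length m
  NumericVector lp, l1p;               // log p, log(1-p) for positives
  int n, m, S, R, Pmu, Pph, Pom;
  double prior_sd, sd_hn;
  std::vector<std::vector<int>> rows_sec, rows_unit;
  // caches
  std::vector<double> eta_mu, eta_ph, eta_om, row_ll; // row_ll: beta loglik per positive
  double ll_bern;

  ZibModel(NumericMatrix Xmu_, NumericMatrix Xph_, NumericMatrix Xom_,
           IntegerVector z_, IntegerVector sec_, IntegerVector unit_,
           NumericVector lp_, NumericVector l1p_, int S_, int R_,
           double prior_sd_, double sd_hn_)
    : Xmu(Xmu_), Xph(Xph_), Xom(Xom_), z(z_), sec(sec_), unit(unit_),
      lp(lp_), l1p(l1p_), S(S_), R(R_), prior_sd(prior_sd_), sd_hn(sd_hn_) {
    n = Xom.nrow(); m = Xmu.nrow();
    Pmu = Xmu.ncol(); Pph = Xph.ncol(); Pom = Xom.ncol();
    rows_sec.assign(S, {}); rows_unit.assign(R, {});
    for (int j = 0; j < m; ++j) {
      rows_sec[sec[j]].push_back(j);
      rows_unit[unit[j]].push_back(j);
    }
    eta_mu.assign(m, 0.0); eta_ph.assign(m, 0.0); eta_om.assign(n, 0.0);
    row_ll.assign(m, 0.0); ll_bern = 0.0;
  }

  double beta_row_ll(int j) const {
    double mu = inv_logit(eta_mu[j]);
    double phi = std::exp(eta_ph[j]);
    double a = mu * phi, b = (1.0 - mu) * phi;
    return R::lgammafn(a + b) - R::lgammafn(a) - R::lgammafn(b) +
           (a - 1.0) * lp[j] + (b - 1.0) * l1p[j];
  }
  double bern_ll(int i) const {
    return z[i] * eta_om[i] - rg_log1pexp(eta_om[i]);
  }
  void refresh(const ZibState& st) {
    for (int j = 0; j < m; ++j) {
      double em = 0, ep = 0;
      for (int k = 0; k < Pmu; ++k) em += Xmu(j, k) * st.beta_mu[k];
      for (int k = 0; k < Pph; ++k) ep += Xph(j, k) * st.beta_ph[k];
      eta_mu[j] = em + st.a_sec[sec[j]] + st.a_unit[unit[j]];
      eta_ph[j] = ep;
      row_ll[j] = beta_row_ll(j);
    }
    ll_bern = 0.0;
    for (int i = 0; i < n; ++i) {
      double eo = 0;
      for (int k = 0; k < Pom; ++k) eo += Xom(i, k) * st.beta_om[k];
      eta_om[i] = eo;
      ll_bern += bern_ll(i);
    }
  }
};

static inline double dnorm_l(double x, double sd) {
  return -0.5 * x * x / (sd * sd);
}

// generic scalar MH step over a set of rows of the beta-part likelihood,
// shifting eta_mu or eta_ph by X column entries
static void mh_beta_coef(ZibModel& M, double& par, bool is_mu, int col,
                         double prior_sd, Adapt& ad, int aidx, int iter) {
  const NumericMatrix& X = is_mu ? M.Xmu : M.Xph;
  std::vector<double>& eta = is_mu ? M.eta_mu : M.eta_ph;
  double step = ad.scale(aidx) * R::norm_rand();
  double cand = par + step;
  double d_ll = dnorm_l(cand, prior_sd) - dnorm_l(par, prior_sd);
  std::vector<int> touched;
  std::vector<double> old_eta, old_ll;
  for (int j = 0; j < M.m; ++j) {
    double x = X(j, col);
    if (x == 0.0) continue;
    touched.push_back(j);
    old_eta.push_back(eta[j]);
    old_ll.push_back(M.row_ll[j]);
    eta[j] += x * (cand - par);
    double nll = M.beta_row_ll(j);
    d_ll += nll - M.row_ll[j];
    M.row_ll[j] = nll;
  }
  double apr = std::min(1.0, std::exp(d_ll));
  if (R::unif_rand() < apr) {
    par = cand;
  } else {
    for (size_t t = 0; t < touched.size(); ++t) {
      eta[touched[t]] = old_eta[t];
      M.row_ll[touched[t]] = old_ll[t];
    }
  }
  ad.update(aidx, apr, iter);
}

static void mh_intercept(ZibModel& M, double& par, const std::vector<int>& rows,
                         double sd_prior, Adapt& ad, int aidx, int iter) {
  double cand = par + ad.scale(aidx) * R::norm_rand();
  double d_ll = dnorm_l(cand, sd_prior) - dnorm_l(par, sd_prior);
  std::vector<double> old_ll(rows.size());
  for (size_t t = 0; t < rows.size(); ++t) {
    int j = rows[t];
    old_ll[t] = M.row_ll[j];
    M.eta_mu[j] += cand - par;
    double nll = M.beta_row_ll(j);
    d_ll += nll - old_ll[t];
    M.row_ll[j] = nll;
  }
  double apr = std::min(1.0, std::exp(d_ll));
  if (R::unif_rand() < apr) {
    par = cand;
  } else {
    for (size_t t = 0; t < rows.size(); ++t) {
      int j = rows[t];
      M.eta_mu[j] -= cand - par;
      M.row_ll[j] = old_ll[t];
    }
  }
  ad.update(aidx, apr, iter);
}

// [[Rcpp::export]]
List cpp_zib_mcmc(NumericMatrix Xmu, NumericMatrix Xph, NumericMatrix Xom,
                  IntegerVector z, IntegerVector sec, IntegerVector unit,
                  NumericVector lp, NumericVector l1p, int S, int R,
                  NumericVector init, int sweeps, int burn,
                  List trans_cols, NumericMatrix trans_vals,
                  double prior_sd = 5.0, double sd_hn = 2.0,
                  bool pointwise = true) {
  ZibModel M(Xmu, Xph, Xom, z, sec, unit, lp, l1p, S, R, prior_sd, sd_hn);
  ZibState st;
  int Pmu = M.Pmu, Pph = M.Pph, Pom = M.Pom;
  int npar = Pmu + S + R + Pph + Pom + 2;
  if (init.size() != npar) stop("bad init length");
  int pos = 0;
  st.beta_mu = NumericVector(init.begin() + pos, init.begin() + pos + Pmu); pos += Pmu;
  st.a_sec = NumericVector(init.begin() + pos, init.begin() + pos + S); pos += S;
  st.a_unit = NumericVector(init.begin() + pos, init.begin() + pos + R); pos += R;
  st.beta_ph = NumericVector(init.begin() + pos, init.begin() + pos + Pph); pos += Pph;
  st.beta_om = NumericVector(init.begin() + pos, init.begin() + pos + Pom); pos += Pom;
  st.log_sd_s = init[pos++]; st.log_sd_r = init[pos++];
  M.refresh(st);

  int ntrans = trans_cols.size();
  Adapt ad(npar + 2 + ntrans, -1.5);   // extra slots: translation moves
  int keep = sweeps - burn;
  NumericMatrix draws(keep, npar);
  NumericMatrix pw;
  if (pointwise) pw = NumericMatrix(keep, M.n);

  for (int it = 1; it <= sweeps; ++it) {
    int aidx = 0;
    double sd_s = std::exp(st.log_sd_s), sd_r = std::exp(st.log_sd_r);
    for (int k = 0; k < Pmu; ++k)
      mh_beta_coef(M, st.beta_mu[k], true, k, prior_sd, ad, aidx++, it);
    for (int s = 0; s < S; ++s)
      mh_intercept(M, st.a_sec[s], M.rows_sec[s], sd_s, ad, aidx++, it);
    for (int r = 0; r < R; ++r)
      mh_intercept(M, st.a_unit[r], M.rows_unit[r], sd_r, ad, aidx++, it);
    for (int k = 0; k < Pph; ++k)
      mh_beta_coef(M, st.beta_ph[k], false, k, prior_sd, ad, aidx++, it);
    // bernoulli part
    for (int k = 0; k < Pom; ++k) {
      double cand = st.beta_om[k] + ad.scale(aidx) * R::norm_rand();
      double d_ll = dnorm_l(cand, prior_sd) - dnorm_l(st.beta_om[k], prior_sd);
      double new_bern = 0.0;
      double diff = cand - st.beta_om[k];
      for (int i = 0; i < M.n; ++i) {
        double x = M.Xom(i, k);
        double eo = M.eta_om[i] + x * diff;
        new_bern += z[i] * eo - rg_log1pexp(eo);
      }
      d_ll += new_bern - M.ll_bern;
      double apr = std::min(1.0, std::exp(d_ll));
      if (R::unif_rand() < apr) {
        for (int i = 0; i < M.n; ++i) M.eta_om[i] += M.Xom(i, k) * diff;
        st.beta_om[k] = cand;
        M.ll_bern = new_bern;
      }
      ad.update(aidx++, apr, it);
    }
    // random-effect scales: prior of intercepts + half-normal hyperprior
    for (int which = 0; which < 2; ++which) {
      double& lsd = which == 0 ? st.log_sd_s : st.log_sd_r;
      NumericVector& a = which == 0 ? st.a_sec : st.a_unit;
      double cand = lsd + ad.scale(aidx) * R::norm_rand();
      double cur_sd = std::exp(lsd), cand_sd = std::exp(cand);
      double d = 0.0;
      for (int t = 0; t < a.size(); ++t)
        d += dnorm_l(a[t], cand_sd) - dnorm_l(a[t], cur_sd);
      d += a.size() * (lsd - cand);                 // normal normalizers
      d += dnorm_l(cand_sd, sd_hn) - dnorm_l(cur_sd, sd_hn); // half-normal
      d += cand - lsd;                               // Jacobian
      double apr = std::min(1.0, std::exp(d));
      if (R::unif_rand() < apr) lsd = cand;
      ad.update(aidx++, apr, it);
    }
    // translation moves: shift mass between the global intercept and a
    // random-intercept block; the likelihood is invariant (X column 0 is the
    // intercept), so acceptance depends on the priors alone
    for (int which = 0; which < 2; ++which) {
      NumericVector& a = which == 0 ? st.a_sec : st.a_unit;
      double sd_a = std::exp(which == 0 ? st.log_sd_s : st.log_sd_r);
      double dlt = ad.scale(aidx) * R::norm_rand();
      double d = dnorm_l(st.beta_mu[0] + dlt, prior_sd) -
                 dnorm_l(st.beta_mu[0], prior_sd);
      for (int t = 0; t < a.size(); ++t)
        d += dnorm_l(a[t] - dlt, sd_a) - dnorm_l(a[t], sd_a);
      double apr = std::min(1.0, std::exp(d));
      if (R::unif_rand() < apr) {
        st.beta_mu[0] += dlt;
        for (int t = 0; t < a.size(); ++t) a[t] -= dlt;
      }
      ad.update(aidx++, apr, it);
    }
    // translation moves along unit-level covariate directions: shift one or
    // more coefficients whose columns sum to a unit-level covariate and
    // compensate through the unit intercepts (likelihood-invariant)
    for (int t = 0; t < ntrans; ++t) {
      IntegerVector cols = trans_cols[t];
      double sd_r2 = std::exp(st.log_sd_r);
      double dlt = ad.scale(aidx) * R::norm_rand();
      double d = 0.0;
      for (int ci = 0; ci < cols.size(); ++ci)
        d += dnorm_l(st.beta_mu[cols[ci]] + dlt, prior_sd) -
             dnorm_l(st.beta_mu[cols[ci]], prior_sd);
      for (int r = 0; r < R; ++r) {
        double shift = dlt * trans_vals(r, t);
        d += dnorm_l(st.a_unit[r] - shift, sd_r2) -
             dnorm_l(st.a_unit[r], sd_r2);
      }
      double apr = std::min(1.0, std::exp(d));
      if (R::unif_rand() < apr) {
        for (int ci = 0; ci < cols.size(); ++ci) st.beta_mu[cols[ci]] += dlt;
        for (int r = 0; r < R; ++r) st.a_unit[r] -= dlt * trans_vals(r, t);
      }
      ad.update(aidx++, apr, it);
    }

    if (it > burn) {
      int row = it - burn - 1;
      int c = 0;
      for (int k = 0; k < Pmu; ++k) draws(row, c++) = st.beta_mu[k];
      for (int s = 0; s < S; ++s) draws(row, c++) = st.a_sec[s];
      for (int r = 0; r < R; ++r) draws(row, c++) = st.a_unit[r];
      for (int k = 0; k < Pph; ++k) draws(row, c++) = st.beta_ph[k];
      for (int k = 0; k < Pom; ++k) draws(row, c++) = st.beta_om[k];
      draws(row, c++) = std::exp(st.log_sd_s);
      draws(row, c++) = std::exp(st.log_sd_r);
      if (pointwise) {
        // per observation: bernoulli term; positives add the beta density
        for (int i = 0; i < M.n; ++i) pw(row, i) = M.bern_ll(i);
        for (int j = 0; j < M.m; ++j) { /* filled below via map */ }
      }
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["draws"] = draws, _["pointwise_bern"] = pw,
                      _["npar"] = npar);
}

// pointwise beta-part log-likelihood for given draws (used to assemble the
// full pointwise log-likelihood in R)
// [[Rcpp::export]]
NumericMatrix cpp_zib_pointwise_beta(NumericMatrix draws, NumericMatrix Xmu,
                                     NumericMatrix Xph, IntegerVector sec,
                                     IntegerVector unit, NumericVector lp,
                                     NumericVector l1p, int S, int R) {
  int m = Xmu.nrow(), Pmu = Xmu.ncol(), Pph = Xph.ncol();
  int nd = draws.nrow();
  NumericMatrix out(nd, m);
  for (int d = 0; d < nd; ++d) {
    int off_sec = Pmu, off_unit = Pmu + S, off_ph = Pmu + S + R;
    for (int j = 0; j < m; ++j) {
      double em = 0, ep = 0;
      for (int k = 0; k < Pmu; ++k) em += Xmu(j, k) * draws(d, k);
      for (int k = 0; k < Pph; ++k) ep += Xph(j, k) * draws(d, off_ph + k);
      em += draws(d, off_sec + sec[j]) + draws(d, off_unit + unit[j]);
      double mu = inv_logit(em), phi = std::exp(ep);
      double a = mu * phi, b = (1 - mu) * phi;
      out(d, j) = R::lgammafn(a + b) - R::lgammafn(a) - R::lgammafn(b) +
                  (a - 1) * lp[j] + (b - 1) * l1p[j];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Zero-and-one inflated Dirichlet regression
//
// Observation i: each of K components independently structural-zero with
// probability psi; surviving components, renormalized, are Dirichlet with
// mean proportional to exp(X beta) (component K is the reference, beta = 0)
// and total concentration tau. A one-component observation is the
// all-others-zero case (degenerate Dirichlet, density 1).
// psi is conjugate (Beta(1,1) prior); beta and log(tau) use adaptive MH.
// ---------------------------------------------------------------------------

class DirModel {
public:
  NumericMatrix lY;       // log Y where positive, 0 elsewhere
  IntegerMatrix ispos;
  NumericMatrix X;
  int n, K, P;
  std::vector<int> npos;
  std::vector<std::vector<int>> rows_of_col; // rows with X(:,p) != 0
  std::vector<double> eta;  // n x (K-1) column-major
  std::vector<double> row_ll;

  DirModel(NumericMatrix lY_, IntegerMatrix ispos_, NumericMatrix X_)
    : lY(lY_), ispos(ispos_), X(X_) {
    n = lY.nrow(); K = lY.ncol(); P = X.ncol();
    npos.assign(n, 0);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < K; ++c) npos[i] += ispos(i, c);
    rows_of_col.assign(P, {});
    for (int p = 0; p < P; ++p)
      for (int i = 0; i < n; ++i)
        if (X(i, p) != 0.0) rows_of_col[p].push_back(i);
    eta.assign(n * (K - 1), 0.0);
    row_ll.assign(n, 0.0);
  }

  double dir_row_ll(int i, double tau) const {
    if (npos[i] < 2) return 0.0;
    double sw = 0.0, w[64];
    for (int c = 0; c < K; ++c) {
      double e = (c < K - 1) ? std::exp(eta[c * n + i]) : 1.0;
      w[c] = ispos(i, c) ? e : 0.0;
      sw += w[c];
    }
    double ll = R::lgammafn(tau);
    for (int c = 0; c < K; ++c) {
      if (!ispos(i, c)) continue;
      double a = tau * w[c] / sw;
      ll += (a - 1.0) * lY(i, c) - R::lgammafn(a);
    }
    return ll;
  }
  void refresh(const std::vector<double>& beta, double tau) {
    for (int c = 0; c < K - 1; ++c)
      for (int i = 0; i < n; ++i) {
        double e = 0;
        for (int p = 0; p < P; ++p) e += X(i, p) * beta[c * P + p];
        eta[c * n + i] = e;
      }
    for (int i = 0; i < n; ++i) row_ll[i] = dir_row_ll(i, tau);
  }
};

// [[Rcpp::export]]
List cpp_zoidir_mcmc(NumericMatrix lY, IntegerMatrix ispos, NumericMatrix X,
                     NumericVector init_beta, double init_logtau,
                     int sweeps, int burn, double prior_sd = 5.0,
                     double prior_logtau_sd = 5.0, bool pointwise = true) {
  DirModel M(lY, ispos, X);
  int K = M.K, P = M.P, n = M.n;
  if (K > 64) stop("too many components");
  std::vector<double> beta(init_beta.begin(), init_beta.end());
  if ((int)beta.size() != P * (K - 1)) stop("bad init_beta length");
  double logtau = init_logtau;
  double tau = std::exp(logtau);
  M.refresh(beta, tau);
  int nz_tot = 0, np_tot = 0;
  for (int i = 0; i < n; ++i) { nz_tot += K - M.npos[i]; np_tot += M.npos[i]; }

  int npar = P * (K - 1) + 2;   // beta, psi, logtau
  Adapt ad(npar, -0.7);
  int keep = sweeps - burn;
  NumericMatrix draws(keep, npar);
  NumericMatrix pw;
  if (pointwise) pw = NumericMatrix(keep, n);
  double psi = (nz_tot + 1.0) / (nz_tot + np_tot + 2.0);

  for (int it = 1; it <= sweeps; ++it) {
    // conjugate psi
    psi = R::rbeta(1.0 + nz_tot, 1.0 + np_tot);
    int aidx = 0;
    for (int c = 0; c < K - 1; ++c) {
      for (int p = 0; p < P; ++p) {
        double& b = beta[c * P + p];
        double cand = b + ad.scale(aidx) * R::norm_rand();
        double diff = cand - b;
        double d_ll = dnorm_l(cand, prior_sd) - dnorm_l(b, prior_sd);
        const std::vector<int>& rows = M.rows_of_col[p];
        std::vector<double> old_ll(rows.size()), old_eta(rows.size());
        for (size_t t = 0; t < rows.size(); ++t) {
          int i = rows[t];
          old_eta[t] = M.eta[c * n + i];
          old_ll[t] = M.row_ll[i];
          M.eta[c * n + i] += M.X(i, p) * diff;
          double nll = M.dir_row_ll(i, tau);
          d_ll += nll - old_ll[t];
          M.row_ll[i] = nll;
        }
        double apr = std::min(1.0, std::exp(d_ll));
        if (R::unif_rand() < apr) {
          b = cand;
        } else {
          for (size_t t = 0; t < rows.size(); ++t) {
            int i = rows[t];
            M.eta[c * n + i] = old_eta[t];
            M.row_ll[i] = old_ll[t];
          }
        }
        ad.update(aidx++, apr, it);
      }
    }
    { // log tau
      double cand = logtau + ad.scale(aidx) * R::norm_rand();
      double cand_tau = std::exp(cand);
      double d_ll = dnorm_l(cand, prior_logtau_sd) - dnorm_l(logtau, prior_logtau_sd);
      std::vector<double> old_ll(M.row_ll);
      for (int i = 0; i < n; ++i) {
        double nll = M.dir_row_ll(i, cand_tau);
        d_ll += nll - old_ll[i];
        M.row_ll[i] = nll;
      }
      double apr = std::min(1.0, std::exp(d_ll));
      if (R::unif_rand() < apr) {
        logtau = cand; tau = cand_tau;
      } else {
        M.row_ll = old_ll;
      }
      ad.update(aidx++, apr, it);
    }

    if (it > burn) {
      int row = it - burn - 1;
      for (int j = 0; j < P * (K - 1); ++j) draws(row, j) = beta[j];
      draws(row, P * (K - 1)) = psi;
      draws(row, P * (K - 1) + 1) = tau;
      if (pointwise)
        for (int i = 0; i < n; ++i)
          pw(row, i) = (K - M.npos[i]) * std::log(psi) +
                       M.npos[i] * std::log1p(-psi) + M.row_ll[i];
    }
    if (it % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["draws"] = draws, _["pointwise"] = pw);
}

// log predictive density of one held-out composition under each draw
// [[Rcpp::export]]
NumericVector cpp_zoidir_logpred(NumericMatrix draws, NumericVector y,
                                 NumericVector x, int K, int P) {
  int nd = draws.nrow();
  NumericVector out(nd);
  for (int d = 0; d < nd; ++d) {
    double psi = draws(d, P * (K - 1));
    double tau = draws(d, P * (K - 1) + 1);
    double sw = 0.0, w[64];
    int npos = 0;
    for (int c = 0; c < K; ++c) {
      double e = 0.0;
      if (c < K - 1)
        for (int p = 0; p < P; ++p) e += x[p] * draws(d, c * P + p);
      bool pos = y[c] > 0;
      w[c] = pos ? std::exp(e) : 0.0;
      sw += w[c];
      if (pos) ++npos;
    }
    double ll = (K - npos) * std::log(psi) + npos * std::log1p(-psi);
    if (npos >= 2) {
      ll += R::lgammafn(tau);
      for (int c = 0; c < K; ++c) {
        if (y[c] <= 0) continue;
        double a = tau * w[c] / sw;
        ll += (a - 1.0) * std::log(y[c]) - R::lgammafn(a);
      }
    }
    out[d] = ll;
  }
  return out;
}
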