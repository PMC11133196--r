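// Joint hierarchical measurement model for slider responses.
//
// Unconstrained parameter vector layout (offsets computed from the data
// list):
//   [ z (N*D, person-major) | y (D(D-1)/2, correlation Cholesky) |
//     mu_free | log_sigma_free |
//     BRM: log_alpha, delta, log_tau | DDRM: log_alpha_loc, delta_loc,
//     log_alpha_wid, delta_wid, log_tau ]
//
// Person parameters are non-centered: P_i = mu + sigma * (L z_i), where L is
// the Cholesky factor of the person correlation matrix, built from tanh-
// transformed canonical partial correlations (the usual unconstrained
// parameterization). Identification: dimensions not listed as free have
// mu = 0, sigma = 1.

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// lgamma and digamma evaluated together: shared upward recurrence into the
// asymptotic region, then Stirling-type series (abs. error ~1e-12 for the
// shape parameters arising here). Substantially faster than separate calls
// through R's math library, which dominate the likelihood cost.
static inline void lgamma_digamma(double x, double* lg, double* dg) {
  double rl = 0.0, rd = 0.0;
  while (x < 8.0) { rl -= std::log(x); rd -= 1.0 / x; x += 1.0; }
  const double lx = std::log(x), ix = 1.0 / x, f = ix * ix;
  *lg = rl + (x - 0.5) * lx - x + 0.91893853320467274178
      + (1.0 / 12 - f * (1.0 / 360 - f * (1.0 / 1260 - f * (1.0 / 1680)))) * ix;
  *dg = rd + lx - 0.5 * ix
      - f * (1.0 / 12 - f * (1.0 / 120 - f * (1.0 / 252 - f * (1.0 / 240 - f / 132))));
}

struct ModelData {
  int N, D, M;
  std::vector<int> free_mu, free_sig;
  // VAS records
  std::vector<int> v_p, v_dim, v_ia, v_id, v_it;
  std::vector<double> v_lx, v_l1x;
  // DRS records
  std::vector<int> d_p, d_diml, d_dimw, d_ial, d_idl, d_iaw, d_idw, d_it;
  std::vector<double> d_lx1, d_lx2, d_lx3;
  int nba, nbd, nbt, ndal, ndl, ndaw, ndw, ndt;
  // prior hyperparameters
  double am, as, dm, ds, tm, ts, dwm, dws, mu_sd, sig_scale, lkj_eta;
  // offsets
  int off_y, off_mu, off_sig, off_ba, off_bd, off_bt,
      off_dal, off_dl, off_daw, off_dw, off_dt, npar;
  int nobs() const { return (int)v_p.size() + (int)d_p.size(); }
};

static std::vector<int> as_ivec(SEXP s) {
  IntegerVector v(s);
  return std::vector<int>(v.begin(), v.end());
}
static std::vector<double> as_dvec(SEXP s) {
  NumericVector v(s);
  return std::vector<double>(v.begin(), v.end());
}

static ModelData unpack(List data) {
  ModelData md;
  md.N = as<int>(data["N"]); md.D = as<int>(data["D"]);
  md.M = md.D * (md.D - 1) / 2;
  md.free_mu = as_ivec(data["free_mu"]); md.free_sig = as_ivec(data["free_sig"]);
  md.v_p = as_ivec(data["v_p"]); md.v_dim = as_ivec(data["v_dim"]);
  md.v_ia = as_ivec(data["v_ia"]); md.v_id = as_ivec(data["v_id"]);
  md.v_it = as_ivec(data["v_it"]);
  md.v_lx = as_dvec(data["v_lx"]); md.v_l1x = as_dvec(data["v_l1x"]);
  md.d_p = as_ivec(data["d_p"]); md.d_diml = as_ivec(data["d_diml"]);
  md.d_dimw = as_ivec(data["d_dimw"]);
  md.d_ial = as_ivec(data["d_ial"]); md.d_idl = as_ivec(data["d_idl"]);
  md.d_iaw = as_ivec(data["d_iaw"]); md.d_idw = as_ivec(data["d_idw"]);
  md.d_it = as_ivec(data["d_it"]);
  md.d_lx1 = as_dvec(data["d_lx1"]); md.d_lx2 = as_dvec(data["d_lx2"]);
  md.d_lx3 = as_dvec(data["d_lx3"]);
  md.nba = as<int>(data["nba"]); md.nbd = as<int>(data["nbd"]);
  md.nbt = as<int>(data["nbt"]);
  md.ndal = as<int>(data["ndal"]); md.ndl = as<int>(data["ndl"]);
  md.ndaw = as<int>(data["ndaw"]); md.ndw = as<int>(data["ndw"]);
  md.ndt = as<int>(data["ndt"]);
  NumericVector pr(data["priors"]);
  md.am = pr[0]; md.as = pr[1]; md.dm = pr[2]; md.ds = pr[3];
  md.tm = pr[4]; md.ts = pr[5]; md.dwm = pr[6]; md.dws = pr[7];
  md.mu_sd = pr[8]; md.sig_scale = pr[9]; md.lkj_eta = pr[10];
  int off = md.N * md.D;
  md.off_y = off; off += md.M;
  md.off_mu = off; off += (int)md.free_mu.size();
  md.off_sig = off; off += (int)md.free_sig.size();
  md.off_ba = off; off += md.nba;
  md.off_bd = off; off += md.nbd;
  md.off_bt = off; off += md.nbt;
  md.off_dal = off; off += md.ndal;
  md.off_dl = off; off += md.ndl;
  md.off_daw = off; off += md.ndaw;
  md.off_dw = off; off += md.ndw;
  md.off_dt = off; off += md.ndt;
  md.npar = off;
  return md;
}

// Build row i (1-based rows have i free entries) of the correlation Cholesky
// factor from its unconstrained entries, returning the row (length i + 1)
// and the row's log-prior + log-Jacobian contribution.
static void chol_row(const double* y, int i, int D, double eta,
                     double* Lrow, double* logw) {
  double acc = 1.0, lw = 0.0;
  for (int j = 0; j < i; ++j) {
    double zc = std::tanh(y[j]);
    double sq = std::sqrt(acc);
    Lrow[j] = zc * sq;
    lw += std::log1p(-zc * zc) + 0.5 * std::log(acc);
    acc -= Lrow[j] * Lrow[j];
    if (acc < 1e-16) acc = 1e-16;
  }
  Lrow[i] = std::sqrt(acc);
  // LKJ density on the Cholesky factor (eta = 1: uniform over correlations)
  lw += (D - (i + 1) + 2.0 * eta - 2.0) * std::log(Lrow[i]);
  *logw = lw;
}

// Full log posterior and gradient. loglik (optional) is filled with the
// pointwise log-likelihood, VAS records first, then DRS records.
static double lp_grad(const ModelData& md, const double* par, double* grad,
                      double* loglik) {
  const int N = md.N, D = md.D;
  std::fill(grad, grad + md.npar, 0.0);
  double lp = 0.0;

  // correlation Cholesky factor
  std::vector<double> L(D * D, 0.0);  // row-major lower
  L[0] = 1.0;
  {
    int k = 0;
    for (int i = 1; i < D; ++i) {
      double lw;
      chol_row(par + md.off_y + k, i, D, md.lkj_eta, &L[i * D], &lw);
      lp += lw;
      k += i;
    }
  }

  // mu / sigma with identification constraints
  std::vector<double> mu(D, 0.0), sigma(D, 1.0), svec(D, 0.0);
  for (size_t k = 0; k < md.free_mu.size(); ++k) {
    double m = par[md.off_mu + k];
    mu[md.free_mu[k]] = m;
    lp += -0.5 * (m / md.mu_sd) * (m / md.mu_sd);
    grad[md.off_mu + k] += -m / (md.mu_sd * md.mu_sd);
  }
  for (size_t k = 0; k < md.free_sig.size(); ++k) {
    double s = par[md.off_sig + k];
    double sg = std::exp(s);
    sigma[md.free_sig[k]] = sg; svec[md.free_sig[k]] = s;
    // half-normal(sig_scale) on sigma plus log-Jacobian of exp
    lp += -0.5 * sg * sg / (md.sig_scale * md.sig_scale) + s;
    grad[md.off_sig + k] += -sg * sg / (md.sig_scale * md.sig_scale) + 1.0;
  }

  // person parameters, non-centered
  std::vector<double> P(D * N), V(D * N);  // column per person
  const double* z = par;  // z person-major blocks of length D
  for (int p = 0; p < N; ++p) {
    const double* zp = z + p * D;
    for (int i = 0; i < D; ++i) {
      double v = 0.0;
      const double* Li = &L[i * D];
      for (int j = 0; j <= i; ++j) v += Li[j] * zp[j];
      V[p * D + i] = v;
      P[p * D + i] = mu[i] + sigma[i] * v;
      lp += -0.5 * zp[i] * zp[i];
      grad[p * D + i] += -zp[i];
    }
  }

  // item-parameter transforms and priors (normal on the unconstrained scale)
  auto prior_block = [&](int off, int n, double m, double s,
                         std::vector<double>* ex) {
    if (ex) ex->resize(n);
    for (int k = 0; k < n; ++k) {
      double u = par[off + k];
      lp += -0.5 * ((u - m) / s) * ((u - m) / s);
      grad[off + k] += -(u - m) / (s * s);
      if (ex) (*ex)[k] = std::exp(u);
    }
  };
  std::vector<double> a_b, t_b, al_d, aw_d, t_d;
  prior_block(md.off_ba, md.nba, md.am, md.as, &a_b);
  prior_block(md.off_bd, md.nbd, md.dm, md.ds, nullptr);
  prior_block(md.off_bt, md.nbt, md.tm, md.ts, &t_b);
  prior_block(md.off_dal, md.ndal, md.am, md.as, &al_d);
  prior_block(md.off_dl, md.ndl, md.dm, md.ds, nullptr);
  prior_block(md.off_daw, md.ndaw, md.am, md.as, &aw_d);
  prior_block(md.off_dw, md.ndw, md.dwm, md.dws, nullptr);
  prior_block(md.off_dt, md.ndt, md.tm, md.ts, &t_d);

  std::vector<double> psi_tb(md.nbt), lg_tb(md.nbt), psi_td(md.ndt), lg_td(md.ndt);
  for (int k = 0; k < md.nbt; ++k) lgamma_digamma(t_b[k], &lg_tb[k], &psi_tb[k]);
  for (int k = 0; k < md.ndt; ++k) lgamma_digamma(t_d[k], &lg_td[k], &psi_td[k]);

  std::vector<double> GP(D * N, 0.0);  // d loglik / d P

  // VAS records: beta likelihood
  const int nv = (int)md.v_p.size();
  for (int r = 0; r < nv; ++r) {
    const int p = md.v_p[r], dim = md.v_dim[r];
    const int ia = md.v_ia[r], id = md.v_id[r], it = md.v_it[r];
    const double alpha = a_b[ia], delta = par[md.off_bd + id], tau = t_b[it];
    const double theta = P[p * D + dim];
    const double lin = alpha * (theta - delta);
    const double m = 1.0 / (1.0 + std::exp(-lin));
    const double a = m * tau, b = (1.0 - m) * tau;
    double lga, dga, lgb, dgb;
    lgamma_digamma(a, &lga, &dga);
    lgamma_digamma(b, &lgb, &dgb);
    const double ll = lg_tb[it] - lga - lgb
      + (a - 1.0) * md.v_lx[r] + (b - 1.0) * md.v_l1x[r];
    lp += ll;
    if (loglik) loglik[r] = ll;
    const double ga = md.v_lx[r] - dga;
    const double gb = md.v_l1x[r] - dgb;
    const double dmu = tau * (ga - gb);
    const double dtau = psi_tb[it] + m * ga + (1.0 - m) * gb;
    const double mp = m * (1.0 - m);
    GP[p * D + dim] += dmu * alpha * mp;
    grad[md.off_ba + ia] += dmu * (theta - delta) * mp * alpha;
    grad[md.off_bd + id] += -dmu * alpha * mp;
    grad[md.off_bt + it] += dtau * tau;
  }

  // DRS records: Dirichlet likelihood
  const int nd = (int)md.d_p.size();
  for (int r = 0; r < nd; ++r) {
    const int p = md.d_p[r], dl = md.d_diml[r], dw = md.d_dimw[r];
    const int ial = md.d_ial[r], idl = md.d_idl[r];
    const int iaw = md.d_iaw[r], idw = md.d_idw[r], it = md.d_it[r];
    const double al = al_d[ial], del_l = par[md.off_dl + idl];
    const double aw = aw_d[iaw], del_w = par[md.off_dw + idw];
    const double tau = t_d[it];
    const double th = P[p * D + dl], et = P[p * D + dw];
    const double m = 1.0 / (1.0 + std::exp(-al * (th - del_l)));
    const double w = 1.0 / (1.0 + std::exp(-aw * (et - del_w)));
    const double m1 = m * (1.0 - w), m2 = w, m3 = (1.0 - m) * (1.0 - w);
    const double a1 = m1 * tau, a2 = m2 * tau, a3 = m3 * tau;
    double lg1, dg1, lg2, dg2, lg3, dg3;
    lgamma_digamma(a1, &lg1, &dg1);
    lgamma_digamma(a2, &lg2, &dg2);
    lgamma_digamma(a3, &lg3, &dg3);
    const double ll = lg_td[it] - lg1 - lg2 - lg3
      + (a1 - 1.0) * md.d_lx1[r] + (a2 - 1.0) * md.d_lx2[r]
      + (a3 - 1.0) * md.d_lx3[r];
    lp += ll;
    if (loglik) loglik[nv + r] = ll;
    const double g1 = md.d_lx1[r] - dg1;
    const double g2 = md.d_lx2[r] - dg2;
    const double g3 = md.d_lx3[r] - dg3;
    const double dm_ = tau * (1.0 - w) * (g1 - g3);
    const double dw_ = tau * (-m * g1 + g2 - (1.0 - m) * g3);
    const double dtau = psi_td[it] + m1 * g1 + m2 * g2 + m3 * g3;
    const double mpl = m * (1.0 - m), mpw = w * (1.0 - w);
    GP[p * D + dl] += dm_ * al * mpl;
    GP[p * D + dw] += dw_ * aw * mpw;
    grad[md.off_dal + ial] += dm_ * (th - del_l) * mpl * al;
    grad[md.off_dl + idl] += -dm_ * al * mpl;
    grad[md.off_daw + iaw] += dw_ * (et - del_w) * mpw * aw;
    grad[md.off_dw + idw] += -dw_ * aw * mpw;
    grad[md.off_dt + it] += dtau * tau;
  }

  // chain rule: z, mu, sigma
  for (int p = 0; p < N; ++p) {
    const double* gp = &GP[p * D];
    double* gz = grad + p * D;
    for (int i = 0; i < D; ++i) {
      const double wgt = sigma[i] * gp[i];
      const double* Li = &L[i * D];
      for (int j = 0; j <= i; ++j) gz[j] += Li[j] * wgt;
    }
  }
  for (size_t k = 0; k < md.free_mu.size(); ++k) {
    const int i = md.free_mu[k];
    double s = 0.0;
    for (int p = 0; p < N; ++p) s += GP[p * D + i];
    grad[md.off_mu + k] += s;
  }
  for (size_t k = 0; k < md.free_sig.size(); ++k) {
    const int i = md.free_sig[k];
    double s = 0.0;
    for (int p = 0; p < N; ++p) s += GP[p * D + i] * V[p * D + i];
    grad[md.off_sig + k] += s * sigma[i];
  }

  // chain rule: correlation Cholesky rows (tiny finite differences through
  // the row transform; the data-side factor GL = (sigma * GP) Z^T is exact)
  {
    std::vector<double> GL(D * D, 0.0);
    for (int p = 0; p < N; ++p) {
      const double* zp = z + p * D;
      for (int i = 0; i < D; ++i) {
        const double wgt = sigma[i] * GP[p * D + i];
        for (int j = 0; j <= i; ++j) GL[i * D + j] += wgt * zp[j];
      }
    }
    const double h = 1e-6;
    int k = 0;
    std::vector<double> yrow(D), Lp(D + 1), Lm(D + 1);
    for (int i = 1; i < D; ++i) {
      for (int j = 0; j < i; ++j) yrow[j] = par[md.off_y + k + j];
      for (int j = 0; j < i; ++j) {
        double lwp, lwm;
        yrow[j] += h; chol_row(yrow.data(), i, D, md.lkj_eta, Lp.data(), &lwp);
        yrow[j] -= 2 * h; chol_row(yrow.data(), i, D, md.lkj_eta, Lm.data(), &lwm);
        yrow[j] += h;
        double g = (lwp - lwm) / (2 * h);
        for (int c = 0; c <= i; ++c) {
          g += (Lp[c] - Lm[c]) / (2 * h) * GL[i * D + c];
        }
        grad[md.off_y + k + j] += g;
      }
      k += i;
    }
  }
  return lp;
}

// [[Rcpp::export(name = ".lp_grad_cpp")]]
List lp_grad_cpp(NumericVector par, List data, bool want_loglik = false) {
  ModelData md = unpack(data);
  if ((int)par.size() != md.npar) stop("parameter vector has wrong length");
  NumericVector grad(md.npar);
  NumericVector ll(want_loglik ? md.nobs() : 0);
  double lp = lp_grad(md, par.begin(), grad.begin(),
                      want_loglik ? ll.begin() : nullptr);
  return List::create(_["lp"] = lp, _["grad"] = grad, _["loglik"] = ll,
                      _["npar"] = md.npar);
}

// [[Rcpp::export(name = ".n_params_cpp")]]
int n_params_cpp(List data) { return unpack(data).npar; }

// ---------------------------------------------------------------------------
// Multinomial No-U-Turn sampler (Hoffman & Gelman 2014; Betancourt 2017
// multinomial variant) with dual-averaged step size and windowed diagonal
// mass-matrix adaptation.

namespace {

struct PhasePoint {
  std::vector<double> q, p, g;
  double lp;
};

struct NutsCtx {
  const ModelData* md;
  int n;
  std::vector<double> inv_mass;
  double H0;
  double max_delta_H = 1000.0;
  std::mt19937_64* rng;
  int n_leap = 0;
  double sum_accept = 0.0;
  bool divergent = false;
};

struct Subtree {
  PhasePoint minus, plus;       // trajectory ends
  std::vector<double> q_prop;   // multinomial proposal within the subtree
  std::vector<double> g_prop;   // gradient at the proposal
  double lp_prop;
  double log_w;                 // log sum of leaf weights
  bool turning;
};

double kinetic_energy(const NutsCtx& ctx, const std::vector<double>& p) {
  double k = 0.0;
  for (int i = 0; i < ctx.n; ++i) k += 0.5 * ctx.inv_mass[i] * p[i] * p[i];
  return k;
}

bool leapfrog_step(NutsCtx& ctx, PhasePoint& z, double eps) {
  for (int i = 0; i < ctx.n; ++i) z.p[i] += 0.5 * eps * z.g[i];
  for (int i = 0; i < ctx.n; ++i) z.q[i] += eps * ctx.inv_mass[i] * z.p[i];
  double l = lp_grad(*ctx.md, z.q.data(), z.g.data(), nullptr);
  ctx.n_leap++;
  if (!std::isfinite(l)) return false;
  for (int i = 0; i < ctx.n; ++i) z.p[i] += 0.5 * eps * z.g[i];
  z.lp = l;
  return true;
}

bool uturn(const NutsCtx& ctx, const PhasePoint& minus, const PhasePoint& plus) {
  double a = 0.0, b = 0.0;
  for (int i = 0; i < ctx.n; ++i) {
    double dq = plus.q[i] - minus.q[i];
    a += ctx.inv_mass[i] * minus.p[i] * dq;
    b += ctx.inv_mass[i] * plus.p[i] * dq;
  }
  return a < 0.0 || b < 0.0;
}

double log_sum_exp(double a, double b) {
  double m = std::max(a, b);
  if (!std::isfinite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Build a subtree of 2^depth leapfrog states extending from z in direction
// dir; returns false in *ok only on hard failure (divergence).
Subtree build_tree(NutsCtx& ctx, PhasePoint z, int depth, int dir, double eps,
                   bool* valid) {
  Subtree t;
  if (depth == 0) {
    bool fine = leapfrog_step(ctx, z, dir * eps);
    double H = fine ? (-z.lp + kinetic_energy(ctx, z.p)) : R_PosInf;
    double dH = H - ctx.H0;
    ctx.sum_accept += std::min(1.0, std::exp(-dH));
    if (!fine || dH > ctx.max_delta_H) {
      ctx.divergent = true;
      *valid = false;
      t.log_w = R_NegInf;
      t.minus = t.plus = z;
      t.turning = false;
      return t;
    }
    t.minus = t.plus = z;
    t.q_prop = z.q;
    t.g_prop = z.g;
    t.lp_prop = z.lp;
    t.log_w = -dH;
    t.turning = false;
    *valid = true;
    return t;
  }
  bool ok1 = false;
  Subtree first = build_tree(ctx, z, depth - 1, dir, eps, &ok1);
  if (!ok1 || first.turning) {
    first.turning = true;
    *valid = false;
    return first;
  }
  bool ok2 = false;
  PhasePoint& edge = (dir == 1) ? first.plus : first.minus;
  Subtree second = build_tree(ctx, edge, depth - 1, dir, eps, &ok2);
  if (!ok2 || second.turning) {
    first.turning = true;
    *valid = false;
    return first;
  }
  Subtree joined;
  joined.minus = (dir == 1) ? first.minus : second.minus;
  joined.plus = (dir == 1) ? second.plus : first.plus;
  joined.log_w = log_sum_exp(first.log_w, second.log_w);
  std::uniform_real_distribution<double> u01(0.0, 1.0);
  if (std::log(u01(*ctx.rng)) < second.log_w - joined.log_w) {
    joined.q_prop = std::move(second.q_prop);
    joined.g_prop = std::move(second.g_prop);
    joined.lp_prop = second.lp_prop;
  } else {
    joined.q_prop = std::move(first.q_prop);
    joined.g_prop = std::move(first.g_prop);
    joined.lp_prop = first.lp_prop;
  }
  joined.turning = uturn(ctx, joined.minus, joined.plus);
  *valid = !joined.turning;
  return joined;
}

}  // namespace

// [[Rcpp::export(name = ".hmc_cpp")]]
List hmc_cpp(List data, NumericVector init, int warmup, int iter, int thin,
             int max_treedepth, double target_accept, int seed,
             bool want_loglik = false) {
  ModelData md = unpack(data);
  const int n = md.npar;
  if ((int)init.size() != n) stop("init has wrong length");
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> rnorm01(0.0, 1.0);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);

  NutsCtx ctx;
  ctx.md = &md; ctx.n = n; ctx.rng = &rng;
  ctx.inv_mass.assign(n, 1.0);
  std::vector<double> mass(n, 1.0);

  PhasePoint cur;
  cur.q.assign(init.begin(), init.end());
  cur.p.assign(n, 0.0);
  cur.g.assign(n, 0.0);
  cur.lp = lp_grad(md, cur.q.data(), cur.g.data(), nullptr);
  if (!std::isfinite(cur.lp)) stop("log posterior not finite at the initial values");

  // initial step size: scale until a single leapfrog step's acceptance
  // crosses one half
  double eps = 0.1 / std::sqrt((double)n);
  for (int tries = 0; tries < 60; ++tries) {
    PhasePoint z = cur;
    for (int i = 0; i < n; ++i) z.p[i] = rnorm01(rng);
    double H0 = -z.lp + kinetic_energy(ctx, z.p);
    bool ok = leapfrog_step(ctx, z, eps);
    double a = ok ? std::exp(H0 - (-z.lp + kinetic_energy(ctx, z.p))) : 0.0;
    if (a > 0.5) { if (a > 0.9) eps *= 2.0; else break; }
    else eps *= 0.5;
    if (eps < 1e-10 || eps > 1e2) break;
  }

  // dual averaging (Hoffman & Gelman 2014 defaults)
  double mu_da = std::log(10.0 * eps), log_eps = std::log(eps),
         log_eps_bar = std::log(eps), h_bar = 0.0;
  const double da_gamma = 0.05, da_t0 = 10.0, da_kappa = 0.75;
  int da_count = 0;
  auto da_update = [&](double accept) {
    da_count++;
    double frac = 1.0 / (da_count + da_t0);
    h_bar = (1.0 - frac) * h_bar + frac * (target_accept - accept);
    log_eps = mu_da - std::sqrt((double)da_count) / da_gamma * h_bar;
    double w = std::pow((double)da_count, -da_kappa);
    log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
    eps = std::exp(log_eps);
  };
  auto da_restart = [&]() {
    mu_da = std::log(10.0 * eps);
    log_eps_bar = std::log(eps);
    h_bar = 0.0; da_count = 0;
  };

  // mass-adaptation windows: step size only until w_a, then two variance
  // windows ending at w_b and w_c, final step-size refinement until warmup
  const int w_a = std::max(1, (int)(0.15 * warmup));
  const int w_b = std::max(w_a + 5, (int)(0.5 * warmup));
  const int w_c = std::max(w_b + 5, (int)(0.9 * warmup));
  std::vector<double> wm(n, 0.0), ws(n, 0.0);
  int wn = 0;
  auto welford_reset = [&]() { std::fill(wm.begin(), wm.end(), 0.0);
                               std::fill(ws.begin(), ws.end(), 0.0); wn = 0; };
  auto update_mass = [&]() {
    if (wn < 5) return;
    for (int i = 0; i < n; ++i) {
      double v = ws[i] / (wn - 1);
      double reg = (wn / (wn + 5.0)) * v + 1e-3 * (5.0 / (wn + 5.0));
      mass[i] = 1.0 / reg;
      ctx.inv_mass[i] = reg;
    }
  };

  int divergences = 0, max_depth_hits = 0;
  double accept_sum = 0.0;
  int accept_n = 0;
  NumericMatrix draws(iter, n);
  NumericMatrix ll_draws(want_loglik ? iter : 0, want_loglik ? md.nobs() : 0);
  std::vector<double> ll_buf(md.nobs()), dummy_grad(n);

  const int total = warmup + iter * thin;
  for (int it = 0; it < total; ++it) {
    const bool in_warmup = it < warmup;
    for (int i = 0; i < n; ++i) cur.p[i] = rnorm01(rng) * std::sqrt(mass[i]);
    ctx.H0 = -cur.lp + kinetic_energy(ctx, cur.p);
    ctx.n_leap = 0; ctx.sum_accept = 0.0; ctx.divergent = false;

    PhasePoint minus = cur, plus = cur;
    std::vector<double> prop_q = cur.q, prop_g = cur.g;
    double prop_lp = cur.lp, log_w_tot = 0.0;
    for (int depth = 0; depth < max_treedepth; ++depth) {
      int dir = runif01(rng) < 0.5 ? -1 : 1;
      bool valid = false;
      Subtree st = build_tree(ctx, dir == 1 ? plus : minus, depth, dir, eps,
                              &valid);
      if (!valid) break;
      if (dir == 1) plus = st.plus; else minus = st.minus;
      if (std::log(runif01(rng)) < st.log_w - log_w_tot) {
        prop_q = std::move(st.q_prop);
        prop_g = std::move(st.g_prop);
        prop_lp = st.lp_prop;
      }
      log_w_tot = log_sum_exp(log_w_tot, st.log_w);
      if (uturn(ctx, minus, plus)) break;
      if (depth == max_treedepth - 1) max_depth_hits++;
    }
    cur.q = prop_q; cur.g = prop_g; cur.lp = prop_lp;
    if (ctx.divergent && !in_warmup) divergences++;
    double accept = ctx.n_leap ? ctx.sum_accept / ctx.n_leap : 0.0;

    if (in_warmup) {
      da_update(accept);
      if (it >= w_a && it < w_c) {
        wn++;
        for (int i = 0; i < n; ++i) {
          double d0 = cur.q[i] - wm[i];
          wm[i] += d0 / wn;
          ws[i] += d0 * (cur.q[i] - wm[i]);
        }
      }
      if (it == w_b - 1 || it == w_c - 1) {
        update_mass();
        welford_reset();
        da_restart();
      }
      if (it == warmup - 1) eps = std::exp(log_eps_bar);
    } else {
      accept_sum += accept; accept_n++;
      int post = it - warmup;
      if ((post + 1) % thin == 0) {
        int row = post / thin;
        for (int i = 0; i < n; ++i) draws(row, i) = cur.q[i];
        if (want_loglik) {
          lp_grad(md, cur.q.data(), dummy_grad.data(), ll_buf.data());
          for (int i = 0; i < md.nobs(); ++i) ll_draws(row, i) = ll_buf[i];
        }
      }
    }
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["draws"] = draws, _["loglik"] = ll_draws,
                      _["stepsize"] = eps,
                      _["accept_rate"] = accept_n ? accept_sum / accept_n : NA_REAL,
                      _["divergences"] = divergences,
                      _["max_depth_hits"] = max_depth_hits,
                      _["mass_diag"] = NumericVector(mass.begin(), mass.end()));
}
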