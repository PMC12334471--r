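// Gradient-based MCMC for the hierarchical DELT occurrence models.
//
// The joint log density (Bernoulli-logit likelihood, normal random effects
// with half-Cauchy SD priors, regularized horseshoe prior on landscape
// coefficients) is evaluated with its gradient in unconstrained
// coordinates: scale parameters on the log scale (with Jacobians), the
// horseshoe block always non-centered (beta = z * tau * lambda_tilde), and
// the random effects either centered or non-centered. Sampling is the
// No-U-Turn variant of Hamiltonian Monte Carlo (slice formulation) with
// dual-averaging step-size adaptation and windowed diagonal mass-matrix
// estimation during warmup. All randomness comes from R's RNG so chains
// are reproducible under set.seed().

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
using namespace Rcpp;

struct Model {
  arma::vec y;                  // binomial successes per cell
  arma::vec trials;             // binomial trials per cell
  arma::mat X;
  arma::uvec ag, eco, sp;       // 0-based group indices, empty if absent
  int n, P, K, R, S;
  bool centered;                // random-effect parameterization
  double b0_scale, sig_scale, lambda_scale, tau0, slab_df, slab_scale;
  // parameter offsets in the unconstrained vector
  int o_b0, o_zb, o_llam, o_ltau, o_lc;
  int o_ag, o_lsa, o_eco, o_lsr, o_sp, o_lss;
  int D;
};

static Model make_model(const List& data) {
  Model m;
  m.y = as<arma::vec>(data["y"]);
  m.trials = as<arma::vec>(data["trials"]);
  m.n = m.y.n_elem;
  m.P = as<int>(data["P"]);
  m.K = as<int>(data["K"]);
  m.R = as<int>(data["R"]);
  m.S = as<int>(data["S"]);
  if (m.P > 0) m.X = as<arma::mat>(data["X"]);
  if (m.K > 0) m.ag = as<arma::uvec>(data["agency"]) - 1;
  if (m.R > 0) m.eco = as<arma::uvec>(data["ecoregion"]) - 1;
  if (m.S > 0) m.sp = as<arma::uvec>(data["species"]) - 1;
  m.centered = as<bool>(data["centered"]);
  List h = data["hyper"];
  m.b0_scale = as<double>(h["intercept_scale"]);
  m.sig_scale = as<double>(h["sigma_scale"]);
  m.lambda_scale = as<double>(h["lambda_scale"]);
  m.tau0 = as<double>(h["tau0"]);
  m.slab_df = as<double>(h["slab_df"]);
  m.slab_scale = as<double>(h["slab_scale"]);
  int o = 1;
  m.o_b0 = 0;
  if (m.P > 0) {
    m.o_zb = o; o += m.P;
    m.o_llam = o; o += m.P;
    m.o_ltau = o++; m.o_lc = o++;
  }
  if (m.K > 0) { m.o_ag = o; o += m.K; m.o_lsa = o++; }
  if (m.R > 0) { m.o_eco = o; o += m.R; m.o_lsr = o++; }
  if (m.S > 0) { m.o_sp = o; o += m.S; m.o_lss = o++; }
  m.D = o;
  return m;
}

static inline double log1pexp_s(double x) {
  if (x > 33.3) return x;
  if (x > 18.0) return x + std::exp(-x);
  return std::log1p(std::exp(x));
}

// half-Cauchy log prior on x > 0 parameterized by log x (includes the
// Jacobian log x term); dg receives d/d(log x)
static inline double hc_logp(double x, double s, double& dg) {
  double q = (x / s) * (x / s);
  dg = 1.0 - 2.0 * q / (1.0 + q);
  return std::log(2.0 / M_PI) - std::log(s) - std::log1p(q) + std::log(x);
}

static const double LOG2PI = std::log(2.0 * M_PI);

// one random-effect block: z (or centered effect) at offset oz..oz+L-1,
// log sigma at offset ols; contributes to eta, lp and gradient
struct ReWork { arma::vec eff; double sig; };

static double logp_grad(const Model& m, const arma::vec& th, arma::vec& g) {
  g.zeros(m.D);
  const double b0 = th(m.o_b0);
  arma::vec eta(m.n);
  eta.fill(b0);

  arma::vec zb, lam, lt, u, beta;
  double tau = 0.0, c = 0.0;
  if (m.P > 0) {
    zb = th.subvec(m.o_zb, m.o_zb + m.P - 1);
    arma::vec llam = th.subvec(m.o_llam, m.o_llam + m.P - 1);
    lam = arma::exp(llam);
    tau = std::exp(th(m.o_ltau));
    c = std::exp(th(m.o_lc));
    u = arma::square(tau * lam / c);
    lt = lam / arma::sqrt(1.0 + u);
    beta = zb % (tau * lt);
    eta += m.X * beta;
  }

  ReWork wa, wr, ws;
  if (m.K > 0) {
    arma::vec za = th.subvec(m.o_ag, m.o_ag + m.K - 1);
    wa.sig = std::exp(th(m.o_lsa));
    wa.eff = m.centered ? za : arma::vec(wa.sig * za);
    for (int i = 0; i < m.n; i++) eta(i) += wa.eff(m.ag(i));
  }
  if (m.R > 0) {
    arma::vec zr = th.subvec(m.o_eco, m.o_eco + m.R - 1);
    wr.sig = std::exp(th(m.o_lsr));
    wr.eff = m.centered ? zr : arma::vec(wr.sig * zr);
    for (int i = 0; i < m.n; i++) eta(i) += wr.eff(m.eco(i));
  }
  if (m.S > 0) {
    arma::vec zs = th.subvec(m.o_sp, m.o_sp + m.S - 1);
    ws.sig = std::exp(th(m.o_lss));
    ws.eff = m.centered ? zs : arma::vec(ws.sig * zs);
    for (int i = 0; i < m.n; i++) eta(i) += ws.eff(m.sp(i));
  }

  // binomial-logit likelihood and residuals (one exp per cell); cells
  // aggregate fish with identical linear predictors, so this equals the
  // per-fish Bernoulli sum exactly
  arma::vec r(m.n);
  double lp = 0.0;
  {
    const double* ep = eta.memptr();
    const double* yp = m.y.memptr();
    const double* tp = m.trials.memptr();
    double* rp = r.memptr();
    for (int i = 0; i < m.n; i++) {
      double e = ep[i], le, p;
      if (e > 0) {
        double q = std::exp(-e);
        le = (e > 33.3) ? e : e + std::log1p(q);
        p = 1.0 / (1.0 + q);
      } else {
        double q = std::exp(e);
        le = std::log1p(q);
        p = q / (1.0 + q);
      }
      lp += yp[i] * e - tp[i] * le;
      rp[i] = yp[i] - tp[i] * p;
    }
  }
  if (!std::isfinite(lp)) return -std::numeric_limits<double>::infinity();

  // intercept
  lp += -0.5 * LOG2PI - std::log(m.b0_scale)
        - 0.5 * b0 * b0 / (m.b0_scale * m.b0_scale);
  g(m.o_b0) = arma::accu(r) - b0 / (m.b0_scale * m.b0_scale);

  if (m.P > 0) {
    arma::vec gX = m.X.t() * r;                    // d loglik / d beta
    // z_beta ~ N(0,1)
    g.subvec(m.o_zb, m.o_zb + m.P - 1) = gX % (tau * lt) - zb;
    lp += -0.5 * arma::dot(zb, zb) - 0.5 * m.P * LOG2PI;
    // local scales: dbeta/dlog lambda = beta/(1+u)
    for (int f = 0; f < m.P; f++) {
      double dg;
      lp += hc_logp(lam(f), m.lambda_scale, dg);
      g(m.o_llam + f) = gX(f) * beta(f) / (1.0 + u(f)) + dg;
    }
    // global scale: dbeta/dlog tau = beta/(1+u)
    double dg_tau;
    lp += hc_logp(tau, m.tau0, dg_tau);
    g(m.o_ltau) = arma::dot(gX, beta / (1.0 + u)) + dg_tau;
    // slab: c^2 ~ InvGamma(df/2, df*scale^2/2), parameterized by log c
    double a = m.slab_df / 2.0;
    double b = m.slab_df * m.slab_scale * m.slab_scale / 2.0;
    double c2 = c * c;
    lp += a * std::log(b) - std::lgamma(a) + std::log(2.0)
          - 2.0 * a * std::log(c) - b / c2;
    g(m.o_lc) = arma::dot(gX, beta % (u / (1.0 + u))) - 2.0 * a + 2.0 * b / c2;
  }

  // random-effect blocks
  struct BlockRef { int L; int oz; int ols; const arma::uvec* idx; ReWork* w; };
  BlockRef blocks[3] = {
    {m.K, m.o_ag, m.o_lsa, &m.ag, &wa},
    {m.R, m.o_eco, m.o_lsr, &m.eco, &wr},
    {m.S, m.o_sp, m.o_lss, &m.sp, &ws}
  };
  for (int bI = 0; bI < 3; bI++) {
    BlockRef& B = blocks[bI];
    if (B.L == 0) continue;
    arma::vec sr(B.L, arma::fill::zeros);           // group sums of residuals
    for (int i = 0; i < m.n; i++) sr((*B.idx)(i)) += r(i);
    double sig = B.w->sig, dg_sig;
    const arma::vec& eff = B.w->eff;
    if (m.centered) {
      // effect is the natural gamma; prior N(0, sigma)
      lp += -B.L * (0.5 * LOG2PI + std::log(sig))
            - 0.5 * arma::dot(eff, eff) / (sig * sig);
      g.subvec(B.oz, B.oz + B.L - 1) = sr - eff / (sig * sig);
      lp += hc_logp(sig, m.sig_scale, dg_sig);
      g(B.ols) = -B.L + arma::dot(eff, eff) / (sig * sig) + dg_sig;
    } else {
      arma::vec z = th.subvec(B.oz, B.oz + B.L - 1);
      lp += -0.5 * arma::dot(z, z) - 0.5 * B.L * LOG2PI;
      g.subvec(B.oz, B.oz + B.L - 1) = sig * sr - z;
      lp += hc_logp(sig, m.sig_scale, dg_sig);
      g(B.ols) = sig * arma::dot(sr, z) + dg_sig;
    }
  }
  if (!std::isfinite(lp)) return -std::numeric_limits<double>::infinity();
  return lp;
}

// ---------------------------------------------------------------- NUTS ---

struct Tree {
  arma::vec thm, rm, gm, thp, rp, gp, thpr;
  double n;
  bool s, div;
  double alpha;
  int nalpha;
};

static double energy(double lp, const arma::vec& r, const arma::vec& minv) {
  return -lp + 0.5 * arma::dot(r, minv % r);
}

static void leapfrog(const Model& m, arma::vec& th, arma::vec& r,
                     arma::vec& grad, double eps, const arma::vec& minv,
                     double& lp) {
  r += 0.5 * eps * grad;
  th += eps * (minv % r);
  lp = logp_grad(m, th, grad);
  if (!std::isfinite(lp)) { grad.zeros(); return; }
  r += 0.5 * eps * grad;
}

static void build_tree(const Model& m, const arma::vec& th,
                       const arma::vec& r, const arma::vec& grad,
                       double logu, int v, int j, double eps, double E0,
                       const arma::vec& minv, Tree& out) {
  if (j == 0) {
    arma::vec th1 = th, r1 = r, g1 = grad;
    double lp1;
    leapfrog(m, th1, r1, g1, v * eps, minv, lp1);
    double E1 = std::isfinite(lp1) ? energy(lp1, r1, minv)
                                   : std::numeric_limits<double>::infinity();
    out.thm = th1; out.rm = r1; out.gm = g1;
    out.thp = th1; out.rp = r1; out.gp = g1;
    out.thpr = th1;
    out.n = (logu <= -E1) ? 1.0 : 0.0;
    out.div = (logu - 1000.0) > -E1 || !std::isfinite(E1);
    out.s = !out.div;
    double d = E0 - E1;
    out.alpha = std::isfinite(d) ? std::min(1.0, std::exp(d)) : 0.0;
    out.nalpha = 1;
    return;
  }
  build_tree(m, th, r, grad, logu, v, j - 1, eps, E0, minv, out);
  if (!out.s) return;
  Tree t2;
  if (v == -1) {
    build_tree(m, out.thm, out.rm, out.gm, logu, v, j - 1, eps, E0, minv, t2);
    out.thm = t2.thm; out.rm = t2.rm; out.gm = t2.gm;
  } else {
    build_tree(m, out.thp, out.rp, out.gp, logu, v, j - 1, eps, E0, minv, t2);
    out.thp = t2.thp; out.rp = t2.rp; out.gp = t2.gp;
  }
  if (t2.s && t2.n > 0 && R::unif_rand() < t2.n / (out.n + t2.n)) {
    out.thpr = t2.thpr;
  }
  out.n += t2.n;
  arma::vec dth = out.thp - out.thm;
  out.s = t2.s &&
    arma::dot(dth, minv % out.rm) >= 0 &&
    arma::dot(dth, minv % out.rp) >= 0;
  out.div = out.div || t2.div;
  out.alpha += t2.alpha;
  out.nalpha += t2.nalpha;
}

static double find_epsilon(const Model& m, const arma::vec& th0,
                           const arma::vec& grad0, double lp0,
                           const arma::vec& minv) {
  double eps = 1.0;
  arma::vec r0(m.D);
  for (int d = 0; d < m.D; d++) r0(d) = R::norm_rand() / std::sqrt(minv(d));
  double E0 = energy(lp0, r0, minv);
  arma::vec th = th0, r = r0, g = grad0;
  double lp;
  leapfrog(m, th, r, g, eps, minv, lp);
  double E1 = std::isfinite(lp) ? energy(lp, r, minv)
                                : std::numeric_limits<double>::infinity();
  while (!std::isfinite(E1)) {
    eps *= 0.5;
    th = th0; r = r0; g = grad0;
    leapfrog(m, th, r, g, eps, minv, lp);
    E1 = std::isfinite(lp) ? energy(lp, r, minv)
                           : std::numeric_limits<double>::infinity();
    if (eps < 1e-10) return 1e-10;
  }
  double a = (E0 - E1 > std::log(0.5)) ? 1.0 : -1.0;
  for (int k = 0; k < 100; k++) {
    if (a * (E0 - E1) <= -a * std::log(2.0)) break;
    eps *= std::pow(2.0, a);
    th = th0; r = r0; g = grad0;
    leapfrog(m, th, r, g, eps, minv, lp);
    E1 = std::isfinite(lp) ? energy(lp, r, minv)
                           : std::numeric_limits<double>::infinity();
    if (!std::isfinite(E1)) { eps *= 0.5; break; }
  }
  return eps;
}

// [[Rcpp::export(name = ".nuts_chain_cpp")]]
List nuts_chain_cpp(List data, List cfg, NumericVector theta0) {
  Model m = make_model(data);
  const int warmup = as<int>(cfg["warmup"]);
  const int iter = as<int>(cfg["sampling"]);
  const int maxdepth = as<int>(cfg["max_treedepth"]);
  const double delta = as<double>(cfg["target_accept"]);

  arma::vec th = as<arma::vec>(theta0);
  if ((int)th.n_elem != m.D) stop("theta0 has wrong length");
  arma::vec minv(m.D, arma::fill::ones);
  arma::vec grad(m.D);
  double lp = logp_grad(m, th, grad);
  if (!std::isfinite(lp)) stop("non-finite log density at initialization");

  double eps = find_epsilon(m, th, grad, lp, minv);
  double mu = std::log(10.0 * eps);
  double logepsbar = std::log(eps), Hbar = 0.0;
  const double gamma_ = 0.05, t0 = 10.0, kappa = 0.75;
  int acount = 0;

  // diagonal metric windows (skipped for short warmups)
  const int init_buf = 75, term_buf = 50, base_win = 25;
  const bool do_metric = warmup >= init_buf + term_buf + base_win;
  int win_start = init_buf, win_size = base_win;
  int win_end = do_metric ? std::min(win_start + win_size, warmup - term_buf)
                          : -1;
  arma::vec wmean(m.D, arma::fill::zeros), wm2(m.D, arma::fill::zeros);
  int wn = 0;

  arma::mat draws(iter, m.D);
  int div_count = 0;
  double accept_sum = 0.0;
  int accept_n = 0;
  double depth_sum = 0.0;
  int depth_n = 0, depth_max_hits = 0;

  for (int it = 0; it < warmup + iter; it++) {
    const bool warm = it < warmup;
    arma::vec r0(m.D);
    for (int d = 0; d < m.D; d++) r0(d) = R::norm_rand() / std::sqrt(minv(d));
    double E0 = energy(lp, r0, minv);
    double logu = std::log(R::unif_rand()) - E0;

    Tree tr;
    tr.thm = th; tr.rm = r0; tr.gm = grad;
    tr.thp = th; tr.rp = r0; tr.gp = grad;
    tr.thpr = th; tr.n = 1.0; tr.s = true; tr.div = false;
    tr.alpha = 0.0; tr.nalpha = 0;

    arma::vec thnew = th;
    int j = 0;
    bool s = true;
    double alpha_sum = 0.0;
    int nalpha = 0;
    bool divergent = false;
    while (s && j < maxdepth) {
      int v = (R::unif_rand() < 0.5) ? -1 : 1;
      Tree t2;
      if (v == -1) {
        build_tree(m, tr.thm, tr.rm, tr.gm, logu, v, j, eps, E0, minv, t2);
        tr.thm = t2.thm; tr.rm = t2.rm; tr.gm = t2.gm;
      } else {
        build_tree(m, tr.thp, tr.rp, tr.gp, logu, v, j, eps, E0, minv, t2);
        tr.thp = t2.thp; tr.rp = t2.rp; tr.gp = t2.gp;
      }
      if (t2.s && t2.n > 0 && R::unif_rand() < t2.n / tr.n) {
        thnew = t2.thpr;
      }
      tr.n += t2.n;
      arma::vec dth = tr.thp - tr.thm;
      s = t2.s &&
        arma::dot(dth, minv % tr.rm) >= 0 &&
        arma::dot(dth, minv % tr.rp) >= 0;
      divergent = divergent || t2.div;
      alpha_sum += t2.alpha;
      nalpha += t2.nalpha;
      j++;
    }
    th = thnew;
    lp = logp_grad(m, th, grad);
    depth_sum += j; depth_n++;
    if (j == maxdepth) depth_max_hits++;

    if (warm) {
      acount++;
      double a = nalpha > 0 ? alpha_sum / nalpha : 0.0;
      Hbar = (1.0 - 1.0 / (acount + t0)) * Hbar + (delta - a) / (acount + t0);
      double logeps = mu - std::sqrt((double)acount) / gamma_ * Hbar;
      double w = std::pow((double)acount, -kappa);
      logepsbar = w * logeps + (1.0 - w) * logepsbar;
      eps = std::exp(logeps);

      if (do_metric && it >= win_start && it < warmup - term_buf) {
        wn++;
        arma::vec dlt = th - wmean;
        wmean += dlt / wn;
        wm2 += dlt % (th - wmean);
        if (it + 1 == win_end) {
          if (wn > 1) {
            arma::vec v2 = wm2 / (wn - 1);
            minv = v2 * ((double)wn / (wn + 5.0)) + 1e-3 * (5.0 / (wn + 5.0));
          }
          wmean.zeros(); wm2.zeros(); wn = 0;
          win_start = win_end;
          win_size *= 2;
          win_end = win_start + win_size;
          if (win_end + 2 * win_size > warmup - term_buf) {
            win_end = warmup - term_buf;
          }
          // restart step-size adaptation around the averaged value
          eps = std::exp(logepsbar);
          eps = find_epsilon(m, th, grad, lp, minv);
          mu = std::log(10.0 * eps);
          Hbar = 0.0; acount = 0; logepsbar = std::log(eps);
        }
      }
      if (it == warmup - 1) eps = std::exp(logepsbar);
    } else {
      draws.row(it - warmup) = th.t();
      if (divergent) div_count++;
      if (nalpha > 0) { accept_sum += alpha_sum / nalpha; accept_n++; }
    }
  }

  return List::create(
    _["draws"] = draws,
    _["divergences"] = div_count,
    _["step_size"] = eps,
    _["mean_accept"] = accept_n > 0 ? accept_sum / accept_n : NA_REAL,
    _["mean_treedepth"] = depth_n > 0 ? depth_sum / depth_n : NA_REAL,
    _["max_treedepth_hits"] = depth_max_hits,
    _["inv_mass"] = minv);
}

// [[Rcpp::export(name = ".delt_logp_grad_cpp")]]
List delt_logp_grad_cpp(List data, NumericVector theta) {
  Model m = make_model(data);
  arma::vec th = as<arma::vec>(theta);
  if ((int)th.n_elem != m.D) stop("theta has wrong length");
  arma::vec g(m.D);
  double lp = logp_grad(m, th, g);
  return List::create(_["lp"] = lp, _["grad"] = g);
}
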