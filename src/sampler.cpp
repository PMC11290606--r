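// Gibbs / Metropolis-within-Gibbs sampler for the hierarchical mixture of
// generalization mechanisms.
//
// Latent groups: 1 Non-Learner, 2 Overgeneralizer, 3 Physical Generalizer,
// 4 Perceptual Generalizer. Discrete membership m_i is drawn from its full
// conditional by enumeration; per-component copies of the truncated
// person-level parameters (lam in (0,B] vs (B,Inf)) keep the augmented
// state consistent under group moves, so label switching is structurally
// absent. Continuous parameters use adaptive random-walk Metropolis on
// unconstrained transforms (scales adapted during burn-in only); mu_w0 and
// the mixture weights have conjugate Gibbs updates.
//
// Model variants: `learning = false` freezes associative strength at its
// asymptote (v+ = 1, v- = -1) and removes the learning rate (ablation that
// neglects the learning process); `n_groups = 3` removes the
// perceptual-distance pathway (ablation that ignores perceptual
// variability).

#include <Rcpp.h>
using namespace Rcpp;

static const double TWOPI = 6.283185307179586;

struct Data {
  NumericMatrix y, dphys_p, dperc_p, dphys_m, dperc_m, rp, kp, rm, km;
  int N, J;
  bool differential;
};

// Gaussian log-likelihood pieces of participant i under group m.
// Returns sum of squares and count; theta is recomputed by the forward pass.
static void accum_ss(const Data &d, int i, int m, double alpha, double lam,
                     double w0, double w1, bool learning,
                     double &ss, int &nobs) {
  ss = 0.0; nobs = 0;
  double vp = 0.0, vm = 0.0;
  if (!learning && m >= 2) { vp = 1.0; vm = d.differential ? -1.0 : 0.0; }
  if (m == 1) { alpha = 0.0; lam = 0.0; }
  for (int j = 0; j < d.J; ++j) {
    double yij = d.y(i, j);
    if (!NumericMatrix::is_na(yij)) {
      double g = 0.0;
      if (vp != 0.0) {
        double dp = (m == 4) ? d.dperc_p(i, j) : d.dphys_p(i, j);
        g += vp * std::exp(-lam * dp);
      }
      if (d.differential && vm != 0.0) {
        double dm = (m == 4) ? d.dperc_m(i, j) : d.dphys_m(i, j);
        g += vm * std::exp(-lam * dm);
      }
      double theta = 1.0 + 9.0 / (1.0 + std::exp(-(w0 + w1 * g)));
      double r = yij - theta;
      ss += r * r; ++nobs;
    }
    if (learning && m != 1) {
      vp += alpha * (d.rp(i, j) - vp) * d.kp(i, j);
      if (d.differential) vm += alpha * (d.rm(i, j) - vm) * d.km(i, j);
    }
  }
}

static inline double ll_from_ss(double ss, int nobs, double sigma) {
  return -0.5 * nobs * std::log(TWOPI * sigma * sigma)
         - ss / (2.0 * sigma * sigma);
}

// truncated normal log density (sd parameterization)
static double dtnorm_log(double x, double mu, double sd, double lo,
                         double hi) {
  if (x < lo || x > hi) return R_NegInf;
  double z = R::pnorm(hi, mu, sd, 1, 0) - R::pnorm(lo, mu, sd, 1, 0);
  if (z <= 0) return R_NegInf;
  return R::dnorm(x, mu, sd, 1) - std::log(z);
}

static double rtnorm1(double mu, double sd, double lo, double hi) {
  double pl = R::pnorm(lo, mu, sd, 1, 0), pu = R::pnorm(hi, mu, sd, 1, 0);
  double u = pl + (pu - pl) * R::runif(0.0, 1.0);
  // guard the extreme tails
  u = std::min(std::max(u, 1e-12), 1.0 - 1e-12);
  double x = R::qnorm(u, mu, sd, 1, 0);
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  return x;
}

static inline double dhalfcauchy_log(double x, double scale) {
  if (x <= 0) return R_NegInf;
  return std::log(2.0) + R::dcauchy(x, 0.0, scale, 1);
}

struct Adapt {
  std::vector<double> ls;   // log proposal sd
  explicit Adapt(int n, double init) : ls(n, std::log(init)) {}
  double sd(int k) const { return std::exp(ls[k]); }
  void tune(int k, bool acc, double gamma) {
    ls[k] += gamma * ((acc ? 1.0 : 0.0) - 0.44);
    if (ls[k] < -12) ls[k] = -12;
    if (ls[k] > 4) ls[k] = 4;
  }
};

// [[Rcpp::export]]
List gm_run_chain(List data, List init, int n_groups, bool learning,
                  bool differential, double boundary,
                  int iterations, int burn_in, int thin) {
  RNGScope scope;
  Data d;
  d.y = as<NumericMatrix>(data["y"]);
  d.dphys_p = as<NumericMatrix>(data["dphys_p"]);
  d.dperc_p = as<NumericMatrix>(data["dperc_p"]);
  d.dphys_m = as<NumericMatrix>(data["dphys_m"]);
  d.dperc_m = as<NumericMatrix>(data["dperc_m"]);
  d.rp = as<NumericMatrix>(data["rp"]);
  d.kp = as<NumericMatrix>(data["kp"]);
  d.rm = as<NumericMatrix>(data["rm"]);
  d.km = as<NumericMatrix>(data["km"]);
  d.N = d.y.nrow(); d.J = d.y.ncol();
  d.differential = differential;
  const int N = d.N, G = n_groups;
  const double B = boundary;

  // state
  std::vector<int> m = as<std::vector<int> >(init["m"]);
  std::vector<double> ar = as<std::vector<double> >(init["alpha_raw"]);
  std::vector<double> l2 = as<std::vector<double> >(init["lam2"]);
  std::vector<double> l34 = as<std::vector<double> >(init["lam34"]);
  std::vector<double> w0 = as<std::vector<double> >(init["w0"]);
  std::vector<double> w1 = as<std::vector<double> >(init["w1"]);
  double mu_a = init["mu_alpha"], kap_a = init["kappa_alpha"];
  double mu_l = init["mu_lambda"], sig_l = init["sigma_lambda"];
  double mu_w0 = init["mu_w0"], sig_w0 = init["sigma_w0"];
  double aw1 = init["a_w1"], bw1 = init["b_w1"];
  double sig1 = init["sigma_learner"], sig2 = init["sigma_nonlearner"];
  std::vector<double> pi = as<std::vector<double> >(init["pi"]);

  // cached residual sums of squares under the current state
  std::vector<double> ss(N); std::vector<int> nobs(N);
  for (int i = 0; i < N; ++i) {
    double a = (m[i] == 1) ? 0.0 : ar[i];
    double lam = (m[i] == 2) ? l2[i] : l34[i];
    accum_ss(d, i, m[i], a, lam, w0[i], w1[i], learning, ss[i], nobs[i]);
  }
  auto sigma_of = [&](int mi) { return mi == 1 ? sig2 : sig1; };

  Adapt ad_ar(N, 0.5), ad_l2(N, B / 4.0), ad_l34(N, 0.05), ad_w0(N, 0.5),
      ad_w1(N, 0.3);
  Adapt ad_h(10, 0.2); // mu_a(logit), kap, mu_l, log sig_l, log sig_w0,
                       // log aw1, log bw1, sig1, sig2, (aw1,bw1) ridge

  int n_keep = (iterations - burn_in) / thin;
  int P = 5 * N + 10 + G;
  NumericMatrix out(n_keep, P);
  int row = 0;

  for (int it = 1; it <= iterations; ++it) {
    bool adapting = it <= burn_in;
    double gamma = adapting ? std::min(0.1, 2.0 / std::sqrt((double)it))
                            : 0.0;

    // ---- mixture weights: conjugate Dirichlet update -------------------
    {
      std::vector<double> cnt(G, 1.0);  // Dirichlet(1,...,1) prior
      for (int i = 0; i < N; ++i) cnt[m[i] - 1] += 1.0;
      double tot = 0.0;
      for (int g = 0; g < G; ++g) { pi[g] = R::rgamma(cnt[g], 1.0); tot += pi[g]; }
      for (int g = 0; g < G; ++g) pi[g] /= tot;
    }

    // ---- group membership: full conditional by enumeration -------------
    for (int i = 0; i < N; ++i) {
      double lp[4], ssm[4]; int nb[4];
      double mx = R_NegInf;
      for (int g = 1; g <= G; ++g) {
        double a = (g == 1) ? 0.0 : ar[i];
        double lam = (g == 2) ? l2[i] : l34[i];
        accum_ss(d, i, g, a, lam, w0[i], w1[i], learning, ssm[g - 1],
                 nb[g - 1]);
        lp[g - 1] = std::log(pi[g - 1])
                    + ll_from_ss(ssm[g - 1], nb[g - 1], sigma_of(g));
        if (lp[g - 1] > mx) mx = lp[g - 1];
      }
      double tot = 0.0, p[4];
      for (int g = 0; g < G; ++g) { p[g] = std::exp(lp[g] - mx); tot += p[g]; }
      double u = R::runif(0.0, 1.0) * tot, c = 0.0;
      int pick = G;
      for (int g = 0; g < G; ++g) { c += p[g]; if (u <= c) { pick = g + 1; break; } }
      m[i] = pick; ss[i] = ssm[pick - 1]; nobs[i] = nb[pick - 1];
    }

    // ---- person-specific continuous parameters --------------------------
    double a_al = mu_a * kap_a, b_al = (1.0 - mu_a) * kap_a;
    for (int i = 0; i < N; ++i) {
      int mi = m[i];
      double sig_i = sigma_of(mi);
      double ll_cur = ll_from_ss(ss[i], nobs[i], sig_i);
      double lam_i = (mi == 2) ? l2[i] : l34[i];
      double alpha_i = (mi == 1) ? 0.0 : ar[i];

      // learning rate (raw copy); prior Beta(a_al, b_al)
      if (learning) {
        if (mi >= 2) {
          double z = std::log(ar[i] / (1.0 - ar[i]));
          double zp = z + ad_ar.sd(i) * R::norm_rand();
          double arp = 1.0 / (1.0 + std::exp(-zp));
          double ssp; int nbp;
          accum_ss(d, i, mi, arp, lam_i, w0[i], w1[i], learning, ssp, nbp);
          double lr = ll_from_ss(ssp, nbp, sig_i) - ll_cur
            + R::dbeta(arp, a_al, b_al, 1) - R::dbeta(ar[i], a_al, b_al, 1)
            + std::log(arp * (1.0 - arp)) - std::log(ar[i] * (1.0 - ar[i]));
          bool acc = std::log(R::unif_rand()) < lr;
          if (acc) { ar[i] = arp; alpha_i = arp; ss[i] = ssp; nobs[i] = nbp;
                     ll_cur = ll_from_ss(ssp, nbp, sig_i); }
          if (adapting) ad_ar.tune(i, acc, gamma);
        } else {
          ar[i] = R::rbeta(a_al, b_al);  // likelihood-free: prior draw
        }
      }

      // generalization rate, overgeneralizer copy in (0, B]
      if (mi == 2) {
        double lp = l2[i] + ad_l2.sd(i) * R::norm_rand();
        if (lp > 0 && lp <= B) {
          double ssp; int nbp;
          accum_ss(d, i, mi, alpha_i, lp, w0[i], w1[i], learning, ssp, nbp);
          double lr = ll_from_ss(ssp, nbp, sig_i) - ll_cur
            + dtnorm_log(lp, mu_l, sig_l, 0.0, B)
            - dtnorm_log(l2[i], mu_l, sig_l, 0.0, B);
          bool acc = std::log(R::unif_rand()) < lr;
          if (acc) { l2[i] = lp; ss[i] = ssp; nobs[i] = nbp;
                     ll_cur = ll_from_ss(ssp, nbp, sig_i); }
          if (adapting) ad_l2.tune(i, acc, gamma);
        } else if (adapting) ad_l2.tune(i, false, gamma);
      } else {
        l2[i] = rtnorm1(mu_l, sig_l, 0.0, B);
      }

      // generalization rate, generalizer copy in (B, Inf)
      if (mi >= 3) {
        double lp = l34[i] + ad_l34.sd(i) * R::norm_rand();
        if (lp > B) {
          double ssp; int nbp;
          accum_ss(d, i, mi, alpha_i, lp, w0[i], w1[i], learning, ssp, nbp);
          double lr = ll_from_ss(ssp, nbp, sig_i) - ll_cur
            + dtnorm_log(lp, mu_l, sig_l, B, R_PosInf)
            - dtnorm_log(l34[i], mu_l, sig_l, B, R_PosInf);
          bool acc = std::log(R::unif_rand()) < lr;
          if (acc) { l34[i] = lp; ss[i] = ssp; nobs[i] = nbp;
                     ll_cur = ll_from_ss(ssp, nbp, sig_i); }
          if (adapting) ad_l34.tune(i, acc, gamma);
        } else if (adapting) ad_l34.tune(i, false, gamma);
      } else {
        l34[i] = rtnorm1(mu_l, sig_l, B, R_PosInf);
      }
      lam_i = (mi == 2) ? l2[i] : l34[i];

      // baseline w0
      {
        double wp = w0[i] + ad_w0.sd(i) * R::norm_rand();
        double ssp; int nbp;
        accum_ss(d, i, mi, alpha_i, lam_i, wp, w1[i], learning, ssp, nbp);
        double lr = ll_from_ss(ssp, nbp, sig_i) - ll_cur
          + R::dnorm(wp, mu_w0, sig_w0, 1) - R::dnorm(w0[i], mu_w0, sig_w0, 1);
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) { w0[i] = wp; ss[i] = ssp; nobs[i] = nbp;
                   ll_cur = ll_from_ss(ssp, nbp, sig_i); }
        if (adapting) ad_w0.tune(i, acc, gamma);
      }

      // scaling w1 (log scale); likelihood-free for Non-Learners
      if (mi == 1) {
        w1[i] = R::rgamma(aw1, 1.0 / bw1);
      } else {
        double zp = std::log(w1[i]) + ad_w1.sd(i) * R::norm_rand();
        double wp = std::exp(zp);
        double ssp; int nbp;
        accum_ss(d, i, mi, alpha_i, lam_i, w0[i], wp, learning, ssp, nbp);
        double lr = ll_from_ss(ssp, nbp, sig_i) - ll_cur
          + R::dgamma(wp, aw1, 1.0 / bw1, 1)
          - R::dgamma(w1[i], aw1, 1.0 / bw1, 1)
          + zp - std::log(w1[i]);
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) { w1[i] = wp; ss[i] = ssp; nobs[i] = nbp; }
        if (adapting) ad_w1.tune(i, acc, gamma);
      }
    }

    // ---- hyperparameters ------------------------------------------------
    if (learning) {
      // mu_alpha (logit RW), flat Beta(1,1) prior
      {
        double z = std::log(mu_a / (1.0 - mu_a));
        double zp = z + ad_h.sd(0) * R::norm_rand();
        double mp = 1.0 / (1.0 + std::exp(-zp));
        double ap = mp * kap_a, bp = (1.0 - mp) * kap_a;
        double lr = 0.0;
        for (int i = 0; i < N; ++i)
          lr += R::dbeta(ar[i], ap, bp, 1) - R::dbeta(ar[i], a_al, b_al, 1);
        lr += std::log(mp * (1.0 - mp)) - std::log(mu_a * (1.0 - mu_a));
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) { mu_a = mp; a_al = ap; b_al = bp; }
        if (adapting) ad_h.tune(0, acc, gamma);
      }
      // kappa_alpha (raw RW in [1, 10]), flat prior
      {
        double kp = kap_a + 3.0 * ad_h.sd(1) * R::norm_rand();
        if (kp >= 1.0 && kp <= 10.0) {
          double ap = mu_a * kp, bp = (1.0 - mu_a) * kp;
          double lr = 0.0;
          for (int i = 0; i < N; ++i)
            lr += R::dbeta(ar[i], ap, bp, 1) - R::dbeta(ar[i], a_al, b_al, 1);
          bool acc = std::log(R::unif_rand()) < lr;
          if (acc) { kap_a = kp; a_al = ap; b_al = bp; }
          if (adapting) ad_h.tune(1, acc, gamma);
        } else if (adapting) ad_h.tune(1, false, gamma);
      }
    } else {
      mu_a = R::rbeta(1.0, 1.0);        // hyperprior draws: no alpha field
      kap_a = R::runif(1.0, 10.0);
    }

    // mu_lambda (raw RW, > 0), prior Normal(0.1, 1) T(0, Inf)
    {
      double mp = mu_l + ad_h.sd(2) * R::norm_rand();
      if (mp > 0) {
        double lr = dtnorm_log(mp, 0.1, 1.0, 0.0, R_PosInf)
                  - dtnorm_log(mu_l, 0.1, 1.0, 0.0, R_PosInf);
        for (int i = 0; i < N; ++i)
          lr += dtnorm_log(l2[i], mp, sig_l, 0.0, B)
              - dtnorm_log(l2[i], mu_l, sig_l, 0.0, B)
              + dtnorm_log(l34[i], mp, sig_l, B, R_PosInf)
              - dtnorm_log(l34[i], mu_l, sig_l, B, R_PosInf);
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) mu_l = mp;
        if (adapting) ad_h.tune(2, acc, gamma);
      } else if (adapting) ad_h.tune(2, false, gamma);
    }
    // sigma_lambda (log RW in (1e-9, 1)), flat prior on the sd
    {
      double zp = std::log(sig_l) + ad_h.sd(3) * R::norm_rand();
      double sp = std::exp(zp);
      if (sp > 1e-9 && sp < 1.0) {
        double lr = zp - std::log(sig_l);  // Jacobian
        for (int i = 0; i < N; ++i)
          lr += dtnorm_log(l2[i], mu_l, sp, 0.0, B)
              - dtnorm_log(l2[i], mu_l, sig_l, 0.0, B)
              + dtnorm_log(l34[i], mu_l, sp, B, R_PosInf)
              - dtnorm_log(l34[i], mu_l, sig_l, B, R_PosInf);
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) sig_l = sp;
        if (adapting) ad_h.tune(3, acc, gamma);
      } else if (adapting) ad_h.tune(3, false, gamma);
    }
    // mu_w0: conjugate Normal update (prior Normal(0, 10^2))
    {
      double sw = 0.0;
      for (int i = 0; i < N; ++i) sw += w0[i];
      double prec = N / (sig_w0 * sig_w0) + 1.0 / 100.0;
      double mean = (sw / (sig_w0 * sig_w0)) / prec;
      mu_w0 = R::rnorm(mean, 1.0 / std::sqrt(prec));
    }
    // sigma_w0 (log RW), Half-Cauchy(0, 2) prior
    {
      double zp = std::log(sig_w0) + ad_h.sd(4) * R::norm_rand();
      double sp = std::exp(zp);
      double lr = dhalfcauchy_log(sp, 2.0) - dhalfcauchy_log(sig_w0, 2.0)
                + zp - std::log(sig_w0);
      for (int i = 0; i < N; ++i)
        lr += R::dnorm(w0[i], mu_w0, sp, 1) - R::dnorm(w0[i], mu_w0, sig_w0, 1);
      bool acc = std::log(R::unif_rand()) < lr;
      if (acc) sig_w0 = sp;
      if (adapting) ad_h.tune(4, acc, gamma);
    }
    // a_w1, b_w1 (log RW), Half-Cauchy(0, 2) priors
    {
      double zp = std::log(aw1) + ad_h.sd(5) * R::norm_rand();
      double ap = std::exp(zp);
      double lr = dhalfcauchy_log(ap, 2.0) - dhalfcauchy_log(aw1, 2.0)
                + zp - std::log(aw1);
      for (int i = 0; i < N; ++i)
        lr += R::dgamma(w1[i], ap, 1.0 / bw1, 1)
            - R::dgamma(w1[i], aw1, 1.0 / bw1, 1);
      bool acc = std::log(R::unif_rand()) < lr;
      if (acc) aw1 = ap;
      if (adapting) ad_h.tune(5, acc, gamma);
    }
    {
      double zp = std::log(bw1) + ad_h.sd(6) * R::norm_rand();
      double bp = std::exp(zp);
      double lr = dhalfcauchy_log(bp, 2.0) - dhalfcauchy_log(bw1, 2.0)
                + zp - std::log(bw1);
      for (int i = 0; i < N; ++i)
        lr += R::dgamma(w1[i], aw1, 1.0 / bp, 1)
            - R::dgamma(w1[i], aw1, 1.0 / bw1, 1);
      bool acc = std::log(R::unif_rand()) < lr;
      if (acc) bw1 = bp;
      if (adapting) ad_h.tune(6, acc, gamma);
    }
    // joint ridge move: rescale shape and rate together (preserves the
    // Gamma mean a/b, the direction the data constrain least)
    {
      double zc = ad_h.sd(9) * R::norm_rand();
      double c = std::exp(zc);
      double ap = aw1 * c, bp = bw1 * c;
      double lr = dhalfcauchy_log(ap, 2.0) - dhalfcauchy_log(aw1, 2.0)
                + dhalfcauchy_log(bp, 2.0) - dhalfcauchy_log(bw1, 2.0)
                + 2.0 * zc;  // Jacobian of (a,b) -> (ac, bc)
      for (int i = 0; i < N; ++i)
        lr += R::dgamma(w1[i], ap, 1.0 / bp, 1)
            - R::dgamma(w1[i], aw1, 1.0 / bw1, 1);
      bool acc = std::log(R::unif_rand()) < lr;
      if (acc) { aw1 = ap; bw1 = bp; }
      if (adapting) ad_h.tune(9, acc, gamma);
    }
    // response noise: learners (Uniform(1e-9, 1.5)) and Non-Learners
    // (Uniform(1.5, 3)); residual sums are cached, theta does not change
    {
      double sp = sig1 + 0.2 * ad_h.sd(7) * R::norm_rand();
      if (sp > 1e-9 && sp < 1.5) {
        double lr = 0.0;
        for (int i = 0; i < N; ++i) if (m[i] >= 2)
          lr += ll_from_ss(ss[i], nobs[i], sp)
              - ll_from_ss(ss[i], nobs[i], sig1);
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) sig1 = sp;
        if (adapting) ad_h.tune(7, acc, gamma);
      } else if (adapting) ad_h.tune(7, false, gamma);
    }
    {
      double sp = sig2 + 0.5 * ad_h.sd(8) * R::norm_rand();
      if (sp > 1.5 && sp < 3.0) {
        double lr = 0.0;
        for (int i = 0; i < N; ++i) if (m[i] == 1)
          lr += ll_from_ss(ss[i], nobs[i], sp)
              - ll_from_ss(ss[i], nobs[i], sig2);
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) sig2 = sp;
        if (adapting) ad_h.tune(8, acc, gamma);
      } else if (adapting) ad_h.tune(8, false, gamma);
    }

    // ---- record ---------------------------------------------------------
    if (it > burn_in && (it - burn_in) % thin == 0 && row < n_keep) {
      for (int i = 0; i < N; ++i) {
        out(row, i) = m[i];
        out(row, N + i) = (m[i] == 1 || !learning) ? 0.0 : ar[i];
        out(row, 2 * N + i) = (m[i] == 1) ? 0.0
                              : (m[i] == 2 ? l2[i] : l34[i]);
        out(row, 3 * N + i) = w0[i];
        out(row, 4 * N + i) = w1[i];
      }
      int o = 5 * N;
      out(row, o + 0) = mu_a;  out(row, o + 1) = kap_a;
      out(row, o + 2) = mu_l;  out(row, o + 3) = sig_l;
      out(row, o + 4) = mu_w0; out(row, o + 5) = sig_w0;
      out(row, o + 6) = aw1;   out(row, o + 7) = bw1;
      out(row, o + 8) = sig1;  out(row, o + 9) = sig2;
      for (int g = 0; g < G; ++g) out(row, o + 10 + g) = pi[g];
      ++row;
    }
  }

  return List::create(_["draws"] = out);
}

// Forward-pass log-likelihood and mean-response trajectory for a single
// participant; used to cross-check the sampler's internal forward model
// against the R reference implementation.
// [[Rcpp::export]]
List gm_cpp_forward(NumericVector y, NumericVector dphys_p,
                    NumericVector dperc_p, NumericVector dphys_m,
                    NumericVector dperc_m, NumericVector rp,
                    NumericVector kp, NumericVector rm, NumericVector km,
                    int m, double alpha, double lam, double w0, double w1,
                    double sigma, bool learning, bool differential) {
  int J = y.size();
  NumericVector theta(J);
  double vp = 0.0, vm = 0.0, ll = 0.0;
  if (!learning && m >= 2) { vp = 1.0; vm = differential ? -1.0 : 0.0; }
  if (m == 1) { alpha = 0.0; lam = 0.0; }
  for (int j = 0; j < J; ++j) {
    double g = 0.0;
    if (vp != 0.0)
      g += vp * std::exp(-lam * ((m == 4) ? dperc_p[j] : dphys_p[j]));
    if (differential && vm != 0.0)
      g += vm * std::exp(-lam * ((m == 4) ? dperc_m[j] : dphys_m[j]));
    theta[j] = 1.0 + 9.0 / (1.0 + std::exp(-(w0 + w1 * g)));
    if (!NumericVector::is_na(y[j]))
      ll += R::dnorm(y[j], theta[j], sigma, 1);
    if (learning && m != 1) {
      vp += alpha * (rp[j] - vp) * kp[j];
      if (differential) vm += alpha * (rm[j] - vm) * km[j];
    }
  }
  return List::create(_["theta"] = theta, _["loglik"] = ll);
}
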