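#include <Rcpp.h>
using namespace Rcpp;

// Model configuration codes (kept in sync with R/models.R):
//   transfer:  0 none, 1 weak, 2 strong
//   weighting: 0 fixed 0.5, 1 free omega, 2 emotion split, 3 arbitration
struct Spec {
  bool learn_opt, learn_par, emo_bonus;
  int transfer;
  int weighting;
};

// Parameter vector order (R side: PARAM_ORDER):
// beta, omega, omega_f, omega_n, alpha_pos_opt, alpha_neg_opt,
// alpha_pos_partner, alpha_neg_partner, theta, gamma
struct Pars {
  double beta, omega, omega_f, omega_n,
         ap_o, an_o, ap_p, an_p, theta, gamma;
};

static Spec as_spec(const IntegerVector& s) {
  Spec sp;
  sp.learn_opt = s[0] != 0;
  sp.learn_par = s[1] != 0;
  sp.transfer  = s[2];
  sp.weighting = s[3];
  sp.emo_bonus = s[4] != 0;
  return sp;
}

static Pars as_pars(const NumericVector& p) {
  Pars q;
  q.beta = p[0]; q.omega = p[1]; q.omega_f = p[2]; q.omega_n = p[3];
  q.ap_o = p[4]; q.an_o = p[5]; q.ap_p = p[6]; q.an_p = p[7];
  q.theta = p[8]; q.gamma = p[9];
  return q;
}

// Rescorla-Wagner step with sign-dependent learning rate; delta == 0
// applies no update.
static inline double rw_step(double p, double d, double ap, double an) {
  if (d > 0.0) return p + ap * d;
  if (d < 0.0) return p + an * d;
  return p;
}

struct Agent {
  Spec sp; Pars q;
  double p_good, p_bad;          // safety estimates of the block's options
  std::vector<double> p_par;     // per-partner reliability estimates
  double ad_o, ad_p;             // previous-trial |delta|s (arbitration)
  int cur_block;

  Agent(const Spec& s, const Pars& qq, int n_partners)
    : sp(s), q(qq), p_good(0.5), p_bad(0.5),
      p_par(n_partners, 0.5), ad_o(0.5), ad_p(0.5), cur_block(-1) {}

  // Block boundary: options are novel. Weak transfer keeps the cached
  // partner estimate; strong transfer additionally seeds the new options
  // from it, oriented by the advice given on the block's first trial.
  // Arbitration |delta| traces are re-initialized with the options.
  void maybe_transition(int block, int k, bool advised_good) {
    if (block == cur_block) return;
    cur_block = block;
    ad_o = 0.5; ad_p = 0.5;
    if (sp.transfer == 0)
      std::fill(p_par.begin(), p_par.end(), 0.5);
    if (sp.transfer == 2) {
      double c = p_par[k];
      if (advised_good) { p_good = c;       p_bad  = 1.0 - c; }
      else              { p_bad  = c;       p_good = 1.0 - c; }
    } else {
      p_good = 0.5; p_bad = 0.5;
    }
  }

  double omega_eff(bool fearful) const {
    switch (sp.weighting) {
      case 0:  return 0.5;
      case 1:  return q.omega;
      case 2:  return fearful ? q.omega_f : q.omega_n;
      default: {
        double a = std::exp(1.0 - ad_o);
        double b = std::exp((1.0 - ad_p) + q.gamma);
        return a / (a + b);
      }
    }
  }

  // log P(choose advised) and log P(choose other), numerically stable.
  void choice_logprobs(int k, bool advised_good, bool fearful,
                       double& lp_adv, double& lp_oth) const {
    double w  = omega_eff(fearful);
    double th = (sp.emo_bonus && fearful) ? q.theta : 0.0;
    double ev_g = 2.0 * p_good - 1.0;
    double ev_b = 2.0 * p_bad  - 1.0;
    double ev_p = 2.0 * p_par[k] - 1.0;
    double q_adv, q_oth;
    if (advised_good) {
      q_adv = w * ev_g + (1.0 - w) * ev_p + th;
      q_oth = w * ev_b;
    } else {
      q_adv = w * ev_b + (1.0 - w) * ev_p + th;
      q_oth = w * ev_g;
    }
    double z = (q_oth - q_adv) / q.beta;  // log-odds against advised
    if (z > 0.0) {
      lp_adv = -z - std::log1p(std::exp(-z));
    } else {
      lp_adv = -std::log1p(std::exp(z));
    }
    lp_oth = lp_adv + z;
  }

  // Feedback: r = 1 when no shock. Only the chosen option is updated;
  // the partner update is congruent with following/defying the advice.
  void update(int k, bool advised_good, bool chosen_good, bool shock) {
    double r  = shock ? 0.0 : 1.0;
    double pc = chosen_good ? p_good : p_bad;
    double d  = r - pc;
    if (sp.learn_opt) {
      double np = rw_step(pc, d, q.ap_o, q.an_o);
      if (chosen_good) p_good = np; else p_bad = np;
    }
    ad_o = std::fabs(d);
    bool followed = (chosen_good == advised_good);
    double dp = (followed ? r : 1.0 - r) - p_par[k];
    if (sp.learn_par)
      p_par[k] = rw_step(p_par[k], dp, q.ap_p, q.an_p);
    ad_p = std::fabs(dp);
  }
};

// Pointwise log-likelihood of one participant's ordered trial sequence.
// [[Rcpp::export]]
NumericVector cpp_seq_loglik(IntegerVector block, IntegerVector partner,
                             LogicalVector fearful, LogicalVector advised_good,
                             LogicalVector chosen_good, LogicalVector shock,
                             IntegerVector spec, NumericVector par,
                             int n_partners) {
  const int n = block.size();
  Agent ag(as_spec(spec), as_pars(par), n_partners);
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    int k = partner[t] - 1;
    ag.maybe_transition(block[t], k, advised_good[t]);
    double lp_adv, lp_oth;
    ag.choice_logprobs(k, advised_good[t], fearful[t], lp_adv, lp_oth);
    out[t] = (chosen_good[t] == advised_good[t]) ? lp_adv : lp_oth;
    ag.update(k, advised_good[t], chosen_good[t], shock[t]);
  }
  return out;
}

// Simulate one agent over a per-trial schedule. Predictive partners gaze
// at the bad option every trial (so the advised, non-gazed option is the
// good one); random partners' gaze is Bernoulli(0.5). Uses R's RNG; the
// per-trial draw order is gaze (random partners only), choice, outcome.
// [[Rcpp::export]]
List cpp_simulate(IntegerVector block, IntegerVector partner,
                  LogicalVector fearful, LogicalVector predictive,
                  double ps_bad, double ps_good,
                  IntegerVector spec, NumericVector par, int n_partners) {
  const int n = block.size();
  Agent ag(as_spec(spec), as_pars(par), n_partners);
  LogicalVector adv(n), cho(n), shk(n);
  for (int t = 0; t < n; ++t) {
    int k = partner[t] - 1;
    bool advised_good = predictive[t] ? true : (unif_rand() < 0.5);
    ag.maybe_transition(block[t], k, advised_good);
    double lp_adv, lp_oth;
    ag.choice_logprobs(k, advised_good, fearful[t], lp_adv, lp_oth);
    bool choose_advised = unif_rand() < std::exp(lp_adv);
    bool chosen_good = (choose_advised == advised_good);
    bool shock = unif_rand() < (chosen_good ? ps_good : ps_bad);
    adv[t] = advised_good; cho[t] = chosen_good; shk[t] = shock;
    ag.update(k, advised_good, chosen_good, shock);
  }
  return List::create(_["advised_good"] = adv,
                      _["chosen_good"]  = cho,
                      _["shock"]        = shk);
}

// Grid runner for the weak-vs-strong transfer scenarios. grid has one row
// per combination with columns alpha_pos_opt, alpha_neg_opt,
// alpha_pos_partner, alpha_neg_partner, beta; omega is fixed at 0.5
// (equal-weighting models), the single partner is neutral. Scenario codes:
// 0 stable predictive (gaze at bad option on every trial), 1 reversal
// (gaze bad during the first two blocks, gaze good afterwards),
// 2 degradation (gaze bad during the first two blocks, uniform random
// afterwards). Returns per-combination per-trial replicate means of the
// safe-choice indicator and of the post-update internal estimates, for
// the weak (columns 1..T) and strong (columns T+1..2T) transfer models.
// [[Rcpp::export]]
List cpp_run_scenario(NumericMatrix grid, int scenario,
                      int n_blocks, int trials_per_block, int n_reps,
                      double ps_bad, double ps_good, bool keep_traj) {
  const int C = grid.nrow();
  const int T = n_blocks * trials_per_block;
  const int switch_at = 2 * trials_per_block;  // phase change, 0-based
  NumericMatrix safe(C, 2 * T);
  NumericMatrix pp(keep_traj ? C : 1, keep_traj ? 2 * T : 1);
  NumericMatrix pb(keep_traj ? C : 1, keep_traj ? 2 * T : 1);
  NumericMatrix pg(keep_traj ? C : 1, keep_traj ? 2 * T : 1);
  NumericVector par(10);
  par[1] = 0.5;  // omega (unused: weighting code 0)
  for (int c = 0; c < C; ++c) {
    if (c % 64 == 0) Rcpp::checkUserInterrupt();
    par[4] = grid(c, 0); par[5] = grid(c, 1);
    par[6] = grid(c, 2); par[7] = grid(c, 3);
    par[0] = grid(c, 4);
    for (int m = 0; m < 2; ++m) {
      Spec sp;
      sp.learn_opt = true; sp.learn_par = true; sp.emo_bonus = false;
      sp.weighting = 0;
      sp.transfer = (m == 0) ? 1 : 2;  // weak, strong
      Pars q = as_pars(par);
      const int off = m * T;
      for (int rep = 0; rep < n_reps; ++rep) {
        Agent ag(sp, q, 1);
        for (int t = 0; t < T; ++t) {
          bool advised_good;
          if (t < switch_at)       advised_good = true;        // gaze bad
          else if (scenario == 0)  advised_good = true;
          else if (scenario == 1)  advised_good = false;       // gaze good
          else                     advised_good = unif_rand() < 0.5;
          ag.maybe_transition(t / trials_per_block + 1, 0, advised_good);
          double lp_adv, lp_oth;
          ag.choice_logprobs(0, advised_good, false, lp_adv, lp_oth);
          bool choose_advised = unif_rand() < std::exp(lp_adv);
          bool chosen_good = (choose_advised == advised_good);
          bool shock = unif_rand() < (chosen_good ? ps_good : ps_bad);
          if (chosen_good) safe(c, off + t) += 1.0;
          ag.update(0, advised_good, chosen_good, shock);
          if (keep_traj) {
            pp(c, off + t) += ag.p_par[0];
            pb(c, off + t) += ag.p_bad;
            pg(c, off + t) += ag.p_good;
          }
        }
      }
      for (int t = 0; t < T; ++t) {
        safe(c, off + t) /= n_reps;
        if (keep_traj) {
          pp(c, off + t) /= n_reps;
          pb(c, off + t) /= n_reps;
          pg(c, off + t) /= n_reps;
        }
      }
    }
  }
  if (keep_traj)
    return List::create(_["safe"] = safe, _["p_partner"] = pp,
                        _["p_bad"] = pb, _["p_good"] = pg);
  return List::create(_["safe"] = safe);
}
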