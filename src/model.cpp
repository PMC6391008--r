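// Hybrid model-based/model-free value recursion for the two-stage task,
// choice-only (softmax) and joint choice+RT (Wiener diffusion) likelihoods,
// and closed-loop agent simulation.
//
// Conventions: first-stage actions 1/2; second-stage states 2/3; the frequent
// destination of action 1 is state 2 (action 2 -> state 3). Second-stage
// bandits are indexed 0..3 as (state2: bandits 0,1), (state3: bandits 2,3).
// All Q-values start at zero at the beginning of a session and persist
// across block breaks; only the perseveration (stay) indicator resets.
#include <Rcpp.h>
using namespace Rcpp;

void twostepr_sample_fpt(double a, double v, int *upper, double *t);
double twostepr_wfpt_logdens_chosen(double t, double a, double delta,
                                    double eps, double floor_dens);

struct QState {
  double q1[2]; // model-free first-stage values
  double q2[4]; // second-stage bandit values
  QState() { q1[0] = q1[1] = 0.0; q2[0] = q2[1] = q2[2] = q2[3] = 0.0; }
};

// model-based first-stage values from the known transition structure
static void mb_values(const QState &qs, double pc, double qmb[2]) {
  double m2 = std::max(qs.q2[0], qs.q2[1]);
  double m3 = std::max(qs.q2[2], qs.q2[3]);
  qmb[0] = pc * m2 + (1.0 - pc) * m3;
  qmb[1] = (1.0 - pc) * m2 + pc * m3;
}

// net first-stage values: (1-w) MF + w MB + p * stay  (stay: 1/2 or 0=none)
static void net_values(const QState &qs, double pc, double w, double p,
                       int prev_choice, double qnet[2]) {
  double qmb[2];
  mb_values(qs, pc, qmb);
  for (int i = 0; i < 2; ++i) {
    qnet[i] = (1.0 - w) * qs.q1[i] + w * qmb[i];
    if (prev_choice == i + 1) qnet[i] += p;
  }
}

// SARSA(lambda) commit at end of trial; prediction errors use pre-update values
static void update_values(QState &qs, int a1, int bandit, int r,
                          double alpha1, double alpha2, double lam) {
  double pe2 = (double)r - qs.q2[bandit];
  qs.q1[a1 - 1] += alpha1 * (qs.q2[bandit] - qs.q1[a1 - 1]) + alpha1 * lam * pe2;
  qs.q2[bandit] += alpha2 * pe2;
}

static double log_softmax_binary(double q_chosen, double q_other, double beta) {
  // log P(chosen) with numerically safe log-sum-exp
  double d = beta * (q_other - q_chosen);
  if (d > 35.0) return -d; // exp(-d) dominates
  return -std::log1p(std::exp(d));
}

// RL par: alpha1, alpha2, beta1, beta2, lambda, w, p
// [[Rcpp::export]]
NumericVector loglik_rl_cpp(NumericVector par, IntegerVector choice1,
                            IntegerVector state2, IntegerVector choice2,
                            IntegerVector reward, IntegerVector block,
                            double p_common, bool by_trial) {
  double alpha1 = par[0], alpha2 = par[1], beta1 = par[2], beta2 = par[3],
         lam = par[4], w = par[5], p = par[6];
  int n = choice1.size();
  QState qs;
  int prev_choice = 0, prev_block = NA_INTEGER;
  double total = 0.0;
  NumericVector out(by_trial ? n : 1);
  for (int t = 0; t < n; ++t) {
    if (t == 0 || block[t] != prev_block) prev_choice = 0;
    prev_block = block[t];
    double qnet[2];
    net_values(qs, p_common, w, p, prev_choice, qnet);
    int a1 = choice1[t];
    double ll = log_softmax_binary(qnet[a1 - 1], qnet[2 - a1], beta1);
    int base = (state2[t] - 2) * 2;
    int bandit = base + (choice2[t] - 1);
    int other = base + (2 - choice2[t]);
    ll += log_softmax_binary(qs.q2[bandit], qs.q2[other], beta2);
    update_values(qs, a1, bandit, reward[t], alpha1, alpha2, lam);
    prev_choice = a1;
    if (by_trial) out[t] = ll; else total += ll;
  }
  if (!by_trial) out[0] = total;
  return out;
}

// DDM-RL par: alpha1, alpha2, lambda, w, p, b1, a1, tau1, b2, a2, tau2
// [[Rcpp::export]]
NumericVector loglik_ddmrl_cpp(NumericVector par, IntegerVector choice1,
                               IntegerVector state2, IntegerVector choice2,
                               IntegerVector reward, NumericVector rt1,
                               NumericVector rt2, IntegerVector block,
                               double p_common, double eps, double floor_dens,
                               bool by_trial) {
  double alpha1 = par[0], alpha2 = par[1], lam = par[2], w = par[3], p = par[4];
  double b1 = par[5], bs1 = par[6], tau1 = par[7];
  double b2 = par[8], bs2 = par[9], tau2 = par[10];
  int n = choice1.size();
  QState qs;
  int prev_choice = 0, prev_block = NA_INTEGER;
  double total = 0.0;
  NumericVector out(by_trial ? n : 1);
  for (int t = 0; t < n; ++t) {
    if (t == 0 || block[t] != prev_block) prev_choice = 0;
    prev_block = block[t];
    double qnet[2];
    net_values(qs, p_common, w, p, prev_choice, qnet);
    int a1 = choice1[t];
    double d1 = b1 * (qnet[a1 - 1] - qnet[2 - a1]);
    double ll = twostepr_wfpt_logdens_chosen(rt1[t] - tau1, bs1, d1, eps, floor_dens);
    int base = (state2[t] - 2) * 2;
    int bandit = base + (choice2[t] - 1);
    int other = base + (2 - choice2[t]);
    double d2 = b2 * (qs.q2[bandit] - qs.q2[other]);
    ll += twostepr_wfpt_logdens_chosen(rt2[t] - tau2, bs2, d2, eps, floor_dens);
    update_values(qs, a1, bandit, reward[t], alpha1, alpha2, lam);
    prev_choice = a1;
    if (by_trial) out[t] = ll; else total += ll;
  }
  if (!by_trial) out[0] = total;
  return out;
}

// Latent value trajectories for an observed session. All recorded values are
// the pre-update values entering each trial's choice rule.
// par: alpha1, alpha2, lambda, w, p
// [[Rcpp::export]]
List latent_cpp(NumericVector par, IntegerVector choice1, IntegerVector state2,
                IntegerVector choice2, IntegerVector reward,
                IntegerVector block, double p_common) {
  double alpha1 = par[0], alpha2 = par[1], lam = par[2], w = par[3], p = par[4];
  int n = choice1.size();
  NumericMatrix qmf1(n, 2), q2(n, 4), qmb(n, 2), qnet(n, 2);
  IntegerVector stay_prev(n);
  QState qs;
  int prev_choice = 0, prev_block = NA_INTEGER;
  for (int t = 0; t < n; ++t) {
    if (t == 0 || block[t] != prev_block) prev_choice = 0;
    prev_block = block[t];
    double qmbv[2], qnetv[2];
    mb_values(qs, p_common, qmbv);
    net_values(qs, p_common, w, p, prev_choice, qnetv);
    for (int i = 0; i < 2; ++i) {
      qmf1(t, i) = qs.q1[i];
      qmb(t, i) = qmbv[i];
      qnet(t, i) = qnetv[i];
    }
    for (int i = 0; i < 4; ++i) q2(t, i) = qs.q2[i];
    stay_prev[t] = prev_choice;
    int a1 = choice1[t];
    int bandit = (state2[t] - 2) * 2 + (choice2[t] - 1);
    update_values(qs, a1, bandit, reward[t], alpha1, alpha2, lam);
    prev_choice = a1;
  }
  return List::create(_["qmf1"] = qmf1, _["q2"] = q2, _["qmb"] = qmb,
                      _["qnet"] = qnet, _["stay_prev"] = stay_prev);
}

// Closed-loop agent simulation. model: 0 = RL (softmax, no RTs),
// 1 = DDM-RL (diffusion choices and RTs).
// par: RL -> alpha1, alpha2, beta1, beta2, lambda, w, p
//      DDM -> alpha1, alpha2, lambda, w, p, b1, a1, tau1, b2, a2, tau2
// walks: n x 4 matrix of reward probabilities; block: per-trial block index.
// deadline <= 0 means none; otherwise timed-out stages are resampled.
// [[Rcpp::export]]
List sim_session_cpp(int model, NumericVector par, NumericMatrix walks,
                     double p_common, IntegerVector block, bool keep_latent,
                     double deadline) {
  int n = walks.nrow();
  double alpha1, alpha2, beta1 = 0, beta2 = 0, lam, w, p;
  double b1 = 0, bs1 = 0, tau1 = 0, b2 = 0, bs2 = 0, tau2 = 0;
  if (model == 0) {
    alpha1 = par[0]; alpha2 = par[1]; beta1 = par[2]; beta2 = par[3];
    lam = par[4]; w = par[5]; p = par[6];
  } else {
    alpha1 = par[0]; alpha2 = par[1]; lam = par[2]; w = par[3]; p = par[4];
    b1 = par[5]; bs1 = par[6]; tau1 = par[7];
    b2 = par[8]; bs2 = par[9]; tau2 = par[10];
  }
  IntegerVector choice1(n), state2(n), choice2(n), reward(n), transition(n);
  NumericVector rt1(n), rt2(n);
  NumericMatrix q2lat;
  if (keep_latent) q2lat = NumericMatrix(n, 4);
  QState qs;
  int prev_choice = 0, prev_block = NA_INTEGER;
  for (int t = 0; t < n; ++t) {
    if (t == 0 || block[t] != prev_block) prev_choice = 0;
    prev_block = block[t];
    if (keep_latent) for (int i = 0; i < 4; ++i) q2lat(t, i) = qs.q2[i];
    double qnet[2];
    net_values(qs, p_common, w, p, prev_choice, qnet);
    int a1;
    double t1 = NA_REAL;
    if (model == 0) {
      double p1 = 1.0 / (1.0 + std::exp(-beta1 * (qnet[0] - qnet[1])));
      a1 = (unif_rand() < p1) ? 1 : 2;
    } else {
      double d1 = b1 * (qnet[0] - qnet[1]);
      int up;
      double dt;
      for (int att = 0; att < 1000; ++att) {
        twostepr_sample_fpt(bs1, d1, &up, &dt);
        t1 = dt + tau1;
        if (deadline <= 0.0 || t1 <= deadline) break;
      }
      a1 = up ? 1 : 2;
    }
    int common = (unif_rand() < p_common) ? 1 : 0;
    int s2 = (a1 == 1) ? (common ? 2 : 3) : (common ? 3 : 2);
    int base = (s2 - 2) * 2;
    int a2;
    double t2 = NA_REAL;
    if (model == 0) {
      double p1 = 1.0 / (1.0 + std::exp(-beta2 * (qs.q2[base] - qs.q2[base + 1])));
      a2 = (unif_rand() < p1) ? 1 : 2;
    } else {
      double d2 = b2 * (qs.q2[base] - qs.q2[base + 1]);
      int up;
      double dt;
      for (int att = 0; att < 1000; ++att) {
        twostepr_sample_fpt(bs2, d2, &up, &dt);
        t2 = dt + tau2;
        if (deadline <= 0.0 || t2 <= deadline) break;
      }
      a2 = up ? 1 : 2;
    }
    int bandit = base + (a2 - 1);
    int r = (unif_rand() < walks(t, bandit)) ? 1 : 0;
    choice1[t] = a1; state2[t] = s2; choice2[t] = a2; reward[t] = r;
    transition[t] = common; rt1[t] = t1; rt2[t] = t2;
    update_values(qs, a1, bandit, r, alpha1, alpha2, lam);
    prev_choice = a1;
  }
  List out = List::create(_["choice1"] = choice1, _["transition"] = transition,
                          _["state2"] = state2, _["choice2"] = choice2,
                          _["reward"] = reward, _["rt1"] = rt1, _["rt2"] = rt2);
  if (keep_latent) out["q2"] = q2lat;
  return out;
}

// Reflected Gaussian random walk for the four reward probabilities.
// [[Rcpp::export]]
NumericMatrix reward_walks_cpp(int n, double sd, double lo, double hi) {
  NumericMatrix probs(n, 4);
  for (int j = 0; j < 4; ++j) {
    double x = lo + (hi - lo) * unif_rand();
    probs(0, j) = x;
    for (int t = 1; t < n; ++t) {
      x += sd * norm_rand();
      // reflect into [lo, hi] (repeat for large excursions)
      for (int it = 0; it < 100; ++it) {
        if (x < lo) x = 2.0 * lo - x;
        else if (x > hi) x = 2.0 * hi - x;
        else break;
      }
      probs(t, j) = x;
    }
  }
  return probs;
}

// Model-agnostic scores computed directly from simulated vectors:
// MB-I(choice) = interaction of previous transition x reward on stay
// probability; MB-II(RT) = mean RT2 after rare minus after common
// transitions. Mirrors the R scoring path; cross-checked in tests.
static void scores_from_session(const IntegerVector &choice1,
                                const IntegerVector &transition,
                                const IntegerVector &reward,
                                const NumericVector &rt2,
                                const IntegerVector &block,
                                double *mb1, double *mb2) {
  double stay_n[2][2] = {{0, 0}, {0, 0}}, stay_k[2][2] = {{0, 0}, {0, 0}};
  double rtsum[2] = {0, 0};
  int rtn[2] = {0, 0};
  int n = choice1.size();
  for (int t = 0; t < n; ++t) {
    int tr = transition[t]; // 1 common, 0 rare
    rtsum[tr] += rt2[t];
    rtn[tr] += 1;
    if (t + 1 < n && block[t + 1] == block[t]) {
      int r = reward[t];
      stay_n[tr][r] += 1.0;
      if (choice1[t + 1] == choice1[t]) stay_k[tr][r] += 1.0;
    }
  }
  bool ok = true;
  double p[2][2];
  for (int tr = 0; tr < 2; ++tr)
    for (int r = 0; r < 2; ++r) {
      if (stay_n[tr][r] == 0) ok = false;
      else p[tr][r] = stay_k[tr][r] / stay_n[tr][r];
    }
  *mb1 = ok ? (p[1][1] - p[0][1]) - (p[1][0] - p[0][0]) : NA_REAL;
  *mb2 = (rtn[0] > 0 && rtn[1] > 0)
    ? rtsum[0] / rtn[0] - rtsum[1] / rtn[1] : NA_REAL;
}

// Simulate a cohort of DDM-RL agents and return their individual MB scores.
// par: n_agents x 11; one independent reward walk per agent.
// [[Rcpp::export]]
NumericMatrix sim_cohort_scores_cpp(NumericMatrix par, int n_trials,
                                    double p_common, double walk_sd,
                                    double walk_lo, double walk_hi,
                                    IntegerVector block, double deadline) {
  int m = par.nrow();
  NumericMatrix out(m, 2);
  for (int i = 0; i < m; ++i) {
    NumericMatrix walks = reward_walks_cpp(n_trials, walk_sd, walk_lo, walk_hi);
    NumericVector p(11);
    for (int j = 0; j < 11; ++j) p[j] = par(i, j);
    List sim = sim_session_cpp(1, p, walks, p_common, block, false, deadline);
    double mb1, mb2;
    scores_from_session(sim["choice1"], sim["transition"], sim["reward"],
                        sim["rt2"], block, &mb1, &mb2);
    out(i, 0) = mb1;
    out(i, 1) = mb2;
  }
  return out;
}
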