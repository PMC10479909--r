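#include <Rcpp.h>
using namespace Rcpp;

// Trial-level log-likelihood of one subject's full log (training + test,
// all blocks, chronological order). Modeled decisions: second-stage
// choices on free-option trials (both phases) and first-stage choices
// (test phase). Forced key presses contribute probability 1 but still
// drive value updates. The stage-1 backup uses pre-update stage-2 values;
// the stage-2 update credits the emitted action with the delivered
// reward (relevant on incoherent trials).
//
// target: 0 = sarsa, 1 = q_learning, 2 = beta_pessimistic
// par: alpha1, alpha2, tau1, tau2, beta, rho, kappa, bias
// [[Rcpp::export]]
List loglik_cpp(IntegerVector block_slot, IntegerVector is_test,
                IntegerVector is_free, IntegerVector action,
                NumericVector reward, int n_blocks, int n_forced_actions,
                bool share_stage1, int target, double q_init,
                NumericVector par) {
  const double alpha1 = par[0], alpha2 = par[1];
  const double tau1 = par[2], tau2 = par[3];
  const double beta = par[4], rho = par[5];
  const double kappa = par[6], bias = par[7];
  const int n = block_slot.size();
  const int nfa = n_forced_actions;

  std::vector<double> q1((share_stage1 ? 1 : n_blocks) * 2, q_init);
  std::vector<double> q2f(n_blocks * 2, q_init);
  std::vector<double> q2c(n_blocks * nfa, q_init);

  double ll = 0.0;
  int nobs = 0;
  int prev = -1;       // previous test trial's stage-1 choice (0 free, 1 forced)
  int cur_block = -1;

  for (int t = 0; t < n; ++t) {
    const int slot = block_slot[t] - 1;
    if (slot != cur_block) { cur_block = slot; prev = -1; }
    const int s1 = share_stage1 ? 0 : slot;
    const bool free_opt = is_free[t] == 1;
    const int a = action[t] - 1;

    if (is_test[t] == 1) {
      double uf = q1[s1 * 2 + 0] + bias;
      double uo = q1[s1 * 2 + 1];
      if (prev == 0) uf += kappa; else if (prev == 1) uo += kappa;
      const double m = std::max(uf, uo);
      const double ef = std::exp((uf - m) / tau1);
      const double eo = std::exp((uo - m) / tau1);
      const double pfree = ef / (ef + eo);
      ll += std::log(free_opt ? pfree : 1.0 - pfree);
      ++nobs;
    }

    double z;  // future-value target of the stage-1 backup
    if (free_opt) {
      const double qa = q2f[slot * 2 + 0], qb = q2f[slot * 2 + 1];
      const double m2 = std::max(qa, qb);
      const double e1 = std::exp((qa - m2) / tau2);
      const double e2 = std::exp((qb - m2) / tau2);
      const double pa1 = e1 / (e1 + e2);
      ll += std::log(a == 0 ? pa1 : 1.0 - pa1);
      ++nobs;
      if (target == 0) z = q2f[slot * 2 + a];
      else if (target == 1) z = std::max(qa, qb);
      else z = beta * std::max(qa, qb) + (1.0 - beta) * std::min(qa, qb);
    } else {
      if (nfa == 1) {
        z = q2c[slot];
      } else {
        const double qa = q2c[slot * 2 + 0], qb = q2c[slot * 2 + 1];
        if (target == 0) z = q2c[slot * 2 + a];
        else if (target == 1) z = std::max(qa, qb);
        else z = beta * std::max(qa, qb) + (1.0 - beta) * std::min(qa, qb);
      }
    }

    const int c1 = free_opt ? 0 : 1;
    q1[s1 * 2 + c1] += alpha1 * (z - q1[s1 * 2 + c1]);
    if (is_test[t] == 1) prev = c1;

    const double reff = reward[t] + (free_opt ? rho : 0.0);
    if (free_opt) {
      q2f[slot * 2 + a] += alpha2 * (reff - q2f[slot * 2 + a]);
    } else {
      q2c[slot * nfa + a] += alpha2 * (reff - q2c[slot * nfa + a]);
    }
  }

  return List::create(_["loglik"] = ll, _["n_obs"] = nobs);
}
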