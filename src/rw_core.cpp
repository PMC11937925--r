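#include <Rcpp.h>
using namespace Rcpp;

// Numerically stable log(1/(1+exp(-x))); exact at |x| up to ~700.
static inline double log_sigmoid(double x) {
  if (x >= 0.0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

// Forward pass of the valenced Rescorla-Wagner learner over one
// participant-by-condition event sequence.
//
// stim      0-based stimulus index (values tracked per stimulus)
// choice_a  1 if option A chosen, 0 if B
// reward    1 rewarding feedback, 0 non-rewarding
// par       alpha_win, alpha_loss, rho_win, rho_loss, theta_win, theta_loss
// signed_coding  outcome -1 for nonreward (TRUE) or 0 (FALSE)
//
// Returns the negative log-likelihood of the observed choices and the
// model probability of choosing A at each event (before that event's update).
// [[Rcpp::export]]
List rw_forward_cpp(IntegerVector stim, IntegerVector choice_a,
                    IntegerVector reward, int n_stim,
                    NumericVector par, bool signed_coding) {
  int n = stim.size();
  std::vector<double> p(n_stim, 0.5);
  int last = -1;  // -1 none yet, 1 win, 0 loss: selects theta
  NumericVector pa(n);
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    int s = stim[i];
    double theta = (last < 0) ? 0.5 * (par[4] + par[5])
                              : (last == 1 ? par[4] : par[5]);
    double x = theta * (2.0 * p[s] - 1.0);  // theta * (P_A - P_B)
    double lpa = log_sigmoid(x);
    pa[i] = std::exp(lpa);
    nll -= (choice_a[i] == 1) ? lpa : log_sigmoid(-x);

    // update the chosen option's value only (P_B = 1 - P_A)
    double pc = (choice_a[i] == 1) ? p[s] : 1.0 - p[s];
    bool win = (reward[i] == 1);
    double outcome = win ? 1.0 : (signed_coding ? -1.0 : 0.0);
    double alpha = win ? par[0] : par[1];
    double rho   = win ? par[2] : par[3];
    pc += alpha * (rho * outcome - pc);
    if (pc < 0.0) pc = 0.0; else if (pc > 1.0) pc = 1.0;
    p[s] = (choice_a[i] == 1) ? pc : 1.0 - pc;
    last = win ? 1 : 0;
  }
  return List::create(_["nll"] = nll, _["p_choice_a"] = pa);
}

// Simulate choices and probabilistic feedback for one condition's schedule.
// correct_a[i] = 1 when A is the high-probability option for that stimulus.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List rw_simulate_cpp(IntegerVector stim, IntegerVector correct_a,
                     double contingency, int n_stim,
                     NumericVector par, bool signed_coding) {
  int n = stim.size();
  std::vector<double> p(n_stim, 0.5);
  int last = -1;
  IntegerVector choice(n), correct(n), rew(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    int s = stim[i];
    double theta = (last < 0) ? 0.5 * (par[4] + par[5])
                              : (last == 1 ? par[4] : par[5]);
    double x = theta * (2.0 * p[s] - 1.0);
    double pa = std::exp(log_sigmoid(x));
    int chose_a = (unif_rand() < pa) ? 1 : 0;
    int is_corr = (chose_a == correct_a[s]) ? 1 : 0;
    double p_rew = is_corr ? contingency : 1.0 - contingency;
    int win = (unif_rand() < p_rew) ? 1 : 0;
    choice[i] = chose_a; correct[i] = is_corr; rew[i] = win;

    double pc = chose_a ? p[s] : 1.0 - p[s];
    double outcome = win ? 1.0 : (signed_coding ? -1.0 : 0.0);
    double alpha = win ? par[0] : par[1];
    double rho   = win ? par[2] : par[3];
    pc += alpha * (rho * outcome - pc);
    if (pc < 0.0) pc = 0.0; else if (pc > 1.0) pc = 1.0;
    p[s] = chose_a ? pc : 1.0 - pc;
    last = win;
  }
  return List::create(_["choice_a"] = choice, _["is_correct"] = correct,
                      _["reward"] = rew);
}
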