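#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial engine for the two-network model. Mirrors the R reference
// loop built on step() exactly, including RNG consumption (one uniform per
// simulated trial), so that seed-aligned runs are bitwise comparable.
//
// Conventions: stimulus/action 0-based, action -1 = lapse (teacher mode),
// reward -1 = missing. Population index pop = s * n_a + a. The active set
// is returned as a bitmask (bit pop set), so n_s * n_a must be <= 31.
//
// [[Rcpp::export]]
List cn_engine(IntegerVector stimulus, IntegerVector action,
               IntegerVector reward, IntegerVector correct_action,
               LogicalVector noisy, int n_s, int n_a,
               double alpha, double beta, double epsilon,
               double qp, double qm, double g_i, double j_inc,
               bool with_inference, bool teacher, bool freeze_tn,
               NumericMatrix tn0) {
  const int T = stimulus.size();
  const int n_pop = n_s * n_a;
  std::vector<double> an(n_s * n_a, 0.0);          // an[s * n_a + a]
  std::vector<double> tn(n_pop * n_pop, 0.0);      // tn[from * n_pop + to]
  if (tn0.nrow() == n_pop && tn0.ncol() == n_pop)
    for (int i = 0; i < n_pop; ++i)
      for (int j = 0; j < n_pop; ++j)
        tn[i * n_pop + j] = tn0(i, j);

  IntegerVector out_action(T), out_reward(T), active_mask(T);
  LogicalVector out_correct(T);
  NumericVector p_action(T, NA_REAL), p_correct(T, NA_REAL),
      w_chosen(T, NA_REAL), inf_mag(T, 0.0);
  NumericMatrix p_mat(T, n_a);

  int prev = -1;  // previous trial's population, -1 = none
  std::vector<double> p(n_a);
  std::vector<int> frontier, nxt;
  std::vector<char> active(n_pop);

  for (int t = 0; t < T; ++t) {
    const int s = stimulus[t];
    // softmax with lapse mixture, log-sum-exp stabilized
    double m = -1e300;
    for (int a = 0; a < n_a; ++a)
      m = std::max(m, beta * an[s * n_a + a]);
    double Z = 0.0;
    for (int a = 0; a < n_a; ++a) {
      p[a] = std::exp(beta * an[s * n_a + a] - m);
      Z += p[a];
    }
    for (int a = 0; a < n_a; ++a) {
      p[a] = epsilon / n_a + (1.0 - epsilon) * p[a] / Z;
      p_mat(t, a) = p[a];
    }

    int a_t;
    if (teacher) {
      a_t = action[t];
      if (reward[t] < 0 || a_t < 0) {  // lapse: no updates, memory cleared
        out_action[t] = -1;
        out_reward[t] = -1;
        out_correct[t] = NA_LOGICAL;
        if (correct_action[t] >= 0) p_correct[t] = p[correct_action[t]];
        prev = -1;
        continue;
      }
    } else {
      const double u = unif_rand();
      double cum = 0.0;
      a_t = n_a - 1;
      for (int a = 0; a < n_a; ++a) {
        cum += p[a];
        if (u < cum) { a_t = a; break; }
      }
    }

    int r;
    bool correct = false;
    if (correct_action[t] >= 0) {
      correct = (a_t == correct_action[t]);
      p_correct[t] = p[correct_action[t]];
    }
    if (teacher) r = reward[t];
    else r = (correct != (bool)noisy[t]) ? 1 : 0;

    out_action[t] = a_t;
    out_reward[t] = r;
    out_correct[t] = correct;
    p_action[t] = p[a_t];
    w_chosen[t] = an[s * n_a + a_t];

    // AN plasticity (row-local, convex-combination soft bounds)
    for (int a = 0; a < n_a; ++a) {
      double &J = an[s * n_a + a];
      const bool chosen = (a == a_t);
      if ((r == 1) == chosen) J = alpha + (1.0 - alpha) * J;  // potentiate
      else J = (1.0 - alpha) * J;                             // depress
    }

    // TN activation closure from the realized conjunction,
    // start-of-trial weights
    const int curr = s * n_a + a_t;
    std::fill(active.begin(), active.end(), 0);
    active[curr] = 1;
    frontier.assign(1, curr);
    while (!frontier.empty()) {
      nxt.clear();
      for (size_t f = 0; f < frontier.size(); ++f) {
        const double *row = &tn[frontier[f] * n_pop];
        for (int k = 0; k < n_pop; ++k)
          if (!active[k] && row[k] >= g_i) {
            active[k] = 1;
            nxt.push_back(k);
          }
      }
      frontier.swap(nxt);
    }
    int mask = 0;
    for (int k = 0; k < n_pop; ++k)
      if (active[k]) mask |= (1 << k);
    active_mask[t] = mask;

    // TN temporal plasticity
    if (!freeze_tn) {
      double *row = &tn[curr * n_pop];
      for (int k = 0; k < n_pop; ++k) row[k] *= (1.0 - qm);
      if (prev >= 0 && prev != curr)
        tn[prev * n_pop + curr] = qp + (1.0 - qp) * tn[prev * n_pop + curr];
      tn[curr * n_pop + curr] = 0.0;
    }

    // inference signal: rewarded trials push AN weights of all active
    // conjunctions toward 1
    if (with_inference && r == 1) {
      double tot = 0.0;
      int cnt = 0;
      for (int k = 0; k < n_pop; ++k)
        if (active[k]) {
          const int ks = k / n_a, ka = k % n_a;
          double &J = an[ks * n_a + ka];
          tot += j_inc * (1.0 - J);
          J = j_inc + (1.0 - j_inc) * J;
          ++cnt;
        }
      inf_mag[t] = tot / cnt;
    }

    prev = curr;
  }

  NumericMatrix an_out(n_s, n_a), tn_out(n_pop, n_pop);
  for (int s = 0; s < n_s; ++s)
    for (int a = 0; a < n_a; ++a) an_out(s, a) = an[s * n_a + a];
  for (int i = 0; i < n_pop; ++i)
    for (int j = 0; j < n_pop; ++j) tn_out(i, j) = tn[i * n_pop + j];

  return List::create(
      _["action"] = out_action, _["reward"] = out_reward,
      _["correct"] = out_correct, _["p"] = p_mat,
      _["p_action"] = p_action, _["p_correct"] = p_correct,
      _["w_chosen"] = w_chosen, _["active_mask"] = active_mask,
      _["inference_magnitude"] = inf_mag,
      _["an"] = an_out, _["tn"] = tn_out);
}

// Fast negative log-likelihood of recorded actions under teacher forcing.
// Identical state dynamics to cn_engine in teacher mode, without trace
// allocation; lapse trials contribute nothing and clear the pair memory.
//
// [[Rcpp::export]]
double cn_nll(IntegerVector stimulus, IntegerVector action,
              IntegerVector reward, int n_s, int n_a,
              double alpha, double beta, double epsilon,
              double qp, double qm, double g_i, double j_inc,
              bool with_inference) {
  const int T = stimulus.size();
  const int n_pop = n_s * n_a;
  std::vector<double> an(n_s * n_a, 0.0);
  std::vector<double> tn(n_pop * n_pop, 0.0);
  std::vector<double> p(n_a);
  std::vector<int> frontier, nxt;
  std::vector<char> active(n_pop);
  int prev = -1;
  double nll = 0.0;

  for (int t = 0; t < T; ++t) {
    const int s = stimulus[t];
    const int a_t = action[t];
    double m = -1e300;
    for (int a = 0; a < n_a; ++a)
      m = std::max(m, beta * an[s * n_a + a]);
    double Z = 0.0;
    for (int a = 0; a < n_a; ++a) {
      p[a] = std::exp(beta * an[s * n_a + a] - m);
      Z += p[a];
    }
    if (a_t < 0 || reward[t] < 0) { prev = -1; continue; }
    nll -= std::log(epsilon / n_a + (1.0 - epsilon) * p[a_t] / Z);

    const int r = reward[t];
    for (int a = 0; a < n_a; ++a) {
      double &J = an[s * n_a + a];
      const bool chosen = (a == a_t);
      if ((r == 1) == chosen) J = alpha + (1.0 - alpha) * J;
      else J = (1.0 - alpha) * J;
    }

    const int curr = s * n_a + a_t;
    const bool need_closure = with_inference && r == 1 && j_inc > 0.0;
    if (need_closure) {
      std::fill(active.begin(), active.end(), 0);
      active[curr] = 1;
      frontier.assign(1, curr);
      while (!frontier.empty()) {
        nxt.clear();
        for (size_t f = 0; f < frontier.size(); ++f) {
          const double *row = &tn[frontier[f] * n_pop];
          for (int k = 0; k < n_pop; ++k)
            if (!active[k] && row[k] >= g_i) {
              active[k] = 1;
              nxt.push_back(k);
            }
        }
        frontier.swap(nxt);
      }
    }

    if (qp > 0.0 || qm > 0.0) {
      double *row = &tn[curr * n_pop];
      for (int k = 0; k < n_pop; ++k) row[k] *= (1.0 - qm);
      if (prev >= 0 && prev != curr)
        tn[prev * n_pop + curr] = qp + (1.0 - qp) * tn[prev * n_pop + curr];
      tn[curr * n_pop + curr] = 0.0;
    }

    if (need_closure) {
      for (int k = 0; k < n_pop; ++k)
        if (active[k]) {
          double &J = an[(k / n_a) * n_a + (k % n_a)];
          J = j_inc + (1.0 - j_inc) * J;
        }
    }

    prev = curr;
  }
  return nll;
}
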