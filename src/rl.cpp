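#include <Rcpp.h>
using namespace Rcpp;

// Model codes shared with R/models.R (.model_code):
//   0 baseline, 1 double_two_pe, 2 double_one_pe, 3 select_reject
//
// Parameter slot layout (natural scale), uniform across models:
//   par[0] = alpha_chosen (select_reject: the shared alpha)
//   par[1] = alpha_unchosen (select_reject: omega; baseline: ignored)
//   par[2] = beta
//
// Arms are 0-based. A choice of -1 marks a no-response trial: it contributes
// no likelihood and triggers no update.

#define MAX_ARMS 16

struct QState {
  double qs[MAX_ARMS]; // plain Q (baseline/double) or Q-select
  double qr[MAX_ARMS]; // Q-reject (select_reject only)
};

static inline void st_init(QState &st, int n_arms) {
  for (int a = 0; a < n_arms; ++a) { st.qs[a] = 0.5; st.qr[a] = 0.5; }
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// probability that arm a is chosen when offered against arm b
static inline double st_prob(int model, const QState &st, int a, int b,
                             const double *par) {
  double beta = par[2];
  double va, vb;
  if (model == 3) {
    double w = par[1];
    va = w * st.qs[a] + (1.0 - w) * st.qr[b];
    vb = w * st.qs[b] + (1.0 - w) * st.qr[a];
  } else {
    va = st.qs[a];
    vb = st.qs[b];
  }
  return 1.0 / (1.0 + std::exp(-beta * (va - vb)));
}

static inline void st_update(int model, QState &st, int ch, int un, int r,
                             const double *par) {
  double a1 = par[0], a2 = par[1], d;
  switch (model) {
  case 0: // baseline: chosen arm only
    st.qs[ch] += a1 * (r - st.qs[ch]);
    break;
  case 1: // double updating, two prediction errors (inverted outcome)
    st.qs[ch] += a1 * (r - st.qs[ch]);
    st.qs[un] += a2 * ((1 - r) - st.qs[un]);
    break;
  case 2: // double updating, one prediction error (inverted portion of delta)
    d = r - st.qs[ch];
    st.qs[ch] += a1 * d;
    st.qs[un] += a2 * (-d);
    break;
  case 3: // select-reject: both ledgers move toward the observed reward
    st.qs[ch] += a1 * (r - st.qs[ch]);
    st.qr[un] += a1 * (r - st.qr[un]);
    break;
  }
  // truncation rule: values are clamped into [0,1] (only double_one_pe can
  // actually leave the interval, but the clamp is applied uniformly)
  st.qs[ch] = clamp01(st.qs[ch]); st.qs[un] = clamp01(st.qs[un]);
  st.qr[ch] = clamp01(st.qr[ch]); st.qr[un] = clamp01(st.qr[un]);
}

// [[Rcpp::export]]
NumericVector cpp_block_loglik(int model, NumericVector par,
                               IntegerVector offer_a, IntegerVector offer_b,
                               IntegerVector choice, IntegerVector reward,
                               int n_arms) {
  int T = offer_a.size();
  NumericVector out(T);
  QState st;
  st_init(st, n_arms);
  double p[3] = {par[0], par[1], par[2]};
  for (int t = 0; t < T; ++t) {
    int a = offer_a[t], b = offer_b[t], ch = choice[t];
    if (ch < 0) { out[t] = NA_REAL; continue; }
    int un = (ch == a) ? b : a;
    double pr = st_prob(model, st, ch, un, p);
    out[t] = std::log(pr);
    st_update(model, st, ch, un, reward[t], p);
  }
  return out;
}

// Summed log-likelihood per participant over an entire (multi-block) record
// stream. `pid` is the 0-based participant index per trial, `new_block`
// marks trials at which the Q state is re-initialized.
// [[Rcpp::export]]
NumericVector cpp_cohort_loglik(int model, NumericMatrix theta,
                                IntegerVector offer_a, IntegerVector offer_b,
                                IntegerVector choice, IntegerVector reward,
                                IntegerVector pid, IntegerVector new_block,
                                int n_arms) {
  int T = offer_a.size(), n = theta.nrow();
  NumericVector out(n);
  QState st;
  double p[3] = {0, 0, 0};
  int cur = -1;
  for (int t = 0; t < T; ++t) {
    int i = pid[t];
    if (i != cur) {
      cur = i;
      p[0] = theta(i, 0); p[1] = theta(i, 1); p[2] = theta(i, 2);
    }
    if (new_block[t]) st_init(st, n_arms);
    int a = offer_a[t], b = offer_b[t], ch = choice[t];
    if (ch < 0) continue;
    int un = (ch == a) ? b : a;
    out[i] += std::log(st_prob(model, st, ch, un, p));
    st_update(model, st, ch, un, reward[t], p);
  }
  return out;
}

// Pointwise expected log predictive density for one held-out block:
// elpd_t = log( (1/S) * sum_s p(choice_t | theta_s) ), with the state run
// teacher-forced through the block separately for every draw.
// [[Rcpp::export]]
NumericVector cpp_block_elpd(int model, NumericMatrix draws,
                             IntegerVector offer_a, IntegerVector offer_b,
                             IntegerVector choice, IntegerVector reward,
                             int n_arms) {
  int T = offer_a.size(), S = draws.nrow();
  std::vector<double> psum(T, 0.0);
  QState st;
  for (int s = 0; s < S; ++s) {
    double p[3] = {draws(s, 0), draws(s, 1), draws(s, 2)};
    st_init(st, n_arms);
    for (int t = 0; t < T; ++t) {
      int a = offer_a[t], b = offer_b[t], ch = choice[t];
      if (ch < 0) continue;
      int un = (ch == a) ? b : a;
      psum[t] += st_prob(model, st, ch, un, p);
      st_update(model, st, ch, un, reward[t], p);
    }
  }
  NumericVector out(T);
  for (int t = 0; t < T; ++t)
    out[t] = (choice[t] < 0) ? NA_REAL : std::log(psum[t] / S);
  return out;
}

// Forward simulation of one block. Uses R's RNG so that set.seed() in R
// makes runs bit-identical. pmat is trials x arms true reward probability.
// [[Rcpp::export]]
List cpp_simulate_block(int model, NumericVector par, NumericMatrix pmat,
                        IntegerVector offer_a, IntegerVector offer_b) {
  int T = offer_a.size();
  int n_arms = pmat.ncol();
  IntegerVector choice(T), reward(T);
  QState st;
  st_init(st, n_arms);
  double p[3] = {par[0], par[1], par[2]};
  RNGScope scope;
  for (int t = 0; t < T; ++t) {
    int a = offer_a[t], b = offer_b[t];
    double pr_a = st_prob(model, st, a, b, p);
    int ch = (unif_rand() < pr_a) ? a : b;
    int un = (ch == a) ? b : a;
    int r = (unif_rand() < pmat(t, ch)) ? 1 : 0;
    choice[t] = ch;
    reward[t] = r;
    st_update(model, st, ch, un, r, p);
  }
  return List::create(_["choice"] = choice, _["reward01"] = reward);
}
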