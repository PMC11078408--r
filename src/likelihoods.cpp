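// Joint choice + response-time likelihoods for all model variants.
// These replay the learning recursion deterministically from the observed
// (state, action, reward) stream; the R-level agent functions are the
// reference implementation and the test suite asserts exact agreement.

#include <Rcpp.h>
using namespace Rcpp;

static const double ALPHA_XI = 0.01;
static const double ALPHA_RHO = 0.01;
static const double SIGMA = 0.9;
static const double T0 = 150.0;
static const double SV = 0.1;
static const double BETA_WM = 50.0;
static const double BETA_MAX = 100.0;
static const double PA_FLOOR = 1e-6;
static const double RT_FLOOR = 1.0;
static const double R_GAP_MIN = 1e-3;
static const double A_FLOOR = 1e-3;
// per-trial density floor for data the LBA deems impossible (rt <= t0) or
// vanishingly unlikely; keeps the objective finite so optimization can
// proceed while still penalizing such trials by ~23 nats each
static const double LBA_DENS_FLOOR = 1e-10;
static const double BIG = 1e10;

// variant codes (must match the R model registry)
enum { FIXED_1B = 1, FIXED_6B, ADAPT_C, ADAPT_V, ADAPT_CV };
enum { STD_RL_1B = 1, STD_RL_6B, RLWM };

static inline void softmax3(const double* logits, int n, double* out) {
  double m = logits[0];
  for (int i = 1; i < n; i++) if (logits[i] > m) m = logits[i];
  double z = 0.0;
  for (int i = 0; i < n; i++) { out[i] = std::exp(logits[i] - m); z += out[i]; }
  for (int i = 0; i < n; i++) out[i] /= z;
}

// log-softmax computed without underflow so log-probabilities stay finite
static inline void log_softmax(const double* logits, int n, double* out) {
  double m = logits[0];
  for (int i = 1; i < n; i++) if (logits[i] > m) m = logits[i];
  double z = 0.0;
  for (int i = 0; i < n; i++) z += std::exp(logits[i] - m);
  const double lse = m + std::log(z);
  for (int i = 0; i < n; i++) out[i] = logits[i] - lse;
}

// overflow guard far outside any sane learning trajectory; keeps the
// likelihood finite (and merely very bad) in pathological parameter corners
static const double STATE_CLAMP = 1e3;
static inline double clamp_state(double x) {
  if (x > STATE_CLAMP) return STATE_CLAMP;
  if (x < -STATE_CLAMP) return -STATE_CLAMP;
  return x;
}

// [[Rcpp::export]]
double nll_compression_cpp(int variant, NumericVector par,
                           IntegerVector state, IntegerVector action,
                           NumericVector reward, NumericVector rt,
                           IntegerVector block_start, IntegerVector tp,
                           IntegerVector cell, int n_states, int n_actions) {
  const int n = state.size();
  // unpack parameters by variant-specific position
  double betas6[6] = {0, 0, 0, 0, 0, 0};
  double C = 0, Cr = 0, Rasp = 0, Rr = 0, beta0 = 0, a_b = 0;
  double a_t, a_V, a_P, b1, b2;
  int k = 0;
  switch (variant) {
  case FIXED_1B:
    beta0 = par[k++]; break;
  case FIXED_6B:
    for (int i = 0; i < 6; i++) betas6[i] = par[k++]; break;
  case ADAPT_C:
    C = par[k++]; Cr = par[k++]; beta0 = par[k++]; a_b = par[k++]; break;
  case ADAPT_V:
    Rasp = par[k++]; Rr = par[k++]; beta0 = par[k++]; a_b = par[k++]; break;
  case ADAPT_CV:
    C = par[k++]; Cr = par[k++]; Rasp = par[k++]; beta0 = par[k++];
    a_b = par[k++]; break;
  default: stop("unknown compression variant");
  }
  a_t = par[k++]; a_V = par[k++]; a_P = par[k++]; b1 = par[k++]; b2 = par[k++];

  std::vector<double> theta(n_states * n_actions), vhat(n_states),
      pa(n_actions), pi(n_actions), logpi(n_actions), logits(n_actions);
  double xi = 0, rho = 0, beta = 0, nll = 0;

  for (int t = 0; t < n; t++) {
    if (block_start[t]) {
      std::fill(theta.begin(), theta.end(), 0.0);
      std::fill(vhat.begin(), vhat.end(), 0.0);
      std::fill(pa.begin(), pa.end(), 1.0 / n_actions);
      xi = 0; rho = 0;
      beta = (variant == FIXED_6B) ? betas6[cell[t] - 1] : beta0;
    }
    const int s = state[t];
    const int a = action[t];
    for (int i = 0; i < n_actions; i++)
      logits[i] = beta * theta[s * n_actions + i] + std::log(pa[i]);
    log_softmax(&logits[0], n_actions, &logpi[0]);
    for (int i = 0; i < n_actions; i++) pi[i] = std::exp(logpi[i]);
    if (a < 0) continue; // missed trial: no likelihood term, no learning

    const double cost = logpi[a] - std::log(pa[a]);
    double H = 0;
    for (int i = 0; i < n_actions; i++)
      if (pi[i] > 0) H -= pi[i] * logpi[i];

    // choice likelihood
    nll -= logpi[a];
    // RT likelihood: lognormal in ms around the regression mean
    double inner = T0 + b1 * cost + b2 * H;
    double mu = std::log(std::max(RT_FLOOR, inner));
    double lrt = std::log(rt[t]);
    nll -= R::dnorm(lrt, mu, SIGMA, 1) - lrt;

    // learning update (pre-update policy throughout)
    const double r = reward[t];
    const double delta = beta * r - cost - vhat[s];
    for (int i = 0; i < n_actions; i++) {
      double g = (i == a) ? a_t * delta * (1.0 - pi[a]) * beta
                          : -a_t * delta * pi[i] * beta;
      theta[s * n_actions + i] = clamp_state(theta[s * n_actions + i] + g);
    }
    vhat[s] = clamp_state(vhat[s] + a_V * delta);
    double z = 0;
    for (int i = 0; i < n_actions; i++) {
      pa[i] += a_P * (pi[i] - pa[i]);
      if (pa[i] < PA_FLOOR) pa[i] = PA_FLOOR;
      z += pa[i];
    }
    for (int i = 0; i < n_actions; i++) pa[i] /= z;
    xi += ALPHA_XI * (cost - xi);
    rho += ALPHA_RHO * (r - rho);

    if (variant == ADAPT_C) {
      beta += a_b * ((tp[t] ? Cr : C) - xi);
    } else if (variant == ADAPT_V) {
      beta += a_b * ((tp[t] ? Rr : Rasp) - rho);
    } else if (variant == ADAPT_CV) {
      double gap = Rasp - rho;
      if (std::fabs(gap) < R_GAP_MIN)
        gap = (gap < 0) ? -R_GAP_MIN : R_GAP_MIN;
      beta += a_b * (((tp[t] ? Cr : C) - xi) / gap - beta);
    }
    if (variant >= ADAPT_C) {
      if (beta < 0) beta = 0;
      if (beta > BETA_MAX) beta = BETA_MAX;
    }
  }
  if (!std::isfinite(nll)) return BIG;
  return nll;
}

static inline double lba_pdf1(double t, double v, double A, double b) {
  if (A < A_FLOOR) A = A_FLOOR;
  const double ts = t * SV;
  const double z1 = (b - A - t * v) / ts;
  const double z2 = (b - t * v) / ts;
  double d = (-v * R::pnorm(z1, 0, 1, 1, 0) + SV * R::dnorm(z1, 0, 1, 0) +
              v * R::pnorm(z2, 0, 1, 1, 0) - SV * R::dnorm(z2, 0, 1, 0)) / A;
  return d > 0 ? d : 0.0;
}

static inline double lba_cdf1(double t, double v, double A, double b) {
  if (A < A_FLOOR) A = A_FLOOR;
  const double ts = t * SV;
  const double z1 = (b - A - t * v) / ts;
  const double z2 = (b - t * v) / ts;
  double p = 1.0 + ((b - A - t * v) / A) * R::pnorm(z1, 0, 1, 1, 0) -
             ((b - t * v) / A) * R::pnorm(z2, 0, 1, 1, 0) +
             (ts / A) * R::dnorm(z1, 0, 1, 0) - (ts / A) * R::dnorm(z2, 0, 1, 0);
  if (p < 0) p = 0;
  if (p > 1) p = 1;
  return p;
}

// [[Rcpp::export]]
double nll_lba_cpp(int variant, NumericVector par,
                   IntegerVector state, IntegerVector action,
                   NumericVector reward, NumericVector rt,
                   IntegerVector block_start, IntegerVector tp,
                   IntegerVector cell, int n_states, int n_actions) {
  const int n = state.size();
  double betas6[6] = {0, 0, 0, 0, 0, 0};
  double beta1 = 0, aQ = 0;
  double Cwm = 0, aRL = 0, phi = 0, rho_wm = 0, gam = 0;
  double A, B1mA, B2mA, eta;
  int k = 0;
  switch (variant) {
  case STD_RL_1B: beta1 = par[k++]; aQ = par[k++]; break;
  case STD_RL_6B:
    for (int i = 0; i < 6; i++) betas6[i] = par[k++];
    aQ = par[k++]; break;
  case RLWM:
    Cwm = par[k++]; aRL = par[k++]; phi = par[k++]; rho_wm = par[k++];
    gam = par[k++]; break;
  default: stop("unknown LBA variant");
  }
  A = par[k++]; B1mA = par[k++]; B2mA = par[k++]; eta = par[k++];

  std::vector<double> Q(n_states * n_actions), W(n_states * n_actions),
      pol(n_states * n_actions), row(n_actions), v(n_actions);
  const double w0 = 1.0 / n_actions;
  double nll = 0;

  for (int t = 0; t < n; t++) {
    if (block_start[t]) {
      std::fill(Q.begin(), Q.end(), 0.0);
      std::fill(W.begin(), W.end(), w0);
    }
    const int s = state[t];
    const int a = action[t];

    // current policy for every state (needed for the prior-uncertainty term)
    for (int si = 0; si < n_states; si++) {
      if (variant == RLWM) {
        double mixw = rho_wm * std::min(1.0, Cwm / n_states);
        double pwm[8], prl[8], lg[8];
        for (int i = 0; i < n_actions; i++) lg[i] = BETA_WM * W[si * n_actions + i];
        softmax3(lg, n_actions, pwm);
        for (int i = 0; i < n_actions; i++) lg[i] = BETA_WM * Q[si * n_actions + i];
        softmax3(lg, n_actions, prl);
        for (int i = 0; i < n_actions; i++)
          pol[si * n_actions + i] = mixw * pwm[i] + (1.0 - mixw) * prl[i];
      } else {
        double beta = (variant == STD_RL_6B) ? betas6[cell[t] - 1] : beta1;
        double lg[8];
        for (int i = 0; i < n_actions; i++) lg[i] = beta * Q[si * n_actions + i];
        softmax3(lg, n_actions, &pol[si * n_actions]);
      }
    }
    if (a < 0) continue;

    double hprior = 0;
    for (int i = 0; i < n_actions; i++) {
      double m = 0;
      for (int si = 0; si < n_states; si++) m += pol[si * n_actions + i];
      m /= n_states;
      if (m > 0) hprior -= m * std::log2(m);
    }
    if (hprior < A_FLOOR) hprior = A_FLOOR;
    for (int i = 0; i < n_actions; i++)
      v[i] = eta * pol[s * n_actions + i] / hprior;

    const double b = A + (tp[t] ? B2mA : B1mA);
    const double dt = rt[t] - T0;
    double dens = 0.0;
    if (dt > 0) {
      dens = lba_pdf1(dt, v[a], A, b);
      for (int i = 0; i < n_actions; i++)
        if (i != a) dens *= 1.0 - lba_cdf1(dt, v[i], A, b);
      double p_any = 1.0;
      for (int i = 0; i < n_actions; i++)
        p_any *= R::pnorm(-v[i] / SV, 0, 1, 1, 0);
      dens /= std::max(1.0 - p_any, 1e-300);
    }
    nll -= std::log(std::max(dens, LBA_DENS_FLOOR));

    // learning
    const double r = reward[t];
    if (variant == RLWM) {
      for (int i = 0; i < n_states * n_actions; i++) W[i] += phi * (w0 - W[i]);
      const double scale = (r == 0.0) ? gam : 1.0;
      Q[s * n_actions + a] += scale * aRL * (r - Q[s * n_actions + a]);
      W[s * n_actions + a] += scale * 1.0 * (r - W[s * n_actions + a]);
    } else {
      Q[s * n_actions + a] += aQ * (r - Q[s * n_actions + a]);
    }
  }
  if (!std::isfinite(nll)) return BIG;
  return nll;
}
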