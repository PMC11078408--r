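# Non-compression comparison models: Standard RL and RLWM value learning,
# with Linear Ballistic Accumulator (LBA) choice/RT generation and the
# defective first-passage density used for their joint likelihood.

#' Initialize the learning state of a baseline agent
#'
#' Q-values start at zero; the RLWM association matrix starts at its decay
#' target W0 = 1/n_actions.
#'
#' @param model_id "std_rl_1b", "std_rl_6b" or "rlwm"
#' @param n_states,n_actions task dimensions
#' @return list with `q` and (RLWM only) `w_assoc`
#' @export
baseline_init <- function(model_id, n_states = 3L, n_actions = 3L) {
  model_id <- match.arg(model_id, LBA_MODELS)
  st <- list(q = matrix(0, n_states, n_actions))
  if (model_id == "rlwm")
    st$w_assoc <- matrix(1 / n_actions, n_states, n_actions)
  st
}

#' Delta-rule update of the Standard RL agent
#'
#' @param state baseline agent state
#' @param params parameter vector (uses `alpha_Q`)
#' @param s,a 0-based state and action
#' @param r binary reward
#' @return updated state
#' @export
standard_rl_learn <- function(state, params, s, a, r) {
  si <- s + 1L; ai <- a + 1L
  state$q[si, ai] <- state$q[si, ai] + params[["alpha_Q"]] * (r - state$q[si, ai])
  state
}

#' Softmax policy of the Standard RL agent
#'
#' @param state baseline agent state
#' @param beta inverse temperature
#' @param s 0-based state
#' @return probability vector over actions
#' @export
standard_rl_policy <- function(state, beta, s) {
  softmax_row(beta * state$q[s + 1L, ])
}

softmax_row <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

#' RLWM learning update
#'
#' All working-memory associations first decay toward W0 = 1/n_actions at
#' rate phi; then the visited cell is updated in both modules, with the WM
#' learning rate fixed at 1 and both learning rates scaled by gamma on
#' "incorrect" (r = 0) feedback.
#'
#' @param state baseline agent state (with `w_assoc`)
#' @param params parameter vector (uses `alpha_RL`, `phi`, `gamma`)
#' @param s,a 0-based state and action
#' @param r binary reward
#' @return updated state
#' @export
rlwm_learn <- function(state, params, s, a, r) {
  si <- s + 1L; ai <- a + 1L
  w0 <- 1 / ncol(state$w_assoc)
  state$w_assoc <- state$w_assoc + params[["phi"]] * (w0 - state$w_assoc)
  scale <- if (r == 0) params[["gamma"]] else 1
  a_rl <- scale * params[["alpha_RL"]]
  a_wm <- scale * 1
  state$q[si, ai] <- state$q[si, ai] + a_rl * (r - state$q[si, ai])
  state$w_assoc[si, ai] <- state$w_assoc[si, ai] + a_wm * (r - state$w_assoc[si, ai])
  state
}

#' Mixture policy of the RLWM agent
#'
#' Weighted sum of the WM and RL softmax policies with weight
#' w = rho_wm * min(1, C_wm / n_S); both softmax temperatures are fixed at 50.
#'
#' @param state baseline agent state
#' @param params parameter vector (uses `C_wm`, `rho_wm`)
#' @param s 0-based state
#' @return probability vector over actions
#' @export
rlwm_policy <- function(state, params, s) {
  n_s <- nrow(state$q)
  w <- params[["rho_wm"]] * min(1, params[["C_wm"]] / n_s)
  p_wm <- softmax_row(POLCOMP_CONST$beta_wm * state$w_assoc[s + 1L, ])
  p_rl <- softmax_row(POLCOMP_CONST$beta_rl * state$q[s + 1L, ])
  w * p_wm + (1 - w) * p_rl
}

#' LBA drift rates from a policy
#'
#' The prior-uncertainty term is the base-2 entropy of the state-averaged
#' policy; each accumulator's mean drift is eta * pi(a|s) / H_prior, so
#' higher prior uncertainty slows all accumulators equally. H_prior is
#' floored to avoid division blow-up when the average policy is degenerate.
#'
#' @param policy_vec action probabilities in the current state
#' @param avg_policy state-averaged action probabilities
#' @param params parameter vector (uses `eta`)
#' @return vector of mean drift rates
#' @export
lba_drift_rates <- function(policy_vec, avg_policy, params) {
  h <- -sum(ifelse(avg_policy > 0, avg_policy * log2(avg_policy), 0))
  params[["eta"]] * policy_vec / max(h, POLCOMP_CONST$lba_A_floor)
}

lba_bound <- function(params, time_pressure) {
  params[["A"]] +
    if (time_pressure) params[["B2_minus_A"]] else params[["B1_minus_A"]]
}

#' Simulate one LBA race
#'
#' Start points are uniform on \[0, A\]; drift rates are drawn from
#' N(v_i, s_v) and redrawn until at least one is positive so that a winner
#' exists; the winner is the accumulator that reaches the bound first, with
#' RT = t0 + (B - k) / d. Races slower than the deadline are resampled.
#'
#' @param v mean drift rates
#' @param params parameter vector (uses `A` and the bound offsets)
#' @param time_pressure TRUE selects the B2 bound (task3/Q2)
#' @param deadline_ms response deadline
#' @param max_tries resampling cap
#' @return list with `action` (0-based) and `rt_ms`
#' @export
lba_sample <- function(v, params, time_pressure = FALSE, deadline_ms = 2000,
                       max_tries = 1000L) {
  b <- lba_bound(params, time_pressure)
  A <- params[["A"]]
  sv <- POLCOMP_CONST$s_v
  n <- length(v)
  best <- NULL
  for (i in seq_len(max_tries)) {
    repeat {
      d <- rnorm(n, v, sv)
      if (any(d > 0)) break
    }
    k <- runif(n, 0, A)
    tt <- ifelse(d > 0, POLCOMP_CONST$t0 + (b - k) / d, Inf)
    w <- which.min(tt)
    if (is.null(best) || tt[w] < best$rt_ms) best <- list(action = w - 1L, rt_ms = tt[w])
    if (tt[w] <= deadline_ms)
      return(list(action = w - 1L, rt_ms = tt[w]))
  }
  best$rt_ms <- min(best$rt_ms, deadline_ms)
  best
}

# First-passage density and CDF of a single LBA accumulator at decision
# time t (ms after non-decision time), start U[0,A], drift N(v, sv),
# threshold b. Standard closed forms.
lba_pdf1 <- function(t, v, A, b, sv) {
  A <- max(A, POLCOMP_CONST$lba_A_floor)
  z1 <- (b - A - t * v) / (t * sv)
  z2 <- (b - t * v) / (t * sv)
  pmax(0, (-v * pnorm(z1) + sv * dnorm(z1) + v * pnorm(z2) - sv * dnorm(z2)) / A)
}

lba_cdf1 <- function(t, v, A, b, sv) {
  A <- max(A, POLCOMP_CONST$lba_A_floor)
  z1 <- (b - A - t * v) / (t * sv)
  z2 <- (b - t * v) / (t * sv)
  p <- 1 + ((b - A - t * v) / A) * pnorm(z1) - ((b - t * v) / A) * pnorm(z2) +
    (t * sv / A) * dnorm(z1) - (t * sv / A) * dnorm(z2)
  pmin(1, pmax(0, p))
}

#' Joint log-density of an LBA choice and response time
#'
#' Defective density of the winning accumulator: its first-passage density
#' times the survivor functions of the losers, normalized by the probability
#' that at least one drift draw is positive (matching the resampling scheme
#' of [lba_sample()]). RTs at or below the non-decision time are impossible.
#'
#' @param action 0-based chosen action
#' @param rt_ms observed RT in ms
#' @param v mean drift rates
#' @param params parameter vector
#' @param time_pressure TRUE selects the B2 bound
#' @return log-density (`-Inf` for rt <= t0)
#' @export
lba_loglik <- function(action, rt_ms, v, params, time_pressure = FALSE) {
  t <- rt_ms - POLCOMP_CONST$t0
  if (t <= 0) return(-Inf)
  A <- params[["A"]]
  b <- lba_bound(params, time_pressure)
  sv <- POLCOMP_CONST$s_v
  dens <- lba_pdf1(t, v[action + 1L], A, b, sv)
  for (j in seq_along(v)[-(action + 1L)])
    dens <- dens * (1 - lba_cdf1(t, v[j], A, b, sv))
  p_any <- 1 - prod(pnorm(-v / sv))
  log(dens) - log(p_any)
}
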