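# Cost-sensitive actor-critic process model ("policy compression" agent).
# This is the reference R implementation; the compiled likelihood in
# src/likelihoods.cpp replays exactly the same recursion and is tested
# against it.

#' Initialize the learning state of a compression agent
#'
#' Propensities, critic and running estimates start at zero; the marginal
#' action estimate starts uniform; beta starts at the fitted fixed beta
#' (per-condition for the 6-beta variant) or at beta0 for adaptive variants.
#'
#' @param model_id a compression model id
#' @param params named parameter vector (see [model_spec()])
#' @param block canonical block index in 1..6 (selects the beta of the
#'   6-beta variant)
#' @param n_states,n_actions dimensions of the task
#' @return agent state: list with `theta`, `v_hat`, `p_a`, `xi`, `rho`, `beta`
#' @export
compression_init <- function(model_id, params, block = 1L,
                             n_states = 3L, n_actions = 3L) {
  model_id <- match.arg(model_id, COMPRESSION_MODELS)
  beta0 <- switch(model_id,
    fixed_1b = params[["beta"]],
    fixed_6b = params[[paste0("beta", block)]],
    params[["beta0"]])
  list(theta = matrix(0, n_states, n_actions),
       v_hat = rep(0, n_states),
       p_a = rep(1 / n_actions, n_actions),
       xi = 0, rho = 0, beta = beta0)
}

#' Action distribution of the compression agent in a state
#'
#' Softmax of beta * theta\[s,\] + log P(a): the learned analogue of the
#' optimal capacity-limited policy, with propensities in place of Q-values.
#'
#' @param state agent state from [compression_init()]
#' @param s 0-based state index
#' @return probability vector over actions
#' @export
compression_policy <- function(state, s) {
  exp(compression_log_policy(state, s))
}

#' @rdname compression_policy
#' @export
compression_log_policy <- function(state, s) {
  logits <- state$beta * state$theta[s + 1L, ] + log(state$p_a)
  m <- max(logits)
  logits - m - log(sum(exp(logits - m)))
}

#' Per-trial policy cost
#'
#' log pi(a|s) - log P(a), in nats; its expectation over the joint state,
#' action distribution is the policy complexity. Negative when the chosen
#' action is less probable in this state than marginally.
#'
#' @param state agent state
#' @param s 0-based state
#' @param a 0-based action
#' @return cost in nats
#' @export
trial_cost <- function(state, s, a) {
  compression_log_policy(state, s)[a + 1L] - log(state$p_a[a + 1L])
}

#' Entropy of the agent's policy in a state
#'
#' @param state agent state
#' @param s 0-based state
#' @return Shannon entropy in nats
#' @export
policy_entropy <- function(state, s) {
  lp <- compression_log_policy(state, s)
  p <- exp(lp)
  -sum(ifelse(p > 0, p * lp, 0))
}

#' One learning update of the compression agent
#'
#' Applies, in order and all using the pre-update policy: the cost-sensitive
#' prediction error delta = beta * r - cost - V(s); the policy-gradient
#' propensity update (chosen action + alpha_theta * delta * (1 - pi) * beta,
#' unchosen - alpha_theta * delta * pi * beta); the critic update; the
#' exponential-moving-average update of the marginal action estimate toward
#' the current policy row (then floored and renormalized); the running
#' complexity (xi) and reward (rho) estimates; and the variant-specific beta
#' update. In the time-pressure block the capacity/aspiration targets are
#' replaced by their reduced counterparts.
#'
#' @param state agent state
#' @param model_id compression model id
#' @param params named parameter vector
#' @param s,a 0-based state and action (a must not be NA)
#' @param r binary reward
#' @param time_pressure TRUE in the task3/Q2 block
#' @return updated agent state
#' @export
compression_learn <- function(state, model_id, params, s, a, r,
                              time_pressure = FALSE) {
  if (is.na(a)) stop("missed trials produce no learning update")
  si <- s + 1L; ai <- a + 1L
  lp <- compression_log_policy(state, s)
  pi_s <- exp(lp)
  cost <- lp[ai] - log(state$p_a[ai])
  delta <- state$beta * r - cost - state$v_hat[si]

  grad <- -params[["alpha_theta"]] * delta * pi_s * state$beta
  grad[ai] <- params[["alpha_theta"]] * delta * (1 - pi_s[ai]) * state$beta
  # overflow guard far outside any sane trajectory (matches the compiled path)
  state$theta[si, ] <- pmin(pmax(state$theta[si, ] + grad, -1e3), 1e3)

  state$v_hat[si] <- min(max(state$v_hat[si] + params[["alpha_V"]] * delta, -1e3), 1e3)

  p_a <- state$p_a + params[["alpha_P"]] * (pi_s - state$p_a)
  p_a <- pmax(p_a, POLCOMP_CONST$p_a_floor)
  state$p_a <- p_a / sum(p_a)

  state$xi <- state$xi + POLCOMP_CONST$alpha_xi * (cost - state$xi)
  state$rho <- state$rho + POLCOMP_CONST$alpha_rho * (r - state$rho)

  state$beta <- update_beta(state, model_id, params, time_pressure)
  state
}

update_beta <- function(state, model_id, params, time_pressure) {
  beta <- state$beta
  if (model_id %in% c("fixed_1b", "fixed_6b")) return(beta)
  ab <- params[["alpha_beta"]]
  if (model_id == "adaptive_capacity") {
    C <- if (time_pressure) params[["C_reduced"]] else params[["C"]]
    beta <- beta + ab * (C - state$xi)
  } else if (model_id == "adaptive_value") {
    R <- if (time_pressure) params[["R_reduced"]] else params[["R"]]
    beta <- beta + ab * (R - state$rho)
  } else { # adaptive_capacity_value
    C <- if (time_pressure) params[["C_reduced"]] else params[["C"]]
    gap <- params[["R"]] - state$rho
    if (abs(gap) < POLCOMP_CONST$r_gap_min)
      gap <- sign(gap + (gap == 0)) * POLCOMP_CONST$r_gap_min
    beta <- beta + ab * ((C - state$xi) / gap - beta)
  }
  min(max(beta, 0), POLCOMP_CONST$beta_max)
}

# Mean of log RT implied by the RT regression; inner term floored so the
# logarithm stays defined when the cost term is negative enough.
rt_log_mean <- function(params, cost, H) {
  inner <- POLCOMP_CONST$t0 + params[["b1"]] * cost + params[["b2"]] * H
  log(max(POLCOMP_CONST$rt_floor_ms, inner))
}

#' Sample a response time for a chosen action
#'
#' log RT = log(t0 + b1 * cost + b2 * H) + eps with eps ~ N(0, sigma^2),
#' sigma = 0.9. When `truncate` is TRUE (the default, used by the session
#' simulator) draws exceeding the deadline are resampled, so simulated
#' agents always respond in time. Draws are not truncated from below: the
#' lognormal noise can produce responses faster than the accumulator
#' models' non-decision time, and the heavy penalty such trials incur under
#' the LBA likelihood is a genuine discriminating signal between the model
#' classes.
#'
#' @param state agent state
#' @param params parameter vector (uses `b1`, `b2`)
#' @param s,a 0-based state and chosen action
#' @param deadline_ms response deadline
#' @param truncate resample draws above the deadline?
#' @param max_tries resampling cap; the deadline is returned if exhausted
#' @return RT in ms
#' @export
predict_rt <- function(state, params, s, a, deadline_ms = 2000,
                       truncate = TRUE, max_tries = 1000L) {
  mu <- rt_log_mean(params, trial_cost(state, s, a), policy_entropy(state, s))
  for (i in seq_len(max_tries)) {
    rt <- exp(mu + rnorm(1, 0, POLCOMP_CONST$sigma))
    if (!truncate || rt <= deadline_ms) return(rt)
  }
  deadline_ms
}

#' Log-density of an observed response time
#'
#' Lognormal density in milliseconds: Gaussian on log RT around the
#' regression mean with SD sigma = 0.9, including the 1/rt
#' change-of-variables term. The density is not truncated at the deadline.
#'
#' @param params parameter vector (uses `b1`, `b2`)
#' @param state agent state
#' @param s,a 0-based state and action
#' @param rt_ms observed RT in ms
#' @return log-density
#' @export
rt_loglik <- function(params, state, s, a, rt_ms) {
  mu <- rt_log_mean(params, trial_cost(state, s, a), policy_entropy(state, s))
  dnorm(log(rt_ms), mu, POLCOMP_CONST$sigma, log = TRUE) - log(rt_ms)
}
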