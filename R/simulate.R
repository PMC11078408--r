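# Forward simulation of full six-block sessions for any model variant.

#' Simulate a full experimental session for one subject
#'
#' Runs the agent through its randomized six-block schedule. The learning
#' state is re-initialized at every task x condition block boundary (each
#' block uses unique stimuli, so nothing transfers). Choices, rewards and
#' response times are generated by the model's own process (softmax policy +
#' lognormal RT regression for compression variants; the LBA race for the
#' comparison models). Simulated agents always respond before the deadline
#' (RT draws are truncated), so no missed trials are emitted.
#'
#' @param model_id any model id from [polcomp_models()]
#' @param params named parameter vector within the model's bounds
#' @param subject_id identifier written to the output
#' @param seed integer seed; the whole session is deterministic given it
#' @param config task configuration
#' @return data.frame of trials in the canonical CSV dialect
#' @export
simulate_session <- function(model_id, params, subject_id = "s1", seed = 1L,
                             config = default_task_config()) {
  model_id <- match.arg(model_id, ALL_MODELS)
  params <- check_params(model_id, params)
  schedule <- build_experiment(seed, config)
  out <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    cond <- build_condition(schedule$task_id[i], schedule$condition_id[i], config)
    states <- generate_trials(cond, seed + 101L * i)
    out[[i]] <- simulate_block(model_id, params, cond, states,
                               block = schedule$block[i])
    out[[i]]$subject <- subject_id
  }
  df <- do.call(rbind, out)
  df[, c("subject", "task", "condition", "trial", "state", "action",
         "reward", "rt_ms", "deadline_ms")]
}

simulate_block <- function(model_id, params, cond, states, block) {
  n <- length(states)
  action <- integer(n); reward <- integer(n); rt <- numeric(n)
  if (model_id %in% COMPRESSION_MODELS) {
    ag <- compression_init(model_id, params, block = block,
                           n_states = cond$n_states, n_actions = cond$n_actions)
    for (t in seq_len(n)) {
      s <- states[t]
      p <- compression_policy(ag, s)
      a <- sample.int(cond$n_actions, 1L, prob = p) - 1L
      r <- sample_feedback(cond, s, a)
      rt[t] <- predict_rt(ag, params, s, a, cond$deadline_ms)
      ag <- compression_learn(ag, model_id, params, s, a, r,
                              time_pressure = cond$time_pressure)
      action[t] <- a; reward[t] <- r
    }
  } else {
    ag <- baseline_init(model_id, cond$n_states, cond$n_actions)
    for (t in seq_len(n)) {
      s <- states[t]
      pol <- baseline_policy_matrix(ag, model_id, params, block)
      v <- lba_drift_rates(pol[s + 1L, ], colMeans(pol), params)
      race <- lba_sample(v, params, time_pressure = cond$time_pressure,
                         deadline_ms = cond$deadline_ms)
      a <- race$action
      r <- sample_feedback(cond, s, a)
      ag <- if (model_id == "rlwm") rlwm_learn(ag, params, s, a, r)
            else standard_rl_learn(ag, params, s, a, r)
      action[t] <- a; reward[t] <- r; rt[t] <- race$rt_ms
    }
  }
  data.frame(task = cond$task_id, condition = cond$condition_id,
             trial = seq_len(n) - 1L, state = states, action = action,
             reward = reward, rt_ms = rt, deadline_ms = cond$deadline_ms,
             stringsAsFactors = FALSE)
}

# Full policy matrix of a baseline agent (rows = states), used both for
# action selection and for the state-averaged prior-uncertainty term.
baseline_policy_matrix <- function(state, model_id, params, block) {
  n_s <- nrow(state$q)
  t(vapply(seq_len(n_s) - 1L, function(s) {
    if (model_id == "rlwm") rlwm_policy(state, params, s)
    else standard_rl_policy(state, beta_for_block(model_id, params, block), s)
  }, numeric(ncol(state$q))))
}

beta_for_block <- function(model_id, params, block) {
  if (model_id %in% c("std_rl_6b", "fixed_6b")) params[[paste0("beta", block)]]
  else params[["beta"]]
}
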