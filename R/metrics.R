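# Descriptive statistics of choice behavior: empirical policy complexity
# (Bayesian posterior-mean mutual information), stochasticity, per-state
# action bias, sliding-window learning dynamics, set-size bias, and simple
# paired statistics.

#' State-action co-occurrence counts
#'
#' Tabulates (state, chosen action) pairs for one subject x condition;
#' missed trials are excluded.
#'
#' @param trials trials data.frame (0-based `state`, `action`)
#' @param n_states,n_actions table dimensions
#' @return integer matrix of counts
#' @export
joint_counts <- function(trials, n_states = 3L, n_actions = 3L) {
  ok <- !is.na(trials$action)
  m <- matrix(0L, n_states, n_actions)
  if (any(ok)) {
    tab <- table(factor(trials$state[ok], levels = 0:(n_states - 1)),
                 factor(trials$action[ok], levels = 0:(n_actions - 1)))
    m <- matrix(as.integer(tab), n_states, n_actions)
  }
  m
}

#' Bayesian (Hutter) estimator of mutual information
#'
#' Posterior expected mutual information of the joint state-action
#' distribution under a symmetric Dirichlet prior, in closed form via
#' digamma functions. With per-cell pseudocount alpha and posterior counts
#' n'_ij = n_ij + alpha (total N), the estimate in nats is
#' sum_ij (n'_ij / N) \[psi(n'_ij + 1) - psi(n'_i. + 1) - psi(n'_.j + 1)
#' + psi(N + 1)\].
#'
#' @param counts non-negative count matrix (states x actions)
#' @param prior_concentration per-cell Dirichlet pseudocount; the default
#'   1/(n cells) keeps the total prior mass at one observation
#' @return estimated mutual information in bits
#' @export
hutter_complexity <- function(counts, prior_concentration = 1 / length(counts)) {
  stopifnot(all(counts >= 0), sum(counts) >= 1)
  np <- counts + prior_concentration
  N <- sum(np)
  ri <- rowSums(np); cj <- colSums(np)
  term <- digamma(np + 1) -
    matrix(digamma(ri + 1), nrow(np), ncol(np)) -
    matrix(digamma(cj + 1), nrow(np), ncol(np), byrow = TRUE) +
    digamma(N + 1)
  sum(np / N * term) / log(2)
}

#' Choice stochasticity: conditional entropy of action given state
#'
#' H(A|S) from row-normalized counts, weighted by the empirical state
#' distribution, in bits.
#'
#' @param counts count matrix (states x actions)
#' @return conditional entropy in bits
#' @export
stochasticity <- function(counts) {
  n <- sum(counts)
  stopifnot(n >= 1)
  p_s <- rowSums(counts) / n
  h <- vapply(seq_len(nrow(counts)), function(i) {
    if (rowSums(counts)[i] == 0) return(0)
    p <- counts[i, ] / sum(counts[i, ])
    -sum(ifelse(p > 0, p * log2(p), 0))
  }, numeric(1))
  sum(p_s * h)
}

# Comparison pairs for the per-state action bias, canonical remapped space:
# entries are (state, preferred action, reference action), all 0-based.
# task1: each state's optimal is its own action; S2/S3 compare the two
#   equally rewarded suboptimals, of which A1 is the high-marginal one.
# task2 Q2: S2/S3 have two deterministic optimals; compare shared A1 with
#   the state-specific optimal. In Q1 those same actions are the two equal
#   suboptimals of each state.
bias_pairs <- function(task, condition) {
  if (task == "task1")
    return(list(c(1L, 0L, 2L), c(2L, 0L, 1L)))
  if (task == "task2") {
    if (condition == "Q2") return(list(c(1L, 0L, 1L), c(2L, 0L, 2L)))
    return(list(c(1L, 0L, 2L), c(2L, 0L, 1L)))
  }
  stop("bias pairs are defined for tasks 1 and 2")
}

#' Per-state action bias
#'
#' For tasks 1 and 2: the difference in choice proportions, per state,
#' between the action with high marginal probability (A1) and the
#' equally-rewarded alternative, Delta P(A) = P(A1) - P(alt), for the two
#' states where the pair is reward-matched (S2, S3), plus their mean.
#' For task 3: the per-state proportion of choosing the suboptimal action
#' (the action with the second-highest reward probability: A2 in S1/S2, A1
#' in S3); when `condition` is NULL, both conditions are computed and the
#' Q2 - Q1 difference returned.
#'
#' @param trials trials for one or more subjects in one task
#' @param task "task1", "task2" or "task3"
#' @param condition "Q1" or "Q2"; for task 3 NULL yields the Q2 - Q1
#'   difference
#' @return list with `per_state` (named vector) and `mean`
#' @export
action_bias <- function(trials, task, condition = NULL) {
  trials <- trials[trials$task == task & !is.na(trials$action), ]
  if (task %in% c("task1", "task2")) {
    stopifnot(!is.null(condition))
    sub <- trials[trials$condition == condition, ]
    ps <- vapply(bias_pairs(task, condition), function(tr) {
      st <- sub[sub$state == tr[1], ]
      if (nrow(st) == 0) return(NA_real_)
      mean(st$action == tr[2]) - mean(st$action == tr[3])
    }, numeric(1))
    names(ps) <- c("S2", "S3")
    return(list(per_state = ps, mean = mean(ps, na.rm = TRUE)))
  }
  # task 3
  subopt <- c(1L, 1L, 0L) # per state, 0-based
  prop <- function(cond) {
    sub <- trials[trials$condition == cond, ]
    vapply(0:2, function(s) {
      st <- sub[sub$state == s, ]
      if (nrow(st) == 0) return(NA_real_)
      mean(st$action == subopt[s + 1L])
    }, numeric(1))
  }
  ps <- if (is.null(condition)) prop("Q2") - prop("Q1") else prop(condition)
  names(ps) <- c("S1", "S2", "S3")
  list(per_state = ps, mean = mean(ps, na.rm = TRUE))
}

#' Sliding-window learning dynamics
#'
#' Policy complexity (Hutter estimate), mean reward and mean RT over a
#' sliding window of trials within one subject x condition block; the
#' series is truncated to `n_trials - window` points (windows starting at
#' trials 1 .. n - window).
#'
#' @param trials one subject x condition block, in trial order
#' @param window window length in trials
#' @param n_states,n_actions table dimensions
#' @return data.frame with columns `t` (0-based index of the window start),
#'   `complexity_bits`, `avg_reward`, `mean_rt_ms`
#' @export
learning_dynamics <- function(trials, window = 30L,
                              n_states = 3L, n_actions = 3L) {
  trials <- trials[order(trials$trial), ]
  n <- nrow(trials)
  stopifnot(window <= n)
  n_out <- max(n - window, 1L)
  out <- data.frame(t = seq_len(n_out) - 1L, complexity_bits = NA_real_,
                    avg_reward = NA_real_, mean_rt_ms = NA_real_)
  for (i in seq_len(n_out)) {
    w <- trials[i:(i + window - 1L), ]
    out$complexity_bits[i] <- hutter_complexity(joint_counts(w, n_states, n_actions))
    out$avg_reward[i] <- mean(w$reward)
    out$mean_rt_ms[i] <- mean(w$rt_ms, na.rm = TRUE)
  }
  out
}

#' Set-size bias in a multi-set-size dataset
#'
#' For blocks in which one optimal action is shared across two or more
#' states, restricts to states whose own optimal differs from that
#' high-marginal action and computes Delta P(A) = P(choose the high-marginal
#' action) - P(choose another suboptimal action, averaged over such
#' actions), then averages within set size.
#'
#' @param data data.frame with columns `subject`, `block`, `set_size`,
#'   `state`, `action`, `optimal_action` (the state's own optimal),
#'   `high_marginal_action` (the block's shared optimal; NA marks blocks
#'   without one), and `n_actions`
#' @return data.frame with columns `set_size`, `delta_p`, `n_cells`;
#'   `delta_p` is NA for set sizes with no qualifying states
#' @export
setsize_bias <- function(data) {
  need <- c("subject", "block", "set_size", "state", "action",
            "optimal_action", "high_marginal_action", "n_actions")
  stopifnot(all(need %in% names(data)))
  d <- data[!is.na(data$high_marginal_action) &
              data$optimal_action != data$high_marginal_action &
              !is.na(data$action), ]
  cells <- unique(d[, c("subject", "block", "state")])
  per_cell <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- d[d$subject == cells$subject[i] & d$block == cells$block[i] &
                d$state == cells$state[i], ]
    h <- cell$high_marginal_action[1]
    opt <- cell$optimal_action[1]
    others <- setdiff(seq_len(cell$n_actions[1]) - 1L, c(h, opt))
    if (length(others) == 0) return(NULL)
    p_other <- mean(vapply(others, function(a) mean(cell$action == a),
                           numeric(1)))
    data.frame(set_size = cell$set_size[1],
               delta_p = mean(cell$action == h) - p_other)
  })
  per_cell <- do.call(rbind, per_cell)
  sizes <- sort(unique(data$set_size))
  out <- data.frame(set_size = sizes, delta_p = NA_real_, n_cells = 0L)
  for (i in seq_along(sizes)) {
    sub <- per_cell[per_cell$set_size == sizes[i], , drop = FALSE]
    if (!is.null(sub) && nrow(sub) > 0) {
      out$delta_p[i] <- mean(sub$delta_p)
      out$n_cells[i] <- nrow(sub)
    }
  }
  out
}

#' Paired group statistics
#'
#' Paired t-test with Cohen's d = mean(diff) / sd(diff), and the Pearson
#' correlation with its two-sided p-value.
#'
#' @param x,y paired numeric vectors
#' @return list with `t`, `df`, `p_t`, `d`, `r`, `p_r`
#' @export
group_stats <- function(x, y) {
  stopifnot(length(x) == length(y))
  diff <- x - y
  if (sd(diff) == 0) {
    t_stat <- 0; p_t <- 1
  } else {
    tt <- t.test(x, y, paired = TRUE)
    t_stat <- unname(tt$statistic); p_t <- tt$p.value
  }
  d <- if (sd(diff) == 0) 0 else mean(diff) / sd(diff)
  if (sd(x) == 0 || sd(y) == 0) {
    r <- NA_real_; p_r <- NA_real_
  } else {
    ct <- cor.test(x, y)
    r <- unname(ct$estimate); p_r <- ct$p.value
  }
  list(t = t_stat, df = length(x) - 1L, p_t = p_t, d = d, r = r, p_r = p_r)
}

#' Per subject x condition behavioral metric table
#'
#' One row per subject x task x condition: empirical policy complexity
#' (Hutter estimate, bits), average reward per trial, stochasticity
#' (conditional entropy, bits), mean RT over responded trials, and the
#' task's mean action bias (for task 3, the mean suboptimal-choice
#' proportion in that condition).
#'
#' @param trials trials data.frame for one or more subjects
#' @return data.frame of metric rows
#' @export
behavior_metrics <- function(trials) {
  cells <- unique(trials[, c("subject", "task", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$subject == cells$subject[i] &
                    trials$task == cells$task[i] &
                    trials$condition == cells$condition[i], ]
    counts <- joint_counts(sub)
    ab <- if (cells$task[i] == "task3")
      action_bias(sub, "task3", cells$condition[i])
    else action_bias(sub, cells$task[i], cells$condition[i])
    data.frame(subject = cells$subject[i], task = cells$task[i],
               condition = cells$condition[i],
               complexity_bits = hutter_complexity(counts),
               avg_reward = mean(sub$reward),
               stochasticity_bits = stochasticity(counts),
               mean_rt_ms = mean(sub$rt_ms, na.rm = TRUE),
               action_bias = ab$mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split subjects at the sample mean of a metric
#'
#' @param values numeric vector
#' @return factor with levels "low", "high"
#' @export
mean_split <- function(values) {
  factor(ifelse(values <= mean(values), "low", "high"),
         levels = c("low", "high"))
}
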