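toy_trials <- function(states, actions, rewards = NULL, rts = NULL,
                       task = "task1", condition = "Q2") {
  n <- length(states)
  data.frame(subject = "s1", task = task, condition = condition,
             trial = seq_len(n) - 1L, state = states, action = actions,
             reward = if (is.null(rewards)) rep(1L, n) else rewards,
             rt_ms = if (is.null(rts)) rep(500, n) else rts,
             deadline_ms = 2000, stringsAsFactors = FALSE)
}

test_that("the Hutter estimator is consistent and well-bounded", {
  set.seed(1)
  # deterministic bijection: estimate near log2(3)
  s_det <- rep(0:2, 1000)
  det <- toy_trials(s_det, s_det)
  expect_lt(abs(hutter_complexity(joint_counts(det)) - log2(3)), 0.05)
  # independent state and action: estimate near zero
  ind <- toy_trials(sample(0:2, 3000, TRUE), sample(0:2, 3000, TRUE))
  expect_lt(hutter_complexity(joint_counts(ind)), 0.02)
  # converges to the plug-in estimate on random joints
  probs <- prop.table(matrix(runif(9) + 0.05, 3, 3))
  idx <- sample(9, 1e4, TRUE, prob = as.numeric(probs))
  counts <- matrix(tabulate(idx, 9), 3, 3)
  plug_in <- mutual_information(counts / rowSums(counts),
                                rowSums(counts) / sum(counts))
  expect_lt(abs(hutter_complexity(counts) - plug_in), 1e-2)
  # bounded by the smaller marginal entropy (plus prior slack)
  for (i in 1:10) {
    cm <- matrix(rpois(9, 20), 3, 3)
    h_s <- -sum(prop.table(rowSums(cm)) * log2(prop.table(rowSums(cm))))
    est <- hutter_complexity(cm)
    expect_gte(est, 0)
    expect_lte(est, min(h_s, log2(3)) + 0.05)
  }
  # shuffling actions within a subject destroys estimated complexity
  shuf <- det; shuf$action <- sample(shuf$action)
  expect_lt(hutter_complexity(joint_counts(shuf)), 0.02)
})

test_that("stochasticity is the state-weighted conditional entropy", {
  det <- joint_counts(toy_trials(rep(0:2, 10), rep(0:2, 10)))
  expect_equal(stochasticity(det), 0)
  unif <- matrix(5L, 3, 3)
  expect_equal(stochasticity(unif), log2(3))
  # hand-computed 2x2: rows (3,1) and (2,2), P(s) = (0.5, 0.5)
  m <- rbind(c(3, 1), c(2, 2))
  by_hand <- 0.5 * (-(3 / 4) * log2(3 / 4) - (1 / 4) * log2(1 / 4)) + 0.5 * 1
  expect_equal(stochasticity(m), by_hand)
})

test_that("action bias contrasts the high-marginal action with its pair", {
  # uniform choices: zero bias in expectation (exactly zero for equal counts)
  states <- rep(1:2, each = 9)
  actions <- rep(0:2, 6)
  expect_equal(action_bias(toy_trials(states, actions), "task1", "Q2")$mean, 0)
  # an agent always choosing the shared optimal in task 2 Q2
  always1 <- toy_trials(rep(0:2, 10), rep(0L, 30), task = "task2")
  ab <- action_bias(always1, "task2", "Q2")
  expect_equal(unname(ab$per_state), c(1, 1))
  expect_equal(ab$mean, 1)
  # hand-computed toy table: S2 choices 6xA1, 2xA2, 2xA3 -> P(A1)-P(A3) = 0.4
  t1 <- toy_trials(rep(1L, 10), c(rep(0L, 6), 1L, 1L, 2L, 2L))
  expect_equal(unname(action_bias(t1, "task1", "Q2")$per_state["S2"]), 0.4)
  # task 3: suboptimal proportions per condition and their Q2-Q1 difference
  q1 <- toy_trials(rep(2L, 10), c(rep(0L, 2), rep(2L, 8)), task = "task3",
                   condition = "Q1")
  q2 <- toy_trials(rep(2L, 10), c(rep(0L, 5), rep(2L, 5)), task = "task3",
                   condition = "Q2")
  both <- rbind(q1, q2)
  expect_equal(unname(action_bias(both, "task3", "Q2")$per_state["S3"]), 0.5)
  expect_equal(unname(action_bias(both, "task3")$per_state["S3"]), 0.3)
})

test_that("sliding-window dynamics have the documented length and content", {
  n <- 90
  tr <- toy_trials(rep(0:2, 30), rep(0:2, 30), rewards = rep(1L, n),
                   rts = rep(400, n))
  dyn <- learning_dynamics(tr, window = 30)
  expect_equal(nrow(dyn), n - 30)
  expect_true(all(dyn$avg_reward == 1))
  expect_true(all(dyn$mean_rt_ms == 400))
  single <- learning_dynamics(tr, window = n)
  expect_equal(nrow(single), 1L)
  # first random, then deterministic: complexity rises across the seam
  set.seed(2)
  tr2 <- toy_trials(rep(0:2, 40), c(sample(0:2, 60, TRUE), rep(0:2, 20)))
  dyn2 <- learning_dynamics(tr2, window = 30)
  expect_gt(mean(tail(dyn2$complexity_bits, 10)),
            mean(head(dyn2$complexity_bits, 10)))
})

test_that("set-size bias isolates the high-marginal suboptimal preference", {
  mk <- function(actions, set_size = 4, state = 1L) {
    data.frame(subject = "s1", block = 1L, set_size = set_size, state = state,
               action = actions, optimal_action = 1L,
               high_marginal_action = 0L, n_actions = 3L)
  }
  biased <- mk(c(rep(0L, 6), rep(1L, 10), rep(2L, 2)))
  out <- setsize_bias(biased)
  expect_equal(out$delta_p[out$set_size == 4],
               6 / 18 - 2 / 18)
  unbiased <- mk(c(rep(0L, 4), rep(1L, 10), rep(2L, 4)))
  expect_equal(setsize_bias(unbiased)$delta_p, 0)
  # no qualifying states: NA for that set size
  none <- mk(rep(1L, 10)); none$optimal_action <- 0L
  expect_true(is.na(setsize_bias(none)$delta_p))
})

test_that("paired statistics match hand calculations", {
  gs <- group_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(gs$t, 0); expect_equal(gs$d, 0)
  gs2 <- group_stats(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(gs2$r, 1)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 2, 4, 3, 6)
  gs3 <- group_stats(x, y)
  dd <- x - y
  expect_equal(gs3$t, mean(dd) / (sd(dd) / sqrt(5)))
  expect_equal(gs3$d, mean(dd) / sd(dd))
})

test_that("the metric table carries one row per subject and condition", {
  cohort <- generate_cohort(cohort_spec("fixed_1b", 2, master_seed = 9))
  m <- behavior_metrics(cohort$trials)
  expect_equal(nrow(m), 2 * 6)
  expect_true(all(m$complexity_bits >= 0))
  expect_true(all(m$stochasticity_bits >= 0 & m$stochasticity_bits <= log2(3)))
  expect_true(all(is.finite(m$mean_rt_ms)))
  expect_equal(levels(mean_split(m$complexity_bits)), c("low", "high"))
})

test_that("RT and complexity correlate positively on heterogeneous cohorts", {
  cohort <- generate_cohort(cohort_spec("adaptive_capacity_value", 30,
                                        master_seed = 44))
  m <- behavior_metrics(cohort$trials)
  for (task in c("task1", "task2", "task3")) {
    sub <- m[m$task == task, ]
    expect_gt(cor(sub$mean_rt_ms, sub$complexity_bits), 0)
  }
})
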