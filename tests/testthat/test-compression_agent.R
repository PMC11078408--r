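test_that("the policy is a softmax of propensities biased by the marginal", {
  ag <- make_agent()
  expect_equal(compression_policy(ag, 0), rep(1 / 3, 3))
  ag2 <- make_agent(p_a = c(0.6, 0.2, 0.2))
  expect_equal(compression_policy(ag2, 1), c(0.6, 0.2, 0.2))
  # beta = 0: the policy equals the marginal whatever theta is
  ag3 <- make_agent(theta = matrix(rnorm(9), 3, 3),
                    p_a = c(0.5, 0.3, 0.2), beta = 0)
  expect_equal(compression_policy(ag3, 2), c(0.5, 0.3, 0.2))
})

test_that("cost and entropy match their definitions", {
  ag <- make_agent(p_a = c(0.5, 0.25, 0.25))
  lp <- compression_log_policy(ag, 0)
  for (a in 0:2)
    expect_equal(trial_cost(ag, 0, a), lp[a + 1] - log(ag$p_a[a + 1]))
  expect_equal(trial_cost(make_agent(), 0, 1), 0) # pi == P(a)
  # deterministic policy over uniform marginal costs ln 3
  hot <- make_agent(theta = rbind(c(40, 0, 0), 0, 0), beta = 1)
  expect_equal(trial_cost(hot, 0, 0), log(3), tolerance = 1e-8)
  expect_equal(policy_entropy(make_agent(), 0), log(3))
  expect_equal(policy_entropy(hot, 0), 0, tolerance = 1e-6)
  ag4 <- make_agent(p_a = c(0.5, 0.25, 0.25), beta = 0)
  expect_equal(policy_entropy(ag4, 0), 1.0397, tolerance = 1e-4)
})

test_that("one learning step reproduces the hand-computed prediction error", {
  p <- typical_params("fixed_1b"); p["beta"] <- 1
  ag <- compression_init("fixed_1b", p)
  ag$beta <- 1
  # theta = 0, uniform marginal, V = 0, r = 1: pi = P so cost = 0, delta = 1
  out <- compression_learn(ag, "fixed_1b", p, s = 0, a = 1, r = 1)
  a_t <- p[["alpha_theta"]]
  expect_equal(out$theta[1, ], c(-a_t / 3, a_t * 2 / 3, -a_t / 3))
  expect_equal(out$v_hat[1], p[["alpha_V"]] * 1)
  expect_equal(out$rho, 0.01)
  expect_error(compression_learn(ag, "fixed_1b", p, 0, NA, 1), "missed")
})

test_that("the propensity update is the exact policy gradient of the objective", {
  # E over actions of the update equals the gradient of
  # J(theta) = sum_a pi(a) [beta Q(a) - log pi(a)/P(a)] with P held fixed
  set.seed(31)
  for (rep in 1:10) {
    theta <- matrix(rnorm(9), 3, 3)
    p_a <- as.numeric(prop.table(runif(3) + 0.1))
    beta <- runif(1, 0.5, 5)
    Qrow <- runif(3)
    s <- sample(0:2, 1)
    pars <- typical_params("fixed_1b")
    a_t <- pars[["alpha_theta"]]
    ag <- make_agent(theta = theta, p_a = p_a, beta = beta)
    pi_s <- compression_policy(ag, s)
    # expected update over the action distribution, reward at its mean Q
    exp_upd <- rep(0, 3)
    for (a in 0:2) {
      delta <- beta * Qrow[a + 1] - trial_cost(ag, s, a) - ag$v_hat[s + 1]
      g <- -a_t * delta * pi_s * beta
      g[a + 1] <- a_t * delta * (1 - pi_s[a + 1]) * beta
      exp_upd <- exp_upd + pi_s[a + 1] * g
    }
    J <- function(th_row) {
      th <- theta; th[s + 1, ] <- th_row
      agj <- make_agent(theta = th, p_a = p_a, beta = beta)
      pj <- compression_policy(agj, s)
      sum(pj * (beta * Qrow - (compression_log_policy(agj, s) - log(p_a))))
    }
    grad_num <- vapply(1:3, function(j) {
      h <- 1e-6
      e <- rep(0, 3); e[j] <- h
      (J(theta[s + 1, ] + e) - J(theta[s + 1, ] - e)) / (2 * h)
    }, numeric(1))
    expect_equal(exp_upd, a_t * grad_num, tolerance = 1e-5)
  }
})

test_that("beta updates move toward the variant-specific targets", {
  p <- typical_params("adaptive_capacity")
  ag <- compression_init("adaptive_capacity", p)
  ag$xi <- p[["C"]] + 0.5 # complexity estimate above capacity
  out <- compression_learn(ag, "adaptive_capacity", p, 0, 0, 1)
  expect_lt(out$beta, ag$beta)
  ag$xi <- 0
  out2 <- compression_learn(ag, "adaptive_capacity", p, 0, 0, 1)
  expect_gt(out2$beta, ag$beta)
  # time pressure substitutes the reduced capacity
  ag$xi <- p[["C_reduced"]] + 0.1
  out3 <- compression_learn(ag, "adaptive_capacity", p, 0, 0, 1,
                            time_pressure = TRUE)
  expect_lt(out3$beta, ag$beta)
  # fixed variants never move beta
  pf <- typical_params("fixed_1b")
  agf <- compression_init("fixed_1b", pf)
  expect_equal(compression_learn(agf, "fixed_1b", pf, 0, 0, 1)$beta,
               pf[["beta"]])
})

test_that("moving averages stay in the hull of their inputs", {
  p <- typical_params("adaptive_capacity_value")
  ag <- compression_init("adaptive_capacity_value", p)
  set.seed(4)
  costs <- c()
  for (t in 1:200) {
    s <- sample(0:2, 1)
    a <- sample(0:2, 1, prob = compression_policy(ag, s))
    costs <- c(costs, trial_cost(ag, s, a))
    ag <- compression_learn(ag, "adaptive_capacity_value", p, s, a,
                            rbinom(1, 1, 0.5))
    expect_gte(ag$rho, 0); expect_lte(ag$rho, 1)
    expect_gte(ag$xi, min(0, costs)); expect_lte(ag$xi, max(0, costs))
    expect_gte(ag$beta, 0); expect_lte(ag$beta, 100)
    expect_equal(sum(ag$p_a), 1)
  }
})

test_that("with a pinned uniform marginal the policy equals standard softmax", {
  p <- typical_params("fixed_1b"); p["alpha_P"] <- 0
  ag <- compression_init("fixed_1b", p)
  set.seed(7)
  cond <- build_condition("task2", "Q1")
  for (t in 1:100) {
    s <- sample(0:2, 1)
    a <- sample(0:2, 1, prob = compression_policy(ag, s))
    ag <- compression_learn(ag, "fixed_1b", p, s, a, sample_feedback(cond, s, a))
  }
  expect_equal(ag$p_a, rep(1 / 3, 3)) # marginal never moved
  for (s in 0:2) {
    z <- exp(ag$beta * ag$theta[s + 1, ])
    expect_equal(compression_policy(ag, s), z / sum(z))
  }
})

test_that("the RT regression mean and noise match the stated model", {
  p <- typical_params("fixed_1b")
  # zero cost and entropy: mean RT is the non-decision time
  expect_equal(exp(polcomp:::rt_log_mean(p, 0, 0)), 150)
  p2 <- p; p2["b1"] <- 100; p2["b2"] <- 100
  expect_equal(exp(polcomp:::rt_log_mean(p2, log(3), 0)), 150 + 100 * log(3))
  # a strongly negative cost term hits the floor instead of log(<=0)
  expect_equal(exp(polcomp:::rt_log_mean(p2, -10, 0)), 1)
  # untruncated draws have log-RT dispersion sigma = 0.9
  hot <- make_agent(params = p)
  set.seed(12)
  draws <- replicate(1e4, predict_rt(hot, p, 0, 0, truncate = FALSE))
  expect_equal(sd(log(draws)), 0.9, tolerance = 0.03)
  # truncated draws respect the deadline
  set.seed(13)
  expect_true(all(replicate(500, predict_rt(hot, p, 0, 0, deadline_ms = 300)) <= 300))
})

test_that("the RT log-density is a normalized lognormal", {
  p <- typical_params("fixed_1b")
  ag <- make_agent(params = p)
  dens <- function(rt) exp(rt_loglik(p, ag, 0, 1, rt))
  total <- integrate(Vectorize(dens), 1e-3, Inf, rel.tol = 1e-8)$value
  expect_equal(total, 1, tolerance = 1e-4)
  # symmetry in log space around the regression mean
  mu <- polcomp:::rt_log_mean(p, trial_cost(ag, 0, 1), policy_entropy(ag, 0))
  d_hi <- rt_loglik(p, ag, 0, 1, exp(mu + 0.5)) + (mu + 0.5)
  d_lo <- rt_loglik(p, ag, 0, 1, exp(mu - 0.5)) + (mu - 0.5)
  expect_equal(d_hi, d_lo)
})

test_that("sessions are reproducible and capacity shapes empirical complexity", {
  p <- typical_params("adaptive_capacity")
  d1 <- simulate_session("adaptive_capacity", p, seed = 3)
  d2 <- simulate_session("adaptive_capacity", p, seed = 3)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 600L)
  expect_true(all(d1$rt_ms <= d1$deadline_ms))
  # long-run complexity of simulated choices increases with capacity
  C_grid <- c(0.7, 1.0, 1.5, 2.2, 3.0)
  seeds <- 1:4
  mean_cx <- vapply(C_grid, function(C) {
    mean(vapply(seeds, function(sd) {
      pc <- p; pc["C"] <- C; pc["C_reduced"] <- min(0.5, C)
      d <- simulate_session("adaptive_capacity", pc, seed = 1000 + sd)
      sub <- d[d$task == "task2" & d$condition == "Q1", ]
      hutter_complexity(joint_counts(sub))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(C_grid, mean_cx, method = "spearman"), 0)
})
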