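test_that("standard RL learning and policy follow the delta rule and softmax", {
  p <- typical_params("std_rl_1b")
  st <- baseline_init("std_rl_1b")
  p["alpha_Q"] <- 0.5
  st1 <- standard_rl_learn(st, p, 0, 1, 1)
  expect_equal(st1$q[1, 2], 0.5)
  for (i in 1:20) st1 <- standard_rl_learn(st1, p, 0, 1, 1)
  expect_equal(st1$q[1, 2], 1, tolerance = 1e-6)
  p0 <- p; p0["alpha_Q"] <- 0
  expect_equal(standard_rl_learn(st, p0, 0, 1, 1)$q, st$q)
  expect_equal(standard_rl_policy(st, 5, 0), rep(1 / 3, 3)) # constant row
  st$q[1, ] <- c(1, 0, 0)
  expect_equal(standard_rl_policy(st, 0, 0), rep(1 / 3, 3)) # beta = 0
  peaked <- standard_rl_policy(st, 30, 0)
  expect_gt(peaked[1], 0.9999)
  expect_equal(peaked[2], peaked[3])
})

test_that("RLWM learns at rate one, decays toward 1/3, and gates on feedback", {
  p <- typical_params("rlwm")
  st <- baseline_init("rlwm")
  st1 <- rlwm_learn(st, p, 0, 0, 1)
  expect_equal(st1$w_assoc[1, 1], 1)
  # repeated decay with no further reward pulls W back to W0 = 1/3
  stD <- st1
  for (i in 1:200) stD$w_assoc <- stD$w_assoc + p[["phi"]] * (1 / 3 - stD$w_assoc)
  expect_equal(stD$w_assoc[1, 1], 1 / 3, tolerance = 1e-6)
  # gamma = 0 on incorrect feedback: decay only, no learning
  pg <- p; pg["gamma"] <- 0
  st2 <- rlwm_learn(st1, pg, 0, 0, 0)
  expect_equal(st2$w_assoc[1, 1],
               st1$w_assoc[1, 1] + p[["phi"]] * (1 / 3 - st1$w_assoc[1, 1]))
  expect_equal(st2$q, st1$q)
})

test_that("the RLWM mixture weight follows rho * min(1, C/n_S)", {
  st <- baseline_init("rlwm")
  st$w_assoc[1, ] <- c(1, 0, 0)
  st$q[1, ] <- c(0, 1, 0)
  p <- typical_params("rlwm")
  p["C_wm"] <- 3; p["rho_wm"] <- 1
  expect_equal(rlwm_policy(st, p, 0),
               polcomp:::softmax_row(50 * st$w_assoc[1, ])) # pure WM
  p["rho_wm"] <- 0
  expect_equal(rlwm_policy(st, p, 0),
               polcomp:::softmax_row(50 * st$q[1, ])) # pure RL
  p["rho_wm"] <- 1; p["C_wm"] <- 2
  mix <- rlwm_policy(st, p, 0)
  expect_equal(mix, (2 / 3) * polcomp:::softmax_row(50 * st$w_assoc[1, ]) +
                 (1 / 3) * polcomp:::softmax_row(50 * st$q[1, ]))
  # proper distribution across random in-bounds parameters
  spec <- model_spec("rlwm")
  set.seed(8)
  for (i in 1:20) {
    pr <- spec$lower + runif(spec$k) * (spec$upper - spec$lower)
    names(pr) <- spec$params
    pol <- rlwm_policy(st, pr, 0)
    expect_equal(sum(pol), 1)
    expect_true(all(pol >= 0))
  }
})

test_that("drift rates scale the policy by eta over the prior uncertainty", {
  p <- typical_params("std_rl_1b"); p["eta"] <- 1
  u <- rep(1 / 3, 3)
  v <- lba_drift_rates(u, u, p)
  expect_equal(v, rep((1 / 3) / log2(3), 3))
  p2 <- p; p2["eta"] <- 0.5
  expect_equal(lba_drift_rates(u, u, p2), v / 2)
  # degenerate average policy: floored, not infinite
  expect_true(all(is.finite(lba_drift_rates(c(1, 0, 0), c(1, 0, 0), p))))
})

test_that("the race picks the fastest accumulator with the expected RT", {
  p <- typical_params("std_rl_1b")
  p["A"] <- 0; p["B1_minus_A"] <- 350
  set.seed(21)
  races <- replicate(400, unlist(lba_sample(c(1, 1e-6, 1e-6), p)))
  expect_true(all(races["action", ] == 0))
  expect_equal(mean(races["rt_ms", ]), 150 + 350 / 1, tolerance = 0.05 * 500)
  # two identical accumulators win equally often
  set.seed(22)
  wins <- replicate(2000, lba_sample(c(0.8, 0.8, 1e-9), p)$action)
  expect_gt(prop.test(sum(wins == 0), sum(wins <= 1), p = 0.5)$p.value, 0.001)
  # raising the bound slows responses
  set.seed(23)
  pB <- p; pB["B1_minus_A"] <- 450
  rt_hi <- mean(replicate(400, lba_sample(c(1, 0.5, 0.2), pB)$rt_ms))
  set.seed(23)
  rt_lo <- mean(replicate(400, lba_sample(c(1, 0.5, 0.2), p)$rt_ms))
  expect_gt(rt_hi, rt_lo)
})

test_that("the defective density normalizes and matches simulation", {
  p <- typical_params("std_rl_1b")
  v <- c(1, 0.5, 0.3)
  # piecewise quadrature: the slowest accumulator has a long tail that a
  # single adaptive pass over (t0, Inf) underestimates
  segs <- list(c(150.01, 500), c(500, 2000), c(2000, 2e4), c(2e4, 1e6),
               c(1e6, 1e8))
  total <- sum(vapply(0:2, function(a) {
    sum(vapply(segs, function(rg)
      integrate(Vectorize(function(rt) exp(lba_loglik(a, rt, v, p))),
                rg[1], rg[2], rel.tol = 1e-9, subdivisions = 500L)$value,
      numeric(1)))
  }, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-3)
  # symmetric accumulators carry equal defective mass
  vs <- c(0.7, 0.7, 0.1)
  m <- vapply(0:1, function(a) {
    sum(vapply(segs, function(rg)
      integrate(Vectorize(function(rt) exp(lba_loglik(a, rt, vs, p))),
                rg[1], rg[2], rel.tol = 1e-9, subdivisions = 500L)$value,
      numeric(1)))
  }, numeric(1))
  expect_equal(m[1], m[2], tolerance = 1e-6)
  expect_equal(lba_loglik(0, 100, v, p), -Inf) # rt below t0 is impossible
  # Monte-Carlo agreement over a grid of (A, bound, eta-scaled drifts)
  set.seed(41)
  for (A in c(20, 120, 300)) for (BmA in c(80, 200, 400)) {
    pp <- p; pp["A"] <- A; pp["B1_minus_A"] <- BmA
    vv <- c(1.2, 0.6, 0.3) * runif(1, 0.5, 1.5)
    sim <- lba_sample_many(1e5, vv, A, A + BmA)
    grid <- seq(151, quantile(sim$rt, 0.999), length.out = 400)
    dens_tot <- rowSums(vapply(0:2, function(a)
      vapply(grid, function(rt) exp(lba_loglik(a, rt, vv, pp)), numeric(1)),
      numeric(length(grid))))
    cdf_ana <- cumsum(dens_tot) * diff(grid)[1]
    cdf_emp <- ecdf(sim$rt)(grid)
    expect_lt(max(abs(cdf_ana - cdf_emp)), 0.02)
  }
})

test_that("standard RL chooses equally-rewarded suboptimal actions equally", {
  # demo task: S1 has optimal A1; suboptimals A2 and A3 both pay nothing
  cond <- demo_condition()
  p <- typical_params("std_rl_1b")
  p["alpha_Q"] <- 0.2
  st <- baseline_init("std_rl_1b")
  set.seed(33)
  picks <- integer(0)
  for (t in 1:10000) {
    s <- sample(0:2, 1)
    pol <- standard_rl_policy(st, 3, s)
    a <- sample(0:2, 1, prob = pol)
    st <- standard_rl_learn(st, p, s, a, sample_feedback(cond, s, a))
    if (s == 0 && a > 0) picks <- c(picks, a)
  }
  expect_gt(prop.test(sum(picks == 1), length(picks), p = 0.5)$p.value, 0.001)
})
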