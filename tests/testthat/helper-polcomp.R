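# Shared fixtures: typical in-bounds parameter vectors and small task objects.

typical_params <- function(model_id) {
  switch(model_id,
    fixed_1b = c(beta = 5, alpha_theta = 0.3, alpha_V = 0.2, alpha_P = 0.1,
                 b1 = 100, b2 = 120),
    fixed_6b = c(beta1 = 4, beta2 = 5, beta3 = 6, beta4 = 7, beta5 = 8,
                 beta6 = 9, alpha_theta = 0.3, alpha_V = 0.2, alpha_P = 0.1,
                 b1 = 100, b2 = 120),
    adaptive_capacity = c(C = 1.5, C_reduced = 0.4, beta0 = 3,
                          alpha_beta = 0.1, alpha_theta = 0.3, alpha_V = 0.2,
                          alpha_P = 0.1, b1 = 100, b2 = 120),
    adaptive_value = c(R = 0.7, R_reduced = 0.4, beta0 = 3, alpha_beta = 0.1,
                       alpha_theta = 0.3, alpha_V = 0.2, alpha_P = 0.1,
                       b1 = 100, b2 = 120),
    adaptive_capacity_value = c(C = 1.5, C_reduced = 0.4, R = 0.7, beta0 = 3,
                                alpha_beta = 0.1, alpha_theta = 0.3,
                                alpha_V = 0.2, alpha_P = 0.1, b1 = 100,
                                b2 = 120),
    std_rl_1b = c(beta = 10, alpha_Q = 0.4, A = 100, B1_minus_A = 200,
                  B2_minus_A = 100, eta = 1.5),
    std_rl_6b = c(beta1 = 8, beta2 = 9, beta3 = 10, beta4 = 11, beta5 = 12,
                  beta6 = 13, alpha_Q = 0.4, A = 100, B1_minus_A = 200,
                  B2_minus_A = 100, eta = 1.5),
    rlwm = c(C_wm = 3, alpha_RL = 0.3, phi = 0.2, rho_wm = 0.8, gamma = 0.5,
             A = 100, B1_minus_A = 200, B2_minus_A = 100, eta = 1.5),
    stop("unknown model"))
}

# the two-states-share-one-deterministic-action illustration task
demo_condition <- function() build_condition("demo", "Q1")

demo_Q <- function() demo_condition()$reward_prob

# fresh compression agent with an optionally overridden learning state
make_agent <- function(model_id = "fixed_1b", params = typical_params(model_id),
                       ...) {
  st <- compression_init(model_id, params)
  mods <- list(...)
  for (nm in names(mods)) st[[nm]] <- mods[[nm]]
  st
}

# vectorized LBA race sampler for oracle comparisons (no deadline truncation)
lba_sample_many <- function(n, v, A, b, t0 = 150, sv = 0.1) {
  k <- length(v)
  d <- matrix(rnorm(n * k, rep(v, each = n), sv), n, k)
  bad <- rowSums(d > 0) == 0
  while (any(bad)) {
    nb <- sum(bad)
    d[bad, ] <- matrix(rnorm(nb * k, rep(v, each = nb), sv), nb, k)
    bad <- rowSums(d > 0) == 0
  }
  start <- matrix(runif(n * k, 0, A), n, k)
  tt <- ifelse(d > 0, t0 + (b - start) / d, Inf)
  act <- max.col(-tt)
  data.frame(action = act - 1L, rt = tt[cbind(seq_len(n), act)])
}
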