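# Joint maximum-likelihood fitting of choice and response time, BIC scoring,
# and parameter-/model-recovery studies.

# Flatten one subject's trials (presentation order) into the arrays consumed
# by the likelihoods. A new block starts wherever the task/condition cell
# changes between consecutive rows.
prepare_subject_data <- function(data) {
  stopifnot(nrow(data) == 0 || length(unique(data$subject)) == 1)
  if (nrow(data) == 0)
    return(list(state = integer(), action = integer(), reward = numeric(),
                rt = numeric(), block_start = integer(), tp = integer(),
                cell = integer(), n_responded = 0L))
  key <- paste(data$task, data$condition)
  block_start <- as.integer(c(TRUE, key[-1] != key[-nrow(data)]))
  action <- data$action
  action[is.na(action)] <- -1L
  rt <- data$rt_ms
  rt[is.na(rt)] <- -1
  list(state = as.integer(data$state),
       action = as.integer(action),
       reward = as.numeric(data$reward),
       rt = as.numeric(rt),
       block_start = block_start,
       tp = as.integer(data$task == "task3" & data$condition == "Q2"),
       cell = as.integer(block_index(data$task, data$condition)),
       n_responded = sum(action >= 0))
}

#' Negative log joint likelihood of one subject's data under a model
#'
#' Sums per-trial negative log joint choice + RT likelihood over the
#' subject's session, replaying the learning recursion deterministically
#' from the observed (state, action, reward) stream. Missed trials
#' contribute no likelihood term and no learning update. The learning state
#' is reset at each block boundary.
#'
#' @param model_id model id
#' @param params named parameter vector within bounds
#' @param data one subject's trials in presentation order
#' @param engine "cpp" (compiled, used for fitting) or "r" (reference
#'   implementation built from the single-step agent functions)
#' @return scalar negative log-likelihood
#' @export
nll_subject <- function(model_id, params, data, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  model_id <- match.arg(model_id, ALL_MODELS)
  params <- check_params(model_id, params)
  d <- prepare_subject_data(data)
  if (length(d$state) == 0) return(0)
  spec <- model_spec(model_id)
  if (engine == "cpp") {
    fn <- if (spec$family == "compression") nll_compression_cpp else nll_lba_cpp
    return(fn(spec$variant, as.numeric(params[spec$params]),
              d$state, d$action, d$reward, d$rt, d$block_start, d$tp, d$cell,
              3L, 3L))
  }
  nll_subject_r(model_id, params, d)
}

# Reference R implementation of the same recursion.
nll_subject_r <- function(model_id, params, d) {
  family <- model_spec(model_id)$family
  nll <- 0
  ag <- NULL
  for (t in seq_along(d$state)) {
    if (d$block_start[t]) {
      ag <- if (family == "compression")
        compression_init(model_id, params, block = d$cell[t])
      else baseline_init(model_id)
    }
    s <- d$state[t]; a <- d$action[t]
    if (a < 0) next
    r <- d$reward[t]
    if (family == "compression") {
      nll <- nll - compression_log_policy(ag, s)[a + 1L] -
        rt_loglik(params, ag, s, a, d$rt[t])
      ag <- compression_learn(ag, model_id, params, s, a, r,
                              time_pressure = d$tp[t] == 1L)
    } else {
      pol <- baseline_policy_matrix(ag, model_id, params, d$cell[t])
      v <- lba_drift_rates(pol[s + 1L, ], colMeans(pol), params)
      ll <- lba_loglik(a, d$rt[t], v, params, time_pressure = d$tp[t] == 1L)
      # per-trial density floor: impossible data (rt <= t0) are heavily
      # penalized but keep the objective finite (matches the compiled path)
      nll <- nll - max(ll, log(POLCOMP_CONST$lba_dens_floor))
      ag <- if (model_id == "rlwm") rlwm_learn(ag, params, s, a, r)
            else standard_rl_learn(ag, params, s, a, r)
    }
  }
  nll
}

#' Bayesian Information Criterion
#'
#' BIC = 2 * nll + k * log(n_obs).
#'
#' @param nll negative log-likelihood at the maximum
#' @param k number of free parameters
#' @param n_obs number of observations entering the likelihood (responded
#'   trials; each contributes one joint choice + RT term)
#' @return scalar BIC
#' @export
bic <- function(nll, k, n_obs) 2 * nll + k * log(n_obs)

# Space-filling start points within the model's box bounds: a Halton
# sequence with a seeded random shift (Cranley-Patterson rotation). Unlike a
# per-size Latin hypercube, the design is nested -- the first k rows of an
# n-start design are the k-start design -- so adding starts can only improve
# the best optimum found.
halton_starts <- function(spec, n_starts, seed) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47)
  k <- spec$k
  stopifnot(k <= length(primes))
  set.seed(seed)
  shift <- runif(k)
  u <- matrix(NA_real_, n_starts, k)
  for (j in seq_len(k)) {
    b <- primes[j]
    u[, j] <- vapply(seq_len(n_starts), function(i) {
      f <- 1; r <- 0
      while (i > 0) { f <- f / b; r <- r + f * (i %% b); i <- i %/% b }
      r
    }, numeric(1))
  }
  u <- (sweep(u, 2, shift, "+")) %% 1
  starts <- sweep(sweep(u, 2, spec$upper - spec$lower, "*"), 2, spec$lower, "+")
  colnames(starts) <- spec$params
  starts
}

# One local search: Nelder-Mead on a logistic-transformed (unbounded)
# parameterization, polished by bounded L-BFGS-B, cycled while it keeps
# improving. The adaptive-beta likelihoods are only piecewise smooth (floors
# and clamps in the learning dynamics), so a simplex stage before the
# quasi-Newton polish is markedly more reliable than L-BFGS-B alone.
local_search <- function(obj, x0, lower, upper, cycles = 3L, nm_maxit = 3000L,
                         maxit = 500L) {
  to_z <- function(x) stats::qlogis(pmin(pmax((x - lower) / (upper - lower),
                                              1e-7), 1 - 1e-7))
  to_x <- function(z) lower + (upper - lower) * stats::plogis(z)
  best <- list(par = x0, value = obj(x0), convergence = 99L)
  for (cy in seq_len(cycles)) {
    nm <- tryCatch(
      optim(to_z(best$par), function(z) obj(to_x(z)), method = "Nelder-Mead",
            control = list(maxit = nm_maxit, reltol = 1e-12)),
      error = function(e) NULL)
    x1 <- if (!is.null(nm) && nm$value < best$value) to_x(nm$par) else best$par
    qn <- tryCatch(
      optim(x1, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit, parscale = upper - lower)),
      error = function(e) NULL)
    cand <- if (!is.null(qn)) qn
            else if (!is.null(nm)) list(par = to_x(nm$par), value = nm$value,
                                        convergence = 1L)
            else break
    improved <- cand$value < best$value - 0.5
    if (cand$value < best$value) best <- cand
    if (!improved) break
  }
  best
}

#' Fit one subject by bounded multi-start maximum likelihood
#'
#' Runs `n_starts` local searches from seeded shifted-Halton start points
#' within the model's box bounds and keeps the best optimum (the start
#' design is nested, so more starts can only improve the result). Each local search is a
#' Nelder-Mead stage on an unbounded reparameterization followed by a
#' bounded L-BFGS-B polish, cycled while the objective improves.
#' Deterministic given the seed.
#'
#' @param model_id model id
#' @param data one subject's trials in presentation order
#' @param n_starts number of optimizer starts
#' @param seed integer seed for the start design
#' @param cycles Nelder-Mead / L-BFGS-B cycles per start; lower this for a
#'   faster, rougher search (e.g. in large model-comparison sweeps)
#' @return object of class `polcomp_fit`: list with `model_id`, `params`,
#'   `nll`, `bic`, `n_obs`, `starts`, `best_start`, `converged`
#' @export
fit_subject <- function(model_id, data, n_starts = 10L, seed = 1L,
                        cycles = 3L) {
  model_id <- match.arg(model_id, ALL_MODELS)
  spec <- model_spec(model_id)
  d <- prepare_subject_data(data)
  fn_raw <- if (spec$family == "compression") nll_compression_cpp else nll_lba_cpp
  obj <- function(p) fn_raw(spec$variant, p, d$state, d$action, d$reward,
                            d$rt, d$block_start, d$tp, d$cell, 3L, 3L)
  starts <- halton_starts(spec, n_starts, seed)
  best <- NULL
  best_i <- NA_integer_
  any_ok <- FALSE
  for (i in seq_len(n_starts)) {
    res <- local_search(obj, starts[i, ], spec$lower, spec$upper,
                        cycles = cycles)
    if (is.null(best) || res$value < best$value) { best <- res; best_i <- i }
    if (res$convergence == 0) any_ok <- TRUE
  }
  params <- best$par
  names(params) <- spec$params
  structure(list(model_id = model_id, params = params, nll = best$value,
                 bic = bic(best$value, spec$k, d$n_responded),
                 n_obs = d$n_responded, starts = n_starts,
                 best_start = best_i, converged = any_ok),
            class = "polcomp_fit")
}

#' @export
print.polcomp_fit <- function(x, ...) {
  cat(sprintf("<fit %s> nll = %.2f, BIC = %.2f, n = %d, converged = %s\n",
              x$model_id, x$nll, x$bic, x$n_obs, x$converged))
  print(round(x$params, 4))
  invisible(x)
}

#' Parameter-recovery study
#'
#' Simulates a synthetic cohort from the model, refits every subject, and
#' correlates the generating with the recovered parameter values.
#'
#' @param model_id generating (and fitted) model
#' @param n_subjects cohort size
#' @param sampler parameter sampler, see [default_param_sampler()]
#' @param seed master seed (controls sampling, simulation and fit starts)
#' @param n_starts optimizer starts per subject
#' @param config task configuration
#' @return object of class `polcomp_recovery`: list with `pairs` (long
#'   data.frame of generating/recovered values), `r` (per-parameter Pearson
#'   correlations; `NA` where a parameter did not vary), `mean_r`, `min_r`
#' @export
parameter_recovery <- function(model_id, n_subjects = 30L,
                               sampler = default_param_sampler(model_id),
                               seed = 1L, n_starts = 10L,
                               config = default_task_config()) {
  spec <- model_spec(model_id)
  cohort <- generate_cohort(cohort_spec(model_id, n_subjects, sampler, seed),
                            config)
  ids <- names(cohort$truth)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- cohort$trials[cohort$trials$subject == ids[i], ]
    fit <- fit_subject(model_id, sub, n_starts = n_starts, seed = seed + i)
    rows[[i]] <- data.frame(subject = ids[i], param = spec$params,
                            generating = as.numeric(cohort$truth[[i]][spec$params]),
                            recovered = as.numeric(fit$params[spec$params]),
                            stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  r <- vapply(spec$params, function(p) {
    sub <- pairs[pairs$param == p, ]
    if (sd(sub$generating) == 0 || sd(sub$recovered) == 0) return(NA_real_)
    cor(sub$generating, sub$recovered)
  }, numeric(1))
  structure(list(model_id = model_id, pairs = pairs, r = r,
                 mean_r = mean(r, na.rm = TRUE),
                 min_r = if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE)),
            class = "polcomp_recovery")
}

#' @export
print.polcomp_recovery <- function(x, ...) {
  cat(sprintf("<recovery %s> mean r = %.3f, min r = %.3f\n",
              x$model_id, x$mean_r, x$min_r))
  print(round(x$r, 3))
  invisible(x)
}

#' Model-recovery study
#'
#' Simulates a cohort from one generating model and fits a set of candidate
#' models to every subject, summarizing mean and SD of BIC per candidate.
#'
#' @param model_ids candidate models to fit (default: all eight)
#' @param generator_id generating model
#' @param n_subjects cohort size
#' @param seed master seed
#' @param n_starts optimizer starts per subject and model
#' @param cycles search-effort knob passed to [fit_subject()]; the default
#'   single cycle is a deliberately rough search, sufficient because the
#'   compression / non-compression BIC separation this study measures is
#'   orders of magnitude larger than the residual optimization error
#' @param sampler parameter sampler for the generating model
#' @param config task configuration
#' @return list with `bic` (subjects x models matrix) and `table`
#'   (data.frame with per-model mean BIC, BIC SD, and the count of subjects
#'   best fit by the model)
#' @export
model_recovery <- function(model_ids = polcomp_models(),
                           generator_id = "adaptive_capacity_value",
                           n_subjects = 20L, seed = 1L, n_starts = 3L,
                           cycles = 1L,
                           sampler = default_param_sampler(generator_id),
                           config = default_task_config()) {
  cohort <- generate_cohort(cohort_spec(generator_id, n_subjects, sampler, seed),
                            config)
  ids <- names(cohort$truth)
  bics <- matrix(NA_real_, length(ids), length(model_ids),
                 dimnames = list(ids, model_ids))
  for (i in seq_along(ids)) {
    sub <- cohort$trials[cohort$trials$subject == ids[i], ]
    for (m in model_ids) {
      fit <- fit_subject(m, sub, n_starts = n_starts, seed = seed + i,
                         cycles = cycles)
      bics[i, m] <- fit$bic
    }
  }
  best <- model_ids[apply(bics, 1, which.min)]
  tab <- data.frame(model = model_ids,
                    mean_bic = colMeans(bics),
                    sd_bic = apply(bics, 2, function(x)
                      if (length(x) > 1) sd(x) else NA_real_),
                    n_best = vapply(model_ids, function(m) sum(best == m),
                                    integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(generator = generator_id, bic = bics, table = tab)
}
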