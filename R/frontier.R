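# Optimal reward-complexity trade-off via alternating minimization.
# Internal logarithms are natural; user-facing complexities are in bits.

#' Mutual information between states and actions under a policy
#'
#' I(S;A) = sum_s P(s) sum_a pi(a|s) log2[ pi(a|s) / P(a) ], with
#' P(a) = sum_s P(s) pi(a|s) and 0 log 0 taken as 0.
#'
#' @param policy row-stochastic n_states x n_actions matrix
#' @param p_s state distribution (simplex vector)
#' @return mutual information in bits
#' @export
mutual_information <- function(policy, p_s) {
  stopifnot(nrow(policy) == length(p_s))
  p_a <- as.numeric(p_s %*% policy)
  terms <- policy * (log(policy) - rep(log(p_a), each = nrow(policy)))
  terms[policy == 0] <- 0
  sum(p_s * rowSums(terms)) / log(2)
}

#' Expected reward of a policy
#'
#' V = sum_s P(s) sum_a pi(a|s) Q(s,a).
#'
#' @param policy row-stochastic matrix
#' @param Q state-action value matrix
#' @param p_s state distribution
#' @return expected reward per trial
#' @export
expected_reward <- function(policy, Q, p_s) {
  sum(p_s * rowSums(policy * Q))
}

#' Optimal capacity-limited policy at a fixed trade-off weight
#'
#' Alternates between the optimal-policy form
#' pi(a|s) proportional to exp\[beta Q(s,a) + log P(a)\] and the marginal
#' update P(a) <- sum_s P(s) pi(a|s) until the policy is stationary. This is
#' the Blahut-Arimoto style fixed-point iteration for the Lagrangian
#' beta * V - I(S;A).
#'
#' @param Q n_states x n_actions value matrix
#' @param p_s state distribution
#' @param beta non-negative trade-off weight (inverse temperature)
#' @param tol convergence tolerance on max-abs policy change
#' @param max_iter iteration cap; non-convergence is flagged, not an error
#' @return object of class `polcomp_policy_solution`: list with `policy`,
#'   `marginal`, `beta`, `iterations`, `converged`
#' @export
blahut_arimoto <- function(Q, p_s, beta, tol = 1e-8, max_iter = 1e4) {
  stopifnot(all(is.finite(Q)), beta >= 0,
            abs(sum(p_s) - 1) < 1e-8, all(p_s >= 0))
  n_a <- ncol(Q)
  p_a <- rep(1 / n_a, n_a)
  policy <- matrix(1 / n_a, nrow(Q), n_a)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    logits <- beta * Q + rep(log(p_a), each = nrow(Q))
    logits <- logits - apply(logits, 1, max)
    new_policy <- exp(logits)
    new_policy <- new_policy / rowSums(new_policy)
    delta <- max(abs(new_policy - policy))
    policy <- new_policy
    p_a <- as.numeric(p_s %*% policy)
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(policy = policy, marginal = p_a, beta = beta,
                 iterations = iter, converged = converged),
            class = "polcomp_policy_solution")
}

#' Reward-complexity frontier over a grid of trade-off weights
#'
#' @param Q value matrix
#' @param p_s state distribution
#' @param beta_grid ascending vector of non-negative trade-off weights
#' @param tol,max_iter passed to [blahut_arimoto()]
#' @return data.frame with columns `beta`, `complexity_bits`, `value`,
#'   `converged`; one row per beta.
#' @export
compute_frontier <- function(Q, p_s, beta_grid = default_beta_grid(),
                             tol = 1e-8, max_iter = 1e4) {
  stopifnot(!is.unsorted(beta_grid))
  rows <- lapply(beta_grid, function(b) {
    sol <- blahut_arimoto(Q, p_s, b, tol = tol, max_iter = max_iter)
    data.frame(beta = b,
               complexity_bits = mutual_information(sol$policy, p_s),
               value = expected_reward(sol$policy, Q, p_s),
               converged = sol$converged)
  })
  do.call(rbind, rows)
}

#' @rdname compute_frontier
#' @export
default_beta_grid <- function() {
  # dense near 0 where the curve bends; capped at 100 (near-greedy regime)
  sort(unique(c(seq(0, 2, by = 0.05), seq(2, 10, by = 0.25),
                seq(10, 100, by = 2.5))))
}

#' Frontier point attaining a capacity limit
#'
#' Returns the highest-value frontier point whose complexity does not exceed
#' the capacity `C` (in bits), i.e. the optimal policy for a capacity-limited
#' agent, recomputed at its beta.
#'
#' @param Q value matrix
#' @param p_s state distribution
#' @param C capacity in bits
#' @param beta_grid grid used to trace the frontier
#' @return list with `beta`, `complexity_bits`, `value`, `solution`
#' @export
frontier_at_capacity <- function(Q, p_s, C, beta_grid = default_beta_grid()) {
  fr <- compute_frontier(Q, p_s, beta_grid)
  ok <- fr$complexity_bits <= C + 1e-9
  if (!any(ok)) stop("no frontier point within capacity ", C)
  i <- which(ok)[which.max(fr$value[ok])]
  sol <- blahut_arimoto(Q, p_s, fr$beta[i])
  list(beta = fr$beta[i], complexity_bits = fr$complexity_bits[i],
       value = fr$value[i], solution = sol)
}

#' Export a frontier as CSV
#'
#' @param frontier data.frame from [compute_frontier()]
#' @param path file path
#' @export
write_frontier <- function(frontier, path) {
  write.csv(frontier[, c("beta", "complexity_bits", "value")], path,
            row.names = FALSE, quote = FALSE)
}
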