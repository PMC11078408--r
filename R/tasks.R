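#' @useDynLib polcomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom runif rnorm optim dnorm pnorm cor cor.test t.test
#'   sd qnorm integrate aggregate
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

TASK_IDS <- c("task1", "task2", "task3", "demo")
CONDITION_IDS <- c("Q1", "Q2")

# Canonical block order used for 6-beta parameter vectors and state resets.
BLOCK_CELLS <- data.frame(
  task_id = rep(c("task1", "task2", "task3"), each = 2),
  condition_id = rep(c("Q1", "Q2"), 3),
  stringsAsFactors = FALSE
)

#' Canonical block index of a task/condition cell
#'
#' Blocks are ordered (task1.Q1, task1.Q2, task2.Q1, task2.Q2, task3.Q1,
#' task3.Q2). Condition-specific parameters (the 6-beta model variants, the
#' LBA bound for the time-pressure block) index conditions in this canonical
#' order, not in a subject's presentation order.
#'
#' @param task_id one of "task1", "task2", "task3"
#' @param condition_id "Q1" or "Q2"
#' @return integer in 1..6
#' @export
block_index <- function(task_id, condition_id) {
  i <- match(paste(task_id, condition_id),
             paste(BLOCK_CELLS$task_id, BLOCK_CELLS$condition_id))
  if (anyNA(i)) stop("unknown task/condition cell")
  i
}

#' Default task configuration
#'
#' Reward-probability matrices, per-state presentation counts and response
#' deadlines for the three experimental tasks (plus the illustrative "demo"
#' task with two states sharing a deterministically rewarded action). Rows
#' index states, columns actions, both in the canonical (remapped) space.
#'
#' Task 2's reward probabilities are fully determined by the design
#' (deterministic reward). Tasks 1 and 3 are probabilistic and only the
#' qualitative ordering of reward probabilities is pinned down by the design;
#' the defaults here (task 1: optimal 0.8 vs. two equal suboptimals at 0.2;
#' task 3: optimal 1.0, second-best 0.25, worst 0) satisfy the design
#' constraint that the two conditions of a task share the same maximum and
#' state-weighted mean of the per-state best reward.
#'
#' @return nested list keyed by task then condition, each cell holding
#'   `reward_prob` (3x3 matrix), `state_counts` (length-3 integer) and
#'   `deadline_ms` (scalar).
#' @export
default_task_config <- function() {
  rp1 <- rbind(c(0.8, 0.2, 0.2),
               c(0.2, 0.8, 0.2),
               c(0.2, 0.2, 0.8))
  rp2_q1 <- rbind(c(1, 0, 0),
                  c(0, 1, 0),
                  c(0, 0, 1))
  rp2_q2 <- rbind(c(1, 0, 0),
                  c(1, 1, 0),
                  c(1, 0, 1))
  # S1, S2 share deterministic-optimal A1; S3's optimal is A3 with A1 its
  # second-best action, so the marginal action distribution concentrates on A1.
  rp3 <- rbind(c(1.00, 0.25, 0.00),
               c(1.00, 0.25, 0.00),
               c(0.25, 0.00, 1.00))
  rp_demo <- rbind(c(1, 0, 0),
                   c(1, 0, 0),
                   c(0, 0, 1))
  list(
    task1 = list(
      Q1 = list(reward_prob = rp1, state_counts = c(30L, 30L, 30L), deadline_ms = 2000),
      Q2 = list(reward_prob = rp1, state_counts = c(90L, 30L, 30L), deadline_ms = 2000)
    ),
    task2 = list(
      Q1 = list(reward_prob = rp2_q1, state_counts = c(30L, 30L, 30L), deadline_ms = 2000),
      Q2 = list(reward_prob = rp2_q2, state_counts = c(30L, 30L, 30L), deadline_ms = 2000)
    ),
    task3 = list(
      Q1 = list(reward_prob = rp3, state_counts = c(30L, 30L, 30L), deadline_ms = 2000),
      Q2 = list(reward_prob = rp3, state_counts = c(30L, 30L, 30L), deadline_ms = 1000)
    ),
    demo = list(
      Q1 = list(reward_prob = rp_demo, state_counts = c(30L, 30L, 30L), deadline_ms = 2000),
      Q2 = list(reward_prob = rp_demo, state_counts = c(30L, 30L, 30L), deadline_ms = 2000)
    )
  )
}

#' Build one task x condition cell
#'
#' @param task_id one of "task1", "task2", "task3", "demo"
#' @param condition_id "Q1" or "Q2"
#' @param config task configuration, see [default_task_config()]
#' @return an object of class `polcomp_condition`: list with `task_id`,
#'   `condition_id`, `n_states`, `n_actions`, `reward_prob`, `state_counts`,
#'   `p_s` (normalized state distribution), `deadline_ms`, `time_pressure`
#'   (TRUE only for task3/Q2).
#' @export
build_condition <- function(task_id, condition_id, config = default_task_config()) {
  task_id <- match.arg(task_id, TASK_IDS)
  condition_id <- match.arg(condition_id, CONDITION_IDS)
  cell <- config[[task_id]][[condition_id]]
  if (is.null(cell)) stop("config has no entry for ", task_id, "/", condition_id)
  rp <- as.matrix(cell$reward_prob)
  counts <- as.integer(cell$state_counts)
  stopifnot(nrow(rp) == length(counts), all(rp >= 0 & rp <= 1), all(counts >= 0))
  validate_condition_pair(task_id, config)
  structure(list(
    task_id = task_id,
    condition_id = condition_id,
    n_states = nrow(rp),
    n_actions = ncol(rp),
    reward_prob = rp,
    state_counts = counts,
    p_s = counts / sum(counts),
    deadline_ms = cell$deadline_ms,
    time_pressure = identical(task_id, "task3") && identical(condition_id, "Q2")
  ), class = "polcomp_condition")
}

# Q1 and Q2 of a task must have the same maximum reward probability and the
# same state-weighted mean of the per-state best reward (motivation control).
validate_condition_pair <- function(task_id, config) {
  q1 <- config[[task_id]][["Q1"]]; q2 <- config[[task_id]][["Q2"]]
  stat <- function(cell) {
    rp <- as.matrix(cell$reward_prob)
    p_s <- cell$state_counts / sum(cell$state_counts)
    c(max(rp), sum(p_s * apply(rp, 1, max)))
  }
  if (max(abs(stat(q1) - stat(q2))) > 1e-12)
    stop("conditions of ", task_id,
         " violate the equal-maximum/equal-mean best-reward constraint")
  invisible(TRUE)
}

#' @export
print.polcomp_condition <- function(x, ...) {
  cat(sprintf("<%s/%s> %d states x %d actions, %d trials, deadline %g ms\n",
              x$task_id, x$condition_id, x$n_states, x$n_actions,
              sum(x$state_counts), x$deadline_ms))
  print(x$reward_prob)
  invisible(x)
}

#' Generate a seeded stimulus presentation sequence
#'
#' Uniformly shuffled sequence containing each state exactly
#' `state_counts[s]` times. States are 0-based.
#'
#' @param cond a `polcomp_condition`
#' @param seed integer seed
#' @return integer vector of 0-based states
#' @export
generate_trials <- function(cond, seed) {
  stopifnot(inherits(cond, "polcomp_condition"))
  states <- rep(seq_len(cond$n_states) - 1L, times = cond$state_counts)
  set.seed(seed)
  sample(states)
}

#' Sample binary feedback for a state/action pair
#'
#' Bernoulli draw with success probability `reward_prob[state, action]`.
#' Uses the current R random number stream.
#'
#' @param cond a `polcomp_condition`
#' @param state 0-based state index
#' @param action 0-based action index (must not be missing)
#' @return reward in {0, 1}
#' @export
sample_feedback <- function(cond, state, action) {
  if (is.na(action)) stop("missed trials earn reward 0; caller must short-circuit")
  p <- cond$reward_prob[state + 1L, action + 1L]
  rbinom(1L, 1L, p)
}

#' Randomized six-block experiment schedule for one subject
#'
#' Task order, and condition order within each task, are permuted from the
#' subject seed; every task x condition cell appears exactly once.
#'
#' @param subject_seed integer seed
#' @param config task configuration
#' @return data.frame with columns `task_id`, `condition_id`, `block`
#'   (canonical block index), in presentation order
#' @export
build_experiment <- function(subject_seed, config = default_task_config()) {
  set.seed(subject_seed)
  tasks <- sample(c("task1", "task2", "task3"))
  rows <- do.call(rbind, lapply(tasks, function(tk) {
    conds <- sample(c("Q1", "Q2"))
    data.frame(task_id = tk, condition_id = conds, stringsAsFactors = FALSE)
  }))
  rows$block <- block_index(rows$task_id, rows$condition_id)
  rows
}

#' Write / read trial data CSV
#'
#' Canonical tabular dialect: columns `subject`, `task`, `condition`, `trial`
#' (0-based within block), `state`, `action` (0-based; empty for a missed
#' response), `reward`, `rt_ms` (empty for a missed response), `deadline_ms`.
#'
#' @param trials data.frame of trials
#' @param path file path
#' @return `read_trials` returns the trials data.frame.
#' @export
write_trials <- function(trials, path) {
  cols <- c("subject", "task", "condition", "trial", "state", "action",
            "reward", "rt_ms", "deadline_ms")
  stopifnot(all(cols %in% names(trials)))
  write.csv(trials[, cols], path, row.names = FALSE, quote = FALSE, na = "")
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("subject", "task", "condition", "trial", "state", "action",
            "reward", "rt_ms", "deadline_ms")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("trial CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  for (cc in c("trial", "state", "action", "reward")) df[[cc]] <- as.integer(df[[cc]])
  df$rt_ms <- as.numeric(df$rt_ms)
  if (any(df$reward[is.na(df$action)] != 0))
    stop("missed trials must carry reward 0")
  ok <- !is.na(df$rt_ms) & df$rt_ms > df$deadline_ms
  if (any(ok)) stop("rt_ms exceeds deadline_ms on ", sum(ok), " trials")
  df
}

#' Write / read task configuration as JSON
#'
#' @param config nested task configuration list
#' @param path file path
#' @export
write_task_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (tk in names(cfg)) for (cd in names(cfg[[tk]])) {
    cfg[[tk]][[cd]]$reward_prob <- as.matrix(cfg[[tk]][[cd]]$reward_prob)
    cfg[[tk]][[cd]]$state_counts <- as.integer(cfg[[tk]][[cd]]$state_counts)
  }
  cfg
}
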