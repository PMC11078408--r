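# Synthetic cohorts: parameter sampling, whole-experiment simulation for N
# subjects, and lossless dataset round trips (trials CSV + truth sidecar).

#' Default per-parameter sampler for a model
#'
#' Uniform over the fitting bounds for every parameter except learning
#' rates, which are log-uniform over \[1e-2, upper\] so that cohorts are not
#' dominated by degenerate non-learners (a near-zero actor learning rate
#' produces flat, uninformative trajectories).
#'
#' @param model_id model id
#' @return named list of functions, each mapping n to n draws
#' @export
default_param_sampler <- function(model_id) {
  spec <- model_spec(model_id)
  samplers <- list()
  for (j in seq_along(spec$params)) {
    nm <- spec$params[j]
    lo <- spec$lower[j]; hi <- spec$upper[j]
    samplers[[nm]] <- if (grepl("^alpha", nm)) {
      local({
        hi0 <- hi
        function(n) exp(runif(n, log(1e-2), log(hi0)))
      })
    } else {
      local({
        lo0 <- lo; hi0 <- hi
        function(n) runif(n, lo0, hi0)
      })
    }
  }
  samplers
}

#' Cohort specification
#'
#' @param model_id generating model
#' @param n_subjects number of synthetic subjects
#' @param sampler named list of per-parameter sampling functions
#' @param master_seed integer seed; all sampling and simulation derive from it
#' @return object of class `polcomp_cohort_spec`
#' @export
cohort_spec <- function(model_id, n_subjects,
                        sampler = default_param_sampler(model_id),
                        master_seed = 1L) {
  model_id <- match.arg(model_id, ALL_MODELS)
  structure(list(model_id = model_id, n_subjects = as.integer(n_subjects),
                 sampler = sampler, master_seed = as.integer(master_seed)),
            class = "polcomp_cohort_spec")
}

#' Draw per-subject parameter vectors for a cohort
#'
#' Deterministic given the spec's master seed; every draw is validated
#' against the model's bounds (a sampler producing out-of-bounds values is
#' an error).
#'
#' @param spec a `polcomp_cohort_spec`
#' @return list of named parameter vectors, one per subject
#' @export
sample_parameters <- function(spec) {
  ms <- model_spec(spec$model_id)
  if (!all(ms$params %in% names(spec$sampler)))
    stop("sampler missing parameters: ",
         paste(setdiff(ms$params, names(spec$sampler)), collapse = ", "))
  set.seed(spec$master_seed)
  draws <- vapply(ms$params, function(nm) spec$sampler[[nm]](spec$n_subjects),
                  numeric(spec$n_subjects))
  if (spec$n_subjects == 1L) draws <- matrix(draws, nrow = 1,
                                             dimnames = list(NULL, ms$params))
  lapply(seq_len(spec$n_subjects), function(i) {
    check_params(spec$model_id, draws[i, ])
  })
}

#' Generate a synthetic cohort
#'
#' Samples per-subject parameters, derives independent per-subject seeds
#' from the master seed, and simulates each subject's full six-block
#' session. The generating parameters are retained as the truth table.
#'
#' @param spec a `polcomp_cohort_spec`
#' @param config task configuration
#' @return object of class `polcomp_cohort`: list with `model_id`, `trials`
#'   (all subjects, canonical dialect), `truth` (named list of generating
#'   parameter vectors), `seeds`
#' @export
generate_cohort <- function(spec, config = default_task_config()) {
  truth <- sample_parameters(spec)
  set.seed(spec$master_seed + 1L)
  seeds <- if (spec$n_subjects > 0)
    sample.int(.Machine$integer.max - 1L, spec$n_subjects) else integer()
  ids <- sprintf("sub%03d", seq_len(spec$n_subjects))
  names(truth) <- ids
  trials <- if (spec$n_subjects == 0) {
    empty_trials()
  } else {
    do.call(rbind, lapply(seq_len(spec$n_subjects), function(i) {
      simulate_session(spec$model_id, truth[[i]], subject_id = ids[i],
                       seed = seeds[i], config = config)
    }))
  }
  structure(list(model_id = spec$model_id, trials = trials, truth = truth,
                 seeds = seeds),
            class = "polcomp_cohort")
}

empty_trials <- function() {
  data.frame(subject = character(), task = character(), condition = character(),
             trial = integer(), state = integer(), action = integer(),
             reward = integer(), rt_ms = numeric(), deadline_ms = numeric(),
             stringsAsFactors = FALSE)
}

#' Write / read a cohort dataset
#'
#' Trials go to `trials.csv` in the canonical dialect; the generating model,
#' parameters and seeds go to a `truth.json` sidecar. The round trip is
#' lossless.
#'
#' @param cohort a `polcomp_cohort`
#' @param dir directory (created if needed)
#' @return `read_dataset` returns the `polcomp_cohort`.
#' @export
write_dataset <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(cohort$trials, file.path(dir, "trials.csv"))
  jsonlite::write_json(
    list(model_id = cohort$model_id,
         truth = lapply(cohort$truth, as.list),
         seeds = cohort$seeds),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  trials <- read_trials(file.path(dir, "trials.csv"))
  truth_path <- file.path(dir, "truth.json")
  meta <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  truth <- lapply(meta$truth, unlist)
  structure(list(model_id = meta$model_id, trials = trials, truth = truth,
                 seeds = meta$seeds),
            class = "polcomp_cohort")
}
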