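# Model registry: the five policy compression variants and the three
# non-compression comparison models, with their free parameters and box
# bounds used for fitting and for the default cohort sampler.

COMPRESSION_MODELS <- c("fixed_1b", "fixed_6b", "adaptive_capacity",
                        "adaptive_value", "adaptive_capacity_value")
LBA_MODELS <- c("std_rl_1b", "std_rl_6b", "rlwm")
ALL_MODELS <- c(COMPRESSION_MODELS, LBA_MODELS)

# Fixed (non-fitted) constants shared across models.
POLCOMP_CONST <- list(
  alpha_xi = 0.01,   # moving-average rate for the complexity estimate
  alpha_rho = 0.01,  # moving-average rate for the reward estimate
  sigma = 0.9,       # SD of Gaussian noise on log RT (compression models)
  t0 = 150,          # non-decision time, ms (all models)
  s_v = 0.1,         # LBA drift-rate SD
  beta_rl = 50,      # RLWM softmax inverse temperatures
  beta_wm = 50,
  beta_max = 100,    # clamp for adaptively updated trade-off weights
  p_a_floor = 1e-6,  # floor on the marginal action estimate
  rt_floor_ms = 1,   # floor on the RT regression inner term
  r_gap_min = 1e-3,  # |R - rho| clamp in the capacity-value beta update
  lba_A_floor = 1e-3, # start-point range floor in the LBA density
  lba_dens_floor = 1e-10 # per-trial LBA density floor used when fitting
)

#' Model specification
#'
#' Free-parameter names, box bounds, and family for one of the eight model
#' variants. Capacity parameters are expressed in nats internally; the
#' boundary `lb` between the `C` and `C_reduced` ranges defaults to 1 bit
#' (log 2 nats), which also guarantees `C_reduced <= C`.
#'
#' @param model_id one of `polcomp_models()`
#' @param lb boundary (nats) splitting the capacity range: `C` is bounded in
#'   `[lb, 3]` and `C_reduced` in `[0, lb]`
#' @return list with `model_id`, `family` ("compression" or "lba"), `variant`
#'   (integer code used by the compiled likelihood), `params` (names),
#'   `lower`, `upper`, `k` (free-parameter count)
#' @export
model_spec <- function(model_id, lb = log(2)) {
  model_id <- match.arg(model_id, ALL_MODELS)
  beta6 <- paste0("beta", 1:6)
  spec <- switch(model_id,
    fixed_1b = list(
      params = c("beta", "alpha_theta", "alpha_V", "alpha_P", "b1", "b2"),
      lower  = c(1, 0, 0, 0, 1, 1),
      upper  = c(30, 1, 1, 1, 500, 500)),
    fixed_6b = list(
      params = c(beta6, "alpha_theta", "alpha_V", "alpha_P", "b1", "b2"),
      lower  = c(rep(1, 6), 0, 0, 0, 1, 1),
      upper  = c(rep(30, 6), 1, 1, 1, 500, 500)),
    adaptive_capacity = list(
      params = c("C", "C_reduced", "beta0", "alpha_beta",
                 "alpha_theta", "alpha_V", "alpha_P", "b1", "b2"),
      lower  = c(lb, 0, 1, 0, 0, 0, 0, 1, 1),
      upper  = c(3, lb, 10, 1, 1, 1, 1, 500, 500)),
    adaptive_value = list(
      params = c("R", "R_reduced", "beta0", "alpha_beta",
                 "alpha_theta", "alpha_V", "alpha_P", "b1", "b2"),
      lower  = c(0, 0, 1, 0, 0, 0, 0, 1, 1),
      upper  = c(1, 1, 10, 1, 1, 1, 1, 500, 500)),
    adaptive_capacity_value = list(
      params = c("C", "C_reduced", "R", "beta0", "alpha_beta",
                 "alpha_theta", "alpha_V", "alpha_P", "b1", "b2"),
      lower  = c(lb, 0, 0, 1, 0, 0, 0, 0, 1, 1),
      upper  = c(3, lb, 1, 10, 1, 1, 1, 1, 500, 500)),
    std_rl_1b = list(
      params = c("beta", "alpha_Q", "A", "B1_minus_A", "B2_minus_A", "eta"),
      lower  = c(1, 0, 0, 0, 0, 0),
      upper  = c(30, 1, 500, 500, 500, 3)),
    std_rl_6b = list(
      params = c(beta6, "alpha_Q", "A", "B1_minus_A", "B2_minus_A", "eta"),
      lower  = c(rep(1, 6), 0, 0, 0, 0, 0),
      upper  = c(rep(30, 6), 1, 500, 500, 500, 3)),
    rlwm = list(
      params = c("C_wm", "alpha_RL", "phi", "rho_wm", "gamma",
                 "A", "B1_minus_A", "B2_minus_A", "eta"),
      lower  = c(2, 0, 0, 0, 0, 0, 0, 0, 0),
      upper  = c(5, 1, 1, 1, 1, 500, 500, 500, 3))
  )
  family <- if (model_id %in% COMPRESSION_MODELS) "compression" else "lba"
  variant <- if (family == "compression") match(model_id, COMPRESSION_MODELS)
             else match(model_id, LBA_MODELS)
  names(spec$lower) <- names(spec$upper) <- spec$params
  c(list(model_id = model_id, family = family, variant = variant,
         k = length(spec$params)), spec)
}

#' Names of all implemented model variants
#' @return character vector of model ids
#' @export
polcomp_models <- function() ALL_MODELS

#' Validate a parameter vector against a model's bounds
#'
#' @param model_id model id
#' @param params named numeric vector
#' @param lb capacity-range boundary, see [model_spec()]
#' @return the parameter vector, reordered to the canonical order
#' @export
check_params <- function(model_id, params, lb = log(2)) {
  spec <- model_spec(model_id, lb = lb)
  if (!all(spec$params %in% names(params)))
    stop("missing parameters: ",
         paste(setdiff(spec$params, names(params)), collapse = ", "))
  p <- unlist(params)[spec$params]
  bad <- p < spec$lower - 1e-9 | p > spec$upper + 1e-9
  if (any(bad))
    stop("parameters out of bounds: ", paste(spec$params[bad], collapse = ", "))
  if (all(c("C", "C_reduced") %in% spec$params) && p["C_reduced"] > p["C"] + 1e-9)
    stop("C_reduced must not exceed C")
  p
}

#' Serialize / deserialize a parameter vector as JSON
#'
#' @param params named numeric vector
#' @param path file path
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(as.list(params), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}
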