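# Synthetic cohorts: participants drawn from a population distribution in
# unconstrained space, simulated through the task. This is the stand-in
# for the (undeposited) human dataset and the substrate for all recovery
# and comparison harnesses.

# Population-average native-space values used as default generating means.
# They are on the scale of the published population estimates for the
# winning emotion-bonus model (beta 0.25, omega 0.68, option learning
# rates 0.53/0.19, partner learning rates 0.45/0.33, theta 0.069); gamma
# defaults to 0 and the emotion-split weights reuse omega's location.
DEFAULT_POP_MEANS <- c(beta = 0.25, omega = 0.68, omega_f = 0.68,
                       omega_n = 0.68, alpha_pos_opt = 0.53,
                       alpha_neg_opt = 0.19, alpha_pos_partner = 0.45,
                       alpha_neg_partner = 0.33, theta = 0.069,
                       gamma = 0)

#' Population specification for synthetic participants
#'
#' Participants are i.i.d. draws in unconstrained (logit) space:
#' `z ~ Normal(location, scale)` per free parameter, mapped through the
#' model's box transforms. Locations are given as native-space means for
#' readability and transformed internally; `scale` is the between-person
#' SD in unconstrained space (default 0.5, giving realistic dispersion,
#' e.g. omega roughly 0.45-0.85 for a 0.68 mean).
#'
#' @param spec a [model_spec()] or model id (the generating model).
#' @param means named numeric vector of native-space means; defaults cover
#'   every parameter and can be partially overridden.
#' @param scale positive scalar or named vector of unconstrained-space SDs.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(spec, means = NULL, scale = 0.5) {
  spec <- model_spec(spec)
  m <- DEFAULT_POP_MEANS
  if (!is.null(means)) {
    stopifnot(!is.null(names(means)), all(names(means) %in% PARAM_ORDER))
    m[names(means)] <- means
  }
  free <- spec$free_params
  location <- vapply(free, function(nm) transform_forward(nm, m[[nm]]), 0.0)
  if (any(!is.finite(location)))
    stop("population mean on a box boundary", call. = FALSE)
  if (length(scale) == 1) scale <- stats::setNames(rep(scale, length(free)),
                                                   free)
  stopifnot(all(free %in% names(scale)), all(scale >= 0))
  structure(list(spec = spec, location = location,
                 scale = scale[free], native_means = m[free]),
            class = "population_spec")
}

#' Draw one participant's parameters from a population
#'
#' @param pop a [population_spec()].
#' @return A [parameter_set()].
#' @export
sample_participant_parameters <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  z <- rnorm(length(pop$location), pop$location, pop$scale)
  to_constrained(z, pop$spec)
}

#' Generate a synthetic cohort
#'
#' Draws `n` participants from `pop`, simulates each through `design`
#' under the generating model, and returns both the ground-truth
#' parameters and the pooled trial table. Each participant gets a
#' deterministic sub-seed derived from `seed`, so cohorts are reproducible
#' and participants are independent of cohort size ordering.
#'
#' @param n cohort size (>= 1).
#' @param design a [build_experiment_design()] object.
#' @param spec generating [model_spec()] or model id.
#' @param pop a [population_spec()]; defaults to `population_spec(spec)`.
#' @param seed optional integer seed.
#' @return An object of class `gazerl_cohort`: `list(truth, trials, spec,
#'   seed)` where `truth` has one row per participant (native-space
#'   parameters) and `trials` is the pooled trial table.
#' @export
generate_cohort <- function(n, design, spec, pop = NULL, seed = NULL) {
  stopifnot(n >= 1)
  spec <- model_spec(spec)
  if (is.null(pop)) pop <- population_spec(spec)
  stopifnot(identical(pop$spec$model_id, spec$model_id))
  ids <- sprintf("p%03d", seq_len(n))
  truth <- vector("list", n)
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    params <- with_seed(derive_seed(seed, 2 * i - 1),
                        sample_participant_parameters(pop))
    truth[[i]] <- data.frame(participant_id = ids[i],
                             as.list(unlist(unclass(params))),
                             stringsAsFactors = FALSE)
    trials[[i]] <- simulate_agent(design, spec, params,
                                  seed = derive_seed(seed, 2 * i),
                                  participant_id = ids[i])
  }
  structure(list(truth = do.call(rbind, truth),
                 trials = do.call(rbind, trials),
                 spec = spec, seed = seed),
            class = "gazerl_cohort")
}

#' @export
print.gazerl_cohort <- function(x, ...) {
  cat(sprintf("<gazerl_cohort: %d participants x %d trials, model %d>\n",
              nrow(x$truth), nrow(x$trials) / nrow(x$truth),
              x$spec$model_id))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes the standard trial CSV plus a truth CSV (`participant_id` and
#' one column per native-space parameter) for recovery scoring.
#'
#' @param cohort a [generate_cohort()] result.
#' @param trials_path,truth_path output CSV paths.
#' @export
write_cohort <- function(cohort, trials_path, truth_path) {
  write_trials(cohort$trials, trials_path)
  write.csv(cohort$truth, truth_path, row.names = FALSE)
  invisible(cohort)
}
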