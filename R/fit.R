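# Per-participant penalized maximum likelihood in unconstrained space.
# The standard-normal penalty on the unconstrained parameters mirrors the
# Normal(0, 1) logit-space priors of the hierarchical scheme and keeps
# estimates off the box boundaries; the full hierarchical sampler lives in
# fit_hierarchical().

neg_log_posterior <- function(z, d, spec_c, spec, penalty) {
  p <- to_constrained(z, spec)
  ll <- sum(cpp_seq_loglik(d$block, d$partner, d$fearful, d$advised_good,
                           d$chosen_good, d$shock, spec_c, par_vector(p),
                           d$n_partners))
  if (!is.finite(ll)) return(1e10)
  -ll + if (penalty) 0.5 * sum(z^2) else 0
}

#' Fit one participant by multi-start penalized MLE
#'
#' Maximizes the summed trial log-likelihood over the model's
#' unconstrained parameter space. Starts are one zero vector (the box
#' centers) plus `n_starts - 1` uniform draws on `[-2, 2]`; the
#' `n_polish` most promising starts are polished with BFGS and the best
#' optimum kept.
#'
#' @param trials trial table of one participant.
#' @param spec a [model_spec()] or model id.
#' @param n_starts number of candidate start points (default 10).
#' @param n_polish how many starts are run through the optimizer.
#' @param penalty add the standard-normal unconstrained-space penalty
#'   (default TRUE).
#' @param seed optional integer seed for the random starts.
#' @param maxit BFGS iteration cap.
#' @return A list with `params` (native [parameter_set()]),
#'   `unconstrained`, `loglik` (unpenalized, at the optimum), `pointwise`
#'   (per-trial log-likelihood), `convergence` (0 = converged), and
#'   `n_starts`.
#' @export
fit_participant_mle <- function(trials, spec, n_starts = 10, n_polish = 3,
                                penalty = TRUE, seed = NULL, maxit = 300) {
  spec <- model_spec(spec)
  d <- trials_to_internal(trials)
  spec_c <- spec_code(spec)
  k <- length(spec$free_params)
  starts <- with_seed(seed, rbind(rep(0, k),
                                  matrix(runif((n_starts - 1) * k, -2, 2),
                                         ncol = k)))
  vals <- apply(starts, 1, neg_log_posterior, d = d, spec_c = spec_c,
                spec = spec, penalty = penalty)
  if (all(!is.finite(vals) | vals >= 1e10))
    stop("non-finite likelihood at all starts: data/model mismatch",
         call. = FALSE)
  keep <- order(vals)[seq_len(min(n_polish, nrow(starts)))]
  best <- NULL
  for (i in keep) {
    o <- optim(starts[i, ], neg_log_posterior, d = d, spec_c = spec_c,
               spec = spec, penalty = penalty, method = "BFGS",
               control = list(maxit = maxit))
    if (is.null(best) || o$value < best$value) best <- o
  }
  params <- to_constrained(best$par, spec)
  pw <- cpp_seq_loglik(d$block, d$partner, d$fearful, d$advised_good,
                       d$chosen_good, d$shock, spec_c, par_vector(params),
                       d$n_partners)
  list(params = params,
       unconstrained = stats::setNames(best$par, spec$free_params),
       loglik = sum(pw), pointwise = pw, convergence = best$convergence,
       n_starts = n_starts)
}

#' Fit every participant of a trial table by penalized MLE
#'
#' @param trials pooled trial table (column `participant_id` splits it).
#' @param spec a [model_spec()] or model id.
#' @param seed optional integer; expands into per-participant sub-seeds.
#' @param ... passed to [fit_participant_mle()].
#' @return An object of class `gazerl_fit`: `estimates` (one row per
#'   participant: native parameters, `loglik`, `convergence`),
#'   `unconstrained` (matrix), `pointwise` (named per-participant summed
#'   log-likelihood), `spec`, and `meta`.
#' @export
fit_cohort_mle <- function(trials, spec, seed = NULL, ...) {
  spec <- model_spec(spec)
  trials <- validate_trials(trials)
  ids <- unique(trials$participant_id)
  fits <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    fits[[i]] <- fit_participant_mle(
      trials[trials$participant_id == ids[i], , drop = FALSE],
      spec, seed = derive_seed(seed, hash_id(ids[i])), ...)
  }
  est <- do.call(rbind, lapply(seq_along(ids), function(i)
    data.frame(participant_id = ids[i],
               as.list(unlist(unclass(fits[[i]]$params))),
               loglik = fits[[i]]$loglik,
               convergence = fits[[i]]$convergence,
               stringsAsFactors = FALSE)))
  structure(list(
    estimates = est,
    unconstrained = do.call(rbind, lapply(fits, `[[`, "unconstrained")),
    pointwise = stats::setNames(vapply(fits, `[[`, 0.0, "loglik"), ids),
    spec = spec,
    meta = list(model_id = spec$model_id, seed = seed,
                method = "penalized_mle", n = length(ids))),
    class = "gazerl_fit")
}

#' @export
print.gazerl_fit <- function(x, ...) {
  cat(sprintf("<gazerl_fit: model %d, %d participants, total loglik %.1f>\n",
              x$spec$model_id, nrow(x$estimates), sum(x$pointwise)))
  invisible(x)
}

#' Serialize a fit as CSV plus JSON metadata
#'
#' @param fit a [fit_cohort_mle()] result.
#' @param csv_path per-participant estimates CSV.
#' @param meta_path JSON sidecar (model id, seed, method, convergence
#'   flags).
#' @export
write_fit <- function(fit, csv_path, meta_path = NULL) {
  write.csv(fit$estimates, csv_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- fit$meta
    meta$convergence <- fit$estimates$convergence
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, null = "null")
  }
  invisible(fit)
}

#' Posterior-predictive safe-choice trajectories
#'
#' Re-simulates every fitted participant `n_sims` times through `design`
#' and summarizes the safe-choice indicator per partner condition,
#' encounter (1st/2nd/3rd block with that partner) and within-block trial.
#'
#' @param fit a `gazerl_fit`.
#' @param design a [build_experiment_design()] object; each simulated
#'   replicate redraws the partner schedule.
#' @param n_sims simulations per participant.
#' @param seed optional integer seed.
#' @return Data frame with `reliability`, `emotion`, `encounter`, `trial`,
#'   `mean_safe`, `lo`, `hi` (95% interval over participant means).
#' @export
posterior_predict <- function(fit, design, n_sims = 100, seed = NULL) {
  stopifnot(inherits(fit, "gazerl_fit"))
  ids <- fit$estimates$participant_id
  acc <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    params <- do.call(parameter_set,
                      as.list(fit$estimates[i, PARAM_ORDER]))
    sims <- vector("list", n_sims)
    for (s in seq_len(n_sims)) {
      des <- build_experiment_design(design$n_blocks,
                                     design$trials_per_block,
                                     design$partners,
                                     design$shock_prob_bad,
                                     design$shock_prob_good,
                                     seed = derive_seed(seed,
                                                        i * 100000 + s))
      d <- simulate_agent(des, fit$spec, params,
                          seed = derive_seed(seed, i * 100000 + s + 50000),
                          participant_id = ids[i])
      # encounter index: rank of the block among that partner's blocks
      d$encounter <- stats::ave(d$block, d$partner_id,
                                FUN = function(b) match(b, sort(unique(b))))
      sims[[s]] <- d
    }
    sim <- do.call(rbind, sims)
    acc[[i]] <- aggregate(safe_choice ~ reliability + emotion + encounter +
                            trial, data = sim, FUN = mean)
  }
  all <- do.call(rbind, acc)
  out <- aggregate(safe_choice ~ reliability + emotion + encounter + trial,
                   data = all, FUN = function(x)
                     c(mean = mean(x),
                       lo = unname(quantile(x, 0.025)),
                       hi = unname(quantile(x, 0.975))))
  data.frame(out[, 1:4], mean_safe = out$safe_choice[, "mean"],
             lo = out$safe_choice[, "lo"], hi = out$safe_choice[, "hi"])
}
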