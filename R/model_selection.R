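# Participant-level predictive model comparison. Trials within a
# participant are not independent, so the pointwise unit for
# cross-validation is the participant: the log-likelihood is summed to the
# participant level before LOO. Two estimators are provided: PSIS-LOO for
# posterior draws and a participant-level k-fold fallback for MLE-only
# fits (where importance sampling has nothing to reweight).

#' Draws x participants pointwise log-likelihood matrix
#'
#' Each entry is the summed log-likelihood of one participant's trials
#' under one draw's parameters. An MLE fit contributes a single row.
#'
#' @param fit a `gazerl_fit` (one row) or `gazerl_hfit` (one row per
#'   posterior draw).
#' @param trials pooled trial table the fit was computed from.
#' @return Numeric matrix, columns named by participant.
#' @export
participant_pointwise_matrix <- function(fit, trials) {
  trials <- validate_trials(trials)
  if (inherits(fit, "gazerl_fit")) {
    ids <- fit$estimates$participant_id
    m <- matrix(fit$pointwise[ids], nrow = 1,
                dimnames = list(NULL, ids))
    return(m)
  }
  stopifnot(inherits(fit, "gazerl_hfit"))
  ids <- fit$participants
  spec_c <- spec_code(fit$spec)
  S <- nrow(fit$draws_mu)
  m <- matrix(NA_real_, S, length(ids), dimnames = list(NULL, ids))
  for (p in seq_along(ids)) {
    d <- trials_to_internal(
      trials[trials$participant_id == ids[p], , drop = FALSE])
    for (s in seq_len(S)) {
      m[s, p] <- sum(cpp_seq_loglik(
        d$block, d$partner, d$fearful, d$advised_good, d$chosen_good,
        d$shock, spec_c, par_vector(hfit_draw_params(fit, s, p)),
        d$n_partners))
    }
  }
  if (any(!is.finite(m)))
    stop("non-finite pointwise log-likelihood entries", call. = FALSE)
  m
}

# --- Pareto-smoothed importance sampling (Zhang-Stephens GPD fit) -------

gpd_fit <- function(x) {
  # x: positive exceedances, sorted ascending
  n <- length(x)
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  kfun <- function(th) mean(log1p(-th * x))
  lprof <- vapply(theta, function(th) {
    k <- kfun(th)
    n * (log(-th / k) - k - 1)
  }, 0.0)
  w <- exp(lprof - logsumexp(lprof))
  theta_hat <- sum(theta * w)
  k <- kfun(theta_hat)
  sigma <- -k / theta_hat
  # weakly informative prior pulling k toward 0.5
  k <- (n * k + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p)
  else sigma * expm1(-k * log1p(-p)) / k
}

# Smooth the upper tail of a log-weight vector; returns normalized log
# weights and the Pareto shape diagnostic.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (S < 16 || M < 5)
    return(list(lw = lw - logsumexp(lw), k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- exp(lw[ord[S - M]])
  exc <- sort(exp(lw[tail_ids]) - cutoff)
  if (max(exc) <= 0)
    return(list(lw = lw - logsumexp(lw), k = NA_real_))
  fit <- gpd_fit(exc[exc > 0])
  pq <- (seq_len(M) - 0.5) / M
  sm <- log(cutoff + qgpd(pq, fit$k, fit$sigma))
  sm <- pmin(sm, 0)  # cap at the raw maximum (lw was max-shifted)
  lw[tail_ids[order(lw[tail_ids])]] <- sm
  list(lw = lw - logsumexp(lw), k = fit$k)
}

#' Expected log predictive density by PSIS-LOO over participants
#'
#' Standard importance-sampling leave-one-out with Pareto-smoothed
#' weights, applied at the participant level. For a single-draw (MLE)
#' matrix the estimate degenerates to the sum of the entries with zero
#' effective parameters; use [elpd_kfold()] for a genuinely predictive
#' score in that case.
#'
#' @param ll_mat draws x participants matrix from
#'   [participant_pointwise_matrix()].
#' @return An object of class `gazerl_elpd`: `elpd`, `se`, `p_eff`,
#'   `p_eff_se`, `pointwise` (per participant), `pareto_k` diagnostics,
#'   and `method`.
#' @export
elpd_loo <- function(ll_mat) {
  stopifnot(is.matrix(ll_mat))
  if (any(!is.finite(ll_mat)))
    stop("non-finite entries in log-likelihood matrix", call. = FALSE)
  S <- nrow(ll_mat); P <- ncol(ll_mat)
  if (P < 2) stop("need at least 2 participants", call. = FALSE)
  ids <- colnames(ll_mat)
  if (S == 1) {
    pw <- drop(ll_mat)
    return(new_elpd(pw, pw, rep(NA_real_, P), ids, "loo_single_draw"))
  }
  lpd <- apply(ll_mat, 2, logsumexp) - log(S)
  pw <- numeric(P); ks <- numeric(P)
  for (p in seq_len(P)) {
    sm <- psis_smooth(-ll_mat[, p])
    pw[p] <- logsumexp(sm$lw + ll_mat[, p])
    ks[p] <- sm$k
  }
  out <- new_elpd(pw, lpd, ks, ids, "psis_loo")
  if (any(is.finite(ks) & ks > 0.7))
    warning(sprintf("unstable importance weights (pareto k > 0.7) for %d participant(s)",
                    sum(is.finite(ks) & ks > 0.7)), call. = FALSE)
  out
}

new_elpd <- function(pointwise, lpd, pareto_k, ids, method) {
  P <- length(pointwise)
  structure(list(
    elpd = sum(pointwise),
    se = sqrt(P * var(pointwise)),
    p_eff = sum(lpd - pointwise),
    p_eff_se = sqrt(P * var(lpd - pointwise)),
    pointwise = stats::setNames(pointwise, ids),
    lpd = stats::setNames(lpd, ids),
    pareto_k = pareto_k, method = method), class = "gazerl_elpd")
}

#' @export
print.gazerl_elpd <- function(x, ...) {
  cat(sprintf("<gazerl_elpd (%s): elpd %.2f (se %.2f), p_eff %.2f (se %.2f)>\n",
              x$method, x$elpd, x$se, x$p_eff, x$p_eff_se))
  invisible(x)
}

#' Participant-level k-fold cross-validated ELPD for MLE fits
#'
#' Splits participants into `k` folds; for each fold the population point
#' estimate is the mean of the training participants' unconstrained MLEs,
#' and each held-out participant is scored by their summed log-likelihood
#' at that population estimate. This measures how well the model
#' generalizes to a new participant, the same question participant-level
#' LOO answers for hierarchical posteriors.
#'
#' @param trials pooled trial table.
#' @param spec a [model_spec()] or model id.
#' @param k number of folds (capped at the number of participants).
#' @param fit optional pre-computed `gazerl_fit` of the same trials (to
#'   reuse the per-participant MLEs).
#' @param seed integer seed (fold assignment and fitting starts).
#' @param ... passed to [fit_cohort_mle()] when `fit` is NULL.
#' @return A `gazerl_elpd` with `method = "kfold"`; `p_eff` reports the
#'   within-sample optimism (own-MLE log-likelihood minus the CV score).
#' @export
elpd_kfold <- function(trials, spec, k = 10, fit = NULL, seed = NULL, ...) {
  spec <- model_spec(spec)
  trials <- validate_trials(trials)
  if (is.null(fit)) fit <- fit_cohort_mle(trials, spec, seed = seed, ...)
  ids <- fit$estimates$participant_id
  P <- length(ids)
  if (P < 2) stop("need at least 2 participants", call. = FALSE)
  k <- min(k, P)
  # fold labels attach to sorted ids, so the split is invariant to the
  # participants' order of appearance in the table
  fold_of <- stats::setNames(
    with_seed(derive_seed(seed, 999),
              sample(rep(seq_len(k), length.out = P))), sort(ids))
  folds <- fold_of[ids]
  spec_c <- spec_code(spec)
  pw <- numeric(P)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    pop <- colMeans(fit$unconstrained[-test, , drop = FALSE])
    params <- to_constrained(pop, spec)
    for (p in test) {
      d <- trials_to_internal(
        trials[trials$participant_id == ids[p], , drop = FALSE])
      pw[p] <- sum(cpp_seq_loglik(d$block, d$partner, d$fearful,
                                  d$advised_good, d$chosen_good, d$shock,
                                  spec_c, par_vector(params), d$n_partners))
    }
  }
  new_elpd(pw, fit$pointwise[ids], rep(NA_real_, P), ids, "kfold")
}

#' Model-comparison table
#'
#' Sorted descending by ELPD; the difference to the best model and its
#' standard error are computed from the paired per-participant pointwise
#' contributions.
#'
#' @param elpds named list of `gazerl_elpd` objects over the same
#'   participants.
#' @return A data frame of class `gazerl_comparison` with columns `model`,
#'   `delta_elpd`, `se_delta`, `elpd`, `se_elpd`, `p_eff`, `se_p_eff`.
#' @export
compare_models <- function(elpds) {
  stopifnot(is.list(elpds), length(elpds) >= 1)
  if (is.null(names(elpds)) || any(names(elpds) == ""))
    names(elpds) <- paste0("model_", seq_along(elpds))
  ids <- names(elpds[[1]]$pointwise)
  for (e in elpds)
    if (!identical(sort(names(e$pointwise)), sort(ids)))
      stop("mismatched participant sets across models", call. = FALSE)
  tot <- vapply(elpds, `[[`, 0.0, "elpd")
  best <- which.max(tot)
  best_pw <- elpds[[best]]$pointwise[ids]
  rows <- lapply(names(elpds), function(nm) {
    e <- elpds[[nm]]
    dpw <- e$pointwise[ids] - best_pw
    data.frame(model = nm, delta_elpd = sum(dpw),
               se_delta = sqrt(length(ids) * var(dpw)),
               elpd = e$elpd, se_elpd = e$se,
               p_eff = e$p_eff, se_p_eff = e$p_eff_se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$elpd), ]
  rownames(out) <- NULL
  class(out) <- c("gazerl_comparison", "data.frame")
  out
}

#' @export
print.gazerl_comparison <- function(x, ...) {
  cat("Model comparison (participant-level ELPD, best first)\n")
  print.data.frame(cbind(x[, 1, drop = FALSE],
                         round(x[, -1], 2)), row.names = FALSE)
  invisible(x)
}

#' Model-recovery confusion matrix
#'
#' Simulates cohorts from each generating model, fits every candidate
#' model, and records which candidate wins the ELPD comparison.
#'
#' @param generating_ids model ids to generate from.
#' @param candidate_ids model ids fitted to each cohort (default: the
#'   generating set).
#' @param design a [build_experiment_design()] object.
#' @param n participants per cohort.
#' @param pops optional named list of [population_spec()]s keyed by
#'   generating model id (as character); defaults per model.
#' @param n_reps cohorts per generating model.
#' @param seed integer seed.
#' @param k folds for [elpd_kfold()].
#' @param ... passed to [fit_cohort_mle()].
#' @return List with `confusion` (generating x candidate winner counts)
#'   and `details` (one row per cohort with the winning model).
#' @export
model_recovery <- function(generating_ids, candidate_ids = generating_ids,
                           design, n = 20, pops = NULL, n_reps = 5,
                           seed = NULL, k = 10, ...) {
  confusion <- matrix(0L, length(generating_ids), length(candidate_ids),
                      dimnames = list(paste0("gen_", generating_ids),
                                      paste0("fit_", candidate_ids)))
  details <- list()
  for (gi in seq_along(generating_ids)) {
    g <- generating_ids[gi]
    pop <- if (!is.null(pops)) pops[[as.character(g)]] else
      population_spec(g)
    for (rep_i in seq_len(n_reps)) {
      sub <- derive_seed(seed, gi * 1000 + rep_i)
      cohort <- generate_cohort(n, design, g, pop, seed = sub)
      elpds <- lapply(candidate_ids, function(cid)
        elpd_kfold(cohort$trials, cid, k = k,
                   seed = derive_seed(sub, cid), ...))
      names(elpds) <- paste0("fit_", candidate_ids)
      winner <- which.max(vapply(elpds, `[[`, 0.0, "elpd"))
      confusion[gi, winner] <- confusion[gi, winner] + 1L
      details[[length(details) + 1]] <-
        data.frame(generating = g, rep = rep_i,
                   winner = candidate_ids[winner],
                   stringsAsFactors = FALSE)
    }
  }
  list(confusion = confusion, details = do.call(rbind, details))
}
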