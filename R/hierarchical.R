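# Hierarchical fitting contract. The published analysis used NUTS in Stan;
# no Stan toolchain is assumed here, so the package ships a desk-scale
# random-walk Metropolis backend ("mh") with the same model structure:
# participant parameters are non-centred deviations from a population mean
# in unconstrained space, with Normal(0, 1) priors on population means
# (Normal(0, 0.5) for learning rates), half-normal priors on population
# SDs, and standard-normal deviations. Requesting an unavailable backend
# raises a capability error rather than crashing downstream.

LR_PARAMS <- c("alpha_pos_opt", "alpha_neg_opt",
               "alpha_pos_partner", "alpha_neg_partner")

#' Hierarchical fit of a cohort (pluggable backend)
#'
#' @param trials pooled trial table.
#' @param spec a [model_spec()] or model id.
#' @param backend `"mh"` (built-in random-walk Metropolis) is the only
#'   available backend; `"stan"` documents the contract for an external
#'   NUTS backend and raises a capability error.
#' @param n_iter,n_warmup total and warm-up iterations.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer seed; identical seed and configuration give
#'   identical draws.
#' @param step_z,step_mu,step_sigma random-walk proposal SDs.
#' @return An object of class `gazerl_hfit` with `draws_mu` (S x K
#'   population means, unconstrained), `draws_population` (S x K native
#'   scale), `draws_z` (S x K x P deviations), `accept` rates, `spec`,
#'   and `participants`.
#' @export
fit_hierarchical <- function(trials, spec, backend = c("mh", "stan"),
                             n_iter = 1000, n_warmup = 500, thin = 2,
                             seed = NULL, step_z = 0.15, step_mu = 0.08,
                             step_sigma = 0.08) {
  backend <- match.arg(backend)
  if (backend == "stan")
    stop(paste("capability error: no Stan/NUTS backend is available in",
               "this installation; use backend = 'mh' or fit_cohort_mle()"),
         call. = FALSE)
  spec <- model_spec(spec)
  trials <- validate_trials(trials)
  ids <- unique(trials$participant_id)
  P <- length(ids); K <- length(spec$free_params)
  dat <- lapply(ids, function(id)
    trials_to_internal(trials[trials$participant_id == id, , drop = FALSE]))
  spec_c <- spec_code(spec)
  ll_one <- function(p, z) {
    d <- dat[[p]]
    sum(cpp_seq_loglik(d$block, d$partner, d$fearful, d$advised_good,
                       d$chosen_good, d$shock, spec_c,
                       par_vector(to_constrained(z, spec)), d$n_partners))
  }
  prior_mu_sd <- ifelse(spec$free_params %in% LR_PARAMS, 0.5, 1)
  with_seed(seed, {
    mu <- rep(0, K); log_sig <- rep(log(0.5), K)
    z <- matrix(0, K, P)
    ll_p <- vapply(seq_len(P), function(p)
      ll_one(p, mu + exp(log_sig) * z[, p]), 0.0)
    lp_mu <- function(m) sum(stats::dnorm(m, 0, prior_mu_sd, log = TRUE))
    # half-normal on sigma plus log-Jacobian of the log transform
    lp_sig <- function(ls) sum(stats::dnorm(exp(ls), 0, 1, log = TRUE) + ls)
    n_keep <- floor((n_iter - n_warmup) / thin)
    draws_mu <- matrix(NA_real_, n_keep, K,
                       dimnames = list(NULL, spec$free_params))
    draws_z <- array(NA_real_, c(n_keep, K, P),
                     dimnames = list(NULL, spec$free_params, ids))
    draws_sig <- matrix(NA_real_, n_keep, K)
    acc <- c(z = 0, mu = 0, sigma = 0); kept <- 0
    for (it in seq_len(n_iter)) {
      sig <- exp(log_sig)
      for (p in seq_len(P)) {
        zp <- z[, p] + rnorm(K, 0, step_z)
        llp <- ll_one(p, mu + sig * zp)
        a <- llp - ll_p[p] - 0.5 * sum(zp^2) + 0.5 * sum(z[, p]^2)
        if (is.finite(a) && log(runif(1)) < a) {
          z[, p] <- zp; ll_p[p] <- llp; acc["z"] <- acc["z"] + 1 / P
        }
      }
      mu2 <- mu + rnorm(K, 0, step_mu)
      ll2 <- vapply(seq_len(P), function(p)
        ll_one(p, mu2 + sig * z[, p]), 0.0)
      a <- sum(ll2) - sum(ll_p) + lp_mu(mu2) - lp_mu(mu)
      if (is.finite(a) && log(runif(1)) < a) {
        mu <- mu2; ll_p <- ll2; acc["mu"] <- acc["mu"] + 1
      }
      ls2 <- log_sig + rnorm(K, 0, step_sigma)
      ll2 <- vapply(seq_len(P), function(p)
        ll_one(p, mu + exp(ls2) * z[, p]), 0.0)
      a <- sum(ll2) - sum(ll_p) + lp_sig(ls2) - lp_sig(log_sig)
      if (is.finite(a) && log(runif(1)) < a) {
        log_sig <- ls2; ll_p <- ll2; acc["sigma"] <- acc["sigma"] + 1
      }
      if (it > n_warmup && (it - n_warmup) %% thin == 0) {
        kept <- kept + 1
        draws_mu[kept, ] <- mu
        draws_sig[kept, ] <- exp(log_sig)
        draws_z[kept, , ] <- z
      }
    }
    pop_native <- draws_mu
    for (j in seq_len(K))
      pop_native[, j] <- transform_backward(spec$free_params[j],
                                            draws_mu[, j])
    structure(list(draws_mu = draws_mu, draws_sigma = draws_sig,
                   draws_population = pop_native, draws_z = draws_z,
                   accept = acc / n_iter, spec = spec,
                   participants = ids,
                   meta = list(backend = backend, n_iter = n_iter,
                               n_warmup = n_warmup, thin = thin,
                               seed = seed)),
              class = "gazerl_hfit")
  })
}

#' @export
print.gazerl_hfit <- function(x, ...) {
  cat(sprintf("<gazerl_hfit: model %d, %d participants, %d draws (mh)>\n",
              x$spec$model_id, length(x$participants), nrow(x$draws_mu)))
  cat("  posterior mean population parameters (native):\n")
  print(round(colMeans(x$draws_population), 3))
  cat(sprintf("  acceptance: z %.2f, mu %.2f, sigma %.2f\n",
              x$accept["z"], x$accept["mu"], x$accept["sigma"]))
  invisible(x)
}

# Native-space participant parameters of one posterior draw.
hfit_draw_params <- function(hfit, s, p) {
  z <- hfit$draws_mu[s, ] + hfit$draws_sigma[s, ] * hfit$draws_z[s, , p]
  to_constrained(z, hfit$spec)
}
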