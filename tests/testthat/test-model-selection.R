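test_that("pointwise matrices reduce to fit log-likelihoods", {
  d <- build_experiment_design(seed = 31)
  co <- generate_cohort(3, d, 3, population_spec(3, scale = 0.3),
                        seed = 32)
  fit <- fit_cohort_mle(co$trials, 3, seed = 1)
  m <- participant_pointwise_matrix(fit, co$trials)
  expect_identical(dim(m), c(1L, 3L))
  expect_equal(unname(m[1, ]), unname(fit$pointwise))
  # column sums match trial-level sums
  par_cols <- c("beta", "omega", "omega_f", "omega_n", "alpha_pos_opt",
                "alpha_neg_opt", "alpha_pos_partner", "alpha_neg_partner",
                "theta", "gamma")
  for (id in colnames(m)) {
    p <- do.call(parameter_set, as.list(
      fit$estimates[fit$estimates$participant_id == id, par_cols]))
    ll <- sequence_loglik(co$trials[co$trials$participant_id == id, ],
                          3, p)$total
    expect_equal(unname(m[1, id]), ll, tolerance = 1e-10)
  }
})

test_that("elpd_loo degenerate cases follow the closed forms", {
  # single draw: ELPD is the sum of entries, no effective parameters
  m1 <- matrix(c(-10, -12, -9), 1, dimnames = list(NULL, c("a", "b", "c")))
  e1 <- elpd_loo(m1)
  expect_equal(e1$elpd, -31)
  expect_equal(e1$p_eff, 0)
  expect_equal(e1$se, sqrt(3 * var(c(-10, -12, -9))))
  # identical columns: pointwise spread is zero
  col <- rnorm(40, -50, 0.3)
  m <- matrix(rep(col, 4), ncol = 4,
              dimnames = list(NULL, paste0("p", 1:4)))
  e <- elpd_loo(m)
  expect_equal(e$se, 0)
  expect_equal(e$elpd, 4 * e$pointwise[[1]])
  # two identical draws behave like one
  m2 <- m1[c(1, 1), , drop = FALSE]
  e2 <- elpd_loo(m2)
  expect_equal(e2$elpd, -31)
  expect_error(elpd_loo(m1[, 1, drop = FALSE]), "at least 2")
})

test_that("PSIS-LOO penalizes spread and stays below the in-sample lpd", {
  set.seed(21)
  S <- 400; P <- 12
  m <- matrix(rnorm(S * P, -30, 1.5), S, P,
              dimnames = list(NULL, paste0("p", 1:P)))
  # wide pointwise spread: the unstable-weight diagnostic must be loud
  expect_warning(e <- elpd_loo(m), "pareto k")
  lpd <- sum(apply(m, 2, function(x) {
    mx <- max(x); mx + log(mean(exp(x - mx)))
  }))
  expect_lt(e$elpd, lpd)
  expect_gt(e$p_eff, 0)
  expect_true(all(is.finite(e$pareto_k)))
})

test_that("comparison tables use paired differences and sort by ELPD", {
  pw <- stats::setNames(rnorm(8, -40, 4), paste0("p", 1:8))
  mk <- function(delta) {
    m <- matrix(pw + delta, 1, dimnames = list(NULL, names(pw)))
    elpd_loo(m)
  }
  tab <- compare_models(list(good = mk(0), ok = mk(-1), bad = mk(-3)))
  expect_identical(tab$model, c("good", "ok", "bad"))
  expect_equal(tab$delta_elpd, c(0, -8, -24))
  # constant shift per participant -> zero paired variance
  expect_equal(tab$se_delta, c(0, 0, 0))
  # comparing a model with itself
  self <- compare_models(list(a = mk(0), b = mk(0)))
  expect_equal(self$delta_elpd, c(0, 0))
  shuffled <- mk(0)
  names(shuffled$pointwise) <- paste0("q", 1:8)
  expect_error(compare_models(list(a = mk(0), b = shuffled)),
               "mismatched")
})

test_that("kfold ELPD prefers the generating model on synthetic data", {
  d <- build_experiment_design(seed = 51)
  co <- generate_cohort(12, d, 9,
                        population_spec(9, means = c(theta = 0.3),
                                        scale = 0.25), seed = 52)
  e9 <- elpd_kfold(co$trials, 9, k = 6, seed = 53)
  e1 <- elpd_kfold(co$trials, 1, k = 6, seed = 53)
  expect_gt(e9$elpd, e1$elpd)
  expect_identical(e9$method, "kfold")
  # ELPD invariant to participant order
  perm <- co$trials[order(rev(co$trials$participant_id),
                          co$trials$block, co$trials$trial), ]
  e9p <- elpd_kfold(perm, 9, k = 6, seed = 53)
  expect_equal(sort(e9p$pointwise), sort(e9$pointwise), tolerance = 1e-8)
})

test_that("one-cohort one-candidate recovery is a trivial 1x1 matrix", {
  d <- build_experiment_design(seed = 61)
  rec <- model_recovery(3, 3, d, n = 4, n_reps = 1, seed = 62, k = 4,
                        n_starts = 4)
  expect_identical(dim(rec$confusion), c(1L, 1L))
  expect_identical(rec$confusion[1, 1], 1L)
})
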