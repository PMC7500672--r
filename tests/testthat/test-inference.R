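test_that("parameter transforms are centred, boxed bijections", {
  centre <- parameter_set(omega = 0.5, beta = 1, alpha_pos_opt = 0.5,
                          alpha_neg_opt = 0.5, alpha_pos_partner = 0.5,
                          alpha_neg_partner = 0.5, theta = 0, gamma = 0)
  z <- to_unconstrained(centre, 9)
  expect_equal(unname(z), rep(0, 7), tolerance = 1e-12)
  # boundary values have no finite image
  expect_error(to_unconstrained(parameter_set(alpha_pos_opt = 0,
                                              beta = 0.5), 1),
               "transform-domain")
  set.seed(3)
  for (id in c(1, 5, 9, 13)) {
    spec <- model_spec(id)
    z <- runif(length(spec$free_params), -3, 3)
    p <- to_constrained(z, spec)
    expect_true(p$beta > 0 && p$beta <= 2)
    expect_true(abs(p$theta) <= 1 && abs(p$gamma) <= 1)
    expect_equal(unname(to_unconstrained(p, spec)), z, tolerance = 1e-10)
  }
})

test_that("population sampling respects transforms and box constraints", {
  pop <- population_spec(9, scale = 0)
  p <- sample_participant_parameters(pop)
  expect_equal(p$omega, 0.68, tolerance = 1e-12)
  expect_equal(p$beta, 0.25, tolerance = 1e-12)
  expect_equal(p$theta, 0.069, tolerance = 1e-12)
  # location 0 in unconstrained space -> median 0.5 for unit parameters
  pop0 <- population_spec(5, means = c(omega = 0.5), scale = 1.5)
  set.seed(8)
  om <- replicate(2001, sample_participant_parameters(pop0)$omega)
  expect_lt(abs(median(om) - 0.5), 0.05)
  expect_true(all(om > 0 & om < 1))
})

test_that("cohort generation is shaped and reproducible", {
  d <- build_experiment_design(seed = 1)
  co <- generate_cohort(3, d, 9, seed = 42)
  expect_identical(nrow(co$trials), 3L * 144L)
  expect_identical(nrow(co$truth), 3L)
  co2 <- generate_cohort(3, d, 9, seed = 42)
  expect_identical(co$trials, co2$trials)
  expect_identical(co$truth, co2$truth)
  # participants keep their draws when the cohort grows
  co4 <- generate_cohort(4, d, 9, seed = 42)
  expect_identical(co4$trials[seq_len(3 * 144), ], co$trials)
  # near-deterministic agent, predictive partner: near-perfect late blocks
  # (fast acquisition, slow unlearning, so stray shocks on the good
  # option do not flip the preference)
  pop <- population_spec(3, means = c(beta = 0.02, alpha_pos_opt = 0.9,
                                      alpha_neg_opt = 0.1,
                                      alpha_pos_partner = 0.9,
                                      alpha_neg_partner = 0.1), scale = 0)
  d1 <- build_experiment_design(4, 12, partners = standard_partners()[1, ],
                                seed = 3)
  co1 <- generate_cohort(1, d1, 3, pop, seed = 9)
  expect_gt(mean(co1$trials$safe_choice[co1$trials$trial > 4]), 0.85)
})

test_that("MLE fitting recovers simulated parameters and handles edge cases", {
  d <- build_experiment_design(seed = 10)
  truth <- table_params(omega = 0.75, theta = 0.2)
  tr <- do.call(rbind, lapply(1:2, function(i) {
    x <- simulate_agent(d, 9, truth, seed = 20 + i,
                        participant_id = paste0("p", i))
    x
  }))
  fit <- fit_cohort_mle(tr, 9, seed = 1)
  expect_identical(nrow(fit$estimates), 2L)
  expect_true(all(fit$estimates$convergence == 0))
  expect_true(all(abs(fit$estimates$omega - 0.75) < 0.25))
  expect_true(all(is.finite(fit$pointwise)))
  # model 3 clamps omega at 0.5
  f3 <- fit_participant_mle(tr[tr$participant_id == "p1", ], 3, seed = 2)
  expect_identical(f3$params$omega, 0.5)
  # single-trial dataset: flat likelihood, but no error
  f1 <- fit_participant_mle(tiny_trials()[1, ], 3, n_starts = 4, seed = 3)
  expect_true(is.finite(f1$loglik))
  # serialization
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, csv, js)
  expect_identical(nrow(read.csv(csv)), 2L)
  expect_identical(jsonlite::read_json(js)$model_id, 9L)
})

test_that("hierarchical backend honours its contract", {
  d <- build_experiment_design(seed = 4)
  co <- generate_cohort(6, d, 3, population_spec(3, scale = 0.3),
                        seed = 77)
  h <- fit_hierarchical(co$trials, 3, n_iter = 120, n_warmup = 60,
                        thin = 2, seed = 5)
  expect_s3_class(h, "gazerl_hfit")
  expect_identical(nrow(h$draws_mu), 30L)
  expect_true(all(is.finite(h$draws_mu)))
  pop <- colMeans(h$draws_population)
  expect_true(pop[["beta"]] > 0 && pop[["beta"]] <= 2)
  expect_true(all(pop[c("alpha_pos_opt", "alpha_neg_opt")] >= 0 &
                    pop[c("alpha_pos_opt", "alpha_neg_opt")] <= 1))
  h2 <- fit_hierarchical(co$trials, 3, n_iter = 120, n_warmup = 60,
                         thin = 2, seed = 5)
  expect_identical(h$draws_mu, h2$draws_mu)
  expect_error(fit_hierarchical(co$trials, 3, backend = "stan"),
               "capability error")
})

test_that("posterior predictions flatten in the noise-dominated limit", {
  d <- build_experiment_design(seed = 6)
  co <- generate_cohort(2, d, 3,
                        population_spec(3, means = c(beta = 1.99),
                                        scale = 0), seed = 8)
  fit <- fit_cohort_mle(co$trials, 3, seed = 2)
  # pin estimates at the flat agent: beta high, no learning
  fit$estimates[, c("alpha_pos_opt", "alpha_neg_opt",
                    "alpha_pos_partner", "alpha_neg_partner")] <- 0
  fit$estimates$beta <- 1.99
  pp <- posterior_predict(fit, d, n_sims = 30, seed = 3)
  expect_true(all(c("reliability", "encounter", "mean_safe") %in%
                    names(pp)))
  expect_lt(max(abs(pp$mean_safe - 0.5)), 0.2)
  expect_lt(abs(mean(pp$mean_safe) - 0.5), 0.03)
})
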