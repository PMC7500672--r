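test_that("the model table reproduces the fourteen-model layout", {
  tab <- model_table()
  expect_identical(nrow(tab), 14L)
  m1 <- model_spec(1)
  expect_false(m1$learn_partner)
  expect_identical(m1$transfer, "none")
  expect_setequal(m1$free_params, c("beta", "alpha_pos_opt",
                                    "alpha_neg_opt"))
  m2 <- model_spec(2)
  expect_false(m2$learn_options)
  expect_identical(m2$transfer, "weak")
  # odd multi-source models weak, even strong
  for (id in 3:14)
    expect_identical(model_spec(id)$transfer,
                     if (id %% 2 == 1) "weak" else "strong")
  expect_setequal(model_spec(9)$free_params,
                  c("beta", "omega", "alpha_pos_opt", "alpha_neg_opt",
                    "alpha_pos_partner", "alpha_neg_partner", "theta"))
  expect_setequal(model_spec(13)$free_params,
                  c("beta", "gamma", "alpha_pos_opt", "alpha_neg_opt",
                    "alpha_pos_partner", "alpha_neg_partner", "theta"))
  expect_error(model_spec(15), "1..14")
})

test_that("expected_value is the linear payoff map", {
  expect_identical(expected_value(0.5), 0)
  expect_identical(expected_value(1), 1)
  expect_equal(expected_value(0.8), 0.6)
  expect_error(expected_value(1.2), "corrupted")
})

test_that("effective_weight covers the four weighting schemes", {
  p <- parameter_set(omega = 0.7, omega_f = 0.9, omega_n = 0.2,
                     gamma = 0)
  expect_identical(effective_weight(3, p), 0.5)
  expect_identical(effective_weight(5, p), 0.7)
  expect_identical(effective_weight(7, p, "fearful"), 0.9)
  expect_identical(effective_weight(7, p, "neutral"), 0.2)
  # arbitration: symmetric errors, no bias -> 0.5
  expect_equal(effective_weight(11, p, last_abs_delta_option = 0.3,
                                last_abs_delta_partner = 0.3), 0.5)
  # |d_opt| = 0, |d_partner| = 1 -> e / (e + 1)
  expect_equal(effective_weight(11, p, last_abs_delta_option = 0,
                                last_abs_delta_partner = 1),
               exp(1) / (exp(1) + 1))
  # equal errors, gamma = 1 -> 1 / (1 + e)
  p$gamma <- 1
  expect_equal(effective_weight(11, p, last_abs_delta_option = 0.5,
                                last_abs_delta_partner = 0.5),
               1 / (1 + exp(1)))
})

test_that("value combination and choice rule match hand arithmetic", {
  expect_identical(combine_values(0, 0, 0, 0.3),
                   c(advised = 0, other = 0))
  q <- combine_values(0, 0, 0.6, 0.68, 0.069)
  expect_equal(q[["advised"]], 0.32 * 0.6 + 0.069)
  expect_equal(q[["other"]], 0)
  # omega = 1: advice has no influence beyond the bonus
  q <- combine_values(0.4, -0.2, 0.9, 1, 0.05)
  expect_equal(unname(q), c(0.45, -0.2))

  expect_identical(choice_probability(0.3, 0.3, 0.5), 0.5)
  expect_equal(choice_probability(0.5, 0, 0.25), 1 / (1 + exp(-2)))
  expect_gt(choice_probability(0.2, 0.1, 1e-4), 1 - 1e-10)
  expect_error(choice_probability(1, 0, 0), "positive")
})

test_that("prediction errors and updates follow the delta rule", {
  expect_equal(option_prediction_error(1, 0.5), 0.5)
  expect_equal(option_prediction_error(0, 0.8), -0.8)
  expect_equal(partner_prediction_error(1, TRUE, 0.6), 0.4)
  expect_equal(partner_prediction_error(1, FALSE, 0.6), -0.6)
  expect_equal(partner_prediction_error(0, FALSE, 0.6), 0.4)
  expect_equal(apply_update(0.5, 0.5, 0.53, 0.19), 0.765)
  expect_identical(apply_update(0.42, 0, 1, 1), 0.42)
  expect_identical(apply_update(0, 0, 0.5, 0.5), 0)
  # asymmetric rates pick the matching branch
  expect_equal(apply_update(0.5, -0.5, 0.53, 0.19), 0.5 - 0.19 * 0.5)
})

test_that("block transitions implement none/weak/strong transfer", {
  st <- init_agent_state(c("a", "b"))
  st$p_hat_partner[["a"]] <- 0.9
  st$p_hat_options[] <- c(0.1, 0.95)
  st$last_abs_delta_option <- 0.9

  weak <- transition_block(st, 3, "good", "a")
  expect_identical(unname(weak$p_hat_options), c(0.5, 0.5))
  expect_identical(weak$p_hat_partner[["a"]], 0.9)
  expect_identical(weak$last_abs_delta_option, 0.5)

  strong <- transition_block(st, 4, "good", "a")
  expect_equal(strong$p_hat_options[["good"]], 0.9)
  expect_equal(strong$p_hat_options[["bad"]], 0.1)
  expect_identical(strong$p_hat_partner[["a"]], 0.9)

  none <- transition_block(st, 1, "good", "a")
  expect_identical(unname(none$p_hat_options), c(0.5, 0.5))
  expect_identical(unname(none$p_hat_partner), c(0.5, 0.5))

  # uninformed partner: strong coincides with weak
  st$p_hat_partner[["a"]] <- 0.5
  expect_identical(transition_block(st, 4, "good", "a")$p_hat_options,
                   transition_block(st, 3, "good", "a")$p_hat_options)
})
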