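# Replay a trial table through the exported R primitives, returning the
# state after every trial (used for property checks on internal estimates).
replay_states <- function(trials, spec, params) {
  state <- init_agent_state(unique(trials$partner_id))
  cur <- -1L
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (tr$block != cur) {
      cur <- tr$block
      state <- transition_block(state, spec, tr$advised, tr$partner_id)
    }
    step <- trial_loglik(state, spec, params, tr)
    state <- step$state
    out[[i]] <- state
  }
  out
}

test_that("three-trial sequence matches an independent hand computation", {
  # Emotion-bonus model, fearful predictive partner; worked step by step
  # with raw arithmetic, independent of the package's likelihood code.
  tr <- tiny_trials(chosen = c("good", "bad", "good"),
                    shock = c(FALSE, TRUE, FALSE))
  p <- table_params()
  sig <- function(x) 1 / (1 + exp(-x))

  # trial 1: everything at 0.5 -> EVs 0; bonus only
  q_adv <- 0.68 * 0 + 0.32 * 0 + 0.069
  ll1 <- log(sig((q_adv - 0) / 0.25))
  p_g <- 0.5 + 0.53 * (1 - 0.5)          # chose good, no shock
  p_p <- 0.5 + 0.45 * (1 - 0.5)          # advice followed
  # trial 2: chose bad (against advice), shocked
  q_adv <- 0.68 * (2 * p_g - 1) + 0.32 * (2 * p_p - 1) + 0.069
  ll2 <- log(1 - sig(q_adv / 0.25))
  p_b <- 0.5 + 0.19 * (0 - 0.5)
  p_p <- p_p + 0.45 * ((1 - 0) - p_p)    # not followed, r = 0
  # trial 3: chose good again, no shock
  q_adv <- 0.68 * (2 * p_g - 1) + 0.32 * (2 * p_p - 1) + 0.069
  q_oth <- 0.68 * (2 * p_b - 1)
  ll3 <- log(sig((q_adv - q_oth) / 0.25))

  for (engine in c("cpp", "r")) {
    got <- sequence_loglik(tr, 9, p, engine = engine)
    expect_equal(got$pointwise, c(ll1, ll2, ll3), tolerance = 1e-12)
    expect_equal(got$total, ll1 + ll2 + ll3, tolerance = 1e-12)
  }
})

test_that("C++ and R likelihood engines agree across the model space", {
  tr <- fixture_trials()
  p <- table_params(gamma = 0.25, omega_f = 0.8, omega_n = 0.4,
                    theta = -0.1)
  for (id in 1:14) {
    a <- sequence_loglik(tr, id, p, engine = "cpp")
    b <- sequence_loglik(tr, id, p, engine = "r")
    expect_equal(a$pointwise, b$pointwise, tolerance = 1e-12,
                 info = paste("model", id))
  }
})

test_that("uninformed first trial has log(0.5) likelihood and sums add up", {
  tr <- tiny_trials(emotion = "neutral")
  for (id in c(1, 2, 3, 5, 9, 11)) {
    out <- sequence_loglik(tr, id, table_params(gamma = 0))
    expect_equal(out$pointwise[1], log(0.5), tolerance = 1e-12)
    expect_equal(out$total, sum(out$pointwise))
  }
})

test_that("probability estimates stay in [0, 1] over fuzzed sequences", {
  set.seed(99)
  for (rep in 1:8) {
    n <- 24
    tr <- tiny_trials(chosen = sample(c("bad", "good"), n, TRUE),
                      shock = sample(c(TRUE, FALSE), n, TRUE),
                      advised = sample(c("bad", "good"), n, TRUE),
                      block = rep(1:2, each = n / 2))
    p <- parameter_set(beta = runif(1, 0.05, 2), omega = runif(1),
                       alpha_pos_opt = runif(1), alpha_neg_opt = runif(1),
                       alpha_pos_partner = runif(1),
                       alpha_neg_partner = runif(1),
                       theta = runif(1, -1, 1), gamma = runif(1, -1, 1))
    id <- sample(1:14, 1)
    states <- replay_states(tr, id, p)
    for (st in states) {
      expect_true(all(st$p_hat_options >= 0 & st$p_hat_options <= 1))
      expect_true(all(st$p_hat_partner >= 0 & st$p_hat_partner <= 1))
      expect_true(st$last_abs_delta_option <= 1 &&
                    st$last_abs_delta_partner <= 1)
    }
    expect_true(all(is.finite(sequence_loglik(tr, id, p)$pointwise)))
  }
})

test_that("partner estimates converge to reliability in expectation", {
  # one agent per partner type, long horizon, averaged over seeds
  # symmetric partner learning rates, so the random-partner fixed point
  # sits at 0.5 (asymmetric rates move it to a_pos / (a_pos + a_neg))
  pred <- standard_partners()[2, ]; rand <- standard_partners()[4, ]
  p <- table_params(omega = 0.5, alpha_pos_partner = 0.4,
                    alpha_neg_partner = 0.4)
  final_pp <- function(partners, seeds) {
    vapply(seeds, function(s) {
      d <- build_experiment_design(4, 12, partners = partners, seed = s)
      tr <- simulate_agent(d, 3, p, seed = s + 1)
      st <- replay_states(tr, 3, p)
      st[[nrow(tr)]]$p_hat_partner[[1]]
    }, 0.0)
  }
  expect_gt(mean(final_pp(pred, 1:25)), 0.7)   # toward 1, outcome-limited
  expect_lt(abs(mean(final_pp(rand, 1:25)) - 0.5), 0.1)
})

test_that("simulation respects the deterministic and noise-dominated limits", {
  d <- build_experiment_design(4, 12, partners = standard_partners()[2, ],
                               seed = 2)
  # beta near 2 with no learning: chance throughout
  p0 <- parameter_set(beta = 2)
  tr <- do.call(rbind, lapply(1:40, function(s)
    simulate_agent(d, 3, p0, seed = s)))
  expect_lt(abs(mean(tr$safe_choice) - 0.5), 0.03)
  # moderate parameters, predictive partner: above-chance late trials
  p <- table_params(omega = 0.5)
  tr <- do.call(rbind, lapply(1:40, function(s)
    simulate_agent(d, 3, p, seed = 100 + s)))
  late <- tr$trial > 6
  expect_gt(mean(tr$safe_choice[late]), 0.6)
  # determinism
  expect_identical(simulate_agent(d, 3, p, seed = 5),
                   simulate_agent(d, 3, p, seed = 5))
})
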