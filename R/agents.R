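# Agent state, per-trial likelihood, block transitions and simulation.
# Two likelihood engines exist on purpose: the C++ path used by fitting and
# the grid simulations, and a step-by-step pure-R path composed from the
# exported primitives. The two are tested against each other to machine
# precision.

#' Initialize agent state
#'
#' All probability estimates start at 0.5 (uninformed); the previous-trial
#' absolute prediction errors that drive arbitration start at 0.5 as well,
#' so the first trial's weight depends only on `gamma`.
#'
#' @param partner_ids character vector of partner identifiers.
#' @return A list with `p_hat_options` (named `bad`/`good`),
#'   `p_hat_partner` (named by partner), `last_abs_delta_option`,
#'   `last_abs_delta_partner`.
#' @export
init_agent_state <- function(partner_ids) {
  list(p_hat_options = c(bad = 0.5, good = 0.5),
       p_hat_partner = stats::setNames(rep(0.5, length(partner_ids)),
                                       partner_ids),
       last_abs_delta_option = 0.5,
       last_abs_delta_partner = 0.5)
}

#' Apply the block-boundary transfer rule
#'
#' Options are novel in every block, so option estimates are
#' re-initialized. Under `none` transfer partner estimates are also reset
#' to 0.5; under `weak` transfer the cached partner estimates carry over;
#' under `strong` transfer the cached reliability of the block's partner
#' additionally seeds the new options: the option advised on the block's
#' first trial starts at the cached `p_hat_partner` and the other at its
#' complement. Arbitration traces reset to 0.5 with the options.
#'
#' @param state agent state from [init_agent_state()].
#' @param spec a [model_spec()] or model id.
#' @param first_trial_advised `"bad"` or `"good"`: the option advised on
#'   the first trial of the new block (needed for strong transfer).
#' @param partner_id the partner met in the new block.
#' @return Updated state.
#' @export
transition_block <- function(state, spec, first_trial_advised, partner_id) {
  spec <- model_spec(spec)
  state$last_abs_delta_option <- 0.5
  state$last_abs_delta_partner <- 0.5
  if (spec$transfer == "none")
    state$p_hat_partner[] <- 0.5
  if (spec$transfer == "strong") {
    cached <- state$p_hat_partner[[partner_id]]
    other <- setdiff(c("bad", "good"), first_trial_advised)
    state$p_hat_options[[first_trial_advised]] <- cached
    state$p_hat_options[[other]] <- 1 - cached
  } else {
    state$p_hat_options[] <- 0.5
  }
  state
}

#' Log-likelihood of one observed choice, plus the learning update
#'
#' Composes the valuation, choice and update rules for a single trial:
#' computes the log-probability of the observed choice under the current
#' state, then applies the Rescorla-Wagner updates for the chosen option
#' and the partner, and stores the absolute prediction errors for the next
#' trial's arbitration. Block transitions are the caller's responsibility
#' (see [transition_block()] and [sequence_loglik()]).
#'
#' @param state agent state.
#' @param spec a [model_spec()] or model id.
#' @param params a [parameter_set()].
#' @param trial a list or one-row data frame with `partner_id`, `emotion`,
#'   `advised`, `chosen`, `shock`.
#' @return `list(loglik = , state = )`.
#' @export
trial_loglik <- function(state, spec, params, trial) {
  spec <- model_spec(spec)
  params <- effective_parameters(params, spec)
  emo <- trial$emotion
  adv <- trial$advised
  oth <- setdiff(c("bad", "good"), adv)
  pid <- trial$partner_id
  w <- effective_weight(spec, params, emo,
                        state$last_abs_delta_option,
                        state$last_abs_delta_partner)
  theta_eff <- if (spec$emotion_bonus && identical(emo, "fearful"))
    params$theta else 0
  q <- combine_values(expected_value(state$p_hat_options[[adv]]),
                      expected_value(state$p_hat_options[[oth]]),
                      expected_value(state$p_hat_partner[[pid]]),
                      w, theta_eff)
  p_adv <- choice_probability(q[["advised"]], q[["other"]], params$beta)
  chose_advised <- trial$chosen == adv
  ll <- log(if (chose_advised) p_adv else 1 - p_adv)
  r <- as.numeric(!trial$shock)
  d <- option_prediction_error(r, state$p_hat_options[[trial$chosen]])
  if (spec$learn_options)
    state$p_hat_options[[trial$chosen]] <-
      apply_update(state$p_hat_options[[trial$chosen]], d,
                   params$alpha_pos_opt, params$alpha_neg_opt)
  state$last_abs_delta_option <- abs(d)
  dp <- partner_prediction_error(r, chose_advised,
                                 state$p_hat_partner[[pid]])
  if (spec$learn_partner)
    state$p_hat_partner[[pid]] <-
      apply_update(state$p_hat_partner[[pid]], dp,
                   params$alpha_pos_partner, params$alpha_neg_partner)
  state$last_abs_delta_partner <- abs(dp)
  list(loglik = ll, state = state)
}

#' Sequence log-likelihood of one participant's trials
#'
#' Runs the full trial loop (block transitions included) and returns the
#' total and pointwise log-likelihood of the observed choices. The
#' `"cpp"` engine is the fast path used everywhere internally; the
#' `"r"` engine composes [trial_loglik()] and [transition_block()] step by
#' step and exists as an independently-written cross-check.
#'
#' @param trials trial table of a single participant, ordered by block and
#'   trial.
#' @param spec a [model_spec()] or model id.
#' @param params a [parameter_set()].
#' @param engine `"cpp"` or `"r"`.
#' @return `list(total = , pointwise = )`.
#' @export
sequence_loglik <- function(trials, spec, params, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  spec <- model_spec(spec)
  params <- effective_parameters(params, spec)
  validate_parameter_set(params)
  if (length(unique(trials$participant_id)) > 1)
    stop("sequence_loglik expects a single participant", call. = FALSE)
  if (engine == "cpp") {
    d <- trials_to_internal(trials)
    pw <- cpp_seq_loglik(d$block, d$partner, d$fearful, d$advised_good,
                         d$chosen_good, d$shock, spec_code(spec),
                         par_vector(params), d$n_partners)
    return(list(total = sum(pw), pointwise = pw))
  }
  trials <- trials[order(trials$block, trials$trial), , drop = FALSE]
  state <- init_agent_state(unique(trials$partner_id))
  pw <- numeric(nrow(trials))
  cur_block <- -1L
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (tr$block != cur_block) {
      cur_block <- tr$block
      state <- transition_block(state, spec, tr$advised, tr$partner_id)
    }
    step <- trial_loglik(state, spec, params, tr)
    pw[i] <- step$loglik
    state <- step$state
  }
  list(total = sum(pw), pointwise = pw)
}

#' Simulate one agent through a task design
#'
#' Choices are sampled from the model's softmax probabilities, outcomes
#' from the option shock probabilities, and all learning and transfer rules
#' are applied exactly as in the likelihood.
#'
#' @param design a [build_experiment_design()] object.
#' @param spec a [model_spec()] or model id.
#' @param params a [parameter_set()].
#' @param seed optional integer seed.
#' @param participant_id id written into the returned table.
#' @return A trial table (see [write_trials()] for the column contract);
#'   `rt` is `NA` for simulated data.
#' @export
simulate_agent <- function(design, spec, params, seed = NULL,
                           participant_id = "sim1") {
  spec <- model_spec(spec)
  params <- effective_parameters(params, spec)
  validate_parameter_set(params)
  stopifnot(inherits(design, "task_design"))
  n_b <- design$n_blocks; n_t <- design$trials_per_block
  block <- rep(seq_len(n_b), each = n_t)
  partner_id <- design$schedule[block]
  pinfo <- design$partners[match(partner_id, design$partners$partner_id), ]
  partner_idx <- match(partner_id, design$partners$partner_id)
  sim <- with_seed(seed,
    cpp_simulate(as.integer(block), as.integer(partner_idx),
                 pinfo$emotion == "fearful",
                 pinfo$reliability == "predictive",
                 design$shock_prob_bad, design$shock_prob_good,
                 spec_code(spec), par_vector(params),
                 nrow(design$partners)))
  advised <- ifelse(sim$advised_good, "good", "bad")
  chosen <- ifelse(sim$chosen_good, "good", "bad")
  data.frame(participant_id = participant_id, block = block,
             trial = rep(seq_len(n_t), n_b), partner_id = partner_id,
             reliability = pinfo$reliability, emotion = pinfo$emotion,
             gaze_target = ifelse(advised == "good", "bad", "good"),
             advised = advised, chosen = chosen, shock = sim$shock,
             safe_choice = chosen == "good", rt = NA_real_,
             stringsAsFactors = FALSE, row.names = NULL)
}
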