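# The 14-model space: which value sources are learned, how the two sources
# are weighted, whether fearful partners get an additive choice bonus, and
# how learned information crosses block boundaries.

PARAM_ORDER <- c("beta", "omega", "omega_f", "omega_n",
                 "alpha_pos_opt", "alpha_neg_opt",
                 "alpha_pos_partner", "alpha_neg_partner",
                 "theta", "gamma")

TRANSFER_CODES  <- c(none = 0L, weak = 1L, strong = 2L)
WEIGHTING_CODES <- c(fixed_half = 0L, free = 1L, emotion_split = 2L,
                     arbitration = 3L)

MODEL_TABLE <- data.frame(
  model_id = 1:14,
  name = c("option_only", "gaze_only",
           "equal_weak", "equal_strong",
           "variable_weak", "variable_strong",
           "emotion_weight_weak", "emotion_weight_strong",
           "emotion_bonus_weak", "emotion_bonus_strong",
           "arbitration_weak", "arbitration_strong",
           "arbitration_bonus_weak", "arbitration_bonus_strong"),
  learn_options = c(TRUE, FALSE, rep(TRUE, 12)),
  learn_partner = c(FALSE, rep(TRUE, 13)),
  transfer = c("none", "weak", rep(c("weak", "strong"), 6)),
  weighting = c("fixed_half", "fixed_half", "fixed_half", "fixed_half",
                "free", "free", "emotion_split", "emotion_split",
                "free", "free", "arbitration", "arbitration",
                "arbitration", "arbitration"),
  emotion_bonus = c(rep(FALSE, 8), TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

model_free_params <- function(row) {
  ps <- "beta"
  if (row$learn_options) ps <- c(ps, "alpha_pos_opt", "alpha_neg_opt")
  if (row$learn_partner) ps <- c(ps, "alpha_pos_partner", "alpha_neg_partner")
  ps <- c(ps, switch(row$weighting,
                     fixed_half = character(),
                     free = "omega",
                     emotion_split = c("omega_f", "omega_n"),
                     arbitration = "gamma"))
  if (row$emotion_bonus) ps <- c(ps, "theta")
  PARAM_ORDER[PARAM_ORDER %in% ps]
}

#' Model configuration by integer id
#'
#' Returns the configuration of one of the fourteen candidate models:
#' which value sources are learned (`learn_options`, `learn_partner`), the
#' between-block transfer rule (`none`, `weak`, `strong`), the weighting
#' scheme combining option and partner values (`fixed_half`, `free`,
#' `emotion_split`, `arbitration`), whether fearful partners confer an
#' additive bonus `theta`, and the resulting free parameter names.
#'
#' Models 1-2 are the single-source null models (`omega` fixed at 0.5 and
#' the unused learning rates clamped to 0); models 3-4 use equal weighting;
#' 5-6 a free `omega`; 7-8 emotion-specific weights; 9-10 a free `omega`
#' plus the fearful-face bonus; 11-12 prediction-error arbitration; 13-14
#' arbitration plus the bonus. Even-numbered multi-source models use strong
#' transfer, odd-numbered ones weak transfer.
#'
#' @param model_id integer in 1..14.
#' @return An object of class `model_spec`.
#' @seealso [model_table()], [sequence_loglik()], [simulate_agent()]
#' @export
#' @examples
#' model_spec(9)
model_spec <- function(model_id) {
  if (inherits(model_id, "model_spec")) return(model_id)
  if (!(is.numeric(model_id) && length(model_id) == 1 &&
        model_id %in% 1:14))
    stop("`model_id` must be a single integer in 1..14", call. = FALSE)
  row <- MODEL_TABLE[MODEL_TABLE$model_id == model_id, , drop = FALSE]
  spec <- as.list(row)
  spec$free_params <- model_free_params(row)
  structure(spec, class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %d: %s>\n", x$model_id, x$name))
  cat(sprintf("  learn options: %s | learn partner: %s\n",
              x$learn_options, x$learn_partner))
  cat(sprintf("  transfer: %s | weighting: %s | emotion bonus: %s\n",
              x$transfer, x$weighting, x$emotion_bonus))
  cat("  free parameters:", paste(x$free_params, collapse = ", "), "\n")
  invisible(x)
}

#' Overview table of the fourteen candidate models
#'
#' @return A data frame with one row per model id.
#' @export
model_table <- function() MODEL_TABLE

# Integer encoding consumed by the C++ core.
spec_code <- function(spec) {
  spec <- model_spec(spec)
  c(as.integer(spec$learn_options), as.integer(spec$learn_partner),
    TRANSFER_CODES[[spec$transfer]], WEIGHTING_CODES[[spec$weighting]],
    as.integer(spec$emotion_bonus))
}

#' Construct a full parameter set
#'
#' Holds every parameter any of the fourteen models can use; parameters
#' inactive under a given [model_spec()] are simply ignored by the
#' likelihood and simulation. Box constraints: learning rates, `omega`,
#' `omega_f`, `omega_n` in `[0, 1]`; inverse gain `beta` in `(0, 2]`;
#' emotion bonus `theta` and arbitration bias `gamma` in `[-1, 1]`.
#'
#' @param beta softmax inverse gain; lower values give more deterministic
#'   choices.
#' @param omega weight on self-experienced option value (vs partner value).
#' @param omega_f,omega_n emotion-split weights for fearful / neutral
#'   partners.
#' @param alpha_pos_opt,alpha_neg_opt option learning rates for positive /
#'   negative prediction errors.
#' @param alpha_pos_partner,alpha_neg_partner partner learning rates.
#' @param theta additive bonus to the option advised by a fearful partner.
#' @param gamma arbitration bias; larger values shift weight toward the
#'   partner's advice.
#' @return An object of class `parameter_set` (a named list).
#' @export
parameter_set <- function(beta = 0.25, omega = 0.5,
                          omega_f = 0.5, omega_n = 0.5,
                          alpha_pos_opt = 0, alpha_neg_opt = 0,
                          alpha_pos_partner = 0, alpha_neg_partner = 0,
                          theta = 0, gamma = 0) {
  p <- list(beta = beta, omega = omega, omega_f = omega_f,
            omega_n = omega_n,
            alpha_pos_opt = alpha_pos_opt, alpha_neg_opt = alpha_neg_opt,
            alpha_pos_partner = alpha_pos_partner,
            alpha_neg_partner = alpha_neg_partner,
            theta = theta, gamma = gamma)
  validate_parameter_set(p)
  structure(p, class = "parameter_set")
}

validate_parameter_set <- function(p) {
  chk <- function(ok, what)
    if (!isTRUE(ok)) stop("invalid parameter_set: ", what, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (nm in PARAM_ORDER) chk(num1(p[[nm]]), paste(nm, "must be a number"))
  chk(p$beta > 0 && p$beta <= 2, "beta must be in (0, 2]")
  for (nm in c("omega", "omega_f", "omega_n", "alpha_pos_opt",
               "alpha_neg_opt", "alpha_pos_partner", "alpha_neg_partner"))
    chk(p[[nm]] >= 0 && p[[nm]] <= 1, paste(nm, "must be in [0, 1]"))
  for (nm in c("theta", "gamma"))
    chk(p[[nm]] >= -1 && p[[nm]] <= 1, paste(nm, "must be in [-1, 1]"))
  invisible(p)
}

# Clamp parameters that a model does not use to their fixed values, so that
# e.g. model 1 never learns about partners regardless of the input set.
effective_parameters <- function(params, spec) {
  spec <- model_spec(spec)
  p <- unclass(params)
  if (!spec$learn_options) p$alpha_pos_opt <- p$alpha_neg_opt <- 0
  if (!spec$learn_partner) p$alpha_pos_partner <- p$alpha_neg_partner <- 0
  if (spec$weighting == "fixed_half") p$omega <- 0.5
  if (spec$weighting != "emotion_split") p$omega_f <- p$omega_n <- 0.5
  if (spec$weighting != "arbitration") p$gamma <- 0
  if (!spec$emotion_bonus) p$theta <- 0
  structure(p, class = "parameter_set")
}

par_vector <- function(params) {
  unlist(unclass(params)[PARAM_ORDER], use.names = FALSE)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  print(round(unlist(unclass(x)), 4))
  invisible(x)
}

#' Expected value of a safety probability
#'
#' A shock is worth -1 and its absence +1, so an option (or a partner's
#' advice) believed safe with probability `p` has expected value
#' `2 * p - 1`.
#'
#' @param p probability in `[0, 1]`.
#' @return Value in `[-1, 1]`.
#' @export
expected_value <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("corrupted state: probability outside [0, 1]", call. = FALSE)
  2 * p - 1
}

#' Effective weight on option value for one trial
#'
#' Under `fixed_half` weighting this is 0.5; under `free` it is `omega`;
#' under `emotion_split` it is `omega_f` or `omega_n` depending on the
#' partner's expression; under `arbitration` it is a softmax of the
#' previous trial's absolute prediction errors,
#' `exp(1 - |d_opt|) / (exp(1 - |d_opt|) + exp(1 - |d_partner| + gamma))`,
#' so the more recently-reliable source gets more weight and `gamma`
#' biases the competition toward the partner.
#'
#' @param spec a [model_spec()] or model id.
#' @param params a [parameter_set()].
#' @param emotion `"fearful"` or `"neutral"`.
#' @param last_abs_delta_option,last_abs_delta_partner previous-trial
#'   absolute prediction errors (initialized at 0.5 after every block
#'   boundary).
#' @return Weight in `[0, 1]`.
#' @export
effective_weight <- function(spec, params, emotion = "neutral",
                             last_abs_delta_option = 0.5,
                             last_abs_delta_partner = 0.5) {
  spec <- model_spec(spec)
  switch(spec$weighting,
         fixed_half = 0.5,
         free = params$omega,
         emotion_split = if (identical(emotion, "fearful")) params$omega_f
                         else params$omega_n,
         arbitration = {
           a <- exp(1 - last_abs_delta_option)
           b <- exp((1 - last_abs_delta_partner) + params$gamma)
           a / (a + b)
         })
}

#' Combine option and partner values into action values
#'
#' The advised (non-gazed) option mixes its own expected value with the
#' expected value of the partner's advice; the other option carries only
#' its own (down-weighted) value. A fearful-partner bonus `theta_eff` is
#' added to the advised option's value.
#'
#' @param ev_advised,ev_other expected values of the advised and non-advised
#'   options.
#' @param ev_partner expected value of the partner's advice.
#' @param omega_eff weight on option value for this trial.
#' @param theta_eff additive bonus (0 for neutral partners or models
#'   without the bonus).
#' @return Named numeric `c(advised = , other = )`.
#' @export
combine_values <- function(ev_advised, ev_other, ev_partner, omega_eff,
                           theta_eff = 0) {
  c(advised = omega_eff * ev_advised + (1 - omega_eff) * ev_partner +
      theta_eff,
    other = omega_eff * ev_other)
}

#' Softmax probability of choosing the advised option
#'
#' @param q_advised,q_other action values.
#' @param beta inverse gain in `(0, 2]`; as `beta -> 0` choice becomes
#'   deterministic.
#' @return Probability of choosing the advised option.
#' @export
choice_probability <- function(q_advised, q_other, beta) {
  if (!is.numeric(beta) || beta <= 0)
    stop("beta must be positive", call. = FALSE)
  plogis((q_advised - q_other) / beta)
}

#' Option prediction error
#'
#' `delta = r - p_hat` where `r` is the no-shock indicator of the current
#' trial's outcome.
#'
#' @param r 1 if the chosen option did not shock, 0 otherwise.
#' @param p_hat current safety estimate of the chosen option.
#' @export
option_prediction_error <- function(r, p_hat) r - p_hat

#' Partner prediction error
#'
#' Congruent with the reinforcement received relative to the gaze cue:
#' if the advice was followed the partner is credited with the outcome,
#' otherwise with its complement.
#'
#' @param r no-shock indicator.
#' @param advice_followed did the agent choose the advised option?
#' @param p_hat_partner current reliability estimate.
#' @export
partner_prediction_error <- function(r, advice_followed, p_hat_partner) {
  if (advice_followed) r - p_hat_partner else (1 - r) - p_hat_partner
}

#' Rescorla-Wagner update with asymmetric learning rates
#'
#' @param p_hat current probability estimate.
#' @param delta prediction error; `delta = 0` applies no update.
#' @param alpha_pos,alpha_neg learning rates for positive / negative
#'   prediction errors, both in `[0, 1]`.
#' @return Updated estimate, guaranteed to remain in `[0, 1]`.
#' @export
apply_update <- function(p_hat, delta, alpha_pos, alpha_neg) {
  if (delta > 0) p_hat + alpha_pos * delta
  else if (delta < 0) p_hat + alpha_neg * delta
  else p_hat
}
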