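# Shared fixtures, built in code.

# Population-average-scale parameters for the winning emotion-bonus model.
table_params <- function(...) {
  args <- list(...)
  base <- list(beta = 0.25, omega = 0.68, alpha_pos_opt = 0.53,
               alpha_neg_opt = 0.19, alpha_pos_partner = 0.45,
               alpha_neg_partner = 0.33, theta = 0.069)
  base[names(args)] <- args
  do.call(parameter_set, base)
}

# A short hand-written single-partner trial table (one block).
tiny_trials <- function(chosen = c("good", "bad", "good"),
                        shock = c(FALSE, TRUE, FALSE),
                        advised = rep("good", length(chosen)),
                        emotion = "fearful", block = rep(1L, length(chosen)),
                        partner_id = "pF") {
  n <- length(chosen)
  data.frame(participant_id = "t1", block = block, trial = seq_len(n),
             partner_id = partner_id,
             reliability = "predictive", emotion = emotion,
             gaze_target = ifelse(advised == "good", "bad", "good"),
             advised = advised, chosen = chosen, shock = shock,
             safe_choice = chosen == "good", rt = NA_real_,
             stringsAsFactors = FALSE)
}

# A simulated mid-size dataset reused by several nesting/likelihood tests.
fixture_trials <- function(seed = 404) {
  design <- build_experiment_design(seed = seed)
  simulate_agent(design, 9, table_params(), seed = seed + 1)
}
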