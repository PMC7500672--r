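# Task environment: blocks of novel option pairs, a partner per block,
# gaze cues, and probabilistic shock outcomes. Options are abstract roles
# {bad, good} within a block (0.8 vs 0.2 shock probability); left/right
# position and fractal identity are randomized in the experiment and play
# no role in any model, so they are not represented.

#' The four standard social partners
#'
#' One partner per cell of the reliability (predictive / random) by
#' emotion (fearful / neutral) design. Predictive partners always gaze at
#' the bad option; random partners gaze at either option with equal
#' probability.
#'
#' @return A data frame with columns `partner_id`, `reliability`,
#'   `emotion`.
#' @export
standard_partners <- function() {
  data.frame(
    partner_id = c("pF", "pN", "rF", "rN"),
    reliability = c("predictive", "predictive", "random", "random"),
    emotion = c("fearful", "neutral", "fearful", "neutral"),
    stringsAsFactors = FALSE
  )
}

#' Build a block/partner schedule for the avoidance task
#'
#' The standard design has 12 blocks of 12 trials (144 trials) with four
#' partners, each met in three separate blocks. Partner order is a uniform
#' random permutation within each "round" of `nrow(partners)` blocks, so
#' every partner is encountered once before any partner repeats.
#'
#' @param n_blocks number of blocks; must be divisible by the number of
#'   partners.
#' @param trials_per_block trials per block.
#' @param partners data frame with columns `partner_id`, `reliability`,
#'   `emotion` (default [standard_partners()]).
#' @param shock_prob_bad,shock_prob_good shock probabilities of the two
#'   option roles; `shock_prob_bad` must exceed `shock_prob_good`.
#' @param seed optional integer making the schedule reproducible.
#' @param encounters_per_partner how many blocks each partner must appear
#'   in. Multi-partner designs default to the experiment's 3 encounters
#'   (so e.g. an 8-block schedule with 4 partners is rejected);
#'   single-partner designs, as used by the transfer simulations, are
#'   unconstrained. Pass a number to override.
#' @return An object of class `task_design`.
#' @export
#' @examples
#' d <- build_experiment_design(seed = 1)
#' table(d$schedule)  # each partner in 3 blocks
build_experiment_design <- function(n_blocks = 12, trials_per_block = 12,
                                    partners = standard_partners(),
                                    shock_prob_bad = 0.8,
                                    shock_prob_good = 0.2,
                                    seed = NULL,
                                    encounters_per_partner =
                                      if (nrow(partners) > 1) 3 else NULL) {
  stopifnot(is.data.frame(partners),
            all(c("partner_id", "reliability", "emotion") %in%
                  names(partners)))
  if (anyDuplicated(partners$partner_id))
    stop("duplicate partner_id in `partners`", call. = FALSE)
  if (!all(partners$reliability %in% c("predictive", "random")) ||
      !all(partners$emotion %in% c("fearful", "neutral")))
    stop("unknown reliability or emotion level", call. = FALSE)
  n_partners <- nrow(partners)
  if (n_blocks < 1 || trials_per_block < 1)
    stop("design error: block and trial counts must be positive",
         call. = FALSE)
  if (n_blocks %% n_partners != 0)
    stop(sprintf(paste("design error: %d blocks cannot be divided evenly",
                       "among %d partners"), n_blocks, n_partners),
         call. = FALSE)
  if (!is.null(encounters_per_partner) &&
      n_blocks != encounters_per_partner * n_partners)
    stop(sprintf(paste("design error: %d encounters per partner are",
                       "impossible with %d blocks and %d partners"),
                 encounters_per_partner, n_blocks, n_partners),
         call. = FALSE)
  if (!(shock_prob_bad >= 0 && shock_prob_bad <= 1 &&
        shock_prob_good >= 0 && shock_prob_good <= 1 &&
        shock_prob_bad > shock_prob_good))
    stop("design error: need shock_prob_bad > shock_prob_good in [0, 1]",
         call. = FALSE)
  schedule <- with_seed(seed, {
    rounds <- n_blocks / n_partners
    unlist(lapply(seq_len(rounds), function(i)
      sample(partners$partner_id, n_partners)))
  })
  structure(list(n_blocks = n_blocks, trials_per_block = trials_per_block,
                 partners = partners, schedule = schedule,
                 shock_prob_bad = shock_prob_bad,
                 shock_prob_good = shock_prob_good,
                 options_novel_per_block = TRUE, seed = seed),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("<task_design: %d blocks x %d trials, %d partners>\n",
              x$n_blocks, x$trials_per_block, nrow(x$partners)))
  cat("  schedule:", paste(x$schedule, collapse = " "), "\n")
  cat(sprintf("  shock P(bad) = %.2f, P(good) = %.2f\n",
              x$shock_prob_bad, x$shock_prob_good))
  invisible(x)
}

#' Draw gaze cues for a partner
#'
#' Predictive partners always gaze at the bad option; random partners'
#' gaze target is Bernoulli(0.5) over the two options.
#'
#' @param reliability `"predictive"` or `"random"` (a one-row partner data
#'   frame is also accepted).
#' @param n number of trials to draw.
#' @return Character vector of gaze targets, `"bad"` / `"good"`.
#' @export
draw_gaze_cue <- function(reliability, n = 1) {
  if (is.data.frame(reliability)) reliability <- reliability$reliability
  reliability <- match.arg(reliability, c("predictive", "random"))
  if (reliability == "predictive") rep("bad", n)
  else ifelse(runif(n) < 0.5, "bad", "good")
}

#' Advised option implied by a gaze target
#'
#' The gaze is read as a danger signal, so the advised option is the one
#' the partner is *not* looking at.
#'
#' @param gaze_target `"bad"` or `"good"` (vectorized).
#' @export
advised_option <- function(gaze_target) {
  if (!all(gaze_target %in% c("bad", "good")))
    stop("gaze_target must be 'bad' or 'good'", call. = FALSE)
  ifelse(gaze_target == "bad", "good", "bad")
}

#' Sample a shock outcome for a chosen option
#'
#' @param chosen_option `"bad"` or `"good"` (vectorized).
#' @param design a [build_experiment_design()] object.
#' @return Logical vector; `TRUE` means shock.
#' @export
sample_outcome <- function(chosen_option, design) {
  if (!all(chosen_option %in% c("bad", "good")))
    stop("chosen_option must be 'bad' or 'good'", call. = FALSE)
  p <- ifelse(chosen_option == "bad", design$shock_prob_bad,
              design$shock_prob_good)
  runif(length(chosen_option)) < p
}

TRIAL_COLUMNS <- c("participant_id", "block", "trial", "partner_id",
                   "reliability", "emotion", "gaze_target", "advised",
                   "chosen", "shock", "safe_choice", "rt")

# Validate a long-format trial table and coerce the columns the likelihood
# consumes. Errors cite offending row numbers (CLI schema contract).
validate_trials <- function(trials) {
  miss <- setdiff(setdiff(TRIAL_COLUMNS, "rt"), names(trials))
  if (length(miss))
    stop("trial table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"rt" %in% names(trials)) trials$rt <- NA_real_
  if (is.character(trials$shock))
    trials$shock <- trials$shock %in% c("TRUE", "true", "1")
  trials$shock <- as.logical(trials$shock)
  trials$safe_choice <- as.logical(trials$safe_choice)
  bad_rows <- function(ok, what) {
    if (!all(ok))
      stop(sprintf("invalid %s in trial table rows: %s", what,
                   paste(utils::head(which(!ok), 5), collapse = ", ")),
           call. = FALSE)
  }
  bad_rows(trials$block >= 1 & trials$trial >= 1, "block/trial index")
  bad_rows(trials$advised %in% c("bad", "good"), "advised")
  bad_rows(trials$chosen %in% c("bad", "good"), "chosen")
  bad_rows(trials$advised != trials$gaze_target, "gaze/advice pair")
  bad_rows(!is.na(trials$shock), "shock")
  bad_rows(trials$safe_choice == (trials$chosen == "good"), "safe_choice")
  trials
}

# One participant's table -> vectors for the C++ core. Partner indices are
# assigned in order of first appearance.
trials_to_internal <- function(trials) {
  ord <- order(trials$block, trials$trial)
  trials <- trials[ord, , drop = FALSE]
  partner_levels <- unique(trials$partner_id)
  list(block = as.integer(trials$block),
       partner = match(trials$partner_id, partner_levels),
       fearful = trials$emotion == "fearful",
       advised_good = trials$advised == "good",
       chosen_good = trials$chosen == "good",
       shock = as.logical(trials$shock),
       n_partners = length(partner_levels))
}

#' Write / read trial tables as CSV
#'
#' Fixed header `participant_id, block, trial, partner_id, reliability,
#' emotion, gaze_target, advised, chosen, shock, safe_choice, rt`; a
#' missing response time is written as an empty field.
#'
#' @param trials a trial table.
#' @param path file path.
#' @return `read_trials` returns the validated trial table.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE, na = "")
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  validate_trials(read.csv(path, stringsAsFactors = FALSE))
}
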