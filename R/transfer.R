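# Ecological simulations contrasting weak and strong transfer of cached
# partner reliability, on a single-partner task of 4 blocks x 12 trials
# with novel options per block. The two agents are the equal-weighting
# models (omega = 0.5): weak transfer carries only the partner estimate
# across blocks; strong transfer also seeds each new option pair from it.

#' Transfer-simulation scenario
#'
#' Three cue schedules over 48 trials: `stable_predictive` — the partner
#' gazes at the bad option on every trial; `reversal` — gazes bad on
#' trials 1-24 and good on trials 25-48 (a trusted source flips its
#' signal); `degradation` — gazes bad on trials 1-24 and uniformly at
#' random on trials 25-48 (the source becomes uninformative). Shock
#' probabilities are 0.8 / 0.2 as in the main experiment.
#'
#' @param scenario one of `"reversal"`, `"degradation"`,
#'   `"stable_predictive"`.
#' @param n_blocks,trials_per_block layout (default 4 x 12).
#' @param shock_prob_bad,shock_prob_good option shock probabilities.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("reversal", "degradation",
                                       "stable_predictive"),
                          n_blocks = 4, trials_per_block = 12,
                          shock_prob_bad = 0.8, shock_prob_good = 0.2) {
  scenario <- match.arg(scenario)
  stopifnot(n_blocks >= 1, trials_per_block >= 1,
            shock_prob_bad > shock_prob_good)
  structure(list(scenario = scenario, n_blocks = n_blocks,
                 trials_per_block = trials_per_block,
                 shock_prob_bad = shock_prob_bad,
                 shock_prob_good = shock_prob_good),
            class = "scenario_spec")
}

#' Parameter grid for the transfer simulations
#'
#' Evenly spaced samples (endpoints included) of the four learning rates
#' in `[0.1, 0.8]` and of the inverse gain `beta` in `[0.2, 1]`, fully
#' crossed; `omega` is fixed at 0.5. The publication-scale grid uses 12
#' points per dimension and 1000 replicates (about 250k combinations); the
#' scaled grid used by the acceptance harness uses 4 points and 500
#' replicates.
#'
#' @param points_per_dim grid points per dimension (>= 2).
#' @param n_reps simulation replicates per combination and model.
#' @param alpha_range,beta_range sampled intervals.
#' @return An object of class `grid_spec` with the `combos` data frame.
#' @export
grid_spec <- function(points_per_dim = 12, n_reps = 1000,
                      alpha_range = c(0.1, 0.8), beta_range = c(0.2, 1)) {
  stopifnot(points_per_dim >= 2, n_reps >= 1)
  a <- seq(alpha_range[1], alpha_range[2], length.out = points_per_dim)
  b <- seq(beta_range[1], beta_range[2], length.out = points_per_dim)
  combos <- expand.grid(alpha_pos_opt = a, alpha_neg_opt = a,
                        alpha_pos_partner = a, alpha_neg_partner = a,
                        beta = b, KEEP.OUT.ATTRS = FALSE)
  structure(list(points_per_dim = points_per_dim, n_reps = n_reps,
                 combos = combos), class = "grid_spec")
}

#' @rdname grid_spec
#' @export
scaled_grid_spec <- function() grid_spec(points_per_dim = 4, n_reps = 500)

#' Run a transfer scenario over a parameter grid
#'
#' Simulates the weak-transfer (model 3) and strong-transfer (model 4)
#' equal-weighting agents `n_reps` times for every grid combination and
#' returns per-combination, per-trial replicate means of the safe-choice
#' indicator and (optionally) of the internal estimates after each
#' trial's update.
#'
#' @param scenario a [scenario_spec()] or scenario name.
#' @param grid a [grid_spec()].
#' @param seed optional integer seed.
#' @param keep_trajectories retain mean internal-estimate trajectories.
#' @return An object of class `gazerl_scenario`: `safe` is a
#'   combinations x trials x model (`weak`, `strong`) array; `traj` holds
#'   matching arrays for `p_partner`, `p_bad`, `p_good`.
#' @export
run_scenario <- function(scenario, grid, seed = NULL,
                         keep_trajectories = TRUE) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(grid, "grid_spec"))
  if (nrow(grid$combos) == 0) stop("empty grid", call. = FALSE)
  code <- match(scenario$scenario,
                c("stable_predictive", "reversal", "degradation")) - 1L
  gm <- as.matrix(grid$combos[, c("alpha_pos_opt", "alpha_neg_opt",
                                  "alpha_pos_partner",
                                  "alpha_neg_partner", "beta")])
  res <- with_seed(seed,
    cpp_run_scenario(gm, code, scenario$n_blocks,
                     scenario$trials_per_block, grid$n_reps,
                     scenario$shock_prob_bad, scenario$shock_prob_good,
                     keep_trajectories))
  T <- scenario$n_blocks * scenario$trials_per_block
  C <- nrow(gm)
  to_array <- function(m) array(as.vector(m), dim = c(C, T, 2),
                                dimnames = list(NULL, NULL,
                                                c("weak", "strong")))
  structure(list(scenario = scenario, grid = grid, seed = seed,
                 safe = to_array(res$safe),
                 traj = if (keep_trajectories)
                   list(p_partner = to_array(res$p_partner),
                        p_bad = to_array(res$p_bad),
                        p_good = to_array(res$p_good))
                 else NULL),
            class = "gazerl_scenario")
}

#' @export
print.gazerl_scenario <- function(x, ...) {
  cat(sprintf("<gazerl_scenario: %s, %d combinations x %d reps, %d trials>\n",
              x$scenario$scenario, dim(x$safe)[1], x$grid$n_reps,
              dim(x$safe)[2]))
  invisible(x)
}

# Drop the model dimension of a combos x trials x model array without
# losing the matrix shape when a single combination is simulated.
slice_model <- function(a3, model) {
  x <- a3[, , model, drop = FALSE]
  dim(x) <- dim(x)[1:2]
  x
}

#' Contrast weak vs strong transfer over a trial window
#'
#' For each grid combination the two models' per-trial safe-choice means
#' (across replicates) are compared in the requested orientation. The
#' difference is the window mean of the per-trial differences, times 100
#' (percentage points); because differencing is linear this equals the
#' difference of window means. The ratio is taken at the trial level —
#' per trial, the ratio of the two models' safe-choice means — and then
#' averaged over the window (`ratio_unit = "trial"`, the default). Early
#' post-change trials, where the disadvantaged model is close to floor,
#' thus contribute large ratios, giving the right-skewed ratio
#' distribution these simulations are known for; `ratio_unit = "window"`
#' instead forms one ratio of window means per combination. Means and
#' 10%/90% quantiles are reported across grid combinations.
#'
#' Trials where the denominator model made zero safe choices across all
#' replicates yield a non-finite trial-level ratio and are excluded from
#' that combination's ratio average (a finite-replicate guard; such
#' trials become vanishingly rare as replicates grow).
#'
#' @param results a [run_scenario()] object.
#' @param window integer trial indices (1-based over the 48 trials), e.g.
#'   `13:24` for block 2, `25:36` for block 3, `25:30` for its first half.
#' @param direction `"strong_minus_weak"` or `"weak_minus_strong"`; the
#'   ratio uses the same orientation (first-named model in the
#'   numerator).
#' @param ratio_unit `"trial"` (default) or `"window"`; see Details.
#' @return A list: `mean_diff_pp`, `diff_q10`, `diff_q90`, `mean_ratio`,
#'   `ratio_q10`, `ratio_q90`, `n_combos`, `window`, `direction`,
#'   `ratio_unit`.
#' @export
summarize_contrast <- function(results, window,
                               direction = c("strong_minus_weak",
                                             "weak_minus_strong"),
                               ratio_unit = c("trial", "window")) {
  stopifnot(inherits(results, "gazerl_scenario"))
  direction <- match.arg(direction)
  ratio_unit <- match.arg(ratio_unit)
  T <- dim(results$safe)[2]
  if (any(window < 1 | window > T))
    stop("window outside simulated trial range", call. = FALSE)
  w <- slice_model(results$safe[, window, , drop = FALSE], "weak")
  s <- slice_model(results$safe[, window, , drop = FALSE], "strong")
  if (direction == "strong_minus_weak") { a <- s; b <- w } else {
    a <- w; b <- s }
  diff_pp <- rowMeans(a - b) * 100
  if (ratio_unit == "trial") {
    rt <- a / b
    rt[!is.finite(rt)] <- NA
    ratio <- rowMeans(rt, na.rm = TRUE)
  } else {
    ratio <- rowMeans(a) / rowMeans(b)
  }
  list(mean_diff_pp = mean(diff_pp),
       diff_q10 = unname(quantile(diff_pp, 0.10)),
       diff_q90 = unname(quantile(diff_pp, 0.90)),
       mean_ratio = mean(ratio, na.rm = TRUE),
       ratio_q10 = unname(quantile(ratio, 0.10, na.rm = TRUE)),
       ratio_q90 = unname(quantile(ratio, 0.90, na.rm = TRUE)),
       n_combos = nrow(a), window = window, direction = direction,
       ratio_unit = ratio_unit)
}

#' The five printed weak/strong transfer contrasts
#'
#' Convenience wrapper computing the block-2, block-3 and
#' first-half-of-block-3 contrasts of the reversal scenario and the
#' block-3 contrasts of the degradation scenario, in the orientations in
#' which they are conventionally reported (strong over weak while the
#' partner is stable, weak over strong after the change).
#'
#' @param reversal,degradation [run_scenario()] results for the two
#'   scenarios.
#' @return Data frame with one row per contrast.
#' @export
transfer_report <- function(reversal, degradation) {
  tpb <- reversal$scenario$trials_per_block
  b2 <- (tpb + 1):(2 * tpb)
  b3 <- (2 * tpb + 1):(3 * tpb)
  b3h <- (2 * tpb + 1):(2 * tpb + ceiling(tpb / 2))
  rows <- list(
    c(list(contrast = "reversal_block2_strong_over_weak"),
      summarize_contrast(reversal, b2, "strong_minus_weak")),
    c(list(contrast = "reversal_block3_weak_over_strong"),
      summarize_contrast(reversal, b3, "weak_minus_strong")),
    c(list(contrast = "reversal_block3_first_half_weak_over_strong"),
      summarize_contrast(reversal, b3h, "weak_minus_strong")),
    c(list(contrast = "degradation_block3_weak_over_strong"),
      summarize_contrast(degradation, b3, "weak_minus_strong")),
    c(list(contrast = "degradation_block3_first_half_weak_over_strong"),
      summarize_contrast(degradation, b3h, "weak_minus_strong")))
  do.call(rbind, lapply(rows, function(r)
    data.frame(contrast = r$contrast, mean_diff_pp = r$mean_diff_pp,
               diff_q10 = r$diff_q10, diff_q90 = r$diff_q90,
               mean_ratio = r$mean_ratio, ratio_q10 = r$ratio_q10,
               ratio_q90 = r$ratio_q90, stringsAsFactors = FALSE)))
}

#' Mean internal-estimate trajectories
#'
#' Per-trial means (across grid combinations) of the partner-reliability
#' and option-safety estimates after each trial's update, per model —
#' the quantities one would plot alongside the safe-choice trajectories.
#'
#' @param results a [run_scenario()] object with trajectories retained.
#' @return Long data frame: `model`, `trial`, `block`, `safe`,
#'   `p_partner`, `p_bad`, `p_good`.
#' @export
trajectory_estimates <- function(results) {
  stopifnot(inherits(results, "gazerl_scenario"))
  if (is.null(results$traj))
    stop("run_scenario() was called with keep_trajectories = FALSE",
         call. = FALSE)
  T <- dim(results$safe)[2]
  tpb <- results$scenario$trials_per_block
  out <- lapply(c("weak", "strong"), function(m)
    data.frame(model = m, trial = seq_len(T),
               block = (seq_len(T) - 1) %/% tpb + 1,
               safe = colMeans(slice_model(results$safe, m)),
               p_partner = colMeans(slice_model(results$traj$p_partner, m)),
               p_bad = colMeans(slice_model(results$traj$p_bad, m)),
               p_good = colMeans(slice_model(results$traj$p_good, m)),
               stringsAsFactors = FALSE))
  do.call(rbind, out)
}
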