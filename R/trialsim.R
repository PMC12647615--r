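#' Effect structure for the direct trial-table generator
#'
#' Population parameters on the scale of the trial x subregion HbDiff
#' outcome (µM). Defaults place the whole program effect (-19 µM for the
#' DNN program) in the left lateral subregion, a +13.46 µM right-handedness
#' offset, a 12 µM between-participant SD and a 60 µM trial-level residual
#' SD - noise of the magnitude real prefrontal recordings show at the
#' single-trial level.
#'
#' @param intercept left-lateral standard-program mean (µM).
#' @param program_effect named per-subregion change under the DNN program.
#' @param region_offset named per-subregion baseline shift relative to
#'   left lateral.
#' @param handedness_effect right-handed offset (µM).
#' @param sd_participant between-participant random-intercept SD.
#' @param sd_resid trial-level residual SD.
#' @param effort_slope_left µM change per effort-rating unit added to
#'   left-lateral trials (brain-behaviour coupling; 0 by default).
#' @return List of class `trial_effects`.
#' @export
trial_effects <- function(intercept = 4.2,
                          program_effect = c(left_lateral = -19,
                                             lower_medial = 0,
                                             right_lateral = 0),
                          region_offset = c(left_lateral = 0,
                                            lower_medial = 0,
                                            right_lateral = 0),
                          handedness_effect = 13.46,
                          sd_participant = 12,
                          sd_resid = 60,
                          effort_slope_left = 0) {
  structure(as.list(environment()), class = "trial_effects")
}

#' Simulate a study-sized trial table directly
#'
#' Generates the long trial x subregion analysis table at the statistical
#' level (no signal processing): participant random intercepts, fixed
#' program / region / handedness effects, trial-level behavioural records
#' and Gaussian residual noise. This is the workbench for validating the
#' multilevel machinery at the study's size (26 participants, 12
#' low-context trials per condition, 3 subregions).
#'
#' @param n_participants number of participants.
#' @param n_trials low-context trials per condition.
#' @param effects a [trial_effects()].
#' @param behav a [behaviour_params()].
#' @param seed integer seed.
#' @param n_left number of left-handed participants (study: 4 of 26).
#' @return Long data frame: `participant`, `condition`, `subregion`,
#'   `event`, `hbdiff`, `effort`, `correct`, `handedness`.
#' @export
simulate_trial_table <- function(n_participants = 26, n_trials = 12,
                                 effects = trial_effects(),
                                 behav = behaviour_params(), seed = 1,
                                 n_left = round(n_participants * 4 / 26)) {
  with_seed(derive_seed(seed, 6), {
    hand <- c(rep("left", n_left),
              rep("right", n_participants - n_left))
    u <- rnorm(n_participants, 0, effects$sd_participant)
    rows <- vector("list", n_participants)
    for (p in seq_len(n_participants)) {
      uc <- setNames(rnorm(2, 0, behav$effort_sd_cond), CONDITIONS)
      ue <- rnorm(1, 0, behav$effort_sd_between)
      grid <- expand.grid(trial = seq_len(n_trials), condition = CONDITIONS,
                          stringsAsFactors = FALSE)
      mu_eff <- behav$effort_mean[grid$condition] + ue + uc[grid$condition]
      effort <- pmin(pmax(round(mu_eff + rnorm(nrow(grid), 0,
                                               behav$effort_sd_trial)), 1), 7)
      correct <- rbinom(nrow(grid), 1, behav$p_correct[grid$condition])
      per_sub <- lapply(SUBREGIONS, function(s) {
        mu <- effects$intercept + effects$region_offset[s] +
          effects$program_effect[s] * (grid$condition == "dnn") +
          effects$handedness_effect * (hand[p] == "right") + u[p]
        if (s == "left_lateral" && effects$effort_slope_left != 0)
          mu <- mu + effects$effort_slope_left *
            (effort - mean(behav$effort_mean))
        data.frame(participant = sprintf("p%02d", p),
                   condition = grid$condition,
                   subregion = s,
                   event = grid$trial,
                   hbdiff = mu + rnorm(nrow(grid), 0, effects$sd_resid),
                   effort = as.integer(effort),
                   correct = correct,
                   handedness = hand[p],
                   stringsAsFactors = FALSE)
      })
      rows[[p]] <- do.call(rbind, per_sub)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
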