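#' Generative behavioral (psychometric) profile
#'
#' Holds, per cue and block, the mean (PSE) and SD (threshold) of the
#' cumulative-Gaussian observer that generates choices, plus a symmetric
#' lapse rate and the vestibular weight used for combined-cue trials.
#'
#' The block-to-block change is a step: the pre-recalibration PSEs apply
#' throughout the pre block and the post-recalibration PSEs throughout the
#' recalibration and post blocks.
#'
#' @param pse_deg Named list `list(vestibular = c(pre =, post =), visual = ...)`
#'   of PSEs in degrees.
#' @param sigma_deg Same structure, psychometric thresholds in degrees
#'   (all > 0).
#' @param lapse Symmetric lapse probability in `[0, 0.1]`.
#' @param w_vest Vestibular weight in `[0, 1]` for the combined-cue observer
#'   (visual weight is `1 - w_vest`).
#' @return An object of class `behavior_profile`.
#' @export
behavior_profile <- function(pse_deg = list(vestibular = c(pre = 0, post = 0),
                                            visual = c(pre = 0, post = 0)),
                             sigma_deg = list(vestibular = c(pre = 4, post = 4),
                                              visual = c(pre = 3, post = 3)),
                             lapse = 0.01,
                             w_vest = 0.6) {
  for (cue in c("vestibular", "visual")) {
    for (blk in c("pre", "post")) {
      if (is.null(pse_deg[[cue]][[blk]]) || is.null(sigma_deg[[cue]][[blk]])) {
        stop("pse_deg and sigma_deg need entries for ", cue, "/", blk)
      }
      if (sigma_deg[[cue]][[blk]] < 0) stop("sigma must be >= 0")
    }
  }
  if (lapse < 0 || lapse > 0.1) stop("lapse must lie in [0, 0.1]")
  if (w_vest < 0 || w_vest > 1) stop("w_vest must lie in [0, 1]")
  structure(list(pse_deg = pse_deg, sigma_deg = sigma_deg,
                 lapse = lapse, w_vest = w_vest),
            class = "behavior_profile")
}

#' Default conflict-reducing behavior for one session
#'
#' Convenience constructor: PSEs start at 0 in the pre block and step, post
#' recalibration, by `shift_vest_deg` (vestibular) and `shift_vis_deg`
#' (visual), both multiplied by `delta_sign`. With the defaults and a
#' positive discrepancy the vestibular psychometric curve shifts rightward
#' (+1.5 deg) and the visual curve leftward (-0.9 deg) -- both cues move so
#' as to reduce the cue conflict, with the vestibular magnitude the larger
#' of the two.
#'
#' @param delta_sign +1 for a delta+ session, -1 for delta-.
#' @param shift_vest_deg,shift_vis_deg Post-minus-pre PSE steps in degrees
#'   for a delta+ session.
#' @param sigma_vest_deg,sigma_vis_deg Psychometric thresholds in degrees.
#' @param lapse,w_vest Passed to [behavior_profile()].
#' @export
default_behavior <- function(delta_sign = 1,
                             shift_vest_deg = 1.5,
                             shift_vis_deg = -0.9,
                             sigma_vest_deg = 4,
                             sigma_vis_deg = 3,
                             lapse = 0.01,
                             w_vest = 0.6) {
  stopifnot(delta_sign %in% c(-1, 1))
  behavior_profile(
    pse_deg = list(
      vestibular = c(pre = 0, post = delta_sign * shift_vest_deg),
      visual = c(pre = 0, post = delta_sign * shift_vis_deg)),
    sigma_deg = list(vestibular = c(pre = sigma_vest_deg, post = sigma_vest_deg),
                     visual = c(pre = sigma_vis_deg, post = sigma_vis_deg)),
    lapse = lapse, w_vest = w_vest)
}

#' Draw session-level behavioral variability around a base profile
#'
#' Sessions differ in how strongly they recalibrate. A common per-session
#' adaptation gain `g ~ N(1, gain_sd)` scales both cues' generative PSE
#' steps (keeping the vestibular and visual shifts anti-correlated, as
#' expected when both cues shift to reduce the same conflict), with small
#' independent per-cue noise added, and the pre-block PSEs jittered around
#' zero.
#'
#' The default gain SD of 1 reproduces session-to-session spreads on the
#' order of the mean shift itself (some sessions recalibrate strongly,
#' some barely, a minority in the counter-adaptive direction), which is the
#' regime heading-recalibration experiments report.
#'
#' @param base A [behavior_profile()] whose post-minus-pre PSE steps define
#'   the mean recalibration.
#' @param gain_sd SD of the shared adaptation gain.
#' @param noise_sd_deg SD (deg) of independent per-cue shift noise.
#' @param pse_jitter_sd_deg SD (deg) of pre-block PSE jitter.
#' @return A `behavior_profile` with attribute `true_shift_deg`, a named
#'   vector of the session's generative PSE shifts.
#' @export
sample_session_behavior <- function(base = default_behavior(),
                                    gain_sd = 1.0,
                                    noise_sd_deg = 0.4,
                                    pse_jitter_sd_deg = 0.3) {
  g <- stats::rnorm(1, 1, gain_sd)
  pse <- base$pse_deg
  shifts <- c(vestibular = NA_real_, visual = NA_real_)
  for (cue in c("vestibular", "visual")) {
    step <- base$pse_deg[[cue]][["post"]] - base$pse_deg[[cue]][["pre"]]
    sh <- g * step + stats::rnorm(1, 0, noise_sd_deg)
    pre <- stats::rnorm(1, 0, pse_jitter_sd_deg)
    pse[[cue]] <- c(pre = pre, post = pre + sh)
    shifts[[cue]] <- sh
  }
  out <- behavior_profile(pse_deg = pse, sigma_deg = base$sigma_deg,
                          lapse = base$lapse, w_vest = base$w_vest)
  attr(out, "true_shift_deg") <- shifts
  out
}

# effective (cue-weighted) heading and combined-observer parameters for a
# block; single-cue trials use that cue's parameters directly
observer_params <- function(trials, behavior) {
  blk <- ifelse(trials$block == "pre", "pre", "post")
  w <- behavior$w_vest
  pse <- sigma <- h_eff <- numeric(nrow(trials))
  for (cue in c("vestibular", "visual")) {
    i <- trials$modality == cue
    pse[i] <- behavior$pse_deg[[cue]][blk[i]]
    sigma[i] <- behavior$sigma_deg[[cue]][blk[i]]
    h_eff[i] <- trials$heading_deg[i]
  }
  i <- trials$modality == "combined"
  if (any(i)) {
    pse[i] <- w * behavior$pse_deg$vestibular[blk[i]] +
      (1 - w) * behavior$pse_deg$visual[blk[i]]
    sigma[i] <- sqrt(w^2 * behavior$sigma_deg$vestibular[blk[i]]^2 +
                       (1 - w)^2 * behavior$sigma_deg$visual[blk[i]]^2)
    h_eff[i] <- w * trials$vest_heading_deg[i] +
      (1 - w) * trials$vis_heading_deg[i]
  }
  list(pse = pse, sigma = sigma, h_eff = h_eff)
}

#' Probability of a rightward choice under the generative observer
#'
#' `P(right) = lapse/2 + (1 - lapse) * pnorm((h_eff - PSE) / sigma)`, where
#' for combined-cue trials `h_eff` is the vestibular-weighted average of the
#' two cue headings and the PSE/threshold come from the weighted-average
#' observer. A zero threshold degenerates to a step function.
#'
#' @param trials Trial table rows (see [build_trial_schedule()]).
#' @param behavior A [behavior_profile()].
#' @return Numeric vector of rightward-choice probabilities.
#' @export
p_rightward <- function(trials, behavior) {
  ob <- observer_params(trials, behavior)
  core <- ifelse(ob$sigma > 0,
                 stats::pnorm((ob$h_eff - ob$pse) / ob$sigma),
                 (ob$h_eff > ob$pse) + 0.5 * (ob$h_eff == ob$pse))
  behavior$lapse / 2 + (1 - behavior$lapse) * core
}

#' Simulate choices and rewards for a trial schedule
#'
#' Draws a left/right choice for every trial that requires one (all pre- and
#' post-block trials; recalibration-block trials keep `choice = "none"`),
#' then applies the reward rule tagged on each trial: `deterministic` trials
#' are rewarded with probability `reward_p_correct` when the choice matches
#' the sign of the task-relevant heading and never otherwise; `stochastic`
#' trials are rewarded with probability `reward_p_stochastic` regardless of
#' choice; `fixation` trials (recalibration block) are always rewarded.
#'
#' @param trials Trial table from [build_trial_schedule()].
#' @param cfg The [paradigm_config()] (for reward probabilities).
#' @param behavior A [behavior_profile()].
#' @return The trial table with `choice` and `rewarded` filled in.
#' @export
simulate_choices <- function(trials, cfg, behavior) {
  stopifnot(inherits(cfg, "paradigm_config"),
            inherits(behavior, "behavior_profile"))
  p <- p_rightward(trials, behavior)
  need <- trials$block != "recal"
  right <- stats::runif(nrow(trials)) < p
  trials$choice[need] <- ifelse(right[need], "right", "left")

  correct <- sign(trials$heading_deg) == ifelse(trials$choice == "right", 1, -1)
  u <- stats::runif(nrow(trials))
  det <- need & trials$reward_rule == "deterministic"
  sto <- need & trials$reward_rule == "stochastic"
  trials$rewarded[det] <- correct[det] & (u[det] < cfg$reward_p_correct)
  trials$rewarded[sto] <- u[sto] < cfg$reward_p_stochastic
  trials
}
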