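#' Configuration of the three-block cue-conflict paradigm
#'
#' Defines the trial structure of one recording session: a pre-recalibration
#' block of randomly interleaved single-cue (vestibular / visual) heading
#' discrimination trials; a recalibration block of combined-cue trials in
#' which a vestibular-visual discrepancy (delta) is ramped up gradually and
#' then held at its maximum (no choices required); and a post-recalibration
#' block in which single-cue trials are re-tested, interleaved with
#' combined-cue trials at the maximum discrepancy to maintain recalibration.
#'
#' The sign of `delta_max_deg` encodes the conflict orientation: positive
#' (delta+) offsets the vestibular cue rightward and the visual cue leftward
#' (each by delta/2), negative (delta-) the reverse.
#'
#' @param headings_deg Signed heading angles in degrees; must be symmetric
#'   about zero and nonzero. Default: ten log-spaced headings
#'   (+-1, +-2, +-4, +-8, +-16).
#' @param reps_pre Repetitions per (cue, heading) in the pre block.
#' @param delta_max_deg Signed maximum discrepancy in degrees.
#' @param delta_ramp_step_deg Ramp step magnitude in degrees; must divide
#'   `abs(delta_max_deg)`.
#' @param reps_per_ramp_increment Trials per ramp increment (including the
#'   first visit to the maximum delta).
#' @param reps_max_delta Additional trials run at the maximum delta.
#' @param reps_post_single Repetitions per (cue, heading) in the post block.
#' @param reps_post_combined Combined-cue repetitions per heading interleaved
#'   in the post block.
#' @param reward_p_correct Reward probability for correct choices under the
#'   deterministic reward rule.
#' @param reward_p_stochastic Reward probability (independent of choice)
#'   under the stochastic rule, applied post-recalibration to single-cue
#'   headings whose implied other-cue heading would fall on the opposite side
#'   of straight ahead.
#' @return An object of class `paradigm_config`.
#' @seealso [build_trial_schedule()]
#' @export
paradigm_config <- function(headings_deg = c(-16, -8, -4, -2, -1, 1, 2, 4, 8, 16),
                            reps_pre = 10,
                            delta_max_deg = 10,
                            delta_ramp_step_deg = 2,
                            reps_per_ramp_increment = 8,
                            reps_max_delta = 12,
                            reps_post_single = 10,
                            reps_post_combined = 4,
                            reward_p_correct = 0.95,
                            reward_p_stochastic = 0.70) {
  headings_deg <- sort(unique(headings_deg))
  if (any(headings_deg == 0)) stop("headings must be nonzero")
  if (!isTRUE(all.equal(sort(-headings_deg), headings_deg))) {
    stop("headings must be symmetric about 0")
  }
  if (abs(delta_max_deg) <= 0) stop("abs(delta_max_deg) must be > 0")
  ratio <- abs(delta_max_deg) / delta_ramp_step_deg
  if (abs(ratio - round(ratio)) > 1e-8) {
    stop("delta_ramp_step_deg must divide abs(delta_max_deg)")
  }
  for (p in c(reward_p_correct, reward_p_stochastic)) {
    if (p < 0 || p > 1) stop("reward probabilities must lie in [0, 1]")
  }
  stopifnot(reps_pre >= 1, reps_per_ramp_increment >= 1, reps_max_delta >= 0,
            reps_post_single >= 1, reps_post_combined >= 0)
  structure(list(
    headings_deg = headings_deg,
    reps_pre = reps_pre,
    delta_max_deg = delta_max_deg,
    delta_ramp_step_deg = delta_ramp_step_deg,
    reps_per_ramp_increment = reps_per_ramp_increment,
    reps_max_delta = reps_max_delta,
    reps_post_single = reps_post_single,
    reps_post_combined = reps_post_combined,
    reward_p_correct = reward_p_correct,
    reward_p_stochastic = reward_p_stochastic
  ), class = "paradigm_config")
}

#' @export
print.paradigm_config <- function(x, ...) {
  cat("Cue-conflict paradigm:\n")
  cat("  headings (deg):", paste(x$headings_deg, collapse = " "), "\n")
  cat(sprintf("  pre: %d reps x 2 cues x %d headings\n",
              x$reps_pre, length(x$headings_deg)))
  cat(sprintf("  recal: delta ramp to %+g deg in %g-deg steps (%d reps/step, +%d at max)\n",
              x$delta_max_deg, x$delta_ramp_step_deg,
              x$reps_per_ramp_increment, x$reps_max_delta))
  cat(sprintf("  post: %d single-cue reps + %d combined reps per heading\n",
              x$reps_post_single, x$reps_post_combined))
  invisible(x)
}

# reward rule tag for post-block single-cue trials: the implied other-cue
# heading in a combined trial at delta_max is h -/+ delta; if it would fall
# on the opposite side of straight ahead the reward becomes stochastic.
post_reward_rule <- function(heading_deg, modality, delta_max_deg) {
  d <- abs(delta_max_deg)
  pos <- delta_max_deg > 0
  stochastic <- ifelse(
    (modality == "vestibular") == pos,
    heading_deg > 0 & heading_deg <= d,    # offset cue sits d to the right
    heading_deg < 0 & heading_deg >= -d)   # offset cue sits d to the left
  ifelse(stochastic, "stochastic", "deterministic")
}

#' Build the trial schedule of one session
#'
#' Expands a [paradigm_config()] into an ordered trial table. Trials are
#' randomly interleaved within each block (pre, recal, post) using the
#' current RNG state; block order is fixed. Combined-cue trials place the
#' vestibular and visual headings at `heading +/- delta/2` (vestibular to the
#' right for positive delta). Recalibration-block trials carry no choice and
#' are rewarded for fixation; post-block single-cue trials are tagged with
#' the deterministic or stochastic reward rule depending on whether the
#' implied other-cue heading lies on the same side of straight ahead.
#'
#' @param cfg A [paradigm_config()].
#' @return A data.frame with one row per trial and columns `trial_id`,
#'   `block` (`pre`/`recal`/`post`), `modality`
#'   (`vestibular`/`visual`/`combined`), `heading_deg` (the single-cue
#'   heading, or the combined-cue midpoint), `vest_heading_deg`,
#'   `vis_heading_deg` (NA for the absent cue), `delta_deg` (0 for
#'   single-cue), `reward_rule`, and placeholder `choice`/`rewarded` columns
#'   filled in by [simulate_choices()].
#' @examples
#' set.seed(1)
#' trials <- build_trial_schedule(paradigm_config())
#' table(trials$block, trials$modality)
#' @export
build_trial_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "paradigm_config"))
  h <- cfg$headings_deg
  d <- cfg$delta_max_deg

  single <- function(block, reps) {
    g <- expand.grid(heading_deg = h,
                     modality = c("vestibular", "visual"),
                     rep = seq_len(reps),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    data.frame(block = block, modality = g$modality,
               heading_deg = g$heading_deg,
               vest_heading_deg = ifelse(g$modality == "vestibular",
                                         g$heading_deg, NA_real_),
               vis_heading_deg = ifelse(g$modality == "visual",
                                        g$heading_deg, NA_real_),
               delta_deg = 0, stringsAsFactors = FALSE)
  }
  combined <- function(block, heading, delta) {
    data.frame(block = block, modality = "combined",
               heading_deg = heading,
               vest_heading_deg = heading + delta / 2,
               vis_heading_deg = heading - delta / 2,
               delta_deg = delta, stringsAsFactors = FALSE)
  }

  pre <- single("pre", cfg$reps_pre)
  pre <- pre[sample.int(nrow(pre)), ]

  # ramp: |delta| rises by one step per increment; the maximum gets the
  # per-increment repetitions plus the extra top-up repetitions
  steps <- seq(cfg$delta_ramp_step_deg, abs(d), by = cfg$delta_ramp_step_deg)
  recal <- do.call(rbind, lapply(steps, function(s) {
    reps <- cfg$reps_per_ramp_increment +
      if (s == abs(d)) cfg$reps_max_delta else 0
    combined("recal", sample(h, reps, replace = TRUE), sign(d) * s)
  }))

  post_single <- single("post", cfg$reps_post_single)
  post_comb <- if (cfg$reps_post_combined > 0) {
    combined("post", rep(h, cfg$reps_post_combined), d)
  } else NULL
  post <- rbind(post_single, post_comb)
  post <- post[sample.int(nrow(post)), ]

  trials <- rbind(pre, recal, post)
  trials$reward_rule <- "deterministic"
  trials$reward_rule[trials$block == "recal"] <- "fixation"
  is_ps <- trials$block == "post" & trials$modality != "combined"
  trials$reward_rule[is_ps] <- post_reward_rule(
    trials$heading_deg[is_ps], trials$modality[is_ps], d)
  trials$choice <- ifelse(trials$block == "recal", "none", NA_character_)
  trials$rewarded <- NA
  trials$rewarded[trials$block == "recal"] <- TRUE
  trials <- cbind(trial_id = seq_len(nrow(trials)), trials)
  rownames(trials) <- NULL
  trials
}
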