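#' Validation studies
#'
#' Each `study_*` function runs one self-contained simulation study that
#' checks a core property of the pipeline: oracle equivalence of the ROC
#' sweep, parameter recovery of the psychometric and neurometric fits,
#' reproduction of the conflict-reducing behavioral sign pattern, the
#' area-profile correlation structure, the selective post-recalibration
#' reduction of choice signals, calibration of the neuron screen, and the
#' temporal localisation of neurometric information. They consume the
#' current RNG state; callers `set.seed()` for reproducibility. The same
#' studies back the package's acceptance checks and the reproduction
#' script.
#'
#' @name validation-studies
#' @keywords internal
NULL

# minimal single-cue trial frame used by the recovery studies
single_cue_frame <- function(headings, reps, block, cue = "vestibular") {
  h <- rep(headings, each = reps)
  data.frame(trial_id = seq_along(h), block = block, modality = cue,
             heading_deg = h,
             vest_heading_deg = if (cue == "vestibular") h else NA_real_,
             vis_heading_deg = if (cue == "visual") h else NA_real_,
             delta_deg = 0, reward_rule = "deterministic",
             choice = "right", rewarded = NA,
             stringsAsFactors = FALSE)
}

#' @describeIn validation-studies Deviation of the criterion-sweep ROC area
#'   from the closed-form oracle over random z-score instances (continuous,
#'   rounded/tied, and spike-count-lattice shaped).
#' @param n_instances Number of random instances.
#' @param n_range Range of per-instance sample sizes.
#' @export
study_roc_oracle <- function(n_instances = 1000, n_range = c(5, 200)) {
  devs <- vapply(seq_len(n_instances), function(i) {
    n <- sample(seq(n_range[1], n_range[2]), 1)
    z <- switch(sample(3, 1),
                stats::rnorm(n, stats::runif(1, -2, 2)),
                round(stats::rnorm(n, stats::runif(1, -2, 2)),
                      sample(0:1, 1)),
                (stats::rpois(n, stats::runif(1, 5, 50)) -
                   stats::runif(1, 5, 50)) / stats::runif(1, 2, 8))
    abs(auc_vs_reference(z) - auc_reference_exact(z))
  }, numeric(1))
  list(max_abs_dev = max(devs), mean_abs_dev = mean(devs),
       n_instances = n_instances)
}

#' @describeIn validation-studies Bias of the fitted psychometric mean and
#'   recovery of a generative PSE step across simulated sessions.
#' @param n_sessions Number of simulated sessions.
#' @param reps Trials per (heading, session) and block.
#' @param mu_deg,sigma_deg Generative post-block PSE and threshold.
#' @param step_deg Generative pre-to-post PSE step (pre PSE is
#'   `mu_deg - step_deg`).
#' @export
study_psychometric_recovery <- function(n_sessions = 200, reps = 20,
                                        mu_deg = 1.5, sigma_deg = 4,
                                        step_deg = 1.5) {
  headings <- paradigm_config()$headings_deg
  h <- rep(headings, each = reps)
  fits <- vapply(seq_len(n_sessions), function(i) {
    draw <- function(mu) {
      ch <- ifelse(stats::runif(length(h)) <
                     stats::pnorm((h - mu) / sigma_deg), "right", "left")
      fit_psychometric(h, ch)
    }
    f_pre <- draw(mu_deg - step_deg)
    f_post <- draw(mu_deg)
    c(mu_hat = f_post$pse_deg, shift = pse_shift(f_pre, f_post))
  }, numeric(2))
  list(mu_bias_deg = mean(fits["mu_hat", ]) - mu_deg,
       shift_mean_deg = mean(fits["shift", ], na.rm = TRUE),
       shift_error_deg = mean(fits["shift", ], na.rm = TRUE) - step_deg,
       n_sessions = n_sessions)
}

#' @describeIn validation-studies Recovery of an injected tuning-curve
#'   shift by the reference-anchored neurometrics, for steeply tuned
#'   Poisson neurons at session trial counts.
#' @param n_neurons Neurons per injected shift.
#' @param delta_deg Injected post-block tuning shift (degrees).
#' @param baseline_hz,slope_hz_per_deg Neuron parameters.
#' @export
study_neurometric_recovery <- function(n_neurons = 100, delta_deg = 3,
                                       reps = 10, baseline_hz = 50,
                                       slope_hz_per_deg = 2.5) {
  cfg <- paradigm_config()
  grid <- time_grid()
  sp <- stimulus_profile()
  trials <- rbind(single_cue_frame(cfg$headings_deg, reps, "pre"),
                  single_cue_frame(cfg$headings_deg, reps, "post"))
  shifts <- vapply(seq_len(n_neurons), function(i) {
    np <- neuron_profile(
      baseline_hz = baseline_hz,
      slope_hz_per_deg = c(vestibular = slope_hz_per_deg,
                           visual = slope_hz_per_deg),
      tuning_shift_deg = list(vestibular = c(pre = 0, post = delta_deg),
                              visual = c(pre = 0, post = delta_deg)))
    counts <- simulate_spike_counts(trials, np, sp, grid)
    rates <- trial_firing_rates(counts, grid, trials$block)
    pre <- trials$block == "pre"
    side <- tuning_regression(rates$fr_bsub_hz[pre],
                              trials$heading_deg[pre])$preferred_side
    ref <- reference_stats(rates$fr_hz[pre])
    f1 <- fit_neurometric(rates$fr_hz[pre], trials$heading_deg[pre], ref, side)
    f2 <- fit_neurometric(rates$fr_hz[!pre], trials$heading_deg[!pre], ref, side)
    neuronal_shift(f1, f2)
  }, numeric(1))
  list(delta_deg = delta_deg,
       mean_shift_deg = mean(shifts, na.rm = TRUE),
       error_deg = mean(shifts, na.rm = TRUE) - delta_deg,
       n_converged = sum(!is.na(shifts)), n_neurons = n_neurons)
}

# simulate a batch of sessions and run the behavioral analysis
simulate_behavior_batch <- function(n_sessions, delta_sign, reps = 10) {
  cfg <- paradigm_config(reps_pre = reps, reps_post_single = reps,
                         reps_post_combined = 2,
                         delta_max_deg = delta_sign * 10)
  do.call(rbind, lapply(seq_len(n_sessions), function(k) {
    beh <- sample_session_behavior(default_behavior(delta_sign))
    ses <- simulate_session(cfg, beh, session_id = sprintf("s%03d", k),
                            monkey_id = sprintf("m%d", 1 + k %% 2))
    analyze_behavior(ses)
  }))
}

#' @describeIn validation-studies Conflict-reducing sign pattern of the
#'   behavioral PSE shifts under one discrepancy orientation.
#' @param delta_sign +1 or -1.
#' @export
study_sign_pattern <- function(n_sessions = 50, delta_sign = 1, reps = 10) {
  behavior <- simulate_behavior_batch(n_sessions, delta_sign, reps)
  out <- behavioral_summary(behavior)$groups
  out[order(out$cue), ]
}

#' @describeIn validation-studies Neuronal-perceptual shift correlations
#'   for one area profile (sessions alternate discrepancy orientation, one
#'   neuron per session), plus the fraction of visual-cue records failing
#'   the tuning screen.
#' @param area Area profile label.
#' @param B Bootstrap resamples for the reliability screen.
#' @export
study_area_profile <- function(area, n_sessions = 40, B = 100, reps = 10) {
  behavior <- list(); neurons <- list()
  for (k in seq_len(n_sessions)) {
    ds <- if (k %% 2 == 1) 1 else -1
    cfg <- paradigm_config(reps_pre = reps, reps_post_single = reps,
                           reps_post_combined = 2, delta_max_deg = ds * 10)
    beh <- sample_session_behavior(default_behavior(ds))
    ses <- simulate_session(cfg, beh,
                            neurons = make_area_population(area, 1, beh),
                            session_id = sprintf("s%03d", k),
                            monkey_id = sprintf("m%d", 1 + k %% 2))
    behavior[[k]] <- analyze_behavior(ses)
    neurons[[k]] <- analyze_neurons(ses, B = B)
  }
  behavior <- do.call(rbind, behavior)
  neurons <- do.call(rbind, neurons)
  report <- group_report(behavior, neurons)
  vis <- neurons[neurons$cue == "visual", ]
  list(correlations = report$correlations,
       visual_tuning_fail_frac = mean(vis$p_pre >= 0.05 & vis$p_post >= 0.05),
       n_passed = table(neurons$cue[neurons$passed]))
}

#' @describeIn validation-studies Detection of a halved post-recalibration
#'   choice gain by the paired test on squared choice partials, and
#'   calibration (uniform p-values) of the matching heading-partial test,
#'   over replicate populations of sustained, choice-coupled neurons.
#' @param n_replicates Replicate populations.
#' @param n_neurons Neurons per replicate.
#' @export
study_choice_reduction <- function(n_replicates = 100, n_neurons = 50,
                                   reps = 10) {
  cfg <- paradigm_config(reps_pre = reps, reps_post_single = reps,
                         reps_post_combined = 2,
                         reps_per_ramp_increment = 1, reps_max_delta = 1)
  grid <- time_grid(); sp <- stimulus_profile()
  res <- vapply(seq_len(n_replicates), function(r) {
    # each neuron is recorded in its own session (own behavior and trials),
    # as in the experiments; shared-session choice statistics would
    # otherwise correlate the per-neuron partials
    partials <- do.call(rbind, lapply(seq_len(n_neurons), function(j) {
      beh <- sample_session_behavior(default_behavior())
      trials <- simulate_choices(build_trial_schedule(cfg), cfg, beh)
      np <- make_area_population("VIP-like", 1, beh)[[1]]
      counts <- simulate_spike_counts(trials, np, sp, grid)
      rates <- trial_firing_rates(counts, grid, trials$block)
      do.call(rbind, lapply(c("pre", "post"), function(blk) {
        i <- trials$block == blk & trials$modality == "vestibular"
        pc <- partial_correlations(rates$fr_hz[i], trials$heading_deg[i],
                                   trials$choice[i])
        data.frame(neuron_id = sprintf("n%03d", j), cue = "vestibular",
                   block = blk, r_h = pc$r_h, r_c = pc$r_c)
      }))
    }))
    cmp <- compare_pre_post_partials(partials)
    rc <- cmp[cmp$measure == "r_c2", ]
    rh <- cmp[cmp$measure == "r_h2", ]
    c(detected = rc$p < 0.05 && rc$mean_diff < 0, p_rh2 = rh$p)
  }, numeric(2))
  list(detection_rate = mean(res["detected", ]),
       rh2_pvalues = unname(res["p_rh2", ]),
       rh2_ks_p = stats::ks.test(res["p_rh2", ], "punif")$p.value,
       n_replicates = n_replicates)
}

#' @describeIn validation-studies Calibration of the neuron screen on
#'   untuned neurons: tuning-regression false-positive rate and the
#'   fraction excluded by the bootstrap PSE-reliability rule.
#' @param baseline_hz Baseline rate of the untuned neurons.
#' @export
study_screen_calibration <- function(n_neurons = 1000, reps = 10, B = 100,
                                     baseline_hz = 20) {
  headings <- paradigm_config()$headings_deg
  h <- rep(headings, each = reps)
  res <- vapply(seq_len(n_neurons), function(i) {
    # pre-block counts of an untuned neuron: stimulus-window rate and an
    # independent 1-s baseline, both at the baseline rate
    fr <- stats::rpois(length(h), baseline_hz)
    base <- stats::rpois(length(h), baseline_hz)
    tun <- tuning_regression(fr - mean(base), h)
    sdv <- bootstrap_pse_sd(fr, h, reference_stats(fr), "right", B = B)
    c(tuned = tun$p_value < 0.05, excluded = !(sdv < 10))
  }, numeric(2))
  list(tuning_fp_rate = mean(res["tuned", ]),
       bootstrap_exclusion_rate = mean(res["excluded", ]),
       n_neurons = n_neurons)
}

#' @describeIn validation-studies Time course of the neuronal-perceptual
#'   shift correlation across 200-ms sliding windows, for a population with
#'   velocity-locked or sustained temporal dynamics.
#' @param mode `"velocity"` or `"sustained"`.
#' @param n_neurons_per_session Neurons averaged per session.
#' @export
study_timecourse <- function(mode = c("velocity", "sustained"),
                             n_sessions = 50, n_neurons_per_session = 6,
                             reps = 20) {
  mode <- match.arg(mode)
  grid <- time_grid(); sp <- stimulus_profile()
  per_window <- matrix(NA_real_, n_sessions, 12)
  perc <- numeric(n_sessions)
  for (k in seq_len(n_sessions)) {
    ds <- if (k %% 2 == 1) 1 else -1
    cfg <- paradigm_config(reps_pre = reps, reps_post_single = reps,
                           reps_post_combined = 2,
                           reps_per_ramp_increment = 1, reps_max_delta = 1,
                           delta_max_deg = ds * 10)
    beh <- sample_session_behavior(default_behavior(ds))
    vest_shift <- attr(beh, "true_shift_deg")[["vestibular"]]
    pop <- lapply(seq_len(n_neurons_per_session), function(j) {
      sgn <- sample(c(-1, 1), 1)
      ts <- vest_shift + stats::rnorm(1, 0, 0.5)
      neuron_profile(
        baseline_hz = stats::runif(1, 30, 50),
        slope_hz_per_deg = c(vestibular = sgn * stats::runif(1, 2.5, 3.5),
                             visual = sgn * stats::runif(1, 2.5, 3.5)),
        tuning_shift_deg = list(vestibular = c(pre = 0, post = ts),
                                visual = c(pre = 0, post = ts)),
        temporal_mode = mode)
    })
    ses <- simulate_session(cfg, beh, neurons = pop, profile = sp,
                            grid = grid, session_id = sprintf("s%03d", k))
    beh_fit <- analyze_behavior(ses)
    perc[k] <- beh_fit$shift_deg[beh_fit$cue == "vestibular"]
    vest_h <- ifelse(ses$trials$modality == "vestibular",
                     ses$trials$vest_heading_deg, NA_real_)
    pre <- ses$trials$block == "pre" & ses$trials$modality == "vestibular"
    shifts <- matrix(NA_real_, n_neurons_per_session, 12)
    for (j in seq_len(n_neurons_per_session)) {
      counts <- ses$spikes[[j]]
      rates <- trial_firing_rates(counts, grid, ses$trials$block)
      side <- tuning_regression(rates$fr_bsub_hz[pre],
                                vest_h[pre])$preferred_side
      sw <- sliding_window_shifts(counts, grid, vest_h, ses$trials$block,
                                  side)
      shifts[j, ] <- sw$shift_deg
    }
    per_window[k, ] <- colMeans(shifts, na.rm = TRUE)
  }
  centers <- seq(0.1, 1.2, by = 0.1)
  cors <- lapply(seq_len(12), function(w) {
    ok <- is.finite(per_window[, w]) & is.finite(perc)
    if (sum(ok) < 5) return(list(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(per_window[ok, w], perc[ok])
    list(r = unname(ct$estimate), p = ct$p.value)
  })
  out <- data.frame(center_s = centers,
                    r = vapply(cors, `[[`, numeric(1), "r"),
                    p = vapply(cors, `[[`, numeric(1), "p"))
  list(windows = out,
       peak_center_s = centers[which.max(abs(out$r))],
       late_p = out$p[out$center_s > 1.0],
       mode = mode)
}
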