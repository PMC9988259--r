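# shared fixtures and small simulation utilities, all generated in code

standard_headings <- function() c(-16, -8, -4, -2, -1, 1, 2, 4, 8, 16)

# a small, fast paradigm for unit tests
tiny_config <- function(...) {
  paradigm_config(reps_pre = 3, reps_per_ramp_increment = 2,
                  reps_max_delta = 2, reps_post_single = 3,
                  reps_post_combined = 1, ...)
}

# single-cue trial table (no scheduling machinery) for direct fits
single_cue_table <- function(headings, reps, block = "pre",
                             modality = "vestibular") {
  h <- rep(headings, each = reps)
  data.frame(trial_id = seq_along(h), block = block, modality = modality,
             heading_deg = h,
             vest_heading_deg = if (modality == "vestibular") h else NA_real_,
             vis_heading_deg = if (modality == "visual") h else NA_real_,
             delta_deg = 0, reward_rule = "deterministic",
             choice = NA_character_, rewarded = NA)
}

# draw choices from an explicit cumulative-Gaussian observer
draw_choices <- function(h, mu, sigma, lapse = 0) {
  p <- lapse / 2 + (1 - lapse) * pnorm((h - mu) / sigma)
  ifelse(runif(length(h)) < p, "right", "left")
}

# per-trial Poisson firing rates (1-s window) for a linear tuning curve
draw_fr <- function(h, baseline, slope, shift = 0) {
  rpois(length(h), pmax(0, baseline + slope * (h - shift)))
}

# mean temporal gain over the stimulus window as the package computes it
stim_window_gain <- function(profile = stimulus_profile(),
                             grid = time_grid(),
                             mode = "velocity", tau_s = 0.5) {
  m <- recalibr:::temporal_modulation(grid$centers_s, profile,
                                      mode = mode, tau_s = tau_s)
  mean(m[grid$centers_s > 0 & grid$centers_s < 1])
}

# independent oracle for partial correlation: correlate residuals of
# linear regressions on the conditioning variable
partial_cor_oracle <- function(x, y, ctrl) {
  rx <- resid(lm(x ~ ctrl))
  ry <- resid(lm(y ~ ctrl))
  cor(rx, ry)
}
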