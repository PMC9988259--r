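#' Generative single-neuron profile
#'
#' A neuron's trial-by-trial rate is
#' `rate(t) = baseline + (slope_cue * (h_cue - tuning_shift[cue, block]) +
#' choice_gain[cue, block] * C) * m(t)`, where `h_cue` is the heading of the
#' cue(s) present on the trial, `C` is the choice code (+1 right, -1 left, 0
#' when no choice is made), and `m(t)` is a temporal gain in `[0, 1]`:
#' the normalized Gaussian stimulus velocity (`temporal_mode = "velocity"`),
#' or a leaky integration of it with time constant `sustain_tau_s` that
#' persists past stimulus offset (`temporal_mode = "sustained"`). Rates are
#' truncated at zero before counts are drawn, Poisson by default.
#'
#' On combined-cue trials both cue drives add, and the choice gain is the
#' mean of the two cues' gains.
#'
#' @param baseline_hz Baseline firing rate, spikes/s (>= 0).
#' @param slope_hz_per_deg Named vector `c(vestibular =, visual =)` of tuning
#'   slopes around straight ahead, spikes/s/deg.
#' @param tuning_shift_deg List per cue of `c(pre =, post =)` tuning-curve
#'   shifts in degrees (the post shift is what recalibration analyses try to
#'   recover).
#' @param choice_gain_hz List per cue of `c(pre =, post =)` choice-coupled
#'   rate modulations, spikes/s.
#' @param temporal_mode `"velocity"` or `"sustained"`.
#' @param sustain_tau_s Decay time constant (s) for the sustained mode.
#' @param noise_model `"poisson"` (integer counts) or `"gaussian"`
#'   (continuous counts, for analytic cross-checks).
#' @param gaussian_sd_hz Rate-scale SD (spikes/s) of the Gaussian noise.
#' @return An object of class `neuron_profile`.
#' @export
neuron_profile <- function(baseline_hz = 20,
                           slope_hz_per_deg = c(vestibular = 0.5, visual = 0.5),
                           tuning_shift_deg = list(vestibular = c(pre = 0, post = 0),
                                                   visual = c(pre = 0, post = 0)),
                           choice_gain_hz = list(vestibular = c(pre = 0, post = 0),
                                                 visual = c(pre = 0, post = 0)),
                           temporal_mode = c("velocity", "sustained"),
                           sustain_tau_s = 0.5,
                           noise_model = c("poisson", "gaussian"),
                           gaussian_sd_hz = 3) {
  temporal_mode <- match.arg(temporal_mode)
  noise_model <- match.arg(noise_model)
  stopifnot(baseline_hz >= 0, sustain_tau_s > 0, gaussian_sd_hz >= 0)
  for (cue in c("vestibular", "visual")) {
    if (is.na(slope_hz_per_deg[[cue]])) stop("missing slope for ", cue)
    for (blk in c("pre", "post")) {
      if (is.null(tuning_shift_deg[[cue]][[blk]]) ||
          is.null(choice_gain_hz[[cue]][[blk]])) {
        stop("tuning_shift_deg and choice_gain_hz need entries for ",
             cue, "/", blk)
      }
    }
  }
  structure(list(baseline_hz = baseline_hz,
                 slope_hz_per_deg = slope_hz_per_deg,
                 tuning_shift_deg = tuning_shift_deg,
                 choice_gain_hz = choice_gain_hz,
                 temporal_mode = temporal_mode,
                 sustain_tau_s = sustain_tau_s,
                 noise_model = noise_model,
                 gaussian_sd_hz = gaussian_sd_hz),
            class = "neuron_profile")
}

# per-trial stimulus-locked rate gain (one value per time bin), shared by all
# trials; returns vector over bin centers
neuron_modulation <- function(neuron, profile, grid) {
  temporal_modulation(grid$centers_s, profile,
                      mode = neuron$temporal_mode,
                      tau_s = neuron$sustain_tau_s)
}

#' Simulate binned spike counts for a set of trials
#'
#' Applies the generative rate model of [neuron_profile()] to each trial of
#' a schedule with choices filled in, and draws spike counts per time bin.
#'
#' @param trials Trial table with `choice` filled (see [simulate_choices()]).
#' @param neuron A [neuron_profile()].
#' @param profile A [stimulus_profile()].
#' @param grid A [time_grid()]; must start at or before -1 s (to cover the
#'   baseline window) and extend past stimulus offset.
#' @return Numeric matrix, trials x bins, of spike counts.
#' @examples
#' set.seed(1)
#' cfg <- paradigm_config(reps_pre = 2, reps_post_single = 2)
#' tr <- simulate_choices(build_trial_schedule(cfg), cfg, default_behavior())
#' counts <- simulate_spike_counts(tr, neuron_profile(), stimulus_profile(),
#'                                 time_grid())
#' @export
simulate_spike_counts <- function(trials, neuron, profile, grid) {
  stopifnot(inherits(neuron, "neuron_profile"),
            inherits(profile, "stimulus_profile"))
  if (grid$start_s > -1 + 1e-9) {
    stop("time grid must cover the 1-s baseline window before onset")
  }
  rate <- trial_rate_matrix(trials, neuron, profile, grid)
  n <- length(rate)
  counts <- if (neuron$noise_model == "poisson") {
    stats::rpois(n, rate * grid$bin_width_s)
  } else {
    pmax(0, stats::rnorm(n, rate * grid$bin_width_s,
                         neuron$gaussian_sd_hz * grid$bin_width_s))
  }
  matrix(counts, nrow = nrow(trials), ncol = length(grid$bin_start_s))
}

# expected rate (spikes/s) per trial x bin, truncated at zero
trial_rate_matrix <- function(trials, neuron, profile, grid) {
  m <- neuron_modulation(neuron, profile, grid)
  blk <- ifelse(trials$block == "pre", "pre", "post")
  C <- ifelse(is.na(trials$choice) | trials$choice == "none", 0,
              ifelse(trials$choice == "right", 1, -1))
  drive <- numeric(nrow(trials))
  gain <- numeric(nrow(trials))
  hcue <- list(vestibular = trials$vest_heading_deg,
               visual = trials$vis_heading_deg)
  for (cue in c("vestibular", "visual")) {
    on <- !is.na(hcue[[cue]])
    drive[on] <- drive[on] + neuron$slope_hz_per_deg[[cue]] *
      (hcue[[cue]][on] - neuron$tuning_shift_deg[[cue]][blk[on]])
    gain[on] <- gain[on] + neuron$choice_gain_hz[[cue]][blk[on]]
  }
  n_cues <- (!is.na(trials$vest_heading_deg)) + (!is.na(trials$vis_heading_deg))
  gain <- gain / pmax(n_cues, 1)
  pmax(0, neuron$baseline_hz + outer(drive + gain * C, m))
}

#' Generate a population of neurons with an area-like recalibration profile
#'
#' Encodes three qualitatively different relations between neuronal tuning
#' shifts and the session's perceptual shifts:
#' * `"MSTd-like"`: each cue's tuning shift tracks that cue's own perceptual
#'   shift (visual slopes dominate vestibular ones); velocity-locked
#'   temporal dynamics.
#' * `"PIVC-like"`: vestibular tuning tracks the vestibular perceptual
#'   shift; visual tuning slopes are near zero (below what the tuning
#'   screen can detect at session trial counts); velocity-locked.
#' * `"VIP-like"`: both cues' tuning shifts track the *vestibular*
#'   perceptual shift; choice gains are halved post-recalibration; sustained
#'   temporal dynamics.
#'
#' Tuning slopes are drawn steep (the neurons these analyses target are the
#' ones with steep, informative tuning around straight ahead), and tuning
#' shifts follow the session's perceptual shift scaled by `shift_gain`:
#' example sessions in this paradigm show neuronal shifts two- to four-fold
#' larger than the simultaneous perceptual shifts, so the default gain is
#' 2.5. The gain preserves signs, so all sign-pattern and correlation
#' properties are gain-invariant.
#'
#' @param area One of `"MSTd-like"`, `"PIVC-like"`, `"VIP-like"`.
#' @param n Number of neurons.
#' @param behavior The session's [behavior_profile()] (its post-minus-pre
#'   PSE steps are the perceptual shifts the tuning shifts follow).
#' @param shift_gain Ratio of neuronal tuning shift to perceptual shift.
#' @param shift_jitter_sd_deg SD (deg) of per-neuron jitter around the
#'   profile-implied tuning shift.
#' @param baseline_range_hz Range of uniform baseline rates.
#' @return List of `n` [neuron_profile()] objects.
#' @export
make_area_population <- function(area = c("MSTd-like", "PIVC-like", "VIP-like"),
                                 n,
                                 behavior,
                                 shift_gain = 2.5,
                                 shift_jitter_sd_deg = 0.5,
                                 baseline_range_hz = c(20, 40)) {
  area <- match.arg(area)
  stopifnot(inherits(behavior, "behavior_profile"), n >= 1)
  pshift <- vapply(c(vestibular = "vestibular", visual = "visual"),
                   function(cue) behavior$pse_deg[[cue]][["post"]] -
                     behavior$pse_deg[[cue]][["pre"]], numeric(1))

  lapply(seq_len(n), function(i) {
    sgn <- sample(c(-1, 1), 2, replace = TRUE)
    if (area == "MSTd-like") {
      slope <- c(vestibular = sgn[1] * stats::runif(1, 1.0, 2.0),
                 visual = sgn[2] * stats::runif(1, 1.5, 3.0))
      target <- pshift
      gain_pre <- gain_post <- 1
      mode <- "velocity"
    } else if (area == "PIVC-like") {
      slope <- c(vestibular = sgn[1] * stats::runif(1, 1.5, 3.0),
                 visual = stats::rnorm(1, 0, 0.02))
      target <- c(vestibular = pshift[["vestibular"]], visual = 0)
      gain_pre <- gain_post <- 1
      mode <- "velocity"
    } else {
      # moderate slopes and high baselines keep the strongly choice-coupled
      # rates away from the truncation floor at anti-preferred extremes
      slope <- c(vestibular = sgn[1] * stats::runif(1, 0.8, 1.8),
                 visual = sgn[2] * stats::runif(1, 0.8, 1.8))
      target <- c(vestibular = pshift[["vestibular"]],
                  visual = pshift[["vestibular"]])
      gain_pre <- 6
      gain_post <- 3
      mode <- "sustained"
    }
    shifts <- lapply(target, function(s) {
      c(pre = 0,
        post = shift_gain * s + stats::rnorm(1, 0, shift_jitter_sd_deg))
    })
    gains <- lapply(c(vestibular = 1, visual = 2), function(k) {
      c(pre = gain_pre * sign(slope[[k]]), post = gain_post * sign(slope[[k]]))
    })
    if (area == "PIVC-like") {
      # choice covaries with heading, so even a small choice gain reads out
      # as apparent visual tuning; the PIVC-like profile is defined by
      # visual drive below tuning-screen detectability
      gains$visual[] <- 0
    }
    base_range <- if (area == "VIP-like") baseline_range_hz + 20 else
      baseline_range_hz
    neuron_profile(
      baseline_hz = stats::runif(1, base_range[1], base_range[2]),
      slope_hz_per_deg = slope,
      tuning_shift_deg = shifts,
      choice_gain_hz = gains,
      temporal_mode = mode)
  })
}
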