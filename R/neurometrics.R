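#' Per-trial firing rates over a window, with per-block baselines
#'
#' Converts binned spike counts to firing rates (spikes/s) over a
#' bin-aligned window, and computes, per block, the mean baseline rate over
#' the second preceding stimulus onset. Baseline-subtracted rates (rate
#' minus the trial's block baseline) are returned alongside the raw rates:
#' tuning curves and the tuning regression conventionally use
#' baseline-subtracted responses, whereas the reference-anchored
#' neurometrics use raw rates.
#'
#' @param counts Trials x bins count matrix.
#' @param grid The [time_grid()] of `counts`.
#' @param block Per-trial block labels (any grouping for the baselines).
#' @param window Window `c(t0, t1)` in seconds; edges must fall on bin
#'   edges. Default: the stimulus interval `c(0, 1)`.
#' @param baseline_window Window for the baseline, default `c(-1, 0)`.
#' @return A list of class `firing_rates`: `fr_hz` (raw per-trial rates),
#'   `fr_bsub_hz` (baseline-subtracted), `baseline_hz` (named per-block
#'   means), `window`.
#' @export
trial_firing_rates <- function(counts, grid, block,
                               window = c(0, 1),
                               baseline_window = c(-1, 0)) {
  fr <- window_rates(counts, grid, window)
  base_fr <- window_rates(counts, grid, baseline_window)
  baseline <- tapply(base_fr, block, mean)
  structure(list(fr_hz = fr,
                 fr_bsub_hz = fr - unname(baseline[as.character(block)]),
                 baseline_hz = baseline,
                 window = window),
            class = "firing_rates")
}

# counts within a bin-aligned window divided by window length
window_rates <- function(counts, grid, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  if (window[1] < grid$start_s - 1e-9 || window[2] > grid$end_s + 1e-9) {
    stop("window outside the time grid")
  }
  edges <- c(grid$bin_start_s, grid$end_s)
  for (w in window) {
    if (min(abs(edges - w)) > 1e-9) {
      stop("window edge ", w, " s does not fall on a bin edge")
    }
  }
  sel <- grid$bin_start_s >= window[1] - 1e-9 &
    grid$bin_start_s <= window[2] - grid$bin_width_s + 1e-9
  rowSums(counts[, sel, drop = FALSE]) / (window[2] - window[1])
}

#' Linear tuning regression of firing rate on heading
#'
#' Ordinary least-squares regression of (conventionally
#' baseline-subtracted) firing rates on signed heading over the narrow
#' range of stimuli presented. A neuron is "tuned" when the slope is
#' significant (two-sided p < 0.05); its preferred side is the slope sign.
#'
#' @param fr Per-trial firing rates (spikes/s).
#' @param heading_deg Per-trial signed headings (>= 3 distinct values).
#' @return A list of class `tuning_fit`: `slope_hz_per_deg`, `intercept_hz`,
#'   `p_value`, `preferred_side` (`"left"`/`"right"`), `n_trials`.
#' @export
tuning_regression <- function(fr, heading_deg) {
  if (length(unique(heading_deg)) < 3) {
    stop("need >= 3 distinct headings for the tuning regression")
  }
  fit <- stats::lm(fr ~ heading_deg)
  sm <- summary(fit)$coefficients
  slope <- sm["heading_deg", "Estimate"]
  structure(list(slope_hz_per_deg = slope,
                 intercept_hz = sm["(Intercept)", "Estimate"],
                 p_value = sm["heading_deg", "Pr(>|t|)"],
                 preferred_side = if (slope >= 0) "right" else "left",
                 n_trials = length(fr)),
            class = "tuning_fit")
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf(
    "Tuning regression: slope %.3f Hz/deg (p = %.3g), prefers %s, n = %d\n",
    x$slope_hz_per_deg, x$p_value, x$preferred_side, x$n_trials))
  invisible(x)
}

#' ROC area of z-scored responses against the fixed reference
#'
#' For one heading's z-scored firing rates (z-scored against the
#' pre-recalibration mean and SD, so the reference point is z = 0), an ROC
#' curve is traced by moving a criterion from the minimum to the maximum
#' z-score in `n_criteria` steps; the criterion steps through the sample
#' quantiles of the observed z-scores (so that for up to `n_criteria`
#' trials every response value is visited), with the reference value 0
#' always included as a criterion. Each criterion yields the ROC point
#' (reference exceeds criterion: 0/1, fraction of z exceeding criterion),
#' with strict `>` comparisons. The trapezoidal area under the swept curve
#' estimates the probability that an ideal observer judges the response to
#' lie on the positive side of the reference; it equals the fraction of
#' z-scores above zero, counting ties at zero as half
#' (see `auc_reference_exact()`), exactly for `length(z) <= n_criteria`
#' and up to quantile-grid skipping beyond that.
#'
#' @param z Numeric vector of z-scores for one heading.
#' @param n_criteria Number of criterion steps (default 100).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_vs_reference(c(-1, 1))        # 0.5
#' auc_vs_reference(c(-1, 0.5, 2))   # 2/3
#' @export
auc_vs_reference <- function(z, n_criteria = 100) {
  if (length(z) < 1) stop("empty z-score vector")
  z <- z[is.finite(z)]
  if (length(z) < 1) stop("no finite z-scores")
  if (max(z, 0) - min(z, 0) < 1e-12) return(0.5)
  crit <- c(stats::quantile(z, seq(0, 1, length.out = n_criteria),
                            type = 1, names = FALSE), 0)
  # The reference coordinate I(0 > c) is binary, so after sorting the swept
  # (I(0 > c), P(z > c)) points (anchored at (0,0) and (1,1)) the only
  # segment with nonzero width runs from the topmost point with x = 0 to
  # the lowest point with x = 1: the criteria immediately at/above and
  # below zero. The trapezoid over the full sweep therefore reduces to the
  # average of P(z > c) at those two criteria.
  neg <- crit[crit < 0]
  y_below <- if (length(neg)) mean(z > max(neg)) else 1
  y_above <- mean(z > 0)                           # criterion at the reference
  (y_below + y_above) / 2
}

# closed-form counterpart used as an oracle in tests (kept exported for
# transparency): fraction of z above 0 plus half-ties
#' @rdname auc_vs_reference
#' @export
auc_reference_exact <- function(z) {
  z <- z[is.finite(z)]
  (sum(z > 0) + 0.5 * sum(z == 0)) / length(z)
}

#' Pre-recalibration reference statistics
#'
#' Mean and SD of the raw firing rates over all pre-recalibration
#' single-cue trials of one cue, pooled across headings. These statistics
#' anchor the z-scoring of both the pre- and the post-recalibration rates,
#' so that z = 0 always marks the pre-recalibration mean.
#'
#' @param fr_pre Raw per-trial firing rates of the pre block (one cue).
#' @return List with `mean_hz` and `sd_hz`.
#' @export
reference_stats <- function(fr_pre) {
  list(mean_hz = mean(fr_pre), sd_hz = stats::sd(fr_pre))
}

#' Fit a reference-anchored neurometric function
#'
#' Builds the ideal-observer neurometric curve of one neuron, cue, and
#' block: firing rates are z-scored with the *pre-recalibration* reference
#' statistics (for the post block as well, so the reference is common),
#' each heading's rates yield an ROC area against the reference via
#' [auc_vs_reference()], the area is mapped to the probability of a
#' rightward choice (`AUC` if the neuron's pre-recalibration preferred side
#' is right, `1 - AUC` otherwise), and a cumulative Gaussian is fitted to
#' the per-heading probabilities weighted by trial counts. The fitted mean
#' is the neurometric PSE: the heading the neuron's response "decodes" as
#' straight ahead, relative to the pre-recalibration mean rate.
#'
#' @param fr Raw per-trial firing rates for one block/cue.
#' @param heading_deg Matching per-trial headings.
#' @param reference [reference_stats()] of the same cue's pre block.
#' @param preferred_side `"left"` or `"right"`, from the pre-block tuning
#'   slope (fixed across blocks).
#' @param n_criteria Criterion steps for the ROC sweep.
#' @return An object of class `neurofit`: `pse_deg`, `sigma_deg`, `curve`
#'   (per-heading AUC and P(rightward) with trial counts), `reference`,
#'   `preferred_side`, `converged` (FALSE when the reference SD is
#'   degenerate or the fit is non-identified).
#' @export
fit_neurometric <- function(fr, heading_deg, reference, preferred_side,
                            n_criteria = 100) {
  stopifnot(preferred_side %in% c("left", "right"))
  if (!is.finite(reference$sd_hz) || reference$sd_hz <= 0) {
    return(structure(list(pse_deg = NA_real_, sigma_deg = NA_real_,
                          curve = NULL, reference = reference,
                          preferred_side = preferred_side,
                          converged = FALSE),
                     class = "neurofit"))
  }
  z <- (fr - reference$mean_hz) / reference$sd_hz
  hs <- sort(unique(heading_deg))
  auc <- vapply(hs, function(h) {
    auc_vs_reference(z[heading_deg == h], n_criteria)
  }, numeric(1))
  n <- vapply(hs, function(h) sum(heading_deg == h), numeric(1))
  p_right <- if (preferred_side == "right") auc else 1 - auc
  core <- fit_cumgauss(hs, p_right * n, n, lapse_fixed = 0)
  structure(list(pse_deg = core$mu, sigma_deg = core$sigma,
                 curve = data.frame(heading_deg = hs, n = n, auc = auc,
                                    p_right = p_right),
                 reference = reference, preferred_side = preferred_side,
                 converged = core$converged),
            class = "neurofit")
}

#' @export
print.neurofit <- function(x, ...) {
  cat("Reference-anchored neurometric fit\n")
  if (!x$converged) cat("  ** degenerate / non-converged **\n")
  cat(sprintf("  neurometric PSE %8.3f deg\n", x$pse_deg))
  cat(sprintf("  sigma           %8.3f deg\n", x$sigma_deg))
  cat(sprintf("  preferred side  %s\n", x$preferred_side))
  invisible(x)
}

#' @export
coef.neurofit <- function(object, ...) {
  c(pse_deg = object$pse_deg, sigma_deg = object$sigma_deg)
}

#' @export
predict.neurofit <- function(object, newdata = NULL, ...) {
  h <- if (is.null(newdata)) object$curve$heading_deg else newdata
  cg_prob(h, object$pse_deg, object$sigma_deg, 0)
}

#' @export
plot.neurofit <- function(x, ..., main = "Neurometric function") {
  graphics::plot(x$curve$heading_deg, x$curve$p_right, pch = 16,
                 xlab = "heading (deg)", ylab = "P(rightward | ideal observer)",
                 ylim = c(0, 1), main = main, ...)
  hh <- seq(min(x$curve$heading_deg), max(x$curve$heading_deg),
            length.out = 200)
  graphics::lines(hh, predict(x, hh))
  graphics::abline(h = 0.5, v = x$pse_deg, lty = 3)
  invisible(x)
}

#' Bootstrap SD of the neurometric PSE
#'
#' Resamples trials with replacement within each heading (preserving the
#' design balance), refits the neurometric function, and returns the SD of
#' the resampled PSEs -- the reliability statistic screened at < 10 deg.
#' Non-converged resamples are dropped; if more than 20% drop, the SD is
#' `Inf` (the neuron fails the screen).
#'
#' @inheritParams fit_neurometric
#' @param B Number of bootstrap resamples (>= 50; default 1000).
#' @return Bootstrap SD of the PSE, degrees.
#' @export
bootstrap_pse_sd <- function(fr, heading_deg, reference, preferred_side,
                             B = 1000, n_criteria = 100) {
  if (B < 50) stop("B must be >= 50")
  if (!is.finite(reference$sd_hz) || reference$sd_hz <= 0) return(Inf)
  z <- (fr - reference$mean_hz) / reference$sd_hz
  idx_by_h <- split(seq_along(heading_deg), heading_deg)
  hs <- as.numeric(names(idx_by_h))
  n <- lengths(idx_by_h)
  flip <- preferred_side == "left"
  pses <- vapply(seq_len(B), function(b) {
    p_right <- vapply(idx_by_h, function(ix) {
      a <- auc_vs_reference(z[sample(ix, length(ix), replace = TRUE)],
                            n_criteria)
      if (flip) 1 - a else a
    }, numeric(1))
    core <- fit_cumgauss(hs, p_right * n, n, lapse_fixed = 0)
    if (core$converged) core$mu else NA_real_
  }, numeric(1))
  dropped <- mean(is.na(pses))
  if (dropped > 0.2) return(Inf)
  stats::sd(pses[!is.na(pses)])
}

#' Apply the neuron inclusion screen
#'
#' A (neuron, cue) enters shift analyses iff it is significantly tuned to
#' that cue in at least one block (pre or post) and both blocks'
#' neurometric PSEs are reliable (bootstrap SD < 10 deg).
#'
#' @param tuning_pre,tuning_post [tuning_regression()] fits.
#' @param sd_pre_deg,sd_post_deg Bootstrap PSE SDs per block.
#' @param alpha Tuning significance level.
#' @param sd_limit_deg Reliability limit.
#' @return List of class `screen_result` with `tuned_pre`, `tuned_post`,
#'   `bootstrap_sd_pre`, `bootstrap_sd_post`, `passed`.
#' @export
screen_neuron <- function(tuning_pre, tuning_post, sd_pre_deg, sd_post_deg,
                          alpha = 0.05, sd_limit_deg = 10) {
  tuned_pre <- is.finite(tuning_pre$p_value) && tuning_pre$p_value < alpha
  tuned_post <- is.finite(tuning_post$p_value) && tuning_post$p_value < alpha
  passed <- (tuned_pre || tuned_post) &&
    is.finite(sd_pre_deg) && sd_pre_deg < sd_limit_deg &&
    is.finite(sd_post_deg) && sd_post_deg < sd_limit_deg
  structure(list(tuned_pre = tuned_pre, tuned_post = tuned_post,
                 bootstrap_sd_pre = sd_pre_deg,
                 bootstrap_sd_post = sd_post_deg,
                 passed = passed),
            class = "screen_result")
}

#' Neuronal PSE shift between blocks
#'
#' Post-minus-pre neurometric PSE, with the same sign convention as the
#' perceptual [pse_shift()]. Refuses to compute a shift for a neuron that
#' failed the inclusion screen.
#'
#' @param fit_pre,fit_post `neurofit` objects.
#' @param screen Optional [screen_neuron()] result; if given and not
#'   passed, an error is raised.
#' @return Shift in degrees.
#' @export
neuronal_shift <- function(fit_pre, fit_post, screen = NULL) {
  if (!is.null(screen) && !isTRUE(screen$passed)) {
    stop("neuron did not pass the inclusion screen; no shift computed")
  }
  if (!isTRUE(fit_pre$converged) || !isTRUE(fit_post$converged)) {
    return(NA_real_)
  }
  fit_post$pse_deg - fit_pre$pse_deg
}

#' Time-resolved neuronal shifts in sliding windows
#'
#' Recomputes the neurometric shift in narrow windows (default 200 ms wide,
#' centers from 0.1 to 1.2 s after stimulus onset in 100 ms steps). For
#' each window, firing rates and the pre-block reference statistics are
#' recomputed *in that window*; the preferred side stays fixed (from the
#' full-window pre-block tuning).
#'
#' @param counts Trials x bins spike-count matrix (one neuron).
#' @param grid The matching [time_grid()].
#' @param heading_deg Per-trial cue headings (NA for trials of other
#'   modalities, which are ignored).
#' @param block Per-trial block labels (`pre`/`recal`/`post`).
#' @param preferred_side Fixed preferred side from pre-block tuning.
#' @param centers_s Window centers (s).
#' @param half_width_s Window half-width (s).
#' @param n_criteria Criterion steps for the ROC sweep.
#' @return Data.frame with one row per window: `center_s`, `pse_pre_deg`,
#'   `pse_post_deg`, `shift_deg` (NA when either fit is non-converged).
#' @export
sliding_window_shifts <- function(counts, grid, heading_deg, block,
                                  preferred_side,
                                  centers_s = seq(0.1, 1.2, by = 0.1),
                                  half_width_s = 0.1,
                                  n_criteria = 100) {
  pre <- block == "pre" & !is.na(heading_deg)
  post <- block == "post" & !is.na(heading_deg)
  out <- lapply(centers_s, function(ct) {
    win <- c(ct - half_width_s, ct + half_width_s)
    fr <- window_rates(counts, grid, win)
    ref <- reference_stats(fr[pre])
    f1 <- fit_neurometric(fr[pre], heading_deg[pre], ref, preferred_side,
                          n_criteria)
    f2 <- fit_neurometric(fr[post], heading_deg[post], ref, preferred_side,
                          n_criteria)
    data.frame(center_s = ct,
               pse_pre_deg = f1$pse_deg, pse_post_deg = f2$pse_deg,
               shift_deg = neuronal_shift(f1, f2))
  })
  do.call(rbind, out)
}
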