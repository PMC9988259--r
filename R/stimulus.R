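#' Gaussian-velocity self-motion stimulus profile
#'
#' Describes the kinematics of a translational heading stimulus with a
#' Gaussian velocity profile, as delivered by a motion platform and matched
#' optic flow. Given the duration, total displacement and peak velocity, the
#' temporal standard deviation of the velocity bell is fully determined:
#' `sigma_t = displacement / (peak_velocity * sqrt(2*pi))`, and the peak of
#' the (biphasic) acceleration profile is
#' `peak_velocity * exp(-1/2) / sigma_t`.
#'
#' The default values (1 s, 13 cm, 0.41 m/s) give `sigma_t` of about 0.127 s
#' and a peak acceleration of about 2.0 m/s^2.
#'
#' @param duration_s Stimulus duration in seconds.
#' @param displacement_m Total displacement in meters.
#' @param peak_velocity_mps Peak velocity in m/s.
#' @return An object of class `stimulus_profile` with elements
#'   `duration_s`, `displacement_m`, `peak_velocity_mps`, `sigma_t_s`,
#'   `peak_accel_mps2`, and functions `velocity_fn(t)` and `accel_fn(t)`
#'   (both vectorised, zero outside `[0, duration_s]`).
#' @examples
#' sp <- stimulus_profile()
#' sp$peak_accel_mps2         # ~1.97 m/s^2
#' integrate(sp$velocity_fn, 0, 1)$value  # ~0.13 m
#' @export
stimulus_profile <- function(duration_s = 1,
                             displacement_m = 0.13,
                             peak_velocity_mps = 0.41) {
  stopifnot(duration_s > 0, displacement_m > 0, peak_velocity_mps > 0)
  sigma_t <- displacement_m / (peak_velocity_mps * sqrt(2 * pi))
  # the bell must essentially fit inside the stimulus interval, otherwise the
  # displacement integral over [0, duration] undershoots the nominal value
  if (duration_s < 6 * sigma_t) {
    stop("duration too short for the implied velocity profile (",
         signif(sigma_t, 4), " s temporal SD)")
  }
  t0 <- duration_s / 2
  velocity_fn <- function(t) {
    ifelse(t >= 0 & t <= duration_s,
           peak_velocity_mps * exp(-(t - t0)^2 / (2 * sigma_t^2)),
           0)
  }
  accel_fn <- function(t) {
    ifelse(t >= 0 & t <= duration_s,
           -peak_velocity_mps * (t - t0) / sigma_t^2 *
             exp(-(t - t0)^2 / (2 * sigma_t^2)),
           0)
  }
  structure(list(
    duration_s = duration_s,
    displacement_m = displacement_m,
    peak_velocity_mps = peak_velocity_mps,
    sigma_t_s = sigma_t,
    peak_accel_mps2 = peak_velocity_mps * exp(-0.5) / sigma_t,
    velocity_fn = velocity_fn,
    accel_fn = accel_fn
  ), class = "stimulus_profile")
}

#' @export
print.stimulus_profile <- function(x, ...) {
  cat("Gaussian velocity profile:\n")
  cat(sprintf("  duration      %.3g s\n", x$duration_s))
  cat(sprintf("  displacement  %.3g m\n", x$displacement_m))
  cat(sprintf("  peak velocity %.3g m/s\n", x$peak_velocity_mps))
  cat(sprintf("  temporal SD   %.4g s\n", x$sigma_t_s))
  cat(sprintf("  peak accel    %.3g m/s^2\n", x$peak_accel_mps2))
  invisible(x)
}

#' Analysis time grid for binned spike counts
#'
#' A fixed grid of contiguous bins spanning the pre-stimulus baseline and the
#' stimulus/post-stimulus epochs, shared by all neurons of a session. The
#' default (100 ms bins from -1.0 to +1.3 s around stimulus onset) aligns all
#' windows used downstream (1 s baseline, 1 s stimulus, 200 ms sliding
#' windows at 100 ms increments up to center 1.2 s) to bin edges.
#'
#' @param start_s,end_s Grid limits in seconds relative to stimulus onset.
#' @param bin_width_s Bin width in seconds; must tile `[start_s, end_s]`.
#' @return A list with `bin_start_s` (left edges), `bin_width_s`,
#'   `start_s`, `end_s`, and `centers_s`.
#' @export
time_grid <- function(start_s = -1, end_s = 1.3, bin_width_s = 0.1) {
  stopifnot(bin_width_s > 0, end_s > start_s)
  n <- (end_s - start_s) / bin_width_s
  if (abs(n - round(n)) > 1e-8) {
    stop("bin_width_s must tile the interval [start_s, end_s] exactly")
  }
  n <- round(n)
  starts <- start_s + bin_width_s * (seq_len(n) - 1)
  list(bin_start_s = starts, bin_width_s = bin_width_s,
       start_s = start_s, end_s = end_s,
       centers_s = starts + bin_width_s / 2)
}

# temporal gain m(t) in [0, 1] applied to the stimulus-driven rate component.
# velocity mode: normalized Gaussian velocity. sustained mode: leaky
# integration of the normalized velocity (time constant tau), peak-normalized,
# so activity rises with the stimulus and decays exponentially after offset.
temporal_modulation <- function(t, profile, mode = c("velocity", "sustained"),
                                tau_s = 0.5) {
  mode <- match.arg(mode)
  if (mode == "velocity") {
    return(profile$velocity_fn(t) / profile$peak_velocity_mps)
  }
  stopifnot(tau_s > 0)
  dt <- 0.002
  tf <- seq(0, max(max(t), profile$duration_s) + dt, by = dt)
  v <- profile$velocity_fn(tf) / profile$peak_velocity_mps
  m <- numeric(length(tf))
  decay <- exp(-dt / tau_s)
  for (i in seq_along(tf)[-1]) {
    m[i] <- m[i - 1] * decay + v[i] * dt / tau_s
  }
  m <- m / max(m)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- stats::approx(tf, m, xout = t[pos], rule = 2)$y
  out
}
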