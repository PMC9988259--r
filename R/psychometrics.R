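#' Fit a psychometric function to heading-discrimination choices
#'
#' Maximum-likelihood fit of a cumulative Gaussian to the proportion of
#' rightward choices as a function of signed heading:
#' `P(right | h) = lapse/2 + (1 - lapse) * pnorm((h - mu) / sigma)`.
#' The mean `mu` is the point of subjective equality (PSE; the heading
#' perceived as straight ahead) and the SD `sigma` is the psychophysical
#' threshold. The lapse is either fixed (default 0) or estimated freely on
#' `[0, 0.1]`; both treatments are useful and PSE shifts should always be
#' computed from fits with matching lapse handling.
#'
#' The optimizer restarts from five deterministic initializations (a probit
#' regression start plus a grid on `mu`, `sigma`); ties are broken by
#' log-likelihood, then smaller `sigma`. The fit is invariant to trial
#' order. With fewer than two distinct headings, or choices on only one
#' side, the fit is flagged non-converged and the PSE left undefined.
#'
#' @param heading_deg Signed heading per trial, degrees.
#' @param choice Per-trial choice: `"left"`/`"right"` (or `"L"`/`"R"`),
#'   logical (TRUE = right), or numeric (-1/+1 or 0/1, positive = right).
#' @param lapse `"fixed"` (at `lapse_value`) or `"free"`.
#' @param lapse_value Fixed lapse value.
#' @return An object of class `psychfit` with elements `pse_deg`,
#'   `threshold_deg`, `lapse`, `n_trials`, `prop` (per-heading trial counts
#'   and rightward proportions), `logLik` and `converged`.
#' @examples
#' set.seed(1)
#' h <- rep(c(-16, -8, -4, -2, -1, 1, 2, 4, 8, 16), each = 20)
#' ch <- ifelse(runif(length(h)) < pnorm((h - 2) / 4), "right", "left")
#' fit <- fit_psychometric(h, ch)
#' coef(fit)
#' @export
fit_psychometric <- function(heading_deg, choice,
                             lapse = c("fixed", "free"), lapse_value = 0) {
  lapse <- match.arg(lapse)
  right <- parse_choice(choice)
  keep <- !is.na(right) & is.finite(heading_deg)
  heading_deg <- heading_deg[keep]
  right <- right[keep]

  agg <- stats::aggregate(right, by = list(h = heading_deg),
                          FUN = function(x) c(k = sum(x), n = length(x)))
  h <- agg$h; k <- agg$x[, "k"]; n <- agg$x[, "n"]
  prop <- data.frame(heading_deg = h, n = n, k = k, p_right = k / n)

  ok <- length(h) >= 2 && sum(k) > 0 && sum(k) < sum(n)
  core <- if (ok) {
    fit_cumgauss(h, k, n,
                 lapse_fixed = if (lapse == "free") NA_real_ else lapse_value)
  } else {
    list(mu = NA_real_, sigma = NA_real_, lapse = NA_real_,
         logLik = NA_real_, converged = FALSE)
  }
  structure(list(pse_deg = core$mu, threshold_deg = core$sigma,
                 lapse = core$lapse, lapse_mode = lapse,
                 n_trials = sum(n), prop = prop,
                 logLik = core$logLik, converged = core$converged),
            class = "psychfit")
}

parse_choice <- function(choice) {
  if (is.logical(choice)) return(as.numeric(choice))
  if (is.numeric(choice)) return(as.numeric(choice > 0))
  ch <- tolower(as.character(choice))
  out <- rep(NA_real_, length(ch))
  out[ch %in% c("right", "r")] <- 1
  out[ch %in% c("left", "l")] <- 0
  out
}

#' @export
print.psychfit <- function(x, ...) {
  cat("Cumulative-Gaussian psychometric fit\n")
  if (!x$converged) cat("  ** did not converge **\n")
  cat(sprintf("  PSE       %8.3f deg\n", x$pse_deg))
  cat(sprintf("  threshold %8.3f deg\n", x$threshold_deg))
  cat(sprintf("  lapse     %8.4f (%s)\n", x$lapse, x$lapse_mode))
  cat(sprintf("  trials    %d over %d headings\n",
              x$n_trials, nrow(x$prop)))
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) {
  c(pse_deg = object$pse_deg, threshold_deg = object$threshold_deg,
    lapse = object$lapse)
}

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$logLik, df = if (object$lapse_mode == "free") 3 else 2,
            class = "logLik")
}

#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  h <- if (is.null(newdata)) object$prop$heading_deg else newdata
  cg_prob(h, object$pse_deg, object$threshold_deg, object$lapse)
}

#' @export
plot.psychfit <- function(x, ..., main = "Psychometric function") {
  graphics::plot(x$prop$heading_deg, x$prop$p_right, pch = 16,
                 xlab = "heading (deg)", ylab = "P(rightward)",
                 ylim = c(0, 1), main = main, ...)
  hh <- seq(min(x$prop$heading_deg), max(x$prop$heading_deg), length.out = 200)
  graphics::lines(hh, predict(x, hh))
  graphics::abline(h = 0.5, v = x$pse_deg, lty = 3)
  invisible(x)
}

#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  h <- rep(object$prop$heading_deg, object$prop$n)
  p <- predict(object, h)
  replicate(nsim, ifelse(stats::runif(length(h)) < p, "right", "left"),
            simplify = FALSE)
}

#' Perceptual PSE shift between two blocks
#'
#' `pse_shift = PSE_post - PSE_pre`. A positive value means the psychometric
#' curve moved rightward, i.e. a leftward perceptual shift. Non-converged
#' fits propagate `NA`.
#'
#' @param fit_pre,fit_post `psychfit` (or `neurofit`) objects.
#' @return Shift in degrees (scalar).
#' @export
pse_shift <- function(fit_pre, fit_post) {
  if (!isTRUE(fit_pre$converged) || !isTRUE(fit_post$converged)) {
    return(NA_real_)
  }
  fit_post$pse_deg - fit_pre$pse_deg
}

#' Group-level summary of behavioral PSE shifts
#'
#' Per (cue, delta sign): mean shift, SEM, and the two-sided paired t-test
#' of post- versus pre-recalibration PSEs across sessions. Additionally the
#' vestibular and visual shift magnitudes are compared after sign-flip
#' pooling (see [pool_signed_shifts()]): sessions with both cues measured
#' contribute a pair to a two-sided paired t-test of vestibular versus
#' visual pooled magnitude.
#'
#' @param shifts Data.frame with columns `session_id`, `cue`
#'   (`vestibular`/`visual`), `delta_sign` (+1/-1), `pse_pre_deg`,
#'   `pse_post_deg`, `shift_deg`.
#' @return A list with `groups` (per cue x delta sign summary, flagged when
#'   degenerate) and `pooled` (vestibular-vs-visual comparison).
#' @export
behavioral_summary <- function(shifts) {
  need <- c("session_id", "cue", "delta_sign", "pse_pre_deg",
            "pse_post_deg", "shift_deg")
  missing <- setdiff(need, names(shifts))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  groups <- do.call(rbind, lapply(split(
    shifts, list(shifts$cue, shifts$delta_sign), drop = TRUE),
    function(d) {
      if (nrow(d) < 2) {
        stop("need >= 2 sessions per (cue, delta_sign) group; got ",
             nrow(d), " for ", d$cue[1])
      }
      s <- d$shift_deg
      degenerate <- stats::sd(s) == 0
      tt <- if (!degenerate) {
        stats::t.test(d$pse_post_deg, d$pse_pre_deg, paired = TRUE)
      } else NULL
      data.frame(cue = d$cue[1], delta_sign = d$delta_sign[1],
                 n = nrow(d), mean_shift_deg = mean(s),
                 sem_deg = stats::sd(s) / sqrt(nrow(d)),
                 t = if (degenerate) NA_real_ else unname(tt$statistic),
                 p = if (degenerate) NA_real_ else tt$p.value,
                 degenerate = degenerate)
    }))
  rownames(groups) <- NULL

  pooled_val <- pool_signed_shifts(shifts$shift_deg, shifts$cue,
                                   shifts$delta_sign)
  wide <- merge(
    data.frame(session_id = shifts$session_id, cue = shifts$cue,
               pooled = pooled_val)[shifts$cue == "vestibular", c(1, 3)],
    data.frame(session_id = shifts$session_id, cue = shifts$cue,
               pooled = pooled_val)[shifts$cue == "visual", c(1, 3)],
    by = "session_id", suffixes = c("_vest", "_vis"))
  pooled <- if (nrow(wide) >= 2 &&
                stats::sd(wide$pooled_vest - wide$pooled_vis) > 0) {
    tt <- stats::t.test(wide$pooled_vest, wide$pooled_vis, paired = TRUE)
    list(n = nrow(wide),
         mean_vest_deg = mean(wide$pooled_vest),
         mean_vis_deg = mean(wide$pooled_vis),
         t = unname(tt$statistic), p = tt$p.value)
  } else {
    list(n = nrow(wide), mean_vest_deg = mean(wide$pooled_vest),
         mean_vis_deg = mean(wide$pooled_vis), t = NA_real_, p = NA_real_)
  }
  list(groups = groups, pooled = pooled)
}
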