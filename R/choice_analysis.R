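#' Heading and choice partial correlations of firing rates
#'
#' Decomposes trial-by-trial firing rates (over the stimulus duration) into
#' a heading component and a choice component by Pearson partial
#' correlation: `R_h = corr(FR, heading | choice)` and
#' `R_c = corr(FR, choice | heading)`, using the identity
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`.
#' Choices are coded -1 (left) / +1 (right), so positive `R_c` means higher
#' rates before rightward choices given the heading. Two-sided p-values use
#' the t transform with `n - 3` degrees of freedom. The squared partials
#' quantify the unique variance explained by heading and by choice.
#'
#' @param fr Per-trial firing rates.
#' @param heading_deg Per-trial signed headings (degrees, linear scale).
#' @param choice Per-trial choices (as accepted by [fit_psychometric()]).
#' @return List of class `partial_corr`: `r_h`, `r_c`, `p_h`, `p_c`,
#'   `r_h2`, `r_c2`, `n_trials`, `flag` (`"ok"` or `"single_choice_class"`).
#' @export
partial_correlations <- function(fr, heading_deg, choice) {
  C <- parse_choice(choice) * 2 - 1
  keep <- !is.na(C) & is.finite(fr) & is.finite(heading_deg)
  fr <- fr[keep]; h <- heading_deg[keep]; C <- C[keep]
  n <- length(fr)
  if (n < 10) stop("need >= 10 trials for partial correlations")
  if (stats::sd(h) == 0) stop("heading has zero variance")
  if (length(unique(C)) < 2) {
    r_h <- stats::cor(fr, h)
    return(structure(list(r_h = r_h, r_c = NA_real_,
                          p_h = cor_p(r_h, n, df = n - 2), p_c = NA_real_,
                          r_h2 = r_h^2, r_c2 = NA_real_, n_trials = n,
                          flag = "single_choice_class"),
                     class = "partial_corr"))
  }
  r_fh <- stats::cor(fr, h)
  r_fc <- stats::cor(fr, C)
  r_hc <- stats::cor(h, C)
  if (abs(r_hc) > 1 - 1e-12) stop("heading and choice perfectly collinear")
  r_h <- (r_fh - r_fc * r_hc) / sqrt((1 - r_fc^2) * (1 - r_hc^2))
  r_c <- (r_fc - r_fh * r_hc) / sqrt((1 - r_fh^2) * (1 - r_hc^2))
  structure(list(r_h = r_h, r_c = r_c,
                 p_h = cor_p(r_h, n, df = n - 3),
                 p_c = cor_p(r_c, n, df = n - 3),
                 r_h2 = r_h^2, r_c2 = r_c^2, n_trials = n, flag = "ok"),
            class = "partial_corr")
}

cor_p <- function(r, n, df) {
  r <- min(max(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}

#' @export
print.partial_corr <- function(x, ...) {
  cat(sprintf(
    "Partial correlations (n = %d): R_h = %.3f (p = %.3g), R_c = %s\n",
    x$n_trials, x$r_h, x$p_h,
    if (is.na(x$r_c)) "undefined (single choice class)"
    else sprintf("%.3f (p = %.3g)", x$r_c, x$p_c)))
  invisible(x)
}

#' Choice-conditioned tuning curves
#'
#' Mean firing rate per heading computed separately for trials followed by
#' leftward and rightward choices, plus the overall curve (which equals the
#' count-weighted mean of the two conditioned curves, exactly). Conditioned
#' cells with fewer than `min_count` trials are masked (`NA`), but still
#' reported with their counts.
#'
#' @inheritParams partial_correlations
#' @param min_count Minimum trials per (heading, choice) cell.
#' @return Data.frame with per-heading `n_left`, `n_right`, `fr_left_hz`,
#'   `fr_right_hz` (masked below `min_count`), `fr_left_raw_hz`,
#'   `fr_right_raw_hz` (unmasked) and `fr_all_hz`.
#' @export
choice_conditioned_tuning <- function(fr, heading_deg, choice,
                                      min_count = 3) {
  right <- parse_choice(choice)
  keep <- !is.na(right)
  fr <- fr[keep]; h <- heading_deg[keep]; right <- right[keep]
  hs <- sort(unique(h))
  row <- function(hd) {
    iL <- h == hd & right == 0
    iR <- h == hd & right == 1
    mL <- if (any(iL)) mean(fr[iL]) else NA_real_
    mR <- if (any(iR)) mean(fr[iR]) else NA_real_
    data.frame(heading_deg = hd, n_left = sum(iL), n_right = sum(iR),
               fr_left_raw_hz = mL, fr_right_raw_hz = mR,
               fr_left_hz = if (sum(iL) >= min_count) mL else NA_real_,
               fr_right_hz = if (sum(iR) >= min_count) mR else NA_real_,
               fr_all_hz = mean(fr[h == hd]))
  }
  out <- do.call(rbind, lapply(hs, row))
  rownames(out) <- NULL
  out
}

#' Pre/post comparison of squared partial correlations
#'
#' Two-sided paired t-tests, per cue, of the post- versus pre-recalibration
#' squared choice partials (`R_c^2`) and squared heading partials
#' (`R_h^2`) across neurons. A reduction in `R_c^2` with unchanged `R_h^2`
#' indicates a selective loss of choice-related signal.
#'
#' @param partials Data.frame with columns `neuron_id`, `cue`, `block`
#'   (`pre`/`post`), `r_h`, `r_c` (one row per neuron x cue x block).
#' @return Data.frame with one row per (cue, measure in `r_c2`/`r_h2`):
#'   `n_pairs`, `mean_diff` (post - pre), `t`, `df`, `p`.
#' @export
compare_pre_post_partials <- function(partials) {
  need <- c("neuron_id", "cue", "block", "r_h", "r_c")
  missing <- setdiff(need, names(partials))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- list()
  for (cue in unique(partials$cue)) {
    d <- partials[partials$cue == cue, ]
    wide <- merge(d[d$block == "pre", c("neuron_id", "r_h", "r_c")],
                  d[d$block == "post", c("neuron_id", "r_h", "r_c")],
                  by = "neuron_id", suffixes = c("_pre", "_post"))
    for (measure in c("r_c2", "r_h2")) {
      v <- if (measure == "r_c2") "r_c" else "r_h"
      pre <- wide[[paste0(v, "_pre")]]^2
      post <- wide[[paste0(v, "_post")]]^2
      ok <- is.finite(pre) & is.finite(post)
      pre <- pre[ok]; post <- post[ok]
      if (length(pre) < 2) {
        stop("need >= 2 paired neurons for ", cue, "/", measure)
      }
      if (length(pre) < 5) {
        warning("fewer than 5 paired neurons for ", cue, "/", measure)
      }
      identical_pairs <- stats::sd(post - pre) == 0
      tt <- if (!identical_pairs) stats::t.test(post, pre, paired = TRUE)
      out[[paste(cue, measure)]] <- data.frame(
        cue = cue, measure = measure, n_pairs = length(pre),
        mean_diff = mean(post - pre),
        t = if (identical_pairs) NA_real_ else unname(tt$statistic),
        df = length(pre) - 1,
        p = if (identical_pairs) NA_real_ else tt$p.value)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pre/post comparison of baseline firing rates
#'
#' Two-sided paired t-test of post- versus pre-recalibration baseline
#' firing rates across neurons, with the mean difference and its 95%
#' confidence interval. Used to check that tuning shifts are not explained
#' by baseline changes.
#'
#' @param baseline_pre_hz,baseline_post_hz Paired per-neuron baseline rates.
#' @return List with `n`, `mean_diff_hz`, `ci_hz`, `t`, `df`, `p`.
#' @export
baseline_fr_comparison <- function(baseline_pre_hz, baseline_post_hz) {
  stopifnot(length(baseline_pre_hz) == length(baseline_post_hz))
  n <- length(baseline_pre_hz)
  if (n < 2) stop("need >= 2 paired baselines")
  d <- baseline_post_hz - baseline_pre_hz
  if (stats::sd(d) == 0) {
    return(list(n = n, mean_diff_hz = mean(d), ci_hz = c(mean(d), mean(d)),
                t = NA_real_, df = n - 1, p = NA_real_))
  }
  tt <- stats::t.test(baseline_post_hz, baseline_pre_hz, paired = TRUE)
  list(n = n, mean_diff_hz = mean(d),
       ci_hz = unname(tt$conf.int), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}
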