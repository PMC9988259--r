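#' Pool signed PSE shifts across discrepancy orientations
#'
#' Under a positive discrepancy (delta+) conflict-reducing recalibration
#' moves the vestibular PSE rightward (positive shift) and the visual PSE
#' leftward (negative); under delta- the signs reverse. To pool magnitudes
#' across conditions, vestibular shifts from delta- sessions and visual
#' shifts from delta+ sessions are sign-flipped, so that positive pooled
#' values always mean recalibration in the conflict-reducing direction.
#' The flip is an involution: applying it twice restores the input.
#'
#' @param shift_deg Signed PSE shifts (degrees).
#' @param cue `"vestibular"` or `"visual"` (vectorised).
#' @param delta_sign +1 / -1 (or `"+"` / `"-"`), vectorised.
#' @return Pooled shifts, same length as `shift_deg`.
#' @examples
#' pool_signed_shifts(c(1.2, -1.76, -0.73),
#'                    c("vestibular", "vestibular", "visual"),
#'                    c(1, -1, 1))   # 1.2, 1.76, 0.73
#' @export
pool_signed_shifts <- function(shift_deg, cue, delta_sign) {
  if (is.character(delta_sign)) {
    delta_sign <- ifelse(delta_sign %in% c("+", "plus"), 1, -1)
  }
  bad <- !(cue %in% c("vestibular", "visual"))
  if (any(bad)) stop("unknown cue: ", paste(unique(cue[bad]), collapse = ", "))
  stopifnot(all(delta_sign %in% c(-1, 1)))
  flip <- (cue == "vestibular" & delta_sign < 0) |
    (cue == "visual" & delta_sign > 0)
  ifelse(flip, -shift_deg, shift_deg)
}

#' Correlation between neuronal and perceptual PSE shifts
#'
#' Pearson correlation (two-sided) between per-session neuronal and
#' perceptual PSE shifts, using raw signed shifts with both discrepancy
#' orientations in one cloud (no pooling flip), as in population
#' scatterplots of neuronal versus perceptual shifts.
#'
#' @param records Data.frame with columns `neuronal_shift_deg` and
#'   `perceptual_shift_deg`; rows with either value missing are dropped,
#'   and rows failing the screen (`passed` column, if present) excluded.
#' @return List with `r`, `p`, `n`.
#' @export
neuronal_perceptual_correlation <- function(records) {
  stopifnot(all(c("neuronal_shift_deg", "perceptual_shift_deg")
                %in% names(records)))
  if (!is.null(records$passed)) records <- records[records$passed, ]
  x <- records$perceptual_shift_deg
  y <- records$neuronal_shift_deg
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 screened records")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in shifts; correlation undefined")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pooled regression versus linear mixed model of neuronal on perceptual shifts
#'
#' Fits (a) a pooled linear regression of neuronal on perceptual shifts
#' ignoring monkey identity and (b) a linear mixed model with by-monkey
#' random intercepts and slopes. The mixed model is estimated by REML for
#' the reported fixed effects and refitted by ML for the AIC/BIC comparison
#' with the pooled model (the two models share fixed effects, so ML
#' likelihoods are the comparable ones). The mixed model is declared
#' preferred only when both its AIC and its BIC are lower. A singular
#' random-effects fit falls back to random intercepts only, flagged.
#'
#' @param records Data.frame with `neuronal_shift_deg`,
#'   `perceptual_shift_deg`, `monkey_id` (>= 2 monkeys with >= 3 records
#'   each).
#' @return List with `slope_pooled`, `slope_lmm` (fixed effect),
#'   `aic_pooled`, `bic_pooled`, `aic_lmm`, `bic_lmm`, `lmm_preferred`,
#'   `random_effects` (`"intercept+slope"` or `"intercept"`), `singular`.
#' @export
mixed_model_comparison <- function(records) {
  stopifnot(all(c("neuronal_shift_deg", "perceptual_shift_deg", "monkey_id")
                %in% names(records)))
  records <- records[is.finite(records$neuronal_shift_deg) &
                       is.finite(records$perceptual_shift_deg), ]
  counts <- table(records$monkey_id)
  if (length(counts) < 2 || any(counts < 3)) {
    stop("need >= 2 monkeys with >= 3 records each")
  }
  records$monkey_id <- factor(records$monkey_id)
  pooled <- stats::lm(neuronal_shift_deg ~ perceptual_shift_deg,
                      data = records)

  fit_lmm <- function(formula) {
    suppressWarnings(suppressMessages(
      lme4::lmer(formula, data = records, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                                               "ignore"))))
  }
  f_full <- neuronal_shift_deg ~ perceptual_shift_deg +
    (1 + perceptual_shift_deg | monkey_id)
  f_int <- neuronal_shift_deg ~ perceptual_shift_deg + (1 | monkey_id)
  lmm <- tryCatch(fit_lmm(f_full), error = function(e) NULL)
  singular <- is.null(lmm) || lme4::isSingular(lmm)
  re <- "intercept+slope"
  if (singular) {
    lmm2 <- tryCatch(fit_lmm(f_int), error = function(e) NULL)
    if (!is.null(lmm2)) {
      lmm <- lmm2
      re <- "intercept"
    }
  }
  if (is.null(lmm)) stop("mixed model could not be fitted")
  lmm_ml <- suppressWarnings(suppressMessages(
    stats::update(lmm, REML = FALSE)))
  list(slope_pooled = unname(stats::coef(pooled)[2]),
       slope_lmm = unname(lme4::fixef(lmm)[2]),
       aic_pooled = stats::AIC(pooled), bic_pooled = stats::BIC(pooled),
       aic_lmm = stats::AIC(lmm_ml), bic_lmm = stats::BIC(lmm_ml),
       lmm_preferred = stats::AIC(lmm_ml) < stats::AIC(pooled) &&
         stats::BIC(lmm_ml) < stats::BIC(pooled),
       random_effects = re, singular = singular)
}
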