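test_that("psychometric fit respects symmetry, translation and scale equivariance", {
  set.seed(20)
  h <- rep(standard_headings(), each = 20)
  # perfect left/right separation on a symmetric design -> PSE at 0
  ch <- ifelse(h > 0, "right", "left")
  f0 <- fit_psychometric(h, ch)
  expect_true(f0$converged)
  expect_equal(f0$pse_deg, 0, tolerance = 0.05)

  ch <- draw_choices(h, mu = 1, sigma = 5)
  f1 <- fit_psychometric(h, ch)
  f2 <- fit_psychometric(h + 3, ch)
  expect_equal(f2$pse_deg, f1$pse_deg + 3, tolerance = 1e-4)
  expect_equal(f2$threshold_deg, f1$threshold_deg, tolerance = 1e-4)
  f3 <- fit_psychometric(h * 2, ch)
  expect_equal(f3$pse_deg, f1$pse_deg * 2, tolerance = 1e-4)
  expect_equal(f3$threshold_deg, f1$threshold_deg * 2, tolerance = 1e-4)
  # trial order must not matter
  perm <- sample(length(h))
  f4 <- fit_psychometric(h[perm], ch[perm])
  expect_equal(coef(f4), coef(f1), tolerance = 1e-10)
})

test_that("choice encodings are interchangeable", {
  set.seed(21)
  h <- rep(standard_headings(), each = 5)
  ch <- draw_choices(h, 0, 4)
  f_chr <- fit_psychometric(h, ch)
  f_num <- fit_psychometric(h, ifelse(ch == "right", 1, -1))
  f_log <- fit_psychometric(h, ch == "right")
  expect_equal(coef(f_chr), coef(f_num))
  expect_equal(coef(f_chr), coef(f_log))
})

test_that("degenerate inputs are flagged instead of fitted", {
  f <- fit_psychometric(rep(1, 20), rep("right", 20))
  expect_false(f$converged)
  expect_true(is.na(f$pse_deg))
  # one-sided choices
  h <- rep(standard_headings(), each = 2)
  f2 <- fit_psychometric(h, rep("left", length(h)))
  expect_false(f2$converged)
})

test_that("free-lapse fits stay within the lapse bound and track the generative curve", {
  set.seed(22)
  h <- rep(standard_headings(), each = 60)
  ch <- draw_choices(h, mu = 1.5, sigma = 4, lapse = 0.04)
  f <- fit_psychometric(h, ch, lapse = "free")
  expect_true(f$converged)
  expect_gte(f$lapse, 0)
  expect_lte(f$lapse, 0.1)
  expect_equal(f$pse_deg, 1.5, tolerance = 0.8)
})

test_that("PSE shift is post minus pre, antisymmetric, and NA-propagating", {
  mkfit <- function(mu) structure(list(pse_deg = mu, converged = TRUE),
                                  class = "psychfit")
  expect_equal(pse_shift(mkfit(1), mkfit(4)), 3)
  expect_equal(pse_shift(mkfit(4), mkfit(1)), -pse_shift(mkfit(1), mkfit(4)))
  bad <- structure(list(pse_deg = NA_real_, converged = FALSE),
                   class = "psychfit")
  expect_true(is.na(pse_shift(bad, mkfit(1))))
})

test_that("a generative PSE step is recovered at session-scale trial counts", {
  set.seed(23)
  shifts <- replicate(40, {
    h <- rep(standard_headings(), each = 10)
    f_pre <- fit_psychometric(h, draw_choices(h, 0, 4))
    f_post <- fit_psychometric(h, draw_choices(h, 1.5, 4))
    pse_shift(f_pre, f_post)
  })
  expect_equal(mean(shifts), 1.5, tolerance = 0.3)
})

test_that("behavioral summary flags degenerate groups and enforces group sizes", {
  sh <- data.frame(session_id = rep(sprintf("s%d", 1:4), 2),
                   cue = rep(c("vestibular", "visual"), each = 4),
                   delta_sign = 1,
                   pse_pre_deg = 0, pse_post_deg = 0, shift_deg = 0)
  out <- behavioral_summary(sh)
  expect_true(all(out$groups$mean_shift_deg == 0))
  expect_true(all(out$groups$degenerate))
  expect_true(all(is.na(out$groups$p)))
  # a single session in a group is refused
  sh1 <- sh[c(1, 5), ]
  expect_error(behavioral_summary(sh1), ">= 2 sessions")
})

test_that("behavioral summary recovers the conflict-reducing sign pattern", {
  set.seed(24)
  n <- 30
  sh <- do.call(rbind, lapply(seq_len(n), function(i) {
    b <- sample_session_behavior(default_behavior())
    ts <- attr(b, "true_shift_deg")
    data.frame(session_id = sprintf("s%02d", i),
               cue = c("vestibular", "visual"), delta_sign = 1,
               pse_pre_deg = c(b$pse_deg$vestibular[["pre"]],
                               b$pse_deg$visual[["pre"]]),
               pse_post_deg = c(b$pse_deg$vestibular[["post"]],
                                b$pse_deg$visual[["post"]]),
               shift_deg = ts)
  }))
  out <- behavioral_summary(sh)
  vest <- out$groups[out$groups$cue == "vestibular", ]
  vis <- out$groups[out$groups$cue == "visual", ]
  expect_gt(vest$mean_shift_deg, 0)
  expect_lt(vis$mean_shift_deg, 0)
  # pooled magnitudes: vestibular larger, paired test defined
  expect_gt(out$pooled$mean_vest_deg, out$pooled$mean_vis_deg)
  expect_false(is.na(out$pooled$p))
})
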