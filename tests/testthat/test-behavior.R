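test_that("rightward-choice probability follows the cumulative-Gaussian observer", {
  beh <- behavior_profile(
    pse_deg = list(vestibular = c(pre = 2, post = 2),
                   visual = c(pre = 0, post = 0)),
    sigma_deg = list(vestibular = c(pre = 4, post = 4),
                     visual = c(pre = 3, post = 3)),
    lapse = 0)
  tr <- single_cue_table(2, 1)
  expect_equal(p_rightward(tr, beh), 0.5)        # heading at the PSE
  # degenerate sigma -> step function
  beh0 <- behavior_profile(sigma_deg = list(vestibular = c(pre = 0, post = 0),
                                            visual = c(pre = 3, post = 3)),
                           lapse = 0)
  expect_equal(p_rightward(single_cue_table(4, 1), beh0), 1)
  expect_equal(p_rightward(single_cue_table(-4, 1), beh0), 0)
})

test_that("empirical choice frequency matches the closed-form probability", {
  # P(right | h = 0, PSE = 1, sigma = 4) = pnorm(-0.25) = 0.4013
  set.seed(10)
  beh <- behavior_profile(
    pse_deg = list(vestibular = c(pre = 1, post = 1),
                   visual = c(pre = 0, post = 0)),
    sigma_deg = list(vestibular = c(pre = 4, post = 4),
                     visual = c(pre = 3, post = 3)),
    lapse = 0)
  tr <- single_cue_table(rep(1e-12, 1), 1)   # heading 0 is excluded by config,
  tr$heading_deg <- tr$vest_heading_deg <- 0 # but the observer accepts it
  tr <- tr[rep(1, 1e5), ]
  cfg <- paradigm_config()
  out <- simulate_choices(tr, cfg, beh)
  expect_equal(mean(out$choice == "right"), pnorm(-0.25), tolerance = 0.005 / 0.4)
})

test_that("combined-cue trials use the vestibular-weighted observer", {
  beh <- behavior_profile(
    pse_deg = list(vestibular = c(pre = 2, post = 2),
                   visual = c(pre = -1, post = -1)),
    sigma_deg = list(vestibular = c(pre = 4, post = 4),
                     visual = c(pre = 3, post = 3)),
    lapse = 0.02, w_vest = 0.6)
  tr <- data.frame(trial_id = 1, block = "post", modality = "combined",
                   heading_deg = 2, vest_heading_deg = 7, vis_heading_deg = -3,
                   delta_deg = 10, reward_rule = "deterministic",
                   choice = NA_character_, rewarded = NA)
  h_eff <- 0.6 * 7 + 0.4 * (-3)
  mu <- 0.6 * 2 + 0.4 * (-1)
  sg <- sqrt(0.36 * 16 + 0.16 * 9)
  expect_equal(p_rightward(tr, beh),
               0.01 + 0.98 * pnorm((h_eff - mu) / sg))
})

test_that("reward rules pay out at the configured rates", {
  set.seed(11)
  cfg <- paradigm_config()
  beh <- default_behavior()
  tr <- build_trial_schedule(cfg)
  tr <- do.call(rbind, replicate(30, tr, simplify = FALSE))
  out <- simulate_choices(tr, cfg, beh)
  sto <- out$reward_rule == "stochastic"
  expect_equal(mean(out$rewarded[sto]), 0.70, tolerance = 0.02)
  det <- out$reward_rule == "deterministic"
  correct <- sign(out$heading_deg) == ifelse(out$choice == "right", 1, -1)
  expect_equal(mean(out$rewarded[det & correct]), 0.95, tolerance = 0.01)
  expect_true(all(!out$rewarded[det & !correct]))
})

test_that("session-level behavior sampling keeps cue shifts anti-correlated", {
  set.seed(12)
  base <- default_behavior()
  shifts <- t(replicate(300, attr(sample_session_behavior(base), "true_shift_deg")))
  expect_equal(mean(shifts[, "vestibular"]), 1.5, tolerance = 0.2)
  expect_equal(mean(shifts[, "visual"]), -0.9, tolerance = 0.25)
  expect_lt(cor(shifts[, "vestibular"], shifts[, "visual"]), -0.5)
})
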