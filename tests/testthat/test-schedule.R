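test_that("block composition matches the configuration arithmetic", {
  set.seed(1)
  cfg <- paradigm_config(reps_pre = 10)
  tr <- build_trial_schedule(cfg)
  expect_equal(sum(tr$block == "pre"), 10 * 2 * 10)
  # per-condition repetition counts are exact
  pre <- tr[tr$block == "pre", ]
  expect_true(all(table(pre$modality, pre$heading_deg) == 10))
  post <- tr[tr$block == "post", ]
  expect_true(all(table(post$modality, post$heading_deg)[c("vestibular", "visual"), ] ==
                    cfg$reps_post_single))
  expect_true(all(table(post$modality, post$heading_deg)["combined", ] ==
                    cfg$reps_post_combined))
})

test_that("discrepancy ramp rises by one step and holds at the maximum", {
  set.seed(2)
  cfg <- paradigm_config(delta_max_deg = 10, delta_ramp_step_deg = 2,
                         reps_per_ramp_increment = 8, reps_max_delta = 12)
  tr <- build_trial_schedule(cfg)
  recal <- tr[tr$block == "recal", ]
  expect_true(all(recal$modality == "combined"))
  counts <- table(abs(recal$delta_deg))
  expect_equal(as.integer(counts[c("2", "4", "6", "8")]), rep(8L, 4))
  expect_equal(as.integer(counts["10"]), 8L + 12L)
  # |delta| is nondecreasing across the block
  expect_true(all(diff(abs(recal$delta_deg)) >= 0))
  expect_error(paradigm_config(delta_max_deg = 10, delta_ramp_step_deg = 3),
               "divide")
})

test_that("combined-cue trials offset each cue by half the discrepancy", {
  set.seed(3)
  for (d in c(10, -10)) {
    tr <- build_trial_schedule(paradigm_config(delta_max_deg = d))
    comb <- tr[tr$modality == "combined", ]
    expect_equal(comb$vest_heading_deg - comb$vis_heading_deg, comb$delta_deg)
    expect_equal((comb$vest_heading_deg + comb$vis_heading_deg) / 2,
                 comb$heading_deg)
  }
  # heading 0 with delta +10 puts the cues at +5 / -5
  comb <- data.frame(block = "x", modality = "combined", heading_deg = 0,
                     vest_heading_deg = 0 + 10 / 2, vis_heading_deg = 0 - 10 / 2,
                     delta_deg = 10)
  expect_equal(comb$vest_heading_deg, 5)
  expect_equal(comb$vis_heading_deg, -5)
})

test_that("post-block reward rule is stochastic exactly when the implied other cue flips side", {
  set.seed(4)
  tr <- build_trial_schedule(paradigm_config(delta_max_deg = 10))
  post <- tr[tr$block == "post" & tr$modality != "combined", ]
  vest <- post[post$modality == "vestibular", ]
  expect_true(all(vest$reward_rule[vest$heading_deg > 0 &
                                     vest$heading_deg <= 10] == "stochastic"))
  expect_true(all(vest$reward_rule[vest$heading_deg < 0 |
                                     vest$heading_deg > 10] == "deterministic"))
  vis <- post[post$modality == "visual", ]
  expect_true(all(vis$reward_rule[vis$heading_deg < 0 &
                                    vis$heading_deg >= -10] == "stochastic"))
  # mirrored under a negative discrepancy
  tr2 <- build_trial_schedule(paradigm_config(delta_max_deg = -10))
  post2 <- tr2[tr2$block == "post" & tr2$modality == "vestibular", ]
  expect_true(all(post2$reward_rule[post2$heading_deg < 0 &
                                      post2$heading_deg >= -10] == "stochastic"))
})

test_that("recalibration block requires no choices; schedules are seed-reproducible", {
  set.seed(5)
  a <- build_trial_schedule(paradigm_config())
  expect_true(all(a$choice[a$block == "recal"] == "none"))
  expect_true(all(a$rewarded[a$block == "recal"]))
  set.seed(5)
  b <- build_trial_schedule(paradigm_config())
  expect_identical(a, b)
})

test_that("composition invariants hold over random configurations", {
  set.seed(6)
  for (i in 1:5) {
    cfg <- paradigm_config(
      reps_pre = sample(3:12, 1),
      delta_max_deg = sample(c(-1, 1), 1) * sample(c(6, 8, 10), 1),
      delta_ramp_step_deg = 2,
      reps_per_ramp_increment = sample(5:10, 1),
      reps_max_delta = sample(8:16, 1),
      reps_post_single = sample(3:12, 1),
      reps_post_combined = sample(0:5, 1))
    tr <- build_trial_schedule(cfg)
    expect_equal(sum(tr$block == "pre"), cfg$reps_pre * 20)
    n_steps <- abs(cfg$delta_max_deg) / cfg$delta_ramp_step_deg
    expect_equal(sum(tr$block == "recal"),
                 n_steps * cfg$reps_per_ramp_increment + cfg$reps_max_delta)
    expect_equal(sum(tr$block == "post"),
                 cfg$reps_post_single * 20 + cfg$reps_post_combined * 10)
    expect_equal(tr$trial_id, seq_len(nrow(tr)))
    # single-cue trials have zero delta and exactly one cue heading
    single <- tr$modality != "combined"
    expect_true(all(tr$delta_deg[single] == 0))
    expect_true(all(xor(is.na(tr$vest_heading_deg[single]),
                        is.na(tr$vis_heading_deg[single]))))
  }
})
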