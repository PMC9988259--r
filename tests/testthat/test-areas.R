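test_that("area profiles encode the intended tuning-shift targets", {
  set.seed(70)
  beh <- default_behavior()    # vestibular +1.5, visual -0.9
  shifts_of <- function(pop, cue) {
    vapply(pop, function(np) np$tuning_shift_deg[[cue]][["post"]], numeric(1))
  }
  vip <- make_area_population("VIP-like", 200, beh, shift_gain = 1)
  expect_equal(mean(shifts_of(vip, "vestibular")), 1.5, tolerance = 0.15)
  # VIP visual tuning follows the vestibular perceptual shift
  expect_equal(mean(shifts_of(vip, "visual")), 1.5, tolerance = 0.15)

  mstd <- make_area_population("MSTd-like", 200, beh, shift_gain = 1)
  expect_equal(mean(shifts_of(mstd, "vestibular")), 1.5, tolerance = 0.15)
  expect_equal(mean(shifts_of(mstd, "visual")), -0.9, tolerance = 0.15)

  # the default shift gain amplifies tuning shifts but preserves signs
  mstd_g <- make_area_population("MSTd-like", 200, beh)
  expect_equal(mean(shifts_of(mstd_g, "vestibular")), 2.5 * 1.5,
               tolerance = 0.15)
  expect_equal(mean(shifts_of(mstd_g, "visual")), 2.5 * -0.9,
               tolerance = 0.15)

  # zero perceptual shift centers all MSTd-like tuning shifts at zero
  null_beh <- default_behavior(shift_vest_deg = 0, shift_vis_deg = 0)
  mstd0 <- make_area_population("MSTd-like", 200, null_beh)
  expect_equal(mean(shifts_of(mstd0, "vestibular")), 0, tolerance = 0.15)
  expect_equal(mean(shifts_of(mstd0, "visual")), 0, tolerance = 0.15)
})

test_that("PIVC-like visual drive is negligible and VIP-like choice gains halve", {
  set.seed(71)
  beh <- default_behavior()
  pivc <- make_area_population("PIVC-like", 100, beh)
  vis_slopes <- vapply(pivc, function(np) np$slope_hz_per_deg[["visual"]],
                       numeric(1))
  vest_slopes <- vapply(pivc, function(np) np$slope_hz_per_deg[["vestibular"]],
                        numeric(1))
  expect_lt(max(abs(vis_slopes)), 0.1)
  expect_gt(min(abs(vest_slopes)), 0.3)

  vip <- make_area_population("VIP-like", 50, beh)
  for (np in vip) {
    expect_equal(np$temporal_mode, "sustained")
    for (cue in c("vestibular", "visual")) {
      g <- np$choice_gain_hz[[cue]]
      expect_equal(abs(g[["post"]]), abs(g[["pre"]]) / 2)
      expect_lt(abs(g[["post"]]), abs(g[["pre"]]))
    }
  }
  expect_error(make_area_population("V1-like", 5, beh))
})

test_that("spike generation reproduces the analytic stimulus-window mean", {
  set.seed(72)
  grid <- time_grid()
  sp <- stimulus_profile()
  tr <- single_cue_table(8, 5000)
  tr$choice <- "right"
  np <- neuron_profile(baseline_hz = 10,
                       slope_hz_per_deg = c(vestibular = 1, visual = 1))
  counts <- simulate_spike_counts(tr, np, sp, grid)
  fr <- recalibr:::window_rates(counts, grid, c(0, 1))
  expected <- 10 + 1 * 8 * stim_window_gain()
  expect_equal(mean(fr), expected, tolerance = 3 * sqrt(expected / 5000) / expected)
  # pre-stimulus bins carry only baseline
  base <- recalibr:::window_rates(counts, grid, c(-1, 0))
  expect_equal(mean(base), 10, tolerance = 0.2)
})

test_that("untuned, choice-free neurons fire at baseline for every heading", {
  set.seed(73)
  tr <- single_cue_table(rep(standard_headings(), 50), 1)
  tr$choice <- sample(c("left", "right"), nrow(tr), replace = TRUE)
  np <- neuron_profile(baseline_hz = 22,
                       slope_hz_per_deg = c(vestibular = 0, visual = 0))
  counts <- simulate_spike_counts(tr, np, stimulus_profile(), time_grid())
  fr <- recalibr:::window_rates(counts, time_grid(), c(0, 1))
  by_h <- tapply(fr, tr$heading_deg, mean)
  expect_true(all(abs(by_h - 22) < 1.5))
})

test_that("rates are truncated at zero before drawing counts", {
  set.seed(74)
  tr <- single_cue_table(-16, 200)
  tr$choice <- "left"
  np <- neuron_profile(baseline_hz = 1,
                       slope_hz_per_deg = c(vestibular = 5, visual = 0))
  counts <- simulate_spike_counts(tr, np, stimulus_profile(), time_grid())
  expect_true(all(counts >= 0))
})

test_that("sustained-mode firing persists after stimulus offset", {
  set.seed(75)
  tr <- single_cue_table(16, 800)
  tr$choice <- "right"
  mk <- function(mode) neuron_profile(baseline_hz = 10,
                                      slope_hz_per_deg = c(vestibular = 2, visual = 0),
                                      temporal_mode = mode)
  g <- time_grid()
  late <- function(np) {
    counts <- simulate_spike_counts(tr, np, stimulus_profile(), g)
    mean(recalibr:::window_rates(counts, g, c(1.1, 1.3))) - 10
  }
  expect_gt(late(mk("sustained")), 5)
  expect_lt(abs(late(mk("velocity"))), 1)
})

test_that("identical seeds reproduce identical sessions bit for bit", {
  cfg <- tiny_config()
  mk <- function() {
    set.seed(99)
    simulate_session(cfg, neurons = make_area_population("VIP-like", 2,
                                                         default_behavior()))
  }
  a <- mk(); b <- mk()
  expect_identical(a$trials, b$trials)
  expect_identical(a$spikes, b$spikes)
})
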