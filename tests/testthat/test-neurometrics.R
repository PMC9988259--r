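test_that("window rates convert counts to spikes/s and validate alignment", {
  g <- time_grid()
  counts <- matrix(0, nrow = 2, ncol = 23)
  counts[1, 11:20] <- 2   # 20 spikes across the stimulus second
  expect_equal(recalibr:::window_rates(counts, g, c(0, 1)), c(20, 0))
  expect_error(recalibr:::window_rates(counts, g, c(0.05, 1)), "bin edge")
  expect_error(recalibr:::window_rates(counts, g, c(0, 1.5)), "outside")
})

test_that("baseline subtraction centers a homogeneous Poisson neuron at zero", {
  set.seed(30)
  g <- time_grid()
  counts <- matrix(rpois(400 * 23, 2), nrow = 400)
  block <- rep(c("pre", "post"), each = 200)
  fr <- trial_firing_rates(counts, g, block)
  expect_equal(mean(fr$fr_bsub_hz), 0, tolerance = 0.5)
  expect_equal(unname(fr$baseline_hz["pre"]), 20, tolerance = 1)
})

test_that("tuning regression recovers exact slopes and calibrates its p-value", {
  h <- rep(standard_headings(), each = 5)
  fit <- tuning_regression(2 * h, h)
  expect_equal(fit$slope_hz_per_deg, 2, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-10)
  expect_equal(fit$preferred_side, "right")
  expect_equal(tuning_regression(-0.5 * h + rnorm(length(h), 0, 1e-6), h)$preferred_side,
               "left")
  expect_error(tuning_regression(rnorm(10), rep(c(1, 2), 5)), "3 distinct")
  # type-I calibration on untuned responses
  set.seed(31)
  p <- replicate(400, tuning_regression(rnorm(length(h), 10, 3), h)$p_value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
})

test_that("criterion-sweep AUC matches hand-counted cases", {
  expect_equal(auc_vs_reference(c(1, 2, 3)), 1)
  expect_equal(auc_vs_reference(c(-1, -2)), 0)
  expect_equal(auc_vs_reference(c(-1, 1)), 0.5)
  expect_equal(auc_vs_reference(c(-1, 0.5, 2)), 2 / 3)
  expect_equal(auc_vs_reference(c(-1, 0, 1)), 0.5)  # tie at the reference
  expect_equal(auc_vs_reference(rep(0, 5)), 0.5)
  expect_error(auc_vs_reference(numeric(0)), "empty")
})

test_that("sweep AUC tracks the closed-form oracle on random instances", {
  set.seed(32)
  for (i in 1:400) {
    n <- sample(5:200, 1)
    z <- switch(sample(3, 1),
                rnorm(n, runif(1, -2, 2)),
                round(rnorm(n, runif(1, -2, 2)), sample(0:1, 1)),
                (rpois(n, 20) - runif(1, 15, 25)) / 4.5)
    expect_lt(abs(auc_vs_reference(z) - auc_reference_exact(z)), 0.02)
  }
})

test_that("neurometric PSE is anchored to the pre-recalibration reference", {
  set.seed(33)
  h <- rep(standard_headings(), each = 12)
  slope_fr <- 1.2
  ref_fr <- 40 + slope_fr * h + rnorm(length(h), 0, 2)
  ref <- reference_stats(ref_fr)
  f_pre <- fit_neurometric(ref_fr, h, ref, "right")
  expect_true(f_pre$converged)
  expect_equal(f_pre$pse_deg, 0, tolerance = 1)
  # adding k Hz to all post rates moves the PSE against the preferred side
  # by about k / slope
  k <- 3
  f_post <- fit_neurometric(ref_fr + k, h, ref, "right")
  expect_equal(f_post$pse_deg - f_pre$pse_deg, -k / slope_fr,
               tolerance = 0.35 * k / slope_fr)
})

test_that("negating headings and preferred side mirrors the neurometric PSE", {
  set.seed(34)
  h <- rep(standard_headings(), each = 10)
  fr <- rpois(length(h), 40 + 1.5 * (h - 2))
  ref <- reference_stats(fr)
  f <- fit_neurometric(fr, h, ref, "right")
  f_neg <- fit_neurometric(fr, -h, ref, "left")
  expect_equal(f_neg$pse_deg, -f$pse_deg, tolerance = 0.05)
})

test_that("P(rightward) is monotone in heading for a noiseless tuned neuron", {
  h <- rep(standard_headings(), each = 4)
  fr <- 30 + 2 * h
  ref <- reference_stats(fr)
  f <- fit_neurometric(fr, h, ref, "right")
  expect_true(all(diff(f$curve$p_right) >= 0))
})

test_that("degenerate reference SD flags the fit instead of z-scoring by zero", {
  f <- fit_neurometric(rep(10, 40), rep(standard_headings(), each = 4),
                       list(mean_hz = 10, sd_hz = 0), "right")
  expect_false(f$converged)
  expect_true(is.na(f$pse_deg))
})

test_that("bootstrap PSE reliability separates steep from untuned neurons", {
  set.seed(35)
  h <- rep(standard_headings(), each = 10)
  fr <- 40 + 3 * h + rnorm(length(h), 0, 0.5)   # near-noiseless steep tuning
  sd_steep <- bootstrap_pse_sd(fr, h, reference_stats(fr), "right", B = 100)
  expect_lt(sd_steep, 1)
  fr_flat <- rpois(length(h), 20)
  sd_flat <- bootstrap_pse_sd(fr_flat, h, reference_stats(fr_flat), "right",
                              B = 100)
  expect_false(sd_flat < 10)
  expect_error(bootstrap_pse_sd(fr, h, reference_stats(fr), "right", B = 20),
               ">= 50")
})

test_that("doubling trials per heading improves bootstrap reliability", {
  set.seed(36)
  med_sd <- vapply(c(5, 10), function(reps) {
    sds <- replicate(12, {
      h <- rep(standard_headings(), each = reps)
      fr <- rpois(length(h), 40 + 0.8 * 0.5 * h)
      bootstrap_pse_sd(fr, h, reference_stats(fr), "right", B = 100)
    })
    median(sds)
  }, numeric(1))
  expect_lt(med_sd[2], med_sd[1])
})

test_that("inclusion screen applies the tuning and reliability rules", {
  tf <- function(p) list(p_value = p)
  expect_true(screen_neuron(tf(0.04), tf(0.3), 3, 5)$passed)
  expect_false(screen_neuron(tf(0.04), tf(0.3), 3, 12)$passed)
  expect_false(screen_neuron(tf(0.2), tf(0.2), 1, 1)$passed)
  expect_true(screen_neuron(tf(0.2), tf(0.01), 9.9, 9.9)$passed)
  expect_false(screen_neuron(tf(0.01), tf(0.01), Inf, 1)$passed)
})

test_that("neuronal shift matches the perceptual sign convention and refuses unscreened neurons", {
  mk <- function(mu) structure(list(pse_deg = mu, converged = TRUE),
                               class = "neurofit")
  expect_equal(neuronal_shift(mk(0.5), mk(5.23)), 4.73)
  expect_equal(neuronal_shift(mk(2), mk(2)), 0)
  scr <- screen_neuron(list(p_value = 0.5), list(p_value = 0.5), 20, 20)
  expect_error(neuronal_shift(mk(0), mk(1), scr), "screen")
})

test_that("sliding windows cover 0.1-1.2 s and recover a shift where the stimulus drives spiking", {
  set.seed(37)
  cfg <- paradigm_config()
  tr <- simulate_choices(build_trial_schedule(cfg), cfg, default_behavior())
  np <- neuron_profile(baseline_hz = 60,
                       slope_hz_per_deg = c(vestibular = 3, visual = 3),
                       tuning_shift_deg = list(vestibular = c(pre = 0, post = 3),
                                               visual = c(pre = 0, post = 3)))
  counts <- simulate_spike_counts(tr, np, stimulus_profile(), time_grid())
  h <- ifelse(tr$modality == "vestibular", tr$vest_heading_deg, NA)
  out <- sliding_window_shifts(counts, time_grid(), h, tr$block, "right")
  expect_equal(nrow(out), 12)
  expect_equal(out$center_s, seq(0.1, 1.2, by = 0.1))
  mid <- out$shift_deg[out$center_s == 0.5]
  expect_equal(mid, 3, tolerance = 2.5)
})
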