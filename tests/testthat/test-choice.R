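test_that("partial correlations match the residual-correlation oracle", {
  set.seed(40)
  for (i in 1:30) {
    n <- sample(10:30, 1)
    h <- sample(standard_headings(), n, replace = TRUE)
    C <- sign(h + rnorm(n, 0, 6)); C[C == 0] <- 1
    fr <- 20 + 0.4 * h + 2 * C + rnorm(n, 0, 3)
    if (length(unique(C)) < 2) next
    pc <- partial_correlations(fr, h, C)
    expect_equal(pc$r_h, partial_cor_oracle(fr, h, C), tolerance = 1e-10)
    expect_equal(pc$r_c, partial_cor_oracle(fr, C, h), tolerance = 1e-10)
    expect_equal(pc$r_h2, pc$r_h^2)
  }
})

test_that("partial correlations separate heading-driven from choice-driven rates", {
  set.seed(41)
  n <- 4000
  h <- sample(standard_headings(), n, replace = TRUE)
  coin <- sample(c(-1, 1), n, replace = TRUE)
  fr_h <- 20 + 0.8 * h + rnorm(n, 0, 4)
  pc_h <- partial_correlations(fr_h, h, coin)
  expect_gt(pc_h$r_h, 0.5)
  expect_lt(abs(pc_h$r_c), 0.05)
  fr_c <- 20 + 3 * coin + rnorm(n, 0, 4)
  pc_c <- partial_correlations(fr_c, h, coin)
  expect_gt(pc_c$r_c, 0.3)
  expect_lt(abs(pc_c$r_h), 0.05)
  expect_lt(pc_c$p_c, 1e-6)
})

test_that("choice relabeling does not change the partial correlations", {
  set.seed(42)
  n <- 60
  h <- sample(standard_headings(), n, replace = TRUE)
  ch <- ifelse(sign(h + rnorm(n, 0, 8)) > 0, "right", "left")
  fr <- rpois(n, 20 + 0.5 * h)
  a <- partial_correlations(fr, h, ch)
  b <- partial_correlations(fr, h, ifelse(ch == "right", 1, -1))
  d <- partial_correlations(fr, h, ifelse(ch == "right", 1, 0))
  expect_equal(a$r_c, b$r_c)
  expect_equal(a$r_c, d$r_c)
  expect_equal(a$r_h, d$r_h)
})

test_that("degenerate choice inputs are flagged or refused", {
  h <- rep(standard_headings(), 2)
  fr <- rnorm(20, 20)
  pc <- partial_correlations(fr, h, rep("right", 20))
  expect_equal(pc$flag, "single_choice_class")
  expect_true(is.na(pc$r_c))
  expect_false(is.na(pc$r_h))
  expect_error(partial_correlations(fr[1:5], h[1:5], rep(c("left", "right"), 3)[1:5]),
               ">= 10")
})

test_that("choice-conditioned curves obey the count-weighted mean identity", {
  set.seed(43)
  n <- 200
  h <- sample(standard_headings(), n, replace = TRUE)
  ch <- ifelse(runif(n) < 0.5, "right", "left")
  fr <- rnorm(n, 20 + 0.5 * h, 3)
  cc <- choice_conditioned_tuning(fr, h, ch, min_count = 1)
  recon <- (cc$n_left * cc$fr_left_raw_hz + cc$n_right * cc$fr_right_raw_hz) /
    (cc$n_left + cc$n_right)
  expect_equal(recon, cc$fr_all_hz, tolerance = 1e-12)
})

test_that("a positive choice gain lifts the rightward-choice curve", {
  set.seed(44)
  n <- 3000
  h <- sample(standard_headings(), n, replace = TRUE)
  C <- sign(h + rnorm(n, 0, 8)); C[C == 0] <- 1
  fr <- rpois(n, 25 + 0.5 * h + 4 * C)
  cc <- choice_conditioned_tuning(fr, h, ifelse(C > 0, "right", "left"))
  ok <- !is.na(cc$fr_left_hz) & !is.na(cc$fr_right_hz)
  expect_true(all(cc$fr_right_hz[ok] > cc$fr_left_hz[ok]))
  # sparse cells are masked but counted
  cc2 <- choice_conditioned_tuning(fr[1:20], h[1:20],
                                   ifelse(C[1:20] > 0, "right", "left"),
                                   min_count = 10)
  expect_true(any(is.na(cc2$fr_left_hz) | is.na(cc2$fr_right_hz)))
  expect_true(all(cc2$n_left + cc2$n_right >= 0))
})

test_that("pre/post partial-correlation comparison handles identity and refuses tiny samples", {
  d <- data.frame(neuron_id = rep(sprintf("n%d", 1:6), 2),
                  cue = "vestibular",
                  block = rep(c("pre", "post"), each = 6),
                  r_h = rep(runif(6, 0.2, 0.6), 2),
                  r_c = rep(runif(6, 0.1, 0.5), 2))
  out <- compare_pre_post_partials(d)
  expect_true(all(out$mean_diff == 0))
  expect_true(all(is.na(out$t)))
  expect_error(compare_pre_post_partials(d[c(1, 7), ]), ">= 2")
})

test_that("baseline comparison detects injected shifts and calibrates under the null", {
  set.seed(45)
  pre <- rnorm(50, 20, 1)
  out0 <- baseline_fr_comparison(pre, pre)
  expect_equal(out0$mean_diff_hz, 0)
  out2 <- baseline_fr_comparison(pre, pre + rnorm(50, 2, 1))
  expect_lt(out2$p, 0.05)
  expect_equal(out2$mean_diff_hz, 2, tolerance = 0.6)
  # null calibration
  pvals <- replicate(300, baseline_fr_comparison(rnorm(20, 20), rnorm(20, 20))$p)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
  expect_error(baseline_fr_comparison(1, 2), ">= 2")
})
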