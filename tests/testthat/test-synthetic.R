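test_that("donor table reproduces the printed cohort descriptives", {
  h <- hand_donors()
  expect_equal(nrow(h), 5)
  expect_equal(describe_values(h$age)$mean, 42.6)
  expect_equal(round(describe_values(h$age, "population")$sd, 2), 5.54)
  expect_equal(round(mean(h$bmi), 2), 27.98)
  expect_equal(range(h$age), c(34, 50))
})

test_that("reference targets table is complete and starts at zero", {
  tg <- reference_moment_targets()
  expect_equal(nrow(tg), 2 * 3 * 6)
  expect_true(all(tg$mean[tg$step == 0] == 0))
  expect_true(all(tg$sd[tg$step == 0] == 0))
  expect_equal(tg$mean[tg$test == 1 & tg$digit == 2],
               c(0, 0.25, 0.49, 1.39, 4.09, 8.57))
})

test_that("templates reject non-monotone or non-zero-start profiles", {
  expect_error(trajectory_template(1, c(0.1, 1, 2, 3, 4, 5),
                                   peak_moment_target = 5), "start at 0")
  expect_error(trajectory_template(1, c(0, 2, 1, 3, 4, 5),
                                   peak_moment_target = 5), "nondecreasing")
})

test_that("zero-noise trajectories equal the template profile and are seeded", {
  tpl <- trajectory_template(1, c(0, 1, 2, 4, 6, 9), peak_moment_target = 9)
  tr <- make_trajectory(tpl, hand_effect = 1, seed = 7)
  expect_equal(tr$amplitude[1], 0)
  expect_true(all(diff(tr$amplitude) >= -1e-12))
  expect_equal(tr$amplitude[seq(1, 51, by = 10)], c(0, 1, 2, 4, 6, 9))
  # determinism with noise
  tpl$noise_sd <- 1
  a <- make_trajectory(tpl, 1, seed = 42)
  b <- make_trajectory(tpl, 1, seed = 42)
  expect_identical(a, b)
  c <- make_trajectory(tpl, 1, seed = 43)
  expect_false(identical(a$amplitude, c$amplitude))
})

test_that("calibration round-trips every reference target within 2 percent", {
  fit <- unit_fit_coarse()
  tg <- reference_moment_targets()
  for (test in 1:2) for (d in 2:4) {
    tab <- tg[tg$test == test & tg$digit == d, ]
    tpl <- calibrate_template(tab$mean, unit_moment = fit$unit_moment,
                              test = test, steps = tab$step)
    tr <- make_trajectory(tpl, hand_effect = 1, seed = 1)
    curve <- normalize_travel(tr$travel, tr$amplitude * fit$unit_moment, test = test)
    got <- resample_moments(curve, tab$step)
    nz <- tab$mean > 0
    expect_lt(max(abs(got[nz] - tab$mean[nz]) / tab$mean[nz]), 0.02)
  }
})

test_that("calibrated fingertip-to-palm curves are convex increasing", {
  fit <- unit_fit_coarse()
  tg <- reference_moment_targets()
  tab <- tg[tg$test == 1 & tg$digit == 2, ]
  tpl <- calibrate_template(tab$mean, unit_moment = fit$unit_moment)
  tr <- make_trajectory(tpl, 1, seed = 1)
  m <- resample_moments(normalize_travel(tr$travel, tr$amplitude * fit$unit_moment))
  expect_true(all(diff(m) > 0))
  # the printed reference curve is convex up to rounding of its first steps
  expect_true(all(diff(diff(m)) >= -0.02 * max(m)))
  expect_gt(m[6] - m[5], m[2] - m[1])
})

test_that("zero target yields a zero-displacement template, unreachable targets fail", {
  tpl <- calibrate_template(rep(0, 6), unit_moment = 1)
  expect_true(all(tpl$shape == 0))
  expect_error(calibrate_template(c(0, 1, 2, 3, 4, 5), unit_moment = 0),
               "unreachable")
  expect_error(calibrate_template(c(0.5, 1, 2, 3, 4, 5), unit_moment = 1),
               "start at 0")
})

test_that("cohort generation honours design counts and exclusions", {
  fit <- unit_fit_coarse()
  tpl <- default_templates(fit$unit_moment)
  co <- generate_cohort(default_cohort_design(), tpl, seed = 3)
  tr <- co$trials
  # per test: 5 hands x 3 digits x 5 trials minus Hand 2 digit 4
  expect_equal(nrow(tr), 2 * (5 * 3 * 5 - 5))
  expect_false(any(tr$hand == "Hand 2" & tr$digit == 4))
  ret <- tr[tr$retained & tr$test == 1, ]
  expect_equal(as.vector(table(ret$digit)), c(15, 15, 12))
  # no exclusions: 15 per digit
  d2 <- cohort_design(exclusions = data.frame(hand = character(), digit = integer()))
  co2 <- generate_cohort(d2, tpl, seed = 3)
  ret2 <- co2$trials[co2$trials$retained & co2$trials$test == 1, ]
  expect_equal(as.vector(table(ret2$digit)), c(15, 15, 15))
  # empty design
  d0 <- cohort_design(hands = hand_donors()[0, ],
                      exclusions = data.frame(hand = character(), digit = integer()))
  co0 <- generate_cohort(d0, tpl, seed = 3)
  expect_equal(nrow(co0$trials), 0)
  expect_equal(nrow(co0$samples), 0)
})

test_that("seeded cohort generation is reproducible bit for bit", {
  fit <- unit_fit_coarse()
  tpl <- default_templates(fit$unit_moment)
  a <- generate_cohort(default_cohort_design(), tpl, seed = 11)
  b <- generate_cohort(default_cohort_design(), tpl, seed = 11)
  expect_identical(a, b)
})

test_that("zero-noise cohorts are identical across hands and trials", {
  fit <- unit_fit_coarse()
  tg <- reference_moment_targets()
  tpl <- list()
  for (test in 1:2) for (d in 2:4) {
    tab <- tg[tg$test == test & tg$digit == d, ]
    tpl[[sprintf("test%d_digit%d", test, d)]] <-
      calibrate_template(tab$mean, unit_moment = fit$unit_moment, test = test,
                         noise_sd = 0, specimen_effect_sd = 0)
  }
  co <- generate_cohort(default_cohort_design(), tpl, seed = 5)
  sm <- co$samples[co$samples$trial %in% 3:5, ]
  sp <- split(sm$amplitude, list(sm$test, sm$digit))
  for (g in sp) {
    m <- matrix(g, nrow = 51)
    expect_lt(max(apply(m, 1, function(x) diff(range(x)))), 1e-12)
  }
})

test_that("cohort CSV export writes one row per sample", {
  fit <- unit_fit_coarse()
  tpl <- default_templates(fit$unit_moment)
  co <- generate_cohort(cohort_design(hands = hand_donors()[1:2, ],
                                      exclusions = data.frame(hand = character(),
                                                              digit = integer())),
                        tpl, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(co$samples))
  expect_true(all(c("hand", "digit", "test", "trial", "travel", "s", "amplitude")
                  %in% names(back)))
  unlink(f)
})
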