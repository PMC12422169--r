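# heteroscedastic three-group dataset (n = 15/15/12) with frozen
# Games-Howell / Welch reference values computed with pingouin 0.6.1
gh_ref_values <- c(
  9.0054, 8.5589, 7.5381, 8.8171, 7.9484, 9.3719, 8.0705, 9.9037, 8.4662,
  8.4922, 8.2323, 8.9846, 7.8746, 6.6796, 9.3783,
  3.19, 5.537, 4.7588, 4.238, 7.0205, 6.1818, 4.2237, 4.9091, 6.186, 3.8712,
  6.3697, 5.0157, 5.3959, 3.989, 5.0421,
  5.085, 4.7339, 5.5467, 4.2315, 4.2871, 4.9569, 5.0787, 5.9441, 5.3233,
  4.9917, 5.444, 4.9595)
gh_ref_groups <- rep(c("g2", "g3", "g4"), c(15, 15, 12))

test_that("descriptives support both SD conventions", {
  ages <- c(41, 41, 50, 47, 34)
  expect_equal(describe_values(ages)$mean, 42.6)
  expect_equal(round(describe_values(ages, "population")$sd, 2), 5.54)
  expect_equal(describe_values(ages, "population")$sd,
               describe_values(ages)$sd * sqrt(4 / 5))
  one <- describe_values(5)
  expect_true(one$degenerate)
  expect_equal(one$sd, 0)
  expect_false(describe_values(5, "population")$degenerate)
  expect_error(describe_values(numeric(0)), "empty")
  # relation holds for arbitrary inputs
  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(sample(2:30, 1))
    expect_equal(describe_values(x, "population")$sd,
                 describe_values(x)$sd * sqrt((length(x) - 1) / length(x)))
  }
})

test_that("weighted pooled mean matches hand arithmetic", {
  expect_equal(round(weighted_group_mean(c(8.57, 4.71, 4.88), c(15, 15, 12)), 2),
               6.14)
  expect_equal(weighted_group_mean(c(2, 4), c(3, 3)), 3)
  expect_equal(weighted_group_mean(5.5, 7), 5.5)
  expect_error(weighted_group_mean(c(1, 2), 3), "mismatch")
})

test_that("paired t follows the formula and handles degenerate input", {
  # d = (1,2,3,4): t = 2.5 / (1.29099/2) = 3.873, df 3, p ~ 0.0305
  a <- c(2, 4, 6, 8); b <- c(1, 2, 3, 4)
  rep1 <- paired_t(a, b)
  expect_equal(round(rep1$statistic, 3), 3.873)
  expect_equal(rep1$df, 3)
  expect_equal(round(rep1$p, 4), 0.0305)
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # missing pairs dropped
  rep2 <- paired_t(c(a, NA), c(b, 1))
  expect_equal(rep2$n, 4)
  # oracle equivalence against the base implementation
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12, 0.3)
    mine <- paired_t(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(round(mine$statistic, 3), round(unname(ref$statistic), 3))
    expect_equal(round(mine$p, 3), round(ref$p.value, 3))
  }
})

test_that("Shapiro-Wilk wrapper enforces its domain and detects skew", {
  expect_error(shapiro_normality(c(1, 2)), "3 <= n")
  expect_error(shapiro_normality(rep(1, 10)), "zero variance")
  set.seed(3)
  rej_norm <- mean(replicate(200, shapiro_normality(rnorm(50))$p < 0.05))
  rej_exp <- mean(replicate(200, shapiro_normality(rexp(50))$p < 0.05))
  expect_lt(rej_norm, 0.12)
  expect_gt(rej_exp, 0.5)
})

test_that("Levene test matches the independent reference implementation", {
  set.seed(4)
  for (i in 1:20) {
    v <- c(rnorm(15, 0, 1), rnorm(15, 0, 2), rnorm(12, 0, 0.5))
    g <- gh_ref_groups
    mine <- levene_test(v, g, center = "mean")
    ref <- car::leveneTest(v, factor(g), center = mean)
    expect_equal(round(mine$statistic, 3), round(ref$`F value`[1], 3))
    expect_equal(round(mine$p, 3), round(ref$`Pr(>F)`[1], 3))
    mine_m <- levene_test(v, g, center = "median")
    ref_m <- car::leveneTest(v, factor(g), center = median)
    expect_equal(round(mine_m$p, 3), round(ref_m$`Pr(>F)`[1], 3))
  }
  ident <- levene_test(rep(c(1, 2, 3), 4), rep(c("a", "b"), each = 6))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)
  # df bookkeeping at the smallest admissible size
  tiny <- levene_test(c(1, 2, 10, 20), c("a", "a", "b", "b"))
  expect_equal(unname(tiny$df), c(1, 2))
})

test_that("Levene rejects strongly under a 10x variance ratio", {
  set.seed(5)
  rej <- mean(replicate(200, {
    v <- c(rnorm(15, 0, 1), rnorm(15, 0, sqrt(10)))
    levene_test(v, rep(c("a", "b"), each = 15))$p < 0.05
  }))
  expect_gt(rej, 0.5)
})

test_that("Welch ANOVA matches oneway.test and classic ANOVA matches aov", {
  set.seed(6)
  for (i in 1:20) {
    v <- c(rnorm(15, 0, 1), rnorm(15, 0.5, 2), rnorm(12, 1, 0.5))
    g <- factor(gh_ref_groups)
    mine <- welch_anova(v, g)
    ref <- oneway.test(v ~ g, var.equal = FALSE)
    expect_equal(round(mine$statistic, 3), round(unname(ref$statistic), 3))
    expect_equal(round(unname(mine$df["df2"]), 3),
                 round(unname(ref$parameter[2]), 3))
    expect_equal(round(mine$p, 3), round(ref$p.value, 3))
    cls <- oneway_anova(v, g)
    ref2 <- oneway.test(v ~ g, var.equal = TRUE)
    expect_equal(round(cls$statistic, 3), round(unname(ref2$statistic), 3))
    expect_equal(round(cls$p, 3), round(ref2$p.value, 3))
  }
  ident <- welch_anova(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3),
                       alpha = 0.05)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)
  expect_error(welch_anova(c(1, 1, 2, 3), rep(c("a", "b"), each = 2)),
               "zero-variance")
})

test_that("two-group Welch ANOVA equals the squared Welch t", {
  set.seed(7)
  v <- c(rnorm(10, 0, 2), rnorm(14, 1, 1))
  g <- rep(c("a", "b"), c(10, 14))
  w <- welch_anova(v, g)
  tt <- t.test(v ~ g)
  expect_equal(round(w$statistic, 6), round(unname(tt$statistic)^2, 6))
  expect_equal(round(w$p, 6), round(tt$p.value, 6))
})

test_that("Games-Howell reproduces the frozen pingouin reference to 3 d.p.", {
  gh <- games_howell(gh_ref_values, gh_ref_groups)
  p <- gh$pairs
  expect_equal(p$group1, c("g2", "g2", "g3"))
  expect_equal(round(p$difference, 3), c(3.426, 3.440, 0.013))
  expect_equal(round(p$se, 3), c(0.347, 0.254, 0.310))
  expect_equal(round(p$df, 2), c(26.17, 23.45, 20.54))
  expect_equal(round(p$p_adj, 3), c(0, 0, 0.999))
  w <- welch_anova(gh_ref_values, gh_ref_groups)
  expect_equal(round(w$statistic, 3), 95.731)
  expect_equal(round(unname(w$df["df2"]), 3), 25.227)
})

test_that("Games-Howell with two groups reduces to the Welch t-test", {
  # frozen two-group reference (pingouin adjusted p = 0.005948)
  vb <- c(4.7035, 3.0074, 6.7219, 1.6839, 3.7231, 8.4406, 0.7744, 2.0922,
          6.7207, 1.3913, 6.5401, 6.9189, 7.8248, 7.0114, 7.7747, 7.9272,
          6.9721, 6.7672, 6.5405, 8.7399, 5.8121, 5.851, 4.9025, 7.0395)
  gb <- rep(c("a", "b"), c(10, 14))
  gh <- games_howell(vb, gb)
  expect_equal(round(gh$pairs$p_adj, 3), 0.006)
  # identity with Welch t on random two-group datasets
  set.seed(8)
  for (i in 1:20) {
    v <- c(rnorm(8, 0, 2), rnorm(13, 1, 1))
    g <- rep(c("a", "b"), c(8, 13))
    gh2 <- games_howell(v, g)
    tt <- t.test(v ~ g)
    expect_equal(round(gh2$pairs$p_adj, 3), round(tt$p.value, 3))
  }
  ident <- games_howell(rep(c(1, 2, 3), 4), rep(c("a", "b"), each = 6))
  expect_gt(min(ident$pairs$p_adj), 1 - 1e-6)
})

test_that("Welch ANOVA holds its nominal size under heteroscedastic H0", {
  set.seed(9)
  ns <- c(15, 15, 12)
  sds <- c(1, 2, 3)
  g <- rep(c("a", "b", "c"), ns)
  reps <- 2000
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    v <- c(rnorm(ns[1], 0, sds[1]), rnorm(ns[2], 0, sds[2]),
           rnorm(ns[3], 0, sds[3]))
    rej[r] <- welch_anova(v, g)$p < 0.05
  }
  rate <- mean(rej)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("Games-Howell familywise error under H0 stays at or below nominal", {
  set.seed(10)
  ns <- c(15, 15, 12)
  sds <- c(1, 2, 3)
  g <- rep(c("a", "b", "c"), ns)
  reps <- 1000
  fwe <- mean(replicate(reps, {
    v <- c(rnorm(ns[1], 0, sds[1]), rnorm(ns[2], 0, sds[2]),
           rnorm(ns[3], 0, sds[3]))
    min(games_howell(v, g)$pairs$p_adj) < 0.05
  }))
  expect_lte(fwe, 0.05 + 1.96 * sqrt(0.05 * 0.95 / reps))
})

test_that("the variance gate picks the branch the data demand", {
  set.seed(11)
  # strongly heteroscedastic: Welch + Games-Howell branch
  v1 <- c(rnorm(15, 0, 0.3), rnorm(15, 1, 3), rnorm(12, 2, 0.3))
  g <- rep(c("a", "b", "c"), c(15, 15, 12))
  res1 <- analysis_gate(v1, g)
  expect_equal(res1$branch, "welch")
  expect_s3_class(res1$post_hoc, "load_test")
  expect_length(res1$normality, 3)
  # homoscedastic: classic branch with flagged pairwise follow-up
  v2 <- c(rnorm(15, 0, 1), rnorm(15, 1, 1), rnorm(12, 2, 1))
  res2 <- analysis_gate(v2, g)
  expect_equal(res2$branch, "classic")
  expect_s3_class(res2$post_hoc, "data.frame")
  expect_match(res2$post_hoc_warning, "unadjusted")
  # gate decisions carry both p-values
  expect_true(is.numeric(res1$levene$p) && is.numeric(res1$anova$p))
})

test_that("non-normal groups do not divert the chain", {
  set.seed(12)
  v <- c(rexp(15), rexp(15) + 1, rexp(12) + 2)
  g <- rep(c("a", "b", "c"), c(15, 15, 12))
  res <- analysis_gate(v, g)
  expect_true(res$branch %in% c("welch", "classic"))
  expect_length(res$normality, 3)
})
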