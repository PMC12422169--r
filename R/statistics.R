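#' Descriptive statistics with both SD conventions
#'
#' @param x numeric values.
#' @param sd_convention `"sample"` (n-1) or `"population"` (n). The two are
#'   related by `sd_pop = sd_sample * sqrt((n-1)/n)`; the mean does not
#'   depend on the convention.
#' @return list with `mean`, `sd`, `n`, and `degenerate` flag for n = 1
#'   under the sample convention.
#' @export
describe_values <- function(x, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  if (!length(x)) stop("empty input")
  n <- length(x)
  degenerate <- FALSE
  if (n == 1) {
    s <- 0
    degenerate <- sd_convention == "sample"
  } else {
    s <- stats::sd(x)
    if (sd_convention == "population") s <- s * sqrt((n - 1) / n)
  }
  list(mean = mean(x), sd = s, n = n, degenerate = degenerate)
}

#' Sample-size weighted pooled mean
#'
#' `sum(n_i * m_i) / sum(n_i)` — used to pool per-digit group means into one
#' cohort-level value.
#'
#' @param means group means.
#' @param ns group sizes.
#' @return Pooled mean.
#' @export
weighted_group_mean <- function(means, ns) {
  if (length(means) != length(ns)) stop("length mismatch")
  if (any(ns <= 0)) stop("group sizes must be positive")
  sum(ns * means) / sum(ns)
}

new_test_report <- function(test, statistic, df, p, alpha = 0.05, extra = list()) {
  structure(c(list(test = test, statistic = statistic, df = df,
                   p = p, alpha = alpha,
                   significant = is.finite(p) && p < alpha), extra),
            class = "load_test")
}

#' @export
print.load_test <- function(x, ...) {
  dfs <- paste(signif(unlist(x$df), 5), collapse = ", ")
  cat(sprintf("%s: statistic = %.5g, df = %s, p = %.4g (%ssignificant at %.3g)\n",
              x$test, x$statistic, dfs, x$p,
              if (x$significant) "" else "not ", x$alpha))
  if (!is.null(x$pairs)) print(x$pairs, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Paired t test (implemented from the formula)
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with two-sided p from Student t on
#' n - 1 df. Pairs with a missing member are dropped; outliers are retained.
#'
#' @param a,b paired measurements of equal length.
#' @param alpha significance level.
#' @return A `load_test` report.
#' @export
paired_t <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  keep <- is.finite(a) & is.finite(b)
  d <- a[keep] - b[keep]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    p <- if (mean(d) == 0) 1 else 0
    return(new_test_report("paired t", t, n - 1, p, alpha,
                           list(mean_difference = mean(d), n = n,
                                degenerate = TRUE)))
  }
  t <- mean(d) / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  new_test_report("paired t", t, n - 1, p, alpha,
                  list(mean_difference = mean(d), n = n, degenerate = FALSE))
}

#' Shapiro-Wilk normality report
#'
#' Thin wrapper around the Royston (AS R94) implementation in base R,
#' with the degenerate constant-sample case turned into an explicit error.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @param alpha significance level.
#' @return A `load_test` report with `W` as the statistic.
#' @export
shapiro_normality <- function(x, alpha = 0.05) {
  if (length(x) < 3 || length(x) > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("zero variance: normality test undefined")
  sw <- stats::shapiro.test(x)
  new_test_report("Shapiro-Wilk", unname(sw$statistic), NA_real_,
                  sw$p.value, alpha)
}

split_groups <- function(values, groups) {
  g <- split(values, groups)
  if (length(g) < 2) stop("need at least 2 groups")
  ns <- lengths(g)
  if (any(ns < 2)) stop("every group needs n >= 2")
  g
}

#' Levene's test for homogeneity of variances
#'
#' Classic Levene statistic: a one-way F test on absolute deviations from
#' the group center (mean by default; `center = "median"` gives the
#' Brown-Forsythe variant).
#'
#' @param values numeric measurements.
#' @param groups group labels.
#' @param center `"mean"` or `"median"`.
#' @param alpha significance level.
#' @return A `load_test` report (F statistic, df `(k-1, N-k)`).
#' @export
levene_test <- function(values, groups, center = c("mean", "median"),
                        alpha = 0.05) {
  center <- match.arg(center)
  g <- split_groups(values, groups)
  cfun <- if (center == "mean") mean else stats::median
  z <- lapply(g, function(v) abs(v - cfun(v)))
  k <- length(z)
  ns <- lengths(z)
  N <- sum(ns)
  zbar <- mean(unlist(z))
  zi <- vapply(z, mean, 0)
  num <- sum(ns * (zi - zbar)^2) / (k - 1)
  den <- sum(unlist(lapply(z, function(v) (v - mean(v))^2))) / (N - k)
  if (den == 0) {
    Fstat <- if (num == 0) 0 else Inf
    p <- if (num == 0) 1 else 0
  } else {
    Fstat <- num / den
    p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  }
  new_test_report("Levene", Fstat, c(df1 = k - 1, df2 = N - k), p, alpha,
                  list(center = center))
}

#' Classic one-way ANOVA (implemented from the formula)
#'
#' @inheritParams levene_test
#' @return A `load_test` report.
#' @export
oneway_anova <- function(values, groups, alpha = 0.05) {
  g <- split_groups(values, groups)
  k <- length(g); ns <- lengths(g); N <- sum(ns)
  gm <- mean(values)
  mi <- vapply(g, mean, 0)
  ssb <- sum(ns * (mi - gm)^2)
  ssw <- sum(unlist(lapply(g, function(v) (v - mean(v))^2)))
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  new_test_report("one-way ANOVA", Fstat, c(df1 = k - 1, df2 = N - k), p, alpha)
}

#' Welch's heteroscedastic one-way ANOVA (implemented from the formula)
#'
#' Weights `w_i = n_i / s_i^2`, Welch's F with Welch-Satterthwaite
#' denominator degrees of freedom. With equal variances and equal group
#' sizes it tracks the classic one-way ANOVA.
#'
#' @inheritParams levene_test
#' @return A `load_test` report (F statistic, fractional df).
#' @export
welch_anova <- function(values, groups, alpha = 0.05) {
  g <- split_groups(values, groups)
  k <- length(g); ns <- lengths(g)
  vars <- vapply(g, stats::var, 0)
  mi <- vapply(g, mean, 0)
  if (any(vars == 0)) {
    if (all(vars == 0) && diff(range(mi)) == 0) {
      # identical groups: no effect, by convention F = 0, p = 1
      return(new_test_report("Welch ANOVA", 0, c(df1 = k - 1, df2 = Inf), 1,
                             alpha, list(degenerate = TRUE)))
    }
    stop("zero-variance group")
  }
  w <- ns / vars
  sw <- sum(w)
  mw <- sum(w * mi) / sw
  tmp <- sum((1 - w / sw)^2 / (ns - 1))
  Fstat <- (sum(w * (mi - mw)^2) / (k - 1)) /
    (1 + 2 * (k - 2) / (k^2 - 1) * tmp)
  df2 <- (k^2 - 1) / (3 * tmp)
  p <- stats::pf(Fstat, k - 1, df2, lower.tail = FALSE)
  new_test_report("Welch ANOVA", Fstat, c(df1 = k - 1, df2 = df2), p, alpha)
}

#' Games-Howell post hoc comparisons (implemented from the formula)
#'
#' For each pair: `t = |m_i - m_j| / sqrt(s_i^2/n_i + s_j^2/n_j)` with
#' Welch-Satterthwaite df, adjusted p from the studentized-range
#' distribution with k groups (`q = t * sqrt(2)`), and confidence intervals
#' with half-width `q_crit * SE / sqrt(2)`. With k = 2 the adjusted p equals
#' the Welch t-test p.
#'
#' @inheritParams levene_test
#' @param conf confidence level for the intervals.
#' @return A `load_test` report whose `pairs` element is a data.frame with
#'   one row per pair: difference, SE, df, p_adj, lower, upper.
#' @export
games_howell <- function(values, groups, conf = 0.95, alpha = 0.05) {
  g <- split_groups(values, groups)
  k <- length(g); ns <- lengths(g)
  vars <- vapply(g, stats::var, 0)
  if (any(vars == 0)) stop("zero-variance group")
  mi <- vapply(g, mean, 0)
  labs <- names(g)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se2 <- vars[i] / ns[i] + vars[j] / ns[j]
      se <- sqrt(se2)
      df <- se2^2 / ((vars[i] / ns[i])^2 / (ns[i] - 1) +
                       (vars[j] / ns[j])^2 / (ns[j] - 1))
      tstat <- (mi[i] - mi[j]) / se
      q <- abs(tstat) * sqrt(2)
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
      qc <- stats::qtukey(conf, nmeans = k, df = df)
      half <- qc * se / sqrt(2)
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = labs[i], group2 = labs[j],
        difference = mi[i] - mi[j], se = se, df = df,
        p_adj = p, lower = mi[i] - mi[j] - half, upper = mi[i] - mi[j] + half)
    }
  }
  pairs <- do.call(rbind, rows)
  new_test_report("Games-Howell", max(abs(pairs$difference / pairs$se)) * sqrt(2),
                  NA_real_, min(pairs$p_adj), alpha, list(pairs = pairs, conf = conf))
}

#' Pairwise Welch t tests (unadjusted)
#'
#' Follow-up comparisons after a homoscedastic one-way ANOVA, where no named
#' post hoc procedure is prescribed; emitted with a warning flag in
#' [analysis_gate()].
#'
#' @inheritParams levene_test
#' @return data.frame of pairwise Welch t results.
#' @export
pairwise_welch_t <- function(values, groups, alpha = 0.05) {
  g <- split_groups(values, groups)
  k <- length(g); ns <- lengths(g)
  vars <- vapply(g, stats::var, 0)
  mi <- vapply(g, mean, 0)
  labs <- names(g)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se2 <- vars[i] / ns[i] + vars[j] / ns[j]
      df <- se2^2 / ((vars[i] / ns[i])^2 / (ns[i] - 1) +
                       (vars[j] / ns[j])^2 / (ns[j] - 1))
      tstat <- (mi[i] - mi[j]) / sqrt(se2)
      p <- 2 * stats::pt(-abs(tstat), df)
      rows[[length(rows) + 1L]] <- data.frame(group1 = labs[i], group2 = labs[j],
                                              t = tstat, df = df, p = p)
    }
  }
  do.call(rbind, rows)
}

#' Statistics chain with the variance-homogeneity gate
#'
#' Runs Shapiro-Wilk per group (reported only: non-normal groups do not
#' divert the chain, which proceeds with ANOVA on robustness grounds), then
#' Levene's test; if variances are heterogeneous at `alpha` the chain is
#' Welch ANOVA with Games-Howell post hoc, otherwise the classic one-way
#' ANOVA with unadjusted pairwise Welch t comparisons (flagged, since no
#' named post hoc applies on that branch).
#'
#' @inheritParams levene_test
#' @return list: `normality` (per-group reports), `levene`, `branch`
#'   (`"welch"` or `"classic"`), `anova`, `post_hoc`, `post_hoc_warning`.
#' @export
analysis_gate <- function(values, groups, alpha = 0.05,
                          center = c("mean", "median")) {
  g <- split_groups(values, groups)
  normality <- lapply(g, function(v) {
    tryCatch(shapiro_normality(v, alpha), error = function(e) NULL)
  })
  lev <- levene_test(values, groups, center = match.arg(center), alpha = alpha)
  if (lev$significant) {
    branch <- "welch"
    av <- welch_anova(values, groups, alpha)
    post <- games_howell(values, groups, alpha = alpha)
    warn <- NULL
  } else {
    branch <- "classic"
    av <- oneway_anova(values, groups, alpha)
    post <- pairwise_welch_t(values, groups, alpha)
    warn <- "homogeneous branch: unadjusted pairwise Welch t tests (no named post hoc prescribed)"
  }
  structure(list(normality = normality, levene = lev, branch = branch,
                 anova = av, post_hoc = post, post_hoc_warning = warn,
                 alpha = alpha),
            class = "analysis_gate")
}

#' @export
print.analysis_gate <- function(x, ...) {
  cat("Variance-gated analysis chain\n")
  print(x$levene)
  cat(sprintf("branch: %s\n", x$branch))
  print(x$anova)
  if (inherits(x$post_hoc, "load_test")) print(x$post_hoc)
  else print(x$post_hoc, row.names = FALSE, digits = 4)
  if (!is.null(x$post_hoc_warning)) cat("note:", x$post_hoc_warning, "\n")
  invisible(x)
}
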