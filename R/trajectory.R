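#' Normalize travel and apply the analysis window
#'
#' Rescales machine travel to normalized distance `s in [0, 1]`. For the
#' wrist-flexion exercise (test 2) only the first half of travel is
#' analyzed (the second half overextends natural flexion); the analyzed
#' half-window is re-normalized onto the 0-1 reporting grid, so "1" marks
#' the half-travel point. Set `renormalize_window = FALSE` to keep the raw
#' window indices instead.
#'
#' @param travel machine travel samples (mm), nondecreasing.
#' @param moment moment samples (N mm) at `travel`.
#' @param test exercise id (1 or 2).
#' @param renormalize_window re-index the analyzed window to 0-1 (default).
#' @return data.frame with `s` (strictly increasing, 0 to 1 over the
#'   analyzed window) and `moment`.
#' @export
normalize_travel <- function(travel, moment, test = 1,
                             renormalize_window = TRUE) {
  stopifnot(length(travel) == length(moment), length(travel) >= 2)
  if (any(diff(travel) < -1e-12)) stop("travel must be nondecreasing")
  span <- travel[length(travel)] - travel[1]
  if (span <= 0) stop("zero total travel")
  s <- (travel - travel[1]) / span
  keep <- !duplicated(s)
  s <- s[keep]; moment <- moment[keep]
  if (test == 2) {
    win <- s <= 0.5 + 1e-12
    s <- s[win]; moment <- moment[win]
    if (length(s) < 2) stop("analysis window contains fewer than 2 samples")
    if (renormalize_window) s <- s / max(s)
  }
  data.frame(s = s, moment = moment)
}

#' Resample a normalized moment curve onto the reporting grid
#'
#' Linear interpolation between bracketing samples; grid points that
#' coincide with samples reuse the sample value exactly. Extrapolation is
#' refused.
#'
#' @param curve data.frame with `s` and `moment` (from [normalize_travel()]).
#' @param grid reporting grid, default `seq(0, 1, 0.2)`.
#' @return Numeric vector of moments at `grid`.
#' @export
resample_moments <- function(curve, grid = seq(0, 1, 0.2)) {
  s <- curve$s; m <- curve$moment
  if (min(grid) < min(s) - 1e-9 || max(grid) > max(s) + 1e-9) {
    stop("grid extends beyond the sampled curve (extrapolation forbidden)")
  }
  stats::approx(s, m, xout = grid, ties = "ordered")$y
}

#' Select the retained trials
#'
#' Each digit is tested five times; trials 3-5 are used in the analysis to
#' discount setup artifacts. Extra trials beyond five are ignored (with a
#' message); fewer than five is an incomplete digit and an error.
#'
#' @param trials recorded trial indices.
#' @return Sorted integer vector `c(3, 4, 5)`.
#' @export
select_trials <- function(trials) {
  trials <- sort(unique(as.integer(trials)))
  if (length(trials) < 5) stop("incomplete digit: fewer than 5 recorded trials")
  if (length(trials) > 5) message("ignoring extra trials beyond the first five")
  intersect(3:5, trials)
}

#' Process a synthetic cohort through the forward model
#'
#' Converts each retained trial's flexion amplitudes to bending-moment
#' samples via the linear unit solution (`moment = amplitude * unit_moment`),
#' normalizes travel, applies the test-2 analysis window, resamples onto the
#' reporting grid and extracts the per-trial maximum over the analyzed
#' window of the raw (not resampled) curve.
#'
#' @param cohort output of [generate_cohort()].
#' @param unit_moment N mm of gap-center bending moment per degree of
#'   distal-fragment flexion, from [unit_bending_solve()].
#' @param grid reporting grid.
#' @return data.frame with one row per retained trial: identifiers,
#'   `max_moment`, and `m0 .. m<k>` grid moments.
#' @export
process_cohort <- function(cohort, unit_moment, grid = seq(0, 1, 0.2)) {
  sm <- cohort$samples
  keys <- unique(sm[, c("hand", "digit", "test", "trial")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    tr_all <- sort(unique(sm$trial[sm$hand == k$hand & sm$digit == k$digit &
                                     sm$test == k$test]))
    retained <- suppressMessages(select_trials(tr_all))
    if (!(k$trial %in% retained)) next
    sel <- sm$hand == k$hand & sm$digit == k$digit & sm$test == k$test &
      sm$trial == k$trial
    tr <- sm[sel, ]
    moment <- tr$amplitude * unit_moment
    curve <- normalize_travel(tr$travel, moment, test = k$test)
    mgrid <- resample_moments(curve, grid)
    rows[[length(rows) + 1L]] <- cbind(
      k, data.frame(max_moment = max(curve$moment)),
      stats::setNames(as.data.frame(as.list(mgrid)),
                      paste0("m", seq_along(grid) - 1L))
    )
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "grid") <- grid
  out
}

#' Summarize a processed cohort
#'
#' Per (test, digit): mean and SD of the grid moments at each step, group
#' size, and the pooled per-trial maxima; plus per-test pooled maxima
#' statistics across digits. Step-0 entries are exactly 0 +- 0 by
#' construction of the normalized curves. Single-trial groups report SD 0
#' with a degeneracy flag.
#'
#' @param processed output of [process_cohort()].
#' @param sd_convention `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @return A `cohort_summary`: list with `table` (long per-step summary),
#'   `maxima` (per-trial), `groups` (per test x digit), `pooled` (per test).
#' @export
summarize_cohort <- function(processed, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  grid <- attr(processed, "grid")
  mcols <- paste0("m", seq_along(grid) - 1L)
  sdfun <- function(x) {
    if (length(x) < 2) return(0)
    s <- stats::sd(x)
    if (sd_convention == "population") s <- s * sqrt((length(x) - 1) / length(x))
    s
  }
  tab <- list(); groups <- list(); pooled <- list()
  for (test in sort(unique(processed$test))) {
    per_digit <- list()
    for (d in sort(unique(processed$digit))) {
      g <- processed[processed$test == test & processed$digit == d, ]
      if (!nrow(g)) next
      for (j in seq_along(grid)) {
        tab[[length(tab) + 1L]] <- data.frame(
          test = test, digit = d, step = grid[j],
          mean = mean(g[[mcols[j]]]), sd = sdfun(g[[mcols[j]]]), n = nrow(g))
      }
      groups[[length(groups) + 1L]] <- data.frame(
        test = test, digit = d, n = nrow(g),
        max_mean = mean(g$max_moment), max_sd = sdfun(g$max_moment),
        degenerate = nrow(g) < 2)
      per_digit[[length(per_digit) + 1L]] <- g$max_moment
    }
    allmax <- unlist(per_digit)
    pooled[[length(pooled) + 1L]] <- data.frame(
      test = test, n = length(allmax), mean = mean(allmax), sd = sdfun(allmax))
  }
  structure(list(table = do.call(rbind, tab),
                 maxima = processed[, c("hand", "digit", "test", "trial", "max_moment")],
                 groups = do.call(rbind, groups),
                 pooled = do.call(rbind, pooled),
                 sd_convention = sd_convention),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (bending moments, N mm)\n")
  cat("\nPer-digit maxima:\n")
  print(x$groups, row.names = FALSE, digits = 3)
  cat("\nPooled maxima per test:\n")
  print(x$pooled, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a cohort summary as CSV tables
#'
#' Writes the per-step summary in a wide layout (rows = steps, columns =
#' test x digit mean and SD) plus the per-trial maxima.
#'
#' @param summary a `cohort_summary`.
#' @param file path of the per-step table; maxima are written next to it
#'   with suffix `_maxima`.
#' @export
write_summary_csv <- function(summary, file) {
  tab <- summary$table
  tab$group <- sprintf("test%d_digit%d", tab$test, tab$digit)
  wide <- stats::reshape(tab[, c("step", "group", "mean", "sd")],
                         idvar = "step", timevar = "group",
                         v.names = c("mean", "sd"), direction = "wide")
  utils::write.csv(wide, file, row.names = FALSE)
  maxfile <- sub("(\\.[^.]*)?$", "_maxima\\1", file)
  utils::write.csv(summary$maxima, maxfile, row.names = FALSE)
  invisible(c(file, maxfile))
}
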