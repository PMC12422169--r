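#' Donor table for the synthetic cohort
#'
#' Covariates of the five hand specimens that define the study conditions
#' (side, sex, age in years, height in cm, weight in kg, BMI). These printed
#' values are inputs to the synthetic cohort; descriptive statistics of this
#' table are part of the verification suite.
#'
#' @return data.frame with one row per hand.
#' @export
hand_donors <- function() {
  data.frame(
    hand = paste("Hand", 1:5),
    side = c("Left", "Right", "Right", "Right", "Right"),
    sex = rep("Male", 5),
    age = c(41, 41, 50, 47, 34),
    height_cm = c(170.2, 170.2, 180.3, 170.2, 182.9),
    weight_kg = c(82.1, 82.1, 95.3, 78.9, 87.1),
    bmi = c(28.4, 28.4, 29.3, 27.3, 26.5)
  )
}

#' Reference bending-moment targets per digit and exercise
#'
#' Per-step mean +- SD of the out-of-plane bending moment (N mm) on the
#' normalized reporting grid for both rehabilitation exercises
#' (test 1 = fingertip-to-palm, test 2 = wrist flexion) and digits 2-4.
#' These published magnitudes are the calibration targets of the synthetic
#' cohort generator.
#'
#' @return data.frame with columns `test`, `digit`, `step`, `mean`, `sd`.
#' @export
reference_moment_targets <- function() {
  steps <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  t1 <- list(
    `2` = list(m = c(0, 0.25, 0.49, 1.39, 4.09, 8.57), s = c(0, 0.23, 0.80, 1.08, 0.75, 1.06)),
    `3` = list(m = c(0, 0.09, 0.29, 0.76, 1.56, 4.71), s = c(0, 0.13, 0.26, 0.59, 1.30, 1.02)),
    `4` = list(m = c(0, 0.19, 0.92, 1.69, 2.53, 4.88), s = c(0, 0.22, 0.72, 0.68, 1.22, 0.51))
  )
  t2 <- list(
    `2` = list(m = c(0, 0.65, 2.26, 3.56, 4.25, 4.77), s = c(0, 0.46, 1.30, 1.67, 1.45, 1.34)),
    `3` = list(m = c(0, 0.42, 1.67, 2.59, 3.03, 2.98), s = c(0, 0.25, 0.64, 0.82, 0.96, 1.42)),
    `4` = list(m = c(0, 0.24, 0.83, 1.38, 1.86, 2.13), s = c(0, 0.18, 0.48, 0.61, 0.69, 0.68))
  )
  rows <- list()
  for (test in 1:2) {
    tab <- if (test == 1) t1 else t2
    for (d in names(tab)) {
      rows[[paste(test, d)]] <- data.frame(test = test, digit = as.integer(d),
                                           step = steps, mean = tab[[d]]$m,
                                           sd = tab[[d]]$s)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# nondecreasing projection (pool-adjacent-violators via isotonic regression)
monotone_projection <- function(y) {
  if (length(y) < 2) return(y)
  stats::isoreg(seq_along(y), y)$yf
}

#' Displacement trajectory template
#'
#' Parametrizes the prescribed rigid-body flexion amplitude of the distal
#' fragment versus normalized machine travel. `shape` gives the flexion
#' amplitudes (degrees) on the reporting grid `steps`; in-between samples are
#' linearly interpolated, which preserves monotonicity and convexity of the
#' grid values. Noise parameters are expressed in moment units (N mm) at the
#' peak, mirroring how between-trial and between-specimen scatter is
#' reported.
#'
#' @param test exercise id: 1 (fingertip-to-palm) or 2 (wrist flexion).
#' @param shape flexion amplitudes (degrees) at `steps`; must start at 0 and
#'   be nondecreasing.
#' @param steps normalized grid of the shape values.
#' @param peak_moment_target target peak moment (N mm, > 0).
#' @param noise_sd between-trial SD (N mm at peak).
#' @param specimen_effect_sd between-hand SD (N mm at peak).
#' @return A `trajectory_template`.
#' @export
trajectory_template <- function(test, shape, steps = seq(0, 1, 0.2),
                                peak_moment_target, noise_sd = 0,
                                specimen_effect_sd = 0) {
  stopifnot(test %in% 1:2, length(shape) == length(steps),
            peak_moment_target > 0, noise_sd >= 0, specimen_effect_sd >= 0)
  if (abs(shape[1]) > 1e-12) stop("displacement profile must start at 0")
  if (any(diff(shape) < -1e-9)) stop("displacement profile must be nondecreasing")
  structure(list(test = test, shape = shape, steps = steps,
                 peak_moment_target = peak_moment_target,
                 noise_sd = noise_sd,
                 specimen_effect_sd = specimen_effect_sd),
            class = "trajectory_template")
}

#' Calibrate a template to a target moment curve
#'
#' Inverts the forward model so that solving the construct along the
#' returned displacement profile reproduces `target_curve` at the grid
#' steps. Because the model is linear-elastic, the inversion is a single
#' unit forward solve followed by scaling (one root per step in closed
#' form). Targets are first projected onto the nondecreasing cone (the
#' displacement magnitude cannot decrease during a flexion exercise);
#' printed target curves with a mild terminal dip are thereby flattened by
#' well under the round-trip tolerance.
#'
#' @param target_curve moments (N mm) at `steps`; nonnegative, starting at 0.
#' @param unit_moment moment per unit flexion amplitude (N mm / degree),
#'   e.g. from [unit_bending_solve()]. Alternatively supply `geometry` (and
#'   optionally `params`, `materials_spec`) to have it computed.
#' @param test exercise id stored in the template.
#' @param steps normalized grid.
#' @param noise_sd,specimen_effect_sd scatter parameters passed through.
#' @param geometry,params,materials_spec forward-model inputs when
#'   `unit_moment` is missing.
#' @return A `trajectory_template` whose forward moments equal the projected
#'   target within numerical tolerance.
#' @export
calibrate_template <- function(target_curve, unit_moment = NULL,
                               test = 1, steps = seq(0, 1, 0.2),
                               noise_sd = 0, specimen_effect_sd = 0,
                               geometry = NULL, params = mesh_params(),
                               materials_spec = default_materials()) {
  stopifnot(length(target_curve) == length(steps))
  if (any(target_curve < -1e-12)) stop("target curve must be nonnegative")
  if (abs(target_curve[1]) > 1e-12) stop("target curve must start at 0")
  if (is.null(unit_moment)) {
    if (is.null(geometry)) stop("supply unit_moment or geometry")
    unit_moment <- unit_bending_solve(geometry, params, materials_spec)$unit_moment
  }
  if (unit_moment <= 0) stop("target unreachable: unit forward moment is not positive")
  tgt <- monotone_projection(target_curve)
  if (all(tgt <= 1e-12)) {
    shape <- rep(0, length(steps))
    peak <- 1e-9
  } else {
    shape <- tgt / unit_moment
    peak <- max(tgt)
  }
  trajectory_template(test = test, shape = shape, steps = steps,
                      peak_moment_target = max(peak, 1e-9),
                      noise_sd = noise_sd,
                      specimen_effect_sd = specimen_effect_sd)
}

#' Realize one displacement trajectory
#'
#' Samples the template profile over normalized travel and applies the trial
#' scatter model: the overall displacement amplitude of the trial is scaled
#' by `hand_effect + eps`, with `eps ~ N(0, noise_sd / peak_moment_target)`.
#' With zero noise and `hand_effect = 1` the path equals the template
#' profile exactly. For the wrist-flexion exercise the template grid spans
#' the analyzed first half of travel; beyond it the profile continues with a
#' mild linear overshoot (8% by the end), emulating the overextended second
#' half that is excluded from analysis.
#'
#' @param template a `trajectory_template`.
#' @param hand_effect multiplicative specimen effect (1 = none).
#' @param seed integer seed; the same seed reproduces the path bit-for-bit.
#' @param n_samples samples along travel.
#' @param travel_total total machine travel (mm), only sets the travel axis
#'   scale.
#' @return data.frame with `travel` (mm), `s` (normalized travel) and
#'   `amplitude` (flexion amplitude, degrees, of the distal fragment).
#' @export
make_trajectory <- function(template, hand_effect = 1, seed = 1L,
                            n_samples = 51, travel_total = 25) {
  stopifnot(inherits(template, "trajectory_template"), n_samples >= 2)
  if (any(diff(template$shape) < -1e-9)) stop("non-monotone shape parameters")
  s <- seq(0, 1, length.out = n_samples)
  if (template$test == 1) {
    prof <- stats::approx(template$steps, template$shape, xout = s)$y
  } else {
    first <- s <= 0.5
    prof <- numeric(n_samples)
    prof[first] <- stats::approx(template$steps, template$shape,
                                 xout = s[first] * 2)$y
    peak_amp <- template$shape[length(template$shape)]
    prof[!first] <- peak_amp * (1 + 0.16 * (s[!first] - 0.5))
  }
  cv <- template$noise_sd / template$peak_moment_target
  eps <- 0
  if (cv > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
    eps <- stats::rnorm(1, 0, cv)
  }
  scale <- max(hand_effect + eps, 0.05)
  data.frame(travel = s * travel_total, s = s, amplitude = scale * prof)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Cohort design
#'
#' Structure of the synthetic study: which hands, digits and trials exist,
#' which trials are retained for analysis and which (hand, digit) pairs are
#' excluded. The default mirrors the study conditions: 5 hands x digits 2-4
#' x 5 trials, trials 3-5 retained, and the 4th digit of Hand 2 excluded
#' (its flexor tendon was unusable), giving per-digit group sizes 15/15/12.
#'
#' @param hands data.frame of donors (see [hand_donors()]).
#' @param digits digit ids.
#' @param trials_per_digit number of recorded trials per digit.
#' @param retained_trials indices of trials used in the analysis.
#' @param exclusions data.frame with columns `hand`, `digit`.
#' @return A `cohort_design`.
#' @export
cohort_design <- function(hands = hand_donors(), digits = 2:4,
                          trials_per_digit = 5, retained_trials = 3:5,
                          exclusions = data.frame(hand = "Hand 2", digit = 4)) {
  stopifnot(all(retained_trials >= 1), all(retained_trials <= trials_per_digit))
  structure(list(hands = hands, digits = digits,
                 trials_per_digit = trials_per_digit,
                 retained_trials = sort(unique(retained_trials)),
                 exclusions = exclusions),
            class = "cohort_design")
}

#' @rdname cohort_design
#' @export
default_cohort_design <- function() cohort_design()

#' Default calibrated templates for the study cohort
#'
#' One template per (test, digit) pair, calibrated so the forward model
#' reproduces the reference moment targets, with scatter split evenly (in
#' variance) between a multiplicative log-normal specimen effect and
#' additive Gaussian trial noise — a choice that yields positive,
#' reference-scale SDs.
#'
#' @param unit_moment forward moment per unit displacement amplitude.
#' @param targets target table, defaults to [reference_moment_targets()].
#' @return Named list of `trajectory_template`s, names `"test<k>_digit<d>"`.
#' @export
default_templates <- function(unit_moment, targets = reference_moment_targets()) {
  out <- list()
  for (test in unique(targets$test)) {
    for (d in unique(targets$digit)) {
      tab <- targets[targets$test == test & targets$digit == d, ]
      tab <- tab[order(tab$step), ]
      peak_sd <- tab$sd[nrow(tab)]
      out[[sprintf("test%d_digit%d", test, d)]] <-
        calibrate_template(tab$mean, unit_moment = unit_moment, test = test,
                           steps = tab$step,
                           noise_sd = peak_sd / sqrt(2),
                           specimen_effect_sd = peak_sd / sqrt(2))
    }
  }
  out
}

#' Generate the synthetic trial inputs
#'
#' One displacement trajectory per (hand, digit, test, trial), excluding the
#' designed exclusions. Specimen effects are multiplicative log-normal with
#' unit mean, drawn once per hand from the seeded stream and shared across
#' that hand's digits and tests; trial noise is drawn per trial inside
#' [make_trajectory()]. The first `trials_per_digit - length(retained)` ...
#' all trials are generated (the settling trials 1-2 receive a small extra
#' amplitude inflation, emulating setup artifacts); moments are not filled
#' in here — that is the forward pipeline's job.
#'
#' @param design a [cohort_design()].
#' @param templates named list from [default_templates()].
#' @param seed integer master seed.
#' @param n_samples,travel_total passed to [make_trajectory()].
#' @return List with `trials` (metadata, one row per trial) and `samples`
#'   (long data.frame: hand, digit, test, trial, travel, s, amplitude).
#' @export
generate_cohort <- function(design, templates, seed = 1L, n_samples = 51,
                            travel_total = 25) {
  hands <- design$hands$hand
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  z_hand <- stats::rnorm(length(hands))
  names(z_hand) <- hands
  artifact <- abs(stats::rnorm(1000, 0, 0.08)) # settling-trial inflations
  meta <- list(); samples <- list(); rowi <- 0L
  for (h in seq_along(hands)) {
    for (d in design$digits) {
      excl <- design$exclusions
      if (nrow(excl) && any(excl$hand == hands[h] & excl$digit == d)) next
      for (test in sort(unique(as.integer(sub("test(\\d)_.*", "\\1", names(templates)))))) {
        tpl <- templates[[sprintf("test%d_digit%d", test, d)]]
        if (is.null(tpl)) stop(sprintf("no template for test %d digit %d", test, d))
        sdlog <- tpl$specimen_effect_sd / tpl$peak_moment_target
        H <- exp(z_hand[h] * sdlog - sdlog^2 / 2)
        for (tr in seq_len(design$trials_per_digit)) {
          rowi <- rowi + 1L
          trial_seed <- (seed * 97L + h * 1009L + d * 101L + test * 7919L + tr * 13L) %% 2147483647L
          Hx <- H
          if (!(tr %in% design$retained_trials)) {
            Hx <- H * (1 + artifact[(trial_seed %% 1000L) + 1L])
          }
          traj <- make_trajectory(tpl, hand_effect = Hx, seed = trial_seed,
                                  n_samples = n_samples,
                                  travel_total = travel_total)
          meta[[rowi]] <- data.frame(hand = hands[h], digit = d, test = test,
                                     trial = tr,
                                     retained = tr %in% design$retained_trials)
          samples[[rowi]] <- cbind(meta[[rowi]][rep(1, nrow(traj)), 1:4],
                                   traj, row.names = NULL)
        }
      }
    }
  }
  if (rowi == 0L) {
    empty_meta <- data.frame(hand = character(), digit = integer(),
                             test = integer(), trial = integer(),
                             retained = logical())
    empty_samples <- cbind(empty_meta[, 1:4],
                           data.frame(travel = numeric(), s = numeric(),
                                      amplitude = numeric()))
    return(list(trials = empty_meta, samples = empty_samples))
  }
  list(trials = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       samples = do.call(rbind, c(samples, list(make.row.names = FALSE))))
}

#' Write cohort trajectories to CSV
#'
#' One row per sample: hand, digit, test, trial, travel, normalized travel
#' and displacement amplitude.
#'
#' @param cohort output of [generate_cohort()].
#' @param file path.
#' @export
write_cohort_csv <- function(cohort, file) {
  utils::write.csv(cohort$samples, file, row.names = FALSE)
  invisible(file)
}
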