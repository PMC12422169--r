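#' Fixation capacity specification
#'
#' Published mechanical capacities of a fixation, used as the numerator of
#' safety factors. [adhfix_capacity()] returns the defaults for the
#' light-curable composite patch: lowest and mean failure moments measured
#' ex vivo in an ovine phalanx four-point-bending model (a different bone
#' and geometry — reports carry that cross-model caveat) and the cured
#' composite's flexural properties.
#'
#' @param lowest_failure_moment lowest observed failure moment (N mm).
#' @param mean_failure_moment mean failure moment (N mm).
#' @param failure_moment_sd SD of the failure moment (N mm).
#' @param flexural_strength flexural strength (MPa).
#' @param flexural_modulus flexural modulus (MPa).
#' @return A `capacity_spec`.
#' @export
capacity_spec <- function(lowest_failure_moment, mean_failure_moment,
                          failure_moment_sd = 0, flexural_strength,
                          flexural_modulus) {
  stopifnot(lowest_failure_moment > 0, mean_failure_moment > 0,
            lowest_failure_moment <= mean_failure_moment,
            failure_moment_sd >= 0, flexural_strength > 0,
            flexural_modulus > 0)
  structure(list(lowest_failure_moment = lowest_failure_moment,
                 mean_failure_moment = mean_failure_moment,
                 failure_moment_sd = failure_moment_sd,
                 flexural_strength = flexural_strength,
                 flexural_modulus = flexural_modulus),
            class = "capacity_spec")
}

#' @rdname capacity_spec
#' @export
adhfix_capacity <- function() {
  capacity_spec(lowest_failure_moment = 728,
                mean_failure_moment = 1220,
                failure_moment_sd = 300,
                flexural_strength = 69,
                flexural_modulus = 6600)
}

#' Safety factor of a fixation against a computed demand
#'
#' `factor = capacity / demand` with the chosen capacity basis. Zero demand
#' passes with an unbounded factor. The cross-model caveat of the capacity
#' source is carried in the report.
#'
#' @param demand_moment computed internal bending moment (N mm), >= 0.
#' @param capacity a [capacity_spec()].
#' @param basis `"lowest"` (conservative, default) or `"mean"`.
#' @param min_factor required factor for a pass (default 1: pure pass/fail).
#' @return A `safety_report`.
#' @export
safety_factor <- function(demand_moment, capacity = adhfix_capacity(),
                          basis = c("lowest", "mean"), min_factor = 1) {
  basis <- match.arg(basis)
  if (demand_moment < 0) stop("demand must be nonnegative")
  cap <- switch(basis, lowest = capacity$lowest_failure_moment,
                mean = capacity$mean_failure_moment)
  factor <- if (demand_moment == 0) Inf else cap / demand_moment
  structure(list(demand = demand_moment, capacity = cap, basis = basis,
                 safety_factor = factor, min_factor = min_factor,
                 pass = factor >= min_factor,
                 caveat = "capacity measured in an ovine phalanx four-point-bending model"),
            class = "safety_report")
}

#' @export
print.safety_report <- function(x, ...) {
  cat(sprintf("Safety factor: %.4g (capacity %.4g N mm [%s] / demand %.4g N mm) -> %s\n",
              x$safety_factor, x$capacity, x$basis, x$demand,
              if (x$pass) "PASS" else "FAIL"))
  cat("note:", x$caveat, "\n")
  invisible(x)
}

#' Flexural-stress check of a composite patch under a demand moment
#'
#' Solves the construct with the plate region given the patch's flexural
#' modulus, scales the linear solution so the gap-center bending moment
#' equals `demand_moment`, and compares the maximum principal stress over
#' the patch elements against the flexural strength. Also reports the
#' moment at which the stress would reach the strength (linear scaling).
#'
#' @param demand_moment bending-moment demand (N mm).
#' @param capacity a [capacity_spec()] providing modulus and strength.
#' @param geometry construct geometry; patch envelope defaults to the plate
#'   envelope.
#' @param params mesh parameters.
#' @param fit optional precomputed [unit_bending_solve()] result with the
#'   patch materials (reused across calls).
#' @return A `patch_stress_report`: max extreme-fiber stress (MPa), pass
#'   flag, and the demand scaling to failure.
#' @export
patch_stress_check <- function(demand_moment, capacity = adhfix_capacity(),
                               geometry = metacarpal_construct(),
                               params = mesh_params(), fit = NULL) {
  if (is.null(fit)) {
    spec <- default_materials(plate = capacity$flexural_modulus)
    fit <- unit_bending_solve(geometry, params, materials_spec = spec)
  }
  st <- element_stresses(fit$solution, fit$mesh, fit$materials)
  # evaluate over the bridging span between the innermost screws: the rigid
  # screw-tie idealization makes stresses at the hole rims singular, so the
  # flexural comparison is made where the patch actually carries the gap load
  x_in <- min(abs(fit$mesh$geometry$screw_offsets)) -
    fit$mesh$geometry$screw_diameter
  corners <- fit$mesh$elems[, 1:4]
  cx <- rowMeans(matrix(fit$mesh$nodes[corners, 1], nrow(corners), 4))
  on_plate <- fit$mesh$region %in% "plate" & abs(cx) <= x_in
  smax_unit <- max(st$max_principal[on_plate])
  m_unit <- abs(fit$loads[["Mz"]])
  if (m_unit <= 0) stop("unit solve produced no bending moment")
  stress_at_demand <- smax_unit * demand_moment / m_unit
  moment_at_strength <- capacity$flexural_strength / smax_unit * m_unit
  structure(list(demand = demand_moment,
                 max_stress = stress_at_demand,
                 strength = capacity$flexural_strength,
                 pass = stress_at_demand < capacity$flexural_strength,
                 moment_at_strength = moment_at_strength,
                 scale_to_failure = moment_at_strength / max(demand_moment, 1e-300)),
            class = "patch_stress_report")
}

#' @export
print.patch_stress_report <- function(x, ...) {
  cat(sprintf("Patch flexural check: max principal stress %.4g MPa vs strength %.4g MPa -> %s\n",
              x$max_stress, x$strength, if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  demand %.4g N mm; strength reached at %.4g N mm (x%.4g)\n",
              x$demand, x$moment_at_strength, x$scale_to_failure))
  invisible(x)
}
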