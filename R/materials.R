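#' Default homogeneous material specification
#'
#' Per-region Young's moduli (MPa) and Poisson ratios. Bone constants are
#' implementation defaults at a typical scale (cortical 15 GPa, trabecular
#' 0.5 GPa); the plate defaults to PEEK (3.6 GPa, nu 0.38). Units are
#' mm / N / MPa throughout, so moments come out in N mm.
#'
#' @param cortical,trabecular,plate,screw Young's moduli in MPa.
#' @param nu named list of Poisson ratios per region.
#' @return A material specification list for [assign_materials()].
#' @export
default_materials <- function(cortical = 15000, trabecular = 500,
                              plate = 3600, screw = 110000,
                              nu = list(cortical = 0.3, trabecular = 0.3,
                                        plate = 0.38, screw = 0.3)) {
  structure(list(kind = "homogeneous",
                 E = list(cortical = cortical, trabecular = trabecular,
                          plate = plate, screw = screw),
                 nu = nu),
            class = "material_spec")
}

#' Density-to-modulus power-law specification
#'
#' Bone elements receive `E = a * rho^b` (MPa, rho in g/cm^3); non-bone
#' regions keep their homogeneous moduli. The power law and its constants
#' are implementation defaults, not measured values.
#'
#' @param a,b power-law coefficients.
#' @param density per-element density (g/cm^3), a single value or a vector
#'   recycled over bone elements.
#' @param base a homogeneous [default_materials()] providing the non-bone
#'   moduli and all Poisson ratios.
#' @return A material specification list.
#' @export
power_law_materials <- function(a = 6850, b = 1.49, density = 1.0,
                                base = default_materials()) {
  structure(list(kind = "power_law", a = a, b = b, density = density,
                 base = base),
            class = "material_spec")
}

#' Assign per-element materials
#'
#' @param mesh an `fe_mesh`.
#' @param spec a [default_materials()] or [power_law_materials()]
#'   specification.
#' @return A `material_field`: list with per-element vectors `E` (MPa) and
#'   `nu`.
#' @export
assign_materials <- function(mesh, spec = default_materials()) {
  region <- as.character(mesh$region)
  present <- unique(region)
  if (spec$kind == "homogeneous") {
    missing_r <- setdiff(present, names(spec$E))
    if (length(missing_r)) stop("no modulus for region(s): ",
                                paste(missing_r, collapse = ", "))
    E <- unlist(spec$E[region], use.names = FALSE)
    nu <- unlist(spec$nu[region], use.names = FALSE)
  } else if (spec$kind == "power_law") {
    base <- spec$base
    E <- unlist(base$E[region], use.names = FALSE)
    nu <- unlist(base$nu[region], use.names = FALSE)
    bone <- region %in% c("cortical", "trabecular")
    rho <- rep_len(spec$density, sum(bone))
    E[bone] <- spec$a * rho^spec$b
  } else stop("unknown material spec kind")
  if (any(E <= 0)) stop("all moduli must be positive")
  if (any(nu <= 0 | nu >= 0.5)) stop("Poisson ratios must lie in (0, 0.5)")
  structure(list(E = E, nu = nu), class = "material_field")
}
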