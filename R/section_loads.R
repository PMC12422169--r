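#' Cut plane through the plate
#'
#' A virtual section with normal along the bone axis. For a construct mesh
#' the plane must lie inside the osteotomy gap so that it intersects plate
#' elements only (the only load path bridging the gap).
#'
#' @param position axial position x (mm); default 0, the gap center.
#' @param ref optional length-3 moment reference point; defaults to the plate
#'   cross-section centroid at `position`.
#' @return A `cut_plane` object.
#' @export
cut_plane <- function(position = 0, ref = NULL) {
  structure(list(position = position, normal = c(1, 0, 0), ref = ref),
            class = "cut_plane")
}

#' Six section loads at a cut plane by free-body summation
#'
#' Splits the mesh at the plane (elements by corner centroid), computes the
#' internal nodal forces `k_e u_e` of the chosen side's elements only, and
#' sums forces and moments over the interface nodes shared with the other
#' side. The result is the force and moment transmitted across the cut onto
#' the chosen side; it is exactly equilibrated at the discrete level, so the
#' proximal and distal evaluations are componentwise negatives.
#'
#' @param solution an `fe_solution`.
#' @param mesh,materials mesh and material field of the solve.
#' @param plane a [cut_plane()].
#' @param side which free body to take: `"distal"` (x > plane) or
#'   `"proximal"`.
#' @return Named vector `Fx, Fy, Fz` (N) and `Mx, My, Mz` (N mm) about the
#'   plane reference point.
#' @export
section_loads <- function(solution, mesh, materials, plane = cut_plane(),
                          side = c("distal", "proximal")) {
  side <- match.arg(side)
  pos <- plane$position
  if (!is.null(mesh$geometry)) {
    half_gap <- mesh$geometry$gap_width / 2
    if (abs(pos) >= half_gap) {
      stop(sprintf("cut plane x = %.3g lies outside the osteotomy gap (+-%.3g)",
                   pos, half_gap))
    }
  }
  corners <- mesh$elems[, 1:4, drop = FALSE]
  cx <- rowMeans(matrix(mesh$nodes[corners, 1], nrow(corners), 4))
  # the plane must cut only plate elements
  xmin <- apply(matrix(mesh$nodes[corners, 1], nrow(corners), 4), 1, min)
  xmax <- apply(matrix(mesh$nodes[corners, 1], nrow(corners), 4), 1, max)
  crossing <- xmin < pos - 1e-9 & xmax > pos + 1e-9
  if (any(crossing & !(mesh$region %in% "plate"))) {
    stop("cut plane intersects non-plate elements")
  }
  pick <- if (side == "distal") cx > pos else cx < pos
  el_side <- which(pick)
  el_other <- which(!pick)
  if (!length(el_side) || !length(el_other)) stop("cut plane leaves one side empty")
  f_side <- tet10_internal_forces(mesh$nodes,
                                  mesh$elems[el_side, , drop = FALSE],
                                  materials$E[el_side], materials$nu[el_side],
                                  solution$U)
  iface <- intersect(unique(as.vector(mesh$elems[el_side, , drop = FALSE])),
                     unique(as.vector(mesh$elems[el_other, , drop = FALSE])))
  ref <- plane$ref
  if (is.null(ref)) {
    yz <- mesh$nodes[iface, 2:3, drop = FALSE]
    ref <- c(pos, mean(range(yz[, 1])), mean(range(yz[, 2])))
  }
  Fv <- colSums(f_side[iface, , drop = FALSE])
  r <- sweep(mesh$nodes[iface, , drop = FALSE], 2, ref)
  f <- f_side[iface, , drop = FALSE]
  Mv <- c(sum(r[, 2] * f[, 3] - r[, 3] * f[, 2]),
          sum(r[, 3] * f[, 1] - r[, 1] * f[, 3]),
          sum(r[, 1] * f[, 2] - r[, 2] * f[, 1]))
  c(Fx = Fv[1], Fy = Fv[2], Fz = Fv[3], Mx = Mv[1], My = Mv[2], Mz = Mv[3])
}

#' Stress-integration cross-check of the section loads
#'
#' Volume-average estimator over a thin slab of plate elements straddling the
#' plane: the axial force from the mean axial stress and the bending moment
#' Mz from the first moment of the axial stress about the section centroid.
#' Less accurate than the free-body route (it interpolates stresses instead
#' of summing equilibrated nodal forces); intended as an independent check at
#' around the 10% level.
#'
#' @inheritParams section_loads
#' @param slab half-width (mm) of the element slab; defaults to twice the
#'   median element size near the plane.
#' @return Named vector with `Fx` (N), `Mz` (N mm).
#' @export
section_loads_stress <- function(solution, mesh, materials,
                                 plane = cut_plane(), slab = NULL) {
  pos <- plane$position
  corners <- mesh$elems[, 1:4, drop = FALSE]
  cxm <- matrix(mesh$nodes[corners, 1], nrow(corners), 4)
  cx <- rowMeans(cxm)
  v <- tet10_volumes(mesh$nodes, mesh$elems)
  if (is.null(slab)) {
    near <- which(mesh$region %in% "plate")
    slab <- 2 * stats::median(v[near])^(1 / 3)
  }
  sel <- which(abs(cx - pos) <= slab & mesh$region %in% "plate")
  if (!length(sel)) stop("no plate elements inside the slab")
  st <- tet10_stresses(mesh$nodes, mesh$elems[sel, , drop = FALSE],
                       materials$E[sel], materials$nu[sel], solution$U)
  sxx <- st$mean[, 1]
  cy <- rowMeans(matrix(mesh$nodes[corners[sel, ], 2], length(sel), 4))
  xlo <- pmax(apply(cxm[sel, , drop = FALSE], 1, min), pos - slab)
  xhi <- pmin(apply(cxm[sel, , drop = FALSE], 1, max), pos + slab)
  L <- 2 * slab
  ref <- plane$ref
  if (is.null(ref)) {
    yz <- mesh$nodes[unique(as.vector(corners[sel, ])), 2:3, drop = FALSE]
    ref <- c(pos, mean(range(yz[, 1])), mean(range(yz[, 2])))
  }
  # traction on the distal free body acts through the face with normal -x
  Fx <- -sum(sxx * v[sel]) / L
  Mz <- sum(sxx * (cy - ref[2]) * v[sel]) / L
  c(Fx = Fx, Mz = Mz)
}

#' Section-load curve over loading steps
#'
#' Either evaluates [section_loads()] for a list of per-step solutions, or —
#' exploiting linearity of the model — scales the loads of a single unit
#' solution by a vector of displacement amplitudes.
#'
#' @param solution an `fe_solution` (unit amplitude) or a list of solutions.
#' @param mesh,materials mesh and materials.
#' @param plane a [cut_plane()].
#' @param amplitudes numeric vector of displacement amplitudes (used with a
#'   single unit solution).
#' @param steps optional step labels (defaults to amplitudes or list index).
#' @param side free-body side.
#' @return data.frame with one row per step: `step`, `Fx..Mz`.
#' @export
moment_curve <- function(solution, mesh, materials, plane = cut_plane(),
                         amplitudes = NULL, steps = NULL,
                         side = "distal") {
  if (inherits(solution, "fe_solution")) {
    if (is.null(amplitudes)) stop("need amplitudes with a single unit solution")
    base <- section_loads(solution, mesh, materials, plane, side)
    out <- outer(amplitudes, base)
    colnames(out) <- names(base)
    if (is.null(steps)) steps <- amplitudes
  } else {
    if (length(solution) < 2) stop("need >= 2 steps")
    rows <- lapply(solution, section_loads, mesh = mesh, materials = materials,
                   plane = plane, side = side)
    out <- do.call(rbind, rows)
    if (is.null(steps)) steps <- seq_along(solution)
  }
  data.frame(step = steps, out, row.names = NULL)
}
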