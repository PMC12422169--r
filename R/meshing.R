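#' Meshing parameters
#'
#' Edge-length targets for the deterministic structured mesher. `min_edge`,
#' `max_edge` and `refinement_max_edge` are upper bounds on tetra edge lengths
#' (the refinement bound applies to the plate part and to the bone's axial
#' grid in and around the plate); internally the hex scaffold pitch is chosen
#' at most `edge / sqrt(3)` — with further allowances near screw holes and
#' for annular cells — so that every tetra edge, including hex diagonals,
#' respects its bound. `scale_factor` multiplies all edge targets
#' for desk-scale coarsening; a convergence check guards the choice.
#'
#' @param min_edge minimum edge length target (mm), informational floor.
#' @param max_edge maximum edge length (mm) away from the plate.
#' @param refinement_max_edge maximum edge length (mm) inside the refinement
#'   region.
#' @param refinement_margin axial margin (mm) added around the plate to form
#'   the refinement region.
#' @param scale_factor multiplier applied to all edge targets.
#' @return A `mesh_params` object.
#' @export
mesh_params <- function(min_edge = 0.25, max_edge = 1, refinement_max_edge = 0.25,
                        refinement_margin = 1, scale_factor = 3) {
  stopifnot(min_edge <= refinement_max_edge, refinement_max_edge <= max_edge,
            scale_factor > 0)
  structure(list(min_edge = min_edge, max_edge = max_edge,
                 refinement_max_edge = refinement_max_edge,
                 refinement_margin = refinement_margin,
                 scale_factor = scale_factor),
            class = "mesh_params")
}

# 1D grid containing all of `breaks`, with spacing at most h inside each span
grid1d <- function(breaks, h) {
  breaks <- sort(unique(breaks))
  out <- breaks[1]
  for (s in seq_len(length(breaks) - 1)) {
    a <- breaks[s]; b <- breaks[s + 1]
    n <- max(1L, ceiling((b - a) / h - 1e-9))
    out <- c(out, seq(a, b, length.out = n + 1)[-1])
  }
  out
}

# structured hex box: nodes + 8-node cells (VTK corner ordering)
build_hex_box <- function(xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nodes <- cbind(rep(xs, times = ny * nz),
                 rep(rep(ys, each = nx), times = nz),
                 rep(zs, each = nx * ny))
  cell <- expand.grid(i = seq_len(nx - 1), j = seq_len(ny - 1), k = seq_len(nz - 1))
  id0 <- cell$i + (cell$j - 1) * nx + (cell$k - 1) * nx * ny
  dz <- nx * ny
  hex <- cbind(id0, id0 + 1, id0 + 1 + nx, id0 + nx,
               id0 + dz, id0 + 1 + dz, id0 + 1 + nx + dz, id0 + nx + dz)
  list(nodes = nodes, hex = hex)
}

# 6-tet decomposition of a hex around the v1-v7 diagonal; conforming on any
# structured grid because shared-face diagonals depend only on local axes
HEX_TETS <- matrix(c(1, 2, 3, 7,
                     1, 3, 4, 7,
                     1, 4, 8, 7,
                     1, 8, 5, 7,
                     1, 5, 6, 7,
                     1, 6, 2, 7), ncol = 4, byrow = TRUE)

hex_to_tets <- function(hex) {
  do.call(rbind, lapply(seq_len(nrow(HEX_TETS)), function(t) hex[, HEX_TETS[t, ], drop = FALSE]))
}

# signed corner volume of tet4 rows
tet4_signed_volume <- function(nodes, tet4) {
  p1 <- nodes[tet4[, 1], , drop = FALSE]
  a <- nodes[tet4[, 2], , drop = FALSE] - p1
  b <- nodes[tet4[, 3], , drop = FALSE] - p1
  c <- nodes[tet4[, 4], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

orient_tets <- function(nodes, tet4) {
  v <- tet4_signed_volume(nodes, tet4)
  flip <- v < 0
  if (any(flip)) tet4[flip, c(3, 4)] <- tet4[flip, c(4, 3)]
  tet4
}

# add mid-edge nodes; local edge ordering follows the VTK tet10 convention
TET_EDGES <- matrix(c(1, 2, 2, 3, 3, 1, 1, 4, 2, 4, 3, 4), ncol = 2, byrow = TRUE)

tet10_from_tet4 <- function(nodes, tet4) {
  n0 <- nrow(nodes)
  lo <- hi <- matrix(0L, nrow(tet4), 6)
  for (e in 1:6) {
    a <- tet4[, TET_EDGES[e, 1]]
    b <- tet4[, TET_EDGES[e, 2]]
    lo[, e] <- pmin(a, b)
    hi[, e] <- pmax(a, b)
  }
  key <- as.numeric(lo) * (n0 + 1) + as.numeric(hi)
  ukey <- unique(key)
  idx <- match(key, ukey)
  ulo <- floor((ukey - 1e-9) / (n0 + 1))
  uhi <- ukey - ulo * (n0 + 1)
  mid <- (nodes[ulo, , drop = FALSE] + nodes[uhi, , drop = FALSE]) / 2
  elems <- cbind(tet4, matrix(n0 + idx, nrow(tet4), 6))
  list(nodes = rbind(nodes, mid), elems = elems)
}

# drop nodes unreferenced by any element, remap connectivity and sets
compact_mesh <- function(nodes, tet4, part) {
  used <- sort(unique(as.vector(tet4)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  list(nodes = nodes[used, , drop = FALSE],
       tet4 = matrix(remap[tet4], nrow(tet4), 4),
       part = part[used])
}

# structured hollow-tube fragment: axis along x, rings at radii rs
# (ascending, innermost = medullary canal wall), nt angular divisions
# (multiple of 4); all cells are annular hexes
build_tube <- function(xs, rs, nt) {
  nx <- length(xs); nr <- length(rs)
  theta <- 2 * pi * (seq_len(nt) - 1) / nt
  ring <- expand.grid(i = seq_len(nt), j = seq_len(nr), k = seq_len(nx))
  rr <- rs[ring$j]
  nodes <- cbind(xs[ring$k], rr * sin(theta[ring$i]), rr * cos(theta[ring$i]))
  RN <- function(i, j, k) {
    i <- ((i - 1) %% nt) + 1
    ((k - 1) * nr + (j - 1)) * nt + i
  }
  cells <- expand.grid(i = seq_len(nt), k = seq_len(nx - 1))
  tets <- vector("list", nr - 1)
  for (j in seq_len(nr - 1)) {
    v0 <- RN(cells$i, j, cells$k); v1 <- RN(cells$i + 1, j, cells$k)
    v2 <- RN(cells$i + 1, j + 1, cells$k); v3 <- RN(cells$i, j + 1, cells$k)
    v4 <- RN(cells$i, j, cells$k + 1); v5 <- RN(cells$i + 1, j, cells$k + 1)
    v6 <- RN(cells$i + 1, j + 1, cells$k + 1); v7 <- RN(cells$i, j + 1, cells$k + 1)
    hex <- cbind(v0, v1, v2, v3, v4, v5, v6, v7)
    tets[[j]] <- hex_to_tets(hex)
  }
  list(nodes = nodes, tet4 = do.call(rbind, tets))
}

# plate grid with carved screw holes; nodes near each hole rim are snapped
# radially onto the hole cylinder before tet splitting
build_plate <- function(geometry, pitch, holes = TRUE) {
  g <- geometry
  # rim snapping is only worthwhile (and only safe) when the grid is coarse
  # relative to the hole; fine grids resolve the rim as a staircase whose
  # volume error is already far below the conservation tolerance
  snap <- holes && length(g$screw_offsets) &&
    pitch > 0.3 * g$screw_diameter / 2
  # snap allowance: snapping stretches edges by up to ~15 percent, so the
  # scaffold pitch is tightened to keep every edge within its bound
  if (snap) pitch <- pitch / 1.15
  hl <- g$plate_length / 2
  hw <- g$plate_width / 2
  rh <- g$screw_diameter / 2
  y0 <- g$fragment_outer_radius
  xb <- c(-hl, hl)
  zb <- c(-hw, 0, hw)
  if (holes && length(g$screw_offsets)) {
    xb <- c(xb, g$screw_offsets, g$screw_offsets - rh, g$screw_offsets + rh)
    zb <- c(zb, -rh, rh)
  }
  xs <- grid1d(xb, pitch)
  ys <- grid1d(c(y0, y0 + g$plate_thickness), pitch)
  zs <- grid1d(zb, pitch)
  box <- build_hex_box(xs, ys, zs)
  nodes <- box$nodes
  hex <- box$hex
  if (snap) {
    h_loc <- max(diff(xs), diff(zs))
    w <- 0.45 * h_loc
    dmin <- rep(Inf, nrow(nodes))
    snapped <- rep(FALSE, nrow(nodes))
    # snap near-rim nodes onto each hole cylinder
    for (x_s in g$screw_offsets) {
      dx <- nodes[, 1] - x_s
      dz <- nodes[, 3]
      d <- sqrt(dx^2 + dz^2)
      dmin <- pmin(dmin, d)
      sel <- abs(d - rh) <= w & d > 1e-12
      if (any(sel)) {
        sc <- rh / d[sel]
        nodes[sel, 1] <- x_s + dx[sel] * sc
        nodes[sel, 3] <- dz[sel] * sc
        snapped <- snapped | sel
      }
    }
    # relax the neighbourhood: constrained Laplacian smoothing in (x, z) of
    # non-snapped, non-boundary nodes near a hole, so rim snapping does not
    # leave sliver corners or over-stretched edges
    nx <- length(xs); ny <- length(ys); nz <- length(zs)
    free <- which(!snapped & dmin < rh + 3 * h_loc &
                    nodes[, 1] > min(xs) + 1e-9 & nodes[, 1] < max(xs) - 1e-9 &
                    nodes[, 3] > min(zs) + 1e-9 & nodes[, 3] < max(zs) - 1e-9)
    if (length(free)) {
      id <- free - 1L
      i <- id %% nx
      k <- id %/% (nx * ny)
      nb <- cbind(free - 1L, free + 1L, free - nx * ny, free + nx * ny)
      ok <- i > 0L & i < nx - 1L & k > 0L & k < nz - 1L
      free <- free[ok]; nb <- nb[ok, , drop = FALSE]
      # orphan nodes inside a hole must not attract their neighbours
      for (cc in 1:4) {
        orphan <- dmin[nb[, cc]] < rh - 1e-9 & !snapped[nb[, cc]]
        nb[orphan, cc] <- free[orphan]
      }
      for (it in 1:4) {
        mx <- (nodes[nb[, 1], 1] + nodes[nb[, 2], 1] +
                 nodes[nb[, 3], 1] + nodes[nb[, 4], 1]) / 4
        mz <- (nodes[nb[, 1], 3] + nodes[nb[, 2], 3] +
                 nodes[nb[, 3], 3] + nodes[nb[, 4], 3]) / 4
        nodes[free, 1] <- nodes[free, 1] + 0.6 * (mx - nodes[free, 1])
        nodes[free, 3] <- nodes[free, 3] + 0.6 * (mz - nodes[free, 3])
      }
    }
  }
  if (holes && length(g$screw_offsets)) {
    # carve cells whose (pre-snap) center lies inside a hole
    cx <- rowMeans(matrix(box$nodes[hex, 1], nrow(hex), 8))
    cz <- rowMeans(matrix(box$nodes[hex, 3], nrow(hex), 8))
    inside <- rep(FALSE, nrow(hex))
    for (x_s in g$screw_offsets) {
      inside <- inside | sqrt((cx - x_s)^2 + cz^2) < rh
    }
    hex <- hex[!inside, , drop = FALSE]
  }
  list(nodes = nodes, tet4 = hex_to_tets(hex))
}

bone_x_grid <- function(geometry, params, pitch, side = c("distal", "proximal")) {
  side <- match.arg(side)
  g <- geometry
  sf <- params$scale_factor
  pitch_ref <- params$refinement_max_edge * sf / sqrt(3)
  x0 <- g$gap_width / 2
  x1 <- x0 + g$fragment_length
  marker_x <- min(g$plate_length / 2 + 1.5, x1 - 1e-6)
  ref_end <- min(g$plate_length / 2 + params$refinement_margin, x1)
  breaks <- sort(unique(c(x0, x1, marker_x, ref_end,
                          abs(g$screw_offsets[g$screw_offsets > 0]),
                          abs(g$screw_offsets[g$screw_offsets < 0]))))
  breaks <- breaks[breaks >= x0 - 1e-9 & breaks <= x1 + 1e-9]
  xs <- numeric(0)
  for (s in seq_len(length(breaks) - 1)) {
    a <- breaks[s]; b <- breaks[s + 1]
    h <- if (b <= ref_end + 1e-9) pitch_ref else pitch
    seg <- grid1d(c(a, b), h)
    xs <- c(xs, if (length(xs)) seg[-1] else seg)
  }
  if (side == "proximal") xs <- rev(-xs)
  list(xs = xs, marker_x = if (side == "proximal") -marker_x else marker_x)
}

bone_radial_grid <- function(geometry, params) {
  sf <- params$scale_factor
  E <- params$max_edge * sf
  ro <- geometry$fragment_outer_radius
  ri <- ro - geometry$cortical_thickness
  rc <- ri - geometry$trabecular_thickness
  # angular divisions: fine enough for the edge bound, capped so annular
  # cells never become extreme pie slivers
  nt_raw <- 4L * ceiling(2 * pi * ro / (E / sqrt(3)) / 4)
  nt <- max(24L, min(40L, nt_raw))
  chord <- 2 * ro * sin(pi / nt)
  # radial/axial pitch so the cell main diagonal respects the edge bound
  pitch <- sqrt(max(E^2 - chord^2, (E / 4)^2) / 2)
  n_trab <- max(1L, ceiling(geometry$trabecular_thickness / pitch))
  n_cort <- max(1L, ceiling(geometry$cortical_thickness / pitch))
  rs <- c(seq(rc, ri, length.out = n_trab + 1),
          seq(ri, ro, length.out = n_cort + 1)[-1])
  # cap axial anisotropy so the 6-tet split keeps acceptable corner angles;
  # the binding chord is the one at the canal wall (innermost radius)
  h_rad <- min(geometry$trabecular_thickness / n_trab,
               geometry$cortical_thickness / n_cort)
  chord_min <- 2 * rc * sin(pi / nt)
  pitch_axial <- min(pitch, 4 * min(chord_min, h_rad))
  list(rs = rs, nt = nt, ri = ri, rc = rc, pitch = pitch_axial)
}

#' Mesh the fixation construct with quadratic tetrahedra
#'
#' Builds a conforming 10-node tetrahedral mesh of the two tubular bone
#' fragments and the plate (with carved screw holes) from a deterministic
#' structured hexahedral scaffold. Mid-edge nodes lie at edge midpoints, so
#' elements are affine. Bone and plate are meshed as disconnected parts;
#' load transfer is established by the rigid screw tie groups
#' ([assign_ties()], called internally). Named node sets `pin_support`,
#' `applied_displacement`, `marker_proximal`, `marker_distal` and
#' `screw_tie_1..k` are attached.
#'
#' @param geometry a [construct_geometry()].
#' @param params a [mesh_params()].
#' @param holes carve the screw holes out of the plate (default `TRUE`).
#' @param ties assign screw tie node sets (default `TRUE`).
#' @return An object of class `fe_mesh`: `nodes` (N x 3, mm), `elems`
#'   (M x 10 corner + mid-edge connectivity), `region` (factor: cortical,
#'   trabecular, plate), `part` (per-node provenance), `node_sets`,
#'   `geometry`, `params`.
#' @export
mesh_construct <- function(geometry, params = mesh_params(), holes = TRUE,
                           ties = TRUE) {
  g <- geometry
  rad <- bone_radial_grid(g, params)
  pitch_ref <- params$refinement_max_edge * params$scale_factor / sqrt(3)

  parts <- list()
  part_names <- c("bone_proximal", "bone_distal", "plate")
  for (side in c("proximal", "distal")) {
    bx <- bone_x_grid(g, params, rad$pitch, side)
    tube <- build_tube(bx$xs, rad$rs, rad$nt)
    parts[[paste0("bone_", side)]] <- c(tube, list(marker_x = bx$marker_x))
  }
  parts$plate <- build_plate(g, pitch_ref, holes = holes)

  nodes <- NULL
  tet4 <- NULL
  part_node <- character(0)
  part_elem <- character(0)
  for (nm in part_names) {
    p <- parts[[nm]]
    off <- if (is.null(nodes)) 0L else nrow(nodes)
    nodes <- rbind(nodes, p$nodes)
    tet4 <- rbind(tet4, p$tet4 + off)
    part_node <- c(part_node, rep(nm, nrow(p$nodes)))
    part_elem <- c(part_elem, rep(nm, nrow(p$tet4)))
  }
  cm <- compact_mesh(nodes, tet4, part_node)
  nodes <- cm$nodes
  tet4 <- orient_tets(nodes, cm$tet4)
  part_node <- cm$part

  v <- tet4_signed_volume(nodes, tet4)
  if (any(v <= 0)) {
    stop(sprintf("meshing produced %d non-positive elements (min volume %.3g); offending pitch %.3g",
                 sum(v <= 0), min(v), pitch_ref))
  }

  # regions from corner centroids
  cx <- rowMeans(matrix(nodes[tet4, 1], nrow(tet4), 4))
  cy <- rowMeans(matrix(nodes[tet4, 2], nrow(tet4), 4))
  cz <- rowMeans(matrix(nodes[tet4, 3], nrow(tet4), 4))
  region <- ifelse(part_elem == "plate", "plate",
                   ifelse(sqrt(cy^2 + cz^2) > rad$ri + 1e-9, "cortical", "trabecular"))

  t10 <- tet10_from_tet4(nodes, tet4)
  nodes <- t10$nodes
  elems <- t10$elems
  part_node <- c(part_node, rep(NA_character_, nrow(nodes) - length(part_node)))
  # mid-edge nodes inherit a part when both ends agree
  n_mid <- nrow(nodes) - length(cm$part)
  mid_ids <- seq_len(n_mid) + length(cm$part)
  # recompute provenance for mid nodes from the elements that use them
  for (nm in part_names) {
    sel <- unique(as.vector(elems[part_elem == nm, , drop = FALSE]))
    part_node[sel[is.na(part_node[sel])]] <- nm
  }

  X <- nodes[, 1]
  tol <- 1e-8
  x_min <- min(X); x_max <- max(X)
  ro <- g$fragment_outer_radius
  r_node <- sqrt(nodes[, 2]^2 + nodes[, 3]^2)
  node_sets <- list(
    pin_support = which(abs(X - x_min) < tol),
    applied_displacement = which(abs(X - x_max) < tol),
    marker_proximal = which(abs(X - parts$bone_proximal$marker_x) < tol &
                              r_node > ro - 1e-6 &
                              part_node %in% "bone_proximal"),
    marker_distal = which(abs(X - parts$bone_distal$marker_x) < tol &
                            r_node > ro - 1e-6 &
                            part_node %in% "bone_distal")
  )

  mesh <- structure(list(
    nodes = nodes,
    elems = elems,
    region = factor(region, levels = c("cortical", "trabecular", "plate", "screw")),
    part = part_node,
    node_sets = node_sets,
    geometry = g,
    params = params
  ), class = "fe_mesh")
  if (ties) mesh <- assign_ties(mesh, g)
  q <- mesh_quality(mesh)
  if (min(q) < 0.05) {
    stop(sprintf("mesh rejected: %d elements with scaled Jacobian < 0.05 (min %.3g); adjust edge parameters and remesh",
                 sum(q < 0.05), min(q)))
  }
  mesh
}

#' Mesh a rectangular block
#'
#' Structured quadratic-tet mesh of a box, used for solver verification
#' (patch tests, cantilever oracles) and as the hole-free plate model.
#'
#' @param lengths numeric length-3 box dimensions (mm).
#' @param pitch scaffold pitch (mm); every tet edge is at most `pitch*sqrt(3)`.
#' @param origin corner of the box (default the origin).
#' @param region_label region tag for all elements.
#' @return An `fe_mesh`.
#' @export
mesh_box <- function(lengths, pitch, origin = c(0, 0, 0), region_label = "plate") {
  xs <- grid1d(origin[1] + c(0, lengths[1]), pitch)
  ys <- grid1d(origin[2] + c(0, lengths[2]), pitch)
  zs <- grid1d(origin[3] + c(0, lengths[3]), pitch)
  box <- build_hex_box(xs, ys, zs)
  tet4 <- orient_tets(box$nodes, hex_to_tets(box$hex))
  t10 <- tet10_from_tet4(box$nodes, tet4)
  structure(list(
    nodes = t10$nodes,
    elems = t10$elems,
    region = factor(rep(region_label, nrow(t10$elems)),
                    levels = c("cortical", "trabecular", "plate", "screw")),
    part = rep("box", nrow(t10$nodes)),
    node_sets = list(),
    geometry = NULL,
    params = NULL
  ), class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("fe_mesh: %d nodes, %d tet10 elements\n", nrow(x$nodes), nrow(x$elems)))
  print(table(droplevels(x$region)))
  if (length(x$node_sets)) {
    cat("node sets:", paste(sprintf("%s(%d)", names(x$node_sets),
                                    lengths(x$node_sets)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-region mesh volumes
#'
#' @param mesh an `fe_mesh`.
#' @return Named numeric vector of summed element volumes (mm^3) per region.
#' @export
mesh_volumes <- function(mesh) {
  v <- tet10_volumes(mesh$nodes, mesh$elems)
  tapply(v, droplevels(mesh$region), sum)
}

#' Corner-edge lengths of the mesh
#'
#' @param mesh an `fe_mesh`.
#' @param region optional region filter.
#' @return Numeric vector of the 6 corner-edge lengths per element.
#' @export
mesh_edge_lengths <- function(mesh, region = NULL) {
  el <- mesh$elems
  if (!is.null(region)) el <- el[mesh$region %in% region, , drop = FALSE]
  out <- numeric(0)
  for (e in 1:6) {
    a <- el[, TET_EDGES[e, 1]]
    b <- el[, TET_EDGES[e, 2]]
    d <- mesh$nodes[a, , drop = FALSE] - mesh$nodes[b, , drop = FALSE]
    out <- c(out, sqrt(rowSums(d^2)))
  }
  out
}

#' Element shape quality (scaled Jacobian)
#'
#' Minimum corner scaled Jacobian per element: at each corner the
#' determinant of the three emanating edges divided by the product of their
#' lengths, normalized so a regular tetrahedron scores 1 (an orthogonal
#' corner scores sqrt(2)). Angle-based, so anisotropic but well-shaped
#' elements are not penalized; values near 0 flag near-degenerate corners.
#'
#' @param mesh an `fe_mesh`.
#' @return Numeric vector, one value per element.
#' @export
mesh_quality <- function(mesh) {
  el <- mesh$elems
  p <- lapply(1:4, function(k) mesh$nodes[el[, k], , drop = FALSE])
  corner_sj <- function(o, a, b, c) {
    e1 <- a - o; e2 <- b - o; e3 <- c - o
    det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
      e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
      e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
    det / (sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)) * sqrt(rowSums(e3^2)))
  }
  sj <- pmin(corner_sj(p[[1]], p[[2]], p[[3]], p[[4]]),
             corner_sj(p[[2]], p[[3]], p[[1]], p[[4]]),
             corner_sj(p[[3]], p[[1]], p[[2]], p[[4]]),
             corner_sj(p[[4]], p[[2]], p[[1]], p[[3]]))
  sqrt(2) * sj
}

#' Assign rigid screw tie groups
#'
#' For each screw a kinematic tie group is formed from the bone nodes along
#' the bicortical screw axis (within half a shank diameter plus tolerance)
#' and the plate nodes on the screw-hole rim. Each group is later condensed
#' to a single 6-DOF rigid body by the solver, which is how bone-plate load
#' transfer is represented (threads are not meshed).
#'
#' @param mesh an `fe_mesh` of the construct.
#' @param geometry the construct geometry (defaults to `mesh$geometry`).
#' @param tol capture tolerance (mm) added to the shank radius.
#' @return The mesh with `screw_tie_k` node sets attached.
#' @export
assign_ties <- function(mesh, geometry = mesh$geometry, tol = 1e-6) {
  g <- geometry
  rh <- g$screw_diameter / 2
  X <- mesh$nodes[, 1]; Y <- mesh$nodes[, 2]; Z <- mesh$nodes[, 3]
  is_bone <- mesh$part %in% c("bone_proximal", "bone_distal")
  is_plate <- mesh$part %in% "plate"
  ri <- g$fragment_outer_radius - g$cortical_thickness
  mesh$node_sets <- mesh$node_sets[!grepl("^screw_tie_", names(mesh$node_sets))]
  for (k in seq_along(g$screw_offsets)) {
    x_s <- g$screw_offsets[k]
    if (abs(x_s) > g$plate_length / 2 - rh + 1e-9) {
      stop(sprintf("screw %d at x = %.3g lies outside the plate", k, x_s))
    }
    if (abs(x_s) < g$gap_width / 2 || abs(x_s) > g$gap_width / 2 + g$fragment_length) {
      stop(sprintf("screw %d at x = %.3g lies outside the bone fragments", k, x_s))
    }
    d <- sqrt((X - x_s)^2 + Z^2)
    grp_bone <- which(is_bone & d <= rh + tol)
    grp_plate <- which(is_plate & d <= rh + tol)
    r_grp <- sqrt(Y[grp_bone]^2 + Z[grp_bone]^2)
    if (!any(r_grp >= ri - 1e-6 & Y[grp_bone] > 0) ||
        !any(r_grp >= ri - 1e-6 & Y[grp_bone] < 0)) {
      stop(sprintf("screw %d tie does not span both cortices", k))
    }
    if (!length(grp_plate)) stop(sprintf("screw %d tie found no plate rim nodes", k))
    mesh$node_sets[[paste0("screw_tie_", k)]] <- sort(c(grp_bone, grp_plate))
  }
  mesh
}

#' Mesh-refinement convergence of the cut-plane bending moment
#'
#' Meshes the construct at a sequence of refinement levels, solves each under
#' the same prescribed flexion rotation of the distal fragment, extracts the
#' gap-center bending moment Mz and reports the
#' relative change between successive levels. Convergence is flagged when
#' the change drops below `criterion` (default 5%).
#'
#' @param geometry a [construct_geometry()].
#' @param params_sequence list of [mesh_params()], coarse to fine.
#' @param displacement flexion amplitude (degrees) applied to the distal
#'   fragment.
#' @param materials_spec material specification, see [assign_materials()].
#' @param criterion relative-change convergence threshold.
#' @param verbose print per-level progress.
#' @return data.frame with one row per level: elements, dofs, `Mz`,
#'   `rel_change` (NA for the first level) and `converged`.
#' @export
check_convergence <- function(geometry, params_sequence,
                              displacement = 0.5,
                              materials_spec = default_materials(),
                              criterion = 0.05, verbose = FALSE) {
  if (length(params_sequence) < 2) stop("need >= 2 refinement levels")
  rows <- vector("list", length(params_sequence))
  for (i in seq_along(params_sequence)) {
    fit <- unit_bending_solve(geometry, params_sequence[[i]],
                              materials_spec = materials_spec,
                              amplitude = displacement)
    rows[[i]] <- data.frame(level = i,
                            scale_factor = params_sequence[[i]]$scale_factor,
                            elements = nrow(fit$mesh$elems),
                            dofs = 3 * nrow(fit$mesh$nodes),
                            Mz = fit$loads["Mz"])
    if (verbose) {
      message(sprintf("level %d (sf %.3g): %d elems, Mz = %.5g",
                      i, params_sequence[[i]]$scale_factor,
                      nrow(fit$mesh$elems), fit$loads["Mz"]))
    }
  }
  out <- do.call(rbind, rows)
  mz <- out$Mz
  out$rel_change <- c(NA, abs(diff(mz)) / abs(mz[-1]))
  out$converged <- !is.na(out$rel_change) & out$rel_change < criterion
  rownames(out) <- NULL
  out
}
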