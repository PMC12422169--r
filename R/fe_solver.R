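#' Assemble the global stiffness operator
#'
#' Sparse symmetric stiffness matrix for the 10-node tetrahedral mesh with
#' 4-point Gaussian quadrature (exact for the quadratic element). Before any
#' constraint the operator is positive semi-definite with the six rigid-body
#' modes in its null space.
#'
#' @param mesh an `fe_mesh`.
#' @param materials a `material_field` from [assign_materials()].
#' @param chunk elements per assembly chunk (memory control).
#' @return A `dsCMatrix` of dimension `3 N x 3 N`.
#' @export
assemble_stiffness <- function(mesh, materials, chunk = 12000L) {
  m <- nrow(mesh$elems)
  ndof <- 3 * nrow(mesh$nodes)
  K <- NULL
  starts <- seq(1L, m, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, m)
    tr <- tet10_stiffness_triplets(mesh$nodes,
                                   mesh$elems[idx, , drop = FALSE],
                                   materials$E[idx], materials$nu[idx])
    Kc <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                               dims = c(ndof, ndof), symmetric = TRUE)
    K <- if (is.null(K)) Kc else K + Kc
  }
  K
}

#' Dirichlet boundary conditions
#'
#' Boundary conditions are collected as (node, dof, value) triplets plus the
#' rigid tie groups taken from the mesh. Helpers: [bc_fix()] pins all
#' translations of a node set, [bc_prescribe()] imposes per-node displacement
#' components, [bc_rigid_motion()] imposes a small rigid-body motion
#' (translation + rotation) on a node set.
#'
#' @param ... any number of bc triplet data.frames from the helpers.
#' @return A `boundary_conditions` object.
#' @export
boundary_conditions <- function(...) {
  parts <- list(...)
  df <- do.call(rbind, parts)
  if (is.null(df)) df <- data.frame(node = integer(), dof = integer(), value = numeric())
  if (any(!is.finite(df$value))) stop("prescribed displacements must be finite")
  key <- paste(df$node, df$dof)
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key) | duplicated(key, fromLast = TRUE), ]
    agg <- tapply(dup$value, paste(dup$node, dup$dof), function(v) diff(range(v)))
    if (any(agg > 1e-12)) stop("conflicting prescribed values on shared nodes")
    df <- df[!duplicated(key), ]
  }
  structure(df, class = c("boundary_conditions", "data.frame"))
}

#' @rdname boundary_conditions
#' @param nodes integer node indices.
#' @export
bc_fix <- function(nodes) {
  data.frame(node = rep(nodes, each = 3), dof = rep(1:3, length(nodes)), value = 0)
}

#' @rdname boundary_conditions
#' @param u displacement: length-3 vector applied to every node, or an
#'   `length(nodes) x 3` matrix. `NA` components are left free.
#' @export
bc_prescribe <- function(nodes, u) {
  if (is.null(dim(u))) u <- matrix(u, length(nodes), 3, byrow = TRUE)
  stopifnot(nrow(u) == length(nodes), ncol(u) == 3)
  df <- data.frame(node = rep(nodes, 3),
                   dof = rep(1:3, each = length(nodes)),
                   value = as.vector(u))
  df[!is.na(df$value), ]
}

#' @rdname boundary_conditions
#' @param coords the mesh node coordinates (N x 3).
#' @param translation length-3 rigid translation (mm).
#' @param rotation length-3 rotation vector (radians, small-angle).
#' @param center rotation center (defaults to the node-set centroid).
#' @export
bc_rigid_motion <- function(nodes, coords, translation = c(0, 0, 0),
                            rotation = c(0, 0, 0), center = NULL) {
  p <- coords[nodes, , drop = FALSE]
  if (is.null(center)) center <- colMeans(p)
  r <- sweep(p, 2, center)
  u <- cbind(translation[1] + rotation[2] * r[, 3] - rotation[3] * r[, 2],
             translation[2] + rotation[3] * r[, 1] - rotation[1] * r[, 3],
             translation[3] + rotation[1] * r[, 2] - rotation[2] * r[, 1])
  bc_prescribe(nodes, u)
}

# build the constraint transformation u = T q + g
build_constraints <- function(mesh, bcs, use_ties = TRUE) {
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  g <- numeric(ndof)
  dir_dof <- integer(0)
  if (nrow(bcs)) {
    dir_dof <- 3L * (bcs$node - 1L) + bcs$dof
    g[dir_dof] <- bcs$value
  }
  tie_sets <- mesh$node_sets[grepl("^screw_tie_", names(mesh$node_sets))]
  if (!use_ties) tie_sets <- list()
  tie_nodes <- unlist(tie_sets, use.names = FALSE)
  if (anyDuplicated(tie_nodes)) stop("a node belongs to more than one tie group")
  tie_dofs <- as.vector(outer(1:3, 3L * (tie_nodes - 1L), "+"))
  if (length(intersect(dir_dof, tie_dofs))) {
    stop("tie-group nodes cannot also carry Dirichlet conditions")
  }
  constrained <- c(dir_dof, tie_dofs)
  free_dof <- setdiff(seq_len(ndof), constrained)
  n_free <- length(free_dof)
  n_grp <- length(tie_sets)

  ti <- free_dof
  tj <- seq_len(n_free)
  tx <- rep(1, n_free)
  centers <- matrix(0, n_grp, 3)
  if (n_grp) {
    for (k in seq_len(n_grp)) {
      nd <- tie_sets[[k]]
      p <- mesh$nodes[nd, , drop = FALSE]
      ctr <- colMeans(p)
      centers[k, ] <- ctr
      r <- sweep(p, 2, ctr)
      col0 <- n_free + 6L * (k - 1L)
      dx <- 3L * (nd - 1L)
      # ux = tx + ry*rz - rz*ry ; see bc_rigid_motion
      ti <- c(ti, dx + 1L, dx + 1L, dx + 1L,
              dx + 2L, dx + 2L, dx + 2L,
              dx + 3L, dx + 3L, dx + 3L)
      tj <- c(tj, rep(col0 + 1L, length(nd)), rep(col0 + 5L, length(nd)),
              rep(col0 + 6L, length(nd)),
              rep(col0 + 2L, length(nd)), rep(col0 + 6L, length(nd)),
              rep(col0 + 4L, length(nd)),
              rep(col0 + 3L, length(nd)), rep(col0 + 4L, length(nd)),
              rep(col0 + 5L, length(nd)))
      tx <- c(tx, rep(1, length(nd)), r[, 3], -r[, 2],
              rep(1, length(nd)), r[, 1], -r[, 3],
              rep(1, length(nd)), r[, 2], -r[, 1])
    }
  }
  Tmat <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                               dims = c(ndof, n_free + 6L * n_grp))
  list(T = Tmat, g = g, free_dof = free_dof, dir_dof = dir_dof,
       n_free = n_free, tie_sets = tie_sets, tie_centers = centers)
}

#' Solve the constrained linear-elastic system
#'
#' Eliminates rigid tie groups by master-slave condensation to one 6-DOF
#' body per screw, applies Dirichlet conditions by partitioning, and solves
#' the reduced symmetric positive-definite system with a sparse Cholesky
#' factorization. Constrained DOFs match their imposed values exactly.
#'
#' @param mesh an `fe_mesh`.
#' @param materials a `material_field`.
#' @param bcs a [boundary_conditions()] object.
#' @param K optional pre-assembled stiffness (reused across solves).
#' @param use_ties honour the mesh's screw tie groups (default `TRUE`).
#' @return An `fe_solution`: nodal displacements `U` (N x 3, mm), nodal
#'   `reactions` (N x 3, N; nonzero only on constrained nodes), relative
#'   `residual` of the free equations, and the rigid-body motion of each tie
#'   group.
#' @export
solve_fe <- function(mesh, materials, bcs, K = NULL, use_ties = TRUE) {
  if (is.null(K)) K <- assemble_stiffness(mesh, materials)
  con <- build_constraints(mesh, bcs, use_ties = use_ties)
  A <- Matrix::forceSymmetric(Matrix::crossprod(con$T, K %*% con$T))
  b <- -as.vector(Matrix::crossprod(con$T, K %*% con$g))
  fact <- tryCatch(suppressWarnings(Matrix::Cholesky(A, LDL = FALSE)),
                   error = function(e) e)
  if (inherits(fact, "error")) {
    stop("system is under-constrained (rigid-body modes remain): ",
         conditionMessage(fact))
  }
  q <- as.vector(Matrix::solve(fact, b))
  # one step of iterative refinement
  q <- q + as.vector(Matrix::solve(fact, b - as.vector(A %*% q)))
  u <- as.vector(con$T %*% q) + con$g
  r_full <- as.vector(K %*% u)
  res_free <- as.vector(Matrix::crossprod(con$T, r_full))
  scale_ref <- max(abs(r_full), 1e-300)
  residual <- max(abs(res_free)) / scale_ref
  if (residual > 1e-8 && max(abs(u)) > 1e-14) {
    warning(sprintf("free-DOF residual %.2e exceeds 1e-8", residual))
  }
  U <- matrix(u, ncol = 3, byrow = TRUE)
  R <- matrix(r_full, ncol = 3, byrow = TRUE)
  free_nodes_mask <- matrix(TRUE, nrow(U), 3)
  if (length(con$dir_dof)) {
    free_nodes_mask[cbind((con$dir_dof - 1L) %/% 3L + 1L,
                          (con$dir_dof - 1L) %% 3L + 1L)] <- FALSE
  }
  tie_nodes <- unlist(con$tie_sets, use.names = FALSE)
  if (length(tie_nodes)) free_nodes_mask[tie_nodes, ] <- FALSE
  R[free_nodes_mask] <- 0
  tie_q <- NULL
  if (length(con$tie_sets)) {
    tie_q <- matrix(q[con$n_free + seq_len(6 * length(con$tie_sets))],
                    ncol = 6, byrow = TRUE,
                    dimnames = list(names(con$tie_sets),
                                    c("tx", "ty", "tz", "rx", "ry", "rz")))
  }
  structure(list(U = U, reactions = R, residual = residual,
                 tie_motion = tie_q, bcs = bcs), class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("fe_solution: %d nodes, max |u| = %.4g mm, residual %.2e\n",
              nrow(x$U), max(abs(x$U)), x$residual))
  invisible(x)
}

#' Element stresses from a solution
#'
#' Cauchy stresses via Hooke's law at the element's four quadrature points.
#'
#' @param solution an `fe_solution`.
#' @param mesh,materials the mesh and materials used for the solve.
#' @return List with `gp` (M x 24: four points x six components in the order
#'   xx, yy, zz, xy, yz, zx), `mean` (M x 6 element averages), and per-element
#'   `max_principal`, `min_principal`, `von_mises` summaries (MPa).
#' @export
element_stresses <- function(solution, mesh, materials) {
  tet10_stresses(mesh$nodes, mesh$elems, materials$E, materials$nu, solution$U)
}

#' Total reaction force and moment
#'
#' Sums nodal reactions (and their moments about `about`) over a node set;
#' with `nodes = NULL` all constrained nodes are used, in which case global
#' equilibrium requires both resultants to vanish.
#'
#' @param solution an `fe_solution`.
#' @param mesh the mesh.
#' @param nodes optional node subset.
#' @param about reference point for moments (default the origin).
#' @return Named vector `Fx, Fy, Fz, Mx, My, Mz` (N, N mm).
#' @export
reaction_resultant <- function(solution, mesh, nodes = NULL, about = c(0, 0, 0)) {
  R <- solution$reactions
  if (!is.null(nodes)) {
    keep <- matrix(0, nrow(R), 3)
    keep[nodes, ] <- R[nodes, ]
    R <- keep
  }
  F <- colSums(R)
  r <- sweep(mesh$nodes, 2, about)
  M <- c(sum(r[, 2] * R[, 3] - r[, 3] * R[, 2]),
         sum(r[, 3] * R[, 1] - r[, 1] * R[, 3]),
         sum(r[, 1] * R[, 2] - r[, 2] * R[, 1]))
  c(Fx = F[1], Fy = F[2], Fz = F[3], Mx = M[1], My = M[2], Mz = M[3])
}
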