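test_that("single-element operator is symmetric with a six-mode null space", {
  nodes4 <- rbind(c(0, 0, 0), c(1.2, 0.1, 0), c(0.2, 1, 0.1), c(0, 0.3, 0.9))
  t10 <- osteoload:::tet10_from_tet4(nodes4, matrix(1:4, 1))
  tr <- osteoload:::tet10_stiffness_triplets(t10$nodes, t10$elems, 1000, 0.3)
  K <- as.matrix(Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                                      dims = c(30, 30), symmetric = TRUE))
  expect_lt(max(abs(K - t(K))) / max(abs(K)), 1e-10)
  X <- t10$nodes
  for (mode in 1:6) {
    u <- matrix(0, 10, 3)
    if (mode <= 3) u[, mode] <- 1 else {
      rot <- c(0, 0, 0); rot[mode - 3] <- 1
      u <- cbind(rot[2] * X[, 3] - rot[3] * X[, 2],
                 rot[3] * X[, 1] - rot[1] * X[, 3],
                 rot[1] * X[, 2] - rot[2] * X[, 1])
    }
    expect_lt(max(abs(K %*% as.vector(t(u)))) / max(abs(K)), 1e-12)
  }
})

test_that("assembly is additive over element subsets", {
  bm <- mesh_box(c(1, 1, 1), pitch = 0.5)
  mat <- assign_materials(bm, default_materials())
  K <- assemble_stiffness(bm, mat)
  half <- seq_len(nrow(bm$elems) %/% 2)
  sub <- function(idx) {
    m2 <- bm; m2$elems <- bm$elems[idx, , drop = FALSE]
    m2$region <- bm$region[idx]
    assemble_stiffness(m2, list(E = mat$E[idx], nu = mat$nu[idx]))
  }
  K2 <- sub(half) + sub(setdiff(seq_len(nrow(bm$elems)), half))
  expect_lt(max(abs(K - K2)), 1e-9 * max(abs(K)))
})

test_that("patch test: uniform strain is reproduced to near machine precision", {
  bm <- mesh_box(c(2, 1, 1), pitch = 0.5)
  mat <- assign_materials(bm, default_materials(plate = 1000))
  X <- bm$nodes
  eps <- 0.01; nu <- 0.38
  U <- cbind(eps * X[, 1], -nu * eps * X[, 2], -nu * eps * X[, 3])
  bnd <- which(abs(X[, 1]) < 1e-9 | abs(X[, 1] - 2) < 1e-9 |
                 abs(X[, 2]) < 1e-9 | abs(X[, 2] - 1) < 1e-9 |
                 abs(X[, 3]) < 1e-9 | abs(X[, 3] - 1) < 1e-9)
  sol <- solve_fe(bm, mat, boundary_conditions(bc_prescribe(bnd, U[bnd, ])))
  expect_lt(max(abs(sol$U - U)) / max(abs(U)), 1e-10)
  st <- element_stresses(sol, bm, mat)
  lam <- 1000 * nu / ((1 + nu) * (1 - 2 * nu)); mu <- 1000 / (2 * (1 + nu))
  tr3 <- eps * (1 - 2 * nu)
  sxx <- lam * tr3 + 2 * mu * eps
  syy <- lam * tr3 - 2 * mu * nu * eps
  expect_lt(max(abs(st$gp[, c(1, 7, 13, 19)] - sxx)) / abs(sxx), 1e-10)
  expect_lt(max(abs(st$gp[, c(2, 8, 14, 20)] - syy)) / abs(sxx), 1e-10)
  expect_lt(max(abs(st$gp[, c(4, 10, 16, 22)])) / abs(sxx), 1e-10)
})

test_that("zero prescribed displacement yields zero solution and reactions", {
  bm <- mesh_box(c(1, 1, 1), pitch = 0.5)
  mat <- assign_materials(bm, default_materials())
  X <- bm$nodes
  bcs <- boundary_conditions(bc_fix(which(abs(X[, 1]) < 1e-9)),
                             bc_prescribe(which(abs(X[, 1] - 1) < 1e-9), c(0, 0, 0)))
  sol <- solve_fe(bm, mat, bcs)
  expect_lt(max(abs(sol$U)), 1e-14)
  expect_lt(max(abs(sol$reactions)), 1e-12)
})

test_that("under-constrained systems are rejected with an explicit error", {
  bm <- mesh_box(c(1, 1, 1), pitch = 0.5)
  mat <- assign_materials(bm, default_materials())
  one <- which(abs(bm$nodes[, 1]) < 1e-9)[1]
  expect_error(solve_fe(bm, mat, boundary_conditions(bc_fix(one))),
               "under-constrained")
})

test_that("cantilever tip reaction matches the Euler-Bernoulli closed form", {
  cf <- cantilever_fixture()
  Fy <- sum(cf$sol$reactions[cf$tip, 2])
  expect_rel(Fy, cf$P, 0.05)
  # solution linearity: doubling the tip displacement doubles the reaction
  bcs2 <- boundary_conditions(bc_fix(cf$clamp),
                              bc_prescribe(cf$tip, c(NA, 2 * cf$delta, NA)))
  sol2 <- solve_fe(cf$mesh, cf$mat, bcs2)
  expect_lt(max(abs(sol2$U - 2 * cf$sol$U)) / max(abs(sol2$U)), 1e-9)
})

test_that("global equilibrium of reactions holds for force and moment", {
  cf <- cantilever_fixture()
  res <- reaction_resultant(cf$sol, cf$mesh)
  scale <- max(abs(cf$sol$reactions))
  expect_lt(max(abs(res[1:3])), 1e-8 * scale)
  expect_lt(max(abs(res[4:6])), 1e-8 * scale * 30)
  res2 <- reaction_resultant(cf$sol, cf$mesh, about = c(5, 7, -3))
  expect_lt(max(abs(res2[4:6])), 1e-8 * scale * 30)
})

test_that("bending stress profile matches the beam extreme-fiber formula", {
  cf <- cantilever_fixture()
  st <- element_stresses(cf$sol, cf$mesh, cf$mat)
  sl <- section_loads(cf$sol, cf$mesh, cf$mat, cut_plane(cf$L / 2))
  I <- cf$w * cf$t^3 / 12
  sig_beam <- abs(sl[["Mz"]]) * (cf$t / 2) / I
  corners <- cf$mesh$elems[, 1:4]
  cx <- rowMeans(matrix(cf$mesh$nodes[corners, 1], nrow(corners), 4))
  cy <- rowMeans(matrix(cf$mesh$nodes[corners, 2], nrow(corners), 4))
  slab <- abs(cx - cf$L / 2) < 0.75 & (cy < 0.2 | cy > 0.8)
  sig_fe <- max(abs(st$mean[slab, 1]))
  # centroid stress extrapolated to the fiber: centroid of outer elements sits
  # at ~ +-(t/2 - h/2); compare on the same fiber
  y_c <- max(abs(cy[slab] - cf$t / 2))
  expect_rel(sig_fe, sig_beam * y_c / (cf$t / 2), 0.08)
})

test_that("tie groups move rigidly and transfer load through the construct", {
  fit <- unit_fit_coarse()
  expect_lt(fit$solution$residual, 1e-8)
  tq <- fit$solution$tie_motion
  expect_equal(nrow(tq), 4)
  # rigid motion: displacements of tie nodes equal the group's 6-DOF motion
  mesh <- fit$mesh
  nd <- mesh$node_sets$screw_tie_1
  ctr <- colMeans(mesh$nodes[nd, ])
  r <- sweep(mesh$nodes[nd, , drop = FALSE], 2, ctr)
  q <- tq[1, ]
  pred <- cbind(q["tx"] + q["ry"] * r[, 3] - q["rz"] * r[, 2],
                q["ty"] + q["rz"] * r[, 1] - q["rx"] * r[, 3],
                q["tz"] + q["rx"] * r[, 2] - q["ry"] * r[, 1])
  expect_lt(max(abs(fit$solution$U[nd, ] - pred)), 1e-10)
})

test_that("doubling all moduli doubles the section loads at fixed displacements", {
  geo <- metacarpal_construct()
  params <- mesh_params(scale_factor = 12)
  f1 <- unit_fit_coarse()
  spec2 <- default_materials(cortical = 30000, trabecular = 1000,
                             plate = 7200, screw = 220000)
  f2 <- unit_bending_solve(geo, params, materials_spec = spec2)
  expect_lt(max(abs(f2$loads - 2 * f1$loads)) / max(abs(f2$loads)), 1e-8)
})
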