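test_that("unit cube mesh conserves volume to machine precision", {
  bm <- mesh_box(c(1, 1, 1), pitch = 0.5)
  v <- osteoload:::tet10_volumes(bm$nodes, bm$elems)
  expect_true(all(v > 0))
  expect_lt(abs(sum(v) - 1), 1e-6)
})

test_that("mid-edge nodes sit at edge midpoints", {
  bm <- mesh_box(c(2, 1, 1), pitch = 0.6)
  ed <- osteoload:::TET_EDGES
  for (e in 1:6) {
    a <- bm$elems[, ed[e, 1]]; b <- bm$elems[, ed[e, 2]]
    mid <- bm$elems[, 4 + e]
    expect_lt(max(abs(bm$nodes[mid, ] - (bm$nodes[a, ] + bm$nodes[b, ]) / 2)), 1e-12)
  }
})

test_that("construct mesh conserves per-region volume within 2 percent", {
  mesh <- fixture("mesh6", function() {
    mesh_construct(metacarpal_construct(), mesh_params(scale_factor = 6))
  })
  mv <- mesh_volumes(mesh)
  av <- analytic_volumes(mesh$geometry)
  for (reg in names(av)) {
    expect_lt(abs(mv[[reg]] / av[[reg]] - 1), 0.02)
  }
})

test_that("element quality never falls below the scaled-Jacobian gate", {
  mesh <- fixture("mesh6", function() {
    mesh_construct(metacarpal_construct(), mesh_params(scale_factor = 6))
  })
  expect_gt(min(mesh_quality(mesh)), 0.05)
  expect_true(all(osteoload:::tet10_volumes(mesh$nodes, mesh$elems) > 0))
})

test_that("edge-length bounds scale with the desk-scale factor", {
  geo <- metacarpal_construct()
  p6 <- mesh_params(scale_factor = 6)
  mesh <- fixture("mesh6", function() mesh_construct(geo, p6))
  expect_lte(max(mesh_edge_lengths(mesh, "plate")), 0.25 * 6 + 1e-9)
  expect_lte(max(mesh_edge_lengths(mesh, c("cortical", "trabecular"))), 1 * 6 + 1e-9)
})

test_that("paper-scale refinement keeps all plate edges within 0.25 mm", {
  # scale_factor 1 reproduces the published refinement-region edge target
  mesh <- mesh_construct(metacarpal_construct(), mesh_params(scale_factor = 1),
                         ties = FALSE)
  expect_lte(max(mesh_edge_lengths(mesh, "plate")), 0.25 + 1e-9)
  expect_lte(max(mesh_edge_lengths(mesh, c("cortical", "trabecular"))), 1 + 1e-9)
  expect_gt(min(mesh_quality(mesh)), 0.05)
  mv <- mesh_volumes(mesh)
  av <- analytic_volumes(mesh$geometry)
  expect_lt(abs(mv[["plate"]] / av[["plate"]] - 1), 0.02)
})

test_that("materials assignment covers regions and applies the power law", {
  mesh <- fixture("mesh6", function() {
    mesh_construct(metacarpal_construct(), mesh_params(scale_factor = 6))
  })
  mat <- assign_materials(mesh, default_materials())
  expect_length(mat$E, nrow(mesh$elems))
  expect_true(all(mat$E > 0))
  expect_setequal(unique(mat$E[mesh$region == "plate"]), 3600)
  # region-constant homogeneous field
  expect_length(unique(mat$E[mesh$region == "cortical"]), 1)
  # power law at rho = 1 gives E = a for bone, leaves the plate alone
  pl <- assign_materials(mesh, power_law_materials(a = 6850, b = 1.49, density = 1))
  expect_setequal(unique(pl$E[mesh$region %in% c("cortical", "trabecular")]), 6850)
  expect_setequal(unique(pl$E[mesh$region == "plate"]), 3600)
  spec <- default_materials()
  spec$E$plate <- NULL
  expect_error(assign_materials(mesh, spec), "plate")
})

test_that("screw ties form four bicortical groups near their axes", {
  geo <- metacarpal_construct()
  mesh <- fixture("mesh6", function() mesh_construct(geo, mesh_params(scale_factor = 6)))
  sets <- grep("^screw_tie_", names(mesh$node_sets), value = TRUE)
  expect_length(sets, 4)
  ri <- geo$fragment_outer_radius - geo$cortical_thickness
  for (k in seq_along(sets)) {
    nd <- mesh$node_sets[[sets[k]]]
    d <- sqrt((mesh$nodes[nd, 1] - geo$screw_offsets[k])^2 + mesh$nodes[nd, 3]^2)
    expect_lte(max(d), geo$screw_diameter / 2 + 1e-6)
    r <- sqrt(mesh$nodes[nd, 2]^2 + mesh$nodes[nd, 3]^2)
    bone <- mesh$part[nd] %in% c("bone_proximal", "bone_distal")
    expect_true(any(bone & r >= ri - 1e-6 & mesh$nodes[nd, 2] > 0))
    expect_true(any(bone & r >= ri - 1e-6 & mesh$nodes[nd, 2] < 0))
    expect_true(any(mesh$part[nd] == "plate"))
  }
})

test_that("removing a screw removes its tie group", {
  geo <- metacarpal_construct(screw_offsets = c(-10, -5, 5))
  mesh <- mesh_construct(geo, mesh_params(scale_factor = 8))
  expect_length(grep("^screw_tie_", names(mesh$node_sets)), 3)
})

test_that("convergence checker enforces its preconditions and reports zero for identical levels", {
  expect_error(check_convergence(metacarpal_construct(),
                                 list(mesh_params(scale_factor = 8))),
               ">= 2")
})

test_that("boundary node sets exist and sit where they should", {
  geo <- metacarpal_construct()
  mesh <- fixture("mesh6", function() mesh_construct(geo, mesh_params(scale_factor = 6)))
  ns <- mesh$node_sets
  expect_true(all(c("pin_support", "applied_displacement",
                    "marker_proximal", "marker_distal") %in% names(ns)))
  x0 <- -(geo$gap_width / 2 + geo$fragment_length)
  expect_true(all(abs(mesh$nodes[ns$pin_support, 1] - x0) < 1e-8))
  expect_true(all(abs(mesh$nodes[ns$applied_displacement, 1] + x0) < 1e-8))
  expect_gt(length(ns$marker_proximal), 0)
  expect_gt(length(ns$marker_distal), 0)
  expect_true(all(mesh$nodes[ns$marker_distal, 1] > geo$plate_length / 2))
})
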