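# lazily built, session-cached fixtures shared across test files
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# coarse construct forward solve reused by synthetic/trajectory/safety tests
unit_fit_coarse <- function() {
  fixture("unit12", function() {
    unit_bending_solve(metacarpal_construct(), mesh_params(scale_factor = 12))
  })
}

# small plate-only cantilever (no holes) with its beam-theory constants
cantilever_fixture <- function() {
  fixture("cantilever", function() {
    L <- 24.25; t <- 1; w <- 4.25; E <- 3600
    mesh <- mesh_box(c(L, t, w), pitch = 0.25 * 3 / sqrt(3))
    mat <- assign_materials(mesh, default_materials(plate = E))
    X <- mesh$nodes
    clamp <- which(abs(X[, 1]) < 1e-9)
    tip <- which(abs(X[, 1] - L) < 1e-9)
    delta <- 0.1
    bcs <- boundary_conditions(bc_fix(clamp), bc_prescribe(tip, c(NA, delta, NA)))
    sol <- solve_fe(mesh, mat, bcs)
    list(mesh = mesh, mat = mat, sol = sol, L = L, t = t, w = w, E = E,
         delta = delta, tip = tip, clamp = clamp,
         P = 3 * E * (w * t^3 / 12) * delta / L^3)
  })
}

expect_rel <- function(got, want, tol) {
  expect_lt(abs(got - want) / abs(want), tol)
}
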