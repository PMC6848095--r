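# Closed-form validations of the corotational beam solver, plus the symmetry
# and conservation properties of the spine load case.

test_that("axial settlement matches the linear bar closed form", {
  mesh <- build_rod_mesh(straight_profile(), n_sub = 1)
  EA <- mesh$material$E * mesh$section$A
  F <- 1e-3 * EA
  loads <- point_loads(forces = tibble::tibble(node = 1L, fx = 0, fy = 0, fz = -F))
  sol <- solve_rod(mesh, loads, n_steps = 2)
  expect_equal(sol$displacement$uz[1], -F / EA, tolerance = 0.005)
})

test_that("cantilever tip deflection matches Euler-Bernoulli", {
  mesh <- build_rod_mesh(straight_profile(), n_sub = 1)
  EI <- mesh$material$E * mesh$section$I
  P <- 1e-3 * EI
  loads <- point_loads(forces = tibble::tibble(node = 1L, fx = 0, fy = P, fz = 0))
  sol <- solve_rod(mesh, loads, bcs = clamped_bcs(mesh, "bottom"), n_steps = 2)
  expect_equal(sol$displacement$uy[1], P / (3 * EI), tolerance = 0.01)
})

test_that("end twist matches the Saint-Venant closed form and scales with length", {
  mat <- rod_material()
  sec <- rod_section()
  GJ <- mat$G * sec$J
  Tq <- 1e-3 * GJ
  expect_identical(twist_angle_of_straight_rod(0), 0)
  expect_equal(twist_angle_of_straight_rod(Tq), Tq / GJ, tolerance = 0.01)
  expect_equal(twist_angle_of_straight_rod(Tq, length = 0.5),
               0.5 * Tq / GJ, tolerance = 0.01)
})

test_that("zero-torque solves of planar profiles stay exactly planar", {
  for (type in c("type1", "type2", "nonscoliotic")) {
    sol <- solve_archetype(type, default_config(), torque_scale = 0)
    in_plane <- max(abs(c(sol$displacement$uy, sol$displacement$uz)))
    expect_lte(max(abs(sol$displacement$ux)), 1e-10 * in_plane)
  }
})

test_that("flipping the torque sign mirrors the out-of-plane field", {
  cfg <- default_config()
  a <- cached_solution("type2")
  b <- solve_archetype("type2", cfg, torque_scale = -1)
  expect_equal(b$displacement$ux, -a$displacement$ux, tolerance = 1e-10)
  expect_equal(b$displacement$uy, a$displacement$uy, tolerance = 1e-10)
  expect_equal(b$displacement$uz, a$displacement$uz, tolerance = 1e-10)
})

test_that("the solution is objective under rigid rotation about Z", {
  cfg <- default_config()
  sol <- cached_solution("type2")
  alpha <- pi / 6
  R <- matrix(c(cos(alpha), sin(alpha), 0,
                -sin(alpha), cos(alpha), 0,
                0, 0, 1), 3, 3)
  prof <- generate_sagittal_profile(archetype_params("type2"))
  xyz <- as.matrix(prof[, c("x", "y", "z")]) %*% t(R)
  prof$x <- xyz[, 1]; prof$y <- xyz[, 2]; prof$z <- xyz[, 3]
  solR <- solve_archetype(prof, cfg)
  expect_equal(displacement_matrix(solR),
               displacement_matrix(sol) %*% t(R),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the converged solution is stable under load-step halving", {
  cfg <- default_config()
  cfg40 <- cfg
  cfg40$fe$n_steps <- 40L
  a <- cached_solution("type2")
  b <- solve_archetype("type2", cfg40)
  expect_lte(rel_diff(displacement_matrix(a), displacement_matrix(b)), 1e-6)
})

test_that("external work balances stored elastic energy at equilibrium", {
  for (type in c("type1", "type2")) {
    g <- glance(cached_solution(type))
    expect_gte(g$external_work, 0)
    expect_equal(g$external_work, g$elastic_energy, tolerance = 0.01)
  }
})

test_that("boundary conditions are satisfied exactly at constrained DOFs", {
  sol <- cached_solution("type1")
  n <- nrow(sol$displacement)
  expect_identical(sol$displacement$ux[n], 0)  # L5 fixed
  expect_identical(sol$displacement$uy[n], 0)
  expect_identical(sol$displacement$uz[n], 0)
  expect_identical(sol$displacement$ux[1], 0)  # T1 horizontal fix
  expect_identical(sol$displacement$uy[1], 0)
  expect_lt(sol$displacement$uz[1], 0)         # T1 settles vertically
})

test_that("deformation normalization scales to unit max vertical deformation", {
  sol <- cached_solution("type1")
  f <- normalize_deformation(sol)
  expect_equal(max(abs(f$uz)), 1)
  # halving example and idempotence
  field <- tibble::tibble(ux = c(0.2, 0.4), uy = c(0, 0.1), uz = c(-2, 1))
  half <- normalize_deformation(field)
  expect_equal(half$ux, c(0.1, 0.2))
  expect_equal(normalize_deformation(half), half)
  zero <- tibble::tibble(ux = 1, uy = 1, uz = 0)
  expect_error(normalize_deformation(zero), class = "spinerod_normalization_error")
})

test_that("invalid solver settings and unconstrained systems raise errors", {
  mesh <- build_rod_mesh(straight_profile(), n_sub = 1)
  loads <- point_loads(forces = tibble::tibble(node = 1L, fx = 0, fy = 0, fz = -1e-9))
  expect_error(solve_rod(mesh, loads, n_steps = 0), class = "spinerod_invalid_parameter")
  expect_error(solve_rod(mesh, loads, tol = -1), class = "spinerod_invalid_parameter")
  bad_bcs <- tibble::tibble(node = 999L, dof = "ux")
  expect_error(solve_rod(mesh, loads, bcs = bad_bcs), class = "spinerod_input_error")
})

test_that("tidy and glance views of a solution are consistent", {
  sol <- cached_solution("type3")
  td <- tidy(sol)
  expect_identical(nrow(td), nrow(sol$initial))
  expect_equal(td$x1 - td$x0, td$ux)
  g <- glance(sol)
  expect_true(g$converged)
  expect_identical(nrow(g), 1L)
})
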