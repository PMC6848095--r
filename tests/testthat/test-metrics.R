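test_that("global torsion vanishes on planar curves, including S-shapes", {
  prof <- generate_sagittal_profile(archetype_params("type1"))
  expect_lt(abs(global_torsion(prof)), 1e-10)
  arc <- tibble::tibble(x = 0, y = sin(seq(0, 1, length.out = 30)),
                        z = seq(0, 1, length.out = 30))
  expect_lt(abs(global_torsion(arc)), 1e-10)
})

test_that("global torsion matches the helix closed form and sign conventions", {
  a <- 1; b <- 0.3
  hel <- helix_curve(a, b, n = 100)
  expect_equal(global_torsion(hel), b / (a^2 + b^2), tolerance = 0.01)
  # chirality: mirroring X negates torsion
  mir <- hel
  mir$x <- -mir$x
  expect_equal(global_torsion(mir), -global_torsion(hel), tolerance = 1e-12)
  # left-handed helix is negative
  lh <- helix_curve(a, -b, n = 100)
  lh$z <- -lh$z
  expect_lt(global_torsion(hel) * global_torsion(mir), 0)
})

test_that("global torsion is rigid-motion invariant and scales as 1/s", {
  hel <- helix_curve(1, 0.3, n = 80)
  tau <- global_torsion(hel)
  alpha <- 0.7
  R <- matrix(c(cos(alpha), sin(alpha), 0, -sin(alpha), cos(alpha), 0, 0, 0, 1), 3, 3)
  rot <- as.data.frame(as.matrix(hel) %*% t(R))
  names(rot) <- c("x", "y", "z")
  rot$x <- rot$x + 5; rot$y <- rot$y - 2; rot$z <- rot$z + 1
  expect_equal(global_torsion(rot), tau, tolerance = 1e-10)
  s <- 2.5
  scaled <- hel; scaled$x <- s * hel$x; scaled$y <- s * hel$y; scaled$z <- s * hel$z
  expect_equal(global_torsion(scaled), tau / s, tolerance = 1e-10)
})

test_that("global torsion flags degenerate input", {
  line <- tibble::tibble(x = 0, y = 0, z = seq(0, 1, length.out = 10))
  out <- global_torsion(line)
  expect_identical(as.numeric(out), 0)
  expect_true(isTRUE(attr(out, "degenerate")))
  expect_error(global_torsion(line[1:3, ]), class = "spinerod_insufficient_data")
})

test_that("axial projection classifier separates line, loop and lemniscate", {
  expect_identical(classify_axial_projection(straight_profile()), "line")
  expect_identical(
    classify_axial_projection(generate_sagittal_profile(archetype_params("type1"))),
    "line"  # planar sagittal curve projects onto a line segment in axial view
  )
  arc <- generate_scoliotic_curve_3d("loop", 0.2)
  expect_identical(classify_axial_projection(arc), "loop")
  expect_identical(classify_axial_projection(gerono_curve()), "lemniscate")
  expect_error(classify_axial_projection(arc[1:4, ]),
               class = "spinerod_insufficient_data")
})

test_that("axial classification is invariant under Z-rotation and scaling", {
  for (curve in list(generate_scoliotic_curve_3d("loop", 0.15), gerono_curve())) {
    cls <- classify_axial_projection(curve)
    alpha <- 1.1
    rot <- curve
    rot$x <- cos(alpha) * curve$x - sin(alpha) * curve$y
    rot$y <- sin(alpha) * curve$x + cos(alpha) * curve$y
    expect_identical(classify_axial_projection(rot), cls)
    sc <- curve
    sc$x <- 3 * curve$x; sc$y <- 3 * curve$y; sc$z <- 3 * curve$z
    expect_identical(classify_axial_projection(sc), cls)
  }
})

test_that("twist counting matches constructed displacement fields", {
  s <- seq(0, 1, length.out = 33)
  base <- tibble::tibble(x = 0, y = 0, z = 1 - s)
  expect_identical(count_twists(base, base), 0L)
  bump <- base; bump$x <- 0.01 * sin(pi * s)          # single-signed bump
  expect_identical(count_twists(base, bump), 0L)
  full <- base; full$x <- 0.01 * sin(2 * pi * s)      # one interior zero
  expect_identical(count_twists(base, full), 1L)
  two <- base; two$x <- 0.01 * sin(3 * pi * s)        # two interior zeros
  expect_identical(count_twists(base, two), 2L)
  expect_error(count_twists(base, bump[1:10, ]), class = "spinerod_input_error")
})

test_that("displacement ratio handles trivial and degenerate cases", {
  s <- seq(0, 1, length.out = 21)
  ini <- tibble::tibble(x = 0, y = 0, z = 1 - s)
  planar <- ini; planar$y <- 0.01 * sin(pi * s)
  expect_identical(displacement_ratio(ini, planar), 0)
  equal <- ini; equal$x <- 0.01 * s; equal$y <- 0.01 * s
  expect_equal(displacement_ratio(ini, equal), 1)
  expect_error(displacement_ratio(ini, ini), class = "spinerod_undefined_ratio")
  # field interface
  f <- tibble::tibble(ux = c(1, 1), uy = c(2, 2))
  expect_equal(displacement_ratio(f), 0.5)
})

test_that("inflection detector flags profiles without a sign change", {
  expect_false(find_inflection(straight_profile())$has_inflection)
  # C-shaped: single-curvature arc
  cshape <- tibble::tibble(
    x = 0,
    y = 0.05 * sin(pi * seq(0, 1, length.out = 17)),
    z = seq(1, 0, length.out = 17)
  )
  expect_false(find_inflection(cshape)$has_inflection)
  expect_error(find_inflection(straight_profile(4)), class = "spinerod_insufficient_data")
})

test_that("shape metrics of a solved model are internally consistent", {
  sol <- cached_solution("type2")
  m <- shape_metrics(sol, run_id = "type2")
  expect_identical(m$run_id, "type2")
  expect_identical(m$kyphotic_len, 6L)
  expect_identical(m$lordotic_len, 11L)
  expect_identical(m$twist_count, count_twists(sol$initial, sol$deformed))
  expect_true(m$axial_class %in% c("line", "loop", "lemniscate"))
  expect_true(is.finite(m$tau_g))
})

test_that("writhe is zero for planar curves and flips under mirroring", {
  prof <- generate_sagittal_profile(archetype_params("type2"))
  expect_lt(abs(global_writhe(prof)), 1e-12)
  hel <- helix_curve(1, 0.3, n = 60)
  w <- global_writhe(hel)
  expect_gt(abs(w), 1e-4)
  mir <- hel; mir$x <- -mir$x
  expect_equal(global_writhe(mir), -w, tolerance = 1e-10)
  # rigid-motion invariance
  alpha <- 0.4
  rot <- hel
  rot$x <- cos(alpha) * hel$x - sin(alpha) * hel$y + 2
  rot$y <- sin(alpha) * hel$x + cos(alpha) * hel$y - 1
  expect_equal(global_writhe(rot), w, tolerance = 1e-10)
  expect_error(global_writhe(prof[1:3, ]), class = "spinerod_insufficient_data")
})
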