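test_that("generated sagittal profiles satisfy the normalization invariants", {
  for (type in c("type1", "type2", "type3", "type4", "type5", "nonscoliotic")) {
    prof <- generate_sagittal_profile(archetype_params(type))
    expect_identical(nrow(prof), 17L)
    expect_identical(prof$level[1], "T1")
    expect_identical(prof$level[17], "L5")
    expect_true(all(diff(prof$z) < 0))            # Z decreasing T1 -> L5
    expect_equal(diff(range(prof$z)), 1)          # unit height, exact
    expect_true(all(prof$x == 0))                 # planar sagittal curve
    expect_equal(prof$y[17], 0)                   # L5 at the origin
  }
})

test_that("profile generation is deterministic and jitter is seed-stable", {
  p <- sagittal_params(6, 11, noise_sd = 0.005, seed = 7)
  a <- generate_sagittal_profile(p)
  b <- generate_sagittal_profile(p)
  expect_identical(a, b)
  p2 <- sagittal_params(6, 11, noise_sd = 0.005, seed = 8)
  expect_false(identical(generate_sagittal_profile(p2), a))
})

test_that("zero amplitudes give a straight vertical unit segment", {
  prof <- generate_sagittal_profile(sagittal_params(6, 11, 0, 0))
  expect_true(all(prof$y == 0))
  expect_true(all(prof$x == 0))
  expect_equal(diff(range(prof$z)), 1)
  expect_false(find_inflection(prof)$has_inflection)
})

test_that("segment structure is recovered exactly by the inflection detector", {
  # property sweep: generator/detector round trip over the kyphotic range
  for (k in 4:13) {
    p <- sagittal_params(k, 17L - k,
                         kyphosis_amplitude = 0.04, lordosis_amplitude = 0.04)
    r <- find_inflection(generate_sagittal_profile(p))
    expect_identical(r$kyphotic_len, as.integer(k))
    expect_identical(r$lordotic_len, as.integer(17L - k))
  }
})

test_that("Group II archetype has the long-kyphosis structure", {
  r <- find_inflection(generate_sagittal_profile(archetype_params("type1")))
  expect_identical(r$kyphotic_len, 12L)
  expect_identical(r$lordotic_len, 5L)
  r2 <- find_inflection(generate_sagittal_profile(archetype_params("nonscoliotic")))
  expect_identical(r2$kyphotic_len, 13L)
  expect_identical(r2$lordotic_len, 4L)
})

test_that("invalid profile parameters are rejected", {
  expect_error(sagittal_params(2, 2, n_levels = 4), class = "spinerod_invalid_parameter")
  expect_error(sagittal_params(6, 12), class = "spinerod_invalid_parameter")
  expect_error(sagittal_params(6, 11, kyphosis_amplitude = -1),
               class = "spinerod_invalid_parameter")
  expect_error(generate_sagittal_profile(sagittal_params(6, 11, 5, 5)),
               class = "spinerod_degenerate_geometry")
})

test_that("profile interpolation is an exact convex combination", {
  a <- generate_sagittal_profile(archetype_params("type2"))
  b <- generate_sagittal_profile(archetype_params("type1"))
  expect_equal(interpolate_profiles(a, b, 0)$y, a$y, tolerance = 1e-12)
  expect_equal(interpolate_profiles(a, b, 1)$y, b$y, tolerance = 1e-12)
  mid <- interpolate_profiles(a, b, 0.5)
  expect_equal(diff(range(mid$z)), 1)
  # inflection of the midpoint lies between the parents' inflection levels
  ia <- find_inflection(a)$inflection_level
  ib <- find_inflection(b)$inflection_level
  im <- find_inflection(mid)$inflection_level
  expect_gte(im, min(ia, ib))
  expect_lte(im, max(ia, ib))
  expect_error(interpolate_profiles(a, b, 1.5), class = "spinerod_invalid_parameter")
})

test_that("load tables conserve the total load and honor each scheme", {
  u <- make_load_table(17, 1, "uniform")
  expect_equal(u$force, rep(1 / 17, 17))
  r <- make_load_table(17, 1, "linear-ramp")
  expect_equal(sum(r$force), 1, tolerance = 1e-15)
  expect_equal(r$force[17] / r$force[1], 17)
  a <- make_load_table(17, 2, "anthropometric")
  expect_equal(sum(a$force), 2, tolerance = 1e-12)
  expect_true(all(diff(a$force) >= 0))   # superincumbent weight grows caudally
  expect_true(all(a$force > 0))
  # documented fraction profile: ~9% at T1 to ~47% at L5 before normalization
  expect_equal(a$fraction[17] / a$fraction[1], 47 / 9, tolerance = 1e-9)
  expect_error(make_load_table(17, -1), class = "spinerod_invalid_parameter")
  expect_error(make_load_table(17, 1, "bogus"), class = "spinerod_configuration_error")
})

test_that("synthetic 3D archetype curves classify as constructed", {
  expect_identical(classify_axial_projection(generate_scoliotic_curve_3d("loop", 0.1)),
                   "loop")
  expect_identical(classify_axial_projection(generate_scoliotic_curve_3d("lemniscate", 0.1)),
                   "lemniscate")
  expect_identical(classify_axial_projection(generate_scoliotic_curve_3d("loop", 0)),
                   "line")
  expect_error(generate_scoliotic_curve_3d("loop", -0.1),
               class = "spinerod_invalid_parameter")
})

test_that("synthetic cohorts are reproducible and normalized", {
  a <- generate_curve_cohort(n_per_type = 3, noise_sd = 0.01, seed = 11)
  b <- generate_curve_cohort(n_per_type = 3, noise_sd = 0.01, seed = 11)
  expect_identical(a, b)
  expect_identical(length(unique(a$curve_id)), 15L)
  heights <- tapply(a$z, a$curve_id, function(z) diff(range(z)))
  expect_equal(as.numeric(heights), rep(1, 15), tolerance = 1e-12)
})
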