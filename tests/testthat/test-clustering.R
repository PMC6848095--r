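test_that("isotropic normalization is a similarity transform", {
  curve <- generate_scoliotic_curve_3d("loop", 0.2)
  doubled <- curve
  doubled$x <- 2 * curve$x + 1
  doubled$y <- 2 * curve$y - 3
  doubled$z <- 2 * curve$z + 0.5
  norm <- isotropic_normalize(doubled)
  expect_equal(diff(range(norm$z)), 1)
  expect_equal(norm$x[which.min(norm$z)], 0)
  # already-normalized curves are unchanged
  expect_equal(as.data.frame(isotropic_normalize(norm)), as.data.frame(norm),
               tolerance = 1e-14)
  # inter-landmark distance ratios preserved
  d0 <- as.matrix(dist(curve[, c("x", "y", "z")]))
  d1 <- as.matrix(dist(norm[, c("x", "y", "z")]))
  ratio <- d1[lower.tri(d1)] / d0[lower.tri(d0)]
  expect_lt(diff(range(ratio)), 1e-12)
  flat <- curve; flat$z <- 0
  expect_error(isotropic_normalize(flat), class = "spinerod_degenerate_geometry")
})

make_two_family_cohort <- function(n_each = 20, noise_sd = 0.005) {
  rows <- c(
    lapply(seq_len(n_each), function(i) {
      dplyr::mutate(
        generate_scoliotic_curve_3d("loop", 0.1, seed = i, noise_sd = noise_sd),
        curve_id = sprintf("loop_%02d", i), type = "loop"
      )
    }),
    lapply(seq_len(n_each), function(i) {
      dplyr::mutate(
        generate_scoliotic_curve_3d("lemniscate", 0.1, seed = 100 + i, noise_sd = noise_sd),
        curve_id = sprintf("lem_%02d", i), type = "lemniscate"
      )
    })
  )
  dplyr::bind_rows(rows)
}

test_that("well-separated families are recovered perfectly at k = 2", {
  cohort <- make_two_family_cohort()
  cl <- cluster_curves(cohort, k = 2, seed = 7)
  expect_equal(label_agreement(cl$labels$cluster, cl$labels$type), 1)
})

test_that("identical curves collapse to a single cluster with zero inertia", {
  one <- generate_scoliotic_curve_3d("loop", 0.1)
  cohort <- dplyr::bind_rows(lapply(1:5, function(i) {
    dplyr::mutate(one, curve_id = paste0("c", i))
  }))
  cl <- cluster_curves(cohort, k = 1, seed = 1)
  expect_identical(unique(cl$labels$cluster), 1L)
  expect_equal(cl$inertia, 0)
})

test_that("permuting cohort order permutes labels consistently", {
  cohort <- make_two_family_cohort(n_each = 10)
  cl1 <- cluster_curves(cohort, k = 2, seed = 3)
  ids <- unique(cohort$curve_id)
  shuffled <- cohort[order(match(cohort$curve_id, rev(ids))), ]
  cl2 <- cluster_curves(shuffled, k = 2, seed = 3)
  merged <- dplyr::left_join(cl1$labels, cl2$labels, by = "curve_id",
                             suffix = c("_a", "_b"))
  # same partition: the label pairing is a bijection
  tab <- table(merged$cluster_a, merged$cluster_b)
  expect_identical(sum(tab > 0), 2L)
})

test_that("inertia is non-increasing in k on a fixed cohort and seed", {
  cohort <- generate_curve_cohort(n_per_type = 8, noise_sd = 0.02, seed = 5)
  inertias <- vapply(1:6, function(k) {
    cluster_curves(cohort, k = k, seed = 9)$inertia
  }, numeric(1))
  expect_true(all(diff(inertias) <= 1e-8))
})

test_that("clustering is a fixed point when initialized at its own centers", {
  cohort <- make_two_family_cohort(n_each = 12)
  cl <- cluster_curves(cohort, k = 2, seed = 21)
  centers <- do.call(rbind, lapply(split(cl$centers, cl$centers$cluster),
                                   function(df) c(df$x, df$y, df$z)))
  cl2 <- cluster_curves(cohort, k = 2, seed = 21, init = centers)
  expect_identical(cl$labels$cluster, cl2$labels$cluster)
})

test_that("the five-type synthetic cohort is recovered at k = 5", {
  cohort <- generate_curve_cohort(n_per_type = 25, noise_sd = 0.01, seed = 1)
  cl <- cluster_curves(cohort, k = 5, seed = 42)
  expect_gte(label_agreement(cl$labels$cluster, cl$labels$type), 0.95)
})

test_that("clustering rejects invalid inputs", {
  cohort <- make_two_family_cohort(n_each = 3)
  expect_error(cluster_curves(cohort, k = 0), class = "spinerod_invalid_parameter")
  expect_error(cluster_curves(cohort, k = 100), class = "spinerod_invalid_parameter")
  ragged <- dplyr::bind_rows(cohort, cohort[1:3, ])
  expect_error(cluster_curves(ragged, k = 2), class = "spinerod_input_error")
})

test_that("label agreement is permutation-maximal", {
  expect_equal(label_agreement(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  expect_equal(label_agreement(c(1, 2, 1, 2), c("a", "a", "b", "b")), 0.5)
})
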