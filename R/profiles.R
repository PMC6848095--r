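#' Parameter set for a synthetic sagittal spine profile
#'
#' Bundles the knobs of the two-arc sagittal profile generator: the number of
#' vertebral levels, how many of them belong to the kyphotic (upper, thoracic)
#' versus lordotic (lower, thoraco-lumbar) segment, the peak sagittal offsets of
#' the two arcs, optional per-landmark jitter, and the RNG seed.
#'
#' The generated curve lives in the sagittal (Y--Z) plane with Z up, the L5
#' centroid at the origin and unit height, and has a vertical tangent at L5
#' (zero sacral slope).  Curvature changes sign exactly once, midway between
#' the last kyphotic and first lordotic vertebra.
#'
#' @param kyphotic_len Number of vertebrae in the kyphotic (cranial) segment.
#' @param lordotic_len Number of vertebrae in the lordotic (caudal) segment.
#'   Must satisfy `kyphotic_len + lordotic_len == n_levels`.
#' @param kyphosis_amplitude,lordosis_amplitude Peak sagittal offsets of the
#'   two arcs, as fractions of the (unit) height.  Both zero gives a straight
#'   vertical profile.
#' @param n_levels Number of vertebral levels (default 17, T1--L5).
#' @param noise_sd Standard deviation of Gaussian jitter added to the sagittal
#'   (Y) coordinate of each landmark, in height units.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param group_tag Label attached to generated profiles.
#'
#' @return An object of class `sagittal_params` (a named list).
#' @export
#' @examples
#' p <- sagittal_params(kyphotic_len = 6, lordotic_len = 11)
#' generate_sagittal_profile(p)
sagittal_params <- function(kyphotic_len,
                            lordotic_len,
                            kyphosis_amplitude = 0.08,
                            lordosis_amplitude = 0.04,
                            n_levels = 17L,
                            noise_sd = 0,
                            seed = 1L,
                            group_tag = "Custom") {
  n_levels <- as.integer(n_levels)
  if (n_levels < 5L) {
    stop_spinerod("`n_levels` must be at least 5", "spinerod_invalid_parameter")
  }
  if (kyphotic_len + lordotic_len != n_levels) {
    stop_spinerod(
      "`kyphotic_len + lordotic_len` must equal `n_levels`",
      "spinerod_invalid_parameter"
    )
  }
  if (kyphotic_len < 1L || lordotic_len < 1L) {
    stop_spinerod("segment lengths must be positive", "spinerod_invalid_parameter")
  }
  if (kyphosis_amplitude < 0 || lordosis_amplitude < 0 || noise_sd < 0) {
    stop_spinerod(
      "amplitudes and `noise_sd` must be non-negative",
      "spinerod_invalid_parameter"
    )
  }
  structure(
    list(
      n_levels = n_levels,
      kyphotic_len = as.integer(kyphotic_len),
      lordotic_len = as.integer(lordotic_len),
      kyphosis_amplitude = kyphosis_amplitude,
      lordosis_amplitude = lordosis_amplitude,
      # index (from T1) of the curvature sign change, halfway between the last
      # kyphotic and first lordotic vertebra
      inflection_level = kyphotic_len + 0.5,
      noise_sd = noise_sd,
      seed = as.integer(seed),
      group_tag = group_tag
    ),
    class = "sagittal_params"
  )
}

# Closed-form two-arc sagittal shape: curvature is a positive sine bump on the
# lordotic (lower) span and a negative sine bump on the kyphotic (upper) span,
# vanishing at the join, integrated twice with y(0) = y'(0) = 0 at L5 (zero
# sacral slope).  The curve runs anterior (+Y) below the inflection, peaking
# at `a_l` there, then bends back, crosses the vertical plumb line through L5
# inside the kyphotic segment, and ends with T1 posterior to L5 by `a_k` --
# the two-sided S of a sagittal spine profile.  The kyphotic curvature scale
# is set so y(1) = -a_k exactly.
sagittal_shape_fun <- function(z_inf, a_l, a_k) {
  h <- 1 - z_inf
  c_l <- if (z_inf > 0) pi * a_l / z_inf^2 else 0
  yp_inf <- if (z_inf > 0) 2 * a_l / z_inf else 0
  c_k <- if (h > 0) pi * (a_l + yp_inf * h + a_k) / h^2 else 0
  y_inf <- a_l
  function(z) {
    ifelse(
      z <= z_inf,
      (c_l * z_inf / pi) * (z - (z_inf / pi) * sin(pi * z / z_inf)),
      {
        xi <- (z - z_inf) / h
        y_inf + yp_inf * h * xi - (c_k * h^2 / pi) * (xi - sin(pi * xi) / pi)
      }
    )
  }
}

#' Generate a planar S-shaped sagittal spine profile
#'
#' Builds the vertebral-centroid centerline of a sagittal spine curve from a
#' [sagittal_params()] specification: two smooth arcs of opposite curvature
#' sign joined C1 at the inflection level, isotropically normalized to unit
#' height, planar in the Y--Z plane (X identically zero), with rows ordered
#' cranial (T1) to caudal (L5) and Z decreasing down the rows.
#'
#' With `noise_sd = 0` the output is deterministic; with jitter the profile is
#' re-normalized after perturbation so the height is exactly 1.
#'
#' @param params A [sagittal_params()] object.
#' @return A tibble with columns `level`, `x`, `y`, `z` and a `group` column.
#' @export
generate_sagittal_profile <- function(params) {
  stopifnot(inherits(params, "sagittal_params"))
  n <- params$n_levels
  z <- 1 - (seq_len(n) - 1) / (n - 1)  # T1 at z = 1 down to L5 at z = 0
  z_inf <- 1 - (params$kyphotic_len - 0.5) / (n - 1)
  shape <- sagittal_shape_fun(z_inf, params$lordosis_amplitude, params$kyphosis_amplitude)
  y <- shape(z)
  if (max(abs(y)) > 0.5) {
    stop_spinerod(
      "amplitudes produce a degenerate (implausibly wide) sagittal curve",
      "spinerod_degenerate_geometry"
    )
  }
  if (params$noise_sd > 0) {
    set.seed(params$seed)
    y <- y + rnorm(n, sd = params$noise_sd)
  }
  prof <- tibble::tibble(
    level = vertebral_levels(n),
    x = 0,
    y = y,
    z = z,
    group = params$group_tag
  )
  isotropic_normalize(prof)
}

#' Interpolate between two sagittal profiles
#'
#' Per-level convex combination `(1 - t) * a + t * b`, re-normalized to unit
#' height.  Used to populate the space of S-shaped curves between the subtype
#' archetypes for sensitivity analyses.
#'
#' @param a,b Profiles with identical level counts (tibbles with x, y, z).
#' @param t Interpolation weight in `[0, 1]`.
#' @return A tibble like `a`, tagged `Interpolated`.
#' @export
interpolate_profiles <- function(a, b, t) {
  check_curve_frame(a, "a")
  check_curve_frame(b, "b")
  if (nrow(a) != nrow(b)) {
    stop_spinerod("profiles must have the same number of levels", "spinerod_input_error")
  }
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 1) {
    stop_spinerod("`t` must be a single number in [0, 1]", "spinerod_invalid_parameter")
  }
  out <- tibble::tibble(
    level = if ("level" %in% names(a)) a$level else vertebral_levels(nrow(a)),
    x = (1 - t) * a$x + t * b$x,
    y = (1 - t) * a$y + t * b$y,
    z = (1 - t) * a$z + t * b$z,
    group = "Interpolated"
  )
  isotropic_normalize(out)
}

#' Isotropically normalize a centerline curve
#'
#' Applies the similarity transform used throughout: translate so the caudal
#' (lowest-Z) landmark sits at the origin, then scale X, Y and Z by the same
#' factor so the height (Z extent) is exactly 1.  Ratios of inter-landmark
#' distances are preserved.
#'
#' @param curve Data frame with columns `x`, `y`, `z`.
#' @return The normalized curve, same columns.
#' @export
isotropic_normalize <- function(curve) {
  check_curve_frame(curve)
  h <- curve_height(curve)
  if (h <= 0) {
    stop_spinerod("curve has zero height; cannot normalize", "spinerod_degenerate_geometry")
  }
  bottom <- which.min(curve$z)
  out <- curve
  out$x <- (curve$x - curve$x[bottom]) / h
  out$y <- (curve$y - curve$y[bottom]) / h
  out$z <- (curve$z - curve$z[bottom]) / h
  tibble::as_tibble(out)
}

#' Per-vertebral-level gravitational load table
#'
#' Distributes a total vertical load over the vertebral levels.  The
#' `anthropometric` scheme (default in the pipeline) makes the force at each
#' level proportional to the superincumbent trunk-weight fraction carried at
#' that level -- rising monotonically from about 9% of body weight at T1 to
#' about 47% at L5, a smooth fit to published trunk-segment data used in spine
#' finite-element loading.  `uniform` and `linear-ramp` are provided for
#' sensitivity checks.
#'
#' @param n_levels Number of vertebral levels.
#' @param total_load Total downward force (model units); must be positive.
#' @param scheme One of `"uniform"`, `"linear-ramp"`, `"anthropometric"`.
#' @return A tibble with columns `level`, `fraction`, `force`; forces sum to
#'   `total_load` exactly and are non-decreasing cranio-caudally.
#' @export
make_load_table <- function(n_levels = 17L,
                            total_load = 1,
                            scheme = c("anthropometric", "uniform", "linear-ramp")) {
  if (!is.numeric(total_load) || total_load <= 0) {
    stop_spinerod("`total_load` must be positive", "spinerod_invalid_parameter")
  }
  if (is.character(scheme) && length(scheme) == 1L &&
      !scheme %in% c("anthropometric", "uniform", "linear-ramp")) {
    stop_spinerod(
      sprintf("unknown load scheme '%s'", scheme),
      "spinerod_configuration_error"
    )
  }
  scheme <- match.arg(scheme)
  n <- as.integer(n_levels)
  w <- switch(scheme,
    uniform = rep(1, n),
    `linear-ramp` = seq_len(n),
    anthropometric = {
      # superincumbent trunk-weight percentage at 17 reference levels T1..L5,
      # interpolated if a different level count is requested
      ref <- seq(9, 47, length.out = 17)
      if (n == 17L) ref else stats::approx(seq(0, 1, length.out = 17), ref,
                                           xout = seq(0, 1, length.out = n))$y
    }
  )
  frac <- w / sum(w)
  tibble::tibble(
    level = vertebral_levels(n),
    fraction = frac,
    force = total_load * frac
  )
}

#' Generate a 3D test curve with a loop or lemniscate axial projection
#'
#' Constructs synthetic 3D centerlines whose top-view (X--Y) projection is,
#' by design, either a single-signed-curvature arc (`loop`) or a self-crossing
#' figure-eight (`lemniscate`).  These serve as fixtures for the axial-shape
#' classifier and for clustering experiments; they are not finite-element
#' output.
#'
#' @param archetype `"loop"` or `"lemniscate"`.
#' @param amplitude Lateral amplitude of the axial projection (height units).
#'   Zero gives a straight vertical line.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param n_levels Number of landmarks.
#' @param noise_sd Gaussian jitter on X and Y per landmark.
#' @return A tibble with columns `level`, `x`, `y`, `z` (unit height).
#' @export
generate_scoliotic_curve_3d <- function(archetype = c("loop", "lemniscate"),
                                        amplitude,
                                        seed = 1L,
                                        n_levels = 17L,
                                        noise_sd = 0) {
  archetype <- match.arg(archetype)
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop_spinerod("`amplitude` must be non-negative", "spinerod_invalid_parameter")
  }
  n <- as.integer(n_levels)
  t <- (seq_len(n) - 1) / (n - 1)
  if (archetype == "loop") {
    x <- amplitude * sin(pi * t)
    y <- amplitude * (1 - cos(pi * t))
  } else {
    x <- amplitude * sin(2 * pi * t)
    y <- (amplitude / 2) * sin(4 * pi * t)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + rnorm(n, sd = noise_sd)
    y <- y + rnorm(n, sd = noise_sd)
  }
  tibble::tibble(
    level = vertebral_levels(n),
    x = x,
    y = y,
    z = 1 - t
  )
}

#' Generate a labelled synthetic cohort of 3D spinal centerlines
#'
#' Builds `n_per_type` noisy copies of each of the five subtype archetypes
#' (sagittal profile plus a type-specific axial deviation: loops for the
#' Group I stand-ins, lemniscates for Group II) for clustering experiments
#' with known ground truth.
#'
#' @param n_per_type Curves per subtype.
#' @param noise_sd Per-landmark Gaussian jitter (height units).
#' @param seed RNG seed.
#' @return A tibble with columns `curve_id`, `type`, `level`, `x`, `y`, `z`,
#'   each curve isotropically normalized.
#' @export
generate_curve_cohort <- function(n_per_type = 25L, noise_sd = 0.01, seed = 1L) {
  types <- paste0("type", 1:5)
  set.seed(seed)
  rows <- purrr::imap(
    stats::setNames(types, types),
    function(type, nm) {
      arch <- archetype_table()[[type]]
      prof <- generate_sagittal_profile(archetype_params(type))
      axial <- generate_scoliotic_curve_3d(
        archetype = arch$axial,
        amplitude = arch$axial_amplitude,
        n_levels = nrow(prof)
      )
      purrr::map(seq_len(n_per_type), function(i) {
        tibble::tibble(
          curve_id = sprintf("%s_%02d", type, i),
          type = type,
          level = prof$level,
          x = axial$x + rnorm(nrow(prof), sd = noise_sd),
          y = prof$y + axial$y + rnorm(nrow(prof), sd = noise_sd),
          z = prof$z
        )
      })
    }
  )
  cohort <- dplyr::bind_rows(purrr::flatten(rows))
  cohort |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::group_modify(function(df, key) isotropic_normalize(df)) |>
    dplyr::ungroup()
}
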