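#' Material properties of the rod
#'
#' Linear isotropic elasticity for the slender-rod model.  Defaults follow the
#' study conditions: Young's modulus 1000 (pressure, model units) and Poisson
#' ratio 0.3; the shear modulus is derived as `G = E / (2 (1 + nu))`.
#'
#' @param young_modulus Young's modulus `E > 0`.
#' @param poisson_ratio Poisson ratio `0 <= nu < 0.5`.
#' @return A list with `E`, `nu`, `G`.
#' @export
rod_material <- function(young_modulus = 1000, poisson_ratio = 0.3) {
  if (young_modulus <= 0) {
    stop_spinerod("`young_modulus` must be positive", "spinerod_invalid_parameter")
  }
  if (poisson_ratio < 0 || poisson_ratio >= 0.5) {
    stop_spinerod("`poisson_ratio` must be in [0, 0.5)", "spinerod_invalid_parameter")
  }
  list(
    E = young_modulus,
    nu = poisson_ratio,
    G = young_modulus / (2 * (1 + poisson_ratio))
  )
}

#' Circular cross-section of the rod
#'
#' @param radius Section radius (length units, default `1e-3` for the
#'   unit-height rod).
#' @return A list with `radius`, area `A`, bending second moment `I`, and
#'   Saint-Venant torsion constant `J` of the circular section.
#' @export
rod_section <- function(radius = 1e-3) {
  if (radius <= 0) {
    stop_spinerod("`radius` must be positive", "spinerod_invalid_parameter")
  }
  list(
    radius = radius,
    A = pi * radius^2,
    I = pi * radius^4 / 4,
    J = pi * radius^4 / 2
  )
}

#' Discretize a profile into a rod finite-element mesh
#'
#' Interpolates the vertebral-centroid profile with natural cubic splines in
#' the profile's Z parameter and subdivides every vertebral interval into
#' `n_sub` two-node beam elements, so the mesh has
#' `1 + n_sub * (n_levels - 1)` nodes.  Each vertebral level maps to exactly
#' one mesh node (recorded in the `level` column of `$nodes`), where the
#' per-level gravity loads are applied.
#'
#' @param profile Centerline tibble with columns `x`, `y`, `z` (and optionally
#'   `level`), rows ordered cranial to caudal.
#' @param n_sub Elements per vertebral interval (`>= 1`).
#' @param material A [rod_material()].
#' @param section A [rod_section()].
#' @return An object of class `rod_mesh`: nodes tibble (`node`, `level`, `x`,
#'   `y`, `z`), element rest lengths, vertebral node index map, material and
#'   section.
#' @export
build_rod_mesh <- function(profile, n_sub = 4L,
                           material = rod_material(),
                           section = rod_section()) {
  check_curve_frame(profile, "profile")
  n_sub <- as.integer(n_sub)
  if (n_sub < 1L) {
    stop_spinerod("`n_sub` must be at least 1", "spinerod_invalid_parameter")
  }
  n_lev <- nrow(profile)
  dz <- diff(profile$z)
  dd <- sqrt(diff(profile$x)^2 + diff(profile$y)^2 + dz^2)
  if (any(dd <= 0)) {
    stop_spinerod("profile contains co-located points", "spinerod_degenerate_geometry")
  }
  # monotone curve parameter: use z if strictly monotone, else chord length
  if (all(dz < 0) || all(dz > 0)) {
    s_lev <- profile$z
  } else {
    s_lev <- cumsum(c(0, dd))
  }
  fx <- stats::splinefun(s_lev, profile$x, method = "natural")
  fy <- stats::splinefun(s_lev, profile$y, method = "natural")
  fz <- stats::splinefun(s_lev, profile$z, method = "natural")

  s_nodes <- unlist(purrr::map(seq_len(n_lev - 1L), function(i) {
    seq(s_lev[i], s_lev[i + 1L], length.out = n_sub + 1L)[-(n_sub + 1L)]
  }))
  s_nodes <- c(s_nodes, s_lev[n_lev])
  lev_map <- 1L + (seq_len(n_lev) - 1L) * n_sub

  lev_col <- rep(NA_character_, length(s_nodes))
  lev_col[lev_map] <- if ("level" %in% names(profile)) profile$level else vertebral_levels(n_lev)

  nodes <- tibble::tibble(
    node = seq_along(s_nodes),
    level = lev_col,
    x = fx(s_nodes),
    y = fy(s_nodes),
    z = fz(s_nodes)
  )
  rest <- sqrt(diff(nodes$x)^2 + diff(nodes$y)^2 + diff(nodes$z)^2)

  structure(
    list(
      nodes = nodes,
      rest_lengths = rest,
      level_nodes = stats::setNames(lev_map, lev_col[lev_map]),
      n_sub = n_sub,
      spline = list(fx = fx, fy = fy, fz = fz, s_levels = s_lev),
      material = material,
      section = section
    ),
    class = "rod_mesh"
  )
}

#' Total arc length of a rod mesh
#'
#' Sum of element rest lengths (the polyline length of the discretized
#' spline).
#'
#' @param mesh A [build_rod_mesh()] result.
#' @return Arc length (height units).
#' @export
rod_arc_length <- function(mesh) {
  sum(mesh$rest_lengths)
}

#' @export
print.rod_mesh <- function(x, ...) {
  cat(sprintf(
    "<rod_mesh> %d nodes, %d elements, arc length %.6f, E = %g, r = %g\n",
    nrow(x$nodes), nrow(x$nodes) - 1L, rod_arc_length(x),
    x$material$E, x$section$radius
  ))
  invisible(x)
}
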