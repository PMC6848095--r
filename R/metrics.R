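cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Global geometric torsion of a 3D centerline
#'
#' Arc-length-weighted mean of the discrete Frenet torsion of a polyline:
#' for each interior quadruple of points the binormals of the two adjacent
#' osculating planes are compared, the signed rotation angle about the shared
#' tangent (right-handed convention) is accumulated, and the total is divided
#' by the arc length covered.  A planar curve has global torsion zero; a
#' right-handed circular helix `(a cos t, a sin t, b t)` has global torsion
#' `b / (a^2 + b^2)`.
#'
#' Joints whose discrete curvature is small contribute zero: torsion is
#' undefined where the curve is straight, and near a curvature sign change
#' (the sagittal inflection of an S-curve) the binormal of a nearly planar
#' curve flips by pi, which would otherwise swamp the metric with an
#' artifact of the planar limit.  The dead band is `kappa_rel` times the
#' median discrete curvature of the curve (so it adapts to the curve's
#' scale), with an absolute floor of `kappa_min` per unit height.
#' `kappa_rel = 0.2` is the smallest value that fully removes the
#' inflection-flip artifact on planar S-shaped test profiles; results are
#' stable for dead bands between 0.2 and 0.5.
#'
#' @param curve Data frame with columns `x`, `y`, `z` (ordered points); at
#'   least 4 points required.
#' @param kappa_rel Relative curvature dead band, as a fraction of the median
#'   discrete curvature (default 0.2).
#' @param kappa_min Absolute curvature floor, per unit height (default `1e-6`).
#' @return Signed scalar, units 1/length.  A fully collinear (or effectively
#'   planar-straight) curve returns 0 with attribute `degenerate = TRUE`.
#' @export
global_torsion <- function(curve, kappa_rel = 0.2, kappa_min = 1e-6) {
  check_curve_frame(curve)
  P <- as.matrix(curve[, c("x", "y", "z")])
  n <- nrow(P)
  if (n < 4L) {
    stop_spinerod("global torsion needs at least 4 points", "spinerod_insufficient_data")
  }
  seg <- diff(P)
  seg_len <- sqrt(rowSums(seg^2))
  height <- max(dist_span(P), .Machine$double.eps)

  # discrete curvature at interior joints 2..n-1
  binormals <- vector("list", n - 2L)
  kappa <- numeric(n - 2L)
  for (j in 2:(n - 1L)) {
    b <- cross3(seg[j - 1L, ], seg[j, ])
    binormals[[j - 1L]] <- b
    kappa[j - 1L] <- 2 * sqrt(sum(b^2)) /
      (seg_len[j - 1L] * seg_len[j] * (seg_len[j - 1L] + seg_len[j]))
  }
  kmin <- max(kappa_rel * stats::median(kappa), kappa_min / height)

  num <- 0
  den <- 0
  degenerate <- TRUE
  for (i in 2:(n - 2L)) {
    den <- den + seg_len[i]
    if (kappa[i - 1L] < kmin || kappa[i] < kmin) next
    degenerate <- FALSE
    b1 <- binormals[[i - 1L]]
    b2 <- binormals[[i]]
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- b2 / sqrt(sum(b2^2))
    t2 <- seg[i, ] / seg_len[i]
    num <- num + atan2(sum(cross3(b1, b2) * t2), sum(b1 * b2))
  }
  out <- if (den > 0) num / den else 0
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

# largest coordinate span of a point set (robust "height" for scale gates)
dist_span <- function(P) {
  max(apply(P, 2, function(v) diff(range(v))))
}

#' Classify the axial (top-view) projection of a 3D curve
#'
#' Projects the curve onto the X--Y plane and decides between three shapes:
#' `line` when the RMS deviation of the projected points from their best-fit
#' line is below `eps_line` times the curve height; otherwise the projection
#' is smoothed and the sign changes of its signed planar curvature are
#' counted -- no sign change is a `loop` (single-signed arc, the V-shaped
#' projection), one or more is a `lemniscate` (figure-eight, the S-shaped
#' projection).  The classification is invariant under rotation about Z and
#' uniform scaling.
#'
#' @param curve Data frame with columns `x`, `y`, `z`; at least 5 points.
#' @param eps_line Line gate, fraction of curve height (default `1e-6`).
#' @param smooth_window Moving-average window for the projection (odd, default 3).
#' @param deadband Relative dead band on the signed curvature measure
#'   (default `1e-8`), suppressing numerical zero-crossing chatter.
#' @return A string: `"line"`, `"loop"` or `"lemniscate"`.
#' @export
classify_axial_projection <- function(curve, eps_line = 1e-6,
                                      smooth_window = 3L, deadband = 1e-8) {
  check_curve_frame(curve)
  if (nrow(curve) < 5L) {
    stop_spinerod("classification needs at least 5 points", "spinerod_insufficient_data")
  }
  P <- cbind(curve$x, curve$y)
  height <- max(dist_span(as.matrix(curve[, c("x", "y", "z")])), .Machine$double.eps)

  centered <- sweep(P, 2, colMeans(P))
  sv <- svd(centered)
  rms_dev <- sqrt(mean((sv$u[, 2] * sv$d[2])^2))
  if (rms_dev <= eps_line * height) {
    return("line")
  }

  xs <- moving_average(curve$x, smooth_window)
  ys <- moving_average(curve$y, smooth_window)
  v <- cbind(diff(xs), diff(ys))
  # z-component of successive segment cross products: signed curvature measure
  cr <- v[-nrow(v), 1] * v[-1, 2] - v[-nrow(v), 2] * v[-1, 1]
  changes <- count_sign_changes(cr, deadband = deadband * height^2)
  if (changes == 0) "loop" else "lemniscate"
}

#' Count twists of a deformed rod relative to its sagittal plane
#'
#' A twist is a crossing of the original sagittal plane by the deformed
#' centerline: the number of sign changes (after smoothing, with a dead band)
#' of the out-of-plane displacement component `u_x` along the rod.  Zero
#' means the deformation stayed planar-sided, one is a single twist, two a
#' double twist.
#'
#' @param initial,deformed Matched centerline tibbles (columns `x`, `y`, `z`).
#' @param smooth_window Moving-average window (odd, default 3).
#' @param deadband Relative dead band, fraction of curve height
#'   (default `1e-8`).
#' @return Integer count of sagittal-plane crossings.
#' @export
count_twists <- function(initial, deformed, smooth_window = 3L, deadband = 1e-8) {
  check_curve_frame(initial, "initial")
  check_curve_frame(deformed, "deformed")
  if (nrow(initial) != nrow(deformed)) {
    stop_spinerod("initial and deformed curves must have matched node counts",
                  "spinerod_input_error")
  }
  ux <- deformed$x - initial$x
  height <- max(curve_height(initial), .Machine$double.eps)
  ux <- moving_average(ux, smooth_window)
  count_sign_changes(ux, deadband = deadband * height)
}

#' Locate the sagittal inflection point of a planar profile
#'
#' Evaluates the signed sagittal curvature (second derivative of the
#' interpolating natural spline of Y over Z) at each vertebral level of a
#' planar profile and finds where it changes sign, scanning cranial to
#' caudal.  The inflection is the boundary between the kyphotic (cranial)
#' and lordotic (caudal) segments; when the sign change happens across a
#' contiguous zone of near-zero curvature, the center of the zone is used.
#' Curvature values below `zero_tol` times the maximum interior curvature are
#' treated as zero, which also suppresses interpolation ringing next to
#' sharp arcs.  C-shaped or straight profiles have no inflection and are
#' flagged rather than raising an error.
#'
#' @param profile Sagittal profile tibble (columns `x`, `y`, `z`, rows
#'   cranial to caudal, Z monotone); at least 5 levels.
#' @param zero_tol Relative curvature dead band (default 0.05 of the maximum
#'   interior curvature).
#' @return A one-row tibble: `has_inflection`, `inflection_level` (index from
#'   T1, halfway values for between-level inflections), `kyphotic_len`,
#'   `lordotic_len`, `n_sign_changes`.
#' @export
find_inflection <- function(profile, zero_tol = 0.05) {
  check_curve_frame(profile, "profile")
  n <- nrow(profile)
  if (n < 5L) {
    stop_spinerod("inflection detection needs at least 5 levels", "spinerod_insufficient_data")
  }
  dz <- diff(profile$z)
  if (!(all(dz > 0) || all(dz < 0))) {
    stop_spinerod("profile Z must be monotone for inflection detection",
                  "spinerod_input_error")
  }
  ord <- order(profile$z)
  f <- stats::splinefun(profile$z[ord], profile$y[ord], method = "natural")
  d2 <- f(profile$z, deriv = 2)  # per level, rows cranial -> caudal

  no_inflection <- tibble::tibble(
    has_inflection = FALSE,
    inflection_level = NA_real_,
    kyphotic_len = NA_integer_,
    lordotic_len = NA_integer_,
    n_sign_changes = 0L
  )
  interior <- 2:(n - 1L)
  cmax <- max(abs(d2[interior]))
  if (cmax == 0) return(no_inflection)
  s <- sign(d2)
  s[abs(d2) < zero_tol * cmax] <- 0L
  nz <- which(s != 0L)
  if (length(nz) < 2L) return(no_inflection)
  flips <- which(diff(s[nz]) != 0)
  if (length(flips) == 0L) return(no_inflection)
  # first sign change, cranial to caudal; zero-zones resolved to their center
  lev_hi <- nz[flips[1]]
  lev_lo <- nz[flips[1] + 1L]
  inflection <- (lev_hi + lev_lo) / 2
  kyph <- floor(inflection)
  tibble::tibble(
    has_inflection = TRUE,
    inflection_level = inflection,
    kyphotic_len = as.integer(kyph),
    lordotic_len = as.integer(n - kyph),
    n_sign_changes = length(flips)
  )
}

#' Ratio of mean lateral to mean sagittal displacement
#'
#' Signed ratio `mean(u_x) / mean(u_y)` over nodes (signed means, not
#' absolute values): how much of the deformation left the sagittal plane,
#' and in which direction, relative to the in-plane response.
#'
#' @param initial,deformed Matched centerline tibbles, or `deformed` may be a
#'   displacement tibble (columns `ux`, `uy`) with `initial = NULL`.
#' @return Signed dimensionless scalar.
#' @export
displacement_ratio <- function(initial, deformed = NULL) {
  if (is.null(deformed)) {
    field <- initial
    if (!all(c("ux", "uy") %in% names(field))) {
      stop_spinerod("displacement field needs columns ux, uy", "spinerod_input_error")
    }
    ux <- field$ux
    uy <- field$uy
  } else {
    check_curve_frame(initial, "initial")
    check_curve_frame(deformed, "deformed")
    if (nrow(initial) != nrow(deformed)) {
      stop_spinerod("curves must have matched node counts", "spinerod_input_error")
    }
    ux <- deformed$x - initial$x
    uy <- deformed$y - initial$y
  }
  my <- mean(uy)
  if (my == 0) {
    stop_spinerod("mean Y displacement is zero; ratio undefined", "spinerod_undefined_ratio")
  }
  mean(ux) / my
}

#' Shape metrics of a solved rod model
#'
#' Bundles the 3D deformation descriptors of one solved model into a one-row
#' tibble: global torsion of the deformed centerline, the axial class of the
#' normalized deformation-field trajectory, the twist count (sagittal-plane
#' crossings), the signed X/Y displacement ratio, and the sagittal inflection
#' structure of the undeformed profile (evaluated at the vertebral levels).
#'
#' @param sol A [solve_rod()] result.
#' @param run_id Optional identifier copied into the output.
#' @return A one-row tibble.
#' @export
shape_metrics <- function(sol, run_id = NA_character_) {
  stopifnot(inherits(sol, "rod_solution"))
  field <- normalize_deformation(sol)
  defo_curve <- tibble::tibble(x = field$ux, y = field$uy, z = field$uz)
  lev <- !is.na(sol$initial$level)
  infl <- find_inflection(sol$initial[lev, ])
  tibble::tibble(
    run_id = run_id,
    tau_g = as.numeric(global_torsion(sol$deformed)),
    axial_class = classify_axial_projection(defo_curve),
    twist_count = count_twists(sol$initial, sol$deformed),
    xy_ratio = displacement_ratio(sol$displacement),
    inflection_level = infl$inflection_level,
    kyphotic_len = infl$kyphotic_len,
    lordotic_len = infl$lordotic_len
  )
}

#' Writhe of a 3D centerline
#'
#' Alternative chirality summary behind the same interface as
#' [global_torsion()]: the Gauss double integral of an open polyline,
#' evaluated exactly segment-pair-wise by the solid-angle (Klenin--Langowski)
#' quadrilateral formula.  Planar curves have zero writhe; mirroring negates
#' it.  Useful as a sensitivity check on the torsion-based metric, since it
#' involves no curvature threshold.
#'
#' @param curve Data frame with columns `x`, `y`, `z`; at least 4 points.
#' @return Signed dimensionless scalar.
#' @export
global_writhe <- function(curve) {
  check_curve_frame(curve)
  P <- as.matrix(curve[, c("x", "y", "z")])
  n <- nrow(P)
  if (n < 4L) {
    stop_spinerod("writhe needs at least 4 points", "spinerod_insufficient_data")
  }
  clamp <- function(x) pmin(1, pmax(-1, x))
  wr <- 0
  for (i in seq_len(n - 3L)) {
    for (j in seq.int(i + 2L, n - 1L)) {
      r1 <- P[i, ]; r2 <- P[i + 1L, ]; r3 <- P[j, ]; r4 <- P[j + 1L, ]
      r13 <- r3 - r1; r14 <- r4 - r1; r23 <- r3 - r2; r24 <- r4 - r2
      n1 <- cross3(r13, r14); n2 <- cross3(r14, r24)
      n3 <- cross3(r24, r23); n4 <- cross3(r23, r13)
      l1 <- sqrt(sum(n1^2)); l2 <- sqrt(sum(n2^2))
      l3 <- sqrt(sum(n3^2)); l4 <- sqrt(sum(n4^2))
      if (min(l1, l2, l3, l4) == 0) next  # coplanar segment pair: no solid angle
      omega <- asin(clamp(sum(n1 * n2) / (l1 * l2))) +
        asin(clamp(sum(n2 * n3) / (l2 * l3))) +
        asin(clamp(sum(n3 * n4) / (l3 * l4))) +
        asin(clamp(sum(n4 * n1) / (l4 * l1)))
      sgn <- sign(sum(cross3(r4 - r3, r2 - r1) * r13))
      wr <- wr + omega * sgn / (4 * pi)
    }
  }
  2 * wr
}
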