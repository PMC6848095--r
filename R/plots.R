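#' Plot a solved rod in the three anatomical views
#'
#' Overlays the initial (black) and deformed (blue) centerlines in the
#' sagittal (Y--Z), frontal (X--Z) and axial (X--Y) planes.  Because the
#' physical displacements are small relative to the height, the deformed
#' curve is drawn with an exaggeration factor (initial + scale * u), noted in
#' the caption.
#'
#' @param object A [solve_rod()] result.
#' @param scale Displacement exaggeration factor; `NULL` (default) picks the
#'   factor that makes the largest drawn offset 10% of the height.
#' @param ... Unused.
#' @return A ggplot object (faceted by view).
#' @export
autoplot.rod_solution <- function(object, scale = NULL, ...) {
  u <- object$displacement
  umax <- max(sqrt(u$ux^2 + u$uy^2 + u$uz^2))
  if (is.null(scale)) scale <- if (umax > 0) 0.1 / umax else 1
  ini <- object$initial
  def <- dplyr::mutate(
    ini,
    x = .data$x + scale * u$ux,
    y = .data$y + scale * u$uy,
    z = .data$z + scale * u$uz
  )
  views <- function(df, which) {
    dplyr::bind_rows(
      tibble::tibble(view = "sagittal (Y-Z)", h = df$y, v = df$z, curve = which),
      tibble::tibble(view = "frontal (X-Z)", h = df$x, v = df$z, curve = which),
      tibble::tibble(view = "axial (X-Y)", h = df$x, v = df$y, curve = which)
    )
  }
  dat <- dplyr::bind_rows(views(ini, "initial"), views(def, "deformed"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$h, y = .data$v, colour = .data$curve)) +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::facet_wrap(~view, scales = "free") +
    ggplot2::scale_colour_manual(values = c(initial = "black", deformed = "#2166ac")) +
    ggplot2::labs(
      x = NULL, y = NULL, colour = NULL,
      caption = sprintf("displacements exaggerated %.3g x", scale)
    ) +
    ggplot2::theme_minimal()
}

#' Axial projection of normalized deformation patterns
#'
#' Superimposes the top-view (`u_x` vs `u_y`) trajectories of the normalized
#' 3D deformation fields of several solved models -- loops for one subtype
#' group, lemniscates for the other.
#'
#' @param solutions Named list of [solve_rod()] results (or normalized
#'   displacement tibbles).
#' @return A ggplot object.
#' @export
plot_deformation_axial <- function(solutions) {
  dat <- purrr::imap(solutions, function(sol, nm) {
    f <- if (inherits(sol, "rod_solution")) normalize_deformation(sol) else sol
    tibble::tibble(model = nm, ux = f$ux, uy = f$uy)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ux, y = .data$uy, colour = .data$model)) +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::labs(x = "normalized u_x", y = "normalized u_y", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the deformation pattern-correlation matrix
#'
#' @param object A [correlation_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pattern_correlation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$model_a, y = .data$model_b,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#b2182b",
                                  mid = "white", high = "#2166ac") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Plot clustered centerlines and their cluster means
#'
#' Frontal-view spaghetti of cohort curves coloured by assigned cluster, with
#' the cluster mean curves overlaid.
#'
#' @param object A [cluster_curves()] result.
#' @param cohort The cohort tibble that was clustered.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.curve_clustering <- function(object, cohort, ...) {
  dat <- dplyr::left_join(cohort, object$labels[, c("curve_id", "cluster")],
                          by = "curve_id")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$z,
                                    group = .data$curve_id,
                                    colour = factor(.data$cluster))) +
    ggplot2::geom_path(alpha = 0.3, linewidth = 0.3) +
    ggplot2::geom_path(
      data = object$centers,
      ggplot2::aes(x = .data$x, y = .data$z, group = .data$cluster,
                   colour = factor(.data$cluster)),
      inherit.aes = FALSE, linewidth = 1
    ) +
    ggplot2::labs(x = "x (frontal)", y = "z", colour = "cluster") +
    ggplot2::theme_minimal()
}
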