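#' Pattern correlation between two normalized deformation fields
#'
#' Pearson correlation between the concatenated `(u_x, u_y, u_z)` displacement
#' vectors of two rod models (both normalized with
#' [normalize_deformation()]), with the 95% confidence interval from the
#' Fisher variance-stabilizing z-transform and a two-sided p-value from the
#' t-statistic on `n - 2` degrees of freedom, where `n` is the number of
#' paired scalar observations (three per node).
#'
#' @param a,b Normalized displacement tibbles (columns `ux`, `uy`, `uz`) with
#'   matched node counts; [solve_rod()] results are normalized automatically.
#' @return One-row tibble: `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
correlate_deformations <- function(a, b) {
  va <- deformation_vector(a)
  vb <- deformation_vector(b)
  if (length(va) != length(vb)) {
    stop_spinerod("deformation fields must have matched node counts", "spinerod_input_error")
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop_spinerod("zero-variance deformation field; correlation undefined",
                  "spinerod_undefined_correlation")
  }
  ct <- stats::cor.test(va, vb, conf.level = 0.95)
  r <- unname(ct$estimate)
  ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA_real_, NA_real_)
  tibble::tibble(
    r = r,
    ci_low = ci[1],
    ci_high = ci[2],
    p = ct$p.value,
    n = length(va)
  )
}

deformation_vector <- function(x) {
  if (inherits(x, "rod_solution")) x <- normalize_deformation(x)
  if (!all(c("ux", "uy", "uz") %in% names(x))) {
    stop_spinerod("expected a displacement field with columns ux, uy, uz",
                  "spinerod_input_error")
  }
  c(x$ux, x$uy, x$uz)
}

#' Pairwise pattern-correlation matrix across models
#'
#' Applies [correlate_deformations()] to every pair of models and returns the
#' full symmetric set of results in long form (diagonal r = 1), mirroring the
#' upper-triangle layout of the subtype correlation table.
#'
#' @param fields Named list of normalized displacement tibbles (or
#'   `rod_solution` objects).
#' @param labels Model names; defaults to `names(fields)`.
#' @return An object of class `pattern_correlation`: long tibble with columns
#'   `model_a`, `model_b`, `r`, `ci_low`, `ci_high`, `p`, `n`.  Use
#'   [corr_matrix()] for the wide r matrix.
#' @export
correlation_matrix <- function(fields, labels = names(fields)) {
  if (length(fields) < 2L) {
    stop_spinerod("need at least two models", "spinerod_input_error")
  }
  if (is.null(labels)) labels <- paste0("model", seq_along(fields))
  fields <- purrr::map(fields, function(x) {
    if (inherits(x, "rod_solution")) normalize_deformation(x) else x
  })
  pairs <- utils::combn(seq_along(fields), 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(ij) {
    res <- correlate_deformations(fields[[ij[1]]], fields[[ij[2]]])
    dplyr::mutate(res, model_a = labels[ij[1]], model_b = labels[ij[2]],
                  .before = 1)
  })
  diag_rows <- purrr::map(seq_along(fields), function(i) {
    tibble::tibble(
      model_a = labels[i], model_b = labels[i],
      r = 1, ci_low = 1, ci_high = 1, p = 0,
      n = length(deformation_vector(fields[[i]]))
    )
  })
  out <- dplyr::bind_rows(c(rows, diag_rows))
  structure(out, class = c("pattern_correlation", class(out)))
}

#' Wide correlation-coefficient matrix
#'
#' @param x A [correlation_matrix()] result.
#' @return A symmetric numeric matrix of r values with model names as
#'   dimnames.
#' @export
corr_matrix <- function(x) {
  labs <- unique(c(x$model_a, x$model_b))
  m <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_len(nrow(x))) {
    m[x$model_a[i], x$model_b[i]] <- x$r[i]
    m[x$model_b[i], x$model_a[i]] <- x$r[i]
  }
  m
}

#' Per-axis pattern correlations
#'
#' Transparency companion to [correlate_deformations()]: the Pearson
#' correlation of each displacement component (`ux`, `uy`, `uz`) separately,
#' showing which axes carry the overall pattern agreement.
#'
#' @inheritParams correlate_deformations
#' @return A three-row tibble with columns `axis`, `r`, `ci_low`, `ci_high`,
#'   `p`, `n`.
#' @export
correlate_deformations_by_axis <- function(a, b) {
  if (inherits(a, "rod_solution")) a <- normalize_deformation(a)
  if (inherits(b, "rod_solution")) b <- normalize_deformation(b)
  if (nrow(a) != nrow(b)) {
    stop_spinerod("deformation fields must have matched node counts", "spinerod_input_error")
  }
  purrr::map(c(ux = "ux", uy = "uy", uz = "uz"), function(axis) {
    ct <- stats::cor.test(a[[axis]], b[[axis]], conf.level = 0.95)
    tibble::tibble(
      axis = axis,
      r = unname(ct$estimate),
      ci_low = ct$conf.int[1],
      ci_high = ct$conf.int[2],
      p = ct$p.value,
      n = nrow(a)
    )
  }) |> dplyr::bind_rows()
}
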