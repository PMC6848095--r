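#' K-means clustering of 3D spinal centerlines
#'
#' Clusters isotropically normalized 3D centerline curves into subtypes with
#' k-means on the concatenated `(x, y, z)` coordinate vector of each curve
#' (`3 * n_levels` features), the number of clusters being known a priori.
#' Greedy multi-restart seeding (`nstart` restarts, best inertia kept) makes
#' the result deterministic given `seed`.
#'
#' @param cohort Long tibble with columns `curve_id`, `x`, `y`, `z` (and
#'   optionally `level`, `type`); every curve must have the same number of
#'   landmarks.  Curves are isotropically normalized before clustering unless
#'   `normalize = FALSE`.
#' @param k Number of clusters (`>= 1`).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart Number of random restarts (default 10).
#' @param normalize Normalize each curve with [isotropic_normalize()] first.
#' @param init Optional matrix of initial centers (rows = k, columns =
#'   features); overrides the seeded restarts.
#' @return An object of class `curve_clustering` with per-curve labels,
#'   cluster center curves, inertia and settings.  Use [tidy()] for labels
#'   and [glance()] for fit summaries.
#' @export
cluster_curves <- function(cohort, k, seed = 1L, nstart = 10L,
                           normalize = TRUE, init = NULL) {
  if (!is.data.frame(cohort) || !all(c("curve_id", "x", "y", "z") %in% names(cohort))) {
    stop_spinerod("`cohort` must have columns curve_id, x, y, z", "spinerod_input_error")
  }
  if (k < 1) {
    stop_spinerod("`k` must be at least 1", "spinerod_invalid_parameter")
  }
  ids <- unique(cohort$curve_id)
  if (length(ids) < k) {
    stop_spinerod("cohort size must be at least `k`", "spinerod_invalid_parameter")
  }
  counts <- table(cohort$curve_id)
  if (length(unique(counts)) != 1L) {
    stop_spinerod("all curves must have the same number of landmarks", "spinerod_input_error")
  }

  curve_list <- split(cohort[, c("x", "y", "z")], cohort$curve_id)[ids]
  if (normalize) curve_list <- purrr::map(curve_list, isotropic_normalize)
  features <- do.call(rbind, purrr::map(curve_list, function(df) c(df$x, df$y, df$z)))
  rownames(features) <- ids

  if (sum(!duplicated(features)) < k) {
    warning("fewer distinct curves than clusters; clustering is degenerate",
            call. = FALSE)
  }

  set.seed(seed)
  fit <- if (is.null(init)) {
    stats::kmeans(features, centers = k, nstart = nstart, iter.max = 100L)
  } else {
    stats::kmeans(features, centers = init, iter.max = 100L)
  }

  n_lev <- nrow(curve_list[[1]])
  centers <- purrr::imap(
    split(fit$centers, seq_len(nrow(fit$centers))),
    function(v, i) {
      tibble::tibble(
        cluster = as.integer(i),
        landmark = seq_len(n_lev),
        x = v[seq_len(n_lev)],
        y = v[n_lev + seq_len(n_lev)],
        z = v[2 * n_lev + seq_len(n_lev)]
      )
    }
  ) |> dplyr::bind_rows()

  labels <- tibble::tibble(curve_id = ids, cluster = unname(fit$cluster))
  if ("type" %in% names(cohort)) {
    truth <- dplyr::distinct(cohort[, c("curve_id", "type")])
    labels <- dplyr::left_join(labels, truth, by = "curve_id")
  }

  structure(
    list(
      labels = labels,
      centers = centers,
      k = as.integer(k),
      seed = as.integer(seed),
      inertia = fit$tot.withinss,
      betweenss = fit$betweenss,
      features = features
    ),
    class = "curve_clustering"
  )
}

#' @describeIn cluster_curves Per-curve cluster assignments.
#' @param x A `curve_clustering` object.
#' @param ... Unused.
#' @export
tidy.curve_clustering <- function(x, ...) {
  x$labels
}

#' @describeIn cluster_curves One-row fit summary (k, inertia, between-cluster
#'   sum of squares).
#' @export
glance.curve_clustering <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = nrow(x$labels),
    inertia = x$inertia,
    betweenss = x$betweenss,
    seed = x$seed
  )
}

#' @export
print.curve_clustering <- function(x, ...) {
  cat(sprintf("<curve_clustering> %d curves in %d clusters; inertia %.4g\n",
              nrow(x$labels), x$k, x$inertia))
  invisible(x)
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

#' Agreement between cluster labels and ground truth
#'
#' Best-permutation accuracy: the fraction of curves assigned to the right
#' group under the cluster-to-truth relabelling that maximizes agreement
#' (exhaustive over permutations, so intended for small k).
#'
#' @param labels Integer or factor cluster labels.
#' @param truth Ground-truth labels, same length.
#' @return Agreement fraction in `[0, 1]`.
#' @export
label_agreement <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  lab <- as.integer(factor(labels))
  tru <- as.integer(factor(truth))
  k <- max(lab, tru)
  if (k > 8L) {
    stop_spinerod("label_agreement supports up to 8 classes", "spinerod_invalid_parameter")
  }
  best <- 0
  for (p in all_permutations(seq_len(k))) {
    best <- max(best, mean(p[lab] == tru))
  }
  best
}
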