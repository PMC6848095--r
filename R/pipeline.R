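#' Default run configuration of the rod deformation experiment
#'
#' One serializable list drives the whole pipeline: the archetype set, the
#' finite-element settings (material, section, mesh density, load stepping,
#' torque, gravity scheme) and the metric thresholds.  A run is reproducible
#' from its configuration alone.
#'
#' `total_load` is calibrated once against the Euler load of the pinned
#' unit rod (`pi^2 EI / L^2` ~ `7.75e-9` at the default section) so the
#' maximum normalized deformation is moderate -- a few percent of the height,
#' matching the regime in which deformation patterns, not magnitudes, carry
#' the signal.
#'
#' @param seed RNG seed recorded in the config (the default experiment is
#'   deterministic; the seed matters for noisy cohorts).
#' @return A nested list of class `rod_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(
    list(
      models = c("type1", "type2", "type3", "type4", "type5", "nonscoliotic"),
      fe = list(
        young_modulus = 1000,
        poisson_ratio = 0.3,
        radius = 1e-3,
        n_sub = 4L,
        n_steps = 20L,
        tol = 1e-9,
        max_iter = 50L,
        torque_stress = -1e-4,
        load_scheme = "anthropometric",
        total_load = 8e-9
      ),
      metrics = list(
        eps_line = 1e-6,
        smooth_window = 3L,
        deadband = 1e-8,
        kappa_rel = 0.2
      ),
      seed = as.integer(seed)
    ),
    class = "rod_config"
  )
}

#' Solve one archetype (or custom profile) under a configuration
#'
#' Convenience wrapper: profile generation, meshing, load assembly and the
#' nonlinear solve for a single model.
#'
#' @param model Archetype name (see [archetype_params()]) or a profile tibble.
#' @param config A [default_config()]-style configuration.
#' @param torque_scale Multiplier on the configured torque (0 disables it).
#' @param load_scale Multiplier on the configured total load.
#' @return A [solve_rod()] result.
#' @export
solve_archetype <- function(model, config = default_config(),
                            torque_scale = 1, load_scale = 1) {
  fe <- config$fe
  profile <- if (is.character(model)) {
    generate_sagittal_profile(archetype_params(model))
  } else {
    model
  }
  mesh <- build_rod_mesh(
    profile,
    n_sub = fe$n_sub,
    material = rod_material(fe$young_modulus, fe$poisson_ratio),
    section = rod_section(fe$radius)
  )
  table <- make_load_table(nrow(profile), fe$total_load * load_scale, fe$load_scheme)
  loads <- make_load_case(mesh, table, torque_stress = fe$torque_stress * torque_scale)
  solve_rod(mesh, loads, n_steps = fe$n_steps, tol = fe$tol,
            max_iter = fe$max_iter)
}

#' Run the end-to-end deformation experiment
#'
#' For every configured model: generate the sagittal profile, mesh it, solve
#' the gravity-plus-torque load case, and compute the shape metrics; then
#' correlate the normalized deformation patterns across all model pairs.
#'
#' @param config A [default_config()]-style configuration.
#' @param keep_solutions Keep the full `rod_solution` objects in the report
#'   (default `TRUE`; set `FALSE` to save memory).
#' @return An object of class `rod_experiment`: `$metrics` (one row per
#'   model), `$correlations` (long pairwise table), `$diagnostics`,
#'   `$solutions` and the `$config` echo.
#' @export
run_experiment <- function(config = default_config(), keep_solutions = TRUE) {
  models <- config$models
  solutions <- purrr::map(
    stats::setNames(models, models),
    function(m) solve_archetype(m, config)
  )
  metrics <- purrr::imap(solutions, function(sol, nm) {
    row <- shape_metrics(sol, run_id = nm)
    row$group <- if (is.character(nm) && nm %in% names(archetype_table())) {
      archetype_group(nm)
    } else {
      NA_character_
    }
    row
  }) |> dplyr::bind_rows()

  correlations <- if (length(solutions) >= 2L) correlation_matrix(solutions) else NULL
  diagnostics <- purrr::imap(solutions, function(sol, nm) {
    dplyr::mutate(sol$diagnostics, run_id = nm, .before = 1)
  }) |> dplyr::bind_rows()

  structure(
    list(
      metrics = metrics,
      correlations = correlations,
      diagnostics = diagnostics,
      solutions = if (keep_solutions) solutions else NULL,
      config = config
    ),
    class = "rod_experiment"
  )
}

#' @export
print.rod_experiment <- function(x, ...) {
  cat(sprintf("<rod_experiment> %d models\n", nrow(x$metrics)))
  print(x$metrics)
  invisible(x)
}

#' @describeIn run_experiment Per-model metrics table.
#' @param x A `rod_experiment`.
#' @param ... Unused.
#' @export
tidy.rod_experiment <- function(x, ...) {
  x$metrics
}

#' @describeIn run_experiment One-row summary of the experiment.
#' @export
glance.rod_experiment <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$metrics),
    n_pairs = if (is.null(x$correlations)) 0L else
      sum(x$correlations$model_a != x$correlations$model_b),
    all_converged = all(x$diagnostics$residual < Inf),
    max_iterations = max(x$diagnostics$iterations)
  )
}

config_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- config
  for (k in keys) {
    if (!k %in% names(out)) {
      stop_spinerod(sprintf("unknown config path '%s'", path),
                    "spinerod_configuration_error")
    }
    out <- out[[k]]
  }
  out
}

config_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  config_get(config, path)  # validates the path
  expr <- Reduce(function(acc, k) call("[[", acc, k), keys, quote(config))
  eval(call("<-", expr, value))
  config
}

#' Sweep one configuration parameter across values
#'
#' Runs the full experiment once per value of a configuration entry
#' (addressed by a dotted path such as `"fe.total_load"` or `"fe.n_sub"`) and
#' stacks the per-model metrics with the swept value as a column.  Used for
#' the robustness analyses: load-scale invariance of the axial classes and
#' mesh-density stability of the torsion metric.
#'
#' @param config Base configuration.
#' @param parameter Dotted config path.
#' @param values Vector of values to sweep.
#' @param models Optional subset of models to run (default: all configured).
#' @return A tibble of stacked metrics with columns `parameter` and `value`.
#' @export
sensitivity_sweep <- function(config, parameter, values,
                              models = config$models) {
  purrr::map(values, function(v) {
    cfg <- config_set(config, parameter, v)
    cfg$models <- models
    out <- run_experiment(cfg, keep_solutions = FALSE)
    dplyr::mutate(out$metrics, parameter = parameter, value = v)
  }) |> dplyr::bind_rows()
}

#' Sweep the interpolation weight between two archetype profiles
#'
#' Solves the rod model for profiles interpolated between two parents at each
#' weight `t`, returning the stacked shape metrics.  Mirrors the sensitivity
#' analysis over additional S-shaped curves generated between the subtype
#' means of a group.
#'
#' @param parent_a,parent_b Archetype names or profile tibbles.
#' @param weights Interpolation weights in `[0, 1]`.
#' @param config Configuration (finite-element settings are taken from it).
#' @return A tibble of metrics, one row per weight, with a `t` column.
#' @export
interpolation_sweep <- function(parent_a, parent_b,
                                weights = c(0, 0.25, 0.5, 0.75, 1),
                                config = default_config()) {
  pa <- if (is.character(parent_a)) generate_sagittal_profile(archetype_params(parent_a)) else parent_a
  pb <- if (is.character(parent_b)) generate_sagittal_profile(archetype_params(parent_b)) else parent_b
  purrr::map(weights, function(t) {
    prof <- interpolate_profiles(pa, pb, t)
    sol <- solve_archetype(prof, config)
    dplyr::mutate(shape_metrics(sol, run_id = sprintf("t=%.2f", t)), t = t)
  }) |> dplyr::bind_rows()
}
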