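# Shared fixtures and a lazy cache for the (moderately expensive) default
# experiment, so multiple test files can reuse the same six solved models.

.cache <- new.env(parent = emptyenv())

cached_experiment <- function() {
  if (is.null(.cache$experiment)) {
    .cache$experiment <- run_experiment(default_config())
  }
  .cache$experiment
}

cached_solution <- function(type) {
  cached_experiment()$solutions[[type]]
}

straight_profile <- function(n = 17L, length = 1) {
  tibble::tibble(
    level = paste0("V", seq_len(n)),
    x = 0, y = 0,
    z = seq(length, 0, length.out = n)
  )
}

helix_curve <- function(a = 1, b = 0.3, n = 100L, turns = 2) {
  th <- seq(0, turns * 2 * pi, length.out = n)
  tibble::tibble(x = a * cos(th), y = a * sin(th), z = b * th)
}

# open figure-eight sampled from the Gerono lemniscate
gerono_curve <- function(amplitude = 0.2, n = 41L) {
  t <- seq(0.02, 0.98, length.out = n)
  tibble::tibble(
    x = amplitude * sin(2 * pi * t),
    y = (amplitude / 2) * sin(4 * pi * t),
    z = 1 - t
  )
}

rel_diff <- function(a, b) {
  sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), .Machine$double.eps)
}

displacement_matrix <- function(sol) {
  as.matrix(sol$displacement[, c("ux", "uy", "uz")])
}
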