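# broom-style tidiers for the package's result objects.

strip_class <- function(x, cls) {
  class(x) <- setdiff(class(x), cls)
  as_tibble(x)
}

#' Tidy a differentiation-call table
#'
#' @param x A `popdiff_calls` object from [classify_differentiated()].
#' @param ... Unused.
#' @return The per-variant call tibble.
#' @export
tidy.popdiff_calls <- function(x, ...) strip_class(x, "popdiff_calls")

#' One-row summary of a differentiation scan
#'
#' @param x A `popdiff_calls` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_variants`, `n_tested`, `n_excluded`,
#'   `n_differentiated`, `fraction_differentiated`, `p_threshold`,
#'   `diff_threshold`.
#' @export
glance.popdiff_calls <- function(x, ...) {
  as_tibble(attr(x, "summary"))
}

#' Tidy a reference panel into its per-gene summaries
#'
#' @param x A `reference_panel`.
#' @param ... Unused.
#' @return Per-gene tibble (`gene`, `n_variants`, `n_dropped`, `mean`,
#'   `sd`), without the raw draws.
#' @export
tidy.reference_panel <- function(x, ...) {
  select(strip_class(x, "reference_panel"), -"values")
}

#' One-row summary of a reference panel
#'
#' @param x A `reference_panel`.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_reps`, `population`, `tissue`.
#' @export
glance.reference_panel <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_reps = attr(x, "n_reps"),
    population = attr(x, "population") %||% NA_character_,
    tissue = attr(x, "tissue") %||% NA_character_
  )
}

#' Tidy a stability test
#'
#' @param x A `stability_test`.
#' @param ... Unused.
#' @return The per-gene KS tibble.
#' @export
tidy.stability_test <- function(x, ...) strip_class(x, "stability_test")

#' One-row summary of a stability test
#'
#' @param x A `stability_test`.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `alpha`, `threshold`,
#'   `n_significant`.
#' @export
glance.stability_test <- function(x, ...) {
  tibble(
    n_genes = attr(x, "n_genes"),
    alpha = attr(x, "alpha"),
    threshold = attr(x, "threshold"),
    n_significant = attr(x, "n_significant")
  )
}

#' Tidy a population comparison
#'
#' @param x A `pop_comparison`.
#' @param ... Unused.
#' @return The per-gene comparison tibble.
#' @export
tidy.pop_comparison <- function(x, ...) strip_class(x, "pop_comparison")

#' One-row summary of a population comparison
#'
#' @param x A `pop_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `mode`, `threshold`,
#'   `n_significant`.
#' @export
glance.pop_comparison <- function(x, ...) {
  tibble(
    n_genes = attr(x, "n_genes"),
    mode = attr(x, "mode"),
    threshold = attr(x, "threshold"),
    n_significant = attr(x, "n_significant")
  )
}

#' Tidy a simulation grid into per-scenario summaries
#'
#' @param x A `sim_grid` from [run_grid()].
#' @param ... Unused.
#' @return Per-scenario tibble without the raw draws.
#' @export
tidy.sim_grid <- function(x, ...) {
  select(strip_class(x, "sim_grid"), -"values")
}

#' One-row summary of a simulation grid
#'
#' @param x A `sim_grid`.
#' @param ... Unused.
#' @return A one-row tibble: `n_scenarios`, `n_reps`, `seed`,
#'   `n_degenerate`.
#' @export
glance.sim_grid <- function(x, ...) {
  tibble(
    n_scenarios = nrow(x),
    n_reps = attr(x, "n_reps"),
    seed = attr(x, "seed"),
    n_degenerate = sum(x$degenerate)
  )
}
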