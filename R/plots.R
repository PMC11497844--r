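# ggplot2 visualisations for the main result objects.

#' Plot ECDF curves of a simulation grid
#'
#' One ECDF curve per difference proportion, faceted by variant count and
#' weight group, for a chosen MAF — the standard view of how the proportion
#' of population-differentiated variants shifts predicted expression.
#'
#' @param object A `sim_grid` from [run_grid()].
#' @param maf Which MAF slice to draw (default: the largest in the grid).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_grid <- function(object, maf = max(object$maf), ...) {
  maf_pick <- maf
  df <- object %>%
    as_tibble() %>%
    filter(abs(.data$maf - maf_pick) < 1e-9) %>%
    mutate(scenario = row_number()) %>%
    tidyr::unnest_longer("values", values_to = "expression")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$expression,
    colour = factor(.data$diff_proportion),
    group = .data$scenario
  )) +
    ggplot2::stat_ecdf(linewidth = 0.4) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$n_variants),
      cols = ggplot2::vars(.data$weight_group),
      scales = "free_x"
    ) +
    ggplot2::labs(
      x = "predicted expression", y = "ECDF",
      colour = "difference\nproportion",
      title = sprintf("Simulated expression ECDFs (MAF = %.2f)", maf_pick)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a reference panel's per-gene distributions
#'
#' Density of the panel draws for a subset of genes.
#'
#' @param object A `reference_panel`.
#' @param genes Genes to show (default: the first 6 in the panel).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reference_panel <- function(object, genes = head(object$gene, 6), ...) {
  idx <- match(genes, object$gene)
  if (anyNA(idx)) abort("Some requested genes are not in the panel.")
  df <- tibble(
    gene = rep(genes, times = vapply(object$values[idx], length, integer(1))),
    expression = unlist(object$values[idx], use.names = FALSE)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expression)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free") +
    ggplot2::labs(
      x = "predicted expression", y = "density",
      title = sprintf("Reference panel (%s, %d draws/gene)",
                      attr(object, "population") %||% "panel",
                      attr(object, "n_reps"))
    ) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of a population comparison
#'
#' Percent mean difference against -log10 KS p-value, with the significance
#' threshold drawn.
#'
#' @param object A `pop_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pop_comparison <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(nlp = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mean_diff_pct, y = .data$nlp, colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(
      yintercept = -log10(attr(object, "threshold")), linetype = 2
    ) +
    ggplot2::labs(
      x = "mean difference (% of comparison panel)",
      y = expression(-log[10] ~ "KS p-value"),
      colour = "significant"
    ) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of a differentiation scan
#'
#' Allele-frequency difference against -log10 p-value for tested variants.
#'
#' @param object A `popdiff_calls`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.popdiff_calls <- function(object, ...) {
  df <- as_tibble(object) %>%
    filter(!.data$excluded) %>%
    mutate(nlp = -log10(pmax(.data$p_value, 1e-300)))
  thr <- attr(object, "summary")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$af_diff, y = .data$nlp, colour = .data$differentiated
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(
      xintercept = c(-1, 1) * thr$diff_threshold, linetype = 2
    ) +
    ggplot2::geom_hline(yintercept = -log10(thr$p_threshold), linetype = 2) +
    ggplot2::labs(
      x = "allele-frequency difference (pop1 - pop2)",
      y = expression(-log[10] ~ "p-value"),
      colour = "differentiated"
    ) +
    ggplot2::theme_minimal()
}
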