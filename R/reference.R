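#' Build an allele-frequency-driven expression reference panel
#'
#' Constructs the empirical per-gene reference distribution of predicted
#' expression for a population: for each of `n_reps` repetitions, a
#' pseudo-individual's dosage at each model variant is drawn from
#' Binomial(2, AF) under Hardy-Weinberg using that population's allele
#' frequency, and the gene's weighted sum is recorded. Variants are drawn
#' independently (no linkage disequilibrium). The panel stores all draws
#' plus the per-gene mean, sample SD (n - 1 denominator) and the number of
#' frequency-matched variants.
#'
#' Model variants lacking a frequency record are dropped from their gene
#' and counted in `n_dropped`; genes with no frequency-matched variants at
#' all are omitted with a warning.
#'
#' @param model An `expr_model` tibble.
#' @param freq A frequency tibble (see [read_frequencies()]); the
#'   population's AF is taken from `AF_<population>`, falling back to
#'   `AC/AN` when AF is absent.
#' @param population `"pop1"` or `"pop2"`: which frequency columns to use.
#' @param n_reps Repetitions per gene (default 500).
#' @param seed Optional integer seed for reproducible panels.
#' @return A tibble of class `reference_panel` with one row per gene:
#'   columns `gene`, `n_variants`, `n_dropped`, `mean`, `sd` and a `values`
#'   list-column of the `n_reps` draws. Attributes: `population`, `n_reps`,
#'   `seed`, `tissue`.
#' @export
build_reference <- function(model, freq, population = c("pop1", "pop2"),
                            n_reps = 500, seed = NULL) {
  population <- arg_match(population)
  model <- validate_model(model)
  stop_if_not_df(freq, "freq")
  if (n_reps < 2) abort("`n_reps` must be at least 2.")
  af_col <- paste0("AF_", population)
  ac_col <- paste0("AC_", population)
  an_col <- paste0("AN_", population)
  if (!all(c("variant_id", af_col) %in% names(freq))) {
    abort(sprintf("`freq` must have columns variant_id and %s.", af_col))
  }
  af <- as.numeric(freq[[af_col]])
  if (ac_col %in% names(freq) && an_col %in% names(freq)) {
    fallback <- is.na(af) & !is.na(freq[[ac_col]]) & !is.na(freq[[an_col]]) &
      freq[[an_col]] > 0
    af[fallback] <- freq[[ac_col]][fallback] / freq[[an_col]][fallback]
  }
  af_map <- setNames(af, as.character(freq$variant_id))
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    abort("Allele frequencies must lie in [0, 1].")
  }

  genes <- unique(model$gene)
  gene_rows <- split(seq_len(nrow(model)), factor(model$gene, levels = genes))
  build_one <- function(rows) {
    w <- model$weight[rows]
    a <- unname(af_map[model$variant_id[rows]])
    keep <- !is.na(a)
    list(w = w[keep], af = a[keep], dropped = sum(!keep))
  }
  prepped <- lapply(gene_rows, build_one)
  empty <- vapply(prepped, function(p) length(p$w) == 0, logical(1))
  if (any(empty)) {
    warn(sprintf(
      "%d gene(s) had no frequency-matched variants and were omitted.",
      sum(empty)
    ))
  }
  keep_genes <- genes[!empty]
  prepped <- prepped[!empty]
  if (!length(keep_genes)) abort("No gene retained any frequency-matched variant.")

  draws <- maybe_with_seed(seed, {
    lapply(prepped, function(p) {
      k <- length(p$w)
      dos <- matrix(
        rbinom(n_reps * k, size = 2, prob = rep(p$af, each = n_reps)),
        nrow = n_reps
      )
      as.numeric(dos %*% p$w)
    })
  })

  out <- tibble(
    gene = keep_genes,
    n_variants = unname(vapply(prepped, function(p) length(p$w), integer(1))),
    n_dropped = unname(vapply(prepped, function(p) p$dropped, integer(1))),
    mean = unname(vapply(draws, mean, numeric(1))),
    sd = unname(vapply(draws, sd, numeric(1))),
    values = unname(draws)
  )
  attr(out, "population") <- population
  attr(out, "n_reps") <- as.integer(n_reps)
  attr(out, "seed") <- seed
  attr(out, "tissue") <- attr(model, "tissue")
  class(out) <- c("reference_panel", class(out))
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided two-sample KS test with the asymptotic p-value (via
#' [stats::ks.test()] with `exact = FALSE`), the distributional comparison
#' used for panel stability and population contrasts. With the reference
#' panels' 500 draws per side the asymptotic approximation is ample.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A one-row tibble with `statistic` (the sup ECDF difference D)
#'   and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("Both samples must have length >= 2.")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("Samples must be finite.")
  }
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  tibble(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

ks_by_gene <- function(panel_a, panel_b) {
  shared <- intersect(panel_a$gene, panel_b$gene)
  if (!length(shared)) abort("The panels share no genes.")
  ia <- match(shared, panel_a$gene)
  ib <- match(shared, panel_b$gene)
  ks <- purrr::map2(panel_a$values[ia], panel_b$values[ib], ks_two_sample)
  tibble(
    gene = shared,
    statistic = vapply(ks, function(k) k$statistic, numeric(1)),
    p_value = vapply(ks, function(k) k$p_value, numeric(1)),
    mean_a = panel_a$mean[ia],
    mean_b = panel_b$mean[ib]
  )
}

#' Test reference-panel stability across repetition counts
#'
#' Compares two panels built from the same model and frequencies (typically
#' at different repetition counts, e.g. 500 vs 2000) gene by gene with the
#' two-sample KS test, under a Bonferroni threshold of `alpha` divided by
#' the number of genes compared. A stable generator yields no significant
#' genes; e.g. alpha 0.05 over 7252 genes gives the threshold 6.89e-06.
#'
#' @param panel_a,panel_b `reference_panel` objects; the gene intersection
#'   is compared and any mismatch is reported in the `unmatched` attribute.
#' @param alpha Family-wise error rate before correction (default 0.05).
#' @return A tibble of class `stability_test` with per-gene `gene`,
#'   `statistic`, `p_value`, `significant`; attributes `threshold`,
#'   `alpha`, `n_genes`, `n_significant`, `unmatched`.
#' @export
stability_test <- function(panel_a, panel_b, alpha = 0.05) {
  res <- ks_by_gene(panel_a, panel_b)
  threshold <- alpha / nrow(res)
  out <- res %>%
    select("gene", "statistic", "p_value") %>%
    mutate(significant = .data$p_value < threshold)
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- alpha
  attr(out, "n_genes") <- nrow(out)
  attr(out, "n_significant") <- sum(out$significant)
  attr(out, "unmatched") <- list(
    only_a = setdiff(panel_a$gene, panel_b$gene),
    only_b = setdiff(panel_b$gene, panel_a$gene)
  )
  class(out) <- c("stability_test", class(out))
  out
}

#' Compare two population reference panels gene by gene
#'
#' Runs the two-sample KS test per shared gene between two panels (e.g. an
#' East Asian and a non-Finnish European panel built from the same model
#' with each population's allele frequencies) and reports the percent mean
#' difference of panel A relative to panel B,
#' `(mean_A - mean_B) / |mean_B| * 100`. Significance uses either the fixed
#' genome-wide threshold 5e-8 (`mode = "fixed"`, the default) or a
#' 1/n-genes Bonferroni-style threshold (`mode = "bonferroni"`).
#'
#' @param panel_a,panel_b `reference_panel` objects.
#' @param mode Threshold mode: `"fixed"` or `"bonferroni"`.
#' @param p_threshold Fixed threshold used when `mode = "fixed"`.
#' @return A tibble of class `pop_comparison` with per-gene `gene`,
#'   `statistic`, `p_value`, `significant`, `mean_a`, `mean_b`,
#'   `mean_diff_pct` (`NA` when `|mean_b|` is numerically zero); attributes
#'   `threshold`, `mode`, `n_genes`, `n_significant`.
#' @export
compare_populations <- function(panel_a, panel_b,
                                mode = c("fixed", "bonferroni"),
                                p_threshold = 5e-8) {
  mode <- arg_match(mode)
  res <- ks_by_gene(panel_a, panel_b)
  threshold <- if (mode == "fixed") p_threshold else 1 / nrow(res)
  out <- res %>%
    mutate(
      significant = .data$p_value < threshold,
      mean_diff_pct = ifelse(abs(.data$mean_b) < 1e-12, NA_real_,
                             (.data$mean_a - .data$mean_b) /
                               abs(.data$mean_b) * 100)
    )
  attr(out, "threshold") <- threshold
  attr(out, "mode") <- mode
  attr(out, "n_genes") <- nrow(out)
  attr(out, "n_significant") <- sum(out$significant)
  class(out) <- c("pop_comparison", class(out))
  out
}

#' Write a reference panel to TSV
#'
#' Header `gene n_variants mean sd v1 ... v{n_reps}` with the draws in
#' fixed order, preceded by commented metadata lines (`# tissue=...`,
#' `# population=...`, `# n_reps=...`, `# seed=...`).
#'
#' @param panel A `reference_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(panel, path) {
  if (!inherits(panel, "reference_panel")) {
    abort("`panel` must be a reference_panel.")
  }
  n_reps <- attr(panel, "n_reps")
  meta <- c(
    sprintf("# tissue=%s", attr(panel, "tissue") %||% ""),
    sprintf("# population=%s", attr(panel, "population") %||% ""),
    sprintf("# n_reps=%d", n_reps),
    sprintf("# seed=%s", attr(panel, "seed") %||% "")
  )
  vals <- do.call(rbind, panel$values)
  colnames(vals) <- paste0("v", seq_len(n_reps))
  body <- dplyr::bind_cols(
    tibble(gene = panel$gene, n_variants = panel$n_variants,
           mean = panel$mean, sd = panel$sd),
    as_tibble(vals)
  )
  writeLines(meta, path)
  readr::write_tsv(body, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read a reference panel written by [write_reference()]
#'
#' @param path Panel TSV path.
#' @return A `reference_panel` tibble.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) abort(sprintf("Panel file not found: %s", path))
  lines <- readLines(path, n = 10)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  body <- readr::read_tsv(path, comment = "#", progress = FALSE,
                          col_types = readr::cols(
                            gene = readr::col_character(),
                            .default = readr::col_double()
                          ))
  vcols <- grep("^v[0-9]+$", names(body), value = TRUE)
  if (!length(vcols)) abort("Panel file has no draw columns (v1, v2, ...).")
  vals <- as.matrix(body[, vcols])
  out <- tibble(
    gene = body$gene,
    n_variants = as.integer(body$n_variants),
    n_dropped = NA_integer_,
    mean = body$mean,
    sd = body$sd,
    values = lapply(seq_len(nrow(vals)), function(i) unname(vals[i, ]))
  )
  attr(out, "population") <- meta$population
  attr(out, "n_reps") <- length(vcols)
  attr(out, "seed") <- if (nzchar(meta$seed %||% "")) as.integer(meta$seed) else NULL
  attr(out, "tissue") <- meta$tissue
  class(out) <- c("reference_panel", class(out))
  out
}
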