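#' Percentile rank of values within a reference distribution
#'
#' The counting definition used by the report: `100 * (#reference values <=
#' value) / n`. Ties are counted inclusively, so with a 500-draw reference
#' ranks fall on the 0.2-percent grid (0, 0.2, ..., 100).
#'
#' @param values Numeric vector of predicted values.
#' @param reference_values Non-empty numeric reference vector.
#' @return Numeric vector of ranks in \[0, 100\], one per value.
#' @examples
#' percentile_rank(2.5, 1:500)  # 0.4: two of 500 reference values are <= 2.5
#' @export
percentile_rank <- function(values, reference_values) {
  if (!length(reference_values)) abort("`reference_values` is empty.")
  if (any(!is.finite(reference_values))) {
    abort("`reference_values` must be finite.")
  }
  s <- sort(reference_values)
  100 * findInterval(values, s) / length(s)
}

#' Empirical reference interval of a gene's panel draws
#'
#' Central empirical interval of the reference distribution at the given
#' level, using the linear-interpolation quantile (type 7): the interval is
#' `(quantile((1-level)/2), quantile(1-(1-level)/2))`, closed at both ends
#' when used for coverage counting. `level = 1` returns the range.
#'
#' @param reference_values Numeric vector of panel draws (or a single
#'   element of a panel's `values` list-column).
#' @param level Coverage level in (0, 1\] (default 0.95).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
reference_interval <- function(reference_values, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level > 1) {
    abort("`level` must lie in (0, 1].")
  }
  if (!length(reference_values) || any(!is.finite(reference_values))) {
    abort("`reference_values` must be non-empty and finite.")
  }
  a <- (1 - level) / 2
  q <- quantile(reference_values, probs = c(a, 1 - a), type = 7, names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Score predicted expression against a reference panel, subject by subject
#'
#' The per-subject evaluation report: each predicted value is matched to its
#' gene's reference distribution and annotated with its percentile rank, the
#' panel's variant count, mean and SD, and (when a population comparison is
#' supplied) the Sig./Nonsig. population-difference flag and the percent
#' mean difference between the two population panels. Rows are grouped by
#' subject in prediction-file order, with genes in panel order within each
#' subject.
#'
#' @param predictions A prediction tibble (`FID`, `IID`, gene columns).
#' @param panel A `reference_panel`.
#' @param comparison Optional `pop_comparison` from [compare_populations()];
#'   when `NULL` the population columns are `NA`.
#' @param subject_dev Also emit `subject_dev = value - ref_mean`? Default
#'   `FALSE`.
#' @return A tibble of class `eval_report` with columns `FID`, `IID`,
#'   `gene`, `value`, `percentile_rank`, `n_variants`, `ref_mean`, `ref_sd`,
#'   `pop_diff` (`"Sig."`/`"Nonsig."`), `mean_diff_pct` and optionally
#'   `subject_dev`; attribute `unmatched_genes` lists prediction genes
#'   absent from the panel.
#' @export
make_report <- function(predictions, panel, comparison = NULL,
                        subject_dev = FALSE) {
  check_subject_table(predictions, "predictions")
  if (!inherits(panel, "reference_panel")) {
    abort("`panel` must be a reference_panel.")
  }
  pred_genes <- names(predictions)[-(1:2)]
  matched <- panel$gene[panel$gene %in% pred_genes]
  unmatched <- setdiff(pred_genes, panel$gene)
  if (!length(matched)) {
    abort("No overlap between prediction genes and panel genes.")
  }
  pi <- match(matched, panel$gene)
  n_sub <- nrow(predictions)

  rank_one <- function(g, i) {
    percentile_rank(predictions[[g]], panel$values[[i]])
  }
  ranks <- mapply(rank_one, matched, pi)  # n_sub x genes
  ranks <- matrix(ranks, nrow = n_sub)

  if (!is.null(comparison)) {
    ci <- match(matched, comparison$gene)
    flag <- ifelse(is.na(ci), NA_character_,
                   ifelse(comparison$significant[ci], "Sig.", "Nonsig."))
    mdp <- comparison$mean_diff_pct[ci]
  } else {
    flag <- rep(NA_character_, length(matched))
    mdp <- rep(NA_real_, length(matched))
  }

  out <- tibble(
    FID = rep(predictions$FID, each = length(matched)),
    IID = rep(predictions$IID, each = length(matched)),
    gene = rep(matched, times = n_sub),
    value = as.numeric(t(as.matrix(predictions[, matched, drop = FALSE]))),
    percentile_rank = as.numeric(t(ranks)),
    n_variants = rep(panel$n_variants[pi], times = n_sub),
    ref_mean = rep(panel$mean[pi], times = n_sub),
    ref_sd = rep(panel$sd[pi], times = n_sub),
    pop_diff = rep(flag, times = n_sub),
    mean_diff_pct = rep(mdp, times = n_sub)
  )
  if (subject_dev) {
    out$subject_dev <- out$value - out$ref_mean
  }
  attr(out, "unmatched_genes") <- unmatched
  class(out) <- c("eval_report", class(out))
  out
}

#' Dataset-level evaluation summary
#'
#' Aggregates a whole dataset of predictions against the panel, one row per
#' matched gene, in the published summary-table layout: the panel mean/SD
#' (`Ref.Mean`, `Ref.Sd`), the dataset mean/SD across subjects (`Data.Mean`,
#' `Data.Sd`), their absolute difference (`Abs.Diff`) and its ratio to the
#' reference mean (`Ratio.Diff`), the per-gene SNP counts available in the
#' data versus required by the model (`Data.SNP.Num`, `Predixcan_SNP.Num`,
#' `SNP.Ratio`), and how many subjects' predictions fall inside the closed
#' empirical reference interval (`GE.Match.Ref.Num`, `GE.Match.Ref.Ratio`).
#'
#' @param predictions A prediction tibble (`FID`, `IID`, gene columns).
#' @param panel A `reference_panel`.
#' @param data_snp_counts Per-gene count of SNPs present in the dataset: a
#'   named numeric vector or a (gene, count) data frame; required for every
#'   matched gene.
#' @param model_snp_counts Per-gene count of SNPs the model uses, same
#'   formats.
#' @param level Reference-interval level (default 0.95).
#' @return A tibble of class `dataset_summary` with columns `Gene`,
#'   `Ref.Mean`, `Ref.Sd`, `Data.Mean`, `Data.Sd`, `Abs.Diff`, `Ratio.Diff`,
#'   `Data.SNP.Num`, `Predixcan_SNP.Num`, `SNP.Ratio`, `GE.Match.Ref.Num`,
#'   `GE.Match.Ref.Ratio`. `Ratio.Diff` is `NA` when the reference mean is
#'   numerically zero; `SNP.Ratio` is `NA` when the model count is zero.
#' @export
dataset_summary <- function(predictions, panel, data_snp_counts,
                            model_snp_counts, level = 0.95) {
  check_subject_table(predictions, "predictions")
  if (!inherits(panel, "reference_panel")) {
    abort("`panel` must be a reference_panel.")
  }
  data_counts <- as_gene_counts(data_snp_counts, "data_snp_counts")
  model_counts <- as_gene_counts(model_snp_counts, "model_snp_counts")
  pred_genes <- names(predictions)[-(1:2)]
  matched <- panel$gene[panel$gene %in% pred_genes]
  if (!length(matched)) {
    abort("No overlap between prediction genes and panel genes.")
  }
  missing_counts <- setdiff(matched, intersect(names(data_counts),
                                               names(model_counts)))
  if (length(missing_counts)) {
    abort(sprintf(
      "SNP counts missing for gene(s): %s%s",
      paste(head(missing_counts, 5), collapse = ", "),
      if (length(missing_counts) > 5) ", ..." else ""
    ))
  }
  pi <- match(matched, panel$gene)
  n_sub <- nrow(predictions)

  rows <- purrr::map(seq_along(matched), function(j) {
    g <- matched[j]
    v <- predictions[[g]]
    ref_mean <- panel$mean[pi[j]]
    iv <- reference_interval(panel$values[[pi[j]]], level = level)
    n_in <- sum(v >= iv[["lo"]] & v <= iv[["hi"]])
    dn <- data_counts[[g]]
    mn <- model_counts[[g]]
    tibble(
      Gene = g,
      Ref.Mean = ref_mean,
      Ref.Sd = panel$sd[pi[j]],
      Data.Mean = mean(v),
      Data.Sd = sd(v),
      Abs.Diff = abs(mean(v) - ref_mean),
      Ratio.Diff = if (abs(ref_mean) < 1e-12) NA_real_ else {
        abs(mean(v) - ref_mean) / abs(ref_mean)
      },
      Data.SNP.Num = dn,
      Predixcan_SNP.Num = mn,
      SNP.Ratio = if (mn == 0) NA_real_ else dn / mn,
      GE.Match.Ref.Num = n_in,
      GE.Match.Ref.Ratio = n_in / n_sub
    )
  })
  out <- bind_rows(rows)
  attr(out, "level") <- level
  attr(out, "n_subjects") <- n_sub
  class(out) <- c("dataset_summary", class(out))
  out
}
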