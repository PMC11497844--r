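#' Predict gene expression from variant dosages
#'
#' Computes the PrediXcan-style linear prediction for each subject and gene:
#' the predicted expression of gene *s* is the sum over its model variants
#' *k* of the variant weight times the subject's effect-allele dosage,
#' `Y_s = sum_k w_ks * X_k`. Dosages count copies of the model's effect
#' allele.
#'
#' Model variants absent from the dosage matrix are handled by `missing`:
#' under `"wildtype"` an absent variant contributes weight times zero (the
#' subject is treated as homozygous for the reference allele); under
#' `"error"` any absent model variant aborts with the missing ids.
#'
#' @param model An `expr_model` tibble (see [read_model()]).
#' @param dosages A dosage tibble (`FID`, `IID`, variant columns), values in
#'   \[0, 2\].
#' @param missing Missing-variant policy: `"wildtype"` (default) or
#'   `"error"`.
#' @return A prediction tibble (`FID`, `IID`, one numeric column per model
#'   gene, genes in model first-appearance order) with a `gene_coverage`
#'   attribute: a tibble of per-gene counts `gene`, `n_model_variants`,
#'   `n_observed`.
#' @examples
#' m <- tibble::tibble(
#'   gene = "gA", variant_id = c("v1", "v2"),
#'   ref_allele = "A", effect_allele = "G", weight = c(0.5, -0.2)
#' )
#' d <- tibble::tibble(FID = "F1", IID = "S1", v1 = 2, v2 = 1)
#' predict_expression(m, d)$gA  # 0.5*2 - 0.2*1 = 0.8
#' @export
predict_expression <- function(model, dosages, missing = c("wildtype", "error")) {
  missing <- arg_match(missing)
  model <- validate_model(model)
  check_subject_table(dosages, "dosages")
  dmat <- subject_values(dosages)
  if (any(!is.finite(dmat)) || any(dmat < 0 | dmat > 2)) {
    abort("Dosages must be finite and lie in [0, 2].")
  }
  genes <- unique(model$gene)
  variants <- colnames(dmat)
  absent <- setdiff(unique(model$variant_id), variants)
  if (missing == "error" && length(absent)) {
    abort(sprintf(
      "%d model variant(s) missing from the dosage matrix: %s%s",
      length(absent), paste(head(absent, 5), collapse = ", "),
      if (length(absent) > 5) ", ..." else ""
    ))
  }
  obs <- model[model$variant_id %in% variants, , drop = FALSE]
  W <- matrix(0, nrow = length(variants), ncol = length(genes),
              dimnames = list(variants, genes))
  if (nrow(obs)) {
    W[cbind(match(obs$variant_id, variants), match(obs$gene, genes))] <- obs$weight
  }
  Y <- dmat %*% W
  coverage <- as_tibble(as.data.frame(model)) %>%
    group_by(gene = .data$gene) %>%
    summarise(
      n_model_variants = dplyr::n(),
      n_observed = sum(.data$variant_id %in% variants),
      .groups = "drop"
    ) %>%
    dplyr::slice(match(genes, .data$gene))
  out <- dplyr::bind_cols(
    tibble(FID = dosages$FID, IID = dosages$IID),
    as_tibble(Y)
  )
  attr(out, "gene_coverage") <- coverage
  out
}

#' Rank-based inverse normal transform
#'
#' Maps a sample to standard-normal quantiles through its ranks, the
#' normalisation routinely applied to expression phenotypes before model
#' training: `qnorm((rank - 3/8) / (n + 1/4))` with the Blom offset and
#' average ranks for ties. Output order matches input order.
#'
#' @param values Numeric vector, length >= 2, all finite, not all identical.
#' @return Numeric vector of the same length.
#' @examples
#' inverse_normal_transform(c(5, 1, 9))  # c(0, -0.869, 0.869)
#' @export
inverse_normal_transform <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    abort("`values` must be a numeric vector of length >= 2.")
  }
  if (any(!is.finite(values))) {
    abort("`values` must be finite.")
  }
  if (length(unique(values)) == 1) {
    abort("All values are identical; ranks are degenerate.")
  }
  n <- length(values)
  r <- rank(values, ties.method = "average")
  qnorm((r - 3 / 8) / (n + 1 / 4))
}
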