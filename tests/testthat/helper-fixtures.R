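# Small in-code fixtures shared across the suite.

# A tiny hand-written model: 2 genes, 3 variants.
tiny_model <- function() {
  tibble::tibble(
    gene = c("gA", "gA", "gB"),
    variant_id = c("chr1_100_A_G_b38", "chr1_200_C_T_b38", "chr2_300_G_A_b38"),
    ref_allele = c("A", "C", "G"),
    effect_allele = c("G", "T", "A"),
    weight = c(0.5, -0.2, 1.0)
  )
}

tiny_dosage <- function() {
  tibble::tibble(
    FID = c("F1", "F2"),
    IID = c("S1", "S2"),
    chr1_100_A_G_b38 = c(2, 0),
    chr1_200_C_T_b38 = c(1, 0),
    chr2_300_G_A_b38 = c(1, 2)
  )
}

# A pool with known segment structure: values 0.01 .. 0.10 so segments are
# {.01,.02}, {.03,.04}, {.05,.06}, {.07,.08}, {.09,.10}.
ladder_pool <- function(n = 10) {
  m <- tibble::tibble(
    gene = "g",
    variant_id = paste0("v", seq_len(n)),
    ref_allele = "A",
    effect_allele = "G",
    weight = seq_len(n) / 100
  )
  build_weight_pool(m)
}

# A pool whose low group is constant `a` and high group constant `b`
# (each segment holds one constant), so scenario means have a closed form.
constant_pool <- function(a = 0.01, b = 0.05, per_segment = 4) {
  vals <- rep(c(a, (a + b) / 2 * 0.8, (a + b) / 2, (a + b) / 2 * 1.2, b),
              each = per_segment)
  m <- tibble::tibble(
    gene = "g",
    variant_id = paste0("v", seq_along(vals)),
    ref_allele = "A",
    effect_allele = "G",
    weight = vals
  )
  build_weight_pool(m)
}

# One-gene model with k variants of given weights.
single_gene_model <- function(weights, gene = "g1") {
  tibble::tibble(
    gene = gene,
    variant_id = paste0("chr1_", seq_along(weights), "_A_G_b38"),
    ref_allele = "A",
    effect_allele = "G",
    weight = weights
  )
}

# Frequency table with identical, exactly consistent AF in both populations.
freq_for <- function(variant_id, af1, af2 = af1, an = 20000) {
  ac1 <- round(af1 * an)
  ac2 <- round(af2 * an)
  tibble::tibble(
    variant_id = variant_id,
    AC_pop1 = ac1, AN_pop1 = an, AF_pop1 = ac1 / an,
    AC_pop2 = ac2, AN_pop2 = an, AF_pop2 = ac2 / an
  )
}
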