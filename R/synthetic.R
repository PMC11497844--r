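#' Configuration for the synthetic-data generator
#'
#' Bundles the knobs of the synthetic fixture generator: tissue and gene
#' counts, the law for per-gene variant counts, the law for signed weights,
#' the fraction of variants with a true between-population frequency shift
#' and its size, the per-population allele number, and the cohort size.
#'
#' Defaults emulate the published PredictDB regime: per-gene variant counts
#' follow a rounded log-normal clamped to \[1, 430\] with mean about 30
#' (`meanlog = log(30) - 0.125`, `sdlog = 0.5`), and signed weights follow
#' a zero-centred Laplace with scale 0.02, giving |weight| quintiles on the
#' order of the thresholds seen in real weight pools. The default cohort
#' size of 61 subjects mirrors a small patient cohort. Generated allele
#' frequencies are clamped to \[0.001, 0.999\].
#'
#' @param n_tissues,n_genes Number of tissues and genes per tissue.
#' @param diff_fraction Fraction of variants given a true AF shift.
#' @param delta_af Size of the AF shift.
#' @param an_per_pop Allele number per population (default 20000).
#' @param n_subjects Cohort size for genotype fixtures (default 61).
#' @param seed Master seed.
#' @param variant_count_law Function `n -> integer vector` of per-gene
#'   variant counts in \[1, 430\]; `NULL` for the default law.
#' @param weight_law Function `n -> numeric vector` of signed weights;
#'   `NULL` for the default Laplace(0, 0.02).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_tissues = 2, n_genes = 50, diff_fraction = 0.3,
                         delta_af = 0.1, an_per_pop = 20000, n_subjects = 61,
                         seed = 1, variant_count_law = NULL,
                         weight_law = NULL) {
  if (diff_fraction < 0 || diff_fraction > 1) {
    abort("`diff_fraction` must lie in [0, 1].")
  }
  if (n_tissues < 1 || n_genes < 1 || an_per_pop < 1 || n_subjects < 1) {
    abort("Counts must be positive.")
  }
  structure(
    list(
      n_tissues = as.integer(n_tissues),
      n_genes = as.integer(n_genes),
      diff_fraction = diff_fraction,
      delta_af = delta_af,
      an_per_pop = as.integer(an_per_pop),
      n_subjects = as.integer(n_subjects),
      seed = as.integer(seed),
      variant_count_law = variant_count_law %||% default_variant_count_law,
      weight_law = weight_law %||% default_weight_law
    ),
    class = "synth_config"
  )
}

# Rounded log-normal clamped to [1, 430]; mean ~ 30, right-skewed like the
# published per-gene variant counts (min 1, mean 30, max ~430).
default_variant_count_law <- function(n) {
  pmin(430L, pmax(1L, as.integer(round(rlnorm(n, log(30) - 0.125, 0.5)))))
}

# Zero-centred Laplace(0, 0.02) signed weights.
default_weight_law <- function(n) {
  rexp(n, rate = 1 / 0.02) * sample(c(-1, 1), n, replace = TRUE)
}

#' Generate synthetic expression models
#'
#' One model per tissue: `n_genes` genes each with a variant count drawn
#' from the configured law and signed weights from the weight law. Variant
#' ids follow the positional `chr_pos_ref_alt_build` token convention and
#' are unique across the whole collection.
#'
#' @param cfg A `synth_config`.
#' @return A list of `expr_model` tibbles, one per tissue.
#' @export
synth_models <- function(cfg) {
  check_synth_config(cfg)
  withr::with_seed(sub_seed(cfg$seed, 101), {
    purrr::map(seq_len(cfg$n_tissues), function(t) {
      counts <- cfg$variant_count_law(cfg$n_genes)
      if (any(counts < 1 | counts > 430)) {
        abort("variant_count_law produced counts outside [1, 430].")
      }
      total <- sum(counts)
      alleles <- c("A", "C", "G", "T")
      ref <- sample(alleles, total, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1),
                    character(1))
      vid <- sprintf(
        "chr%d_%.0f_%s_%s_b38",
        sample.int(22, total, replace = TRUE),
        sample.int(2e8, total) + t * 3e8,
        ref, alt
      )
      tbl <- tibble(
        gene = rep(sprintf("GENE%04d", seq_len(cfg$n_genes)), counts),
        variant_id = vid,
        ref_allele = ref,
        effect_allele = alt,
        weight = cfg$weight_law(total)
      )
      new_expr_model(tbl, sprintf("tissue_%02d", t))
    })
  })
}

check_synth_config <- function(cfg) {
  if (!inherits(cfg, "synth_config")) {
    abort("`cfg` must be a synth_config (see synth_config()).")
  }
  invisible(cfg)
}

#' Generate a synthetic two-population allele-frequency table
#'
#' One record per unique variant. Population 1 allele frequencies are drawn
#' from Uniform(0.05, 0.5); a fraction `diff_fraction` of variants get a
#' population 2 frequency shifted by `delta_af` (random direction, flipped
#' if clamping to \[0.001, 0.999\] would shrink the shift), the rest share
#' population 1's frequency. Allele counts are then drawn as
#' `Binomial(AN, AF)` per population so the table carries realistic
#' sampling noise, and the reported AF is the realised `AC/AN`.
#'
#' @param variants An `expr_model`, a list of them, or a character vector of
#'   variant ids.
#' @param cfg A `synth_config`.
#' @return A frequency tibble (`variant_id`, `AC_pop1`, `AN_pop1`,
#'   `AF_pop1`, `AC_pop2`, `AN_pop2`, `AF_pop2`) with a `truth` attribute
#'   holding the generating frequencies and shift indicator.
#' @export
synth_frequencies <- function(variants, cfg) {
  check_synth_config(cfg)
  if (is.data.frame(variants)) variants <- list(variants)
  if (is.list(variants)) {
    variants <- unique(unlist(lapply(variants, function(m) m$variant_id),
                              use.names = FALSE))
  }
  if (!is.character(variants) || !length(variants)) {
    abort("`variants` must name at least one variant.")
  }
  n <- length(variants)
  an <- cfg$an_per_pop
  withr::with_seed(sub_seed(cfg$seed, 202), {
    af1 <- runif(n, 0.05, 0.5)
    shifted <- runif(n) < cfg$diff_fraction
    sign <- sample(c(-1, 1), n, replace = TRUE)
    af2 <- af1 + sign * cfg$delta_af * shifted
    clamp <- function(x) pmin(0.999, pmax(0.001, x))
    # flip the shift direction where clamping would shrink it
    flip <- shifted & abs(clamp(af2) - af1) < cfg$delta_af - 1e-12
    af2[flip] <- af1[flip] - sign[flip] * cfg$delta_af
    af2 <- clamp(af2)
    ac1 <- rbinom(n, an, af1)
    ac2 <- rbinom(n, an, af2)
    out <- tibble(
      variant_id = variants,
      AC_pop1 = ac1, AN_pop1 = an, AF_pop1 = ac1 / an,
      AC_pop2 = ac2, AN_pop2 = an, AF_pop2 = ac2 / an
    )
    attr(out, "truth") <- tibble(
      variant_id = variants, af_pop1 = af1, af_pop2 = af2, shifted = shifted
    )
    out
  })
}

#' Generate synthetic genotype dosages for a population
#'
#' Dosages are drawn per subject and variant from `Binomial(2, AF)` using
#' the requested population's allele frequency.
#'
#' @param freq A frequency tibble (see [synth_frequencies()]).
#' @param population `"pop1"` or `"pop2"`.
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @return A dosage tibble (`FID`, `IID`, variant columns).
#' @export
synth_genotypes <- function(freq, population, n_subjects, seed = 1) {
  stop_if_not_df(freq, "freq")
  if (!is.character(population) || length(population) != 1 ||
      !population %in% c("pop1", "pop2")) {
    abort("`population` must be \"pop1\" or \"pop2\".")
  }
  af <- freq[[paste0("AF_", population)]]
  if (is.null(af)) abort("`freq` lacks the population's AF column.")
  n_var <- nrow(freq)
  withr::with_seed(as.integer(seed), {
    m <- matrix(
      rbinom(n_subjects * n_var, 2, rep(af, each = n_subjects)),
      nrow = n_subjects,
      dimnames = list(NULL, as.character(freq$variant_id))
    )
    dplyr::bind_cols(
      tibble(
        FID = sprintf("F%04d", seq_len(n_subjects)),
        IID = sprintf("S%04d", seq_len(n_subjects))
      ),
      as_tibble(m)
    )
  })
}

#' Predict expression for synthetic genotypes
#'
#' Convenience wrapper over [predict_expression()] so evaluation fixtures
#' are internally consistent with the prediction engine.
#'
#' @param model An `expr_model`.
#' @param genotypes A dosage tibble from [synth_genotypes()].
#' @return A prediction tibble.
#' @export
synth_predictions <- function(model, genotypes) {
  predict_expression(model, genotypes, missing = "wildtype")
}
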