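#' Two-proportion chi-square test on allele counts
#'
#' Pooled two-sided two-proportion test (1 df, no continuity correction) on
#' allele counts from two populations, the genome-wide scan statistic used
#' to call population-differentiated variants. Vectorised over variants.
#'
#' With allele frequencies `p_i = ac_i / an_i` and pooled frequency
#' `p = (ac1 + ac2) / (an1 + an2)`, the statistic is
#' `(p1 - p2)^2 / (p (1 - p) (1/an1 + 1/an2))`, compared to a chi-square
#' with one degree of freedom. A degenerate pooled frequency (0 or 1) gives
#' statistic 0 and p-value 1.
#'
#' @param ac1,an1 Allele count and allele number in population 1.
#' @param ac2,an2 Allele count and allele number in population 2.
#' @return A tibble with columns `chi_square` and `p_value` (one row per
#'   variant).
#' @examples
#' two_proportion_test(90, 100, 10, 100)  # chi_square = 128
#' @export
two_proportion_test <- function(ac1, an1, ac2, an2) {
  n <- length(ac1)
  if (!all(lengths(list(an1, ac2, an2)) == n)) {
    abort("ac1, an1, ac2, an2 must have equal lengths.")
  }
  bad <- !is.finite(an1) | !is.finite(an2) | an1 <= 0 | an2 <= 0
  if (any(bad)) abort("Allele numbers (AN) must be positive.")
  if (any(ac1 < 0 | ac1 > an1 | ac2 < 0 | ac2 > an2)) {
    abort("Allele counts (AC) must satisfy 0 <= AC <= AN.")
  }
  p1 <- ac1 / an1
  p2 <- ac2 / an2
  pp <- (ac1 + ac2) / (an1 + an2)
  denom <- pp * (1 - pp) * (1 / an1 + 1 / an2)
  chi <- ifelse(denom <= 0, 0, (p1 - p2)^2 / denom)
  p <- ifelse(denom <= 0, 1, pchisq(chi, df = 1, lower.tail = FALSE))
  tibble(chi_square = chi, p_value = p)
}

#' Call population-differentiated variants from a frequency table
#'
#' Screens a gnomAD-style two-population allele-frequency table and flags
#' significant population-differentiated variants: those with a pooled
#' two-proportion test p-value strictly below `p_threshold` (default the
#' genome-wide 5e-8) *and* an absolute allele-frequency difference strictly
#' greater than `diff_threshold` (default 0.05). Variants lacking frequency
#' information in either population are excluded from testing and counted.
#'
#' When a population's AC is absent but AF and AN are present, AC is
#' reconstructed as `round(AF * AN)`; with no usable counts the variant is
#' excluded. Where both AF and counts are present they must agree to 1e-6.
#'
#' @param freq A tibble with columns `variant_id`, `AC_pop1`, `AN_pop1`,
#'   `AF_pop1`, `AC_pop2`, `AN_pop2`, `AF_pop2`; `NA` marks an absent field.
#' @param p_threshold P-value threshold (strict `<`).
#' @param diff_threshold Allele-frequency-difference threshold (strict `>`).
#' @return A tibble of class `popdiff_calls` with columns `variant_id`,
#'   `af_pop1`, `af_pop2`, `af_diff` (pop1 minus pop2), `chi_square`,
#'   `p_value`, `differentiated`, `excluded`, `exclude_reason`, and a
#'   `summary` attribute (`n_variants`, `n_tested`, `n_excluded`,
#'   `n_differentiated`, `fraction_differentiated`); see
#'   [glance.popdiff_calls()].
#' @export
classify_differentiated <- function(freq, p_threshold = 5e-8,
                                    diff_threshold = 0.05) {
  stop_if_not_df(freq, "freq")
  need <- c("variant_id", "AC_pop1", "AN_pop1", "AF_pop1",
            "AC_pop2", "AN_pop2", "AF_pop2")
  if (!all(need %in% names(freq))) {
    abort(sprintf("`freq` must have columns: %s.", paste(need, collapse = ", ")))
  }
  if (nrow(freq) == 0) abort("`freq` is empty.")

  resolve_pop <- function(ac, an, af) {
    an <- as.numeric(an)
    ac <- as.numeric(ac)
    af <- as.numeric(af)
    usable_an <- !is.na(an) & an > 0
    ac_out <- ifelse(!is.na(ac), ac,
                     ifelse(usable_an & !is.na(af), round(af * an), NA_real_))
    ok <- usable_an & !is.na(ac_out)
    # record-level consistency where everything is present
    chk <- ok & !is.na(af) & !is.na(ac)
    if (any(chk & abs(af - ac / an) > 1e-6)) {
      bad <- which(chk & abs(af - ac / an) > 1e-6)[1]
      abort(sprintf(
        "AF inconsistent with AC/AN (|AF - AC/AN| > 1e-6) for variant '%s'.",
        as.character(freq$variant_id[bad])
      ))
    }
    if (any(ok & ac_out > an)) {
      bad <- which(ok & ac_out > an)[1]
      abort(sprintf("AC > AN for variant '%s'.", as.character(freq$variant_id[bad])))
    }
    list(ac = ac_out, an = an,
         af = ifelse(!is.na(af), af, ifelse(ok, ac_out / an, NA_real_)),
         ok = ok)
  }

  p1 <- resolve_pop(freq$AC_pop1, freq$AN_pop1, freq$AF_pop1)
  p2 <- resolve_pop(freq$AC_pop2, freq$AN_pop2, freq$AF_pop2)
  tested <- p1$ok & p2$ok
  reason <- dplyr::case_when(
    !p1$ok & !p2$ok ~ "missing_both",
    !p1$ok ~ "missing_pop1",
    !p2$ok ~ "missing_pop2",
    TRUE ~ NA_character_
  )

  chi <- rep(NA_real_, nrow(freq))
  pval <- rep(NA_real_, nrow(freq))
  if (any(tested)) {
    tt <- two_proportion_test(p1$ac[tested], p1$an[tested],
                              p2$ac[tested], p2$an[tested])
    chi[tested] <- tt$chi_square
    pval[tested] <- tt$p_value
  }
  af_diff <- ifelse(tested, p1$af - p2$af, NA_real_)
  differentiated <- tested & !is.na(pval) &
    pval < p_threshold & abs(af_diff) > diff_threshold

  out <- tibble(
    variant_id = as.character(freq$variant_id),
    af_pop1 = ifelse(tested, p1$af, NA_real_),
    af_pop2 = ifelse(tested, p2$af, NA_real_),
    af_diff = af_diff,
    chi_square = chi,
    p_value = pval,
    differentiated = differentiated,
    excluded = !tested,
    exclude_reason = reason
  )
  attr(out, "summary") <- list(
    n_variants = nrow(out),
    n_tested = sum(tested),
    n_excluded = sum(!tested),
    n_differentiated = sum(differentiated),
    fraction_differentiated = if (sum(tested) > 0) {
      sum(differentiated) / sum(tested)
    } else {
      NA_real_
    },
    p_threshold = p_threshold,
    diff_threshold = diff_threshold
  )
  class(out) <- c("popdiff_calls", class(out))
  out
}

#' Read a two-population allele-frequency table
#'
#' TSV with header `variant_id AC_pop1 AN_pop1 AF_pop1 AC_pop2 AN_pop2
#' AF_pop2`; empty fields mark absent records.
#'
#' @param path Path to the frequency TSV.
#' @return A tibble with the seven columns above.
#' @export
read_frequencies <- function(path) {
  if (!file.exists(path)) abort(sprintf("Frequency file not found: %s", path))
  out <- readr::read_tsv(path,
    col_types = readr::cols(
      variant_id = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  need <- c("variant_id", "AC_pop1", "AN_pop1", "AF_pop1",
            "AC_pop2", "AN_pop2", "AF_pop2")
  if (!all(need %in% names(out))) {
    abort(sprintf("Frequency table must have columns: %s.",
                  paste(need, collapse = ", ")))
  }
  out
}

#' Write a two-population allele-frequency table
#'
#' @param freq Frequency tibble (see [read_frequencies()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequencies <- function(freq, path) {
  stop_if_not_df(freq, "freq")
  readr::write_tsv(as_tibble(as.data.frame(freq)), path, progress = FALSE)
  invisible(path)
}
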