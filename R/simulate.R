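#' Pool model weights and segment them into quintile groups
#'
#' Pools the absolute values of every weight row across one or more
#' expression models (no deduplication), sorts them ascending, and
#' partitions the sorted vector into five contiguous, near-equal segments.
#' The first, third and fifth segments are the low, medium and high weight
#' groups used by the simulation grid; taking absolute values avoids
#' cancellation when weights of both signs enter the linear combination.
#'
#' When the pool size is not divisible by five, the remainder `r` is spread
#' one-per-segment over the first `r` segments, so segment sizes differ by
#' at most one.
#'
#' @param models An `expr_model` tibble or a list of them.
#' @return An object of class `weight_pool`: a list with `weights` (sorted
#'   absolute weights), `segment` (segment index 1-5 per weight), and
#'   `bounds` (per-segment size, min and max).
#' @examples
#' m <- tibble::tibble(
#'   gene = "g", variant_id = paste0("v", 1:10),
#'   ref_allele = "A", effect_allele = "G", weight = (1:10) / 100
#' )
#' pool <- build_weight_pool(m)
#' pool_group_weights(pool, "high")  # 0.09 0.10
#' @export
build_weight_pool <- function(models) {
  if (is.data.frame(models)) models <- list(models)
  if (!length(models)) abort("`models` is empty.")
  w <- unlist(lapply(models, function(m) validate_model(m)$weight),
              use.names = FALSE)
  if (!length(w)) abort("Weight pool is empty.")
  w <- sort(abs(w), method = "radix")  # stable ascending
  n <- length(w)
  base <- n %/% 5L
  r <- n %% 5L
  sizes <- base + as.integer(seq_len(5L) <= r)
  if (any(sizes == 0)) {
    abort(sprintf("Pool of %d weights is too small for five segments.", n))
  }
  seg_of <- rep.int(seq_len(5L), sizes)
  bounds <- tibble(
    segment = 1:5,
    group = c("low", NA, "medium", NA, "high"),
    size = sizes,
    min = as.numeric(tapply(w, seg_of, min)[as.character(1:5)]),
    max = as.numeric(tapply(w, seg_of, max)[as.character(1:5)])
  )
  structure(
    list(weights = w, segment = seg_of, bounds = bounds),
    class = "weight_pool"
  )
}

#' @export
print.weight_pool <- function(x, ...) {
  cat(sprintf("<weight_pool> %d pooled |weights|\n", length(x$weights)))
  print(x$bounds)
  invisible(x)
}

#' Extract the weights of a named group from a weight pool
#'
#' @param pool A `weight_pool` (see [build_weight_pool()]).
#' @param group `"low"`, `"medium"` or `"high"` (segments 1, 3, 5).
#' @return Numeric vector of the group's absolute weights.
#' @export
pool_group_weights <- function(pool, group = c("low", "medium", "high")) {
  group <- arg_match(group)
  if (!inherits(pool, "weight_pool")) abort("`pool` must be a weight_pool.")
  seg <- c(low = 1L, medium = 3L, high = 5L)[[group]]
  pool$weights[pool$segment == seg]
}

#' Simulate effect-allele dosages under Hardy-Weinberg
#'
#' Draws i.i.d. dosages from Binomial(2, maf) for each repetition and
#' variant; the random stream is variant-major (all repetitions of variant
#' 1, then variant 2, ...).
#'
#' @param n_variants Number of variants (columns).
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param n_reps Number of repetitions (rows).
#' @param seed Optional integer seed; when given, the global RNG state is
#'   left untouched.
#' @return An `n_reps` x `n_variants` integer matrix of dosages in {0,1,2}.
#' @export
sample_dosages <- function(n_variants, maf, n_reps, seed = NULL) {
  if (!is.numeric(maf) || length(maf) != 1 || maf <= 0 || maf > 0.5) {
    abort("`maf` must lie in (0, 0.5].")
  }
  if (n_variants < 1 || n_reps < 1) {
    abort("`n_variants` and `n_reps` must be positive.")
  }
  maybe_with_seed(seed, {
    matrix(rbinom(n_reps * n_variants, size = 2, prob = maf), nrow = n_reps)
  })
}

#' Simulate one scenario of the four-parameter grid
#'
#' One scenario fixes the number of variants, the MAF shared by all
#' variants, the proportion of population-differentiated variants, and the
#' weight group those differentiated variants draw from. The number of
#' differentiated variants is `round(diff_proportion * n_variants)`
#' (half-up), so e.g. 30 variants at proportion 0.1 give exactly 3.
#' Differentiated variants receive weights sampled with replacement from the
#' requested group; the remaining variants receive weights sampled from the
#' low group. Weights are drawn once and held fixed across repetitions; only
#' the dosages vary. Each repetition draws dosages from Binomial(2, maf) and
#' records the weighted sum.
#'
#' @param pool A `weight_pool`.
#' @param n_variants Number of variants.
#' @param maf Shared minor allele frequency, in (0, 0.5].
#' @param diff_proportion Proportion of differentiated variants, in \[0, 1).
#' @param weight_group Weight group of the differentiated variants.
#' @param n_reps Repetitions (default 500).
#' @param seed Optional integer seed.
#' @return An object of class `scenario_result`: a list with `spec` (the
#'   parameter list, including the realised `n_diff` and a `degenerate` flag
#'   set when `n_diff` is 0 for a non-low group), `weights` (the fixed
#'   per-variant weights, differentiated variants first) and `values` (the
#'   `n_reps` simulated expression draws).
#' @export
simulate_scenario <- function(pool, n_variants, maf, diff_proportion,
                              weight_group = c("low", "medium", "high"),
                              n_reps = 500, seed = NULL) {
  weight_group <- arg_match(weight_group)
  if (diff_proportion < 0 || diff_proportion >= 1) {
    abort("`diff_proportion` must lie in [0, 1).")
  }
  n_diff <- as.integer(round_half_up(diff_proportion * n_variants))
  maybe_with_seed(seed, {
    w_low_pool <- pool_group_weights(pool, "low")
    w_grp_pool <- pool_group_weights(pool, weight_group)
    w_diff <- if (n_diff > 0) {
      w_grp_pool[sample.int(length(w_grp_pool), n_diff, replace = TRUE)]
    } else {
      numeric(0)
    }
    n_rest <- n_variants - n_diff
    w_rest <- if (n_rest > 0) {
      w_low_pool[sample.int(length(w_low_pool), n_rest, replace = TRUE)]
    } else {
      numeric(0)
    }
    w <- c(w_diff, w_rest)
    dos <- sample_dosages(n_variants, maf, n_reps)
    values <- as.numeric(dos %*% w)
    structure(
      list(
        spec = list(
          n_variants = n_variants, maf = maf,
          diff_proportion = diff_proportion, weight_group = weight_group,
          n_reps = n_reps, seed = seed, n_diff = n_diff,
          degenerate = n_diff == 0L && weight_group != "low"
        ),
        weights = w,
        values = values
      ),
      class = "scenario_result"
    )
  })
}

#' Run the full simulation grid
#'
#' Runs [simulate_scenario()] over every combination of variant number, MAF,
#' differentiated-variant proportion and weight group. The defaults span the
#' grid used throughout: 4 variant counts x 5 MAFs x 9 proportions x 3
#' weight groups = 540 scenarios, 500 repetitions each. Each scenario is
#' seeded deterministically from the master seed and its grid index, so any
#' scenario can be reproduced in isolation and the whole grid is
#' bit-reproducible.
#'
#' @param pool A `weight_pool`.
#' @param n_variants Variant counts (default `c(1, 30, 200, 430)`).
#' @param maf MAF grid (default `0.05 + 0.1 * (0:4)`, i.e. 0.05 to 0.45 in
#'   steps of 0.1, generated by index to avoid floating-point drift).
#' @param diff_proportion Proportion grid (default `0.05 * (0:8)`, i.e. 0 to
#'   0.4 in steps of 0.05).
#' @param weight_group Weight groups (default all three).
#' @param n_reps Repetitions per scenario (default 500).
#' @param seed Master seed (default 1).
#' @return A tibble of class `sim_grid` with one row per scenario: columns
#'   `n_variants`, `maf`, `diff_proportion`, `weight_group`, `n_diff`,
#'   `degenerate`, `mean`, `sd`, and a `values` list-column of the raw
#'   draws. Attributes: `n_reps`, `seed`.
#' @export
run_grid <- function(pool,
                     n_variants = c(1, 30, 200, 430),
                     maf = 0.05 + 0.1 * (0:4),
                     diff_proportion = 0.05 * (0:8),
                     weight_group = c("low", "medium", "high"),
                     n_reps = 500, seed = 1) {
  grid <- tidyr::expand_grid(
    n_variants = n_variants,
    maf = maf,
    diff_proportion = diff_proportion,
    weight_group = weight_group
  )
  res <- purrr::pmap(
    list(grid$n_variants, grid$maf, grid$diff_proportion, grid$weight_group,
         seq_len(nrow(grid))),
    function(nv, m, dp, wg, i) {
      simulate_scenario(pool, nv, m, dp, wg,
                        n_reps = n_reps, seed = sub_seed(seed, i))
    }
  )
  out <- grid %>%
    mutate(
      n_diff = vapply(res, function(r) r$spec$n_diff, integer(1)),
      degenerate = vapply(res, function(r) r$spec$degenerate, logical(1)),
      mean = vapply(res, function(r) mean(r$values), numeric(1)),
      sd = vapply(res, function(r) sd(r$values), numeric(1)),
      values = lapply(res, `[[`, "values")
    )
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  class(out) <- c("sim_grid", class(out))
  out
}

#' Empirical cumulative distribution function of simulated draws
#'
#' Thin wrapper over [stats::ecdf()] with the input checks the simulation
#' grid needs: the returned step function is right-continuous, 0 below the
#' minimum and 1 at the maximum.
#'
#' @param values Non-empty numeric vector of finite values.
#' @return A function of class `ecdf`.
#' @export
expression_ecdf <- function(values) {
  if (!length(values)) abort("`values` is empty.")
  if (any(!is.finite(values))) abort("`values` must be finite.")
  ecdf(values)
}

#' Summarise a simulation grid against its zero-proportion baseline
#'
#' For every (n_variants, maf, weight_group) stratum the scenario with
#' `diff_proportion = 0` is the baseline; each scenario is summarised by its
#' mean expression, the mean difference from the baseline mean, and the
#' ratio to the baseline mean (reported as `NA` when the baseline mean is
#' numerically zero).
#'
#' @param grid A `sim_grid` from [run_grid()].
#' @return A tibble of class `grid_summary` with columns `n_variants`,
#'   `maf`, `diff_proportion`, `weight_group`, `mean`, `diff_vs_baseline`,
#'   `ratio_vs_baseline`.
#' @export
summarize_vs_baseline <- function(grid) {
  stop_if_not_df(grid, "grid")
  need <- c("n_variants", "maf", "diff_proportion", "weight_group", "mean")
  if (!all(need %in% names(grid))) {
    abort("`grid` must be a sim_grid (see run_grid()).")
  }
  base <- grid %>%
    as_tibble() %>%
    filter(.data$diff_proportion == 0) %>%
    select("n_variants", "maf", "weight_group", baseline_mean = "mean")
  if (nrow(base) == 0) abort("No diff_proportion = 0 baseline scenarios found.")
  out <- grid %>%
    as_tibble() %>%
    select("n_variants", "maf", "diff_proportion", "weight_group", "mean") %>%
    left_join(base, by = c("n_variants", "maf", "weight_group"))
  if (anyNA(out$baseline_mean)) {
    abort("Missing diff_proportion = 0 baseline for at least one stratum.")
  }
  out <- out %>%
    mutate(
      diff_vs_baseline = .data$mean - .data$baseline_mean,
      ratio_vs_baseline = ifelse(abs(.data$baseline_mean) < 1e-12,
                                 NA_real_, .data$mean / .data$baseline_mean)
    ) %>%
    select(-"baseline_mean")
  class(out) <- c("grid_summary", class(out))
  out
}
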