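test_that("weight pooling takes absolute values and sorts ascending", {
  m <- single_gene_model(c(-0.5, 0.1, 0.3, -0.2, 0.4))
  pool <- build_weight_pool(m)
  expect_equal(pool$weights, c(0.1, 0.2, 0.3, 0.4, 0.5))
  # pooling over several models concatenates without deduplication
  pool2 <- build_weight_pool(list(m, m))
  expect_equal(length(pool2$weights), 10)
  expect_equal(sum(pool2$weights == 0.3), 2)
})

test_that("quintile segmentation matches the forced small-pool layouts", {
  pool <- ladder_pool(10)
  expect_equal(pool_group_weights(pool, "low"), c(0.01, 0.02))
  expect_equal(pool_group_weights(pool, "medium"), c(0.05, 0.06))
  expect_equal(pool_group_weights(pool, "high"), c(0.09, 0.10))

  # remainder goes one-per-segment to the first segments: 7 -> (2,2,1,1,1)
  pool7 <- ladder_pool(7)
  expect_equal(pool7$bounds$size, c(2L, 2L, 1L, 1L, 1L))

  # exhaustive check of the partition rule for all small pool sizes
  for (n in 5:29) {
    sizes <- ladder_pool(n)$bounds$size
    expect_equal(sum(sizes), n)
    expect_lte(diff(range(sizes)), 1)
    expect_true(all(diff(sizes) <= 0)) # larger segments come first
  }
  expect_error(ladder_pool(4), "five segments")
})

test_that("dosage sampling respects the binomial law and the MAF domain", {
  d <- sample_dosages(10, 0.5, 10000, seed = 1)
  expect_true(all(d %in% 0:2))
  expect_gt(mean(d), 0.97)
  expect_lt(mean(d), 1.03)
  expect_identical(sample_dosages(5, 0.25, 20, seed = 9),
                   sample_dosages(5, 0.25, 20, seed = 9))
  expect_error(sample_dosages(10, 0, 10), "maf")
  expect_error(sample_dosages(10, 0.51, 10), "maf")
})

test_that("scenario assigns round-half-up differentiated counts", {
  pool <- ladder_pool(10)
  sc <- simulate_scenario(pool, 30, 0.25, 0.1, "high", n_reps = 10, seed = 2)
  expect_equal(sc$spec$n_diff, 3L)
  expect_equal(length(sc$weights), 30)
  expect_equal(length(sc$values), 10)
  # single-variant scenarios are degenerate for every proportion <= 0.4
  sc1 <- simulate_scenario(pool, 1, 0.25, 0.4, "high", n_reps = 5, seed = 2)
  expect_equal(sc1$spec$n_diff, 0L)
  expect_true(sc1$spec$degenerate)
  # half-up tie-break
  sc2 <- simulate_scenario(pool, 10, 0.25, 0.15, "high", n_reps = 5, seed = 2)
  expect_equal(sc2$spec$n_diff, 2L)
})

test_that("zero difference proportion is identical across weight groups at a seed", {
  pool <- ladder_pool(10)
  a <- simulate_scenario(pool, 20, 0.25, 0, "low", n_reps = 50, seed = 7)
  b <- simulate_scenario(pool, 20, 0.25, 0, "medium", n_reps = 50, seed = 7)
  c <- simulate_scenario(pool, 20, 0.25, 0, "high", n_reps = 50, seed = 7)
  expect_identical(a$values, b$values)
  expect_identical(a$values, c$values)
})

test_that("constant-weight pools give the closed-form weighted dosage sum", {
  # every pool weight equals c: all draws are c * sum(dosages)
  m <- single_gene_model(rep(0.04, 10))
  pool <- build_weight_pool(m)
  sc <- simulate_scenario(pool, 15, 0.3, 0.2, "high", n_reps = 40, seed = 5)
  expect_true(all(abs(sc$weights - 0.04) < 1e-15))
  # every draw is 0.04 times an integer dosage total in 0..30
  expect_true(all(vapply(sc$values / 0.04,
                         function(v) abs(v - round(v)) < 1e-9, logical(1))))
  expect_true(all(sc$values >= 0 & sc$values <= 0.04 * 30))
})

test_that("the default grid has the documented shape and is bit-reproducible", {
  expect_length(formals(run_grid)$maf |> eval(), 5)
  expect_length(formals(run_grid)$diff_proportion |> eval(), 9)
  pool <- ladder_pool(20)
  g1 <- run_grid(pool, n_variants = c(1, 30), maf = c(0.05, 0.45),
                 diff_proportion = c(0, 0.2), n_reps = 30, seed = 42)
  g2 <- run_grid(pool, n_variants = c(1, 30), maf = c(0.05, 0.45),
                 diff_proportion = c(0, 0.2), n_reps = 30, seed = 42)
  expect_identical(g1$values, g2$values)
  expect_equal(nrow(g1), 2 * 2 * 2 * 3)
  # scenarios are independently reproducible from their sub-seeds
  i <- 11
  sc <- simulate_scenario(pool, g1$n_variants[i], g1$maf[i],
                          g1$diff_proportion[i], g1$weight_group[i],
                          n_reps = 30,
                          seed = popexpress:::sub_seed(42, i))
  expect_identical(sc$values, g1$values[[i]])
})

test_that("ECDF wrapper normalises correctly at the support boundaries", {
  x <- c(3, 1, 4, 1, 5)
  F <- expression_ecdf(x)
  expect_equal(F(5), 1)
  expect_equal(F(0.999), 0)
  expect_equal(F(1), 0.4)
  y <- sort(rnorm(500))
  expect_equal(expression_ecdf(y)(y[250]), 0.5)
  expect_error(expression_ecdf(numeric(0)), "empty")
})

test_that("baseline summaries have zero difference and unit ratio on baselines", {
  pool <- constant_pool(a = 0.01, b = 0.05)
  g <- run_grid(pool, n_variants = c(30), maf = c(0.25),
                diff_proportion = c(0, 0.1, 0.2), n_reps = 200, seed = 3)
  s <- summarize_vs_baseline(g)
  base_rows <- s[s$diff_proportion == 0, ]
  expect_true(all(base_rows$diff_vs_baseline == 0))
  expect_true(all(base_rows$ratio_vs_baseline == 1))
  expect_error(
    summarize_vs_baseline(g[g$diff_proportion > 0, ]),
    "baseline"
  )
})

test_that("scenario means track the analytic expectation for two-level pools", {
  # low segment constant a, high segment constant b: expected difference of a
  # diff_proportion scenario vs baseline is d * (b - a) * 2 * maf
  a <- 0.01
  b <- 0.05
  pool <- constant_pool(a = a, b = b)
  maf <- 0.25
  n_reps <- 4000
  sc_base <- simulate_scenario(pool, 30, maf, 0, "high", n_reps, seed = 21)
  sc_diff <- simulate_scenario(pool, 30, maf, 0.2, "high", n_reps, seed = 22)
  d <- sc_diff$spec$n_diff
  expect_equal(d, 6L)
  expected_diff <- d * (b - a) * 2 * maf
  observed_diff <- mean(sc_diff$values) - mean(sc_base$values)
  # 3 binomial standard errors of the mean difference
  var_one <- function(w) sum(w^2) * 2 * maf * (1 - maf)
  se <- sqrt((var_one(sc_diff$weights) + var_one(sc_base$weights)) / n_reps)
  expect_lt(abs(observed_diff - expected_diff), 3 * se)
})

test_that("mean expression orders high > medium > low for differentiated scenarios", {
  cfg <- synth_config(n_tissues = 3, n_genes = 40, seed = 31)
  pool <- build_weight_pool(synth_models(cfg))
  means <- vapply(c("low", "medium", "high"), function(g) {
    mean(simulate_scenario(pool, 200, 0.25, 0.3, g,
                           n_reps = 1500, seed = 77)$values)
  }, numeric(1))
  expect_true(means[["high"]] > means[["medium"]])
  expect_true(means[["medium"]] > means[["low"]])
})
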