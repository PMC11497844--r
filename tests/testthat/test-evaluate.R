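test_that("percentile rank follows the inclusive counting definition", {
  ref <- 1:500
  expect_equal(percentile_rank(0, ref), 0)
  expect_equal(percentile_rank(500, ref), 100)
  expect_equal(percentile_rank(12.5, ref), 2.4) # 12 of 500 are <= 12.5
  expect_equal(percentile_rank(c(0, 12.5, 500), ref), c(0, 2.4, 100))
  # ties count inclusively
  expect_equal(percentile_rank(2, c(1, 2, 2, 3)), 75)
  # ranks land on the 100/n grid
  set.seed(1)
  r <- percentile_rank(rnorm(50), rnorm(500))
  expect_true(all(abs(r * 5 - round(r * 5)) < 1e-9))
  expect_error(percentile_rank(1, numeric(0)), "empty")
})

test_that("reference intervals use the linear-interpolation quantile", {
  expect_equal(reference_interval(1:500, 0.95),
               c(lo = 13.475, hi = 487.525))
  expect_equal(reference_interval(c(5, 1, 9), 1), c(lo = 1, hi = 9))
  expect_equal(reference_interval(rep(3.3, 10), 0.9), c(lo = 3.3, hi = 3.3))
  expect_error(reference_interval(1:10, 0), "level")
  expect_error(reference_interval(1:10, 1.2), "level")
})

make_eval_fixture <- function(n_genes = 5, n_subjects = 4, seed = 300) {
  cfg <- synth_config(n_tissues = 1, n_genes = n_genes, seed = seed,
                      diff_fraction = 0.4, delta_af = 0.2)
  m <- synth_models(cfg)[[1]]
  freq <- synth_frequencies(m, cfg)
  panel <- build_reference(m, freq, "pop1", n_reps = 200, seed = seed + 1)
  panel_b <- build_reference(m, freq, "pop2", n_reps = 200, seed = seed + 2)
  cmp <- compare_populations(panel, panel_b)
  geno <- synth_genotypes(freq, "pop1", n_subjects, seed = seed + 3)
  pred <- synth_predictions(m, geno)
  list(model = m, panel = panel, cmp = cmp, pred = pred)
}

test_that("reports are subject-major with genes in panel order", {
  fx <- make_eval_fixture(n_genes = 3, n_subjects = 2)
  rep_tbl <- make_report(fx$pred, fx$panel, fx$cmp)
  expect_equal(nrow(rep_tbl), 2 * 3)
  expect_equal(rep_tbl$IID, rep(fx$pred$IID, each = 3))
  expect_equal(rep_tbl$gene, rep(fx$panel$gene, times = 2))
  expect_true(all(rep_tbl$pop_diff %in% c("Sig.", "Nonsig.")))
  # panel columns match the panel rows gene by gene
  i <- match(rep_tbl$gene, fx$panel$gene)
  expect_equal(rep_tbl$ref_mean, fx$panel$mean[i])
  expect_equal(rep_tbl$ref_sd, fx$panel$sd[i])
  expect_equal(rep_tbl$n_variants, fx$panel$n_variants[i])
  # rank recomputes from the raw values
  j <- 4
  expect_equal(
    rep_tbl$percentile_rank[j],
    percentile_rank(rep_tbl$value[j],
                    fx$panel$values[[match(rep_tbl$gene[j], fx$panel$gene)]])
  )
})

test_that("a predicted value at the panel median ranks near 50", {
  fx <- make_eval_fixture(n_genes = 1, n_subjects = 1)
  med <- median(fx$panel$values[[1]])
  pred <- fx$pred
  pred[[fx$panel$gene[1]]] <- med
  rep_tbl <- make_report(pred, fx$panel)
  expect_gt(rep_tbl$percentile_rank, 45)
  expect_lt(rep_tbl$percentile_rank, 56)
})

test_that("genes absent from the panel are excluded and reported", {
  fx <- make_eval_fixture(n_genes = 3, n_subjects = 2)
  pred <- fx$pred
  pred$NOT_A_GENE <- 1.0
  rep_tbl <- make_report(pred, fx$panel, fx$cmp)
  expect_false("NOT_A_GENE" %in% rep_tbl$gene)
  expect_identical(attr(rep_tbl, "unmatched_genes"), "NOT_A_GENE")
  pred_none <- pred[, c("FID", "IID", "NOT_A_GENE")]
  expect_error(make_report(pred_none, fx$panel), "overlap")
})

test_that("the optional subject deviation column is value minus panel mean", {
  fx <- make_eval_fixture(n_genes = 2, n_subjects = 2)
  rep_tbl <- make_report(fx$pred, fx$panel, fx$cmp, subject_dev = TRUE)
  expect_equal(rep_tbl$subject_dev, rep_tbl$value - rep_tbl$ref_mean)
  expect_false("subject_dev" %in% names(make_report(fx$pred, fx$panel)))
})

test_that("dataset summaries satisfy the column identities", {
  fx <- make_eval_fixture(n_genes = 4, n_subjects = 61)
  data_counts <- setNames(pmax(fx$panel$n_variants - 1, 1), fx$panel$gene)
  model_counts <- setNames(fx$panel$n_variants, fx$panel$gene)
  ds <- dataset_summary(fx$pred, fx$panel, data_counts, model_counts)
  expect_identical(
    names(ds),
    c("Gene", "Ref.Mean", "Ref.Sd", "Data.Mean", "Data.Sd", "Abs.Diff",
      "Ratio.Diff", "Data.SNP.Num", "Predixcan_SNP.Num", "SNP.Ratio",
      "GE.Match.Ref.Num", "GE.Match.Ref.Ratio")
  )
  expect_equal(ds$Abs.Diff, abs(ds$Data.Mean - ds$Ref.Mean))
  expect_equal(ds$Ratio.Diff, ds$Abs.Diff / abs(ds$Ref.Mean))
  expect_equal(ds$SNP.Ratio, ds$Data.SNP.Num / ds$Predixcan_SNP.Num)
  expect_equal(ds$GE.Match.Ref.Ratio, ds$GE.Match.Ref.Num / 61)
  # counting oracle for the interval membership
  g <- ds$Gene[1]
  iv <- reference_interval(fx$panel$values[[match(g, fx$panel$gene)]], 0.95)
  expect_equal(
    ds$GE.Match.Ref.Num[1],
    sum(fx$pred[[g]] >= iv[["lo"]] & fx$pred[[g]] <= iv[["hi"]])
  )
  # 45 of 61 inside -> ratio 0.7377 at 4 dp
  expect_equal(round(45 / 61, 4), 0.7377)
})

test_that("dataset summaries handle hand-computed and degenerate cases", {
  # ref_mean 2.0, data_mean 1.5 -> abs 0.5, ratio 0.25
  expect_equal(abs(1.5 - 2.0) / abs(2.0), 0.25)
  fx <- make_eval_fixture(n_genes = 2, n_subjects = 3)
  counts <- setNames(rep(1, nrow(fx$panel)), fx$panel$gene)
  expect_error(
    dataset_summary(fx$pred, fx$panel, counts[1], counts),
    "missing"
  )
  zero_model <- setNames(rep(0, nrow(fx$panel)), fx$panel$gene)
  ds <- dataset_summary(fx$pred, fx$panel, counts, zero_model)
  expect_true(all(is.na(ds$SNP.Ratio)))
})

test_that("self-ranked panels are uniform and coverage is calibrated (small n)", {
  cfg <- synth_config(n_tissues = 1, n_genes = 25, seed = 900,
                      diff_fraction = 0, n_subjects = 200,
                      variant_count_law = function(n) rep.int(30L, n))
  m <- synth_models(cfg)[[1]]
  freq <- synth_frequencies(m, cfg)
  panel <- build_reference(m, freq, "pop1", n_reps = 200, seed = 901)
  # ranks of a panel's own draws are the full grid 0.5, 1.0, ..., 100
  ranks <- percentile_rank(panel$values[[1]], panel$values[[1]])
  expect_equal(sort(ranks), seq(0.5, 100, by = 0.5))
  # same-population predictions hit the 95% interval about 95% of the time
  geno <- synth_genotypes(freq, "pop1", cfg$n_subjects, seed = 902)
  pred <- synth_predictions(m, geno)
  hits <- vapply(panel$gene, function(g) {
    iv <- reference_interval(panel$values[[match(g, panel$gene)]], 0.95)
    mean(pred[[g]] >= iv[["lo"]] & pred[[g]] <= iv[["hi"]])
  }, numeric(1))
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})
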