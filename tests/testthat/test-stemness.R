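test_that("module score is zero when all genes are identical", {
  counts <- matrix(7L, nrow = 20, ncol = 30)
  coh <- normalize_cells(toy_cohort(counts))
  sc <- score_cells(coh, colnames(coh$counts)[1:6])
  expect_true(all(abs(sc$score) < 1e-12))
})

test_that("scores separate planted populations and are deterministic", {
  sim <- shared_sim()
  sc <- score_cells(sim$cohort, sim$truth$signature_genes, seed = 4)
  stem <- sim$truth$cells$true_label == "stem"
  expect_gte(auc_score(sc$score, stem), 0.9)
  sc2 <- score_cells(sim$cohort, sim$truth$signature_genes, seed = 4)
  expect_identical(sc$score, sc2$score)
})

test_that("scores are invariant to gene order and to absent genes", {
  sim <- shared_sim()
  genes <- sim$truth$signature_genes
  a <- score_cells(sim$cohort, genes, seed = 9)
  b <- score_cells(sim$cohort, rev(genes), seed = 9)
  expect_identical(a$score, b$score)
  expect_warning(score_cells(sim$cohort, c(genes, "NOT_A_GENE"), seed = 9),
                 "absent")
  c_ <- suppressWarnings(
    score_cells(sim$cohort, c(genes, "NOT_A_GENE"), seed = 9))
  expect_identical(a$score, c_$score)
  expect_error(suppressWarnings(score_cells(sim$cohort, c("NOPE1", "NOPE2"))),
               "No signature")
})

test_that("Jenks breaks match the worked examples", {
  expect_equal(jenks_breaks(c(1, 2, 3, 10, 11, 12, 20, 21, 22), k = 3),
               c(3, 12))
  expect_equal(jenks_breaks(c(1, 1, 1, 9, 9, 9), k = 2), 1)
  expect_error(jenks_breaks(rep(5, 10), k = 2), "distinct")
})

test_that("Jenks equals the exhaustive-partition oracle on random inputs", {
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    k <- sample(2:4, 1)
    x <- round(runif(n, 0, 100), 3)
    if (length(unique(x)) < k) next
    expect_equal(jenks_breaks(x, k), oracle_jenks(x, k),
                 info = sprintf("n=%d k=%d", n, k))
  }
})

test_that("classification is strict and categories follow the cutoffs", {
  expect_false(classify_cells(0.25, 0.25))
  expect_true(classify_cells(0.26, 0.25))
  expect_identical(sum(classify_cells(c(-1, 0, 0.2), 0.25)), 0L)
  expect_error(classify_cells(c(0.1), NA), "finite")

  expect_identical(as.character(categorize_sample(c(0.20, 0.10, 0.15, 0.05,
                                                    0.04))),
                   c("high", "moderate", "moderate", "moderate", "low"))
  expect_error(categorize_sample(1.3), "\\[0, 1\\]")
})

test_that("the stemness wrapper threads scores, breaks and categories", {
  sim <- shared_sim()
  st <- stemness(sim$cohort, sim$truth$signature_genes, seed = 2)
  expect_length(st$breaks, 3)
  expect_true(all(diff(st$breaks) > 0))
  expect_equal(st$threshold, max(st$breaks))
  expect_identical(st$cells$stem, st$cells$score > st$threshold)
  expect_true(all(st$samples$stem_fraction >= 0 & st$samples$stem_fraction <= 1))
  expect_identical(as.character(st$samples$category),
                   as.character(categorize_sample(st$samples$stem_fraction)))
  # the uppermost-break threshold yields a high-precision stem-like call:
  # everything above the top class boundary belongs to the planted population
  truth_stem <- sim$truth$cells$true_label == "stem"
  expect_gte(mean(truth_stem[st$cells$stem]), 0.95)
  expect_gte(sum(st$cells$stem & truth_stem) / sum(truth_stem), 0.5)
  per_sample <- dplyr::inner_join(st$samples, sim$truth$sample_fractions,
                                  by = "sample")
  expect_gt(cor(per_sample$stem_fraction.x, per_sample$stem_fraction.y), 0.9)
  # tidiers
  expect_identical(tidy(st), st$samples)
  g <- glance(st)
  expect_equal(g$stem_frequency_pct,
               round(100 * mean(st$cells$stem), 2))
  # fixed-threshold mode
  st2 <- stemness(sim$cohort, sim$truth$signature_genes, threshold = 0.25,
                  seed = 2)
  expect_identical(st2$threshold_source, "fixed")
  expect_identical(st2$cells$stem, st2$cells$score > 0.25)
})

test_that("bulk scoring and group comparisons follow their formulas", {
  set.seed(5)
  expr <- matrix(rnorm(40), nrow = 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  sc <- score_bulk(expr, paste0("g", 1:4))
  z <- t(scale(t(expr)))
  expect_equal(sc$score, unname(colMeans(z)), tolerance = 1e-12)

  # paired differences [1,2,3]: t = 3.464, p = 0.074 at df 2
  r <- compare_groups(c(2, 4, 6), paired = TRUE, y = c(1, 2, 3))
  expect_equal(unname(r$statistic), sqrt(12), tolerance = 1e-3)
  expect_equal(r$p_value, 2 * pt(-sqrt(12), df = 2), tolerance = 1e-9)

  # identical groups (with variance): t = 0, p = 1
  r2 <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(unname(r2$statistic), 0)
  expect_equal(r2$p_value, 1)

  # degenerate paired input flagged
  r3 <- compare_groups(c(1, 2), paired = TRUE, y = c(1, 2))
  expect_true(r3$degenerate)
})

test_that("bulk group shift is detected at the simulated cohort scale", {
  cfg <- sim_config(n_genes = 300, n_signature_genes = 50,
                    n_samples_per_group = 100, group_score_shift = 0.5,
                    seed = 19)
  sig <- sprintf("SIG%04d", 1:50)
  bulk <- simulate_bulk(cfg, sig)
  sc <- score_bulk(bulk$expr, sig)
  keep <- bulk$samples$group %in% c("M1", "M3")
  r <- compare_groups(sc$score[keep], bulk$samples$group[keep])
  expect_lt(r$p_value, 0.05)
  expect_lt(r$estimate, 0)  # M1 mean below M3
})
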