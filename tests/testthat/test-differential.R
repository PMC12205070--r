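test_that("rank-sum test matches its exact enumeration on small inputs", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(rank_sum_test(c(1, 3), c(2, 4))$p_value, 2 / 3)
  expect_equal(rank_sum_test(c(5), c(5))$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("exact branch equals the enumeration oracle for all small sizes", {
  set.seed(7)
  for (nx in 1:4) {
    for (ny in 1:4) {
      for (rep in 1:3) {
        x <- sample(100, nx)
        y <- sample(setdiff(1:200, x), ny)
        expect_equal(rank_sum_test(x, y)$p_value, oracle_rank_sum_p(x, y),
                     tolerance = 1e-12,
                     info = sprintf("nx=%d ny=%d rep=%d", nx, ny, rep))
      }
    }
  }
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.04, 0.9)), c(0.08, 0.9))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("log2 fold-change follows its closed form with pseudocount", {
  m <- rbind(a1 = c(4, 4, 1), a2 = c(4, 4, 1),
             b1 = c(1, 4, 0), b2 = c(1, 4, 0))
  colnames(m) <- c("up", "flat", "aonly")
  lfc <- log2_fold_change(m, c("a1", "a2"), c("b1", "b2"))
  expect_equal(lfc$log2fc[lfc$gene == "up"], 2, tolerance = 1e-6)
  expect_equal(lfc$log2fc[lfc$gene == "flat"], 0)
  expect_equal(lfc$log2fc[lfc$gene == "aonly"], log2((1 + 1e-9) / 1e-9),
               tolerance = 1e-6)
  expect_true(all(is.finite(lfc$log2fc)))
  expect_error(log2_fold_change(m, c("a1", "b1"), c("b1", "b2")), "disjoint")
})

test_that("signature derivation recovers the planted gene set", {
  sim <- shared_sim()
  sig <- derive_signature(sim$cohort, sim$truth$cells$true_label, "stem")
  expect_gte(jaccard(sig$gene, sim$truth$signature_genes), 0.7)
  expect_true(all(diff(sig$log2fc) <= 0))
  expect_true(all(sig$p_adjusted < 0.05 & sig$log2fc > 0.5))
  # impossible threshold empties the signature
  sig_inf <- derive_signature(sim$cohort, sim$truth$cells$true_label, "stem",
                              lfc_min = Inf)
  expect_identical(nrow(sig_inf), 0L)
  expect_error(derive_signature(sim$cohort, rep("x", nrow(sim$cohort$counts)),
                                "stem"))
})

test_that("label swap negates fold changes and preserves p-values", {
  sim <- shared_sim()
  a <- attr(derive_signature(sim$cohort, sim$truth$cells$true_label, "stem"),
            "tested")
  b <- attr(derive_signature(sim$cohort, sim$truth$cells$true_label, "other"),
            "tested")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-9)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("vectorized DE p-values agree with the per-gene test", {
  sim <- shared_sim()
  tested <- attr(derive_signature(sim$cohort, sim$truth$cells$true_label,
                                  "stem"), "tested")
  norm <- as.matrix(sim$cohort$normalized)
  stem <- sim$truth$cells$true_label == "stem"
  for (g in tested$gene[c(1, 50, 300)]) {
    ref <- rank_sum_test(norm[stem, g], norm[!stem, g])
    row <- tested[tested$gene == g, ]
    expect_equal(row$p_value, ref$p_value, tolerance = 1e-9, info = g)
    expect_equal(row$statistic, unname(ref$statistic), info = g)
  }
})

test_that("no planted effect keeps null DE discoveries at or below 5%", {
  cfg <- sim_config(n_patients = 1, cells_per_sample = 400, n_genes = 500,
                    n_signature_genes = 50, signature_log2fc = 0,
                    quiescence_fold = 1, phase_fold = 1,
                    stem_fraction_initial = 0.3, stem_fraction_relapse = 0.3,
                    seed = 77)
  sim <- simulate_cohort(cfg)
  coh <- normalize_cells(sim$cohort)
  tested <- attr(derive_signature(coh, sim$truth$cells$true_label, "stem"),
                 "tested")
  expect_lte(mean(tested$p_adjusted < 0.05), 0.05)
})

test_that("Fisher regulon enrichment matches hypergeometric enumeration", {
  # the worked 2x2 example: [[3,1],[1,3]] -> p = 34/70
  act <- matrix(c(rep(0.9, 3), 0.1, 0.9, rep(0.1, 3)), ncol = 1,
                dimnames = list(NULL, "R1"))
  labels <- rep(c("in", "out"), each = 4)
  res <- regulon_enrichment(act, labels, "in", thresholds = c(R1 = 0.5))
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-9)

  set.seed(3)
  for (rep in 1:25) {
    n_in <- sample(2:15, 1); n_out <- sample(2:15, 1)
    act <- matrix(runif(n_in + n_out), ncol = 1, dimnames = list(NULL, "R"))
    labels <- rep(c("t", "o"), c(n_in, n_out))
    thr <- 0.5
    a <- sum(act[labels == "t"] > thr); b <- sum(act[labels == "o"] > thr)
    res <- regulon_enrichment(act, labels, "t", thresholds = c(R = thr))
    if (res$degenerate) next
    expect_equal(res$p_value,
                 oracle_fisher_p(a, b, n_in - a, n_out - b),
                 tolerance = 1e-9)
  }
})

test_that("degenerate and planted regulons are handled as specified", {
  sim <- shared_sim()
  stem <- sim$truth$cells$true_label
  res <- regulon_enrichment(sim$cohort, stem, "stem")
  planted <- sim$truth$regulons
  enriched <- res$regulon[res$significant & res$log2fc > 0]
  depleted <- res$regulon[res$significant & res$log2fc < 0]
  expect_setequal(enriched, planted$regulon[planted$planted == "enriched"])
  expect_setequal(depleted, planted$regulon[planted$planted == "depleted"])

  # all-active regulon: degenerate, p = 1, log2fc = 0
  act <- matrix(0.99, nrow = 10, ncol = 1, dimnames = list(NULL, "R1"))
  r <- regulon_enrichment(act, rep(c("a", "b"), 5), "a",
                          thresholds = c(R1 = 0.5))
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  expect_equal(r$log2fc, 0)
})
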