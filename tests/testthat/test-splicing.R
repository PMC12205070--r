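test_that("psi arithmetic and boundaries", {
  expect_equal(compute_psi(30, 70), 0.3)
  expect_equal(compute_psi(0, 50), 0)
  expect_equal(compute_psi(50, 0), 1)
  expect_warning(out <- compute_psi(c(3, 0), c(7, 0)), "zero total")
  expect_equal(out, c(0.3, NA))
  expect_error(compute_psi(-1, 5), "non-negative")
})

test_that("beta significance matches the closed-form Beta(2,2) example", {
  # reference mean 0.5, variance 0.05 -> alpha = beta = 2;
  # F(0.9) = 3 * 0.81 - 2 * 0.729 = 0.972, p = 0.056
  ref <- c(0.5 + sqrt(0.05) * scale(qnorm((1:20 - 0.5) / 20))[, 1])
  expect_equal(mean(ref), 0.5, tolerance = 1e-9)
  expect_equal(var(ref), 0.05, tolerance = 1e-9)
  r <- beta_significance(0.9, ref)
  expect_equal(r$alpha, 2, tolerance = 1e-6)
  expect_equal(r$beta, 2, tolerance = 1e-6)
  expect_equal(r$p_value, 2 * (1 - (3 * 0.9^2 - 2 * 0.9^3)), tolerance = 1e-6)

  # observation at the reference centre is unremarkable
  expect_gt(beta_significance(0.5, ref)$p_value, 0.95)
  # degenerate when the reference has no variance
  expect_true(beta_significance(0.5, rep(0.4, 10))$degenerate)
  expect_error(beta_significance(0.5, c(0.1, 0.2)), "at least 5")
})

test_that("beta significance is symmetric under reflection about 0.5", {
  set.seed(21)
  ref <- rbeta(50, 4, 7)
  for (obs in c(0.1, 0.35, 0.8)) {
    a <- beta_significance(obs, ref)$p_value
    b <- beta_significance(1 - obs, 1 - ref)$p_value
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("differential nodes flag the planted shift and respect filters", {
  cfg <- sim_config(n_patients = 1, cells_per_sample = 200, n_genes = 200,
                    n_signature_genes = 30, stem_fraction_initial = 0.5,
                    stem_fraction_relapse = 0.5, n_nodes = 30,
                    n_planted_nodes = 5, reads_per_node = 200,
                    psi_background = 0.2, psi_stem = 0.7, seed = 51)
  sim <- simulate_cohort(cfg)
  tbl <- simulate_splice_counts(cfg, sim$truth)
  stem_cells <- sim$truth$cells$barcode[sim$truth$cells$true_label == "stem"]
  res <- differential_nodes(tbl, stem_cells)
  truth_nodes <- attr(tbl, "node_truth")
  planted <- truth_nodes$node_id[truth_nodes$planted]
  hit <- res[res$node_id %in% planted, ]
  expect_true(all(hit$significant))
  expect_equal(hit$delta_psi, rep(0.5, nrow(hit)), tolerance = 0.08)
  # cell-order invariance
  res2 <- differential_nodes(tbl[sample(nrow(tbl)), ], stem_cells)
  expect_equal(res[order(res$node_id), ]$p_wilcox,
               res2[order(res2$node_id), ]$p_wilcox)

  # all cells below min_reads: node excluded; none qualifying: empty result
  expect_identical(nrow(differential_nodes(tbl, stem_cells, min_reads = 1e6)),
                   0L)
})

test_that("null nodes are rarely flagged across replicates", {
  hits <- 0L
  n_nodes_total <- 0L
  for (r in 1:20) {
    cfg <- sim_config(n_patients = 1, cells_per_sample = 60, n_genes = 200,
                      n_signature_genes = 30, stem_fraction_initial = 0.5,
                      stem_fraction_relapse = 0.5, n_nodes = 10,
                      n_planted_nodes = 0, reads_per_node = 200, seed = 600 + r)
    sim <- simulate_cohort(cfg)
    tbl <- simulate_splice_counts(cfg, sim$truth)
    stem_cells <- sim$truth$cells$barcode[sim$truth$cells$true_label == "stem"]
    res <- differential_nodes(tbl, stem_cells)
    hits <- hits + sum(res$significant)
    n_nodes_total <- n_nodes_total + nrow(res)
  }
  expect_lte(hits / n_nodes_total, 0.05)
})

test_that("recurrence across patients is a straight incidence filter", {
  sets <- list(P1 = c("g1", "g2"), P2 = c("g2", "g3"))
  rec <- recurrent_as_genes(sets)
  expect_identical(rec$gene, "g2")
  expect_identical(rec$n_patients, 2)
  expect_true(rec$P1 && rec$P2)

  expect_identical(nrow(recurrent_as_genes(list(P1 = "a", P2 = "b"))), 0L)
  un <- recurrent_as_genes(list(P1 = c("a", "b"), P2 = "c"), min_patients = 1)
  expect_setequal(un$gene, c("a", "b", "c"))
  expect_error(recurrent_as_genes(list(P1 = "a")), "2 patients")
})

test_that("GO over-representation equals the hypergeometric closed form", {
  universe <- paste0("u", 1:20)
  term <- list(big = universe,
               hit = paste0("u", 1:5))
  query <- paste0("u", c(1:4, 10))
  res <- go_overrepresentation(query, term, universe)
  expect_equal(res$p_value[res$term == "big"], 1)
  expect_equal(res$p_value[res$term == "hit"], 76 / 15504, tolerance = 1e-9)
  expect_equal(res$p_adjusted, bh_adjust(res$p_value))
  expect_error(go_overrepresentation(character(0), term, universe), "empty")
  expect_error(go_overrepresentation(c("zz"), term, universe), "outside")
  expect_warning(
    go_overrepresentation(query, list(t = c("u1", "not_in_universe")),
                          universe),
    "trimmed")
})
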