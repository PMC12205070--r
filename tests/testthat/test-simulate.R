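test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_genes = -5), "positive integer")
  expect_error(sim_config(cells_per_sample = 10.5), "positive integer")
  expect_error(sim_config(stem_fraction_relapse = 1.2), "proportion")
  expect_error(sim_config(nb_dispersion = 0), "positive")
  expect_error(sim_config(reads_per_node = 0), "positive")
  expect_error(sim_config(n_genes = 250, n_signature_genes = 200,
                          n_phase_genes = 50), "exceed")
})

test_that("cohort simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 1, cells_per_sample = 60, n_genes = 200,
                    n_signature_genes = 30, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.matrix(a$cohort$counts), as.matrix(b$cohort$counts))
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$cohort$regulons, b$cohort$regulons)
})

test_that("planted stem fractions behave like the configured binomials", {
  cfg <- sim_config(n_patients = 1, cells_per_sample = 1000, n_genes = 200,
                    n_signature_genes = 30, stem_fraction_initial = 0,
                    stem_fraction_relapse = 0.25, seed = 9)
  sim <- simulate_cohort(cfg)
  fr <- sim$truth$sample_fractions
  expect_identical(fr$n_stem[fr$timepoint == "initial"], 0L)
  n_rel <- fr$n_stem[fr$timepoint == "relapse"]
  sd3 <- 3 * sqrt(1000 * 0.25 * 0.75)
  expect_lt(abs(n_rel - 250), sd3)
  # truth labels reproduce the recorded per-sample fractions exactly
  recount <- sim$truth$cells |>
    dplyr::group_by(sample) |>
    dplyr::summarise(f = mean(true_label == "stem"))
  expect_equal(sort(recount$f), sort(fr$stem_fraction))
})

test_that("counts are non-negative integers with recoverable moments", {
  cfg <- sim_config(n_patients = 1, cells_per_sample = 2000, n_genes = 300,
                    n_signature_genes = 30, stem_fraction_initial = 0,
                    stem_fraction_relapse = 0, phase_fold = 1,
                    nb_dispersion = 0.3, seed = 21)
  sim <- simulate_cohort(cfg)
  m <- as.matrix(sim$cohort$counts[sim$truth$cells$timepoint == "initial", ])
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  # pooled method-of-moments dispersion across well-expressed genes
  mu <- colMeans(m)
  v <- matrixStats::colVars(m)
  keep <- mu > 1
  phi <- sum(v[keep] - mu[keep]) / sum(mu[keep]^2)
  expect_lt(abs(phi - 0.3) / 0.3, 0.1)
  # configured sequencing depth is recovered by the mean library size
  expect_lt(abs(mean(rowSums(m)) - cfg$library_size_mean) /
              cfg$library_size_mean, 0.1)
})

test_that("splice counts carry the planted inclusion shifts", {
  cfg <- sim_config(n_patients = 1, cells_per_sample = 150, n_genes = 200,
                    n_signature_genes = 30, stem_fraction_initial = 0.3,
                    stem_fraction_relapse = 0.3, n_nodes = 20,
                    n_planted_nodes = 4, reads_per_node = 200,
                    psi_background = 0.3, psi_stem = 0.3, seed = 31)
  sim <- simulate_cohort(cfg)
  tbl <- simulate_splice_counts(cfg, sim$truth)
  truth_nodes <- attr(tbl, "node_truth")
  # psi_stem == psi_background: nothing is differential
  expect_true(all(truth_nodes$psi_stem == truth_nodes$psi_other))
  # pooled psi estimate within 3 binomial SEs of the planted rate
  one <- tbl[tbl$node_id == "node001", ]
  psi_hat <- sum(one$incl_count) / sum(one$incl_count + one$excl_count)
  se <- sqrt(0.3 * 0.7 / sum(one$incl_count + one$excl_count))
  expect_lt(abs(psi_hat - 0.3), 3 * se)

  # boundary: psi = 1 means no exclusion reads anywhere
  cfg1 <- sim_config(n_patients = 1, cells_per_sample = 40, n_genes = 200,
                     n_signature_genes = 30, n_nodes = 5, n_planted_nodes = 5,
                     stem_fraction_initial = 0.5, stem_fraction_relapse = 0.5,
                     psi_background = 1, psi_stem = 1, seed = 32)
  sim1 <- simulate_cohort(cfg1)
  tbl1 <- simulate_splice_counts(cfg1, sim1$truth)
  expect_true(all(tbl1$excl_count == 0))
})

test_that("bulk cohorts shift signature scores per ordinal group step", {
  cfg <- sim_config(n_genes = 300, n_signature_genes = 50,
                    n_samples_per_group = 100, group_score_shift = 0.5,
                    seed = 41)
  sig <- sprintf("SIG%04d", 1:50)
  bulk <- simulate_bulk(cfg, sig)
  expect_identical(dim(bulk$expr)[2], 300L)
  sc <- score_bulk(bulk$expr, sig)
  means <- tapply(sc$score, bulk$samples$group, mean)
  # z-scoring across samples attenuates the raw 2*shift difference by the
  # total per-gene SD sqrt(1 + shift^2 * var(steps)); var(0,1,2) = 2/3
  expected <- 2 * 0.5 / sqrt(1 + 0.5^2 * 2 / 3)
  se <- sqrt(2 / (50 * 100))  # ~SE of the mean difference of mean z-scores
  expect_lt(abs((means[["M3"]] - means[["M1"]]) - expected), 3 * se + 0.02)
  expect_gt(means[["M2"]], means[["M1"]])

  # zero shift: group means equal within sampling error
  cfg0 <- sim_config(n_genes = 300, n_signature_genes = 50,
                     n_samples_per_group = 100, group_score_shift = 0,
                     seed = 42)
  bulk0 <- simulate_bulk(cfg0, sig)
  sc0 <- score_bulk(bulk0$expr, sig)
  m0 <- tapply(sc0$score, bulk0$samples$group, mean)
  expect_lt(max(m0) - min(m0), 0.15)
  # reproducible under the seed
  bulk0b <- simulate_bulk(cfg0, sig)
  expect_identical(bulk0$expr, bulk0b$expr)
  expect_error(simulate_bulk(cfg0, character(0)), "non-empty")
})
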