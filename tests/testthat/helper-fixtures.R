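# Small shared fixtures, built in code at test time.

toy_cohort <- function(counts = NULL, n_cells = 6, n_genes = 5) {
  if (is.null(counts)) {
    set.seed(42)
    counts <- matrix(rpois(n_cells * n_genes, 5), nrow = n_cells)
  }
  rownames(counts) <- sprintf("cell%02d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("gene%02d", seq_len(ncol(counts)))
  cells <- tibble::tibble(
    barcode = rownames(counts),
    patient = "P01",
    sample = rep(c("P01_initial", "P01_relapse"), length.out = nrow(counts)),
    timepoint = rep(c("initial", "relapse"), length.out = nrow(counts))
  )
  cohort(counts, cells)
}

# a small simulated cohort reused by several files (memoized per session)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_patients = 2, cells_per_sample = 200, n_genes = 600,
                        n_signature_genes = 80, signature_log2fc = 2,
                        stem_fraction_initial = 0.1, stem_fraction_relapse = 0.3,
                        seed = 101)
      sim <- simulate_cohort(cfg)
      sim$cohort <- normalize_cells(sim$cohort)
      cache <<- sim
    }
    cache
  }
})
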