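#' Pipeline configuration
#'
#' Collects the thresholds and sizes of the full synthetic analysis pipeline.
#' Round-trips losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param sim A [sim_config()] for the synthetic cohort.
#' @param lfc_min,alpha Signature derivation thresholds.
#' @param log2fd_min,B Composition-test effect floor and permutation count.
#' @param stem_threshold Fixed stemness threshold; `NULL` derives it from the
#'   uppermost Jenks break.
#' @param jenks_k Number of Jenks classes.
#' @param category_bounds Two ascending proportions separating low / moderate
#'   / high stem-fraction samples.
#' @param n_perm GSEA permutations.
#' @param seed Pipeline seed (simulation sub-seeds derive from the sim config).
#' @param out_dir Output directory for the report bundle.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            lfc_min = 0.5, alpha = 0.05,
                            log2fd_min = 0.25, B = 1000,
                            stem_threshold = NULL, jenks_k = 4,
                            category_bounds = c(0.05, 0.15),
                            n_perm = 500, seed = 1L,
                            out_dir = tempfile("stemscore_run_")) {
  stopifnot(inherits(sim, "sim_config"))
  if (lfc_min < 0 || alpha <= 0 || alpha > 1 || log2fd_min < 0) {
    abort("Thresholds out of range.")
  }
  if (jenks_k < 2) abort("`jenks_k` must be at least 2.")
  if (length(category_bounds) != 2 || diff(category_bounds) <= 0 ||
      any(category_bounds < 0) || any(category_bounds > 1)) {
    abort("`category_bounds` must be two ascending proportions.")
  }
  structure(
    list(sim = sim, lfc_min = lfc_min, alpha = alpha,
         log2fd_min = log2fd_min, B = B, stem_threshold = stem_threshold,
         jenks_k = jenks_k, category_bounds = category_bounds,
         n_perm = n_perm, seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst$sim <- unclass(lst$sim)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  sim <- do.call(sim_config, lst$sim)
  lst$sim <- NULL
  do.call(pipeline_config, c(list(sim = sim), lst))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full synthetic pipeline
#'
#' Simulate a cohort with known truth, normalize, cluster on expression,
#' assign cell-cycle phases, pick the most quiescent cluster (highest G1
#' fraction) as the stem-like candidate, derive its signature, score and
#' threshold all cells, categorize samples, run the composition and paired
#' expansion tests, test splicing nodes and their cross-patient recurrence,
#' and run pre-ranked GSEA against the planted gene programs. Each stage
#' writes a TSV into `out_dir`; a machine-readable `summary.json` (carrying
#' the config hash and seed) and a plain-text log are written at the end.
#' Runs with the same configuration are byte-identical in `summary.json`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log_lines <- c(paste0("stemscore pipeline, package version ",
                        as.character(utils::packageVersion("stemscore"))),
                 paste0("started: ", format(Sys.time(), tz = "UTC")),
                 paste0("seed: ", config$seed))

  sim <- run_stage("simulate", simulate_cohort(config$sim))
  coh <- sim$cohort
  truth <- sim$truth
  write_cohort(coh, out("input"))
  readr::write_tsv(truth$sample_fractions, out("truth_sample_fractions.tsv"))

  coh <- run_stage("normalize", normalize_cells(coh))
  coh <- run_stage("cluster", cluster_cells(coh, seed = config$seed))
  coh <- run_stage("cell_cycle",
                   assign_cell_cycle(coh, truth$s_genes, truth$g2m_genes,
                                     seed = config$seed))

  # stem-like candidate: the cluster that expands most from diagnosis to
  # relapse -- the defining behaviour of the treatment-resistant population.
  # Its quiescence (high G1 share) is then a checked property of the result,
  # not part of the selection.
  by_cluster <- coh$cells |>
    group_by(.data$cluster) |>
    summarise(g1 = mean(.data$phase == "G1"),
              p_ini = sum(.data$timepoint == "initial"),
              p_rel = sum(.data$timepoint == "relapse"),
              .groups = "drop") |>
    mutate(p_ini = .data$p_ini / sum(.data$p_ini),
           p_rel = .data$p_rel / sum(.data$p_rel),
           expansion = log2((.data$p_rel + 1e-3) / (.data$p_ini + 1e-3)))
  target <- by_cluster$cluster[which.max(by_cluster$expansion)]

  signature <- run_stage("signature",
    derive_signature(coh, coh$cells$cluster, target,
                     lfc_min = config$lfc_min, alpha = config$alpha))
  readr::write_tsv(signature, out("signature.tsv"))

  stem <- run_stage("stemness",
    stemness(coh, signature, k = config$jenks_k,
             threshold = config$stem_threshold, seed = config$seed))
  readr::write_tsv(stem$cells, out("cell_scores.tsv"))
  readr::write_tsv(stem$samples, out("sample_stemness.tsv"))

  cells_aug <- coh$cells |>
    left_join(select(stem$cells, "barcode", "score", "stem"), by = "barcode")
  comp <- run_stage("composition",
    proportion_test(
      mutate(cells_aug, pop = ifelse(.data$stem, "stem", "other")),
      category = pop, condition = timepoint,
      B = config$B, seed = config$seed, lfd_min = config$log2fd_min))
  readr::write_tsv(comp, out("composition_test.tsv"))

  frac <- stem$samples |>
    select("patient", "timepoint", "stem_fraction") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "stem_fraction")
  expansion <- run_stage("expansion",
    paired_expansion_test(frac$initial, frac$relapse))
  readr::write_tsv(expansion, out("expansion_test.tsv"))

  regulon <- run_stage("regulons",
    regulon_enrichment(coh, ifelse(cells_aug$stem, "stem", "other"), "stem"))
  readr::write_tsv(select(regulon, -dplyr::any_of("genes")),
                   out("regulon_enrichment.tsv"))

  splice_tbl <- run_stage("simulate_splice",
                          simulate_splice_counts(config$sim, truth))
  readr::write_tsv(splice_tbl, out("splice_counts.tsv"))
  splice <- run_stage("splice",
    differential_nodes(splice_tbl, stem$cells$barcode[stem$cells$stem],
                       alpha = config$alpha))
  readr::write_tsv(splice, out("splice_nodes.tsv"))
  sig_by_patient <- split(splice$gene[splice$significant],
                          splice$patient[splice$significant])
  recurrence <- if (length(sig_by_patient) >= 2) {
    recurrent_as_genes(sig_by_patient)
  } else {
    tibble(gene = character(0), n_patients = integer(0))
  }
  readr::write_tsv(recurrence, out("recurrent_as_genes.tsv"))

  gene_sets <- list(planted_signature = truth$signature_genes,
                    s_phase = truth$s_genes,
                    g2m_phase = truth$g2m_genes)
  write_gmt(gene_sets, out("gene_sets.gmt"))
  ranking <- rank_genes(attr(signature, "tested"))
  gsea <- run_stage("gsea",
    preranked_gsea(ranking, gene_sets, n_perm = config$n_perm,
                   seed = config$seed))
  readr::write_tsv(select(gsea, -"leading_edge"), out("gsea.tsv"))

  summary <- list(
    config_hash = rlang::hash(list(unclass(config$sim),
                                   config[setdiff(names(config),
                                                  c("sim", "out_dir"))])),
    seed = config$seed,
    n_cells = nrow(coh$counts),
    n_clusters = length(unique(coh$cells$cluster)),
    target_cluster = target,
    n_signature_genes = nrow(signature),
    stem_threshold = stem$threshold,
    jenks_breaks = stem$breaks,
    stem_frequency_pct = round(100 * mean(stem$cells$stem), 2),
    samples = stem$samples,
    composition = select(comp, "category", "log2fd", "p_value",
                         "p_adjusted", "significant"),
    expansion = expansion,
    regulons_significant = regulon$regulon[regulon$significant],
    splice_significant = sum(splice$significant),
    recurrent_genes = recurrence$gene,
    gsea = select(gsea, "set", "es", "nes", "p_value", "fdr")
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  log_lines <- c(log_lines, paste0("finished: ", format(Sys.time(), tz = "UTC")),
                 paste0("cells: ", nrow(coh$counts)),
                 paste0("signature genes: ", nrow(signature)))
  writeLines(log_lines, out("pipeline.log"))

  invisible(list(cohort = coh, truth = truth, signature = signature,
                 stemness = stem, composition = comp, expansion = expansion,
                 regulons = regulon, splice = splice, recurrence = recurrence,
                 gsea = gsea, summary = summary, out_dir = config$out_dir))
}
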