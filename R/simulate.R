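#' Simulation configuration
#'
#' Parameters for the synthetic T-ALL cohort generator. Defaults emulate the
#' structure of the study design the package targets: paired diagnosis/relapse
#' samples per patient, a small quiescent stem-like subpopulation at diagnosis
#' that expands at relapse, an up-regulated stemness signature, designated
#' S-phase and G2M-phase gene blocks whose expression encodes cell-cycle state,
#' planted enriched/depleted regulons, splicing nodes with shifted inclusion
#' rates in stem-like cells, and a bulk cohort with ordered response groups.
#'
#' @param n_patients Number of patients; each contributes a paired initial and
#'   relapse sample.
#' @param cells_per_sample Cells simulated per sample.
#' @param n_genes Total genes. The first `n_signature_genes` are the planted
#'   stemness signature; the next `n_phase_genes` each form the S and G2M
#'   blocks.
#' @param n_signature_genes Number of planted up-regulated signature genes.
#' @param signature_log2fc Planted log2 fold-change of signature genes in
#'   stem-like cells.
#' @param stem_fraction_initial,stem_fraction_relapse Expected stem-like cell
#'   proportion per sample at diagnosis and at relapse.
#' @param nb_dispersion Shared negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param library_size_mean Expected total counts per cell; per-cell depths are
#'   log-normal around this with `library_size_sdlog` spread.
#' @param library_size_sdlog Log-scale standard deviation of per-cell depth.
#' @param patient_sdlog Log-scale SD of per-patient per-gene scaling factors,
#'   which make cells cluster by patient as real cohorts do.
#' @param n_phase_genes Genes in each of the S and G2M blocks.
#' @param phase_fold Fold-up of the matching block in cycling (S or G2M) cells.
#' @param quiescence_fold Fold-down of both cycle blocks in stem-like cells,
#'   encoding their quiescence.
#' @param p_g1_stem,p_g1_other Probability that a stem-like (resp. other) cell
#'   is in G1; the remainder splits evenly between S and G2M.
#' @param n_regulons,n_enriched_regulons,n_depleted_regulons Regulon-activity
#'   matrix dimensions and the number of regulons planted as enriched or
#'   depleted in stem-like cells.
#' @param p_active_high,p_active_low Activation probabilities used for planted
#'   regulons (high in the favored group, low in the other); neutral regulons
#'   use their midpoint in both groups.
#' @param n_nodes,n_planted_nodes,reads_per_node,psi_background,psi_stem
#'   Splicing-node simulation: number of nodes, how many carry a planted
#'   inclusion shift, expected reads per cell per node, and the inclusion rates
#'   (psi) outside and inside the stem-like population at planted nodes.
#' @param n_samples_per_group,group_score_shift Bulk cohort: samples per
#'   response group (M1, M2, M3) and the per-step shift (log-scale units) of
#'   signature-gene expression across the ordered groups.
#' @param seed Integer seed; all randomness in the generators flows from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 8,
                       cells_per_sample = 500,
                       n_genes = 2000,
                       n_signature_genes = 200,
                       signature_log2fc = 1.5,
                       stem_fraction_initial = 0.01,
                       stem_fraction_relapse = 0.25,
                       nb_dispersion = 0.3,
                       library_size_mean = 5000,
                       library_size_sdlog = 0.1,
                       patient_sdlog = 0.15,
                       n_phase_genes = 50,
                       phase_fold = 4,
                       quiescence_fold = 2,
                       p_g1_stem = 0.76,
                       p_g1_other = 0.29,
                       n_regulons = 30,
                       n_enriched_regulons = 3,
                       n_depleted_regulons = 2,
                       p_active_high = 0.9,
                       p_active_low = 0.1,
                       n_nodes = 60,
                       n_planted_nodes = 10,
                       reads_per_node = 50,
                       psi_background = 0.2,
                       psi_stem = 0.7,
                       n_samples_per_group = 100,
                       group_score_shift = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_patients", "cells_per_sample", "n_genes", "n_signature_genes",
              "n_phase_genes", "n_regulons", "n_nodes", "library_size_mean",
              "n_samples_per_group")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v != round(v)) {
      abort(paste0("`", nm, "` must be a positive integer."))
    }
  }
  props <- c("stem_fraction_initial", "stem_fraction_relapse", "psi_background",
             "psi_stem", "p_g1_stem", "p_g1_other", "p_active_high", "p_active_low")
  for (nm in props) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(paste0("`", nm, "` must be a proportion in [0, 1]."))
    }
  }
  if (cfg$nb_dispersion <= 0) abort("`nb_dispersion` must be positive.")
  if (cfg$reads_per_node <= 0) abort("`reads_per_node` must be positive.")
  if (cfg$n_signature_genes + 2 * cfg$n_phase_genes >= cfg$n_genes) {
    abort("`n_genes` must exceed signature plus cell-cycle block genes.")
  }
  if (cfg$n_enriched_regulons + cfg$n_depleted_regulons > cfg$n_regulons) {
    abort("More planted regulons than regulons.")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

gene_ids <- function(config) {
  n_sig <- config$n_signature_genes
  n_ph <- config$n_phase_genes
  n_bg <- config$n_genes - n_sig - 2 * n_ph
  c(sprintf("SIG%04d", seq_len(n_sig)),
    sprintf("SPH%03d", seq_len(n_ph)),
    sprintf("G2M%03d", seq_len(n_ph)),
    sprintf("BG%05d", seq_len(n_bg)))
}

#' Simulate a paired diagnosis/relapse single-cell cohort with known truth
#'
#' Draws negative-binomial counts for `2 * n_patients` samples. Per-gene
#' relative abundances are log-normal and shared across the cohort;
#' per-patient log-normal scaling factors reproduce patient-driven clustering
#' structure. Each cell is either stem-like (with probability
#' `stem_fraction_initial` or `stem_fraction_relapse` depending on timepoint)
#' or not. Stem-like cells have the signature genes up-shifted by
#' `signature_log2fc` and both cell-cycle blocks down-shifted by
#' `quiescence_fold`; every cell carries a planted cell-cycle phase that
#' up-shifts the matching phase block by `phase_fold`. A cell-by-regulon
#' activity matrix with planted enriched/depleted regulons is attached to the
#' cohort.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (a [cohort()] with `regulons`
#'   attached) and `truth` (class `synthetic_truth`: per-cell labels and
#'   phases, the planted signature with signed effects, per-sample planted
#'   stem fractions, per-regulon planted status, and the S/G2M gene lists).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  genes <- gene_ids(config)
  G <- config$n_genes
  n_sig <- config$n_signature_genes
  n_ph <- config$n_phase_genes
  idx_sig <- seq_len(n_sig)
  idx_s <- n_sig + seq_len(n_ph)
  idx_g2m <- n_sig + n_ph + seq_len(n_ph)

  rel <- rlnorm(G, meanlog = 0, sdlog = 1)
  # cell-cycle machinery (cyclins, histones, ...) is well expressed in real
  # cells: draw the phase blocks from the mid-to-upper quantiles of the same
  # abundance law, deep enough to carry phase signal but inside the range
  # where abundance-matched control genes exist
  rel[c(idx_s, idx_g2m)] <- stats::qlnorm(runif(2 * n_ph, 0.55, 0.9),
                                          meanlog = 0, sdlog = 1)
  patient_factors <- matrix(
    rlnorm(config$n_patients * G, meanlog = 0, sdlog = config$patient_sdlog),
    nrow = config$n_patients
  )

  samples <- tidyr::expand_grid(
    patient = sprintf("P%02d", seq_len(config$n_patients)),
    timepoint = c("initial", "relapse")
  )
  samples$sample <- paste(samples$patient, samples$timepoint, sep = "_")

  cell_list <- list()
  count_list <- list()
  for (i in seq_len(nrow(samples))) {
    p_idx <- match(samples$patient[i], sprintf("P%02d", seq_len(config$n_patients)))
    frac <- if (samples$timepoint[i] == "initial") {
      config$stem_fraction_initial
    } else {
      config$stem_fraction_relapse
    }
    nc <- config$cells_per_sample
    stem <- runif(nc) < frac
    p_g1 <- ifelse(stem, config$p_g1_stem, config$p_g1_other)
    u <- runif(nc)
    phase <- ifelse(u < p_g1, "G1", ifelse(u < p_g1 + (1 - p_g1) / 2, "S", "G2M"))
    lib <- rlnorm(nc, meanlog = log(config$library_size_mean) -
                    config$library_size_sdlog^2 / 2,
                  sdlog = config$library_size_sdlog)

    base_w <- rel * patient_factors[p_idx, ]
    counts <- matrix(0L, nrow = nc, ncol = G)
    # draw counts jointly for each (stem, phase) class: expected expression is
    # identical within a class up to the per-cell depth factor
    for (st in c(FALSE, TRUE)) {
      for (ph in c("G1", "S", "G2M")) {
        j <- which(stem == st & phase == ph)
        if (length(j) == 0) next
        w <- base_w
        if (st) {
          w[idx_sig] <- w[idx_sig] * 2^config$signature_log2fc
          w[c(idx_s, idx_g2m)] <- w[c(idx_s, idx_g2m)] / config$quiescence_fold
        }
        if (ph == "S") w[idx_s] <- w[idx_s] * config$phase_fold
        if (ph == "G2M") w[idx_g2m] <- w[idx_g2m] * config$phase_fold
        mu <- outer(lib[j], w / sum(w))
        counts[j, ] <- rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
      }
    }
    barcodes <- sprintf("%s_C%04d", samples$sample[i], seq_len(nc))
    rownames(counts) <- barcodes
    count_list[[i]] <- counts
    cell_list[[i]] <- tibble(
      barcode = barcodes,
      patient = samples$patient[i],
      sample = samples$sample[i],
      timepoint = samples$timepoint[i],
      true_label = ifelse(stem, "stem", "other"),
      true_phase = phase
    )
  }

  counts <- do.call(rbind, count_list)
  colnames(counts) <- genes
  cells <- bind_rows(cell_list)

  regulons <- simulate_regulons(config, cells$true_label == "stem")
  rownames(regulons$activity) <- cells$barcode

  coh <- cohort(methods::as(counts, "CsparseMatrix"), cells,
                regulons = regulons$activity)

  signature <- tibble(
    gene = c(genes[idx_sig], genes[idx_s], genes[idx_g2m]),
    planted_log2fc = c(rep(config$signature_log2fc, n_sig),
                       rep(-log2(config$quiescence_fold), 2 * n_ph)),
    role = c(rep("signature", n_sig), rep("s_phase", n_ph), rep("g2m_phase", n_ph))
  )

  sample_fractions <- cells |>
    group_by(.data$patient, .data$sample, .data$timepoint) |>
    summarise(n_cells = n(),
              n_stem = sum(.data$true_label == "stem"),
              stem_fraction = mean(.data$true_label == "stem"),
              .groups = "drop")

  truth <- structure(
    list(
      cells = cells,
      signature = signature,
      signature_genes = genes[idx_sig],
      s_genes = genes[idx_s],
      g2m_genes = genes[idx_g2m],
      sample_fractions = sample_fractions,
      regulons = regulons$truth,
      config = config
    ),
    class = "synthetic_truth"
  )

  list(cohort = coh, truth = truth)
}

simulate_regulons <- function(config, is_stem) {
  n <- length(is_stem)
  R <- config$n_regulons
  ids <- sprintf("REG%03d", seq_len(R))
  status <- rep("null", R)
  status[seq_len(config$n_enriched_regulons)] <- "enriched"
  status[config$n_enriched_regulons + seq_len(config$n_depleted_regulons)] <- "depleted"
  p_mid <- (config$p_active_high + config$p_active_low) / 2
  activity <- matrix(0, nrow = n, ncol = R, dimnames = list(NULL, ids))
  for (r in seq_len(R)) {
    p_on <- switch(status[r],
      enriched = ifelse(is_stem, config$p_active_high, config$p_active_low),
      depleted = ifelse(is_stem, config$p_active_low, config$p_active_high),
      null = rep(p_mid, n)
    )
    on <- runif(n) < p_on
    # AUC-like activity: clearly separated beta mixtures for on/off states
    activity[, r] <- ifelse(on, rbeta(n, 6, 2), rbeta(n, 2, 6))
  }
  list(activity = activity,
       truth = tibble(regulon = ids, planted = status))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nrow(x$cells), " cells, ",
      sum(x$cells$true_label == "stem"), " stem-like\n", sep = "")
  cat("  planted signature: ", length(x$signature_genes), " genes at log2FC ",
      x$config$signature_log2fc, "\n", sep = "")
  invisible(x)
}

#' Simulate splicing-node inclusion/exclusion counts
#'
#' For each cell and splicing node, a read total is drawn Poisson around
#' `reads_per_node` and inclusion reads are binomial with the node's group
#' inclusion rate: planted nodes use `psi_stem` for stem-like cells and
#' `psi_background` otherwise; unplanted nodes use a node-specific rate shared
#' by both groups. Event types are drawn from the four node classes (intron
#' retention, core exon skip, alternative donor, alternative acceptor).
#'
#' @param config A [sim_config()].
#' @param truth The `synthetic_truth` from [simulate_cohort()] (provides cell
#'   identities and stem labels).
#' @return A tibble with columns `cell_id`, `patient`, `node_id`, `gene`,
#'   `event_type`, `incl_count`, `excl_count`, carrying the per-node truth as
#'   attribute `"node_truth"`.
#' @export
simulate_splice_counts <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "synthetic_truth"))
  if (config$reads_per_node <= 0) abort("`reads_per_node` must be positive.")
  withr::with_seed(config$seed + 1L, {
    cells <- truth$cells
    n <- nrow(cells)
    is_stem <- cells$true_label == "stem"
    types <- c("intron_retention", "core_exon_skip", "alt_donor", "alt_acceptor")
    nodes <- tibble(
      node_id = sprintf("node%03d", seq_len(config$n_nodes)),
      gene = sprintf("ASG%03d", ceiling(seq_len(config$n_nodes) / 2)),
      event_type = sample(types, config$n_nodes, replace = TRUE),
      planted = seq_len(config$n_nodes) <= config$n_planted_nodes
    )
    base_psi <- ifelse(nodes$planted, config$psi_background,
                       runif(config$n_nodes, 0.15, 0.85))
    nodes$psi_other <- base_psi
    nodes$psi_stem <- ifelse(nodes$planted, config$psi_stem, base_psi)

    out <- purrr::map(seq_len(config$n_nodes), function(k) {
      total <- rpois(n, config$reads_per_node)
      psi <- ifelse(is_stem, nodes$psi_stem[k], nodes$psi_other[k])
      incl <- rbinom(n, total, psi)
      tibble(cell_id = cells$barcode, patient = cells$patient,
             node_id = nodes$node_id[k], gene = nodes$gene[k],
             event_type = nodes$event_type[k],
             incl_count = incl, excl_count = total - incl)
    })
    out <- bind_rows(out)
    attr(out, "node_truth") <- nodes
    out
  })
}

#' Simulate a bulk expression cohort with ordered response groups
#'
#' Log-scale Gaussian expression for three groups (M1 < M2 < M3). Signature
#' genes gain `group_score_shift` per ordinal step so the mean stemness score
#' increases with group; all other genes are exchangeable across groups.
#'
#' @param config A [sim_config()].
#' @param signature A `signature_set` (or character vector of gene ids); must
#'   be non-empty.
#' @return A list with `expr` (genes-by-samples matrix of log-scale values)
#'   and `samples` (tibble: `sample_id`, `group`).
#' @export
simulate_bulk <- function(config, signature) {
  stopifnot(inherits(config, "sim_config"))
  sig_genes <- signature_genes(signature)
  if (length(sig_genes) == 0) abort("`signature` must be non-empty.")
  withr::with_seed(config$seed + 2L, {
    genes <- union(sig_genes, gene_ids(config))
    G <- length(genes)
    n_per <- config$n_samples_per_group
    groups <- rep(c("M1", "M2", "M3"), each = n_per)
    steps <- rep(0:2, each = n_per)
    n <- length(groups)
    mu <- rnorm(G, mean = 5, sd = 1)
    expr <- matrix(rnorm(G * n, mean = mu, sd = 1), nrow = G,
                   dimnames = list(genes, sprintf("BULK%04d", seq_len(n))))
    in_sig <- genes %in% sig_genes
    expr[in_sig, ] <- expr[in_sig, ] +
      matrix(rep(steps * config$group_score_shift, each = sum(in_sig)),
             nrow = sum(in_sig))
    list(expr = expr,
         samples = tibble(sample_id = colnames(expr), group = groups))
  })
}
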