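#' Percent spliced in
#'
#' `psi = incl / (incl + excl)`. Entries with zero total reads are undefined;
#' they return `NA` with a warning and are excluded downstream.
#'
#' @param incl,excl Non-negative integer read counts (vectorized).
#' @return Numeric psi values in `[0, 1]`, `NA` where the total is zero.
#' @export
compute_psi <- function(incl, excl) {
  if (any(incl < 0) || any(excl < 0)) abort("Read counts must be non-negative.")
  total <- incl + excl
  if (any(total == 0)) {
    warn(paste0(sum(total == 0), " observation(s) with zero total reads;",
                " psi undefined (NA)."))
  }
  ifelse(total > 0, incl / total, NA_real_)
}

#' Beta-CDF significance of a pooled inclusion rate
#'
#' Fits a Beta distribution to the reference group's per-cell psi values by
#' method of moments (`alpha = m (m (1 - m) / v - 1)`, `beta = (1 - m)
#' (m (1 - m) / v - 1)`, both clamped to at least 0.01) and evaluates the
#' two-sided tail probability of the observed pooled psi under that null:
#' `p = 2 min(F(psi_obs), 1 - F(psi_obs))`, capped at 1.
#'
#' @param psi_obs Pooled psi in the target group.
#' @param ref_psi Per-cell psi values in the reference group (at least 5
#'   defined values).
#' @return One-row tibble: `alpha`, `beta`, `p_value`, `degenerate`.
#' @export
beta_significance <- function(psi_obs, ref_psi) {
  ref_psi <- ref_psi[!is.na(ref_psi)]
  if (length(ref_psi) < 5) abort("Need at least 5 reference cells with defined psi.")
  m <- mean(ref_psi)
  v <- var(ref_psi)
  if (v <= .Machine$double.eps) {
    return(tibble(alpha = NA_real_, beta = NA_real_, p_value = 1,
                  degenerate = TRUE))
  }
  common <- m * (1 - m) / v - 1
  a <- max(m * common, 0.01)
  b <- max((1 - m) * common, 0.01)
  f <- pbeta(psi_obs, a, b)
  tibble(alpha = a, beta = b, p_value = min(1, 2 * min(f, 1 - f)),
         degenerate = FALSE)
}

#' Differential inclusion of splicing nodes in stem-like cells
#'
#' Restricts each node to cells with at least `min_reads` supporting reads,
#' requires at least `min_cells` qualifying cells per group, and tests the
#' node twice: a two-sided Wilcoxon rank-sum test on per-cell psi and the
#' beta-CDF significance of the pooled stem-like psi against the reference
#' cells. Both p-value families are BH-adjusted within patient when a
#' `patient` column is present (otherwise globally); a node is significant
#' when both adjusted values fall below `alpha` and `|delta psi| > dpsi_min`.
#'
#' @param table Splicing-node count table (see [read_splice_table()] /
#'   [simulate_splice_counts()]): columns `cell_id`, `node_id`, `gene`,
#'   `event_type`, `incl_count`, `excl_count`, optional `patient`.
#' @param stem_cells Character vector of stem-like cell ids, or a logical
#'   vector aligned with the rows of `table`.
#' @param min_reads Minimum reads per cell and node (default 5).
#' @param min_cells Minimum qualifying cells per group at a node (default 5).
#' @param alpha Significance level on adjusted values (default 0.05).
#' @param dpsi_min Effect-size floor on the pooled psi difference.
#' @return An `as_result` tibble: per (patient,) node the group sizes, pooled
#'   psi values, `delta_psi`, both p-values, adjusted values and the flag.
#'   Nodes failing the filters are absent; no qualifying node yields an empty
#'   tibble.
#' @export
differential_nodes <- function(table, stem_cells, min_reads = 5, min_cells = 5,
                               alpha = 0.05, dpsi_min = 0.1) {
  tbl <- as_tibble(table)
  is_stem <- if (is.logical(stem_cells)) {
    if (length(stem_cells) != nrow(tbl)) {
      abort("Logical `stem_cells` must align with table rows.")
    }
    stem_cells
  } else {
    tbl$cell_id %in% stem_cells
  }
  tbl$.stem <- is_stem
  tbl$.total <- tbl$incl_count + tbl$excl_count
  tbl <- filter(tbl, .data$.total >= min_reads)
  if (nrow(tbl) == 0) return(empty_as_result())
  tbl$.psi <- tbl$incl_count / tbl$.total

  by_patient <- "patient" %in% names(tbl)
  keys <- if (by_patient) c("patient", "node_id") else "node_id"
  res <- tbl |>
    group_by(across(dplyr::all_of(c(keys, "gene", "event_type")))) |>
    dplyr::group_modify(function(d, g) {
      ns <- sum(d$.stem); no <- sum(!d$.stem)
      if (ns < min_cells || no < min_cells) {
        return(tibble(n_stem = integer(0), n_other = integer(0),
                      psi_stem = numeric(0), psi_other = numeric(0),
                      delta_psi = numeric(0), p_beta = numeric(0),
                      beta_degenerate = logical(0), p_wilcox = numeric(0)))
      }
      pooled_s <- sum(d$incl_count[d$.stem]) / sum(d$.total[d$.stem])
      pooled_o <- sum(d$incl_count[!d$.stem]) / sum(d$.total[!d$.stem])
      bs <- beta_significance(pooled_s, d$.psi[!d$.stem])
      wx <- rank_sum_test(d$.psi[d$.stem], d$.psi[!d$.stem])
      tibble(n_stem = ns, n_other = no,
             psi_stem = pooled_s, psi_other = pooled_o,
             delta_psi = pooled_s - pooled_o,
             p_beta = bs$p_value, beta_degenerate = bs$degenerate,
             p_wilcox = wx$p_value)
    }) |>
    ungroup()
  if (nrow(res) == 0) return(empty_as_result())

  adj_scope <- if (by_patient) res$patient else rep("all", nrow(res))
  res$padj_beta <- unsplit(lapply(split(res$p_beta, adj_scope), bh_adjust),
                           adj_scope)
  res$padj_wilcox <- unsplit(lapply(split(res$p_wilcox, adj_scope), bh_adjust),
                             adj_scope)
  res$significant <- res$padj_beta < alpha & res$padj_wilcox < alpha &
    abs(res$delta_psi) > dpsi_min
  class(res) <- c("as_result", class(res))
  res
}

empty_as_result <- function() {
  out <- tibble(node_id = character(0), gene = character(0),
                event_type = character(0), n_stem = integer(0),
                n_other = integer(0), psi_stem = numeric(0),
                psi_other = numeric(0), delta_psi = numeric(0),
                p_beta = numeric(0), beta_degenerate = logical(0),
                p_wilcox = numeric(0), padj_beta = numeric(0),
                padj_wilcox = numeric(0), significant = logical(0))
  class(out) <- c("as_result", class(out))
  out
}

#' Genes with recurrent alternative splicing across patients
#'
#' Intersects per-patient sets of significantly spliced genes and keeps genes
#' occurring in at least `min_patients` of them, together with the per-patient
#' incidence matrix.
#'
#' @param sets Named list (one element per patient) of character gene vectors.
#' @param min_patients Minimum number of patients (default 2).
#' @return Tibble: `gene`, `n_patients`, one logical column per patient;
#'   sorted by decreasing recurrence.
#' @export
recurrent_as_genes <- function(sets, min_patients = 2) {
  if (length(sets) < 2) abort("Need per-patient sets from at least 2 patients.")
  if (is.null(names(sets))) names(sets) <- paste0("patient", seq_along(sets))
  genes <- sort(unique(unlist(sets)))
  if (length(genes) == 0) {
    return(tibble(gene = character(0), n_patients = integer(0)))
  }
  inc <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  inc <- matrix(inc, nrow = length(genes),
                dimnames = list(genes, names(sets)))
  out <- tibble(gene = genes, n_patients = unname(rowSums(inc))) |>
    bind_cols_safely(inc) |>
    filter(.data$n_patients >= min_patients) |>
    arrange(desc(.data$n_patients), .data$gene)
  out
}

bind_cols_safely <- function(tbl, m) {
  dplyr::bind_cols(tbl, as_tibble(as.data.frame(m)))
}

#' Gene Ontology over-representation by hypergeometric test
#'
#' One-sided upper-tail hypergeometric test of the overlap between a query
#' gene set and each annotation term, BH-adjusted across terms. Term genes
#' outside the universe are trimmed with a warning.
#'
#' @param genes Query gene set (non-empty, contained in `universe`).
#' @param annotation Named list mapping term to character gene vectors.
#' @param universe Background gene identifiers.
#' @return Tibble per term: term sizes, overlap, `p_value`, `p_adjusted` and
#'   the overlapping genes (list column).
#' @export
go_overrepresentation <- function(genes, annotation, universe) {
  genes <- unique(genes)
  universe <- unique(universe)
  if (length(genes) == 0) abort("Query gene set is empty.")
  outside <- setdiff(genes, universe)
  if (length(outside) > 0) {
    abort(paste0("Query gene(s) outside the universe: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  trimmed <- vapply(annotation, function(s) length(setdiff(s, universe)),
                    integer(1))
  if (any(trimmed > 0)) {
    warn(paste0(sum(trimmed > 0), " term(s) had genes outside the universe;",
                " trimmed."))
  }
  N <- length(universe)
  n_query <- length(genes)
  rows <- purrr::imap(annotation, function(term_genes, term) {
    tg <- intersect(term_genes, universe)
    ov <- intersect(tg, genes)
    K <- length(tg)
    p <- if (K == 0) 1 else phyper(length(ov) - 1, K, N - K, n_query,
                                   lower.tail = FALSE)
    tibble(term = term, n_term = K, n_query = n_query,
           overlap = length(ov), p_value = p,
           genes = list(sort(ov)))
  })
  out <- bind_rows(rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  arrange(out, .data$p_value)
}
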