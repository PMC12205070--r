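#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midrank handling of ties. Uses the exact null
#' distribution when the combined sample size is at most 12 and there are no
#' ties, and the tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param x,y Non-empty numeric vectors.
#' @return A one-row tibble with `statistic` (the Mann-Whitney W for `x`) and
#'   `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 12
  res <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  p <- res$p.value
  if (is.na(p)) p <- 1  # zero-variance normal approximation (all ties)
  tibble(statistic = unname(res$statistic),
         p_value = min(1, p))
}

# Vectorized tie-corrected normal-approximation rank-sum test across the
# columns of a dense matrix; used for genome-wide one-vs-rest DE where the
# exact branch never applies.
rank_sum_matrix <- function(mat, in_a) {
  n <- nrow(mat)
  na <- sum(in_a)
  nb <- n - na
  stat <- numeric(ncol(mat))
  pval <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    r <- rank(v)
    w <- sum(r[in_a]) - na * (na + 1) / 2
    tab <- tabulate(match(v, unique(v)))
    tie_term <- sum(tab^3 - tab)
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- w - na * nb / 2
    if (sigma2 <= 0) {
      stat[j] <- w
      pval[j] <- 1
      next
    }
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    stat[j] <- w
    pval[j] <- min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = stat, p_value = pval)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; a validating wrapper around
#' [stats::p.adjust()] that preserves input order and caps at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the same order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Per-gene log2 fold-change between two cell groups
#'
#' Computed on depth-normalized (pre-log) expression as
#' `log2((mean_a + eps) / (mean_b + eps))`; the pseudocount keeps the value
#' finite when one group mean is zero.
#'
#' @param x A [cohort()] (its normalized slot, back-transformed with `expm1`)
#'   or a matrix of pre-log normalized expression, cells in rows.
#' @param cells_a,cells_b Disjoint, non-empty vectors of cell barcodes (or a
#'   logical/integer index into the rows).
#' @param eps Pseudocount (default `1e-9`).
#' @return A tibble with `gene` and `log2fc`.
#' @export
log2_fold_change <- function(x, cells_a, cells_b, eps = 1e-9) {
  m <- prelog_matrix(x)
  ia <- resolve_cells(m, cells_a)
  ib <- resolve_cells(m, cells_b)
  if (length(ia) == 0 || length(ib) == 0) abort("Both groups must be non-empty.")
  if (length(intersect(ia, ib)) > 0) abort("Cell groups must be disjoint.")
  ma <- unname(Matrix::colMeans(m[ia, , drop = FALSE]))
  mb <- unname(Matrix::colMeans(m[ib, , drop = FALSE]))
  tibble(gene = colnames(m), log2fc = log2((ma + eps) / (mb + eps)))
}

prelog_matrix <- function(x) {
  if (inherits(x, "cohort")) {
    m <- normalized_matrix(x)
    m@x <- expm1(m@x)
    return(m)
  }
  x
}

resolve_cells <- function(m, cells) {
  if (is.character(cells)) {
    idx <- match(cells, rownames(m))
    if (anyNA(idx)) {
      abort(paste0("Unknown barcodes: ",
                   paste(head(cells[is.na(idx)], 5), collapse = ", ")))
    }
    idx
  } else if (is.logical(cells)) {
    which(cells)
  } else {
    as.integer(cells)
  }
}

#' Derive a stemness signature by one-vs-rest differential expression
#'
#' Runs a Wilcoxon rank-sum test per gene for the target population against
#' all other cells, BH-adjusts over the tested genes, and keeps genes with
#' `log2fc > lfc_min` and `p_adjusted < alpha`, ordered by decreasing fold
#' change. Genes detected in fewer than `min_cells` cells of both groups are
#' excluded before testing so near-empty genes cannot reach the candidate set.
#'
#' @param x A [cohort()] with normalized expression.
#' @param labels Per-cell group labels (cluster ids or any factor aligned with
#'   the cohort's cells).
#' @param target_label The label defining the population of interest; must
#'   cover at least 3 cells.
#' @param lfc_min,alpha Selection thresholds (defaults 0.5 and 0.05).
#' @param min_cells Detection filter (default 3 cells).
#' @return A `signature_set`: a tibble (`gene`, `log2fc`, `p_value`,
#'   `p_adjusted`) with the thresholds stored as attributes.
#' @export
derive_signature <- function(x, labels, target_label, lfc_min = 0.5,
                             alpha = 0.05, min_cells = 3) {
  stopifnot(inherits(x, "cohort"))
  norm <- normalized_matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(norm)) abort("`labels` must align with cells.")
  in_a <- labels == as.character(target_label)
  if (sum(in_a) < 3) abort("Target group has fewer than 3 cells.")
  if (sum(!in_a) < 3) abort("Reference group has fewer than 3 cells.")

  detected <- x$counts > 0
  n_det_a <- Matrix::colSums(detected[in_a, , drop = FALSE])
  n_det_b <- Matrix::colSums(detected[!in_a, , drop = FALSE])
  testable <- n_det_a >= min_cells | n_det_b >= min_cells
  if (!any(testable)) {
    return(new_signature_set(tibble(gene = character(0), log2fc = numeric(0),
                                    p_value = numeric(0), p_adjusted = numeric(0)),
                             lfc_min, alpha))
  }
  dense <- as.matrix(norm[, testable, drop = FALSE])
  rs <- rank_sum_matrix(dense, in_a)
  lfc <- log2_fold_change(x, which(in_a), which(!in_a))$log2fc[testable]
  res <- tibble(gene = colnames(dense), log2fc = lfc,
                statistic = rs$statistic, p_value = rs$p_value,
                p_adjusted = bh_adjust(rs$p_value))
  keep <- res |>
    filter(.data$log2fc > lfc_min, .data$p_adjusted < alpha) |>
    arrange(desc(.data$log2fc)) |>
    select("gene", "log2fc", "p_value", "p_adjusted")
  attr(keep, "tested") <- res
  new_signature_set(keep, lfc_min, alpha)
}

new_signature_set <- function(tbl, lfc_min, alpha) {
  attr(tbl, "lfc_min") <- lfc_min
  attr(tbl, "alpha") <- alpha
  class(tbl) <- c("signature_set", class(tbl))
  tbl
}

#' @export
print.signature_set <- function(x, ...) {
  cat("<signature_set> ", nrow(x), " genes (log2FC > ",
      attr(x, "lfc_min") %||% NA, ", padj < ", attr(x, "alpha") %||% NA, ")\n",
      sep = "")
  NextMethod()
}

signature_genes <- function(signature) {
  if (is.character(signature)) return(unique(signature))
  if (is.data.frame(signature) && "gene" %in% names(signature)) {
    return(unique(signature$gene))
  }
  abort("`signature` must be a signature_set or a character vector of genes.")
}

#' Regulon enrichment in a target population by Fisher's exact test
#'
#' Binarizes each regulon's activity (default threshold: per-regulon
#' mean + 1 SD) and tests the 2x2 table of activity status against membership
#' in the target population with the two-sided Fisher exact test (sum of all
#' table probabilities no larger than the observed one). The effect size is
#' the log2 ratio of active fractions inside vs outside the population.
#' Regulons active in all cells or in none carry no information: they are
#' returned with `p_value = 1`, `log2fc = 0` and `degenerate = TRUE`.
#'
#' @param activity Cell-by-regulon numeric matrix in `[0, 1]`, or a [cohort()]
#'   with a regulon slot.
#' @param labels Per-cell labels aligned with the activity rows.
#' @param target_label Label of the population of interest.
#' @param thresholds Optional named numeric vector of per-regulon binarization
#'   thresholds; default `mean + 1 SD` per regulon.
#' @param lfc_min,alpha Significance thresholds for the `significant` flag
#'   (defaults 0.25 and 0.05).
#' @param eps Pseudocount for the active-fraction ratio.
#' @return A `regulon_enrichment` tibble: per regulon the 2x2 counts, odds
#'   ratio, Fisher p, BH-adjusted p, active-fraction log2fc and flags.
#' @export
regulon_enrichment <- function(activity, labels, target_label,
                               thresholds = NULL, lfc_min = 0.25, alpha = 0.05,
                               eps = 1e-9) {
  if (inherits(activity, "cohort")) {
    if (is.null(activity$regulons)) abort("Cohort has no regulon activities.")
    activity <- activity$regulons
  }
  activity <- as.matrix(activity)
  labels <- as.character(labels)
  if (length(labels) != nrow(activity)) abort("`labels` must align with cells.")
  in_t <- labels == as.character(target_label)
  if (!any(in_t) || all(in_t)) abort("Target population must be a strict subset.")
  if (is.null(thresholds)) {
    thresholds <- matrixStats::colMeans2(activity) + matrixStats::colSds(activity)
    names(thresholds) <- colnames(activity)
  }
  rows <- purrr::map(seq_len(ncol(activity)), function(r) {
    active <- activity[, r] > thresholds[r]
    a <- sum(active & in_t); b <- sum(active & !in_t)
    c_ <- sum(!active & in_t); d <- sum(!active & !in_t)
    frac_t <- a / sum(in_t)
    frac_o <- b / sum(!in_t)
    degenerate <- all(active) || all(!active)
    if (degenerate) {
      p <- 1; or <- NA_real_; lfc <- 0
    } else {
      ft <- fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE))
      p <- ft$p.value; or <- unname(ft$estimate)
      lfc <- log2((frac_t + eps) / (frac_o + eps))
    }
    tibble(regulon = colnames(activity)[r],
           active_in = a, active_out = b, inactive_in = c_, inactive_out = d,
           frac_active_in = frac_t, frac_active_out = frac_o,
           odds_ratio = or, log2fc = lfc, p_value = p, degenerate = degenerate)
  })
  out <- bind_rows(rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out$significant <- !out$degenerate & out$p_adjusted < alpha &
    abs(out$log2fc) > lfc_min
  class(out) <- c("regulon_enrichment", class(out))
  out
}
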