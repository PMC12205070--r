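#' Depth-normalize a cohort
#'
#' Scales each cell to `target_sum` total counts and applies `log1p`. Cells
#' with zero total counts cannot be scaled; they are dropped with a warning
#' naming them.
#'
#' @param x A [cohort()].
#' @param target_sum Per-cell total after scaling (default 10,000, the usual
#'   single-cell convention).
#' @return The cohort with its `normalized` slot filled.
#' @export
normalize_cells <- function(x, target_sum = 1e4) {
  stopifnot(inherits(x, "cohort"))
  libsize <- rowSums(x$counts)
  if (all(libsize == 0)) abort("All cells have zero counts; nothing to normalize.")
  zero <- libsize == 0
  if (any(zero)) {
    warn(paste0("Dropping ", sum(zero), " zero-count cell(s): ",
                paste(head(rownames(x$counts)[zero], 10), collapse = ", ")))
    x$counts <- x$counts[!zero, , drop = FALSE]
    x$cells <- x$cells[!zero, , drop = FALSE]
    if (!is.null(x$regulons)) x$regulons <- x$regulons[!zero, , drop = FALSE]
    libsize <- libsize[!zero]
  }
  # cells x genes, column-compressed: @i holds the row (cell) of each entry
  norm <- x$counts
  norm@x <- norm@x / libsize[norm@i + 1L] * target_sum
  norm@x <- log1p(norm@x)
  x$normalized <- norm
  x
}

sparse_col_vars <- function(m) {
  # column variances of a sparse matrix without densifying
  mu <- Matrix::colMeans(m)
  ex2 <- Matrix::colMeans(m^2)
  (ex2 - mu^2) * nrow(m) / max(1, nrow(m) - 1)
}

#' Graph-based clustering of cells
#'
#' Louvain community detection on a k-nearest-neighbour graph. For expression
#' input the graph is built in PCA space of the scaled top-variable genes; a
#' regulon-activity matrix (few dense columns) is used directly. Cluster
#' labels are integers `0..K-1` ordered by decreasing cluster size, so
#' cluster 0 is always the largest population.
#'
#' @param x A [cohort()] or a numeric matrix (cells in rows).
#' @param use For cohorts: `"expression"` (PCA of normalized counts) or
#'   `"regulons"` (activity matrix).
#' @param n_neighbors Neighbours in the kNN graph.
#' @param resolution Louvain resolution parameter.
#' @param seed Seed for the (stochastic) community detection.
#' @param n_pcs,n_hvg PCA depth and number of highly variable genes used for
#'   expression input; scaled values are clipped at 10 before PCA.
#' @return For a cohort, the cohort with a `cluster` metadata column; for a
#'   matrix, an integer vector of labels.
#' @export
cluster_cells <- function(x, use = c("expression", "regulons"),
                          n_neighbors = 15, resolution = 0.8, seed = 1L,
                          n_pcs = 30, n_hvg = 2000) {
  use <- match.arg(use)
  if (inherits(x, "cohort")) {
    emb <- if (use == "regulons") {
      if (is.null(x$regulons)) abort("Cohort has no regulon activity matrix.")
      x$regulons
    } else {
      expression_embedding(normalized_matrix(x), n_pcs = n_pcs, n_hvg = n_hvg)
    }
    labels <- knn_louvain(emb, n_neighbors, resolution, seed)
    x$cells$cluster <- labels
    return(x)
  }
  knn_louvain(as.matrix(x), n_neighbors, resolution, seed)
}

expression_embedding <- function(norm, n_pcs = 30, n_hvg = 2000) {
  v <- sparse_col_vars(norm)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, sum(v > 0)))]
  m <- as.matrix(norm[, keep, drop = FALSE])
  m <- scale(m)
  m[m > 10] <- 10
  m[m < -10] <- -10
  n_pcs <- min(n_pcs, ncol(m) - 1, nrow(m) - 1)
  pca <- irlba::prcomp_irlba(m, n = n_pcs, center = FALSE, scale. = FALSE)
  pca$x
}

knn_louvain <- function(emb, n_neighbors, resolution, seed) {
  n <- nrow(emb)
  if (n <= n_neighbors) {
    abort(paste0("Need more than ", n_neighbors, " cells (have ", n, ")."))
  }
  # identical embeddings make the kNN graph fully symmetric; short-circuit
  if (all(abs(sweep(emb, 2, emb[1, ])) < 1e-12)) {
    return(rep(0L, n))
  }
  nn <- FNN::get.knn(emb, k = n_neighbors)$nn.index
  edges <- cbind(rep(seq_len(n), each = n_neighbors), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  raw <- igraph::membership(comm)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  as.integer(relabel[as.character(raw)])
}

#' Assign cell-cycle phase from S and G2M gene programs
#'
#' Scores each cell for the S-phase and G2M-phase programs with the same
#' control-matched module score used by [score_cells()], then calls the phase:
#' the arg-max of the two scores when either is positive, `G1` otherwise
#' (quiescent/non-cycling cells express neither program above background).
#'
#' @param x A [cohort()] (normalized on the fly if needed).
#' @param s_genes,g2m_genes Character vectors of phase marker genes; each must
#'   intersect the cohort's genes.
#' @param n_bins,n_ctrl,seed Passed to the module scorer.
#' @return The cohort with `s_score`, `g2m_score` and `phase` metadata columns.
#' @export
assign_cell_cycle <- function(x, s_genes, g2m_genes, n_bins = 25, n_ctrl = 50,
                              seed = 0L) {
  stopifnot(inherits(x, "cohort"))
  norm <- normalized_matrix(x)
  if (length(intersect(s_genes, colnames(norm))) == 0 ||
      length(intersect(g2m_genes, colnames(norm))) == 0) {
    abort("Cell-cycle gene lists do not intersect the cohort's genes.")
  }
  s <- module_score(norm, s_genes, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  g2m <- module_score(norm, g2m_genes, n_bins = n_bins, n_ctrl = n_ctrl,
                      seed = seed + 1L)
  # tolerance guards the both-scores-zero case against floating-point residue
  tol <- 1e-9
  phase <- ifelse(s <= tol & g2m <= tol, "G1", ifelse(s > g2m, "S", "G2M"))
  x$cells$s_score <- s
  x$cells$g2m_score <- g2m
  x$cells$phase <- phase
  x
}
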