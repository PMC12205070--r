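# Control-matched module score on a normalized (log1p) matrix.
# For each signature gene, n_ctrl control genes are drawn from its
# average-expression bin -- a rank window of width ~n_genes/n_bins centered
# on the gene, excluding other signature genes -- and the score is
# mean(signature) - mean(control pool). Centering the bin on each gene keeps
# the matching unbiased in the skewed upper expression tail, where fixed
# quantile bins systematically under-match the most abundant genes.
# Iteration over signature genes follows their sorted order so the score does
# not depend on how the caller ordered the list.
module_score <- function(norm, genes, n_bins = 25, n_ctrl = 50, seed = 0L) {
  present <- sort(intersect(unique(genes), colnames(norm)))
  absent <- setdiff(unique(genes), colnames(norm))
  if (length(absent) > 0) {
    warn(paste0(length(absent), " signature gene(s) absent from matrix: ",
                paste(head(absent, 10), collapse = ", ")))
  }
  if (length(present) == 0) abort("No signature gene is present in the matrix.")
  sig_mean <- Matrix::rowMeans(norm[, present, drop = FALSE])
  if (n_ctrl == 0) return(as.numeric(sig_mean))

  avg <- Matrix::colMeans(norm)
  G <- length(avg)
  half <- max(1L, ceiling(G / n_bins / 2))
  r <- rank(avg, ties.method = "first")
  by_rank <- colnames(norm)[order(r)]
  candidate <- !(by_rank %in% present)
  ctrl <- withr::with_seed(seed, {
    unlist(lapply(present, function(g) {
      centre <- r[match(g, colnames(norm))]
      lo <- max(1L, centre - half)
      hi <- min(G, centre + half)
      pool <- by_rank[lo:hi][candidate[lo:hi]]
      if (length(pool) == 0) pool <- by_rank[lo:hi]
      sample(pool, min(n_ctrl, length(pool)))
    }), use.names = FALSE)
  })
  ctrl <- unique(ctrl)
  ctrl_mean <- Matrix::rowMeans(norm[, ctrl, drop = FALSE])
  as.numeric(sig_mean - ctrl_mean)
}

#' Per-cell stemness score
#'
#' Scores each cell for a gene signature as the mean normalized expression of
#' the signature genes minus the mean over matched control genes sampled from
#' the same average-expression bins (the standard module-score construction).
#' The control term centers the score near zero for cells without signature
#' expression, which is what makes an absolute threshold such as 0.25
#' meaningful. Setting `n_ctrl = 0` gives the plain signature mean.
#'
#' @param x A [cohort()] or a normalized (log1p) matrix, cells in rows.
#' @param signature A `signature_set` from [derive_signature()] or a character
#'   vector of genes. Genes absent from the matrix are dropped with a warning;
#'   at least one must be present.
#' @param n_bins Number of average-expression bins.
#' @param n_ctrl Control genes sampled per signature gene.
#' @param seed Seed for control sampling (scores are deterministic given it).
#' @return A tibble with `barcode` and `score`.
#' @export
score_cells <- function(x, signature, n_bins = 25, n_ctrl = 50, seed = 0L) {
  norm <- normalized_matrix(x)
  genes <- signature_genes(signature)
  s <- module_score(norm, genes, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  tibble(barcode = rownames(norm), score = s)
}

#' Jenks natural breaks
#'
#' Fisher-Jenks dynamic programming: partitions the sorted values into `k`
#' classes minimizing the total within-class sum of squared deviations, and
#' returns the `k - 1` internal break values (the maximum of each class but
#' the last). Ties in the optimization are resolved toward the smaller upper
#' class.
#'
#' @param values Numeric vector with at least `k` distinct values.
#' @param k Number of classes (default 4, matching the stemness thresholding
#'   convention).
#' @return Sorted numeric vector of `k - 1` internal breaks.
#' @export
jenks_breaks <- function(values, k = 4) {
  x <- sort(values[is.finite(values)])
  n <- length(x)
  if (length(unique(x)) < k) {
    abort(paste0("Need at least k = ", k, " distinct values."))
  }
  s1 <- cumsum(x)
  s2 <- cumsum(x^2)
  ssd <- function(i, j) {
    # within-class SSD of x[i..j]
    s2[j] - ifelse(i > 1, s2[i - 1], 0) -
      (s1[j] - ifelse(i > 1, s1[i - 1], 0))^2 / (j - i + 1)
  }
  # cost[m, i]: best total SSD of x[1..i] split into m classes
  cost <- matrix(Inf, nrow = k, ncol = n)
  split_at <- matrix(0L, nrow = k, ncol = n)
  cost[1, ] <- vapply(seq_len(n), function(i) ssd(1, i), numeric(1))
  for (m in 2:k) {
    for (i in m:n) {
      j <- m:i                       # first index of the top class
      tot <- cost[m - 1, j - 1] + ssd(j, i)
      # prefer the largest j on ties: smaller upper class
      best <- max(j[tot <= min(tot) + 1e-12])
      cost[m, i] <- tot[best - m + 1]
      split_at[m, i] <- best
    }
  }
  breaks <- numeric(k - 1)
  i <- n
  for (m in k:2) {
    j <- split_at[m, i]
    breaks[m - 1] <- x[j - 1]        # max of the class below the split
    i <- j - 1
  }
  sort(breaks)
}

#' Classify cells as stem-like
#'
#' A cell is stem-like when its score is strictly greater than the threshold.
#'
#' @param scores Numeric scores (or the tibble from [score_cells()]).
#' @param threshold Finite numeric threshold; by convention the uppermost
#'   internal Jenks break, or the fixed value 0.25 for cross-dataset use.
#' @return Logical vector of stem flags.
#' @export
classify_cells <- function(scores, threshold) {
  if (is.data.frame(scores)) scores <- scores$score
  if (!is.finite(threshold)) abort("`threshold` must be finite.")
  scores > threshold
}

#' Categorize a sample by its stem-like fraction
#'
#' `high` above 15%, `moderate` for 5-15% (both bounds inclusive), `low`
#' below 5%.
#'
#' @param stem_fraction Numeric fraction(s) in `[0, 1]`.
#' @return Factor with levels `low < moderate < high`.
#' @export
categorize_sample <- function(stem_fraction) {
  if (anyNA(stem_fraction) || any(stem_fraction < 0) || any(stem_fraction > 1)) {
    abort("`stem_fraction` must lie in [0, 1].")
  }
  out <- ifelse(stem_fraction > 0.15, "high",
                ifelse(stem_fraction >= 0.05, "moderate", "low"))
  factor(out, levels = c("low", "moderate", "high"), ordered = TRUE)
}

#' Score, threshold and classify a cohort in one step
#'
#' Convenience wrapper: computes per-cell scores, derives the stem threshold
#' from Jenks natural breaks (`k` classes, uppermost internal break) unless a
#' fixed `threshold` is supplied, flags stem-like cells, and summarizes
#' per-sample stem fractions and categories.
#'
#' @param x A [cohort()] whose metadata has a `sample` column.
#' @param signature Signature genes (see [score_cells()]).
#' @param k Number of Jenks classes.
#' @param threshold Optional fixed threshold overriding the Jenks-derived one.
#' @param ... Passed to [score_cells()].
#' @return A `stemness_result`: list with `cells` (barcode, sample, score,
#'   stem), `breaks`, `threshold`, `threshold_source` and `samples` (per-sample
#'   n, n_stem, stem_fraction, category).
#' @export
stemness <- function(x, signature, k = 4, threshold = NULL, ...) {
  stopifnot(inherits(x, "cohort"))
  sc <- score_cells(x, signature, ...)
  breaks <- jenks_breaks(sc$score, k = k)
  source <- if (is.null(threshold)) "jenks" else "fixed"
  thr <- threshold %||% max(breaks)
  cells <- x$cells |>
    select(dplyr::any_of(c("barcode", "patient", "sample", "timepoint"))) |>
    left_join(sc, by = "barcode") |>
    mutate(stem = classify_cells(.data$score, thr))
  samples <- cells |>
    group_by(across(dplyr::any_of(c("patient", "sample", "timepoint")))) |>
    summarise(n = n(), n_stem = sum(.data$stem),
              stem_fraction = mean(.data$stem), .groups = "drop") |>
    mutate(category = categorize_sample(.data$stem_fraction))
  structure(
    list(cells = cells, breaks = breaks, threshold = thr,
         threshold_source = source, samples = samples),
    class = "stemness_result"
  )
}

#' @export
print.stemness_result <- function(x, ...) {
  cat("<stemness_result> ", nrow(x$cells), " cells, ",
      sum(x$cells$stem), " stem-like (",
      sprintf("%.2f%%", 100 * mean(x$cells$stem)), ")\n", sep = "")
  cat("  threshold ", format(x$threshold, digits = 4), " (", x$threshold_source,
      "); breaks: ", paste(format(x$breaks, digits = 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname stemness
#' @param object,... A `stemness_result` (for the tidiers).
#' @method tidy stemness_result
#' @export
tidy.stemness_result <- function(x, ...) x$samples

#' @rdname stemness
#' @method glance stemness_result
#' @export
glance.stemness_result <- function(x, ...) {
  tibble(n_cells = nrow(x$cells),
         n_stem = sum(x$cells$stem),
         stem_frequency_pct = round(100 * mean(x$cells$stem), 2),
         threshold = x$threshold,
         threshold_source = x$threshold_source)
}

#' Stemness score for bulk expression profiles
#'
#' Each signature gene is z-scored across samples (so platform scale cancels)
#' and the per-sample score is the mean z-score over signature genes.
#'
#' @param expr Genes-by-samples numeric matrix (log scale).
#' @param signature Signature genes; those absent or with zero variance across
#'   samples are dropped with a warning.
#' @return Tibble with `sample_id` and `score`.
#' @export
score_bulk <- function(expr, signature) {
  genes <- intersect(signature_genes(signature), rownames(expr))
  if (length(genes) == 0) abort("No signature gene is present in `expr`.")
  m <- expr[genes, , drop = FALSE]
  sds <- matrixStats::rowSds(m)
  if (any(sds == 0)) {
    warn(paste0("Dropping ", sum(sds == 0), " zero-variance signature gene(s)."))
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (m - rowMeans(m)) / sds
  tibble(sample_id = colnames(expr), score = unname(colMeans(z)))
}

#' Compare score distributions between two groups
#'
#' Welch two-sample t-test (unpaired) or Student paired t-test on matched
#' differences. Degenerate inputs (no variance anywhere, or zero-variance
#' paired differences) are flagged rather than raising.
#'
#' @param scores Numeric vector of scores, or the tibble from [score_bulk()].
#' @param groups Group labels (exactly two levels), aligned with `scores`;
#'   ignored when `paired = TRUE` and `scores`/`y` are the matched vectors.
#' @param paired Paired test?
#' @param y For `paired = TRUE`: the second matched vector (first is `scores`).
#' @return One-row tibble: `estimate` (mean difference), `statistic`,
#'   `p_value`, `df`, `method`, `degenerate`.
#' @export
compare_groups <- function(scores, groups = NULL, paired = FALSE, y = NULL) {
  if (is.data.frame(scores)) scores <- scores$score
  if (paired) {
    if (is.null(y)) abort("Paired comparison needs `y`.")
    if (length(scores) != length(y)) abort("Paired vectors must match in length.")
    d <- scores - y
    if (sd(d) == 0) {
      return(tibble(estimate = mean(d), statistic = NA_real_,
                    p_value = NA_real_, df = length(d) - 1,
                    method = "paired t", degenerate = TRUE))
    }
    tt <- t.test(scores, y, paired = TRUE)
    return(tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
                  p_value = tt$p.value, df = unname(tt$parameter),
                  method = "paired t", degenerate = FALSE))
  }
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) abort("`groups` must have exactly two levels.")
  a <- scores[groups == lev[1]]
  b <- scores[groups == lev[2]]
  if (length(a) < 2 || length(b) < 2) abort("Each group needs at least 2 samples.")
  if (sd(a) == 0 && sd(b) == 0) {
    same <- mean(a) == mean(b)
    return(tibble(estimate = mean(a) - mean(b),
                  statistic = if (same) 0 else Inf,
                  p_value = if (same) 1 else 0,
                  df = NA_real_, method = "Welch t", degenerate = TRUE))
  }
  tt <- t.test(a, b)
  tibble(estimate = unname(tt$estimate[1] - tt$estimate[2]),
         statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter), method = "Welch t", degenerate = FALSE)
}
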