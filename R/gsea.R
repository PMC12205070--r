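# Weighted Kolmogorov-Smirnov running-sum statistic for one gene set.
# positions: 1-based hit positions in the ranking; w: |score|^weight at hits.
# Evaluates the running sum just before and at each hit, which is where the
# extrema of the walk occur.
es_walk <- function(positions, w, N) {
  o <- order(positions)
  positions <- positions[o]
  w <- w[o]
  nh <- length(positions)
  miss <- 1 / (N - nh)
  wsum <- sum(w)
  if (wsum == 0) w <- rep(1 / nh, nh) else w <- w / wsum
  cw <- cumsum(w)
  at_hit <- cw - (positions - seq_len(nh)) * miss
  before_hit <- c(0, cw[-nh]) - (positions - seq_len(nh)) * miss
  cand <- c(at_hit, before_hit)
  es <- cand[which.max(abs(cand))]
  peak <- if (es >= 0) {
    positions[which.max(at_hit)]
  } else {
    positions[which.min(before_hit)]
  }
  list(es = es, peak = peak)
}

#' Pre-ranked gene-set enrichment analysis
#'
#' The standard weighted Kolmogorov-Smirnov walk: genes are ordered by a
#' ranking score, the running sum gains `|score|^weight` (normalized) at each
#' set member and loses `1/(N - Nh)` elsewhere, and the enrichment score (ES)
#' is the maximum deviation from zero. The null distribution comes from
#' permuting gene labels (resampling hit positions); the normalized score
#' (NES) divides ES by the mean magnitude of same-sign permutation scores,
#' and FDR uses the usual pooling of permutation NES values across sets
#' within each sign.
#'
#' @param stats Named numeric vector of per-gene ranking scores (e.g. signed
#'   `-log10(p)` from [rank_genes()]), or a two-column data frame
#'   (`gene`, `score`). Gene names must be unique.
#' @param gene_sets Named list of character vectors; sets overlapping the
#'   ranking in fewer than `min_size` genes are skipped with a warning.
#' @param weight Walk exponent (1 = classic weighted GSEA; 0 = unweighted KS).
#' @param n_perm Gene-label permutations.
#' @param seed Permutation seed.
#' @param min_size Minimum overlap with the ranking (default 5).
#' @return A `gsea_result` tibble: per set `size`, `es`, `nes`, `p_value`,
#'   `fdr` and the leading-edge genes (list column).
#' @export
preranked_gsea <- function(stats, gene_sets, weight = 1, n_perm = 1000,
                           seed = 1L, min_size = 5) {
  if (is.data.frame(stats)) stats <- setNames(stats$score, stats$gene)
  if (is.null(names(stats))) abort("`stats` must be named by gene.")
  if (anyDuplicated(names(stats))) abort("Ranking genes must be unique.")
  stats <- sort(stats, decreasing = TRUE)
  N <- length(stats)
  genes <- names(stats)
  wts <- abs(stats)^weight

  overlaps <- lapply(gene_sets, function(s) which(genes %in% s))
  small <- vapply(overlaps, length, integer(1)) < min_size
  if (any(small)) {
    warn(paste0("Skipping ", sum(small), " set(s) with < ", min_size,
                " genes in the ranking: ",
                paste(head(names(gene_sets)[small], 5), collapse = ", ")))
  }
  overlaps <- overlaps[!small]
  if (length(overlaps) == 0) {
    return(structure(tibble(set = character(0), size = integer(0),
                            es = numeric(0), nes = numeric(0),
                            p_value = numeric(0), fdr = numeric(0),
                            leading_edge = list()),
                     class = c("gsea_result", "tbl_df", "tbl", "data.frame")))
  }

  obs <- lapply(overlaps, function(pos) es_walk(pos, wts[pos], N))
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  perm_nes <- vector("list", length(overlaps))
  nes_obs <- numeric(length(overlaps))
  p_nom <- numeric(length(overlaps))
  withr::with_seed(seed, {
    for (k in seq_along(overlaps)) {
      nh <- length(overlaps[[k]])
      es_p <- vapply(seq_len(n_perm), function(b) {
        pos <- sample.int(N, nh)
        es_walk(pos, wts[pos], N)$es
      }, numeric(1))
      pos_mean <- mean(es_p[es_p > 0])
      neg_mean <- mean(abs(es_p[es_p < 0]))
      norm_one <- function(e) {
        if (e > 0) {
          if (is.nan(pos_mean)) NA_real_ else e / pos_mean
        } else if (e < 0) {
          if (is.nan(neg_mean)) NA_real_ else e / neg_mean
        } else 0
      }
      nes_obs[k] <- norm_one(es_obs[k])
      perm_nes[[k]] <- vapply(es_p, norm_one, numeric(1))
      same <- if (es_obs[k] >= 0) es_p >= 0 else es_p <= 0
      p_nom[k] <- (1 + sum(abs(es_p[same]) >= abs(es_obs[k]))) / (1 + sum(same))
    }
  })

  all_perm <- unlist(perm_nes)
  all_perm <- all_perm[!is.na(all_perm)]
  fdr <- vapply(seq_along(overlaps), function(k) {
    nes <- nes_obs[k]
    if (is.na(nes) || nes == 0) return(1)
    if (nes > 0) {
      num_den <- sum(all_perm > 0)
      num <- if (num_den == 0) 1 else sum(all_perm >= nes) / num_den
      den_den <- sum(nes_obs > 0, na.rm = TRUE)
      den <- sum(nes_obs >= nes, na.rm = TRUE) / den_den
    } else {
      num_den <- sum(all_perm < 0)
      num <- if (num_den == 0) 1 else sum(all_perm <= nes) / num_den
      den_den <- sum(nes_obs < 0, na.rm = TRUE)
      den <- sum(nes_obs <= nes, na.rm = TRUE) / den_den
    }
    min(1, num / den)
  }, numeric(1))

  leading <- lapply(seq_along(overlaps), function(k) {
    pos <- sort(overlaps[[k]])
    peak <- obs[[k]]$peak
    if (es_obs[k] >= 0) genes[pos[pos <= peak]] else genes[pos[pos >= peak]]
  })

  out <- tibble(set = names(overlaps),
                size = unname(vapply(overlaps, length, integer(1))),
                es = unname(es_obs), nes = nes_obs, p_value = p_nom, fdr = fdr,
                leading_edge = leading)
  class(out) <- c("gsea_result", class(out))
  out
}

#' Ranking metric for pre-ranked GSEA from a DE table
#'
#' Signed significance: `-log10(p) * sign(log2fc)`, with p floored at the
#' smallest positive double to keep the metric finite.
#'
#' @param de A data frame with `gene`, `p_value` and `log2fc` columns (e.g.
#'   the `"tested"` attribute of a [derive_signature()] result).
#' @return Named numeric vector sorted in decreasing order.
#' @export
rank_genes <- function(de) {
  stopifnot(all(c("gene", "p_value", "log2fc") %in% names(de)))
  p <- pmax(de$p_value, .Machine$double.xmin)
  s <- -log10(p) * sign(de$log2fc)
  sort(setNames(s, de$gene), decreasing = TRUE)
}
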