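# Independent brute-force oracles used to pin down the statistical primitives.
# Each oracle is a direct transcription of the definition, with no shortcuts
# shared with the package implementation.

# Exact two-sided rank-sum p by enumerating every assignment of the pooled
# ranks to group x (tie-free inputs only).
oracle_rank_sum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(length(pooled), nx)
  w_all <- apply(sets, 2, function(ix) sum(r[ix])) - nx * (nx + 1) / 2
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Step-up BH from the definition: sort, scale by m/i, enforce monotonicity
# from the top, cap at 1, restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive Fisher-Jenks: minimize total within-class SSD over every
# composition of the sorted values into k contiguous non-empty classes;
# returns the k-1 internal class maxima.
oracle_jenks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  cuts <- utils::combn(n - 1, k - 1)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf
  best_breaks <- NULL
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], n)
    tot <- sum(vapply(seq_len(k), function(c_) {
      ssd(x[(bounds[c_] + 1):bounds[c_ + 1]])
    }, numeric(1)))
    if (tot < best - 1e-12) {
      best <- tot
      best_breaks <- x[cuts[, j]]
    }
  }
  best_breaks
}

# Two-sided Fisher exact p: sum of hypergeometric probabilities of all tables
# with the observed margins that are no more probable than the observed one
# (with the conventional (1 + 1e-7) tolerance on "no more probable").
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_
  n_ <- b + d
  k <- a + b
  support <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Unweighted GSEA enrichment score by walking every rank position.
oracle_es_unweighted <- function(ranked_genes, set) {
  hit <- ranked_genes %in% set
  nh <- sum(hit)
  n <- length(ranked_genes)
  walk <- cumsum(ifelse(hit, 1 / nh, -1 / (n - nh)))
  walk[which.max(abs(walk))]
}

# Rank-based AUC of a score for separating a binary label.
auc_score <- function(score, positive) {
  np <- sum(positive)
  nn <- sum(!positive)
  (sum(rank(score)[positive]) - np * (np + 1) / 2) / (np * nn)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
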