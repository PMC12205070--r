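#' Permutation test for cell-population composition differences
#'
#' For each category (cell type, cluster, cycle phase, ...) the observed
#' effect is the log2 fold-difference of its proportion between the two
#' conditions, `log2((p_B + eps) / (p_A + eps))`; the small pseudo-proportion
#' keeps categories absent from one condition finite. The null is built by
#' permuting condition labels across cells (fixed margins, optionally within
#' strata), the two-sided p-value uses the add-one estimator so it can never
#' be zero, and a bootstrap over cells within each condition yields percentile
#' confidence intervals. BH adjustment runs across categories.
#'
#' @param data Data frame with one row per cell.
#' @param category,condition Column names (tidy-eval) holding the per-cell
#'   category and the condition; the condition must have exactly two levels.
#'   For an unquoted factor the first level is condition A.
#' @param B Number of permutations and bootstrap resamples (default 1000; a
#'   warning is issued below 100).
#' @param seed Seed for permutations and bootstrap.
#' @param eps Pseudo-proportion for empty categories (default `1e-4`).
#' @param stratify_by Optional column name: permute labels within its strata.
#' @param lfd_min,fdr_max Thresholds for the `significant` flag (defaults
#'   0.25 and 0.05).
#' @return A `proportion_test` tibble: per category the counts and proportions
#'   in each condition, `log2fd`, bootstrap `ci_lo`/`ci_hi`, permutation
#'   `p_value`, `p_adjusted` and `significant`.
#' @export
proportion_test <- function(data, category, condition, B = 1000, seed = 1L,
                            eps = 1e-4, stratify_by = NULL,
                            lfd_min = 0.25, fdr_max = 0.05) {
  cat_v <- factor(rlang::eval_tidy(rlang::enquo(category), data))
  cond_v <- factor(rlang::eval_tidy(rlang::enquo(condition), data))
  strata <- rlang::eval_tidy(rlang::enquo(stratify_by), data)
  if (nlevels(cond_v) != 2) {
    abort(paste0("`condition` must have exactly 2 levels (found ",
                 nlevels(cond_v), ")."))
  }
  if (B < 100) warn("Fewer than 100 permutations; p-values will be coarse.")
  K <- nlevels(cat_v)
  cat_i <- as.integer(cat_v)
  in_b <- cond_v == levels(cond_v)[2]
  n <- length(cat_i)
  n_b <- sum(in_b)

  lfd_of <- function(sel_b) {
    cb <- tabulate(cat_i[sel_b], nbins = K)
    ca <- tabulate(cat_i[!sel_b], nbins = K)
    log2((cb / sum(cb) + eps) / (ca / sum(ca) + eps))
  }
  obs <- lfd_of(in_b)

  withr::with_seed(seed, {
    # permute by shuffling the observed label vector itself: swapping the two
    # condition labels then flips every permuted log2FD's sign exactly, so the
    # p-value is invariant under relabeling
    perm <- matrix(NA_real_, nrow = K, ncol = B)
    if (is.null(strata)) {
      for (b in seq_len(B)) {
        perm[, b] <- lfd_of(in_b[sample.int(n)])
      }
    } else {
      strata <- factor(strata)
      idx_by <- split(seq_len(n), strata)
      for (b in seq_len(B)) {
        sel <- logical(n)
        for (s in seq_along(idx_by)) {
          i <- idx_by[[s]]
          sel[i] <- in_b[i][sample.int(length(i))]
        }
        perm[, b] <- lfd_of(sel)
      }
    }
    boot <- matrix(NA_real_, nrow = K, ncol = B)
    idx_a <- which(!in_b); idx_bb <- which(in_b)
    for (b in seq_len(B)) {
      sel <- logical(n)
      ra <- sample(idx_a, replace = TRUE)
      rb <- sample(idx_bb, replace = TRUE)
      cb <- tabulate(cat_i[rb], nbins = K)
      ca <- tabulate(cat_i[ra], nbins = K)
      boot[, b] <- log2((cb / sum(cb) + eps) / (ca / sum(ca) + eps))
    }
  })

  p <- (1 + rowSums(abs(perm) >= abs(obs) - 1e-12)) / (B + 1)
  count_a <- tabulate(cat_i[!in_b], nbins = K)
  count_b <- tabulate(cat_i[in_b], nbins = K)
  out <- tibble(
    category = levels(cat_v),
    n_a = count_a,
    n_b = count_b,
    prop_a = count_a / sum(count_a),
    prop_b = count_b / sum(count_b),
    log2fd = obs,
    ci_lo = matrixStats::rowQuantiles(boot, probs = 0.025),
    ci_hi = matrixStats::rowQuantiles(boot, probs = 0.975),
    p_value = p,
    p_adjusted = bh_adjust(p)
  )
  out$significant <- out$p_adjusted < fdr_max & abs(out$log2fd) > lfd_min
  attr(out, "conditions") <- levels(cond_v)
  attr(out, "B") <- B
  class(out) <- c("proportion_test", class(out))
  out
}

#' Paired expansion test across timepoints
#'
#' Student paired t-test on per-patient stem-like fractions at diagnosis vs
#' relapse (df = n - 1). Zero-variance differences are degenerate and flagged
#' instead of tested.
#'
#' @param fractions_initial,fractions_relapse Matched per-patient fractions,
#'   length at least 3.
#' @return One-row tibble: `estimate` (mean relapse - initial difference),
#'   `statistic`, `p_value`, `df`, `degenerate`.
#' @export
paired_expansion_test <- function(fractions_initial, fractions_relapse) {
  if (length(fractions_initial) != length(fractions_relapse)) {
    abort("Fraction vectors must be matched per patient (equal length).")
  }
  n <- length(fractions_initial)
  if (n < 3) abort("Need at least 3 patients.")
  d <- fractions_relapse - fractions_initial
  if (sd(d) == 0) {
    return(tibble(estimate = mean(d), statistic = NA_real_, p_value = NA_real_,
                  df = n - 1, degenerate = TRUE))
  }
  tt <- t.test(fractions_relapse, fractions_initial, paired = TRUE)
  tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         p_value = tt$p.value, df = unname(tt$parameter), degenerate = FALSE)
}

#' Composition of a table by groups
#'
#' Counts and percentage shares of `category` within each `group`; the
#' arithmetic behind stacked-barplot panels and reported population
#' frequencies.
#'
#' @param data Data frame with one row per cell.
#' @param category,group Column names (tidy-eval); `group` may be omitted for
#'   a single overall table.
#' @param digits Rounding for the percentage column.
#' @return Tibble with `n`, `prop` and `pct` per category (and group).
#' @export
composition_table <- function(data, category, group = NULL, digits = 2) {
  cat_q <- rlang::enquo(category)
  grp_q <- rlang::enquo(group)
  grouped <- if (rlang::quo_is_null(grp_q)) {
    data |> group_by(category = factor({{ category }}))
  } else {
    data |> group_by(group = {{ group }}, category = factor({{ category }}))
  }
  grouped |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(prop = .data$n / sum(.data$n),
           pct = round(100 * .data$n / sum(.data$n), digits)) |>
    ungroup()
}
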