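## Permutation-based differential-expression statistics.
##
## Two-group Welch-style t-tests and one-way ANOVA, with p-values and
## false-discovery-rate estimates obtained by permuting sample labels
## (group sizes preserved, the same permutation set reused across all
## proteins per round — the SAM convention of row-wise exchangeability).
## The FDR estimator is SAM's median-based one: at each observed |statistic|
## threshold, the median across permutations of the genome-wide count of
## permuted statistics exceeding the threshold, divided by the observed
## count, then made monotone.

#' Permutation-test configuration
#'
#' @param n_permutations Number of label permutations (>= 100).
#' @param seed Integer RNG seed; fixed seed gives bit-identical results.
#' @param s0 Non-negative variance-moderation constant added to the standard
#'   error in the t denominator (SAM's fudge factor); default 0 gives the
#'   plain Welch statistic.
#' @param fdr_level Significance level on the q-value scale, default 0.05.
#' @return A list of class `"permutation_config"`.
#' @export
permutation_config <- function(n_permutations = 1000L, seed = 1L,
                               s0 = 0, fdr_level = 0.05) {
  if (n_permutations < 100) stopf("n_permutations must be >= 100")
  if (s0 < 0) stopf("s0 must be non-negative")
  if (fdr_level <= 0 || fdr_level >= 1) stopf("fdr_level must be in (0, 1)")
  structure(
    list(n_permutations = as.integer(n_permutations),
         seed = as.integer(seed), s0 = s0, fdr_level = fdr_level),
    class = "permutation_config"
  )
}

## Welch-style moderated t for every row, given column index sets.
## Rows with <2 present values in either group get NA.
welch_stat <- function(X, ia, ib, s0) {
  a <- row_group_stats(X[, ia, drop = FALSE])
  b <- row_group_stats(X[, ib, drop = FALSE])
  num <- a$mean - b$mean
  se <- sqrt(a$var / a$n + b$var / b$n)
  den <- s0 + se
  stat <- num / den
  # zero spread and zero difference: define the statistic as 0
  zero <- !is.na(num) & !is.na(den) & den == 0
  stat[zero & num == 0] <- 0
  stat[zero & num != 0] <- sign(num[zero & num != 0]) * Inf
  stat[is.na(a$var) | is.na(b$var)] <- NA_real_
  stat
}

## One-way F for every row given a list of column index sets.
anova_stat <- function(X, idx_list) {
  k <- length(idx_list)
  st <- lapply(idx_list, function(ix) row_group_stats(X[, ix, drop = FALSE]))
  ns <- vapply(st, `[[`, numeric(nrow(X)), "n")
  ms <- vapply(st, `[[`, numeric(nrow(X)), "mean")
  vs <- vapply(st, `[[`, numeric(nrow(X)), "var")
  if (is.null(dim(ns))) { # single-protein matrix
    ns <- matrix(ns, nrow = 1); ms <- matrix(ms, nrow = 1)
    vs <- matrix(vs, nrow = 1)
  }
  N <- rowSums(ns)
  grand <- rowSums(ns * ms) / N
  ss_between <- rowSums(ns * (ms - grand)^2)
  ss_within <- rowSums((ns - 1) * vs)
  fstat <- (ss_between / (k - 1)) / (ss_within / (N - k))
  zero <- is.finite(ss_between) & ss_between == 0 & ss_within == 0
  fstat[zero] <- 0
  fstat[!is.finite(ss_within) | N <= k | apply(ns < 2, 1, any)] <- NA_real_
  fstat
}

## SAM-style permutation FDR for a vector of observed |stats| and a
## proteins x permutations matrix of permuted |stats|.
## q_i = mean_b #{|perm_b| >= |obs_i|} / #{|obs| >= |obs_i|}, capped at 1
## and made monotone non-decreasing in decreasing |obs|. The permuted
## exceedance counts are averaged rather than medianed: the median count is
## 0 for the extreme tail in about half of null datasets (its distribution
## there is concentrated on {0, 1}), which hands the top-ranked protein a
## spurious q of 0; the average is the convention of the desktop software
## this engine replaces and is calibrated under the null.
sam_qvalues <- function(abs_obs, abs_perm) {
  p <- length(abs_obs)
  ok <- !is.na(abs_obs) & !is.nan(abs_obs)
  q <- rep(NA_real_, p)
  if (!any(ok)) return(q)
  obs <- abs_obs[ok]
  ord <- order(obs, decreasing = TRUE)
  thresholds <- obs[ord]
  r_obs <- seq_along(thresholds) # observed count at each threshold
  B <- ncol(abs_perm)
  counts <- matrix(0L, nrow = length(thresholds), ncol = B)
  for (b in seq_len(B)) {
    sb <- sort(abs_perm[, b][is.finite(abs_perm[, b])])
    # #{sb >= t} = length(sb) - #{sb < t}
    counts[, b] <- length(sb) - findInterval(thresholds, sb, left.open = TRUE)
  }
  v_exp <- rowMeans(counts)
  q_sorted <- pmin(1, v_exp / r_obs)
  # monotone enforcement: a more extreme statistic never has a larger q
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_ok <- numeric(length(obs))
  q_ok[ord] <- q_sorted
  q[ok] <- q_ok
  q
}

## Shared permutation driver for both tests. stat_fun(X, perm_cols) must
## return a numeric vector over rows for one column ordering.
permute_stats <- function(X, cols, stat_fun, n_perm, seed) {
  with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      stat_fun(sample(cols))
    }, numeric(nrow(X)))
  })
}

#' Two-group permutation t-test with SAM-style FDR
#'
#' Computes, per protein, a Welch-style statistic (optionally moderated by
#' `cfg$s0`), a two-sided permutation p-value with the add-one rule
#' `p = (1 + #permuted |t| >= observed |t|) / (1 + B)`, and a SAM-style
#' permutation-FDR q-value. Missing values are tolerated: each protein is
#' tested on its present values, requiring at least two per group (otherwise
#' it is reported with `NA` statistics).
#'
#' @param m An `abundance_matrix` (log2 scale expected).
#' @param metadata Sample metadata (`sample_id`, `group`).
#' @param group_a,group_b Group labels to compare; the fold change and
#'   statistic are positive when higher in `group_a`.
#' @param cfg A [permutation_config()].
#' @return A data.frame with columns `protein`, `statistic`, `log2_fc`,
#'   `p_raw`, `q_value`, `significant`.
#' @export
permutation_ttest <- function(m, metadata, group_a, group_b,
                              cfg = permutation_config()) {
  stopifnot(inherits(m, "abundance_matrix"))
  check_metadata(m, metadata)
  ia <- group_columns(m, metadata, group_a)
  ib <- group_columns(m, metadata, group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stopf("both groups need >= 2 samples (got %d '%s', %d '%s')",
          length(ia), group_a, length(ib), group_b)
  }
  X <- m$values[, c(ia, ib), drop = FALSE]
  na <- length(ia)
  obs <- welch_stat(X, seq_len(na), na + seq_len(length(ib)), cfg$s0)
  cols <- seq_len(ncol(X))
  perm <- permute_stats(
    X, cols,
    function(pc) welch_stat(X, pc[seq_len(na)], pc[-seq_len(na)], cfg$s0),
    cfg$n_permutations, cfg$seed
  )
  if (is.null(dim(perm))) perm <- matrix(perm, nrow = 1)
  abs_obs <- abs(obs)
  abs_perm <- abs(perm)
  exceed <- rowSums(abs_perm >= abs_obs, na.rm = TRUE)
  p_raw <- (1 + exceed) / (1 + cfg$n_permutations)
  p_raw[is.na(abs_obs)] <- NA_real_
  q <- sam_qvalues(abs_obs, abs_perm)
  fc <- rowMeans(X[, seq_len(na), drop = FALSE], na.rm = TRUE) -
    rowMeans(X[, na + seq_len(length(ib)), drop = FALSE], na.rm = TRUE)
  fc[is.nan(fc)] <- NA_real_
  res <- data.frame(
    protein = protein_ids(m),
    statistic = obs,
    log2_fc = fc,
    p_raw = p_raw,
    q_value = q,
    significant = !is.na(q) & q < cfg$fdr_level,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "comparison") <- c(group_a, group_b)
  attr(res, "config") <- cfg
  res
}

#' One-way permutation ANOVA with SAM-style FDR
#'
#' One-way F statistic per protein across all groups in `metadata`
#' (typically IUP, PUC, NU), with permutation p-values and q-values exactly
#' as in [permutation_ttest()]; group labels are permuted jointly.
#'
#' @inheritParams permutation_ttest
#' @return A data.frame with columns `protein`, `statistic`, `p_raw`,
#'   `q_value`, `significant` (no `log2_fc`: the F test is directionless).
#' @export
permutation_anova <- function(m, metadata, cfg = permutation_config()) {
  stopifnot(inherits(m, "abundance_matrix"))
  check_metadata(m, metadata)
  groups <- unique(metadata$group)
  if (length(groups) < 3) stopf("ANOVA requires >= 3 groups")
  idx_list <- lapply(groups, function(g) group_columns(m, metadata, g))
  sizes <- lengths(idx_list)
  if (any(sizes < 2)) stopf("every group needs >= 2 samples")
  keep_cols <- unlist(idx_list)
  X <- m$values[, keep_cols, drop = FALSE]
  # rebuild index sets relative to X's column order
  off <- cumsum(c(0, sizes[-length(sizes)]))
  rel_idx <- lapply(seq_along(sizes), function(i) off[i] + seq_len(sizes[i]))
  obs <- anova_stat(X, rel_idx)
  cols <- seq_len(ncol(X))
  perm <- permute_stats(
    X, cols,
    function(pc) anova_stat(X, lapply(rel_idx, function(ix) pc[ix])),
    cfg$n_permutations, cfg$seed
  )
  if (is.null(dim(perm))) perm <- matrix(perm, nrow = 1)
  exceed <- rowSums(perm >= obs, na.rm = TRUE)
  p_raw <- (1 + exceed) / (1 + cfg$n_permutations)
  p_raw[is.na(obs)] <- NA_real_
  q <- sam_qvalues(obs, perm)
  res <- data.frame(
    protein = protein_ids(m),
    statistic = obs,
    p_raw = p_raw,
    q_value = q,
    significant = !is.na(q) & q < cfg$fdr_level,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "groups") <- groups
  attr(res, "config") <- cfg
  res
}

#' Per-protein log2 fold change between two groups
#'
#' `mean(group_a) - mean(group_b)` on the log2 scale; positive values mean
#' higher abundance in `group_a`. Proteins with no present value in a whole
#' group get `NA` and are flagged in the `flagged` column.
#'
#' @inheritParams permutation_ttest
#' @return Data.frame with columns `protein`, `log2_fc`, `flagged`.
#' @export
fold_change <- function(m, metadata, group_a, group_b) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (!m$log_transformed) stopf("fold_change expects a log2-scale matrix")
  check_metadata(m, metadata)
  ia <- group_columns(m, metadata, group_a)
  ib <- group_columns(m, metadata, group_b)
  if (!length(ia) || !length(ib)) stopf("group not found in matrix")
  ma <- rowMeans(m$values[, ia, drop = FALSE], na.rm = TRUE)
  mb <- rowMeans(m$values[, ib, drop = FALSE], na.rm = TRUE)
  fc <- ma - mb
  flagged <- is.nan(ma) | is.nan(mb)
  fc[flagged] <- NA_real_
  data.frame(protein = protein_ids(m), log2_fc = unname(fc),
             flagged = unname(flagged), stringsAsFactors = FALSE)
}
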