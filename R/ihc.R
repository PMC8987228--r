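## Immunohistochemistry validation statistics.
##
## Per-specimen H-scores from digital-pathology per-cell intensity calls,
## Mann-Whitney group comparison, the U-statistic AUROC with a
## Hanley-McNeil test against 0.5, Youden-optimal cutoffs, and
## Clopper-Pearson exact binomial confidence intervals for sensitivity and
## specificity.

#' Read a per-cell detection table
#'
#' @param path CSV with columns `specimen_id`, `diagnosis`, `intensity_bin`
#'   (digital-pathology detection exports reduced to binned DAB intensity
#'   0/1/2/3).
#' @return Data.frame of cell detections.
#' @export
read_cell_detections <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "diagnosis", "intensity_bin")
  if (!all(need %in% names(cells))) {
    stopf("cell table must have columns: %s", paste(need, collapse = ", "))
  }
  cells
}

#' Compute per-specimen H-scores
#'
#' H-score = 1*(% cells 1+) + 2*(% cells 2+) + 3*(% cells 3+), with all
#' detected cells (0-intensity included) in the percentage denominator;
#' range 0 (all negative) to 300 (all cells 3+).
#'
#' @param cells Data.frame with columns `specimen_id`, `diagnosis`,
#'   `intensity_bin` in \{0, 1, 2, 3\}; at least one cell per specimen.
#' @return Data.frame with columns `specimen_id`, `diagnosis`, `n_cells`,
#'   `h_score`.
#' @export
compute_hscore <- function(cells) {
  need <- c("specimen_id", "diagnosis", "intensity_bin")
  if (!is.data.frame(cells) || !all(need %in% names(cells))) {
    stopf("cell table must have columns: %s", paste(need, collapse = ", "))
  }
  if (!nrow(cells)) stopf("empty cell table")
  if (!all(cells$intensity_bin %in% 0:3)) {
    stopf("intensity_bin values must be 0, 1, 2 or 3")
  }
  specs <- unique(cells$specimen_id)
  out <- lapply(specs, function(s) {
    sub <- cells[cells$specimen_id == s, ]
    pct <- 100 * tabulate(sub$intensity_bin + 1L, nbins = 4L) / nrow(sub)
    data.frame(specimen_id = s,
               diagnosis = sub$diagnosis[1],
               n_cells = nrow(sub),
               h_score = 1 * pct[2] + 2 * pct[3] + 3 * pct[4],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mann-Whitney comparison of two groups of H-scores
#'
#' Exact-distribution two-sided p when the smaller group has at most 8
#' observations and there are no ties; otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param scores Numeric vector of scores.
#' @param labels Group label per score (exactly two groups).
#' @return List with `U` (statistic for the first group level) and
#'   `p_value`.
#' @export
mannwhitney_compare <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stopf("exactly two groups required")
  x <- scores[labels == levels(labels)[1]]
  y <- scores[labels == levels(labels)[2]]
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  use_exact <- min(length(x), length(y)) <= 8 &&
    !anyDuplicated(c(x, y))
  wt <- stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' AUROC with Hanley-McNeil inference
#'
#' AUC estimated as the normalized Mann-Whitney U (tied pairs count 1/2):
#' the probability that a random positive scores above a random negative.
#' The standard error uses the Hanley-McNeil formula at the observed AUC
#' (falling back to the null-AUC SE when the observed SE is zero, i.e.
#' perfect separation), and the p-value tests AUC = 0.5.
#'
#' @param scores Numeric scores.
#' @param labels Class labels.
#' @param positive_label Label of the positive class (assumed to score
#'   higher).
#' @param method `"hanley"` (default) or `"delong"` for the variance.
#' @return List with `auc`, `se`, `p_value`, `n_positive`, `n_negative`.
#' @export
roc_auc <- function(scores, labels, positive_label,
                    method = c("hanley", "delong")) {
  method <- match.arg(method)
  pos <- labels == positive_label
  n1 <- sum(pos); n0 <- sum(!pos)
  if (!n1 || !n0) stopf("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  hm_se <- function(a) {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
           (n1 * n0))
  }
  if (method == "hanley") {
    se <- hm_se(auc)
  } else {
    # DeLong: placement-value variance components
    v10 <- vapply(scores[pos], function(s) {
      (sum(scores[!pos] < s) + 0.5 * sum(scores[!pos] == s)) / n0
    }, numeric(1))
    v01 <- vapply(scores[!pos], function(s) {
      (sum(scores[pos] > s) + 0.5 * sum(scores[pos] == s)) / n1
    }, numeric(1))
    se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  }
  se_test <- if (is.finite(se) && se > 0) se else hm_se(0.5)
  p <- 2 * stats::pnorm(-abs(auc - 0.5) / se_test)
  list(auc = auc, se = se, p_value = p, n_positive = n1, n_negative = n0)
}

#' Youden-optimal diagnostic cutoff
#'
#' Scans all midpoints between adjacent distinct score values and returns
#' the threshold maximizing Youden's J = sensitivity + specificity - 1;
#' ties resolve to the lowest threshold. With `direction = "greater"`
#' (default) a specimen is called positive when its score exceeds the
#' cutoff.
#'
#' @inheritParams roc_auc
#' @param direction `"greater"` if positives score higher, `"less"` if
#'   lower.
#' @return List with `cutoff`, `sensitivity`, `specificity` (percent),
#'   `youden`.
#' @export
youden_cutoff <- function(scores, labels, positive_label,
                          direction = c("greater", "less")) {
  direction <- match.arg(direction)
  pos <- labels == positive_label
  if (!sum(pos) || !sum(!pos)) stopf("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2) stopf("cutoff undefined for constant scores")
  thresholds <- (u[-1] + u[-length(u)]) / 2
  eval_at <- function(t) {
    called <- if (direction == "greater") scores > t else scores < t
    sens <- mean(called[pos])
    spec <- mean(!called[!pos])
    c(sens, spec)
  }
  ss <- vapply(thresholds, eval_at, numeric(2))
  j <- ss[1, ] + ss[2, ] - 1
  best <- which(j == max(j))[1] # thresholds ascend: first hit = lowest
  list(cutoff = thresholds[best],
       sensitivity = 100 * ss[1, best],
       specificity = 100 * ss[2, best],
       youden = j[best])
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from beta-distribution quantiles, returned in percent:
#' lower = 0 when there are no successes, upper = 100 when all trials
#' succeed. 18 successes of 25 at 95% gives (50.6, 87.9) after rounding to
#' one decimal.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)` in percent, unrounded.
#' @export
exact_binomial_ci <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n ||
      successes != round(successes) || n != round(n)) {
    stopf("need integer counts with 0 <= successes <= n and n >= 1")
  }
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = 100 * lower, upper = 100 * upper)
}

#' Full diagnostic report for one marker
#'
#' Convenience wrapper chaining [compute_hscore()], [mannwhitney_compare()],
#' [roc_auc()], [youden_cutoff()] and [exact_binomial_ci()] for a per-cell
#' detection table of a two-diagnosis validation cohort.
#'
#' @param cells Per-cell detection table (see [compute_hscore()]).
#' @param positive_label Diagnosis whose specimens score higher (e.g.
#'   `"IUP"` for a marker retained in papilloma).
#' @param level Confidence level for the sensitivity/specificity intervals.
#' @return List with `h_scores`, `mann_whitney`, `roc`, `youden`,
#'   `sensitivity_ci`, `specificity_ci`.
#' @export
ihc_diagnostic_report <- function(cells, positive_label, level = 0.95) {
  hs <- compute_hscore(cells)
  mw <- mannwhitney_compare(hs$h_score, hs$diagnosis)
  roc <- roc_auc(hs$h_score, hs$diagnosis, positive_label)
  yc <- youden_cutoff(hs$h_score, hs$diagnosis, positive_label)
  pos <- hs$diagnosis == positive_label
  tp <- sum(hs$h_score[pos] > yc$cutoff)
  tn <- sum(hs$h_score[!pos] <= yc$cutoff)
  list(h_scores = hs,
       mann_whitney = mw,
       roc = roc,
       youden = yc,
       sensitivity_ci = exact_binomial_ci(tp, sum(pos), level),
       specificity_ci = exact_binomial_ci(tn, sum(!pos), level))
}
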