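## SVM-RFE feature ranking with an RBF kernel.
##
## Recursive feature elimination around an RBF-kernel support-vector
## classifier. The RBF kernel has no primal weight vector, so each feature is
## scored by the change in the kernel-space margin objective
## W2 = sum_ij a_i a_j y_i y_j K(x_i, x_j) when that feature is removed from
## the kernel (the standard nonlinear RFE criterion); the lowest-scoring
## fraction of remaining features is dropped each round. Panel quality is
## measured by stratified cross-validated error at every panel size visited,
## and the chosen panel is the smallest size achieving the minimum error —
## "the lowest error rates, along with keeping the protein lists short".

## W2 and per-feature removal scores from a fitted e1071 RBF svm.
## sv: support vectors (rows), coefs: y_i * alpha_i, gamma: kernel width.
rbf_removal_scores <- function(sv, coefs, gamma) {
  d2 <- as.matrix(stats::dist(sv))^2
  K <- exp(-gamma * d2)
  aKa <- function(K) drop(crossprod(coefs, K %*% coefs))
  w2 <- aKa(K)
  vapply(seq_len(ncol(sv)), function(j) {
    dj <- outer(sv[, j], sv[, j], `-`)^2
    # dividing feature j out of the squared distance
    abs(w2 - aKa(K * exp(gamma * dj)))
  }, numeric(1))
}

scale_train_apply <- function(train, test = NULL) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  tr <- sweep(sweep(train, 2, mu, `-`), 2, sdv, `/`)
  if (is.null(test)) return(list(train = tr))
  te <- sweep(sweep(test, 2, mu, `-`), 2, sdv, `/`)
  list(train = tr, test = te)
}

## Stratified fold assignment preserving class ratios within one sample.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    i <- which(y == cl)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' SVM-RFE ranking of proteins separating two groups
#'
#' Ranks proteins by recursive feature elimination around an RBF-kernel SVM
#' and records the stratified cross-validated misclassification rate at each
#' panel size visited by the elimination schedule.
#'
#' @param m A complete (imputed) log2 `abundance_matrix`.
#' @param metadata Sample metadata.
#' @param group_a,group_b Group labels to discriminate.
#' @param cv_folds Cross-validation folds (default 5); reduced with a warning
#'   when a class has fewer samples than folds.
#' @param seed RNG seed controlling fold assignment.
#' @param drop_fraction Fraction of remaining features eliminated per round
#'   (default 0.1, at least one feature per round).
#' @param cost SVM cost parameter (default 10: with standardized features
#'   and the tiny cohorts typical here, a firmer margin ranks informative
#'   features more stably than the soft default of 1).
#' @param gamma RBF width; default `0.1 / n_features` of the current panel.
#'   Standardized features put squared sample distances near
#'   `2 * n_features`, so this keeps the kernel mildly nonlinear — the
#'   regime where the margin-objective removal criterion stays sensitive on
#'   cohorts of a few dozen samples.
#' @return An object of class `"feature_ranking"`: list with
#'   `ordered_proteins` (best first), `error_curve` (data.frame
#'   `panel_size`, `cv_error`), `chosen_panel_size`, `cv_folds`, `seed`.
#' @export
svm_rfe_rank <- function(m, metadata, group_a, group_b,
                         cv_folds = 5, seed = 1L,
                         drop_fraction = 0.1, cost = 10, gamma = NULL) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (anyNA(m$values)) stopf("svm_rfe_rank requires a complete matrix")
  check_metadata(m, metadata)
  ia <- group_columns(m, metadata, group_a)
  ib <- group_columns(m, metadata, group_b)
  if (!length(ia) || !length(ib)) stopf("empty class")
  X <- t(m$values[, c(ia, ib), drop = FALSE]) # samples x features
  y <- factor(rep(c(group_a, group_b), c(length(ia), length(ib))),
              levels = c(group_a, group_b))
  n_min <- min(length(ia), length(ib))
  if (cv_folds > n_min) {
    warnf("reducing cv_folds from %d to %d (smallest class size)",
          cv_folds, n_min)
    cv_folds <- n_min
  }
  if (cv_folds < 2) stopf("need >= 2 samples per class for cross-validation")

  fit_svm <- function(x, yy, g) {
    e1071::svm(x, yy, kernel = "radial", cost = cost, gamma = g,
               scale = FALSE, type = "C-classification")
  }
  gam <- function(nf) if (is.null(gamma)) 0.1 / nf else gamma

  ## --- elimination on the full data (ranking) ---
  remaining <- colnames(X)
  eliminated <- character(0)
  sizes <- integer(0)
  Xs_all <- scale_train_apply(X)$train
  while (length(remaining) >= 1) {
    sizes <- c(sizes, length(remaining))
    if (length(remaining) == 1) {
      eliminated <- c(remaining, eliminated)
      break
    }
    Xr <- Xs_all[, remaining, drop = FALSE]
    const <- apply(X[, remaining, drop = FALSE], 2, stats::sd) == 0
    scores <- rep(0, length(remaining))
    fit <- fit_svm(Xr, y, gam(length(remaining)))
    sv <- Xr[fit$index, , drop = FALSE]
    scores[!const] <- rbf_removal_scores(sv, fit$coefs,
                                         gam(length(remaining)))[!const]
    n_drop <- max(1L, floor(drop_fraction * length(remaining)))
    n_drop <- min(n_drop, length(remaining) - 1L)
    drop_i <- order(scores, remaining)[seq_len(n_drop)]
    # least important features leave first => prepend to keep best-first order
    eliminated <- c(remaining[drop_i][order(-scores[drop_i])], eliminated)
    remaining <- remaining[-drop_i]
  }
  ordered_proteins <- eliminated

  ## --- cross-validated error at each visited panel size ---
  folds <- with_seed(seed, stratified_folds(y, cv_folds))
  cv_error_at <- function(feats) {
    errs <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      sc <- scale_train_apply(X[tr, feats, drop = FALSE],
                              X[!tr, feats, drop = FALSE])
      fit <- fit_svm(sc$train, y[tr], gam(length(feats)))
      pred <- stats::predict(fit, sc$test)
      errs <- errs + sum(pred != y[!tr])
    }
    errs / length(y)
  }
  err <- vapply(sizes, function(k) {
    cv_error_at(ordered_proteins[seq_len(k)])
  }, numeric(1))
  curve <- data.frame(panel_size = sizes, cv_error = err)
  curve <- curve[order(curve$panel_size), , drop = FALSE]
  rownames(curve) <- NULL
  chosen <- curve$panel_size[which(curve$cv_error == min(curve$cv_error))[1]]
  structure(
    list(ordered_proteins = ordered_proteins,
         error_curve = curve,
         chosen_panel_size = chosen,
         cv_folds = cv_folds,
         seed = as.integer(seed),
         comparison = c(group_a, group_b)),
    class = "feature_ranking"
  )
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf(
    "feature_ranking: %d proteins (%s vs %s), chosen panel %d (CV error %.3g)\n",
    length(x$ordered_proteins), x$comparison[1], x$comparison[2],
    x$chosen_panel_size,
    min(x$error_curve$cv_error)
  ))
  invisible(x)
}

#' Select the biomarker panel from an error curve
#'
#' Returns the top-k ranked proteins, where k is the smallest panel size
#' achieving the minimum cross-validated error.
#'
#' @param r A `"feature_ranking"` from [svm_rfe_rank()].
#' @return Character vector of panel proteins, best first.
#' @export
choose_panel <- function(r) {
  stopifnot(inherits(r, "feature_ranking"))
  if (!nrow(r$error_curve)) stopf("empty error curve")
  r$ordered_proteins[seq_len(r$chosen_panel_size)]
}

#' Shortlist panel candidates by combined ML and FDR rank
#'
#' Re-orders the chosen panel by the unweighted sum of each protein's
#' machine-learning rank and its rank by ascending t-test q-value, and
#' returns the top `k` — the rule used to reduce the 10-protein panel to the
#' five most robust candidates.
#'
#' @param r A `"feature_ranking"`.
#' @param ttest A [permutation_ttest()] result for the same comparison.
#' @param k Shortlist size (default 5).
#' @return Character vector of shortlisted proteins, best first.
#' @export
shortlist_candidates <- function(r, ttest, k = 5) {
  stopifnot(inherits(r, "feature_ranking"))
  panel <- choose_panel(r)
  if (k > length(panel)) {
    warnf("k = %d exceeds panel size %d; returning the whole panel",
          k, length(panel))
    k <- length(panel)
  }
  qv <- ttest$q_value[match(panel, ttest$protein)]
  if (anyNA(match(panel, ttest$protein))) {
    stopf("t-test results missing for some panel proteins")
  }
  ml_rank <- seq_along(panel)
  q_rank <- rank(qv, ties.method = "min")
  combined <- ml_rank + q_rank
  ord <- order(combined, qv, panel)
  panel[ord][seq_len(k)]
}
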