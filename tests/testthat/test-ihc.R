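cells_of <- function(specimen, diagnosis, bins) {
  data.frame(specimen_id = specimen, diagnosis = diagnosis,
             intensity_bin = bins, stringsAsFactors = FALSE)
}

test_that("H-scores follow the weighted-percentage formula and bounds", {
  expect_equal(compute_hscore(cells_of("a", "IUP", rep(3, 40)))$h_score, 300)
  expect_equal(compute_hscore(cells_of("a", "IUP", rep(0, 40)))$h_score, 0)
  mix <- c(rep(1, 50), rep(2, 25), rep(3, 25))
  expect_equal(compute_hscore(cells_of("a", "IUP", mix))$h_score, 175)
  # bounds hold for arbitrary tables; merged table is the
  # cell-count-weighted mean of its parts
  set.seed(2)
  for (i in 1:20) {
    b1 <- sample(0:3, sample(5:60, 1), replace = TRUE)
    b2 <- sample(0:3, sample(5:60, 1), replace = TRUE)
    h1 <- compute_hscore(cells_of("s1", "IUP", b1))$h_score
    h2 <- compute_hscore(cells_of("s2", "IUP", b2))$h_score
    expect_true(h1 >= 0 && h1 <= 300)
    merged <- compute_hscore(cells_of("m", "IUP", c(b1, b2)))$h_score
    expect_equal(merged,
                 (length(b1) * h1 + length(b2) * h2) / (length(b1) + length(b2)))
  }
  expect_error(compute_hscore(cells_of("a", "IUP", c(1, 4))), "0, 1, 2 or 3")
  empty <- data.frame(specimen_id = character(0), diagnosis = character(0),
                      intensity_bin = integer(0))
  expect_error(compute_hscore(empty), "empty")
})

test_that("Mann-Whitney comparison matches the exact small-sample case", {
  mw <- mannwhitney_compare(c(1, 2, 3, 4, 5, 6),
                            rep(c("a", "b"), each = 3))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1) # full enumeration of 20 orderings
  # identical groups: p = 1; label swap leaves p unchanged
  x <- c(10, 12, 14, 11, 13, 15)
  mw_id <- mannwhitney_compare(x, rep(c("a", "b"), 3))
  expect_gt(mw_id$p_value, 0.5)
  sw <- mannwhitney_compare(x, rep(c("b", "a"), 3))
  expect_equal(mw_id$p_value, sw$p_value)
  expect_error(mannwhitney_compare(1:3, rep("a", 3)), "two groups")
})

test_that("AUC equals the normalized pairwise count and pROC agrees", {
  scores <- c(30, 40, 10, 20, 25)
  labels <- c("P", "P", "N", "N", "N")
  a <- roc_auc(scores, labels, "P")
  pw <- outer(scores[labels == "P"], scores[labels == "N"],
              function(p, n) (p > n) + 0.5 * (p == n))
  expect_equal(a$auc, mean(pw))
  # antisymmetry and separation
  expect_equal(roc_auc(-scores, labels, "P")$auc, 1 - a$auc)
  expect_equal(roc_auc(c(5, 6, 1, 2, 3), labels, "P")$auc, 1)
  # independent oracle: pROC on a larger tied instance
  set.seed(9)
  sc <- sample(1:20, 60, replace = TRUE)
  lb <- sample(c("P", "N"), 60, replace = TRUE, prob = c(0.4, 0.6))
  expect_equal(roc_auc(sc, lb, "P")$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("N", "P"),
                                              direction = "<", quiet = TRUE))))
  # labels independent of scores: AUC near 1/2
  set.seed(10)
  sc2 <- rnorm(2000)
  lb2 <- sample(c("P", "N"), 2000, replace = TRUE)
  a2 <- roc_auc(sc2, lb2, "P")
  expect_lt(abs(a2$auc - 0.5), 3 * a2$se)
  expect_gt(a2$p_value, 0.001)
})

test_that("Youden cutoff matches exhaustive threshold search", {
  y <- youden_cutoff(c(30, 40, 10, 20), c("IUP", "IUP", "PUC", "PUC"), "IUP")
  expect_equal(y$cutoff, 25)
  expect_equal(y$sensitivity, 100)
  expect_equal(y$specificity, 100)
  # complete overlap: J = 0
  y0 <- youden_cutoff(c(1, 2, 1, 2), c("P", "P", "N", "N"), "P")
  expect_equal(y0$youden, 0)
  expect_error(youden_cutoff(rep(3, 4), c("P", "P", "N", "N"), "P"),
               "constant")
  # random instances against brute force, ties resolved to lowest threshold
  set.seed(11)
  for (i in 1:30) {
    n <- sample(8:50, 1)
    sc <- round(runif(n, 0, 100), sample(0:1, 1))
    lb <- sample(c("P", "N"), n, replace = TRUE)
    if (length(unique(lb)) < 2 || length(unique(sc)) < 2) next
    yc <- youden_cutoff(sc, lb, "P")
    u <- sort(unique(sc))
    th <- (u[-1] + u[-length(u)]) / 2
    j <- vapply(th, function(t) {
      mean(sc[lb == "P"] > t) + mean(sc[lb == "N"] <= t) - 1
    }, numeric(1))
    expect_equal(yc$youden, max(j))
    expect_equal(yc$cutoff, th[which(j == max(j))[1]])
  }
})

test_that("Clopper-Pearson intervals match printed clinical values and cover", {
  expect_equal(round(exact_binomial_ci(18, 25), 1),
               c(lower = 50.6, upper = 87.9))
  expect_equal(round(exact_binomial_ci(16, 16), 1),
               c(lower = 79.4, upper = 100.0))
  expect_equal(exact_binomial_ci(0, 10)[["lower"]], 0)
  expect_equal(exact_binomial_ci(10, 10)[["upper"]], 100)
  expect_error(exact_binomial_ci(5, 4), "<= n")
  # exact coverage at n = 25 across p in {0.1, ..., 0.9} (no simulation:
  # sum binomial probabilities of the k whose interval covers p)
  for (p in seq(0.1, 0.9, by = 0.1)) {
    covers <- vapply(0:25, function(k) {
      ci <- exact_binomial_ci(k, 25) / 100
      ci[["lower"]] <= p && p <= ci[["upper"]]
    }, logical(1))
    expect_gte(sum(dbinom(0:25, 25, p)[covers]), 0.95)
  }
})

test_that("the combined IHC report is internally consistent", {
  sim <- simulate_ihc(ihc_sim_spec(cells_per_specimen = 200, seed = 6))
  rep <- ihc_diagnostic_report(sim$cells, "IUP")
  expect_equal(nrow(rep$h_scores), 41)
  expect_gt(rep$roc$auc, 0.9)
  expect_lt(rep$mann_whitney$p_value, 1e-4)
  expect_true(rep$sensitivity_ci[["lower"]] <= rep$youden$sensitivity)
  expect_true(rep$sensitivity_ci[["upper"]] >= rep$youden$sensitivity)
  expect_true(rep$specificity_ci[["lower"]] <= rep$youden$specificity)
})
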