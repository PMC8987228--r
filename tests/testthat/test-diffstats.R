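make_two_group <- function(values_a, values_b, n_extra = 0, seed = 1) {
  # one protein of interest plus optional iid background proteins
  set.seed(seed)
  na <- length(values_a); nb <- length(values_b)
  v <- rbind(c(values_a, values_b))
  if (n_extra > 0) v <- rbind(v, matrix(rnorm(n_extra * (na + nb)), n_extra))
  rownames(v) <- sprintf("P%03d", seq_len(nrow(v)))
  colnames(v) <- sprintf("S%03d", seq_len(na + nb))
  list(m = abundance_matrix(v, log_transformed = TRUE),
       metadata = data.frame(sample_id = colnames(v),
                             group = rep(c("A", "B"), c(na, nb)),
                             stringsAsFactors = FALSE))
}

test_that("zero-effect proteins get statistic 0 and p near 1", {
  d <- make_two_group(c(5, 5, 5), c(5, 5, 5), n_extra = 3)
  res <- permutation_ttest(d$m, d$metadata, "A", "B",
                           permutation_config(n_permutations = 200))
  expect_equal(res$statistic[1], 0)
  expect_equal(res$p_raw[1], 1)
  expect_false(res$significant[1])
  expect_equal(res$log2_fc[1], 0)
})

test_that("separation far beyond noise drives p to the permutation floor", {
  # with 8 vs 8 samples only label shuffles reproducing the original split
  # can match the observed statistic, so p sits essentially at the add-one
  # floor; it can never go below it
  set.seed(4)
  d <- make_two_group(rnorm(8, 10, 0.1), rnorm(8, 0, 0.1), n_extra = 5,
                      seed = 4)
  cfg <- permutation_config(n_permutations = 1000, seed = 2)
  res <- permutation_ttest(d$m, d$metadata, "A", "B", cfg)
  expect_gte(res$p_raw[1], 1 / 1001)
  expect_lte(res$p_raw[1], 5 / 1001)
  expect_true(res$significant[1])
})

test_that("random permutation p approaches the exact enumeration for tiny n", {
  # independent oracle: enumerate all C(6,3) = 20 assignments
  xa <- c(1.3, 2.1, 0.4)
  xb <- c(3.0, 2.6, 4.1)
  pooled <- c(xa, xb)
  welch_t <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  obs <- abs(welch_t(xa, xb))
  splits <- combn(6, 3)
  perm_ts <- apply(splits, 2, function(ia) {
    abs(welch_t(pooled[ia], pooled[-ia]))
  })
  p_exact <- mean(perm_ts >= obs - 1e-12)
  d <- make_two_group(xa, xb)
  res <- permutation_ttest(d$m, d$metadata, "A", "B",
                           permutation_config(n_permutations = 4000, seed = 5))
  expect_lt(abs(res$p_raw[1] - p_exact), 0.05)
})

test_that("q-values are monotone in |statistic| and results are deterministic", {
  set.seed(7)
  v <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(sprintf("P%02d", 1:50), sprintf("S%02d", 1:12)))
  v[1:5, 1:6] <- v[1:5, 1:6] + 4
  m <- abundance_matrix(v, TRUE)
  md <- data.frame(sample_id = colnames(v), group = rep(c("A", "B"), each = 6))
  cfg <- permutation_config(n_permutations = 300, seed = 11)
  r1 <- permutation_ttest(m, md, "A", "B", cfg)
  r2 <- permutation_ttest(m, md, "A", "B", cfg)
  expect_identical(r1, r2)
  ord <- order(abs(r1$statistic), decreasing = TRUE)
  expect_true(all(diff(r1$q_value[ord]) >= -1e-12))
  expect_true(all(r1$p_raw >= 1 / 301 & r1$p_raw <= 1))
  expect_true(all(r1$q_value >= 0 & r1$q_value <= 1))
  # significance is exactly the q < level rule
  expect_identical(r1$significant, r1$q_value < cfg$fdr_level)
})

test_that("proteins with sparse groups are flagged rather than tested", {
  v <- matrix(c(1, NA, NA, 5, 6, 7,
                1, 2, 3, 4, 5, 6), 2, 6, byrow = TRUE,
              dimnames = list(c("sparse", "full"), sprintf("S%d", 1:6)))
  md <- data.frame(sample_id = colnames(v), group = rep(c("A", "B"), each = 3))
  res <- permutation_ttest(abundance_matrix(v, TRUE), md, "A", "B",
                           permutation_config(n_permutations = 100))
  expect_true(is.na(res$statistic[res$protein == "sparse"]))
  expect_false(is.na(res$statistic[res$protein == "full"]))
})

test_that("ANOVA flags a shifted group and agrees with the parametric F test", {
  means <- cbind(IUP = c(0, 5), PUC = c(0, 0), NU = c(0, 0))
  rownames(means) <- c("null", "shifted")
  d <- grouped_matrix(means, n_per_group = c(IUP = 9, PUC = 12, NU = 10),
                      noise_sd = 1, seed = 13)
  cfg <- permutation_config(n_permutations = 10000, seed = 13)
  res <- permutation_anova(d$m, d$metadata, cfg)
  expect_true(res$significant[res$protein == "shifted"])
  expect_false(res$significant[res$protein == "null"])
  # permutation p within 0.05 of the classical F-test p on normal data
  for (p in c("null", "shifted")) {
    x <- d$m$values[p, ]
    par_p <- anova(lm(x ~ d$metadata$group))$`Pr(>F)`[1]
    expect_lt(abs(res$p_raw[res$protein == p] - par_p), 0.05)
  }
  expect_error(permutation_anova(d$m, d$metadata[d$metadata$group != "NU", ],
                                 cfg))
})

test_that("fold changes are antisymmetric and respect the direction convention", {
  means <- cbind(IUP = c(5, 3, 2), PUC = c(3, 3, 4), NU = c(1, 1, 1))
  rownames(means) <- c("up", "flat", "down")
  d <- grouped_matrix(means, noise_sd = 0, seed = 1)
  fc_ab <- fold_change(d$m, d$metadata, "IUP", "PUC")
  fc_ba <- fold_change(d$m, d$metadata, "PUC", "IUP")
  expect_equal(fc_ab$log2_fc, c(2, 0, -2), tolerance = 1e-12)
  expect_equal(fc_ab$log2_fc, -fc_ba$log2_fc)
  # protein absent in a whole group is flagged with NA value
  v <- d$m$values
  v["up", d$metadata$group == "IUP"] <- NA
  fc_na <- fold_change(abundance_matrix(v, TRUE), d$metadata, "IUP", "PUC")
  expect_true(fc_na$flagged[fc_na$protein == "up"])
  expect_true(is.na(fc_na$log2_fc[fc_na$protein == "up"]))
})

test_that("permutation p-values are not anticonservative under the null", {
  # pooled over a small global-null matrix: empirical CDF of p at 0.05
  # should not exceed 0.05 by more than binomial noise
  set.seed(21)
  v <- matrix(rnorm(200 * 12), 200, 12,
              dimnames = list(sprintf("P%03d", 1:200), sprintf("S%02d", 1:12)))
  md <- data.frame(sample_id = colnames(v), group = rep(c("A", "B"), each = 6))
  res <- permutation_ttest(abundance_matrix(v, TRUE), md, "A", "B",
                           permutation_config(n_permutations = 400, seed = 3))
  frac05 <- mean(res$p_raw <= 0.05)
  expect_lt(frac05, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})
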