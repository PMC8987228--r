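test_that("abundance tables parse with configurable missing tokens", {
  path <- write_abundance_tsv(c(
    "protein\tS1\tS2",
    "A\t10\t20",
    "B\tNaN\t5",
    "C\t1\t2"
  ))
  m <- read_abundance_table(path)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(is.na(m$values)), 1L)
  expect_equal(m$values["A", "S2"], 20)
  # "0" treated as missing by default (MaxQuant dialect)
  path0 <- write_abundance_tsv(c("protein\tS1", "A\t0"))
  expect_true(is.na(read_abundance_table(path0)$values[1, 1]))
  expect_false(is.na(
    read_abundance_table(path0, missing_tokens = "")$values[1, 1]))
})

test_that("malformed abundance tables are rejected with informative errors", {
  empty <- write_abundance_tsv(character(0))
  expect_error(read_abundance_table(empty), "no data rows")
  dup <- write_abundance_tsv(c("protein\tS1", "A\t1", "A\t2"))
  expect_error(read_abundance_table(dup), "duplicate")
  ragged <- write_abundance_tsv(c("protein\tS1\tS2", "A\t1"))
  expect_error(read_abundance_table(ragged), "ragged")
  text <- write_abundance_tsv(c("protein\tS1", "A\tabc"))
  expect_error(read_abundance_table(text), "non-numeric")
})

test_that("presence filter applies the inclusive >= rule on exact fractions", {
  # 2/10 = 0.20 survives; protein present everywhere survives
  v10 <- matrix(NA_real_, 2, 10)
  v10[1, ] <- 1
  v10[2, 1:2] <- 1
  m10 <- tiny_matrix(v10)
  kept <- filter_by_presence(m10, preprocess_config())
  expect_equal(protein_ids(kept), c("P01", "P02"))
  # 6/31 ~ 0.194 < 0.20 removed; planted counts {31, 7, 6, 0} -> 2 survive
  counts <- c(31, 7, 6, 0)
  v31 <- matrix(NA_real_, 4, 31)
  for (i in seq_along(counts)) if (counts[i] > 0) v31[i, seq_len(counts[i])] <- 1
  m31 <- tiny_matrix(v31)
  kept31 <- filter_by_presence(m31, preprocess_config())
  expect_equal(protein_ids(kept31), c("P01", "P02"))
  # idempotent, order-preserving, and survivors/removed partition correctly
  expect_identical(filter_by_presence(kept31, preprocess_config())$values,
                   kept31$values)
  frac <- rowSums(!is.na(v31)) / 31
  expect_true(all(frac[rownames(v31) %in% protein_ids(kept31)] >= 0.2))
})

test_that("log transform and median centring behave as stated", {
  m <- tiny_matrix(matrix(c(4, 16), 2, 1))
  out <- log_and_normalize(m, preprocess_config())
  expect_equal(unname(out$values[, 1]), c(-1, 1))
  expect_true(out$log_transformed)
  # per-column median of present values is 0 after the op, any input
  set.seed(42)
  v <- matrix(2^rnorm(60, 10, 2), 10, 6)
  v[sample(60, 12)] <- NA
  out2 <- log_and_normalize(tiny_matrix(v), preprocess_config())
  meds <- apply(out2$values, 2, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(0, 6))
  # back-transform recovers input when normalization = none
  cfg_none <- preprocess_config(normalization = "none")
  out3 <- log_and_normalize(tiny_matrix(v), cfg_none)
  expect_equal(2^out3$values, tiny_matrix(v)$values)
  # degenerate and invalid inputs
  v_allmiss <- matrix(c(1, NA, 2, NA), 2, 2,
                      dimnames = list(c("A", "B"), c("S1", "S2")))
  v_allmiss[, 2] <- NA
  expect_warning(log_and_normalize(abundance_matrix(v_allmiss),
                                   preprocess_config()), "all-missing")
  expect_error(log_and_normalize(tiny_matrix(matrix(c(0, 1), 1, 2)),
                                 preprocess_config()), "> 0")
  expect_error(log_and_normalize(out, preprocess_config()), "already log")
})

test_that("downshifted-normal imputation matches its stated distribution", {
  # identity on complete matrices; determinism under fixed seed
  cfg <- preprocess_config(seed = 9)
  complete <- tiny_matrix(matrix(rnorm(20), 4, 5), log_transformed = TRUE)
  expect_identical(impute_missing(complete, cfg)$values, complete$values)
  set.seed(1)
  v <- matrix(rnorm(4000, 20, 2), 2000, 2)
  v[sample(2000, 800), 1] <- NA
  m <- tiny_matrix(v, log_transformed = TRUE)
  a <- impute_missing(m, cfg)
  b <- impute_missing(m, cfg)
  expect_identical(a$values, b$values)
  # present values never altered
  pres <- !is.na(v)
  expect_identical(a$values[pres], v[pres])
  # imputed mean within 3 SE of column mean - 1.8 * column SD (width 0.3)
  mu <- mean(v[pres[, 1], 1])
  s <- sd(v[pres[, 1], 1])
  imp <- a$values[!pres[, 1], 1]
  se <- 0.3 * s / sqrt(length(imp))
  expect_lt(abs(mean(imp) - (mu - 1.8 * s)), 3 * se)
  # column with <2 present values falls back to global stats with warning
  v2 <- matrix(rnorm(20), 4, 5,
               dimnames = list(paste0("P", 1:4), paste0("S", 1:5)))
  v2[2:4, 1] <- NA
  expect_warning(impute_missing(abundance_matrix(v2, TRUE), cfg), "global")
})

test_that("PCA embedding reflects planted group structure", {
  means <- cbind(IUP = c(8, 8, 2), PUC = c(8, 8, 2), NU = c(2, 2, 8))
  rownames(means) <- c("A", "B", "C")
  d <- grouped_matrix(means, noise_sd = 0.05, seed = 3)
  emb <- pca_embed(d$m, 2)
  expect_true(all(diff(emb$explained_variance) <= 1e-12))
  expect_lte(sum(emb$explained_variance), 1 + 1e-12)
  xy <- as.matrix(emb$coordinates[, c("PC1", "PC2")])
  grp <- d$metadata$group
  pair_dist <- function(a, b) {
    mean(as.matrix(dist(xy))[grp == a, grp == b])
  }
  # IUP planted closer to PUC than to NU
  expect_lt(pair_dist("IUP", "PUC"), pair_dist("IUP", "NU"))
  # identical samples map to identical coordinates
  v <- matrix(c(1, 2, 1, 2, 5, 9), 2, 3,
              dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  emb2 <- pca_embed(abundance_matrix(v, TRUE), 1)
  expect_equal(emb2$coordinates$PC1[1], emb2$coordinates$PC1[2])
  # distances invariant to protein reordering
  shuf <- abundance_matrix(d$m$values[sample(nrow(d$m$values)), ], TRUE)
  emb3 <- pca_embed(shuf, 2)
  d_orig <- dist(xy)
  d_shuf <- dist(as.matrix(emb3$coordinates[, c("PC1", "PC2")]))
  expect_equal(as.vector(d_shuf), as.vector(d_orig), tolerance = 1e-8)
  # missing values rejected
  v[1, 1] <- NA
  expect_error(pca_embed(abundance_matrix(v, TRUE)), "complete")
})
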