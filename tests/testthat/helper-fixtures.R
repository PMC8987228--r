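# Shared fixtures, built in code at test time.

# Tiny abundance matrix with explicit values; proteins x samples.
tiny_matrix <- function(values, log_transformed = FALSE,
                        proteins = sprintf("P%02d", seq_len(nrow(values))),
                        samples = sprintf("S%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(proteins, samples)
  abundance_matrix(values, log_transformed)
}

# Three-group matrix with per-protein group means and iid normal noise,
# on the log2 scale. means: proteins x 3 matrix (IUP, PUC, NU).
grouped_matrix <- function(means, n_per_group = c(IUP = 4, PUC = 4, NU = 4),
                           noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  groups <- rep(names(n_per_group), n_per_group)
  vals <- means[, match(groups, colnames(means)), drop = FALSE] +
    matrix(rnorm(nrow(means) * length(groups), 0, noise_sd),
           nrow(means), length(groups))
  colnames(vals) <- paste0(groups, "_", unlist(lapply(n_per_group, seq_len)))
  rownames(vals) <- rownames(means)
  list(m = abundance_matrix(vals, log_transformed = TRUE),
       metadata = data.frame(sample_id = colnames(vals), group = groups,
                             stringsAsFactors = FALSE))
}

# Preprocess chain used by recovery tests.
preprocess_chain <- function(m, seed = 1) {
  cfg <- preprocess_config(seed = seed)
  impute_missing(log_and_normalize(filter_by_presence(m, cfg), cfg), cfg)
}

# 50-feature two-class fixture with two perfectly separating planted
# features (3-SD shift, informative-feature noise redrawn until each
# feature separates the classes with a clear margin).
separable_fixture <- function(seed, n1 = 9, n2 = 12, n_features = 50,
                              effect = 3, min_gap = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n1 + n2) * n_features), n1 + n2, n_features)
  for (j in 1:2) {
    repeat {
      x <- rnorm(n1 + n2)
      x[seq_len(n1)] <- x[seq_len(n1)] + effect
      if (min(x[seq_len(n1)]) - max(x[-seq_len(n1)]) >= min_gap) {
        X[, j] <- x
        break
      }
    }
  }
  colnames(X) <- sprintf("F%02d", seq_len(n_features))
  rownames(X) <- sprintf("S%02d", seq_len(n1 + n2))
  list(m = abundance_matrix(t(X), log_transformed = TRUE),
       metadata = data.frame(sample_id = rownames(X),
                             group = rep(c("IUP", "PUC"), c(n1, n2)),
                             stringsAsFactors = FALSE))
}

# Write a small abundance TSV and return its path.
write_abundance_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
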