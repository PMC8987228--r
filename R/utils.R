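## Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package functions never perturb the user's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Row variances with missing-value support
#'
#' Unbiased per-row variance over present values; rows with fewer than two
#' present values get NA.
#' @noRd
row_group_stats <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  m[n == 0] <- NA_real_
  ss <- rowSums(x * x, na.rm = TRUE)
  v <- (ss - n * m * m) / (n - 1)
  v[n < 2] <- NA_real_
  # numerical floor: tiny negative values from cancellation
  v <- pmax(v, 0)
  list(n = n, mean = m, var = v)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Validate a sample metadata data frame against a matrix
#' @noRd
check_metadata <- function(m, metadata) {
  if (!is.data.frame(metadata) ||
      !all(c("sample_id", "group") %in% names(metadata))) {
    stopf("metadata must be a data.frame with columns 'sample_id' and 'group'")
  }
  if (anyDuplicated(metadata$sample_id)) {
    stopf("duplicated sample_id in metadata")
  }
  missing <- setdiff(sample_ids(m), metadata$sample_id)
  if (length(missing)) {
    stopf("samples missing from metadata: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Columns of an abundance matrix belonging to one group
#' @noRd
group_columns <- function(m, metadata, group) {
  ids <- metadata$sample_id[metadata$group == group]
  idx <- which(sample_ids(m) %in% ids)
  idx
}
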