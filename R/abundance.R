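## Data model and preprocessing for label-free protein abundance matrices.
##
## The central container is `abundance_matrix`: a proteins x samples numeric
## matrix of iBAQ-style intensities with NA marking non-detection, plus a flag
## recording whether values are on the log2 scale. Preprocessing follows the
## usual label-free workflow: presence filtering, log2 transformation,
## per-sample median centring, and downshifted-normal imputation of missing
## values, followed by PCA embedding of the samples.

#' Construct an abundance matrix
#'
#' Wraps a proteins-by-samples numeric matrix of label-free protein
#' intensities. Missing (not-detected) values are `NA`. Row names are protein
#' identifiers (gene symbols), column names are sample identifiers; both must
#' be unique.
#'
#' @param values Numeric matrix, proteins in rows, samples in columns, with
#'   `NA` for missing values. Must have unique, non-empty dimnames.
#' @param log_transformed Logical; `TRUE` once values are on the log2 scale
#'   (negative values allowed), `FALSE` for raw intensities (values must be
#'   non-negative).
#' @return An object of class `"abundance_matrix"`.
#' @export
abundance_matrix <- function(values, log_transformed = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("values must have protein row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    stopf("duplicate protein identifiers: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stopf("duplicate sample identifiers")
  }
  present <- values[!is.na(values)]
  if (any(!is.finite(present))) stopf("present values must be finite")
  if (!log_transformed && length(present) && any(present < 0)) {
    stopf("raw intensities must be non-negative")
  }
  structure(
    list(values = values, log_transformed = isTRUE(log_transformed)),
    class = "abundance_matrix"
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "abundance_matrix: %d proteins x %d samples (%s scale, %.1f%% missing)\n",
    nrow(v), ncol(v),
    if (x$log_transformed) "log2" else "raw",
    100 * mean(is.na(v))
  ))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Protein identifiers of an abundance matrix
#' @param m An `abundance_matrix`.
#' @return Character vector of protein ids.
#' @export
protein_ids <- function(m) rownames(m$values)

#' Sample identifiers of an abundance matrix
#' @param m An `abundance_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(m) colnames(m$values)

#' Preprocessing configuration
#'
#' Bundles the tunable preprocessing choices: the presence threshold (a
#' protein is kept when detected in at least this fraction of samples), the
#' normalization and imputation methods, and the downshifted-normal
#' parameters. The imputation draws replacements for missing values from a
#' normal distribution centred `impute_downshift` sample standard deviations
#' below the per-sample mean with standard deviation `impute_width` times the
#' sample standard deviation — the convention for left-censored label-free
#' data, where low-abundance proteins drop out preferentially.
#'
#' @param min_presence_fraction Fraction in (0, 1]; default 0.20.
#' @param log_base Logarithm base for transformation (fixed at 2).
#' @param normalization `"median-center"` (default) or `"none"`.
#' @param imputation `"downshifted-normal"` (default) or `"none"`.
#' @param impute_width Positive scale factor for the imputation SD
#'   (default 0.3).
#' @param impute_downshift Downshift in units of the per-sample SD
#'   (default 1.8).
#' @param seed Integer seed for the imputation RNG.
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(min_presence_fraction = 0.20,
                              log_base = 2,
                              normalization = c("median-center", "none"),
                              imputation = c("downshifted-normal", "none"),
                              impute_width = 0.3,
                              impute_downshift = 1.8,
                              seed = 1L) {
  normalization <- match.arg(normalization)
  imputation <- match.arg(imputation)
  if (!is.numeric(min_presence_fraction) ||
      min_presence_fraction <= 0 || min_presence_fraction > 1) {
    stopf("min_presence_fraction must be in (0, 1]")
  }
  if (log_base != 2) stopf("only log base 2 is supported")
  if (!is.numeric(impute_width) || impute_width <= 0) {
    stopf("impute_width must be > 0")
  }
  structure(
    list(min_presence_fraction = min_presence_fraction,
         log_base = log_base,
         normalization = normalization,
         imputation = imputation,
         impute_width = impute_width,
         impute_downshift = impute_downshift,
         seed = as.integer(seed)),
    class = "preprocess_config"
  )
}

#' Read a protein abundance table
#'
#' Reads a tab-delimited abundance table: first column protein identifiers,
#' remaining columns one per sample, header row of sample ids. Cells matching
#' any of `missing_tokens` become `NA` (MaxQuant-style exports encode
#' non-detection variously as empty cells, `NaN`, or `0`).
#'
#' @param path Path to a TSV file.
#' @param missing_tokens Character vector of cell values to treat as missing.
#' @return An `abundance_matrix` (raw scale).
#' @export
read_abundance_table <- function(path,
                                 missing_tokens = c("", "NA", "NaN", "0")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stopf("parse error: %s has no data rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  if (width < 2) stopf("parse error: header must name at least one sample")
  bad <- which(lengths(fields) != width)
  if (length(bad)) {
    stopf("parse error: ragged row at line %d of %s", bad[1], path)
  }
  header <- fields[[1]]
  samples <- header[-1]
  body <- fields[-1]
  proteins <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(proteins)) {
    stopf("duplicate protein identifiers in %s: %s", path,
          paste(unique(proteins[duplicated(proteins)]), collapse = ", "))
  }
  cells <- t(vapply(body, function(f) f[-1], character(width - 1)))
  if (ncol(cells) != length(samples)) cells <- matrix(cells, ncol = length(samples))
  cells[cells %in% missing_tokens] <- NA_character_
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = length(proteins),
                                  dimnames = list(proteins, samples)))
  unparsed <- !is.na(cells) & is.na(vals)
  if (any(unparsed)) {
    ij <- which(unparsed, arr.ind = TRUE)[1, ]
    stopf("parse error: non-numeric cell at data row %d, column '%s'",
          ij[1], samples[ij[2]])
  }
  abundance_matrix(vals, log_transformed = FALSE)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id` and `group`; groups are typically
#'   `IUP`, `PUC`, `NU`.
#' @return A data.frame with columns `sample_id`, `group`.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(md))) {
    stopf("metadata must have columns 'sample_id' and 'group'")
  }
  if (anyDuplicated(md$sample_id)) stopf("duplicated sample_id in %s", path)
  md[c("sample_id", "group")]
}

#' Filter proteins by detection presence
#'
#' Retains proteins detected (non-missing) in at least
#' `min_presence_fraction` of samples. The comparison is inclusive on the
#' exact fraction: a protein present in 2 of 10 samples survives a 0.20
#' threshold. Idempotent and order-preserving.
#'
#' @param m An `abundance_matrix`.
#' @param cfg A [preprocess_config()].
#' @return The filtered `abundance_matrix`.
#' @export
filter_by_presence <- function(m, cfg = preprocess_config()) {
  stopifnot(inherits(m, "abundance_matrix"))
  v <- m$values
  if (nrow(v) == 0 || ncol(v) == 0) stopf("empty abundance matrix")
  frac <- rowSums(!is.na(v)) / ncol(v)
  keep <- frac >= cfg$min_presence_fraction
  abundance_matrix(v[keep, , drop = FALSE], m$log_transformed)
}

#' Log2-transform and normalize
#'
#' Replaces intensities by their log2 and, under `"median-center"`
#' normalization, subtracts each sample column's median of present values so
#' every column's median becomes zero. The missingness pattern is unchanged.
#'
#' @param m A raw-scale `abundance_matrix` with strictly positive present
#'   values.
#' @param cfg A [preprocess_config()].
#' @return A log2-scale `abundance_matrix`.
#' @export
log_and_normalize <- function(m, cfg = preprocess_config()) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (m$log_transformed) stopf("matrix is already log transformed")
  v <- m$values
  if (any(v[!is.na(v)] <= 0)) {
    stopf("all present values must be > 0 before log transformation")
  }
  lv <- log2(v)
  if (cfg$normalization == "median-center") {
    med <- apply(lv, 2, stats::median, na.rm = TRUE)
    empty <- !is.finite(med)
    if (any(empty)) {
      warnf("all-missing sample column(s) left unchanged: %s",
            paste(colnames(lv)[empty], collapse = ", "))
      med[empty] <- 0
    }
    lv <- sweep(lv, 2, med, `-`)
  }
  abundance_matrix(lv, log_transformed = TRUE)
}

#' Impute missing values from a downshifted normal
#'
#' Replaces each missing value by a draw from
#' `N(mean_s - downshift * sd_s, (width * sd_s)^2)` where `mean_s` and `sd_s`
#' are the per-sample-column statistics of present values. This emulates the
#' left-censored (missing-not-at-random) character of label-free proteomics:
#' absent proteins are assumed to sit below the detection limit. Columns with
#' fewer than two present values fall back to the global mean/SD with a
#' warning. Present values are never altered; results are reproducible under
#' `cfg$seed`.
#'
#' @param m A log2-scale `abundance_matrix`.
#' @param cfg A [preprocess_config()].
#' @return A complete `abundance_matrix`.
#' @export
impute_missing <- function(m, cfg = preprocess_config()) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (!m$log_transformed) stopf("impute_missing expects a log2-scale matrix")
  if (cfg$imputation == "none") return(m)
  v <- m$values
  if (!anyNA(v)) return(m)
  gmean <- mean(v, na.rm = TRUE)
  gsd <- stats::sd(v[!is.na(v)])
  if (!is.finite(gsd) || gsd == 0) gsd <- 1
  with_seed(cfg$seed, {
    for (j in seq_len(ncol(v))) {
      miss <- is.na(v[, j])
      if (!any(miss)) next
      pres <- v[!miss, j]
      if (length(pres) >= 2 && stats::sd(pres) > 0) {
        mu <- mean(pres)
        s <- stats::sd(pres)
      } else {
        warnf("column '%s' has <2 present values; using global statistics",
              colnames(v)[j])
        mu <- gmean
        s <- gsd
      }
      v[miss, j] <- stats::rnorm(sum(miss),
                                 mean = mu - cfg$impute_downshift * s,
                                 sd = cfg$impute_width * s)
    }
  })
  abundance_matrix(v, log_transformed = TRUE)
}

#' PCA embedding of samples
#'
#' Principal component analysis of the samples (proteins as variables,
#' centred, unscaled), as used to visualise the relative positions of the
#' IUP, PUC and NU proteomes.
#'
#' @param m A complete (imputed) `abundance_matrix` with at least 2 samples.
#' @param n_components Number of components to return.
#' @return A list with `coordinates` (data.frame: `sample_id` plus `PC1`,
#'   `PC2`, ...) and `explained_variance` (non-increasing fractions summing
#'   to at most 1).
#' @export
pca_embed <- function(m, n_components = 2) {
  stopifnot(inherits(m, "abundance_matrix"))
  v <- m$values
  if (anyNA(v)) stopf("pca_embed requires a complete matrix; impute first")
  if (ncol(v) < 2) stopf("need at least 2 samples")
  n_components <- min(n_components, ncol(v) - 1, nrow(v))
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- as.data.frame(pc$x[, seq_len(n_components), drop = FALSE])
  coords <- cbind(sample_id = colnames(v), coords)
  rownames(coords) <- NULL
  list(coordinates = coords,
       explained_variance = ev[seq_len(n_components)])
}
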