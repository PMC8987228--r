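## Human Protein Atlas immunoscore concordance screen.
##
## The immunoscore weights antibody staining intensity levels (high = 4,
## medium = 3, low = 2, not detected = 1) by the proportion of stained
## samples at each level and averages over antibodies; a candidate whose
## atlas profile says "overexpressed in urothelial carcinoma" while the
## proteomics says "down in carcinoma relative to IUP" is discordant and is
## excluded.

#' Read antibody staining profiles
#'
#' @param path TSV with columns `protein`, `antibody`, `tissue`, `p_high`,
#'   `p_medium`, `p_low`, `p_not_detected`.
#' @return Data.frame of staining profiles.
#' @export
read_staining_profiles <- function(path) {
  pr <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "antibody", "p_high", "p_medium", "p_low",
            "p_not_detected")
  if (!all(need %in% names(pr))) {
    stopf("profile table must have columns: %s", paste(need, collapse = ", "))
  }
  pr
}

#' Antibody-staining immunoscore
#'
#' Per antibody: `4*p_high + 3*p_medium + 2*p_low + 1*p_not_detected`; per
#' protein: the arithmetic mean over its antibodies. A convex combination of
#' {1,2,3,4}, so always in [1, 4].
#'
#' @param profiles Data.frame with columns `protein`, `antibody`, `p_high`,
#'   `p_medium`, `p_low`, `p_not_detected`; each row's proportions must sum
#'   to 1.
#' @return Data.frame with columns `protein`, `n_antibodies`, `immunoscore`.
#' @export
immunoscore <- function(profiles) {
  need <- c("protein", "p_high", "p_medium", "p_low", "p_not_detected")
  if (!is.data.frame(profiles) || !all(need %in% names(profiles))) {
    stopf("profiles must contain columns: %s", paste(need, collapse = ", "))
  }
  if (!nrow(profiles)) stopf("need at least one staining profile")
  p <- as.matrix(profiles[c("p_high", "p_medium", "p_low", "p_not_detected")])
  if (any(p < 0 | p > 1)) stopf("staining proportions must be in [0, 1]")
  tot <- rowSums(p)
  if (any(abs(tot - 1) > 1e-9)) {
    stopf("staining proportions must sum to 1 (row %d sums to %.6f)",
          which(abs(tot - 1) > 1e-9)[1], tot[abs(tot - 1) > 1e-9][1])
  }
  score <- drop(p %*% c(4, 3, 2, 1))
  agg <- stats::aggregate(score,
                          by = list(protein = profiles$protein),
                          FUN = mean)
  cnt <- as.data.frame(table(profiles$protein), stringsAsFactors = FALSE)
  out <- data.frame(protein = agg$protein,
                    n_antibodies = cnt$Freq[match(agg$protein, cnt$Var1)],
                    immunoscore = agg$x,
                    stringsAsFactors = FALSE)
  out[order(out$protein), , drop = FALSE]
}

#' Concordance screen against public-atlas expression
#'
#' Excludes a candidate when the atlas calls it relatively overexpressed in
#' urothelial carcinoma (immunoscore at or above `cutoff`) while the
#' proteomics found it *down* in carcinoma — i.e. a positive log2 fold
#' change under the convention positive = higher in IUP. Candidates with a
#' missing score or fold change are flagged `unscreenable` and retained with
#' a warning.
#'
#' @param candidates Character vector of candidate proteins.
#' @param scores [immunoscore()] output (or any data.frame with `protein`,
#'   `immunoscore`).
#' @param fc [fold_change()] output for IUP vs PUC (`protein`, `log2_fc`).
#' @param cutoff Immunoscore at or above which the atlas expression counts
#'   as high (default 2.5, the scale midpoint).
#' @return Data.frame with columns `protein`, `immunoscore`, `log2_fc`,
#'   `verdict`, `retained`.
#' @export
concordance_filter <- function(candidates, scores, fc, cutoff = 2.5) {
  sc <- scores$immunoscore[match(candidates, scores$protein)]
  lfc <- fc$log2_fc[match(candidates, fc$protein)]
  unscreenable <- is.na(sc) | is.na(lfc)
  if (any(unscreenable)) {
    warnf("no immunoscore or fold change for: %s (retained unscreened)",
          paste(candidates[unscreenable], collapse = ", "))
  }
  discordant <- !unscreenable & sc >= cutoff & lfc > 0
  verdict <- rep("retained (concordant)", length(candidates))
  verdict[discordant] <-
    "excluded (atlas-high in carcinoma, proteomics down in PUC)"
  verdict[unscreenable] <- "unscreenable"
  data.frame(protein = candidates,
             immunoscore = sc,
             log2_fc = lfc,
             verdict = verdict,
             retained = !discordant,
             stringsAsFactors = FALSE)
}
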