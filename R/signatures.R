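## Partition of ANOVA-significant proteins into IUP signature classes.
##
## A protein is 'NU-like' when IUP is statistically indistinguishable from
## normal urothelium but differs from carcinoma, and 'PUC-like' in the
## reverse pattern; up/down records whether IUP sits above or below the
## dissimilar group. The partition operationalises the similarity structure
## with post-hoc two-group permutation tests sharing the ANOVA's permutation
## machinery and FDR level.

SIGNATURE_CLASSES <- c("NU_like_up", "NU_like_down",
                       "PUC_like_up", "PUC_like_down", "unassigned")

#' Assign signature classes to ANOVA-significant proteins
#'
#' For each protein significant in the three-group ANOVA, runs post-hoc
#' permutation t-tests IUP-vs-NU and IUP-vs-PUC. A protein is
#' `NU_like_*` when IUP-vs-NU is non-significant and IUP-vs-PUC is
#' significant (IUP resembles normal tissue), `PUC_like_*` in the reverse
#' case; the `up`/`down` suffix is the sign of `mean(IUP) - mean(dissimilar
#' group)`. Proteins matching neither pattern, and non-significant ANOVA
#' proteins, are `unassigned`.
#'
#' @param anova Result of [permutation_anova()] on the same matrix.
#' @param m The complete log2 `abundance_matrix` the ANOVA was run on.
#' @param metadata Sample metadata with groups IUP, PUC, NU.
#' @param cfg [permutation_config()] for the post-hoc tests.
#' @param groups Named character vector mapping the roles `iup`, `puc`, `nu`
#'   to the labels used in `metadata`.
#' @return Data.frame with columns `protein`, `class`, `mean_IUP`,
#'   `mean_PUC`, `mean_NU`, `q_IUP_vs_NU`, `q_IUP_vs_PUC`.
#' @export
assign_signatures <- function(anova, m, metadata,
                              cfg = permutation_config(),
                              groups = c(iup = "IUP", puc = "PUC", nu = "NU")) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (!setequal(anova$protein, protein_ids(m))) {
    stopf("ANOVA results and matrix cover different proteins")
  }
  check_metadata(m, metadata)
  mi <- group_columns(m, metadata, groups[["iup"]])
  mp <- group_columns(m, metadata, groups[["puc"]])
  mn <- group_columns(m, metadata, groups[["nu"]])
  mean_iup <- rowMeans(m$values[, mi, drop = FALSE], na.rm = TRUE)
  mean_puc <- rowMeans(m$values[, mp, drop = FALSE], na.rm = TRUE)
  mean_nu <- rowMeans(m$values[, mn, drop = FALSE], na.rm = TRUE)

  sig <- anova$protein[anova$significant]
  cls <- rep("unassigned", nrow(anova))
  names(cls) <- anova$protein
  q_in <- q_ip <- rep(NA_real_, nrow(anova))
  names(q_in) <- names(q_ip) <- anova$protein

  if (length(sig)) {
    # pairwise tests run genome-wide (matching how the t-test surface is
    # used elsewhere) so their FDR is calibrated against the full
    # distribution, then restricted to the ANOVA-significant proteins
    t_in_all <- permutation_ttest(m, metadata, groups[["iup"]],
                                  groups[["nu"]], cfg)
    t_ip_all <- permutation_ttest(m, metadata, groups[["iup"]],
                                  groups[["puc"]], cfg)
    t_in <- t_in_all[match(sig, t_in_all$protein), ]
    t_ip <- t_ip_all[match(sig, t_ip_all$protein), ]
    q_in[sig] <- t_in$q_value
    q_ip[sig] <- t_ip$q_value
    nu_like <- !t_in$significant & t_ip$significant
    puc_like <- t_in$significant & !t_ip$significant
    d_puc <- mean_iup[sig] - mean_puc[sig] # dissimilar group for NU-like
    d_nu <- mean_iup[sig] - mean_nu[sig]   # dissimilar group for PUC-like
    lab <- rep("unassigned", length(sig))
    lab[nu_like & d_puc > 0] <- "NU_like_up"
    lab[nu_like & d_puc < 0] <- "NU_like_down"
    lab[puc_like & d_nu > 0] <- "PUC_like_up"
    lab[puc_like & d_nu < 0] <- "PUC_like_down"
    cls[sig] <- lab
  }

  data.frame(
    protein = anova$protein,
    class = factor(unname(cls), levels = SIGNATURE_CLASSES),
    mean_IUP = unname(mean_iup[anova$protein]),
    mean_PUC = unname(mean_puc[anova$protein]),
    mean_NU = unname(mean_nu[anova$protein]),
    q_IUP_vs_NU = unname(q_in),
    q_IUP_vs_PUC = unname(q_ip),
    stringsAsFactors = FALSE
  )
}

#' Top-ranked proteins of each signature class
#'
#' Within each class, proteins are ordered by ascending ANOVA q-value, ties
#' broken by descending |F| and then lexicographic protein id; the top `k`
#' (fewer if the class is smaller) are returned, mirroring the 40-protein
#' summaries of each signature.
#'
#' @param assignments Result of [assign_signatures()].
#' @param anova The matching [permutation_anova()] result.
#' @param k Number of proteins per class (default 40).
#' @return Named list of character vectors, one per non-`unassigned` class.
#' @export
rank_top_signatures <- function(assignments, anova, k = 40) {
  if (!is.numeric(k) || k < 1) stopf("k must be >= 1")
  key <- match(assignments$protein, anova$protein)
  if (anyNA(key)) stopf("assignments and ANOVA results do not match")
  q <- anova$q_value[key]
  f <- abs(anova$statistic[key])
  classes <- setdiff(SIGNATURE_CLASSES, "unassigned")
  out <- lapply(classes, function(cl) {
    i <- which(assignments$class == cl)
    i <- i[order(q[i], -f[i], assignments$protein[i])]
    utils::head(assignments$protein[i], k)
  })
  names(out) <- classes
  out
}
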