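## End-to-end orchestration of the discovery workflow:
## preprocess -> ANOVA + pairwise t-test -> signature partition -> SVM-RFE
## panel -> FDR/ML shortlist -> HPA concordance screen -> optional IHC and
## survival validation, with per-stage TSV outputs and a run log.

#' Pipeline run configuration
#'
#' @param abundance `abundance_matrix` or path to an abundance TSV.
#' @param metadata Metadata data.frame or path to a metadata TSV.
#' @param preprocess A [preprocess_config()].
#' @param perm A [permutation_config()].
#' @param groups Named vector mapping roles `iup`, `puc`, `nu` to labels.
#' @param cv_folds Cross-validation folds for feature selection.
#' @param shortlist_k Shortlist size (default 5).
#' @param hpa_profiles Optional staining profiles (data.frame or TSV path).
#' @param hpa_cutoff Immunoscore high-expression cutoff.
#' @param ihc_cells Optional per-cell detection table (data.frame or CSV
#'   path).
#' @param ihc_positive Diagnosis label treated as positive in IHC stats.
#' @param survival_cohort Optional survival cohort (data.frame or TSV path).
#' @param survival_genes Genes to screen in the survival cohort; defaults to
#'   all expression columns.
#' @param top_k Per-class signature list size.
#' @param out_dir Optional output directory for stage TSVs and the run log.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(abundance, metadata,
                       preprocess = preprocess_config(),
                       perm = permutation_config(),
                       groups = c(iup = "IUP", puc = "PUC", nu = "NU"),
                       cv_folds = 5,
                       shortlist_k = 5,
                       hpa_profiles = NULL,
                       hpa_cutoff = 2.5,
                       ihc_cells = NULL,
                       ihc_positive = "IUP",
                       survival_cohort = NULL,
                       survival_genes = NULL,
                       top_k = 40,
                       out_dir = NULL) {
  for (p in Filter(is.character, list(abundance, metadata, hpa_profiles,
                                      ihc_cells, survival_cohort))) {
    if (!file.exists(p)) stopf("input file not found: %s", p)
  }
  structure(as.list(environment()), class = "run_config")
}

write_stage <- function(x, name, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(x, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes every stage in order and returns all intermediate results plus
#' the final candidate list with its audit trail. Any stage failure aborts
#' with the stage name; outputs written so far are retained.
#'
#' @param cfg A [run_config()].
#' @return List of class `"pipeline_result"` with elements `preprocessed`,
#'   `pca`, `anova`, `ttest`, `signatures`, `top_signatures`, `ranking`,
#'   `panel`, `shortlist`, `screen`, `candidates`, and (when inputs were
#'   supplied) `ihc`, `survival`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  m <- if (is.character(cfg$abundance)) {
    read_abundance_table(cfg$abundance)
  } else cfg$abundance
  md <- if (is.character(cfg$metadata)) {
    read_sample_metadata(cfg$metadata)
  } else cfg$metadata

  ## 1. preprocess
  prep <- stage("preprocess", {
    f <- filter_by_presence(m, cfg$preprocess)
    l <- log_and_normalize(f, cfg$preprocess)
    impute_missing(l, cfg$preprocess)
  })
  pca <- stage("pca", pca_embed(prep, 2))
  write_stage(pca$coordinates, "pca", cfg$out_dir)

  ## 2. differential expression
  anova <- stage("anova", permutation_anova(prep, md, cfg$perm))
  ttest <- stage("ttest", permutation_ttest(
    prep, md, cfg$groups[["iup"]], cfg$groups[["puc"]], cfg$perm))
  write_stage(anova, "anova", cfg$out_dir)
  write_stage(ttest, "ttest_IUP_vs_PUC", cfg$out_dir)

  ## 3. signature partition
  sigs <- stage("signatures",
                assign_signatures(anova, prep, md, cfg$perm, cfg$groups))
  top_sigs <- stage("signatures", rank_top_signatures(sigs, anova, cfg$top_k))
  write_stage(sigs, "signatures", cfg$out_dir)

  ## 4. feature selection + shortlist
  ranking <- stage("feature_selection", svm_rfe_rank(
    prep, md, cfg$groups[["iup"]], cfg$groups[["puc"]],
    cv_folds = cfg$cv_folds, seed = cfg$perm$seed))
  panel <- choose_panel(ranking)
  shortlist <- stage("shortlist",
                     shortlist_candidates(ranking, ttest, cfg$shortlist_k))
  write_stage(ranking$error_curve, "error_curve", cfg$out_dir)
  write_stage(data.frame(protein = ranking$ordered_proteins,
                         ml_rank = seq_along(ranking$ordered_proteins),
                         panel_member = ranking$ordered_proteins %in% panel),
              "ranking", cfg$out_dir)

  ## 5. HPA concordance screen
  screen <- NULL
  candidates <- shortlist
  if (!is.null(cfg$hpa_profiles)) {
    profiles <- if (is.character(cfg$hpa_profiles)) {
      read_staining_profiles(cfg$hpa_profiles)
    } else cfg$hpa_profiles
    screen <- stage("hpa_screen", {
      sc <- immunoscore(profiles)
      fc <- fold_change(prep, md, cfg$groups[["iup"]], cfg$groups[["puc"]])
      concordance_filter(shortlist, sc, fc, cfg$hpa_cutoff)
    })
    candidates <- screen$protein[screen$retained]
    write_stage(screen, "hpa_screen", cfg$out_dir)
  }

  ## 6. optional IHC validation
  ihc <- NULL
  if (!is.null(cfg$ihc_cells)) {
    cells <- if (is.character(cfg$ihc_cells)) {
      read_cell_detections(cfg$ihc_cells)
    } else cfg$ihc_cells
    ihc <- stage("ihc_validation",
                 ihc_diagnostic_report(cells, cfg$ihc_positive))
    write_stage(ihc$h_scores, "h_scores", cfg$out_dir)
  }

  ## 7. optional survival screen
  surv <- NULL
  if (!is.null(cfg$survival_cohort)) {
    cohort <- if (is.character(cfg$survival_cohort)) {
      utils::read.delim(cfg$survival_cohort, stringsAsFactors = FALSE)
    } else cfg$survival_cohort
    genes <- cfg$survival_genes
    if (is.null(genes)) {
      genes <- setdiff(names(cohort), c("patient_id", "time", "event"))
    }
    surv <- stage("survival_screen",
                  do.call(rbind, lapply(genes, cox_univariate,
                                        cohort = cohort)))
    write_stage(surv, "cox_univariate", cfg$out_dir)
  }

  res <- structure(
    list(preprocessed = prep, pca = pca, anova = anova, ttest = ttest,
         signatures = sigs, top_signatures = top_sigs, ranking = ranking,
         panel = panel, shortlist = shortlist, screen = screen,
         candidates = candidates, ihc = ihc, survival = surv,
         config = cfg),
    class = "pipeline_result"
  )
  if (!is.null(cfg$out_dir)) {
    log <- c(
      sprintf("invpap %s", as.character(utils::packageVersion("invpap"))),
      sprintf("seed: %d", cfg$perm$seed),
      sprintf("n_permutations: %d", cfg$perm$n_permutations),
      sprintf("fdr_level: %g", cfg$perm$fdr_level),
      sprintf("min_presence_fraction: %g",
              cfg$preprocess$min_presence_fraction),
      sprintf("proteins_after_filter: %d", nrow(prep$values)),
      sprintf("deps_anova: %d", sum(anova$significant)),
      sprintf("panel_size: %d", ranking$chosen_panel_size),
      sprintf("final_candidates: %s", paste(candidates, collapse = ", "))
    )
    writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("invpap pipeline result\n")
  cat(sprintf("  proteins analysed: %d\n", nrow(x$preprocessed$values)))
  cat(sprintf("  ANOVA DEPs (q < %g): %d\n",
              x$config$perm$fdr_level, sum(x$anova$significant)))
  cat(sprintf("  signature classes: %s\n",
              paste(sprintf("%s=%d", names(x$top_signatures),
                            vapply(x$top_signatures, length, 1L)),
                    collapse = " ")))
  cat(sprintf("  SVM panel: %d proteins (CV error %.3g)\n",
              length(x$panel), min(x$ranking$error_curve$cv_error)))
  cat(sprintf("  shortlist: %s\n", paste(x$shortlist, collapse = ", ")))
  cat(sprintf("  final candidates: %s\n",
              paste(x$candidates, collapse = ", ")))
  invisible(x)
}
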