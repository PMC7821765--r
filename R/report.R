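#' Run the full pipeline and assemble a report
#'
#' Convenience driver: filters the raw variant pool through the cascade,
#' classes the survivors, and assembles every summary table (filter trace,
#' class distribution, class-wise mean reference frequency, ACMG tier
#' distribution, molecular burden, HGMD carriers, functional categories,
#' clinical covariate tests) into one self-contained report object.
#'
#' @param cohort A `vt_cohort` whose variant table is the raw called pool.
#' @param control_ids Variant ids observed in the control arm.
#' @param category_map Named gene -> category vector (optional; category
#'   table skipped when absent).
#' @param curation_exclusions Curation exclusion id list (default none).
#' @param acmg_evidence Named list of per-variant ACMG code sets (optional).
#' @param maf_cutoff,dbs Passed to the cascade.
#' @param seed Recorded in metadata (the pipeline itself is deterministic).
#' @return Object of class `vt_report`: list of tables plus run metadata.
#' @export
build_report <- function(cohort, control_ids = character(),
                         category_map = NULL,
                         curation_exclusions = character(),
                         acmg_evidence = list(),
                         maf_cutoff = 0.005, dbs = REMOVAL_DBS_DEFAULT,
                         seed = NA_integer_) {
  if (!inherits(cohort, "vt_cohort")) {
    vt_stop("vt_assembly_error", "missing stage output: cohort")
  }
  casc <- run_cascade(cohort$variants, control_ids, curation_exclusions,
                      maf_cutoff, dbs)
  classified <- classify_variants(casc$kept)
  classified <- acmg_classify(classified, acmg_evidence)
  # burden statistics run on carriage of analysis-set variants only
  geno_analysis <- cohort$genotypes[
    cohort$genotypes$variant_id %in% classified$variant_id, , drop = FALSE]
  cohort_analysis <- cohort
  cohort_analysis$genotypes <- geno_analysis

  clin <- clinical_tests(cohort$patients)

  rep <- list(
    meta = list(seed = seed, maf_cutoff = maf_cutoff, dbs = dbs,
                n_patients = nrow(cohort$patients),
                package_version = as.character(utils::packageVersion("vtburden")),
                timestamp = NA),
    trace = casc$trace,
    classified = classified,
    class_distribution = class_distribution(classified),
    mean_maf = mean_maf_by_class(classified),
    acmg = acmg_distribution(classified$acmg_verdict),
    burden = burden_table(cohort_analysis, classified),
    hgmd = hgmd_carrier_table(cohort_analysis, classified),
    categories = if (!is.null(category_map))
      category_distribution(classified, category_map) else NULL,
    gene_frequency = gene_frequency_table(cohort_analysis, classified),
    clinical = clin
  )
  class(rep) <- "vt_report"
  rep
}

# Kruskal-Wallis across the three case arms for each quantitative covariate
clinical_tests <- function(patients) {
  cases <- patients[patients$subgroup %in% CASE_SUBGROUPS, , drop = FALSE]
  vars <- intersect(c("lvef", "la", "lv_edd", "lv_esd", "qrs", "qt"),
                    names(cases))
  out <- list()
  for (v in vars) {
    vals <- cases[[v]]
    tab <- table(cases$subgroup[!is.na(vals)])
    if (length(tab) < 2L || any(tab < 2L)) next
    out[[v]] <- kruskal_wallis_pairwise(vals, cases$subgroup, variable = v)
  }
  out
}

#' @export
print.vt_report <- function(x, ...) {
  cat("== Variant prioritization report ==\n\n")
  cat("Filtering cascade:\n")
  print(x$trace[, c("stage", "n_input", "n_removed", "n_kept")],
        row.names = FALSE)
  cat("\nConsensus class distribution (analysis set):\n")
  print(x$class_distribution, row.names = FALSE)
  cat("\nMean reference-db frequency by class:\n")
  print(signif(x$mean_maf, 3))
  cat("\nACMG five-tier distribution:\n")
  print(x$acmg, row.names = FALSE)
  cat("\nMolecular burden (per subgroup x class threshold):\n")
  print(x$burden, row.names = FALSE)
  cat("\nHGMD carriers:\n")
  print(x$hgmd$carriers, row.names = FALSE)
  if (!is.null(x$categories)) {
    cat("\nFunctional-category distribution (pooled unique variants):\n")
    print(x$categories, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.vt_report <- function(object, ...) {
  cat(sprintf("Analysis set: %d variants; %d patients; %d burden rows\n",
              nrow(object$classified), object$meta$n_patients,
              nrow(object$burden)))
  for (v in names(object$clinical)) {
    ct <- object$clinical[[v]]
    cat(sprintf("  %s: KW p = %s\n", v, format_pvalue(ct$p)))
  }
  invisible(object)
}

#' Write report tables to a directory
#'
#' Emits each table as TSV plus a `report.txt` rendering of the printed
#' report, so two runs with the same seed and config are byte-identical.
#'
#' @param x A `vt_report`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  tr <- x$trace; tr$removed_ids <- NULL
  wt(tr, "filter_trace")
  wt(x$class_distribution, "class_distribution")
  wt(x$acmg, "acmg_distribution")
  wt(x$burden, "burden")
  wt(x$hgmd$carriers, "hgmd_carriers")
  if (!is.null(x$categories)) wt(x$categories, "categories")
  wt(x$gene_frequency, "gene_frequency")
  con <- file(file.path(dir, "report.txt"), "w")
  sink(con); print(x); sink()
  close(con)
  invisible(dir)
}
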