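#' Flag common variants against reference databases
#'
#' A variant is common iff its allele frequency strictly exceeds
#' `maf_cutoff` in \emph{any} of the listed frequency databases, or it is a
#' dbSNP130 member when `"dbSNP130"` is listed. A variant absent from every
#' listed database is rare: absence can never exceed a cutoff. The
#' comparison is strict-greater, so removal of everything "above 0.5%"
#' coincides with keeping everything at \eqn{\le} 0.5%.
#'
#' @param variants A `vt_variants` table.
#' @param maf_cutoff Frequency cutoff in `(0, 1)`; default 0.005.
#' @param dbs Databases consulted; subset of
#'   `c("ESP6500", "1000G", "ExAC", "dbSNP130")`. ExAC is not consulted by
#'   default: it participates in frequency averaging, not removal.
#' @return List with elements `common` and `rare`, each a `vt_variants`
#'   table partitioning the input.
#' @export
flag_common <- function(variants, maf_cutoff = 0.005,
                        dbs = REMOVAL_DBS_DEFAULT) {
  stopifnot(maf_cutoff > 0, maf_cutoff < 1)
  known <- c(names(FREQ_DB_COLS), "dbSNP130")
  bad <- setdiff(dbs, known)
  if (length(bad) > 0 || length(dbs) == 0) {
    vt_stop("vt_config_error", "unknown or empty reference db set: %s",
            paste(bad, collapse = ", "))
  }
  is_common <- rep(FALSE, nrow(variants))
  for (db in intersect(dbs, names(FREQ_DB_COLS))) {
    f <- variants[[FREQ_DB_COLS[[db]]]]
    is_common <- is_common | (!is.na(f) & f > maf_cutoff)
  }
  if ("dbSNP130" %in% dbs) {
    is_common <- is_common | (variants$dbsnp130 %in% TRUE)
  }
  list(common = variants[is_common, , drop = FALSE],
       rare = variants[!is_common, , drop = FALSE])
}

#' Partition variants by synonymy
#'
#' Synonymous single-nucleotide variants are set aside; every other effect
#' class (missense, stop-gain, frameshift and non-frameshift indels, splice
#' site) is kept.
#'
#' @param variants A `vt_variants` table.
#' @return List with elements `synonymous` and `non_synonymous`.
#' @export
flag_synonymous <- function(variants) {
  bad <- setdiff(unique(variants$effect), VARIANT_EFFECTS)
  if (length(bad) > 0) {
    vt_stop("vt_schema_error", "unknown effect label(s): %s",
            paste(bad, collapse = ", "))
  }
  syn <- variants$effect == "synonymous_snv"
  list(synonymous = variants[syn, , drop = FALSE],
       non_synonymous = variants[!syn, , drop = FALSE])
}

#' Subtract control-cohort variants
#'
#' Removes every variant whose id was observed in the control group, leaving
#' the patient-only set.
#'
#' @param variants A `vt_variants` table.
#' @param control_observed_ids Character vector of variant ids seen in the
#'   control arm.
#' @return List with elements `shared` (seen in controls) and `patient_only`.
#' @export
subtract_control <- function(variants, control_observed_ids) {
  shared <- variants$variant_id %in% control_observed_ids
  list(shared = variants[shared, , drop = FALSE],
       patient_only = variants[!shared, , drop = FALSE])
}

#' Run the stepwise filtering cascade
#'
#' Applies, in order: common-variant removal, synonymous removal,
#' control-cohort subtraction, and a user-supplied curation exclusion list
#' (empty by default — curation has no algorithmic definition, so it is
#' externalized as a reproducible id list). Stage accounting is returned as
#' a `FilterTrace` in which `n_input = n_removed + n_kept` at every stage
#' and each stage's kept count is the next stage's input.
#'
#' @param variants Raw called `vt_variants` table.
#' @param control_ids Variant ids observed in the control arm (default none).
#' @param curation_exclusions Variant ids removed by manual curation
#'   (default none). Ids not present in the surviving set produce a warning,
#'   not an error.
#' @param maf_cutoff,dbs Passed to [flag_common()].
#' @return List with elements `kept` (the analysis set, a `vt_variants`
#'   table) and `trace` (data.frame with columns `stage`, `n_input`,
#'   `n_removed`, `n_kept`, `removed_ids` (list-column)).
#' @export
run_cascade <- function(variants, control_ids = character(),
                        curation_exclusions = character(),
                        maf_cutoff = 0.005, dbs = REMOVAL_DBS_DEFAULT) {
  stages <- list()
  note <- function(stage, n_in, removed_ids, n_kept) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = stage, n_input = n_in, n_removed = length(removed_ids),
      n_kept = n_kept, stringsAsFactors = FALSE)
    stages[[length(stages)]]$removed_ids <<- list(removed_ids)
  }

  cur <- variants
  part <- flag_common(cur, maf_cutoff, dbs)
  note("common", nrow(cur), part$common$variant_id, nrow(part$rare))
  cur <- part$rare

  part <- flag_synonymous(cur)
  note("synonymous", nrow(cur), part$synonymous$variant_id,
       nrow(part$non_synonymous))
  cur <- part$non_synonymous

  part <- subtract_control(cur, control_ids)
  note("control_subtraction", nrow(cur), part$shared$variant_id,
       nrow(part$patient_only))
  cur <- part$patient_only

  stray <- setdiff(curation_exclusions, cur$variant_id)
  if (length(stray) > 0) {
    warning(sprintf("curation exclusion id(s) not in surviving set: %s",
                    paste(utils::head(stray, 10), collapse = ", ")))
  }
  excl <- cur$variant_id %in% curation_exclusions
  note("curation", nrow(cur), cur$variant_id[excl], sum(!excl))
  cur <- cur[!excl, , drop = FALSE]

  trace <- do.call(rbind, stages)
  stopifnot(all(trace$n_input == trace$n_removed + trace$n_kept),
            all(utils::head(trace$n_kept, -1) == utils::tail(trace$n_input, -1)))
  list(kept = cur, trace = trace)
}
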