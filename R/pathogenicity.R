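#' Consensus pathogenicity class from ten predictor calls
#'
#' The ordinal class is keyed to how many of the ten in-silico tools call
#' the variant damaging: at least 7 gives class I (highest pathogenic
#' potential), 4-6 class II (intermediate), 1-3 class III (low), and 0
#' class IV (benign). Severity is ordered I > II > III > IV. A missing call
#' counts as not damaging; the number of available calls is surfaced so
#' users can gate on predictor coverage.
#'
#' @param pred Character vector of 10-character call strings over
#'   `{D, T, .}` in [PREDICTOR_TOOLS] order, or an integer vector of
#'   damaging counts in `0:10`.
#' @return A data.frame with columns `class` (ordered factor,
#'   levels `IV < III < II < I`), `damaging_count`, `n_available`
#'   (`NA` when counts were supplied directly).
#' @examples
#' consensus_class("DDDDDDDTTT")$class  # I
#' consensus_class("TTTTTTTTTT")$class  # IV
#' @export
consensus_class <- function(pred) {
  if (is.numeric(pred)) {
    dc <- as.integer(pred)
    if (any(dc < 0L | dc > 10L, na.rm = TRUE)) {
      vt_stop("vt_schema_error", "damaging counts must lie in 0..10")
    }
    na <- rep(NA_integer_, length(dc))
  } else {
    if (any(!grepl("^[DT.]{10}$", pred))) {
      vt_stop("vt_schema_error",
              "pred must be 10-character strings over {D,T,.}")
    }
    dc <- damaging_count(pred)
    na <- n_available(pred)
  }
  cls <- class_from_count(dc)
  data.frame(class = cls, damaging_count = dc, n_available = na,
             stringsAsFactors = FALSE)
}

# band rule: >=7 -> I, 4-6 -> II, 1-3 -> III, 0 -> IV
class_from_count <- function(dc) {
  lab <- ifelse(dc >= 7L, "I",
         ifelse(dc >= 4L, "II",
         ifelse(dc >= 1L, "III", "IV")))
  factor(lab, levels = c("IV", "III", "II", "I"), ordered = TRUE)
}

#' Attach consensus classes to a variant table
#'
#' @param variants A `vt_variants` table (filtered analysis set).
#' @return The same table with columns `damaging_count`, `n_available` and
#'   `class` (ordered factor, severity I highest) appended.
#' @export
classify_variants <- function(variants) {
  cc <- consensus_class(variants$pred)
  variants$damaging_count <- cc$damaging_count
  variants$n_available <- cc$n_available
  variants$class <- cc$class
  variants
}

#' Per-class counts with HGMD split
#'
#' @param variants A classified variant table (see [classify_variants()]).
#' @return Data.frame with one row per class I-IV: `n`, `pct` (half-up, one
#'   decimal), `n_hgmd`, `n_non_hgmd`.
#' @export
class_distribution <- function(variants) {
  if (is.null(variants$class)) variants <- classify_variants(variants)
  cls <- factor(as.character(variants$class), levels = PATHO_CLASSES)
  n <- as.integer(table(cls))
  hg <- !is.na(variants$hgmd_id)
  n_h <- as.integer(table(cls[hg]))
  data.frame(class = PATHO_CLASSES, n = n,
             pct = percent(n, sum(n)),
             n_hgmd = n_h, n_non_hgmd = n - n_h,
             stringsAsFactors = FALSE)
}

#' Mean reference-database frequency per consensus class
#'
#' Each variant contributes the arithmetic mean of its available
#' frequencies over the listed databases (databases it is absent from are
#' skipped; a variant absent from all of them contributes 0). Classes are
#' then averaged over their variants. An empty class yields `NA`
#' (undefined), never 0.
#'
#' @param variants A classified variant table.
#' @param dbs Databases averaged; default ESP6500, 1000G, ExAC.
#' @return Named numeric vector of per-class means, names `I`-`IV`.
#' @export
mean_maf_by_class <- function(variants, dbs = MAF_DBS_DEFAULT) {
  if (is.null(variants$class)) variants <- classify_variants(variants)
  cols <- FREQ_DB_COLS[intersect(dbs, names(FREQ_DB_COLS))]
  if (length(cols) == 0) vt_stop("vt_config_error", "no known frequency dbs")
  m <- as.matrix(as.data.frame(variants)[, cols, drop = FALSE])
  per_variant <- apply(m, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) 0 else mean(r)
  })
  out <- stats::setNames(rep(NA_real_, 4L), PATHO_CLASSES)
  for (k in PATHO_CLASSES) {
    idx <- as.character(variants$class) == k
    if (any(idx)) out[[k]] <- mean(per_variant[idx])
  }
  out
}

# --- ACMG/AMP combination --------------------------------------------------

acmg_code_counts <- function(codes) {
  codes <- unique(codes)
  bad <- setdiff(codes, ACMG_CODES)
  if (length(bad) > 0) {
    vt_stop("vt_schema_error", "unknown ACMG code(s): %s",
            paste(bad, collapse = ", "))
  }
  c(pvs = sum(codes == "PVS1"),
    ps = sum(grepl("^PS", codes)),
    pm = sum(grepl("^PM", codes)),
    pp = sum(grepl("^PP", codes)),
    ba = sum(codes == "BA1"),
    bs = sum(grepl("^BS", codes)),
    bp = sum(grepl("^BP", codes)))
}

#' Combine ACMG/AMP evidence codes into a five-tier verdict
#'
#' Implements the 2015 ACMG/AMP combining rules over weighted evidence:
#' very strong (PVS1), strong (PS1-4), moderate (PM1-6), supporting
#' (PP1-5) on the pathogenic side; stand-alone (BA1), strong (BS1-4),
#' supporting (BP1-6) on the benign side. When rules fire on both sides the
#' verdict is uncertain significance (conflict), as the guideline requires.
#'
#' @param codes Character vector of evidence codes (a set; duplicates are
#'   ignored).
#' @return List with `verdict` (one of [ACMG_TIERS]) and `rule` (the
#'   combination satisfied, e.g. `"P.1a"`, or `"none"`/`"conflict"`).
#' @examples
#' acmg_combine(c("PVS1", "PS1"))$verdict  # pathogenic
#' acmg_combine("BA1")$verdict             # benign
#' acmg_combine(character())$verdict       # VUS
#' @export
acmg_combine <- function(codes) {
  k <- acmg_code_counts(codes)
  path_rule <-
    if (k["pvs"] >= 1 && k["ps"] >= 1) "P.1a"
    else if (k["pvs"] >= 1 && k["pm"] >= 2) "P.1b"
    else if (k["pvs"] >= 1 && k["pm"] == 1 && k["pp"] == 1) "P.1c"
    else if (k["pvs"] >= 1 && k["pp"] >= 2) "P.1d"
    else if (k["ps"] >= 2) "P.2"
    else if (k["ps"] == 1 && k["pm"] >= 3) "P.3a"
    else if (k["ps"] == 1 && k["pm"] == 2 && k["pp"] >= 2) "P.3b"
    else if (k["ps"] == 1 && k["pm"] == 1 && k["pp"] >= 4) "P.3c"
    else NA_character_
  lp_rule <-
    if (k["pvs"] >= 1 && k["pm"] == 1) "LP.1"
    else if (k["ps"] == 1 && k["pm"] >= 1 && k["pm"] <= 2) "LP.2"
    else if (k["ps"] == 1 && k["pp"] >= 2) "LP.3"
    else if (k["pm"] >= 3) "LP.4"
    else if (k["pm"] == 2 && k["pp"] >= 2) "LP.5"
    else if (k["pm"] == 1 && k["pp"] >= 4) "LP.6"
    else NA_character_
  ben_rule <-
    if (k["ba"] >= 1) "B.1"
    else if (k["bs"] >= 2) "B.2"
    else NA_character_
  lb_rule <-
    if (k["bs"] >= 1 && k["bp"] >= 1) "LB.1"
    else if (k["bp"] >= 2) "LB.2"
    else NA_character_

  patho_side <- !is.na(path_rule) || !is.na(lp_rule)
  benign_side <- !is.na(ben_rule) || !is.na(lb_rule)
  if (patho_side && benign_side) {
    return(list(verdict = "VUS", rule = "conflict"))
  }
  if (!is.na(path_rule)) return(list(verdict = "pathogenic", rule = path_rule))
  if (!is.na(lp_rule)) return(list(verdict = "likely_pathogenic", rule = lp_rule))
  if (!is.na(ben_rule)) return(list(verdict = "benign", rule = ben_rule))
  if (!is.na(lb_rule)) return(list(verdict = "likely_benign", rule = lb_rule))
  list(verdict = "VUS", rule = "none")
}

#' Attach ACMG verdicts to a variant table
#'
#' Combines per-variant evidence codes with [acmg_combine()] and reconciles
#' the result with any ingested assertion (e.g. a ClinVar/Varsome five-tier
#' label carried in the `clinvar` column). By default the ingested
#' assertion takes precedence as the reported verdict, mirroring the use of
#' curated databases as the final word; both verdicts are retained.
#'
#' @param variants A `vt_variants` table.
#' @param evidence Named list: for each variant_id a character vector of
#'   ACMG codes. Variants without an entry get no local codes (VUS).
#' @param prefer `"ingested"` (default) or `"local"`.
#' @return The table with columns `acmg_codes` (collapsed `+`-separated),
#'   `acmg_local` (combined verdict), `acmg_verdict` (reported tier).
#' @export
acmg_classify <- function(variants, evidence = list(),
                          prefer = c("ingested", "local")) {
  prefer <- match.arg(prefer)
  local <- character(nrow(variants))
  codes_str <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    codes <- evidence[[variants$variant_id[i]]] %||% character()
    res <- acmg_combine(codes)
    local[i] <- res$verdict
    codes_str[i] <- paste(codes, collapse = "+")
  }
  ingested <- variants$clinvar
  reported <- if (prefer == "ingested") {
    ifelse(!is.na(ingested), ingested, local)
  } else {
    local
  }
  variants$acmg_codes <- codes_str
  variants$acmg_local <- local
  variants$acmg_verdict <- reported
  variants
}

#' Five-tier verdict distribution
#'
#' @param verdicts Character vector of tiers (one per variant), or a
#'   variant table with an `acmg_verdict` column.
#' @return Data.frame with one row per tier in [ACMG_TIERS] order: `n` and
#'   `pct` (count/total*100, half-up to one decimal). Counts sum to the
#'   input size.
#' @export
acmg_distribution <- function(verdicts) {
  if (is.data.frame(verdicts)) verdicts <- verdicts$acmg_verdict
  bad <- setdiff(unique(verdicts), ACMG_TIERS)
  if (length(bad) > 0) {
    vt_stop("vt_schema_error", "unknown verdict tier(s): %s",
            paste(bad, collapse = ", "))
  }
  n <- as.integer(table(factor(verdicts, levels = ACMG_TIERS)))
  data.frame(tier = ACMG_TIERS, n = n, pct = percent(n, sum(n)),
             stringsAsFactors = FALSE)
}
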