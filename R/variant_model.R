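#' Build a validated annotated-variant table
#'
#' The central container of the package is a plain `data.frame` with one row
#' per unique variant and a fixed column set. Annotation absence is a
#' first-class state: a frequency that was never observed in a reference
#' database is `NA`, never 0 — the distinction matters because the rarity
#' filter treats "absent everywhere" as rare.
#'
#' Columns:
#' \describe{
#'   \item{variant_id}{opaque unique key (character)}
#'   \item{chrom, pos, ref, alt}{1-based VCF-convention coordinates; indels
#'     are left-normalized on ingest}
#'   \item{gene}{HGNC symbol}
#'   \item{effect}{one of [VARIANT_EFFECTS]}
#'   \item{af_esp6500, af_1000g, af_exac}{allele frequencies in `[0, 1]`,
#'     `NA` when the variant is absent from that database}
#'   \item{dbsnp130}{logical membership flag (dbSNP130 is a membership
#'     database here, not a frequency source)}
#'   \item{hgmd_id}{HGMD accession, `NA` when not listed}
#'   \item{clinvar}{ingested five-tier assertion, one of [ACMG_TIERS] or `NA`}
#'   \item{pred}{10-character string over `D`/`T`/`.` giving the ten
#'     predictor calls in [PREDICTOR_TOOLS] order (damaging / tolerated /
#'     missing)}
#'   \item{phylop100, siphy29}{conservation scores, `NA` allowed}
#' }
#'
#' @param df A data.frame holding at least the mandatory columns above.
#' @param normalize Left-normalize indel alleles (default `TRUE`).
#' @return A validated variant table (`data.frame`, class `vt_variants`).
#' @export
variant_table <- function(df, normalize = TRUE) {
  mandatory <- c("variant_id", "chrom", "pos", "ref", "alt", "gene",
                 "effect", "pred")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    vt_stop("vt_schema_error", "missing mandatory column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  optional <- c(af_esp6500 = NA_real_, af_1000g = NA_real_,
                af_exac = NA_real_, phylop100 = NA_real_,
                siphy29 = NA_real_)
  for (col in names(optional)) {
    if (is.null(df[[col]])) df[[col]] <- rep(optional[[col]], nrow(df))
  }
  if (is.null(df$dbsnp130)) df$dbsnp130 <- rep(FALSE, nrow(df))
  if (is.null(df$hgmd_id)) df$hgmd_id <- rep(NA_character_, nrow(df))
  if (is.null(df$clinvar)) df$clinvar <- rep(NA_character_, nrow(df))

  df$variant_id <- as.character(df$variant_id)
  df$pos <- as.integer(df$pos)
  df$dbsnp130 <- as.logical(df$dbsnp130)

  dup <- df$variant_id[duplicated(df$variant_id)]
  if (length(dup) > 0) {
    vt_stop("vt_integrity_error", "duplicate variant_id(s): %s",
            paste(unique(dup), collapse = ", "))
  }
  bad_eff <- setdiff(unique(df$effect), VARIANT_EFFECTS)
  if (length(bad_eff) > 0) {
    vt_stop("vt_schema_error", "unknown effect label(s): %s",
            paste(bad_eff, collapse = ", "))
  }
  for (col in c("af_esp6500", "af_1000g", "af_exac")) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      vt_stop("vt_schema_error", "column %s has frequencies outside [0,1]", col)
    }
  }
  if (any(df$pos < 1L, na.rm = TRUE)) {
    vt_stop("vt_schema_error", "pos must be >= 1")
  }
  bad_pred <- !grepl("^[DT.]{10}$", df$pred)
  if (any(bad_pred)) {
    vt_stop("vt_schema_error",
            "pred must be a 10-character string over {D,T,.} (rows: %s)",
            paste(which(bad_pred), collapse = ", "))
  }
  if (normalize && nrow(df) > 0) {
    norm <- normalize_indels(df$pos, df$ref, df$alt)
    df$pos <- norm$pos; df$ref <- norm$ref; df$alt <- norm$alt
  }
  order_cols <- c(mandatory[1:7], "af_esp6500", "af_1000g", "af_exac",
                  "dbsnp130", "hgmd_id", "clinvar", "pred",
                  "phylop100", "siphy29")
  df <- df[, c(order_cols, setdiff(names(df), order_cols)), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("vt_variants", "data.frame")
  df
}

# Left-normalize indel alleles: drop the shared suffix, then the shared
# prefix (always keeping one base), shifting pos right by the prefix drop.
normalize_indels <- function(pos, ref, alt) {
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]
    if (nchar(r) == nchar(a) && nchar(r) == 1L) next
    # shared suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # shared prefix
    while (nchar(r) > 1L && nchar(a) > 1L && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Count damaging calls in a predictor string
#'
#' @param pred Character vector of 10-character predictor strings
#'   (`D` damaging, `T` tolerated, `.` missing).
#' @return Integer vector of damaging counts (0-10). Missing calls count as
#'   not damaging.
#' @export
damaging_count <- function(pred) {
  nchar(pred) - nchar(gsub("D", "", pred, fixed = TRUE))
}

#' @rdname damaging_count
#' @return `n_available()`: number of non-missing calls (0-10).
#' @export
n_available <- function(pred) {
  nchar(pred) - nchar(gsub(".", "", pred, fixed = TRUE))
}

#' Read / write annotated-variant tables
#'
#' `read_variant_table()` ingests either the package's tab-delimited layout
#' (`dialect = "tsv"`; empty cells are absent annotations) or a sites-only
#' VCF 4.2 with INFO keys `GENE`, `EFFECT`, `AF_ESP6500`, `AF_1000G`,
#' `AF_EXAC`, `DBSNP130`, `HGMD`, `CLINVAR`, `PRED`, `PHYLOP100`, `SIPHY29`
#' (`dialect = "vcf"`, parsed with \pkg{vcfR}). Row order is preserved.
#'
#' @param path File to read or write.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param variants A `vt_variants` table.
#' @return `read_variant_table()`: a validated `vt_variants` table.
#'   `write_variant_table()`: `path`, invisibly. Writing then re-reading is
#'   the identity on every field, including the absent-vs-zero distinction.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) vt_stop("vt_io_error", "file not found: %s", path)
  if (dialect == "tsv") read_variant_tsv(path) else read_variant_vcf(path)
}

read_variant_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "")
  mandatory <- c("variant_id", "chrom", "pos", "ref", "alt", "gene",
                 "effect", "pred")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    vt_stop("vt_schema_error", "missing mandatory column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  for (col in c("af_esp6500", "af_1000g", "af_exac", "phylop100", "siphy29")) {
    if (!is.null(df[[col]])) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(!is.na(df[[col]]) & is.na(v))
      if (length(bad) > 0) {
        vt_stop("vt_parse_error",
                "unparsable frequency in column %s at line(s) %s",
                col, paste(bad + 1L, collapse = ", "))
      }
      df[[col]] <- v
    }
  }
  if (!is.null(df$dbsnp130)) {
    df$dbsnp130 <- df$dbsnp130 %in% c("1", "TRUE", "true", "yes")
  }
  df$pos <- as.integer(df$pos)
  variant_table(df, normalize = FALSE)
}

#' @rdname read_variant_table
#' @export
write_variant_table <- function(variants, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    out <- as.data.frame(variants)
    out$dbsnp130 <- ifelse(out$dbsnp130, "1", "0")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    write_variant_vcf(variants, path)
  }
  invisible(path)
}

# --- VCF dialect -----------------------------------------------------------

vcf_info_field <- function(info, key) {
  info2 <- paste0(";", info)
  pat <- paste0(";", key, "=")
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info2, fixed = TRUE)
  rest <- sub(paste0("^.*;", key, "="), "", info2[hit])
  out[hit] <- sub(";.*$", "", rest)
  out
}

read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info <- fix$INFO
  num <- function(key) suppressWarnings(as.numeric(vcf_info_field(info, key)))
  df <- data.frame(
    variant_id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = vcf_info_field(info, "GENE"),
    effect = vcf_info_field(info, "EFFECT"),
    af_esp6500 = num("AF_ESP6500"),
    af_1000g = num("AF_1000G"),
    af_exac = num("AF_EXAC"),
    dbsnp130 = grepl(";DBSNP130(;|$|=1)", paste0(";", info)),
    hgmd_id = vcf_info_field(info, "HGMD"),
    clinvar = vcf_info_field(info, "CLINVAR"),
    pred = vcf_info_field(info, "PRED"),
    phylop100 = num("PHYLOP100"),
    siphy29 = num("SIPHY29"),
    stringsAsFactors = FALSE
  )
  variant_table(df)
}

write_variant_vcf <- function(variants, path) {
  v <- as.data.frame(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"HGNC gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
    "##INFO=<ID=AF_ESP6500,Number=1,Type=Float,Description=\"ESP6500 allele frequency\">",
    "##INFO=<ID=AF_1000G,Number=1,Type=Float,Description=\"1000 Genomes allele frequency\">",
    "##INFO=<ID=AF_EXAC,Number=1,Type=Float,Description=\"ExAC allele frequency\">",
    "##INFO=<ID=DBSNP130,Number=0,Type=Flag,Description=\"dbSNP130 member\">",
    "##INFO=<ID=HGMD,Number=1,Type=String,Description=\"HGMD accession\">",
    "##INFO=<ID=CLINVAR,Number=1,Type=String,Description=\"Ingested five-tier assertion\">",
    "##INFO=<ID=PRED,Number=1,Type=String,Description=\"Ten predictor calls over {D,T,.}\">",
    "##INFO=<ID=PHYLOP100,Number=1,Type=Float,Description=\"PhyloP100 conservation\">",
    "##INFO=<ID=SIPHY29,Number=1,Type=Float,Description=\"SiPhy 29-way conservation\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  fmt_num <- function(x) ifelse(is.na(x), NA_character_,
                                formatC(x, format = "g", digits = 15))
  info <- vapply(seq_len(nrow(v)), function(i) {
    kv <- c(
      paste0("GENE=", v$gene[i]),
      paste0("EFFECT=", v$effect[i]),
      if (!is.na(v$af_esp6500[i])) paste0("AF_ESP6500=", fmt_num(v$af_esp6500[i])),
      if (!is.na(v$af_1000g[i])) paste0("AF_1000G=", fmt_num(v$af_1000g[i])),
      if (!is.na(v$af_exac[i])) paste0("AF_EXAC=", fmt_num(v$af_exac[i])),
      if (isTRUE(v$dbsnp130[i])) "DBSNP130",
      if (!is.na(v$hgmd_id[i])) paste0("HGMD=", v$hgmd_id[i]),
      if (!is.na(v$clinvar[i])) paste0("CLINVAR=", v$clinvar[i]),
      paste0("PRED=", v$pred[i]),
      if (!is.na(v$phylop100[i])) paste0("PHYLOP100=", fmt_num(v$phylop100[i])),
      if (!is.na(v$siphy29[i])) paste0("SIPHY29=", fmt_num(v$siphy29[i]))
    )
    paste(kv, collapse = ";")
  }, character(1))
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# --- cohort ----------------------------------------------------------------

#' Assemble a cross-linked cohort
#'
#' A cohort bundles the annotated-variant table, the patient metadata table
#' and the genotype (carriage) table, after checking that every carried
#' variant resolves against the variant table and every subgroup label is
#' known.
#'
#' @param variants A `vt_variants` table (or data.frame coercible to one).
#' @param patients Patient metadata data.frame with columns `patient_id`,
#'   `subgroup` (one of [SUBGROUPS]) and the clinical covariates `age`,
#'   `sex`, `bmi`, `nyha`, `lvef`, `la`, `lv_edd`, `lv_esd`, `qrs`, `qt`,
#'   `familial` (missing covariates allowed, `NA`).
#' @param genotypes Carriage table with columns `patient_id`, `variant_id`,
#'   `zygosity` (`"het"`/`"hom"`). Zygosity is carried but all burden
#'   statistics count carriers, not alleles.
#' @return An object of class `vt_cohort`: a list with elements `variants`,
#'   `patients`, `genotypes`.
#' @export
cohort <- function(variants, patients, genotypes) {
  if (!inherits(variants, "vt_variants")) variants <- variant_table(variants)
  req_p <- c("patient_id", "subgroup")
  if (!all(req_p %in% names(patients))) {
    vt_stop("vt_schema_error", "patients table needs columns: %s",
            paste(setdiff(req_p, names(patients)), collapse = ", "))
  }
  bad_sub <- setdiff(unique(as.character(patients$subgroup)), SUBGROUPS)
  if (length(bad_sub) > 0) {
    vt_stop("vt_schema_error", "unknown subgroup label(s): %s",
            paste(bad_sub, collapse = ", "))
  }
  if (nrow(genotypes) > 0) {
    dangling <- setdiff(genotypes$variant_id, variants$variant_id)
    if (length(dangling) > 0) {
      vt_stop("vt_integrity_error",
              "genotype rows reference unknown variant_id(s): %s",
              paste(utils::head(dangling, 10), collapse = ", "))
    }
    dangling_p <- setdiff(genotypes$patient_id, patients$patient_id)
    if (length(dangling_p) > 0) {
      vt_stop("vt_integrity_error",
              "genotype rows reference unknown patient_id(s): %s",
              paste(utils::head(dangling_p, 10), collapse = ", "))
    }
  }
  dup_p <- patients$patient_id[duplicated(patients$patient_id)]
  if (length(dup_p) > 0) {
    vt_stop("vt_integrity_error", "duplicate patient_id(s): %s",
            paste(unique(dup_p), collapse = ", "))
  }
  structure(list(variants = variants,
                 patients = as.data.frame(patients),
                 genotypes = as.data.frame(genotypes)),
            class = "vt_cohort")
}

#' Read a cohort from its three tables
#'
#' @param variants_path Variant table (TSV dialect).
#' @param patients_path Patient metadata CSV.
#' @param genotypes_path Genotype/carriage CSV (`patient_id`, `variant_id`,
#'   `zygosity`).
#' @return A `vt_cohort`.
#' @export
read_cohort <- function(variants_path, patients_path, genotypes_path) {
  variants <- read_variant_table(variants_path, "tsv")
  patients <- utils::read.csv(patients_path, stringsAsFactors = FALSE,
                              na.strings = "")
  genotypes <- utils::read.csv(genotypes_path, stringsAsFactors = FALSE,
                               na.strings = "")
  if (nrow(genotypes) == 0) {
    genotypes <- data.frame(patient_id = character(), variant_id = character(),
                            zygosity = character(), stringsAsFactors = FALSE)
  }
  cohort(variants, patients, genotypes)
}

#' Write a cohort to its three tables
#'
#' @param x A `vt_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "vt_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(variants = file.path(dir, "variants.tsv"),
             patients = file.path(dir, "patients.csv"),
             genotypes = file.path(dir, "genotypes.csv"))
  write_variant_table(x$variants, paths["variants"], "tsv")
  utils::write.csv(x$patients, paths["patients"], row.names = FALSE, na = "")
  utils::write.csv(x$genotypes, paths["genotypes"], row.names = FALSE, na = "")
  invisible(paths)
}

#' @export
print.vt_cohort <- function(x, ...) {
  cat("Cohort:", nrow(x$patients), "patients,",
      nrow(x$variants), "unique variants,",
      nrow(x$genotypes), "carried instances\n")
  print(table(x$patients$subgroup))
  invisible(x)
}

#' Validate a cohort against its invariants
#'
#' Reporting operation: never throws. Checks clinical covariates for
#' negative values, reference frequencies for range, effect labels, carried
#' variant resolution and duplicate ids, and returns one row per violation.
#'
#' @param x A `vt_cohort` (or a bare list with the same elements, so that
#'   broken inputs can still be audited).
#' @return A data.frame with columns `record`, `field`, `message`; zero rows
#'   iff the cohort is consistent.
#' @export
validate_cohort <- function(x) {
  viol <- list()
  add <- function(record, field, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      record = record, field = field, message = message,
      stringsAsFactors = FALSE)
  }
  v <- x$variants; p <- x$patients; g <- x$genotypes
  for (col in c("af_esp6500", "af_1000g", "af_exac")) {
    bad <- which(!is.na(v[[col]]) & (v[[col]] < 0 | v[[col]] > 1))
    for (i in bad) add(v$variant_id[i], col, "frequency outside [0,1]")
  }
  bad <- which(!v$effect %in% VARIANT_EFFECTS)
  for (i in bad) add(v$variant_id[i], "effect",
                     paste0("unknown effect '", v$effect[i], "'"))
  bad <- which(!is.na(v$pos) & v$pos < 1L)
  for (i in bad) add(v$variant_id[i], "pos", "position < 1")
  dup <- unique(v$variant_id[duplicated(v$variant_id)])
  for (id in dup) add(id, "variant_id", "duplicate variant_id")

  nonneg <- c("age", "bmi", "lvef", "la", "lv_edd", "lv_esd", "qrs", "qt")
  for (col in intersect(nonneg, names(p))) {
    bad <- which(!is.na(p[[col]]) & p[[col]] < 0)
    for (i in bad) add(p$patient_id[i], col, "negative clinical covariate")
  }
  bad <- which(!p$subgroup %in% SUBGROUPS)
  for (i in bad) add(p$patient_id[i], "subgroup",
                     paste0("unknown subgroup '", p$subgroup[i], "'"))
  if (nrow(g) > 0) {
    dangling <- setdiff(g$variant_id, v$variant_id)
    for (id in dangling) add(id, "variant_id",
                             "carried variant_id missing from variant table")
  }
  if (length(viol) == 0) {
    return(data.frame(record = character(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, viol)
}

#' Read a gene-to-functional-category map
#'
#' Two-column TSV (`gene`, `category`) mapping every panel gene to one of
#' the seven functional categories in [GENE_CATEGORIES].
#'
#' @param path TSV file.
#' @return Named character vector: `category` named by `gene`.
#' @export
read_gene_categories <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "category") %in% names(df))) {
    vt_stop("vt_schema_error", "gene map needs columns gene, category")
  }
  bad <- setdiff(unique(df$category), GENE_CATEGORIES)
  if (length(bad) > 0) {
    vt_stop("vt_schema_error", "unknown categories: %s",
            paste(bad, collapse = ", "))
  }
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup) > 0) {
    vt_stop("vt_integrity_error", "genes mapped twice: %s",
            paste(unique(dup), collapse = ", "))
  }
  stats::setNames(df$category, df$gene)
}
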