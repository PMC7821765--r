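# Burden statistics count carried instances: a variant carried by two
# patients contributes two instances to cumulative counts, while carrier
# percentages count patients. Thresholds are cumulative in severity:
# class I only, classes I/II, classes I/II/III.

# internal: genotype table joined with class, restricted to case subgroups
carried_with_class <- function(cohort, classified) {
  g <- cohort$genotypes
  cls <- stats::setNames(as.character(classified$class), classified$variant_id)
  sub <- stats::setNames(as.character(cohort$patients$subgroup),
                         cohort$patients$patient_id)
  g$class <- cls[g$variant_id]
  if (any(is.na(g$class))) {
    vt_stop("vt_integrity_error",
            "carried variant(s) missing from the classified set: %s",
            paste(utils::head(unique(g$variant_id[is.na(g$class)]), 10),
                  collapse = ", "))
  }
  g$subgroup <- sub[g$patient_id]
  g
}

#' Molecular-burden table per subgroup and class threshold
#'
#' For each case subgroup and each cumulative severity threshold (class I;
#' classes I/II; classes I/II/III) reports: the number and percentage of
#' patients carrying at least one variant at or above the threshold, the
#' cumulative number of carried variant instances at or above the
#' threshold, that count as a percentage of all carried instances in the
#' subgroup (all classes), and the average number of qualifying instances
#' per positive patient.
#'
#' @param cohort A `vt_cohort`.
#' @param classified Classified variant table covering every carried
#'   variant (see [classify_variants()]).
#' @param subgroups Subgroups tabulated (default the three case arms).
#' @return Data.frame of burden rows; `variants_per_positive` is `NA` when
#'   a subgroup has no positive patients. Percentages half-up to one
#'   decimal; instances-per-patient to two.
#' @export
burden_table <- function(cohort, classified,
                         subgroups = CASE_SUBGROUPS) {
  g <- carried_with_class(cohort, classified)
  thresholds <- list("I" = "I", "I/II" = c("I", "II"),
                     "I/II/III" = c("I", "II", "III"))
  out <- list()
  for (sg in subgroups) {
    pats <- cohort$patients$patient_id[cohort$patients$subgroup == sg]
    n_pat <- length(pats)
    if (n_pat == 0) {
      warning(sprintf("subgroup %s has no patients; row omitted", sg))
      next
    }
    gs <- g[g$subgroup == sg, , drop = FALSE]
    total_instances <- nrow(gs)
    for (th in names(thresholds)) {
      qual <- gs[gs$class %in% thresholds[[th]], , drop = FALSE]
      pos <- unique(qual$patient_id)
      n_pos <- length(pos)
      cum <- nrow(qual)
      out[[length(out) + 1L]] <- data.frame(
        subgroup = sg, class_threshold = th,
        n_patients = n_pat, n_positive = n_pos,
        pct_positive = percent(n_pos, n_pat),
        cumulative_variants = cum,
        pct_of_all_variants = percent(cum, total_instances),
        variants_per_positive = if (n_pos > 0)
          round_half_up(cum / n_pos, 2L) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' HGMD carrier summary
#'
#' @param cohort A `vt_cohort`.
#' @param classified Classified variant table with `hgmd_id` flags.
#' @param subgroups Subgroups tabulated (default the case arms).
#' @return List with `carriers`: per-subgroup data.frame (`n_patients`,
#'   `n_carriers`, `pct_carriers` — patients carrying at least one
#'   HGMD-listed variant), and `class_split`: distribution of the unique
#'   HGMD-flagged variants over classes I-IV with percentages.
#' @export
hgmd_carrier_table <- function(cohort, classified,
                               subgroups = CASE_SUBGROUPS) {
  g <- carried_with_class(cohort, classified)
  hgmd_ids <- classified$variant_id[!is.na(classified$hgmd_id)]
  rows <- lapply(subgroups, function(sg) {
    pats <- cohort$patients$patient_id[cohort$patients$subgroup == sg]
    carriers <- unique(g$patient_id[g$subgroup == sg &
                                      g$variant_id %in% hgmd_ids])
    data.frame(subgroup = sg, n_patients = length(pats),
               n_carriers = length(carriers),
               pct_carriers = percent(length(carriers), length(pats)),
               stringsAsFactors = FALSE)
  })
  hv <- classified[!is.na(classified$hgmd_id), , drop = FALSE]
  cls <- factor(as.character(hv$class), levels = PATHO_CLASSES)
  n <- as.integer(table(cls))
  list(carriers = do.call(rbind, rows),
       class_split = data.frame(class = PATHO_CLASSES, n = n,
                                pct = percent(n, max(sum(n), 1L)),
                                stringsAsFactors = FALSE))
}

#' Functional-category by class distribution
#'
#' Cross-tabulates variants by gene functional category (seven categories)
#' and consensus class, with row-wise percentages. Pooled scope counts
#' unique variants across the whole analysis set; per-subgroup scope counts
#' carried instances restricted to one subgroup's patients.
#'
#' @param classified Classified variant table.
#' @param category_map Named character vector gene -> category
#'   (see [read_gene_categories()]).
#' @param scope `"pooled"` (default) or `"per_subgroup"`.
#' @param cohort Required for `scope = "per_subgroup"`.
#' @param classes Class filter (default all four).
#' @return For pooled scope: data.frame with `category`, one count and one
#'   percentage column per class (`n_I` ... `pct_IV`), and `total`. Row
#'   percentages are over the category's total. For per-subgroup scope: a
#'   named list of such tables.
#' @export
category_distribution <- function(classified, category_map,
                                  scope = c("pooled", "per_subgroup"),
                                  cohort = NULL, classes = PATHO_CLASSES) {
  scope <- match.arg(scope)
  unmapped <- setdiff(unique(classified$gene), names(category_map))
  if (length(unmapped) > 0) {
    vt_stop("vt_config_error", "genes missing from category map: %s",
            paste(unmapped, collapse = ", "))
  }
  tab_one <- function(genes, cls) {
    cat_f <- factor(category_map[genes], levels = GENE_CATEGORIES)
    cls_f <- factor(as.character(cls), levels = PATHO_CLASSES)
    keep <- cls_f %in% classes
    tt <- table(cat_f[keep], cls_f[keep])
    tt <- tt[, classes, drop = FALSE]
    out <- data.frame(category = rownames(tt), stringsAsFactors = FALSE)
    tot <- rowSums(tt)
    for (k in classes) {
      out[[paste0("n_", k)]] <- as.integer(tt[, k])
      out[[paste0("pct_", k)]] <- percent(as.integer(tt[, k]), pmax(tot, 1L))
      out[[paste0("pct_", k)]][tot == 0] <- NA_real_
    }
    out$total <- as.integer(tot)
    rownames(out) <- NULL
    out
  }
  if (scope == "pooled") {
    return(tab_one(classified$gene, classified$class))
  }
  if (is.null(cohort)) {
    vt_stop("vt_config_error", "per_subgroup scope needs a cohort")
  }
  g <- carried_with_class(cohort, classified)
  gene_of <- stats::setNames(classified$gene, classified$variant_id)
  out <- list()
  for (sg in CASE_SUBGROUPS) {
    gs <- g[g$subgroup == sg, , drop = FALSE]
    out[[sg]] <- tab_one(gene_of[gs$variant_id], gs$class)
  }
  out
}

#' Per-gene carrier frequency by subgroup
#'
#' Fraction of each subgroup's patients carrying at least one qualifying
#' variant in each gene. Qualification can be restricted to HGMD-listed
#' variants only, or include all rare classified variants.
#'
#' @param cohort A `vt_cohort`.
#' @param classified Classified variant table.
#' @param mode `"hgmd_plus"` (default: any classified variant) or
#'   `"hgmd_only"`.
#' @param classes Class filter (default all).
#' @param subgroups Subgroups (default case arms).
#' @return Data.frame `gene` x subgroup columns of carrier percentages
#'   (half-up, one decimal), sorted by the maximum frequency, plus carrier
#'   counts `n_<subgroup>`.
#' @export
gene_frequency_table <- function(cohort, classified,
                                 mode = c("hgmd_plus", "hgmd_only"),
                                 classes = PATHO_CLASSES,
                                 subgroups = CASE_SUBGROUPS) {
  mode <- match.arg(mode)
  g <- carried_with_class(cohort, classified)
  keep_ids <- classified$variant_id[classified$class %in% classes &
    (mode == "hgmd_plus" | !is.na(classified$hgmd_id))]
  g <- g[g$variant_id %in% keep_ids, , drop = FALSE]
  gene_of <- stats::setNames(classified$gene, classified$variant_id)
  g$gene <- gene_of[g$variant_id]
  genes <- sort(unique(classified$gene))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (sg in subgroups) {
    pats <- cohort$patients$patient_id[cohort$patients$subgroup == sg]
    gs <- g[g$subgroup == sg, , drop = FALSE]
    n_car <- vapply(genes, function(gene) {
      length(unique(gs$patient_id[gs$gene == gene]))
    }, integer(1))
    out[[paste0("n_", sg)]] <- n_car
    out[[paste0("pct_", sg)]] <- percent(n_car, length(pats))
  }
  pct_cols <- grep("^pct_", names(out), value = TRUE)
  out[order(-apply(out[, pct_cols, drop = FALSE], 1L, max)), , drop = FALSE]
}
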