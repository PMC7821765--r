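#' Predictor tools, controlled vocabularies and panel constants
#'
#' Fixed vocabularies used throughout the package: the ten in-silico
#' predictor tools whose calls drive the consensus class, the closed set of
#' variant effect labels, the clinical subgroups, the seven gene functional
#' categories, and the ACMG/AMP evidence codes.
#'
#' @name vocabularies
#' @keywords internal
NULL

#' @rdname vocabularies
#' @export
PREDICTOR_TOOLS <- c(
  "SIFT", "Polyphen2_HDIV", "Polyphen2_HVAR", "LRT", "MutationTaster",
  "MutationAssessor", "FATHMM", "RadialSVM", "LR", "MetaSVM"
)

#' @rdname vocabularies
#' @export
VARIANT_EFFECTS <- c(
  "nonsynonymous_snv", "synonymous_snv", "stopgain",
  "frameshift_indel", "nonframeshift_indel", "splice_site"
)

#' @rdname vocabularies
#' @export
SUBGROUPS <- c("CHD_VT", "DCM_VT", "iVT", "CONTROL")

#' @rdname vocabularies
#' @export
CASE_SUBGROUPS <- c("CHD_VT", "DCM_VT", "iVT")

#' @rdname vocabularies
#' @export
GENE_CATEGORIES <- c(
  "cell_membrane", "cytoskeleton", "sarcomere", "metabolism",
  "intercalated_disc", "ion_flux", "nucleus"
)

#' @rdname vocabularies
#' @export
PATHO_CLASSES <- c("I", "II", "III", "IV")

#' @rdname vocabularies
#' @export
ACMG_TIERS <- c("pathogenic", "likely_pathogenic", "VUS",
                "likely_benign", "benign")

#' @rdname vocabularies
#' @export
ACMG_CODES <- c(
  "PVS1",
  paste0("PS", 1:4),
  paste0("PM", 1:6),
  paste0("PP", 1:5),
  "BA1",
  paste0("BS", 1:4),
  paste0("BP", 1:6)
)

# reference frequency databases: the removal set and the averaging set
FREQ_DB_COLS <- c(ESP6500 = "af_esp6500", `1000G` = "af_1000g",
                  ExAC = "af_exac")
REMOVAL_DBS_DEFAULT <- c("ESP6500", "1000G", "dbSNP130")
MAF_DBS_DEFAULT <- c("ESP6500", "1000G", "ExAC")
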