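#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure of a three-arm
#' ventricular-tachycardia case series (coronary-heart-disease VT, dilated
#' cardiomyopathy VT, idiopathic VT) with an unaffected population control
#' group, sequenced on a 96-gene cardiac panel. Defaults encode the study
#' conditions this package targets: subgroup sizes 23/32/37 cases plus 60
#' controls, a raw pool of ~2,400 called variants that collapses to ~300
#' rare non-synonymous patient-only variants after the filtering cascade, a
#' latent pathogenicity class mix taken from the functional-category
#' table's column sums (48/70/156/33 over 307), per-subgroup per-class
#' Poisson carriage rates taken from the molecular-burden table's
#' cumulative counts, and clinical covariates drawn per subgroup from the
#' published mean/SD (normal covariates) or median/IQR (scaled-logistic
#' covariates).
#'
#' @param n_per_subgroup Named integer vector over [SUBGROUPS].
#' @param n_genes Panel size.
#' @param n_raw_variants Raw called unique variants before filtering.
#' @param frac_common Probability a raw variant is a common polymorphism
#'   (frequency above the cutoff in a removal database and/or a dbSNP130
#'   member).
#' @param frac_synonymous Probability a raw variant is synonymous.
#' @param control_overlap Probability a surviving rare non-synonymous
#'   variant is also observed in the control group (and hence subtracted).
#' @param class_mix Latent class proportions (named I-IV, sums to 1).
#' @param class_maf_mean Target mean reference-database frequency per
#'   latent class, strictly increasing from I to IV.
#' @param hgmd_rate Fraction of rare variants carrying an HGMD accession.
#' @param hgmd_carriage_weight Relative sampling weight of HGMD-listed
#'   variants when drawing patient carriage. HGMD variants are recurrent:
#'   with a fifth of unique analysis-set variants HGMD-listed but over a
#'   third of carried instances, the implied enrichment odds ratio is about
#'   2.35, which is the default.
#' @param carrier_rate 3x4 matrix (case subgroup x class) of expected
#'   carried variants per patient.
#' @param control_carrier_rate Expected carried (control-observed) variants
#'   per control individual.
#' @param effect_probs Effect mix for non-synonymous variants.
#' @param missing_rate Probability an individual predictor call is missing.
#' @param gene_weights Optional per-gene sampling weights (uniform default).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `vt_sim_config`.
#' @export
sim_config <- function(n_per_subgroup = c(CHD_VT = 23L, DCM_VT = 32L,
                                          iVT = 37L, CONTROL = 60L),
                       n_genes = 96L,
                       n_raw_variants = 2400L,
                       frac_common = 0.79,
                       frac_synonymous = 0.25,
                       control_overlap = 0.19,
                       class_mix = c(I = 48, II = 70, III = 156, IV = 33) / 307,
                       class_maf_mean = c(I = 0.000279, II = 0.00267,
                                          III = 0.00372, IV = 0.0192),
                       hgmd_rate = 61 / 307,
                       hgmd_carriage_weight = (168 / 456) / (288 / 456) /
                         ((61 / 307) / (246 / 307)),
                       carrier_rate = rbind(
                         CHD_VT = c(I = 13, II = 18, III = 58, IV = 21) / 23,
                         DCM_VT = c(I = 13, II = 36, III = 82, IV = 28) / 32,
                         iVT    = c(I = 26, II = 44, III = 90, IV = 27) / 37),
                       control_carrier_rate = 3,
                       effect_probs = c(nonsynonymous_snv = 0.955,
                                        stopgain = 0.016,
                                        frameshift_indel = 0.005,
                                        nonframeshift_indel = 0.008,
                                        splice_site = 0.016),
                       missing_rate = 0,
                       gene_weights = NULL,
                       seed = 1L) {
  cfg <- list(n_per_subgroup = n_per_subgroup, n_genes = as.integer(n_genes),
              n_raw_variants = as.integer(n_raw_variants),
              frac_common = frac_common, frac_synonymous = frac_synonymous,
              control_overlap = control_overlap, class_mix = class_mix,
              hgmd_carriage_weight = hgmd_carriage_weight,
              class_maf_mean = class_maf_mean, hgmd_rate = hgmd_rate,
              carrier_rate = carrier_rate,
              control_carrier_rate = control_carrier_rate,
              effect_probs = effect_probs, missing_rate = missing_rate,
              gene_weights = gene_weights,
              clinical_params = default_clinical_params(),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "vt_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  prop_ok <- function(x) all(x >= 0 & x <= 1)
  if (!prop_ok(c(cfg$frac_common, cfg$frac_synonymous, cfg$control_overlap,
                 cfg$hgmd_rate, cfg$missing_rate, cfg$class_mix))) {
    vt_stop("vt_config_error", "proportions must lie in [0,1]")
  }
  if (abs(sum(cfg$class_mix) - 1) > 1e-8) {
    vt_stop("vt_config_error", "class_mix must sum to 1")
  }
  if (any(cfg$n_per_subgroup < 1L)) {
    vt_stop("vt_config_error", "every subgroup needs n >= 1")
  }
  if (cfg$n_raw_variants < 1L) {
    vt_stop("vt_config_error", "n_raw_variants must be >= 1")
  }
  if (any(cfg$carrier_rate < 0)) {
    vt_stop("vt_config_error", "carrier rates must be nonnegative")
  }
  demanded <- colnames(cfg$carrier_rate)[colSums(cfg$carrier_rate) > 0]
  zero_mix <- names(cfg$class_mix)[cfg$class_mix == 0]
  clash <- intersect(demanded, zero_mix)
  if (length(clash) > 0) {
    vt_stop("vt_config_error",
            "infeasible mix: carriage demanded for class(es) %s with zero class_mix",
            paste(clash, collapse = ", "))
  }
  if (any(diff(cfg$class_maf_mean) <= 0)) {
    vt_stop("vt_config_error",
            "class_maf_mean must be strictly increasing from I to IV")
  }
  invisible(cfg)
}

# Published per-subgroup covariate parameterizations: mean/SD for the
# approximately symmetric covariates, median and quartiles for the skewed
# echocardiographic ones (drawn from a scaled logistic, whose quartiles
# are location +/- scale*log(3)).
default_clinical_params <- function() {
  norm <- list(
    age = rbind(CHD_VT = c(62.3, 8.8), DCM_VT = c(43.0, 13.3),
                iVT = c(37.1, 19.2), CONTROL = c(37.5, 10.9)),
    bmi = rbind(CHD_VT = c(27.9, 5.5), DCM_VT = c(27.0, 7.2),
                iVT = c(24.9, 5.6)),
    qrs = rbind(CHD_VT = c(112.4, 29.7), DCM_VT = c(117.4, 27.3),
                iVT = c(89.9, 15.4)),
    qt = rbind(CHD_VT = c(401.5, 72.0), DCM_VT = c(389.0, 38.0),
               iVT = c(400.5, 44.8)))
  logi <- list(  # median, q25, q75
    lvef = rbind(CHD_VT = c(35.00, 26.13, 45.00),
                 DCM_VT = c(24.50, 18.25, 30.00),
                 iVT = c(61.29, 57.13, 67.48)),
    la = rbind(CHD_VT = c(44.0, 37.0, 46.0), DCM_VT = c(45.5, 42.0, 49.75),
               iVT = c(31.0, 26.6, 35.0)),
    lv_edd = rbind(CHD_VT = c(6.10, 5.70, 6.60), DCM_VT = c(6.87, 6.33, 7.45),
                   iVT = c(4.70, 4.22, 4.97)),
    lv_esd = rbind(CHD_VT = c(4.80, 4.00, 5.90), DCM_VT = c(5.92, 5.63, 6.50),
                   iVT = c(3.20, 2.63, 3.50)))
  sex_male <- c(CHD_VT = 22 / 23, DCM_VT = 21 / 32, iVT = 16 / 37,
                CONTROL = 0.63)
  nyha <- rbind(CHD_VT = c(1, 6, 16, 0) / 23, DCM_VT = c(1, 1, 20, 10) / 32,
                iVT = c(25, 11, 1, 0) / 37)
  familial <- rbind(CHD_VT = c(6, 17, 0) / 23, DCM_VT = c(8, 24, 0) / 32,
                    iVT = c(11, 24, 2) / 37)
  list(normal = norm, logistic = logi, sex_male = sex_male, nyha = nyha,
       familial = familial)
}

#' Simulate predictor-call panels for a latent class
#'
#' Inverts the consensus band rule: a class-I variant receives 7-10
#' damaging calls (uniform within the band), class II 4-6, class III 1-3,
#' class IV exactly 0. Damaging calls are placed on a uniformly random
#' subset of the ten tools. An optional missing-call rate independently
#' replaces calls with missing (`.`); with a nonzero rate the recomputed
#' class can drop below the latent class, which is exactly the coverage
#' artifact the rate models.
#'
#' @param latent_class Character vector over `{"I","II","III","IV"}` (one
#'   panel simulated per element).
#' @param missing_rate Per-call missing probability (default 0).
#' @return Character vector of 10-character call strings.
#' @export
simulate_predictor_calls <- function(latent_class, missing_rate = 0) {
  bands <- list(I = 7:10, II = 4:6, III = 1:3, IV = 0L)
  bad <- setdiff(unique(latent_class), names(bands))
  if (length(bad) > 0) {
    vt_stop("vt_config_error", "unknown latent class(es): %s",
            paste(bad, collapse = ", "))
  }
  vapply(latent_class, function(k) {
    band <- bands[[k]]
    n_dam <- if (length(band) == 1L) band else sample(band, 1L)
    calls <- rep("T", 10L)
    if (n_dam > 0) calls[sample.int(10L, n_dam)] <- "D"
    if (missing_rate > 0) {
      calls[stats::runif(10L) < missing_rate] <- "."
    }
    paste(calls, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# class-conditional reference frequencies: a latent per-variant frequency
# (lognormal, class-specific mean) realized per database with presence
# probability increasing in class number; removal-database values for
# non-common variants are truncated at the rarity cutoff so the variant
# survives filtering, while ExAC is left free (it is not a removal db).
simulate_ref_freqs <- function(latent_class, is_common, class_maf_mean) {
  n <- length(latent_class)
  sdlog <- 0.8
  p_present <- c(I = 0.25, II = 0.55, III = 0.75, IV = 0.95)
  pres <- p_present[latent_class]
  # scale target up for absence so the class-mean of the per-variant
  # average (0 when absent everywhere) still tracks the target ordering
  p_any <- 1 - (1 - pres)^3
  target <- class_maf_mean[latent_class] / pmax(p_any, 1e-6)
  mu <- log(target) - sdlog^2 / 2
  f <- stats::rlnorm(n, meanlog = mu, sdlog = sdlog)
  draw_db <- function(cap) {
    present <- stats::runif(n) < pres
    val <- f * exp(stats::rnorm(n, 0, 0.2))
    if (!is.null(cap)) val <- pmin(val, cap)
    ifelse(present, val, NA_real_)
  }
  out <- data.frame(af_esp6500 = draw_db(0.005),
                    af_1000g = draw_db(0.005),
                    af_exac = draw_db(NULL))
  # common polymorphisms: high frequency in at least one removal db
  if (any(is_common)) {
    m <- sum(is_common)
    hi <- stats::runif(m, 0.01, 0.30)
    out$af_esp6500[is_common] <- hi
    out$af_1000g[is_common] <- hi * exp(stats::rnorm(m, 0, 0.1))
    out$af_exac[is_common] <- hi * exp(stats::rnorm(m, 0, 0.1))
  }
  out
}

#' Simulate the annotated-variant pool
#'
#' Draws `n_raw_variants` unique variants spanning the panel genes. Each
#' variant receives a latent pathogenicity class from `class_mix`,
#' predictor calls inside the class's band, reference-database frequencies
#' whose expected mean is strictly increasing from class I to IV, a common
#' flag (frequency above the cutoff and/or dbSNP130 membership), a
#' synonymous flag, an HGMD accession for a configurable fraction, and a
#' control-observed flag for the fraction that the control subtraction will
#' remove.
#'
#' @param config A `vt_sim_config`.
#' @param seed Optional override of `config$seed`; `NULL` leaves the RNG
#'   state untouched (for use inside larger simulations).
#' @return List with `variants` (a `vt_variants` table) and `ledger`
#'   (data.frame of ground truth per variant: `latent_class`, `is_common`,
#'   `is_synonymous`, `kcg_observed`, `in_analysis_set`).
#' @export
simulate_variant_pool <- function(config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_raw_variants
  genes <- panel_genes(config$n_genes)
  gw <- config$gene_weights %||% rep(1, config$n_genes)

  latent <- sample(names(config$class_mix), n, replace = TRUE,
                   prob = config$class_mix)
  is_common <- stats::runif(n) < config$frac_common
  is_syn <- stats::runif(n) < config$frac_synonymous
  effect <- ifelse(is_syn, "synonymous_snv",
                   sample(names(config$effect_probs), n, replace = TRUE,
                          prob = config$effect_probs))
  freqs <- simulate_ref_freqs(latent, is_common, config$class_maf_mean)
  dbsnp130 <- is_common & stats::runif(n) < 0.9
  rare_nonsyn <- !is_common & !is_syn
  hgmd <- rare_nonsyn & stats::runif(n) < config$hgmd_rate
  kcg <- rare_nonsyn & stats::runif(n) < config$control_overlap

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1),
                USE.NAMES = FALSE)
  ids <- sprintf("var%05d", seq_len(n))
  variants <- variant_table(data.frame(
    variant_id = ids,
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(2e8, n),
    ref = ref, alt = alt,
    gene = sample(genes, n, replace = TRUE, prob = gw),
    effect = effect,
    af_esp6500 = freqs$af_esp6500,
    af_1000g = freqs$af_1000g,
    af_exac = freqs$af_exac,
    dbsnp130 = dbsnp130,
    hgmd_id = ifelse(hgmd, sprintf("CM%06d", sample.int(999999, n)), NA),
    clinvar = NA_character_,
    pred = simulate_predictor_calls(latent, config$missing_rate),
    stringsAsFactors = FALSE), normalize = FALSE)
  ledger <- data.frame(variant_id = ids, latent_class = latent,
                       is_common = is_common, is_synonymous = is_syn,
                       kcg_observed = kcg,
                       in_analysis_set = rare_nonsyn & !kcg,
                       stringsAsFactors = FALSE)
  list(variants = variants, ledger = ledger)
}

panel_genes <- function(n_genes) sprintf("GENE%03d", seq_len(n_genes))

draw_clinical <- function(sg, n, cp) {
  out <- data.frame(row.names = seq_len(n))
  for (v in names(cp$normal)) {
    pars <- cp$normal[[v]]
    out[[v]] <- if (sg %in% rownames(pars)) {
      pmax(stats::rnorm(n, pars[sg, 1L], pars[sg, 2L]), 0)
    } else NA_real_
  }
  for (v in names(cp$logistic)) {
    pars <- cp$logistic[[v]]
    out[[v]] <- if (sg %in% rownames(pars)) {
      s <- (pars[sg, 3L] - pars[sg, 2L]) / (2 * log(3))
      pmax(stats::rlogis(n, location = pars[sg, 1L], scale = s), 0)
    } else NA_real_
  }
  out$sex <- ifelse(stats::runif(n) < cp$sex_male[[sg]], "M", "F")
  out$nyha <- if (sg %in% rownames(cp$nyha)) {
    sample(c("I", "II", "III", "IV"), n, replace = TRUE, prob = cp$nyha[sg, ])
  } else NA_character_
  out$familial <- if (sg %in% rownames(cp$familial)) {
    sample(c("familial", "sporadic", "unknown"), n, replace = TRUE,
           prob = cp$familial[sg, ])
  } else NA_character_
  out
}

#' Simulate a full cohort with ground truth
#'
#' Simulates the variant pool, the patient roster with per-subgroup
#' clinical covariates, and per-patient carriage. Case patients draw, for
#' each latent class, a Poisson number of distinct analysis-set variants of
#' that class at the configured per-patient rate, so the expected
#' molecular-burden table matches the configuration. Control individuals
#' draw from the control-observed subset; the union of their carried ids is
#' the control-observed id set the filtering cascade subtracts.
#'
#' @param config A `vt_sim_config`.
#' @param seed Optional override of `config$seed`; `NULL` leaves the RNG
#'   state untouched.
#' @return List with `cohort` (a `vt_cohort`), `ledger` (per-variant ground
#'   truth), `control_ids` (variant ids observed in the control arm) and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  pool <- simulate_variant_pool(config, seed = NULL)
  led <- pool$ledger
  cp <- config$clinical_params

  analysis_ids <- split(led$variant_id[led$in_analysis_set],
                        led$latent_class[led$in_analysis_set])
  kcg_ids <- led$variant_id[led$kcg_observed]
  hgmd_ids <- pool$variants$variant_id[!is.na(pool$variants$hgmd_id)]
  carriage_weight <- function(ids) {
    ifelse(ids %in% hgmd_ids, config$hgmd_carriage_weight %||% 1, 1)
  }

  patients <- list(); geno <- list()
  prefix <- c(CHD_VT = "CHD", DCM_VT = "DCM", iVT = "IVT", CONTROL = "CTL")
  for (sg in SUBGROUPS) {
    n <- config$n_per_subgroup[[sg]]
    ids <- sprintf("%s%03d", prefix[[sg]], seq_len(n))
    p <- cbind(data.frame(patient_id = ids, subgroup = sg,
                          stringsAsFactors = FALSE),
               draw_clinical(sg, n, cp))
    patients[[sg]] <- p
    for (i in seq_len(n)) {
      carried <- character()
      if (sg == "CONTROL") {
        if (length(kcg_ids) > 0) {
          k <- min(stats::rpois(1L, config$control_carrier_rate),
                   length(kcg_ids))
          if (k > 0) carried <- sample(kcg_ids, k)
        }
      } else {
        for (cls in PATHO_CLASSES) {
          pool_k <- analysis_ids[[cls]] %||% character()
          rate <- config$carrier_rate[sg, cls]
          if (rate <= 0 || length(pool_k) == 0) next
          k <- min(stats::rpois(1L, rate), length(pool_k))
          if (k > 0) {
            carried <- c(carried,
                         sample(pool_k, k, prob = carriage_weight(pool_k)))
          }
        }
      }
      if (length(carried) > 0) {
        geno[[length(geno) + 1L]] <- data.frame(
          patient_id = ids[i], variant_id = carried,
          zygosity = ifelse(stats::runif(length(carried)) < 0.95,
                            "het", "hom"),
          stringsAsFactors = FALSE)
      }
    }
  }
  patients <- do.call(rbind, patients)
  rownames(patients) <- NULL
  genotypes <- if (length(geno) > 0) do.call(rbind, geno) else
    data.frame(patient_id = character(), variant_id = character(),
               zygosity = character(), stringsAsFactors = FALSE)
  rownames(genotypes) <- NULL
  ctl_pat <- patients$patient_id[patients$subgroup == "CONTROL"]
  control_ids <- sort(unique(
    genotypes$variant_id[genotypes$patient_id %in% ctl_pat]))
  list(cohort = cohort(pool$variants, patients, genotypes),
       ledger = led, control_ids = control_ids, config = config)
}

#' Write a simulated cohort plus ground-truth ledger to disk
#'
#' Emits the three cohort tables (variant TSV, patient CSV, genotype CSV)
#' plus `ledger.tsv` and `control_ids.txt`.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory.
#' @return Named vector of file paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  paths <- write_cohort(sim$cohort, dir)
  lp <- file.path(dir, "ledger.tsv")
  utils::write.table(sim$ledger, lp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cp <- file.path(dir, "control_ids.txt")
  writeLines(sim$control_ids, cp)
  invisible(c(paths, ledger = lp, control_ids = cp))
}
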