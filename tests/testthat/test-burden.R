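test_that("burden rows reproduce hand-computed carrier arithmetic", {
  # 23 patients, 10 positives holding 13 class-I instances
  co <- cohort_from_layout(table3_layout["CHD_VT"])
  cl <- classify_variants(co$variants)
  bt <- burden_table(co, cl, subgroups = "CHD_VT")
  r1 <- bt[bt$class_threshold == "I", ]
  expect_equal(r1$n_positive, 10)
  expect_equal(r1$pct_positive, 43.5)
  expect_equal(r1$cumulative_variants, 13)
  expect_equal(r1$variants_per_positive, 1.3)
  expect_equal(r1$pct_of_all_variants, 11.8)  # denominator: all 110 instances
})

test_that("no carriers means zero positives and undefined variants-per-positive", {
  v <- make_variants(4, pred = PRED_FOR_CLASS)
  p <- make_patients(c("a", "b"), c("CHD_VT", "iVT"))
  g <- data.frame(patient_id = character(), variant_id = character(),
                  zygosity = character())
  bt <- suppressWarnings(burden_table(cohort(v, p, g), classify_variants(v)))
  expect_true(all(bt$n_positive == 0))
  expect_true(all(is.na(bt$variants_per_positive)))
})

test_that("burden equals a naive per-patient double-loop recount", {
  sim <- simulate_cohort(small_config(seed = 29))
  cl <- classify_variants(sim$cohort$variants)
  bt <- burden_table(sim$cohort, cl)
  cls_of <- setNames(as.character(cl$class), cl$variant_id)
  sev <- c(I = 1, II = 2, III = 3, IV = 4)
  thresholds <- c("I" = 1, "I/II" = 2, "I/II/III" = 3)
  for (row in seq_len(nrow(bt))) {
    sg <- bt$subgroup[row]; th <- thresholds[[bt$class_threshold[row]]]
    pats <- sim$cohort$patients$patient_id[sim$cohort$patients$subgroup == sg]
    n_pos <- 0L; cum <- 0L
    for (p in pats) {
      carried <- sim$cohort$genotypes$variant_id[
        sim$cohort$genotypes$patient_id == p]
      qual <- sum(sev[cls_of[carried]] <= th)
      if (qual > 0) n_pos <- n_pos + 1L
      cum <- cum + qual
    }
    expect_equal(bt$n_positive[row], n_pos)
    expect_equal(bt$cumulative_variants[row], cum)
  }
})

test_that("widening the class threshold never decreases burden", {
  sim <- simulate_cohort(small_config(seed = 31))
  cl <- classify_variants(sim$cohort$variants)
  bt <- burden_table(sim$cohort, cl)
  for (sg in unique(bt$subgroup)) {
    r <- bt[bt$subgroup == sg, ]
    expect_true(all(diff(r$n_positive) >= 0))
    expect_true(all(diff(r$cumulative_variants) >= 0))
  }
})

test_that("HGMD carrier fractions match per-patient recount", {
  v <- make_variants(4, pred = PRED_FOR_CLASS,
                     hgmd_id = c("CM000001", NA, "CM000002", NA))
  p <- make_patients(sprintf("p%d", 1:3), rep("CHD_VT", 3))
  g <- data.frame(patient_id = c("p1", "p2", "p3"),
                  variant_id = c("v0001", "v0003", "v0002"),
                  zygosity = "het", stringsAsFactors = FALSE)
  ht <- hgmd_carrier_table(cohort(v, p, g), classify_variants(v),
                           subgroups = "CHD_VT")
  expect_equal(ht$carriers$n_carriers, 2)   # p3 carries only a non-HGMD variant
  expect_equal(ht$carriers$pct_carriers, 66.7)
  expect_equal(ht$class_split$n, c(1, 0, 1, 0))

  sim <- simulate_cohort(small_config(seed = 37))
  cl <- classify_variants(sim$cohort$variants)
  ht <- hgmd_carrier_table(sim$cohort, cl)
  hgmd_ids <- cl$variant_id[!is.na(cl$hgmd_id)]
  for (row in seq_len(nrow(ht$carriers))) {
    sg <- ht$carriers$subgroup[row]
    pats <- sim$cohort$patients$patient_id[sim$cohort$patients$subgroup == sg]
    brute <- sum(vapply(pats, function(p) {
      any(sim$cohort$genotypes$variant_id[
        sim$cohort$genotypes$patient_id == p] %in% hgmd_ids)
    }, logical(1)))
    expect_equal(ht$carriers$n_carriers[row], brute)
  }
})

test_that("category table computes row percentages and conserves totals", {
  # one gene per category, ion-flux row with counts (12, 7, 18, 2)
  counts <- c(I = 12, II = 7, III = 18, IV = 2)
  v <- make_variants(sum(counts), gene = "KCNQ1",
                     pred = rep(PRED_FOR_CLASS, counts))
  cmap <- c(KCNQ1 = "ion_flux")
  tab <- category_distribution(classify_variants(v), cmap)
  r <- tab[tab$category == "ion_flux", ]
  expect_equal(c(r$n_I, r$n_II, r$n_III, r$n_IV), unname(counts))
  expect_equal(c(r$pct_I, r$pct_II, r$pct_III, r$pct_IV),
               c(30.8, 17.9, 46.2, 5.1))
  expect_equal(sum(tab$total), nrow(v))

  v_single <- make_variants(3, gene = "MYH7", pred = PRED_FOR_CLASS[["I"]])
  tab2 <- category_distribution(classify_variants(v_single),
                                c(MYH7 = "sarcomere"))
  expect_equal(tab2$pct_I[tab2$category == "sarcomere"], 100.0)

  expect_error(category_distribution(classify_variants(v_single),
                                     c(OTHER = "nucleus")),
               "MYH7", class = "vt_config_error")
})

test_that("category table matches a brute-force group-by on a synthetic pool", {
  sim <- simulate_cohort(small_config(seed = 41))
  cl <- classify_variants(sim$cohort$variants)
  genes <- unique(cl$gene)
  cmap <- setNames(rep(GENE_CATEGORIES, length.out = length(genes)), genes)
  tab <- category_distribution(cl, cmap)
  for (cat in GENE_CATEGORIES) {
    for (k in PATHO_CLASSES) {
      brute <- sum(cmap[cl$gene] == cat & as.character(cl$class) == k)
      expect_equal(tab[[paste0("n_", k)]][tab$category == cat], brute)
    }
  }
})

test_that("per-gene carrier frequency divides carriers by subgroup size", {
  v <- make_variants(2, gene = "LAMA2", pred = PRED_FOR_CLASS[["I"]],
                     hgmd_id = c("CM000009", NA))
  p <- make_patients(sprintf("d%02d", 1:32), rep("DCM_VT", 32))
  g <- data.frame(patient_id = sprintf("d%02d", 1:11),
                  variant_id = rep("v0001", 11),
                  zygosity = "het", stringsAsFactors = FALSE)
  gf <- gene_frequency_table(cohort(v, p, g), classify_variants(v),
                             subgroups = "DCM_VT")
  expect_equal(gf$pct_DCM_VT[gf$gene == "LAMA2"], 34.4)  # 11/32
  # hgmd_only mode ignores carriage of the unflagged variant
  g2 <- rbind(g, data.frame(patient_id = "d20", variant_id = "v0002",
                            zygosity = "het"))
  gf2 <- gene_frequency_table(cohort(v, p, g2), classify_variants(v),
                              mode = "hgmd_only", subgroups = "DCM_VT")
  expect_equal(gf2$n_DCM_VT[gf2$gene == "LAMA2"], 11)
  gf3 <- gene_frequency_table(cohort(v, p, g2), classify_variants(v),
                              mode = "hgmd_plus", subgroups = "DCM_VT")
  expect_equal(gf3$n_DCM_VT[gf3$gene == "LAMA2"], 12)
})
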