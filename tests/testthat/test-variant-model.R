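test_that("variant table construction validates schema and invariants", {
  v <- make_variants(3, gene = c("A1", "B2", "C3"))
  expect_s3_class(v, "vt_variants")
  expect_equal(v$gene, c("A1", "B2", "C3"))

  expect_error(variant_table(data.frame(variant_id = "x")),
               class = "vt_schema_error")
  expect_error(make_variants(2, ids = c("dup", "dup")),
               class = "vt_integrity_error")
  expect_error(make_variants(1, effect = "missense"),
               class = "vt_schema_error")
  expect_error(make_variants(1, af_1000g = 1.5), class = "vt_schema_error")
  expect_error(make_variants(1, pred = "DDDD"), class = "vt_schema_error")
})

test_that("absent annotations stay distinct from zero through TSV round-trip", {
  v <- make_variants(3, af_esp6500 = c(NA, 0, 0.004),
                     af_1000g = c(0.001, NA, NA),
                     hgmd_id = c("CM000001", NA, NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, path, "tsv")
  back <- read_variant_table(path, "tsv")
  expect_true(is.na(back$af_esp6500[1]))
  expect_identical(back$af_esp6500[2], 0)     # observed zero survives as 0
  expect_identical(back$af_1000g, v$af_1000g)
  expect_identical(back$hgmd_id, v$hgmd_id)
})

test_that("generated 500-row table round-trips identically through TSV and VCF", {
  pool <- simulate_variant_pool(sim_config(n_raw_variants = 500L, seed = 11))
  v <- pool$variants
  for (dialect in c("tsv", "vcf")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_variant_table(v, path, dialect)
    back <- read_variant_table(path, dialect)
    expect_equal(back$variant_id, v$variant_id)
    expect_equal(back$pos, v$pos)
    expect_equal(back$af_esp6500, v$af_esp6500, tolerance = 1e-12)
    expect_equal(back$af_exac, v$af_exac, tolerance = 1e-12)
    expect_identical(back$dbsnp130, v$dbsnp130)
    expect_identical(back$pred, v$pred)
    expect_identical(back$effect, v$effect)
    expect_identical(back$hgmd_id, v$hgmd_id)
    # idempotent: second read equal to first
    expect_identical(read_variant_table(path, dialect), back)
  }
})

test_that("unparsable frequency reports the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tchrom\tpos\tref\talt\tgene\teffect\tpred\taf_1000g",
               "v1\t1\t10\tA\tG\tX\tnonsynonymous_snv\tTTTTTTTTTT\toops"),
             path)
  expect_error(read_variant_table(path, "tsv"), "af_1000g",
               class = "vt_parse_error")
})

test_that("indels are left-normalized on ingest", {
  v <- variant_table(data.frame(
    variant_id = c("i1", "i2"), chrom = "1", pos = c(100L, 200L),
    ref = c("CTT", "ACGT"), alt = c("CT", "AT"), gene = "G",
    effect = "frameshift_indel", pred = "TTTTTTTTTT",
    stringsAsFactors = FALSE))
  expect_equal(v$ref[1], "CT"); expect_equal(v$alt[1], "C")
  expect_equal(v$pos[1], 100L)
  expect_equal(v$ref[2], "ACG"); expect_equal(v$alt[2], "A")
})

test_that("cohort assembly cross-links and counts carriage", {
  v <- make_variants(10)
  p <- make_patients(sprintf("p%02d", 1:5), c("CHD_VT", "DCM_VT", "iVT",
                                              "iVT", "CONTROL"))
  g <- data.frame(patient_id = rep(p$patient_id, c(3, 3, 3, 2, 1)),
                  variant_id = v$variant_id[c(1:3, 2:4, 5:7, 8:9, 10)],
                  zygosity = "het", stringsAsFactors = FALSE)
  co <- cohort(v, p, g)
  expect_equal(nrow(co$genotypes), 12)

  empty <- cohort(v, p, g[0, ])
  expect_equal(nrow(empty$genotypes), 0)

  g_bad <- g; g_bad$variant_id[1] <- "ghost"
  expect_error(cohort(v, p, g_bad), "ghost", class = "vt_integrity_error")
  p_bad <- p; p_bad$subgroup[1] <- "HCM"
  expect_error(cohort(v, p_bad, g), class = "vt_schema_error")
})

test_that("a simulated cohort round-trips through disk with equal burden tables", {
  sim <- simulate_cohort(small_config(seed = 3))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  back <- read_cohort(file.path(dir, "variants.tsv"),
                      file.path(dir, "patients.csv"),
                      file.path(dir, "genotypes.csv"))
  cl <- classify_variants(sim$cohort$variants)
  expect_equal(burden_table(back, cl), burden_table(sim$cohort, cl))
})

test_that("validate_cohort reports exactly the injected violations", {
  sim <- simulate_cohort(small_config(seed = 5))
  co <- sim$cohort
  expect_equal(nrow(validate_cohort(co)), 0)

  # fault injection with a known answer list
  co$patients$lvef[2] <- -5
  co$variants$af_exac[7] <- 1.5
  co$variants$effect[9] <- "weird"
  injected <- c(co$patients$patient_id[2], co$variants$variant_id[7],
                co$variants$variant_id[9])
  rep <- validate_cohort(co)
  expect_equal(nrow(rep), 3)
  expect_setequal(rep$record, injected)
  expect_setequal(rep$field, c("lvef", "af_exac", "effect"))
})

test_that("gene-category map reader enforces the closed vocabulary", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tcategory", "MYH7\tsarcomere", "KCNQ1\tion_flux"), path)
  m <- read_gene_categories(path)
  expect_identical(unname(m["MYH7"]), "sarcomere")
  writeLines(c("gene\tcategory", "MYH7\tmuscle"), path)
  expect_error(read_gene_categories(path), class = "vt_schema_error")
})
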