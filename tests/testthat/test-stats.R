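test_that("normality gate separates normal from heavy-tailed samples", {
  expect_error(normality_gate(c(1, 2)), class = "vt_data_error")
  expect_error(normality_gate(rep(3, 10)), class = "vt_data_error")

  set.seed(53)
  heavy <- c(rnorm(180), rcauchy(20, scale = 20))  # contaminated mixture
  expect_equal(normality_gate(heavy)$decision, "non_normal")

  # calibration: standard normal draws pass the gate in >= 90% of seeds
  passes <- vapply(1:60, function(s) {
    set.seed(s)
    normality_gate(rnorm(5000))$decision == "normal"
  }, logical(1))
  expect_gte(mean(passes), 0.9)
})

test_that("identical groups give H = 0, p = 1 and all adjusted p = 1", {
  res <- kruskal_wallis_pairwise(rep(c(1, 2, 3), 3),
                                 rep(c("a", "b", "c"), each = 3))
  expect_equal(res$H, 0)
  expect_equal(res$p, 1)
  expect_true(all(res$pairwise$p_adj == 1))
})

test_that("H statistic matches exhaustive permutation enumeration", {
  # two groups {1,2,3} vs {4,5,6}: enumerate all 20 assignments
  vals <- 1:6
  obs <- kruskal_wallis_pairwise(vals, rep(c("g1", "g2"), each = 3))
  h_of <- function(sel) {
    r <- rank(vals)
    R1 <- sum(r[sel]); R2 <- sum(r[-sel])
    12 / (6 * 7) * (R1^2 / 3 + R2^2 / 3) - 3 * 7
  }
  combos <- combn(6, 3)
  h_all <- apply(combos, 2, h_of)
  expect_equal(obs$H, h_of(1:3))
  # chi-square reference p as the implementation documents
  expect_equal(obs$p, pchisq(obs$H, df = 1, lower.tail = FALSE))
  # the exact permutation p for this extreme split is 2/20
  expect_equal(mean(h_all >= obs$H - 1e-12), 0.1)
})

test_that("group of size below two is rejected by name", {
  expect_error(
    kruskal_wallis_pairwise(c(1, 2, 3, 4), c("a", "a", "a", "b")),
    "b", class = "vt_data_error")
})

test_that("Bonferroni adjustment is min(1, m * p) and never below raw p", {
  set.seed(59)
  vals <- rnorm(60)
  grp <- rep(c("x", "y", "z", "w"), each = 15)
  res <- kruskal_wallis_pairwise(vals, grp)
  m <- choose(4, 2)
  expect_equal(nrow(res$pairwise), m)
  expect_equal(res$pairwise$p_adj, pmin(1, m * res$pairwise$p))
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p))
})

test_that("simulated cohorts separate ejection fraction of iVT from both structural arms", {
  # power check at the default clinical parameterization
  hits <- 0L; n_rep <- 20L
  for (s in seq_len(n_rep)) {
    sim <- simulate_cohort(sim_config(n_raw_variants = 50L, seed = 100 + s))
    cases <- sim$cohort$patients[sim$cohort$patients$subgroup != "CONTROL", ]
    res <- kruskal_wallis_pairwise(cases$lvef, cases$subgroup)
    pw <- res$pairwise
    ivt <- grepl("iVT", pw$group1) | grepl("iVT", pw$group2)
    if (all(pw$p_adj[ivt] < 0.05)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("carrier test selects Fisher under the expected-count rule", {
  perfect <- carrier_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(perfect$p, 1.0)

  small <- carrier_test(matrix(c(3, 1, 20, 31), 2))
  expect_equal(small$test, "fisher")
  large <- carrier_test(matrix(c(50, 50, 50, 50), 2) * 10)
  expect_equal(large$test, "chisq")

  # 2x3 tables always use chi-square
  expect_equal(carrier_test(matrix(c(3, 1, 2, 4, 9, 2), 2))$test, "chisq")
  expect_error(carrier_test(matrix(c(0, 0, 3, 4), 2)),
               class = "vt_data_error")
  expect_error(carrier_test(matrix(c(-1, 2, 3, 4), 2)),
               class = "vt_data_error")
})

test_that("Fisher p equals hypergeometric tail enumeration on sample tables", {
  # two-sided by point-probability summation, written out independently
  fisher_oracle <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p_obs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tabs <- list(matrix(c(3, 1, 20, 31), 2), matrix(c(1, 9, 11, 2), 2),
               matrix(c(0, 5, 6, 2), 2), matrix(c(2, 2, 2, 2), 2))
  for (tab in tabs) {
    res <- carrier_test(tab)
    expect_equal(res$test, "fisher")
    expect_equal(res$p, fisher_oracle(tab), tolerance = 1e-10)
  }
})

test_that("percent reproduces printed table cells and guards division by zero", {
  expect_equal(percent(10, 23), 43.5)
  expect_equal(percent(36, 37), 97.3)
  expect_equal(percent(0, 7), 0.0)
  expect_true(is.na(percent(3, 0)))
  expect_equal(percent(c(1, 1), c(3, 0)), c(33.3, NA))
  expect_equal(round_half_up(2.675, 2), 2.68)  # true half-up, not banker's
  expect_equal(round_half_up(0.125, 2), 0.13)
})

test_that("report assembly is structurally complete and deterministic", {
  sim <- simulate_cohort(small_config(seed = 61))
  genes <- unique(sim$cohort$variants$gene)
  cmap <- setNames(rep(GENE_CATEGORIES, length.out = length(genes)), genes)
  rep1 <- build_report(sim$cohort, sim$control_ids, category_map = cmap,
                       seed = 61)
  expect_s3_class(rep1, "vt_report")
  expect_equal(nrow(rep1$burden), 9)  # 3 subgroups x 3 thresholds

  sim2 <- simulate_cohort(small_config(seed = 61))
  rep2 <- build_report(sim2$cohort, sim2$control_ids, category_map = cmap,
                       seed = 61)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(rep1, d1); write_report(rep2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }

  # report percentages re-derive from report integers
  expect_equal(rep1$acmg$pct, percent(rep1$acmg$n, sum(rep1$acmg$n)))
  expect_equal(rep1$burden$pct_positive,
               percent(rep1$burden$n_positive, rep1$burden$n_patients))
  expect_error(build_report(list()), class = "vt_assembly_error")
})
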