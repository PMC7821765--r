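#' Shapiro-Wilk normality gate
#'
#' Clinical covariates are summarized parametrically only when the
#' Shapiro-Wilk test does not reject normality at the 5% level
#' (p > 0.05 means normality is assumed); otherwise they are treated
#' nonparametrically (medians, quartiles, rank tests).
#'
#' @param x Numeric sample, `n >= 3`, not constant.
#' @return List with `decision` (`"normal"` or `"non_normal"`), `p`, `n`.
#' @export
normality_gate <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) {
    vt_stop("vt_data_error", "normality gate needs at least 3 observations")
  }
  if (stats::sd(x) == 0) {
    vt_stop("vt_data_error", "normality gate undefined for a constant sample")
  }
  # shapiro.test caps n at 5000; subsample deterministically above that
  if (length(x) > 5000L) x <- x[seq(1L, length(x), length.out = 5000L)]
  p <- stats::shapiro.test(x)$p.value
  list(decision = if (p > 0.05) "normal" else "non_normal", p = p,
       n = length(x))
}

# tie-corrected Dunn z statistic for groups i, j after a Kruskal-Wallis
# rank transform; returns two-sided p
dunn_pairwise_p <- function(ranks, groups) {
  N <- length(ranks)
  tie_tab <- table(ranks)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  res <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (r in seq_len(ncol(pairs))) {
    gi <- groups == pairs[1L, r]; gj <- groups == pairs[2L, r]
    ni <- sum(gi); nj <- sum(gj)
    num <- mean(ranks[gi]) - mean(ranks[gj])
    den <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni + 1 / nj))
    res$z[r] <- num / den
    res$p[r] <- 2 * stats::pnorm(-abs(res$z[r]))
  }
  res
}

#' Kruskal-Wallis test with Dunn pairwise post-hocs
#'
#' Overall tie-corrected Kruskal-Wallis H test (chi-square reference) with
#' all pairwise Dunn rank comparisons, Bonferroni-adjusted over the number
#' of pairs and capped at 1. Medians and quartiles (type-6 quantiles,
#' matching the convention of mainstream clinical statistics software) are
#' reported per group.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @param variable Optional variable name carried into the result.
#' @return Object of class `vt_grouptest`: list with `variable`, `summary`
#'   (per-group n/median/q25/q75), `H`, `df`, `p`, and `pairwise`
#'   (data.frame `group1`, `group2`, `z`, `p`, `p_adj`).
#' @export
kruskal_wallis_pairwise <- function(values, groups, variable = "value") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  tab <- table(groups)
  if (length(tab) < 2L) {
    vt_stop("vt_data_error", "need at least two groups")
  }
  small <- names(tab)[tab < 2L]
  if (length(small) > 0) {
    vt_stop("vt_data_error", "group(s) with fewer than 2 observations: %s",
            paste(small, collapse = ", "))
  }
  kw <- stats::kruskal.test(values, groups)
  ranks <- rank(values)
  pw <- dunn_pairwise_p(ranks, groups)
  m <- nrow(pw)
  pw$p_adj <- pmin(1, m * pw$p)
  qs <- t(vapply(levels(groups), function(g) {
    stats::quantile(values[groups == g], c(0.25, 0.5, 0.75), type = 6)
  }, numeric(3)))
  structure(list(
    variable = variable,
    summary = data.frame(group = levels(groups), n = as.integer(tab),
                         median = qs[, 2L], q25 = qs[, 1L], q75 = qs[, 3L],
                         stringsAsFactors = FALSE),
    H = unname(kw$statistic), df = unname(kw$parameter),
    p = kw$p.value, pairwise = pw
  ), class = "vt_grouptest")
}

#' @export
print.vt_grouptest <- function(x, ...) {
  cat("Kruskal-Wallis:", x$variable, "\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("H = %.3f, df = %d, p = %s\n", x$H, x$df, format_pvalue(x$p)))
  pw <- x$pairwise
  pw$p <- format_pvalue(pw$p); pw$p_adj <- format_pvalue(pw$p_adj)
  print(pw, row.names = FALSE)
  invisible(x)
}

#' Carrier-frequency contingency test
#'
#' Compares categorical carrier counts between groups. A 2x2 table with any
#' expected cell count below 5 is tested with the two-sided Fisher exact
#' test (point-probability summation); every other table uses the
#' chi-square test without continuity correction. Two-tailed p throughout.
#'
#' @param tab Integer matrix (2x2 or 2xk) of nonnegative counts.
#' @return List with `p`, `test` (`"fisher"` or `"chisq"`), `expected`
#'   (matrix of expected counts).
#' @export
carrier_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    vt_stop("vt_data_error", "counts must be nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    vt_stop("vt_data_error", "degenerate table: zero row or column margin")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- all(dim(tab) == c(2L, 2L)) && any(expected < 5)
  if (use_fisher) {
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    list(p = min(p, 1), test = "fisher", expected = expected)
  } else {
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    list(p = p, test = "chisq", expected = expected)
  }
}
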