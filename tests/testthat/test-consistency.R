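test_that("pearson correlation matches closed-form evaluation", {
  x <- c(1, 2, 3)
  expect_equal(pearson_cor(x, x * 2 + 1, min_pairs = 3), 1)
  expect_equal(pearson_cor(x, -x, min_pairs = 3), -1)
  # hand evaluation of the product-moment formula:
  # Sxy = 5, Sxx = 2, Syy = 114/9, rho = 15 / sqrt(228)
  expect_equal(pearson_cor(x, c(2, 4, 7), min_pairs = 3), 15 / sqrt(228))
  expect_error(pearson_cor(1:3, 1:4), "equal length")
})

test_that("pearson is undefined below min_pairs or on constant input", {
  expect_true(is.na(pearson_cor(1:5, c(1, 2, NA, 4, 5), min_pairs = 5)))
  expect_true(is.na(pearson_cor(rep(1, 12), 1:12, min_pairs = 10)))
  expect_equal(pearson_cor(1:12, 12:1, min_pairs = 10), -1)
})

test_that("pearson is invariant to positive affine transforms", {
  set.seed(2)
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  r <- pearson_cor(x, y)
  expect_equal(pearson_cor(3 * x + 1, y), r)
  expect_equal(pearson_cor(x, 0.2 * y - 7), r)
})

test_that("cohen kappa matches the direct formula on the 40/10/10/40 table", {
  a <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  b <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  # p_o = 0.8, p_e = 0.5 -> kappa = 0.6
  expect_equal(cohen_kappa(a, b), 0.6)
  v <- rep(c(0, 1), 8)
  expect_equal(cohen_kappa(v, v), 1)
  expect_true(is.na(cohen_kappa(rep(1, 20), rep(1, 20))))
  expect_error(cohen_kappa(c(0, 2), c(0, 1)), "binary")
})

test_that("cohen kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(4)
  for (i in 1:10) {
    a <- stats::rbinom(60, 1, stats::runif(1, 0.2, 0.8))
    b <- ifelse(stats::rbinom(60, 1, 0.3), stats::rbinom(60, 1, 0.5), a)
    tab <- table(factor(a, 0:1), factor(b, 0:1))
    expect_equal(cohen_kappa(a, b), e1071::classAgreement(tab)$kappa)
  }
})

test_that("kappa is near zero for independent raters at any prevalence", {
  set.seed(6)
  for (prev in c(0.2, 0.5, 0.8)) {
    a <- stats::rbinom(1e4, 1, prev)
    b <- stats::rbinom(1e4, 1, prev)
    expect_lt(abs(cohen_kappa(a, b)), 0.05)
  }
})

test_that("kappa is invariant to swapping 0/1 labels in both raters", {
  set.seed(8)
  a <- stats::rbinom(50, 1, 0.4)
  b <- ifelse(stats::rbinom(50, 1, 0.4), 1 - a, a)
  expect_equal(cohen_kappa(1 - a, 1 - b), cohen_kappa(a, b))
})

test_that("agreement categories follow the stated thresholds", {
  out <- classify_agreement(data.frame(
    rho = c(0.57, 0.8, 0.5, 0.3, NA),
    kappa = c(0.45, 0.85, 0.6, 0.25, 0.1)))
  expect_identical(out$rho_category,
                   c("REASONABLE", "GOOD", "BELOW", "BELOW", NA))
  expect_identical(out$kappa_category,
                   c("MODERATE", "ALMOST_PERFECT", "SUBSTANTIAL", "FAIR",
                     "POOR"))
})

test_that("rank-sum test matches enumeration and handles identical input", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4), "less")
  expect_true(w$exact)
  expect_equal(w$p, 1 / 6)
  expect_equal(w$statistic, 3)  # ranks 1 + 2
  same <- wilcoxon_rank_sum(c(1, 2, 3, 3), c(3, 1, 2, 3), "two_sided")
  expect_gte(same$p, 0.99)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("exact and normal-approximation p agree on moderate samples", {
  set.seed(10)
  for (i in 1:10) {
    x <- stats::rnorm(8); y <- stats::rnorm(8, mean = stats::runif(1, 0, 1))
    p_exact <- wilcoxon_rank_sum(x, y, "two_sided")$p
    p_approx <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_approx), 0.05)
  }
})

test_that("per-entity reports summarize fractions over defined statistics", {
  n <- 20
  x <- matrix(rep(1:n, 15), n, 15,
              dimnames = list(sprintf("C%02d", 1:n), sprintf("D%02d", 1:15)))
  y <- x
  y[, 9:15] <- -x[, 9:15]  # 8 drugs at rho 1, 7 at rho -1
  rep <- consistency_from_matrices(x, y, axis = "cols")
  expect_equal(rep$summary$fraction_rho_gt_reasonable, 8 / 15)
  expect_equal(rep$summary$fraction_rho_ge_good, 8 / 15)
  expect_equal(rep$summary$n_rho_defined, 15)
  ident <- consistency_from_matrices(x + 0.0, x + 0.0, axis = "cols")
  expect_true(all(ident$results$rho == 1))
  expect_equal(ident$summary$fraction_rho_ge_good, 1)
})

test_that("paired-study consistency requires the datatype on both sides", {
  p <- simulation_params(n_cell_lines = 30, n_drugs = 3, n_genes = 4,
                         n_causal_pairs = 0, seed = 2)
  pair <- generate_pair(p)
  ps <- intersect_studies(pair$study_a, pair$study_b)
  ps$study_b$profiles$CNV <- NULL
  expect_error(per_entity_consistency(ps, "CNV"), "both studies")
})

test_that("noise-only pairs show no consistency", {
  p <- simulation_params(n_cell_lines = 400, n_drugs = 15, n_genes = 5,
                         n_causal_pairs = 0,
                         reliability = c(AUC = 0, IC50 = 0), seed = 31)
  pair <- generate_pair(p)
  ps <- intersect_studies(pair$study_a, pair$study_b)
  rep <- per_entity_consistency(ps, "AUC")
  expect_lt(abs(stats::median(rep$results$rho)), 2 / sqrt(400))
})

test_that("datatype comparison detects a consistency shift one-sided", {
  mk_report <- function(rho) structure(
    list(results = data.frame(entity_id = seq_along(rho), rho = rho,
                              kappa = NA_real_)),
    class = "consistency_report")
  genomic <- mk_report(c(0.9, 0.91, 0.89, 0.92, 0.9))
  pharm <- mk_report(c(0.3, 0.32, 0.28, 0.31, 0.3))
  out <- compare_datatype_consistency(genomic, pharm, "greater")
  expect_lt(out$p, 0.05)
  same <- compare_datatype_consistency(genomic, genomic, "greater")
  expect_gte(same$p, 0.5)
  expect_error(compare_datatype_consistency(mk_report(NA_real_), pharm),
               "no defined")
})

test_that("union of tests is monotone and labelled non-evidential", {
  mk_report <- function(rho) structure(
    list(results = data.frame(entity_id = paste0("d", seq_along(rho)),
                              rho = rho, kappa = NA_real_)),
    class = "consistency_report")
  r1 <- mk_report(c(0.9, 0.2, 0.6, 0.1, 0.4))
  r2 <- mk_report(c(0.1, 0.8, 0.3, 0.7, 0.2))
  u <- union_of_tests(list(auc = r1, ic50 = r2))
  expect_true(u$non_evidential)
  expect_gte(u$fraction_union, max(u$fraction_by_measure))
  expect_equal(u$fraction_union, 4 / 5)
  expect_equal(unname(u$fraction_by_measure), c(2 / 5, 2 / 5))
})
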