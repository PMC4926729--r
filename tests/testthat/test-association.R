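test_that("two-group association matches its closed form and the stats oracle", {
  r <- c(1, 2, 3, 7, 8, 9)
  g <- c(0, 0, 0, 1, 1, 1)
  out <- associate(r, g)
  expect_equal(out$effect, 6)
  tt <- stats::t.test(r[g == 1], r[g == 0], var.equal = TRUE)
  expect_equal(out$statistic, unname(tt$statistic))
  expect_equal(out$p, tt$p.value)
  # F = t^2: literally the one-way ANOVA on mutation status
  fv <- summary(stats::aov(r ~ factor(g)))[[1]]$`F value`[1]
  expect_equal(out$statistic^2, fv)
})

test_that("degenerate association inputs are flagged, not fabricated", {
  same <- associate(rep(c(1, 2, 3), 2), c(0, 0, 0, 1, 1, 1))
  expect_equal(same$effect, 0)
  expect_equal(same$p, 1)
  allmut <- associate(stats::rnorm(10), rep(1, 10))
  expect_false(allmut$defined)
  expect_true(is.na(allmut$p))
  expect_error(associate(1:4, c(0, 1, 2, 1)), "0, 1 or missing")
})

test_that("association p agrees with an exact permutation oracle", {
  set.seed(12)
  diffs <- replicate(20, {
    n <- 10
    g <- sample(rep(c(0, 1), each = n / 2))
    r <- stats::rnorm(n) + g * stats::runif(1, 0, 2)
    abs(associate(r, g)$p - perm_t_p(r, g))
  })
  # permutation granularity is 1/choose(10,5); gaussian-theory and
  # permutation p track each other well within it
  expect_lt(max(diffs), 0.1)
  expect_lt(mean(diffs), 0.03)
})

test_that("the vectorized screen equals the scalar test with missing data", {
  set.seed(13)
  n <- 40
  resp <- matrix(stats::rnorm(n * 4), n, 4,
                 dimnames = list(sprintf("C%02d", 1:n), sprintf("D%d", 1:4)))
  resp[sample(length(resp), 15)] <- NA
  mut <- stats::rbinom(n, 1, 0.3)
  mut[sample(n, 4)] <- NA
  fast <- pgxagree:::associate_gene(resp, mut, min_group = 3L)
  for (j in 1:4) {
    slow <- associate(resp[, j], mut, min_group = 3L)
    expect_equal(fast$effect[j], slow$effect)
    expect_equal(fast$statistic[j], slow$statistic)
    expect_equal(fast$p[j], slow$p)
    expect_equal(fast$n_mut[j], slow$n_mut)
  }
})

make_test_pair <- function(seed = 21, ...) {
  p <- simulation_params(n_cell_lines = 120, n_drugs = 6, n_genes = 8,
                         n_causal_pairs = 5, seed = seed, ...)
  pair <- generate_pair(p)
  intersect_studies(pair$study_a, pair$study_b)
}

test_that("design wiring is validated and auditable from the output", {
  ps <- make_test_pair()
  expect_error(design_spec("A", mutation_source = "study_a"), "own")
  expect_error(design_spec("B", mutation_source = "own"), "duplicates")
  expect_error(design_spec("C", measure_a = "AUC", measure_b = "AUC"),
               "different measures")
  scr_b <- run_association_screen(ps, design_spec("B"))
  expect_identical(unique(scr_b$study_a$mutation_source), "study_a")
  expect_identical(unique(scr_b$study_b$mutation_source), "study_a")
  scr_c <- run_association_screen(ps, design_spec("C"))
  expect_identical(unique(scr_c$study_a$measure), "IC50")
  expect_identical(unique(scr_c$study_b$measure), "AUC")
  scr_a <- run_association_screen(ps, design_spec("A"))
  expect_identical(unique(scr_a$study_a$mutation_source), "study_a")
  expect_identical(unique(scr_a$study_b$mutation_source), "study_b")
})

test_that("BH q-values are monotone in p-rank and bounded by 1", {
  ps <- make_test_pair(seed = 22)
  scr <- run_association_screen(ps, design_spec("A"))
  for (side in scr) {
    d <- side[side$defined, ]
    o <- order(d$p)
    expect_true(all(diff(d$q[o]) >= -1e-12))
    expect_true(all(d$q <= 1))
    expect_equal(d$q, stats::p.adjust(d$p, "BH"))
  }
})

test_that("identical studies yield identical association lists", {
  ps <- make_test_pair(seed = 23)
  ps$study_b <- ps$study_a
  scr <- run_association_screen(ps, design_spec("A"))
  expect_identical(scr$study_a$effect, scr$study_b$effect)
  conc <- biomarker_concordance(scr$study_a, scr$study_b)
  expect_equal(conc$effect_rho, 1)
  if (conc$n_hits_a > 0) expect_equal(conc$hit_kappa, 1)
})

test_that("independent effects show no biomarker concordance", {
  set.seed(30)
  n <- 400
  mk <- function() data.frame(
    gene = rep("g", n), drug = sprintf("d%03d", 1:n),
    effect = stats::rnorm(n), p = stats::runif(n),
    q = stats::runif(n), defined = TRUE)
  conc <- biomarker_concordance(mk(), mk(), sig_q = 0.5)
  expect_lt(abs(conc$effect_rho), 2 / sqrt(n))
  expect_lt(abs(conc$hit_kappa), 2 / sqrt(n))
  bad <- mk(); bad$defined <- FALSE
  expect_error(biomarker_concordance(bad, bad), "no .*defined")
})

test_that("design comparison is deterministic given the seed", {
  p <- simulation_params(n_cell_lines = 80, n_drugs = 5, n_genes = 6,
                         n_causal_pairs = 4)
  t1 <- run_design_comparison(p, n_reps = 2, seed = 9, designs = c("A", "B"))
  t2 <- run_design_comparison(p, n_reps = 2, seed = 9, designs = c("A", "B"))
  expect_identical(t1, t2)
  expect_setequal(unique(t1$design_id), c("A", "B"))
  expect_equal(nrow(t1), 4)
})
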