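test_that("parameter validation rejects out-of-range settings", {
  expect_error(simulation_params(mutation_prevalence = 1.2))
  expect_error(simulation_params(reliability = c(AUC = 1.5)))
  expect_error(simulation_params(n_genes = 2, n_drugs = 2,
                                 n_causal_pairs = 5))
  expect_error(simulation_params(ic50_max_conc = -1))
})

test_that("generation is fully determined by the seed", {
  p <- simulation_params(n_cell_lines = 40, n_drugs = 4, n_genes = 6,
                         n_causal_pairs = 3, seed = 99)
  a <- generate_pair(p)
  b <- generate_pair(p)
  expect_identical(a$study_a$sensitivity$AUC$values,
                   b$study_a$sensitivity$AUC$values)
  expect_identical(a$study_b$profiles$MUTATION$values,
                   b$study_b$profiles$MUTATION$values)
  expect_identical(a$truth$causal, b$truth$causal)
})

test_that("zero noise reproduces the latent truth through the links", {
  p <- simulation_params(n_cell_lines = 50, n_drugs = 4, n_genes = 6,
                         n_causal_pairs = 3,
                         reliability = c(AUC = 1, IC50 = 1, EXPRESSION = 1,
                                         CNV = 1),
                         mutation_flip_rate = 0, seed = 17)
  pair <- generate_pair(p)
  expect_identical(pair$study_a$profiles$MUTATION$values,
                   pair$truth$mutation)
  expect_identical(pair$study_b$profiles$MUTATION$values,
                   pair$truth$mutation)
  expect_equal(pair$study_a$sensitivity$AUC$values,
               pair$study_b$sensitivity$AUC$values)
  ps <- intersect_studies(pair$study_a, pair$study_b)
  rep <- per_entity_consistency(ps, "AUC")
  expect_equal(rep$results$rho, rep(1, 4))
})

test_that("observed mutation prevalence matches the flip arithmetic", {
  p <- simulation_params(n_cell_lines = 2000, n_drugs = 2, n_genes = 10,
                         n_causal_pairs = 0, mutation_prevalence = 0.2,
                         mutation_flip_rate = 0.1, seed = 41)
  pair <- generate_pair(p)
  obs <- mean(pair$study_a$profiles$MUTATION$values)
  expected <- 0.2 * 0.9 + 0.8 * 0.1
  n <- 2000 * 10
  expect_lt(abs(obs - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("flip rate one half destroys mutation agreement", {
  p <- simulation_params(n_cell_lines = 10000, n_drugs = 1, n_genes = 3,
                         n_causal_pairs = 0, mutation_flip_rate = 0.5,
                         seed = 43)
  pair <- generate_pair(p)
  for (g in rownames(pair$truth$mutation)) {
    k <- cohen_kappa(pair$study_a$profiles$MUTATION$values[g, ],
                     pair$study_b$profiles$MUTATION$values[g, ])
    expect_lt(abs(k), 0.05)
  }
})

test_that("the attenuation law gives the expected inter-study correlation", {
  expect_equal(expected_attenuation(1, 1), 1)
  expect_equal(expected_attenuation(0.64, 1), 0.8)
  expect_equal(expected_attenuation(0.5, 0.5), 0.5)
  expect_error(expected_attenuation(1.2, 0.5), "\\[0, 1\\]")
})

test_that("IC50 observations never exceed the censoring bound", {
  p <- simulation_params(n_cell_lines = 300, n_drugs = 5, n_genes = 4,
                         n_causal_pairs = 0, ic50_max_conc = 8, seed = 47)
  pair <- generate_pair(p)
  for (st in list(pair$study_a, pair$study_b)) {
    ic <- st$sensitivity$IC50
    expect_true(all(ic$values <= log10(8)))
    expect_true(any(ic$censored))  # bound actually binds somewhere
    expect_identical(unname(ic$values[ic$censored]),
                     rep(log10(8), sum(ic$censored)))
  }
})

test_that("fixtures round-trip bit-exactly and deterministically", {
  p <- simulation_params(n_cell_lines = 25, n_drugs = 3, n_genes = 4,
                         n_causal_pairs = 2, seed = 53)
  pair <- generate_pair(p)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(pair, d1)
  write_fixture(pair, d2)
  rel <- list.files(d1, recursive = TRUE)
  expect_identical(rel, list.files(d2, recursive = TRUE))
  for (f in rel)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  studies <- read_fixture(file.path(d1, "manifest.yaml"))
  expect_identical(studies$study_a$sensitivity$AUC$values,
                   pair$study_a$sensitivity$AUC$values)
  expect_identical(studies$study_b$sensitivity$IC50$values,
                   pair$study_b$sensitivity$IC50$values)
  expect_identical(studies$study_a$profiles$MUTATION$values,
                   pair$study_a$profiles$MUTATION$values)
  ps <- intersect_studies(studies$study_a, studies$study_b)
  expect_identical(ps$common_cell_lines,
                   rownames(pair$study_a$sensitivity$AUC$values))
})
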