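test_that("labels harmonize by uppercasing and stripping non-alphanumerics", {
  expect_identical(harmonize_label("MCF-7"), "MCF7")
  expect_identical(harmonize_label("NCI-H460"), "NCIH460")
  expect_identical(harmonize_label("t.t"), "TT")
  expect_identical(harmonize_label(c("a b", "A-b")), c("AB", "AB"))
  expect_error(harmonize_label(""), "empty")
  expect_error(harmonize_label("--!"), "empty")
})

test_that("sensitivity tables parse, convert IC50 to log10 and flag bad cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",d-1,d2", "MCF-7,0.5,0.25", "A549,,0.75", "SK-BR-3,1.0,0"),
             path)
  m <- read_sensitivity_table(path, "AUC", "gdsc")
  expect_identical(rownames(m$values), c("MCF7", "A549", "SKBR3"))
  expect_identical(colnames(m$values), c("D1", "D2"))
  expect_identical(sum(is.na(m$values)), 1L)
  expect_identical(m$values["A549", "D2"], 0.75)

  ic_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",d1", "x,10", "y,1", "z,0.1"), ic_path)
  ic <- read_sensitivity_table(ic_path, "IC50")
  expect_equal(unname(ic$values[, 1]), c(1, 0, -1))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",d1", "x,0.5", "y,oops"), bad)
  err <- tryCatch(read_sensitivity_table(bad, "AUC"), error = identity)
  expect_match(conditionMessage(err), "non-numeric cell")
  expect_match(conditionMessage(err), "y")
  expect_match(conditionMessage(err), "d1")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",d1", "MCF-7,0.5", "MCF7,0.6"), dup)
  expect_error(read_sensitivity_table(dup, "AUC"), "duplicate")
})

test_that("headers with and without a corner cell read identically", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",d1,d2", "x,0.1,0.2", "y,0.3,0.4"), p1)
  writeLines(c("d1,d2", "x,0.1,0.2", "y,0.3,0.4"), p2)
  expect_identical(read_sensitivity_table(p1, "AUC")$values,
                   read_sensitivity_table(p2, "AUC")$values)
})

test_that("AUC range and mutation coding are validated", {
  expect_error(toy_sensitivity(matrix(c(0.2, 1.4), 2, 1)), "\\[0, 1\\]")
  expect_error(
    molecular_profile(matrix(c(0, 2), 1, 2,
                             dimnames = list("g1", c("c1", "c2"))),
                      "MUTATION"),
    "0, 1 or missing")
})

test_that("IC50 values above the tested range are censored at the bound", {
  m <- toy_sensitivity(matrix(c(0.2, 1.5, log10(8)), 3, 1), "IC50",
                       ic50_max_conc = 8)
  expect_true(all(m$values <= log10(8)))
  expect_identical(unname(m$censored[, 1]), c(FALSE, TRUE, FALSE))
  expect_identical(m$values[2, 1], log10(8))
})

test_that("intersection keeps exactly the common labels and reports drops", {
  mk <- function(cells, drugs, id)
    study_collection(toy_sensitivity(
      matrix(stats::runif(length(cells) * length(drugs)),
             length(cells), length(drugs)),
      study_id = id, cells = cells, drugs = drugs))
  set.seed(1)
  a <- mk(c("X", "Y", "Z"), c("D1", "D2"), "a")
  b <- mk(c("Y", "Z", "W"), c("D2", "D3"), "b")
  p <- intersect_studies(a, b)
  expect_identical(p$common_cell_lines, c("Y", "Z"))
  expect_identical(p$common_drugs, "D2")
  expect_identical(p$dropped$cell_lines_a, 1L)
  expect_identical(p$dropped$drugs_b, 1L)
  # symmetry of the common sets
  q <- intersect_studies(b, a)
  expect_setequal(q$common_cell_lines, p$common_cell_lines)
  expect_setequal(q$common_drugs, p$common_drugs)
  # idempotence
  r <- intersect_studies(p$study_a, p$study_b)
  expect_identical(r$study_a$sensitivity$AUC$values,
                   p$study_a$sensitivity$AUC$values)
  expect_identical(r$common_cell_lines, p$common_cell_lines)
  # degenerate overlaps
  c2 <- mk(c("Q", "R"), "D1", "c")
  expect_error(intersect_studies(a, c2), "fewer than 2")
})

test_that("write/read round trip is bit-exact with label order preserved", {
  set.seed(42)
  vals <- matrix(stats::runif(12), 4, 3)
  vals[2, 3] <- NA
  m <- toy_sensitivity(vals, "AUC", "a")
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_table(m, path)
  back <- read_sensitivity_table(path, "AUC", "a")
  expect_identical(back$values, m$values)

  prof <- molecular_profile(
    matrix(stats::rnorm(6), 2, 3,
           dimnames = list(c("G1", "G2"), c("C1", "C2", "C3"))),
    "EXPRESSION", "a")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_study_table(prof, p2)
  expect_identical(read_profile_table(p2, "EXPRESSION", "a")$values,
                   prof$values)
})
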