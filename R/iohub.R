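#' Harmonize a cell-line, drug or gene identifier
#'
#' Cross-study matching of cell-line names is notoriously inconsistent
#' ("MCF-7" vs "MCF7", "NCI-H460" vs "NCIH460"). Labels are harmonized by
#' uppercasing and stripping every non-alphanumeric character; matching across
#' studies is then exact on the harmonized form. No synonym tables or fuzzy
#' matching are applied.
#'
#' @param raw Character vector of raw labels.
#' @return Character vector of harmonized labels.
#' @examples
#' harmonize_label(c("MCF-7", "NCI-H460", "t.t"))
#' @export
harmonize_label <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  if (length(raw) == 0L) stop("no labels supplied")
  if (anyNA(raw) || any(!nzchar(raw))) stop("empty label cannot be harmonized")
  out <- toupper(gsub("[^A-Za-z0-9]", "", raw))
  bad <- !nzchar(out)
  if (any(bad)) {
    stop("label(s) reduce to empty after harmonization: ",
         paste(sQuote(raw[bad]), collapse = ", "))
  }
  out
}

#' @keywords internal
#' @noRd
harmonize_dimnames <- function(values, what = c("rows", "cols")) {
  for (w in what) {
    d <- if (w == "rows") 1L else 2L
    labs <- dimnames(values)[[d]]
    if (is.null(labs)) stop("matrix lacks ", w, " labels")
    h <- harmonize_label(labs)
    dup <- unique(h[duplicated(h)])
    if (length(dup)) {
      coll <- vapply(dup, function(x)
        paste(sQuote(labs[h == x]), collapse = " / "), character(1))
      stop("duplicate labels after harmonization: ",
           paste(paste0(dup, " <- {", coll, "}"), collapse = "; "))
    }
    dimnames(values)[[d]] <- h
  }
  values
}

#' Construct a drug-sensitivity matrix
#'
#' A `sensitivity_matrix` stores one study's response summaries as cell lines
#' (rows) by drugs (columns). Two measures are supported: `"AUC"`, the
#' activity-area convention (dimensionless fraction in \[0, 1\], higher values
#' meaning greater sensitivity), and `"IC50"`, stored on the log10 micromolar
#' scale. When `ic50_max_conc` is given, IC50 values above the tested
#' concentration range are censored: set to `log10(ic50_max_conc)` and flagged
#' in the `"censored"` attribute rather than dropped.
#'
#' @param values Numeric matrix, cell lines x drugs, with dimnames. For IC50
#'   the values must already be log10(micromolar); [read_sensitivity_table()]
#'   converts from micromolar on read.
#' @param measure `"AUC"` or `"IC50"`.
#' @param study_id Label identifying the study.
#' @param ic50_max_conc Optional censoring bound in micromolar (e.g. 8 for a
#'   screen whose tested range tops out at 8 uM).
#' @param harmonize Harmonize row/column labels (default `TRUE`).
#' @return An object of class `sensitivity_matrix`.
#' @export
sensitivity_matrix <- function(values, measure = c("AUC", "IC50"),
                               study_id = "study", ic50_max_conc = NULL,
                               harmonize = TRUE) {
  measure <- match.arg(measure)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (harmonize) values <- harmonize_dimnames(values, c("rows", "cols"))
  censored <- NULL
  if (measure == "AUC") {
    rng <- range(values, na.rm = !all(is.na(values)))
    if (!all(is.na(values)) && (rng[1] < 0 || rng[2] > 1))
      stop("AUC values must lie in [0, 1]")
    ic50_max_conc <- NULL
  } else if (!is.null(ic50_max_conc)) {
    stopifnot(is.numeric(ic50_max_conc), ic50_max_conc > 0)
    bound <- log10(ic50_max_conc)
    censored <- !is.na(values) & values > bound
    values[censored] <- bound
  }
  structure(
    list(study_id = as.character(study_id), measure = measure,
         values = values, ic50_max_conc = ic50_max_conc,
         censored = censored),
    class = "sensitivity_matrix")
}

#' Construct a molecular-profile matrix
#'
#' Genes (rows) by cell lines (columns) for one study and one data type.
#' `EXPRESSION` and `CNV` are continuous; `MUTATION` is binary
#' (0 = wild-type, 1 = mutant, `NA` = not assayed).
#'
#' @param values Numeric matrix, genes x cell lines, with dimnames.
#' @param datatype `"EXPRESSION"`, `"CNV"` or `"MUTATION"`.
#' @param study_id Label identifying the study.
#' @param harmonize Harmonize labels (default `TRUE`).
#' @return An object of class `molecular_profile`.
#' @export
molecular_profile <- function(values,
                              datatype = c("EXPRESSION", "CNV", "MUTATION"),
                              study_id = "study", harmonize = TRUE) {
  datatype <- match.arg(datatype)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (harmonize) values <- harmonize_dimnames(values, c("rows", "cols"))
  if (datatype == "MUTATION" &&
      !all(values %in% c(0, 1) | is.na(values)))
    stop("MUTATION values must be 0, 1 or missing")
  structure(
    list(study_id = as.character(study_id), datatype = datatype,
         values = values),
    class = "molecular_profile")
}

#' Bundle one study's matrices
#'
#' Collects any number of [sensitivity_matrix()] and [molecular_profile()]
#' objects for a single study. Sensitivity matrices are keyed by measure and
#' profiles by datatype.
#'
#' @param ... `sensitivity_matrix` / `molecular_profile` objects.
#' @param study_id Study label; defaults to the first member's.
#' @return An object of class `study_collection` with elements `sensitivity`
#'   (named list by measure) and `profiles` (named list by datatype).
#' @export
study_collection <- function(..., study_id = NULL) {
  members <- list(...)
  if (length(members) == 1L && is.list(members[[1]]) &&
      !inherits(members[[1]], c("sensitivity_matrix", "molecular_profile")))
    members <- members[[1]]
  sens <- list(); prof <- list()
  for (m in members) {
    if (inherits(m, "sensitivity_matrix")) {
      if (!is.null(sens[[m$measure]])) stop("duplicate measure: ", m$measure)
      sens[[m$measure]] <- m
    } else if (inherits(m, "molecular_profile")) {
      if (!is.null(prof[[m$datatype]])) stop("duplicate datatype: ", m$datatype)
      prof[[m$datatype]] <- m
    } else stop("unsupported member of class ", paste(class(m), collapse = "/"))
  }
  if (is.null(study_id)) {
    ids <- unique(c(vapply(sens, `[[`, "", "study_id"),
                    vapply(prof, `[[`, "", "study_id")))
    study_id <- if (length(ids)) ids[[1]] else "study"
  }
  structure(list(study_id = study_id, sensitivity = sens, profiles = prof),
            class = "study_collection")
}

#' @keywords internal
#' @noRd
collection_cell_lines <- function(s) {
  sets <- c(lapply(s$sensitivity, function(m) rownames(m$values)),
            lapply(s$profiles,   function(m) colnames(m$values)))
  if (!length(sets)) stop("study ", s$study_id, " holds no matrices")
  Reduce(intersect, sets)
}

#' @keywords internal
#' @noRd
subset_collection <- function(s, cells, drugs = NULL, genes = NULL) {
  s$sensitivity <- lapply(s$sensitivity, function(m) {
    d <- if (is.null(drugs)) colnames(m$values) else drugs
    m$values <- m$values[cells, d, drop = FALSE]
    if (!is.null(m$censored)) m$censored <- m$censored[cells, d, drop = FALSE]
    m
  })
  s$profiles <- lapply(s$profiles, function(m) {
    g <- if (is.null(genes)) rownames(m$values) else genes
    m$values <- m$values[g, cells, drop = FALSE]
    m
  })
  s
}

#' Intersect two studies onto common cell lines, drugs and genes
#'
#' The precondition of an independent inter-study comparison: every matrix on
#' both sides is subset and reordered to the shared harmonized label sets.
#' Common cell lines are the intersection across all matrices of both studies;
#' common drugs across both studies' sensitivity matrices; common genes across
#' both studies' molecular profiles. Counts of labels dropped on each side are
#' recorded in the `dropped` element.
#'
#' @param a,b `study_collection` objects (or lists coercible by
#'   [study_collection()]).
#' @return An object of class `paired_study` with elements `study_a`,
#'   `study_b`, `common_cell_lines`, `common_drugs`, `common_genes`,
#'   `dropped`.
#' @export
intersect_studies <- function(a, b) {
  if (!inherits(a, "study_collection")) a <- study_collection(a)
  if (!inherits(b, "study_collection")) b <- study_collection(b)
  cells <- intersect(collection_cell_lines(a), collection_cell_lines(b))
  if (length(cells) < 2L)
    stop("fewer than 2 cell lines in common (", length(cells),
         "): correlation across cell lines is undefined")
  drug_sets <- c(lapply(a$sensitivity, function(m) colnames(m$values)),
                 lapply(b$sensitivity, function(m) colnames(m$values)))
  drugs <- if (length(drug_sets)) Reduce(intersect, drug_sets) else character()
  gene_sets <- c(lapply(a$profiles, function(m) rownames(m$values)),
                 lapply(b$profiles, function(m) rownames(m$values)))
  genes <- if (length(gene_sets)) Reduce(intersect, gene_sets) else character()
  dropped <- list(
    cell_lines_a = length(collection_cell_lines(a)) - length(cells),
    cell_lines_b = length(collection_cell_lines(b)) - length(cells),
    drugs_a = if (length(a$sensitivity))
      length(setdiff(unlist(lapply(a$sensitivity, function(m)
        colnames(m$values))), drugs)) else 0L,
    drugs_b = if (length(b$sensitivity))
      length(setdiff(unlist(lapply(b$sensitivity, function(m)
        colnames(m$values))), drugs)) else 0L,
    genes_a = if (length(a$profiles))
      length(setdiff(unlist(lapply(a$profiles, function(m)
        rownames(m$values))), genes)) else 0L,
    genes_b = if (length(b$profiles))
      length(setdiff(unlist(lapply(b$profiles, function(m)
        rownames(m$values))), genes)) else 0L)
  structure(
    list(study_a = subset_collection(a, cells, drugs, genes),
         study_b = subset_collection(b, cells, drugs, genes),
         common_cell_lines = cells, common_drugs = drugs,
         common_genes = genes, dropped = dropped),
    class = "paired_study")
}

# ---- delimited text I/O ----------------------------------------------------

#' @keywords internal
#' @noRd
read_labelled_matrix <- function(path, sep = ",", transpose = FALSE) {
  hdr <- scan(path, what = "", sep = sep, quote = "\"", nlines = 1L,
              quiet = TRUE, fileEncoding = "UTF-8", blank.lines.skip = FALSE)
  raw <- utils::read.table(path, sep = sep, header = FALSE, skip = 1L,
                           row.names = NULL, colClasses = "character",
                           check.names = FALSE, quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) stop("expected a label column plus >=1 data column")
  # header may or may not carry a corner cell above the label column
  if (length(hdr) == ncol(raw)) hdr <- hdr[-1]
  if (length(hdr) != ncol(raw) - 1L)
    stop("header of ", path, " does not match the data columns")
  rlabs <- raw[[1]]
  dat <- as.matrix(raw[, -1, drop = FALSE])
  colnames(dat) <- hdr
  vals <- suppressWarnings(array(as.numeric(dat), dim = dim(dat)))
  bad <- which(is.na(vals) & !is.na(dat) & nzchar(trimws(dat)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric cell at row ", sQuote(rlabs[bad[1, 1]]),
         ", column ", sQuote(colnames(dat)[bad[1, 2]]),
         " in ", path, ": ", sQuote(dat[bad[1, , drop = FALSE]]))
  }
  dimnames(vals) <- list(rlabs, colnames(dat))
  if (transpose) vals <- t(vals)
  vals
}

#' Read a drug-sensitivity table
#'
#' Reads delimited text (RFC-4180 CSV by default; tab via `sep = "\t"`) with
#' cell-line labels in the first column and drug labels in the header row.
#' Empty cells become missing values. IC50 tables are expected in micromolar
#' and are converted to log10(uM) on read; values above `ic50_max_conc` are
#' censored at the bound and flagged.
#'
#' @inheritParams sensitivity_matrix
#' @param path Path to the delimited file.
#' @param sep Field separator (default `","`).
#' @param transpose Set `TRUE` if the file is drugs x cell lines.
#' @return A [sensitivity_matrix()].
#' @export
read_sensitivity_table <- function(path, measure = c("AUC", "IC50"),
                                   study_id = "study", ic50_max_conc = NULL,
                                   sep = ",", transpose = FALSE) {
  measure <- match.arg(measure)
  vals <- read_labelled_matrix(path, sep = sep, transpose = transpose)
  if (measure == "IC50") {
    if (any(vals <= 0, na.rm = TRUE))
      stop("IC50 concentrations must be positive (micromolar) in ", path)
    vals <- log10(vals)
  }
  sensitivity_matrix(vals, measure = measure, study_id = study_id,
                     ic50_max_conc = ic50_max_conc)
}

#' Read a molecular-profile table
#'
#' Delimited text with gene labels in the first column and cell-line labels in
#' the header row (use `transpose = TRUE` for the opposite orientation).
#'
#' @inheritParams molecular_profile
#' @inheritParams read_sensitivity_table
#' @return A [molecular_profile()].
#' @export
read_profile_table <- function(path,
                               datatype = c("EXPRESSION", "CNV", "MUTATION"),
                               study_id = "study", sep = ",",
                               transpose = FALSE) {
  datatype <- match.arg(datatype)
  vals <- read_labelled_matrix(path, sep = sep, transpose = transpose)
  molecular_profile(vals, datatype = datatype, study_id = study_id)
}

#' @keywords internal
#' @noRd
format_cell <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "" else formatC(v, digits = 17, format = "g"), character(1))
  out
}

#' Write a labelled matrix as delimited text
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces every double bit-exactly; missing values are written as empty
#' cells. IC50 matrices are written back on the micromolar scale, inverting
#' the log10 applied on read.
#'
#' @param m A `sensitivity_matrix` or `molecular_profile`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(m, path, sep = ",") {
  vals <- m$values
  if (inherits(m, "sensitivity_matrix") && m$measure == "IC50")
    vals <- 10^vals
  header <- paste(c("", colnames(vals)), collapse = sep)
  rows <- vapply(seq_len(nrow(vals)), function(i)
    paste(c(rownames(vals)[i], format_cell(vals[i, ])), collapse = sep),
    character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("<sensitivity_matrix> study %s, measure %s: %d cell lines x %d drugs",
              x$study_id, x$measure, nrow(x$values), ncol(x$values)))
  if (!is.null(x$ic50_max_conc))
    cat(sprintf(", censored at %g uM (%d values)", x$ic50_max_conc,
                sum(x$censored)))
  cat(sprintf(", %d missing\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.molecular_profile <- function(x, ...) {
  cat(sprintf("<molecular_profile> study %s, %s: %d genes x %d cell lines, %d missing\n",
              x$study_id, x$datatype, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.paired_study <- function(x, ...) {
  cat(sprintf("<paired_study> %s vs %s: %d common cell lines, %d drugs, %d genes\n",
              x$study_a$study_id, x$study_b$study_id,
              length(x$common_cell_lines), length(x$common_drugs),
              length(x$common_genes)))
  d <- x$dropped
  cat(sprintf("  dropped: cell lines %d/%d, drugs %d/%d, genes %d/%d (a/b)\n",
              d$cell_lines_a, d$cell_lines_b, d$drugs_a, d$drugs_b,
              d$genes_a, d$genes_b))
  invisible(x)
}
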