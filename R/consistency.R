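#' Pearson correlation over complete pairs
#'
#' Product-moment correlation computed on pairwise-complete observations,
#' returned as `NA` (undefined, never coerced to zero) when fewer than
#' `min_pairs` complete pairs remain or either vector is constant over them.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_pairs Minimum complete pairs for a defined estimate
#'   (default 10).
#' @return Correlation in \[-1, 1\], or `NA_real_` if undefined.
#' @export
pearson_cor <- function(x, y, min_pairs = 10L) {
  if (length(x) != length(y))
    stop("x and y must have equal length (", length(x), " vs ", length(y), ")")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_pairs) return(NA_real_)
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), where p_o is
#' the observed proportion of agreeing pairs and p_e the agreement expected
#' from the two raters' marginal proportions. Undefined (`NA`) when fewer
#' than `min_pairs` complete pairs remain or when the marginals are
#' degenerate (p_e = 1, e.g. both raters constant).
#'
#' @param a,b Vectors over \{0, 1, `NA`\} of equal length.
#' @param min_pairs Minimum complete pairs for a defined estimate
#'   (default 10).
#' @return Kappa in \[-1, 1\], or `NA_real_` if undefined.
#' @examples
#' # 2x2 table 40/10/10/40: p_o = 0.8, p_e = 0.5, kappa = 0.6
#' a <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
#' b <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
#' cohen_kappa(a, b)
#' @export
cohen_kappa <- function(a, b, min_pairs = 10L) {
  if (length(a) != length(b))
    stop("a and b must have equal length (", length(a), " vs ", length(b), ")")
  if (!all(a %in% c(0, 1) | is.na(a)) || !all(b %in% c(0, 1) | is.na(b)))
    stop("kappa requires binary (0/1/missing) inputs")
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < min_pairs) return(NA_real_)
  av <- a[ok]; bv <- b[ok]
  p_o <- mean(av == bv)
  pa1 <- mean(av); pb1 <- mean(bv)
  p_e <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (p_e >= 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' @keywords internal
#' @noRd
classify_rho <- function(rho, cfg) {
  ifelse(is.na(rho), NA_character_,
         ifelse(rho >= cfg$rho_good, "GOOD",
                ifelse(rho > cfg$rho_reasonable, "REASONABLE", "BELOW")))
}

#' @keywords internal
#' @noRd
classify_kappa <- function(kappa, cfg) {
  # Landis-Koch bands, left-closed; slight and poor merged below 0.2
  ifelse(is.na(kappa), NA_character_,
         ifelse(kappa >= 0.8, "ALMOST_PERFECT",
                ifelse(kappa >= cfg$kappa_substantial_min, "SUBSTANTIAL",
                       ifelse(kappa >= cfg$kappa_moderate_min, "MODERATE",
                              ifelse(kappa >= 0.2, "FAIR", "POOR")))))
}

#' Classify agreement statistics against the standard thresholds
#'
#' Fills `rho_category` (`GOOD` for rho >= 0.8, the inter-laboratory
#' reproducibility criterion, boundary inclusive; `REASONABLE` for
#' rho > 0.5; else `BELOW`) and `kappa_category` (Landis-Koch bands:
#' `POOR` < 0.2 <= `FAIR` < 0.4 <= `MODERATE` < 0.6 <= `SUBSTANTIAL`
#' < 0.8 <= `ALMOST_PERFECT`).
#'
#' @param results Data frame with columns `rho` and/or `kappa` (an
#'   `AgreementResult` table), or a single numeric `rho` value together with
#'   `kappa`.
#' @param cfg A [threshold_config()].
#' @return The data frame with category columns filled.
#' @export
classify_agreement <- function(results, cfg = threshold_config()) {
  if (is.numeric(results))
    results <- data.frame(rho = results)
  if (!is.null(results$rho))
    results$rho_category <- classify_rho(results$rho, cfg)
  if (!is.null(results$kappa))
    results$kappa_category <- classify_kappa(results$kappa, cfg)
  results
}

#' @keywords internal
#' @noRd
report_summary <- function(results, cfg) {
  rho <- results$rho[!is.na(results$rho)]
  kap <- results$kappa[!is.na(results$kappa)]
  list(
    n_entities = nrow(results),
    n_rho_defined = length(rho),
    n_kappa_defined = length(kap),
    median_rho = if (length(rho)) stats::median(rho) else NA_real_,
    fraction_rho_gt_reasonable =
      if (length(rho)) mean(rho > cfg$rho_reasonable) else NA_real_,
    fraction_rho_ge_good =
      if (length(rho)) mean(rho >= cfg$rho_good) else NA_real_,
    median_kappa = if (length(kap)) stats::median(kap) else NA_real_,
    fraction_kappa_ge_moderate =
      if (length(kap)) mean(kap >= cfg$kappa_moderate_min) else NA_real_)
}

#' Per-entity consistency between two aligned matrices
#'
#' Workhorse behind [per_entity_consistency()]: given two matrices aligned on
#' identical dimnames, computes for every entity (row or column, per `axis`)
#' the agreement between the two studies across cell lines — Pearson rho for
#' continuous values, Cohen's kappa for binary — and assembles a
#' `consistency_report`.
#'
#' @param values_a,values_b Aligned numeric matrices.
#' @param axis `"rows"` or `"cols"`: the entity dimension (cell lines run
#'   along the other one).
#' @param binary Compute kappa instead of rho.
#' @param datatype,study_pair Report metadata.
#' @param cfg A [threshold_config()].
#' @param min_pairs Passed to [pearson_cor()] / [cohen_kappa()].
#' @return An object of class `consistency_report`: `results` data frame
#'   (entity_id, n_pairs, rho, kappa, categories) and `summary` list with
#'   median rho and the fractions of entities clearing each threshold
#'   (computed over defined statistics only, denominators reported).
#' @export
consistency_from_matrices <- function(values_a, values_b,
                                      axis = c("cols", "rows"),
                                      binary = FALSE, datatype = "",
                                      study_pair = c("a", "b"),
                                      cfg = threshold_config(),
                                      min_pairs = 10L) {
  axis <- match.arg(axis)
  if (axis == "rows") { values_a <- t(values_a); values_b <- t(values_b) }
  if (!identical(dimnames(values_a), dimnames(values_b)))
    stop("matrices are not aligned on identical labels; intersect first")
  entities <- colnames(values_a)
  stat <- vapply(seq_along(entities), function(j) {
    xa <- values_a[, j]; xb <- values_b[, j]
    c(n = sum(!is.na(xa) & !is.na(xb)),
      s = if (binary) cohen_kappa(xa, xb, min_pairs)
          else pearson_cor(xa, xb, min_pairs))
  }, numeric(2))
  results <- data.frame(
    entity_id = entities,
    n_pairs = as.integer(stat["n", ]),
    rho = if (binary) NA_real_ else stat["s", ],
    kappa = if (binary) stat["s", ] else NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)
  results <- classify_agreement(results, cfg)
  structure(list(study_pair = study_pair, datatype = datatype,
                 results = results,
                 summary = report_summary(results, cfg)),
            class = "consistency_report")
}

#' Per-drug or per-gene consistency for a paired study
#'
#' For each drug (sensitivity measures, binary calls) or gene (molecular
#' profiles), computes the agreement between the two studies across their
#' common cell lines: Pearson rho for continuous data types (AUC, log10 IC50,
#' expression, copy number), Cohen's kappa for binary ones (mutation,
#' sensitivity calls).
#'
#' @param p A [intersect_studies()] result (`paired_study`).
#' @param datatype One of `"AUC"`, `"IC50"`, `"EXPRESSION"`, `"CNV"`,
#'   `"MUTATION"`.
#' @param cfg A [threshold_config()].
#' @param min_pairs Minimum complete pairs per entity (default 10).
#' @return A `consistency_report`; see [consistency_from_matrices()].
#' @export
per_entity_consistency <- function(p, datatype, cfg = threshold_config(),
                                   min_pairs = 10L) {
  stopifnot(inherits(p, "paired_study"))
  datatype <- match.arg(datatype,
                        c("AUC", "IC50", "EXPRESSION", "CNV", "MUTATION"))
  pair_ids <- c(p$study_a$study_id, p$study_b$study_id)
  if (datatype %in% c("AUC", "IC50")) {
    ma <- p$study_a$sensitivity[[datatype]]
    mb <- p$study_b$sensitivity[[datatype]]
    if (is.null(ma) || is.null(mb))
      stop(datatype, " not present in both studies")
    consistency_from_matrices(ma$values, mb$values, axis = "cols",
                              binary = FALSE, datatype = datatype,
                              study_pair = pair_ids, cfg = cfg,
                              min_pairs = min_pairs)
  } else {
    ma <- p$study_a$profiles[[datatype]]
    mb <- p$study_b$profiles[[datatype]]
    if (is.null(ma) || is.null(mb))
      stop(datatype, " not present in both studies")
    consistency_from_matrices(ma$values, mb$values, axis = "rows",
                              binary = datatype == "MUTATION",
                              datatype = datatype, study_pair = pair_ids,
                              cfg = cfg, min_pairs = min_pairs)
  }
}

#' Per-drug consistency of binary sensitivity calls
#'
#' Compares two studies' call matrices (from [call_waterfall()] or
#' [call_fixed()]) drug by drug with Cohen's kappa.
#'
#' @param calls_a,calls_b `binary_call_matrix` objects aligned on common
#'   cell lines and drugs.
#' @inheritParams per_entity_consistency
#' @return A `consistency_report` with `datatype = "CALLS"`.
#' @export
call_consistency <- function(calls_a, calls_b, cfg = threshold_config(),
                             min_pairs = 10L) {
  stopifnot(inherits(calls_a, "binary_call_matrix"),
            inherits(calls_b, "binary_call_matrix"))
  cells <- intersect(rownames(calls_a$calls), rownames(calls_b$calls))
  drugs <- intersect(colnames(calls_a$calls), colnames(calls_b$calls))
  consistency_from_matrices(calls_a$calls[cells, drugs, drop = FALSE],
                            calls_b$calls[cells, drugs, drop = FALSE],
                            axis = "cols", binary = TRUE,
                            datatype = paste0("CALLS_", calls_a$measure, "_",
                                              calls_a$method),
                            study_pair = c(calls_a$study_id,
                                           calls_b$study_id),
                            cfg = cfg, min_pairs = min_pairs)
}

#' @export
print.consistency_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<consistency_report> %s vs %s, %s: %d entities\n",
              x$study_pair[1], x$study_pair[2], x$datatype, s$n_entities))
  if (s$n_rho_defined)
    cat(sprintf("  rho: median %.3f; >0.5 (reasonable): %d/%d (%.0f%%); >=0.8 (good): %d/%d (%.0f%%)\n",
                s$median_rho,
                round(s$fraction_rho_gt_reasonable * s$n_rho_defined),
                s$n_rho_defined, 100 * s$fraction_rho_gt_reasonable,
                round(s$fraction_rho_ge_good * s$n_rho_defined),
                s$n_rho_defined, 100 * s$fraction_rho_ge_good))
  if (s$n_kappa_defined)
    cat(sprintf("  kappa: median %.3f; >=0.4 (moderate+): %d/%d (%.0f%%)\n",
                s$median_kappa,
                round(s$fraction_kappa_ge_moderate * s$n_kappa_defined),
                s$n_kappa_defined, 100 * s$fraction_kappa_ge_moderate))
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with midrank ties. The p-value is computed by
#' exact enumeration when the combined sample size is at most 16 and there
#' are no ties, otherwise by the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param alternative `"two_sided"`, `"greater"` (x shifted above y) or
#'   `"less"`.
#' @return List with `statistic` (the rank-sum of `x` in the combined
#'   midranked sample), `u` (the Mann-Whitney U for `x`), `p` and `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 16L && !ties
  alt <- switch(alternative, two_sided = "two.sided", greater = "greater",
                less = "less")
  wt <- stats::wilcox.test(x, y, alternative = alt, exact = exact,
                           correct = TRUE)
  r <- rank(c(x, y))
  list(statistic = sum(r[seq_along(x)]),
       u = unname(wt$statistic),
       p = wt$p.value,
       exact = exact)
}

#' Compare two data types' consistency distributions
#'
#' Tests whether the per-entity consistency of one data type (e.g. gene
#' expression or copy number) is shifted relative to another (e.g. drug
#' sensitivity) with a one-sided Wilcoxon rank-sum test on the distributions
#' of per-entity correlations (kappa for binary-only reports).
#'
#' @param report_a,report_b `consistency_report` objects.
#' @param alternative `"greater"` tests whether `report_a`'s consistency
#'   exceeds `report_b`'s.
#' @return List with `statistic`, `p`, `n_a`, `n_b`.
#' @export
compare_datatype_consistency <- function(report_a, report_b,
                                         alternative = c("greater", "less",
                                                         "two_sided")) {
  alternative <- match.arg(alternative)
  pick <- function(r) {
    v <- r$results$rho[!is.na(r$results$rho)]
    if (!length(v)) v <- r$results$kappa[!is.na(r$results$kappa)]
    v
  }
  va <- pick(report_a); vb <- pick(report_b)
  if (!length(va) || !length(vb))
    stop("a report has no defined consistency statistics")
  out <- wilcoxon_rank_sum(va, vb, alternative = alternative)
  out$n_a <- length(va); out$n_b <- length(vb)
  out
}

#' Union of consistency tests across measures
#'
#' Computes, for entities shared by several reports, the fraction passing
#' each report's criterion (rho above the reasonable threshold for
#' continuous reports, kappa at or above moderate for binary ones) and the
#' fraction passing *any* of them. The union fraction is monotone: it can
#' only grow as measures are added — even uninformative ones — so it is
#' reported with `non_evidential = TRUE` and labelled as such wherever the
#' package prints it. It must never be quoted as evidence of agreement.
#'
#' @param reports Named list of `consistency_report` objects over a common
#'   entity set.
#' @param cfg A [threshold_config()].
#' @return List with `fraction_by_measure`, `fraction_union`, `n_entities`
#'   and `non_evidential = TRUE`.
#' @export
union_of_tests <- function(reports, cfg = threshold_config()) {
  stopifnot(length(reports) >= 1L)
  ids <- Reduce(intersect, lapply(reports, function(r) r$results$entity_id))
  if (!length(ids)) stop("reports share no entities")
  pass <- vapply(reports, function(r) {
    res <- r$results[match(ids, r$results$entity_id), ]
    p_rho <- !is.na(res$rho) & res$rho > cfg$rho_reasonable
    p_kap <- !is.na(res$kappa) & res$kappa >= cfg$kappa_moderate_min
    p_rho | p_kap
  }, logical(length(ids)))
  pass <- matrix(pass, nrow = length(ids))
  indiv <- colMeans(pass)
  names(indiv) <- names(reports)
  list(fraction_by_measure = indiv,
       fraction_union = mean(apply(pass, 1L, any)),
       n_entities = length(ids),
       non_evidential = TRUE)
}
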