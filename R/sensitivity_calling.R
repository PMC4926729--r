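#' Threshold configuration for calling and agreement classification
#'
#' Central registry of the cutoffs used throughout the package.
#'
#' @param auc_sensitive_min AUC at or above which a cell line is called
#'   sensitive under the fixed rule (activity-area fraction; default 0.2).
#' @param ic50_sensitive_max_um IC50 in micromolar at or below which a cell
#'   line is called sensitive under the fixed rule (default 1 uM; the rule is
#'   applied on the log10 scale).
#' @param rho_reasonable Pearson correlation above which agreement is
#'   classified `REASONABLE` (default 0.5, exclusive).
#' @param rho_good Pearson correlation at or above which agreement is
#'   classified `GOOD` (default 0.8, inclusive — the FDA/MAQC
#'   inter-laboratory reproducibility criterion).
#' @param kappa_moderate_min,kappa_substantial_min Lower edges of the
#'   Landis-Koch `MODERATE` (0.4) and `SUBSTANTIAL` (0.6) kappa bands.
#' @param waterfall_linearity_min Pearson correlation of the sorted response
#'   curve with its least-squares line at or above which the distribution is
#'   treated as linear and the cutoff falls back to the median (default 0.95).
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(auc_sensitive_min = 0.2,
                             ic50_sensitive_max_um = 1.0,
                             rho_reasonable = 0.5,
                             rho_good = 0.8,
                             kappa_moderate_min = 0.4,
                             kappa_substantial_min = 0.6,
                             waterfall_linearity_min = 0.95) {
  stopifnot(auc_sensitive_min >= 0, auc_sensitive_min <= 1,
            ic50_sensitive_max_um > 0,
            rho_reasonable >= -1, rho_reasonable <= 1,
            rho_good >= -1, rho_good <= 1,
            kappa_moderate_min >= -1, kappa_moderate_min <= 1,
            kappa_substantial_min >= kappa_moderate_min,
            kappa_substantial_min <= 1,
            waterfall_linearity_min >= 0, waterfall_linearity_min <= 1)
  structure(list(auc_sensitive_min = auc_sensitive_min,
                 ic50_sensitive_max_um = ic50_sensitive_max_um,
                 rho_reasonable = rho_reasonable, rho_good = rho_good,
                 kappa_moderate_min = kappa_moderate_min,
                 kappa_substantial_min = kappa_substantial_min,
                 waterfall_linearity_min = waterfall_linearity_min),
            class = "threshold_config")
}

#' Waterfall cutoff for one drug
#'
#' Sorts a drug's response values in decreasing order to form the
#' response-distribution ("waterfall") curve and places the
#' sensitive/insensitive cutoff at its inflection. If the sorted curve is
#' essentially linear — Pearson correlation with its least-squares line over
#' rank at least `linearity_min` — there is no inflection and the cutoff is
#' the median. Otherwise both axes are min-max scaled to \[0, 1\] and the
#' cutoff is the value at the point of maximal perpendicular distance from
#' the chord joining the first and last points of the curve. Ties are broken
#' towards the smallest rank (the most-sensitive end for AUC). Deterministic.
#'
#' @param values Numeric vector: one drug's responses over all cell lines of
#'   the study panel (missing values ignored; at least 3 required).
#' @param linearity_min Linearity threshold (default 0.95).
#' @param cutoff_bounds Optional length-2 interval into which the cutoff is
#'   clamped.
#' @return The cutoff (scalar), with attributes `branch` (`"linear"` or
#'   `"elbow"`, or `"degenerate"` for a constant vector) and `r_lin`.
#' @examples
#' waterfall_cutoff(seq(1, 0.1, by = -0.1))     # linear -> median 0.55
#' waterfall_cutoff(c(1, 0.98, 0.96, 0.94, 0.2, 0.18, 0.16))  # elbow
#' @export
waterfall_cutoff <- function(values, linearity_min = 0.95,
                             cutoff_bounds = NULL) {
  x <- values[!is.na(values)]
  if (length(x) < 3L)
    stop("waterfall cutoff needs >= 3 non-missing values, got ", length(x))
  if (!is.null(cutoff_bounds))
    stopifnot(length(cutoff_bounds) == 2L, cutoff_bounds[1] <= cutoff_bounds[2])
  y <- sort(x, decreasing = TRUE)
  n <- length(y)
  if (diff(range(y)) == 0) {
    cutoff <- y[1]
    attr(cutoff, "branch") <- "degenerate"
    attr(cutoff, "r_lin") <- NA_real_
    return(clamp_cutoff(cutoff, cutoff_bounds))
  }
  r_lin <- abs(stats::cor(seq_len(n), y))
  if (r_lin >= linearity_min) {
    cutoff <- stats::median(y)
    branch <- "linear"
  } else {
    t <- (seq_len(n) - 1) / (n - 1)
    v <- (y - min(y)) / (max(y) - min(y))
    # perpendicular distance of (t_i, v_i) from the chord (0, 1) -- (1, 0)
    d <- abs(t + v - 1) / sqrt(2)
    cutoff <- y[which.max(d)]
    branch <- "elbow"
  }
  attr(cutoff, "branch") <- branch
  attr(cutoff, "r_lin") <- r_lin
  clamp_cutoff(cutoff, cutoff_bounds)
}

#' @keywords internal
#' @noRd
clamp_cutoff <- function(cutoff, bounds) {
  if (is.null(bounds)) return(cutoff)
  out <- min(max(cutoff, bounds[1]), bounds[2])
  attributes(out) <- attributes(cutoff)
  out
}

#' @keywords internal
#' @noRd
binary_call_matrix <- function(calls, study_id, measure, method,
                               per_drug_cutoff, degenerate = NULL) {
  structure(list(study_id = study_id, measure = measure, method = method,
                 calls = calls, per_drug_cutoff = per_drug_cutoff,
                 degenerate = degenerate),
            class = "binary_call_matrix")
}

#' @export
print.binary_call_matrix <- function(x, ...) {
  cat(sprintf("<binary_call_matrix> study %s, %s calls on %s: %d cell lines x %d drugs, %d sensitive / %d insensitive / %d missing\n",
              x$study_id, x$method, x$measure, nrow(x$calls), ncol(x$calls),
              sum(x$calls == 1, na.rm = TRUE), sum(x$calls == 0, na.rm = TRUE),
              sum(is.na(x$calls))))
  invisible(x)
}

#' @keywords internal
#' @noRd
emit_calls <- function(values, measure, cutoffs) {
  calls <- matrix(NA_real_, nrow(values), ncol(values),
                  dimnames = dimnames(values))
  for (j in seq_len(ncol(values))) {
    cj <- cutoffs[j]
    if (is.na(cj)) next
    calls[, j] <- if (measure == "AUC")
      as.numeric(values[, j] >= cj) else as.numeric(values[, j] <= cj)
  }
  calls
}

#' Waterfall sensitivity calls
#'
#' Computes per-drug waterfall cutoffs on *all* cell lines of the study panel
#' and only then, if `restrict_to` is given, subsets the calls to those cell
#' lines. Calling before restriction matters: the cutoff reflects the full
#' response distribution of the panel, not whichever subset two studies
#' happen to share. For AUC, values at or above the cutoff are sensitive (1);
#' for IC50 (log10 uM), values at or below the cutoff are sensitive.
#'
#' Drugs with fewer than 3 non-missing values get all-missing calls with a
#' warning rather than an error, so one unusable drug does not abort a
#' screen-wide run.
#'
#' @param m A [sensitivity_matrix()].
#' @param cfg A [threshold_config()].
#' @param restrict_to Optional cell-line labels (harmonized) to subset the
#'   returned calls to; unknown labels are an error.
#' @param cutoff_bounds Passed to [waterfall_cutoff()].
#' @return A `binary_call_matrix` (calls coded 1 = sensitive,
#'   0 = insensitive, `NA` = missing) with per-drug cutoffs attached.
#' @export
call_waterfall <- function(m, cfg = threshold_config(), restrict_to = NULL,
                           cutoff_bounds = NULL) {
  stopifnot(inherits(m, "sensitivity_matrix"))
  vals <- m$values
  drugs <- colnames(vals)
  cutoffs <- stats::setNames(rep(NA_real_, length(drugs)), drugs)
  degenerate <- stats::setNames(logical(length(drugs)), drugs)
  for (j in seq_along(drugs)) {
    v <- vals[, j]
    if (sum(!is.na(v)) < 3L) {
      warning("drug ", drugs[j], ": fewer than 3 non-missing values; ",
              "calls set to missing")
      next
    }
    cj <- waterfall_cutoff(v, linearity_min = cfg$waterfall_linearity_min,
                           cutoff_bounds = cutoff_bounds)
    degenerate[j] <- identical(attr(cj, "branch"), "degenerate")
    cutoffs[j] <- as.numeric(cj)
  }
  calls <- emit_calls(vals, m$measure, cutoffs)
  if (!is.null(restrict_to)) {
    restrict_to <- harmonize_label(restrict_to)
    unknown <- setdiff(restrict_to, rownames(calls))
    if (length(unknown))
      stop("unknown cell line(s) in restrict_to: ",
           paste(unknown, collapse = ", "))
    calls <- calls[restrict_to, , drop = FALSE]
  }
  binary_call_matrix(calls, m$study_id, m$measure, "WATERFALL", cutoffs,
                     degenerate)
}

#' Fixed-cutoff sensitivity calls
#'
#' Applies the fixed rules: AUC at or above `auc_sensitive_min` (default 0.2)
#' is sensitive; IC50 at or below `ic50_sensitive_max_um` (default 1 uM,
#' i.e. log10 value <= 0) is sensitive. Both boundaries are inclusive on the
#' sensitive side.
#'
#' @inheritParams call_waterfall
#' @return A `binary_call_matrix`.
#' @examples
#' m <- sensitivity_matrix(
#'   matrix(c(0.1, 0.2, 0.3), 3, 1,
#'          dimnames = list(c("A1", "A2", "A3"), "D1")),
#'   measure = "AUC")
#' call_fixed(m)$calls
#' @export
call_fixed <- function(m, cfg = threshold_config()) {
  stopifnot(inherits(m, "sensitivity_matrix"))
  cut <- if (m$measure == "AUC") cfg$auc_sensitive_min
         else log10(cfg$ic50_sensitive_max_um)
  drugs <- colnames(m$values)
  cutoffs <- stats::setNames(rep(cut, length(drugs)), drugs)
  calls <- emit_calls(m$values, m$measure, cutoffs)
  binary_call_matrix(calls, m$study_id, m$measure, "FIXED", cutoffs)
}
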