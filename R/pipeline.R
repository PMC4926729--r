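#' Run the full agreement assessment
#'
#' Orchestrates the whole pipeline on a pair of studies: intersect onto
#' common labels; binarize drug response (waterfall and fixed cutoffs, with
#' waterfall cutoffs computed on each study's full panel before restriction
#' to the common cell lines); per-drug and per-gene consistency reports for
#' every shared data type; a one-sided rank-sum comparison of genomic vs
#' pharmacological consistency; gene-drug association screens under the
#' independent (A), shared-mutation (B) and mixed-measure (C) designs with
#' their biomarker concordances; and a summary whose per-measure fractions
#' are reported separately — any union-of-tests fraction is printed but
#' explicitly labelled non-evidential.
#'
#' All outputs are plain CSV/JSON without timestamps, so a rerun with the
#' same inputs and seed is byte-identical.
#'
#' @param x Input pair: a [generate_pair()] result, a manifest path (see
#'   [write_fixture()]), or a list with `study_a` and `study_b`
#'   [study_collection()]s.
#' @param out_dir Output directory (created if needed).
#' @param cfg A [threshold_config()].
#' @param min_pairs Minimum complete pairs per entity statistic.
#' @param sig_q BH significance threshold for association hits.
#' @param design_reps If `x` carries simulation parameters, number of
#'   replicates for the design comparison simulation (0 skips it).
#' @param seed Seed for the design-comparison simulation.
#' @return Invisibly, the report bundle: a list with `pair`, `calls`,
#'   `consistency` (list of reports), `datatype_comparison`,
#'   `design_single` (concordance per design on this pair),
#'   `design_table` (replicated simulation, if run), `union`, `summary`.
#' @export
run_full_assessment <- function(x, out_dir, cfg = threshold_config(),
                                min_pairs = 10L, sig_q = 0.05,
                                design_reps = 10L, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status_path <- file.path(out_dir, "status.txt")
  status <- character()
  note <- function(msg) status <<- c(status, msg)
  on.exit(writeLines(status, status_path), add = TRUE)

  params <- NULL
  if (inherits(x, "synthetic_study_pair")) {
    params <- x$params
    studies <- list(study_a = x$study_a, study_b = x$study_b)
  } else if (is.character(x) && length(x) == 1L) {
    studies <- read_fixture(x)
  } else if (is.list(x) && !is.null(x$study_a) && !is.null(x$study_b)) {
    studies <- list(study_a = x$study_a, study_b = x$study_b)
  } else stop("unsupported input to run_full_assessment")
  pair <- intersect_studies(studies$study_a, studies$study_b)
  note(sprintf("intersect: %d common cell lines, %d drugs, %d genes",
               length(pair$common_cell_lines), length(pair$common_drugs),
               length(pair$common_genes)))
  note(sprintf("dropped: %s",
               paste(names(pair$dropped), unlist(pair$dropped),
                     sep = "=", collapse = " ")))

  # calls: cutoffs on each study's full panel, then restrict to common cells
  calls <- list()
  for (side in c("study_a", "study_b")) {
    for (meas in names(studies[[side]]$sensitivity)) {
      m <- studies[[side]]$sensitivity[[meas]]
      calls[[paste(side, meas, "WATERFALL", sep = "_")]] <-
        call_waterfall(m, cfg, restrict_to = pair$common_cell_lines)
      full_fixed <- call_fixed(m, cfg)
      full_fixed$calls <-
        full_fixed$calls[pair$common_cell_lines, , drop = FALSE]
      calls[[paste(side, meas, "FIXED", sep = "_")]] <- full_fixed
    }
  }

  # per-entity consistency per datatype
  reports <- list()
  for (dt in c("AUC", "IC50", "EXPRESSION", "CNV", "MUTATION")) {
    present <- if (dt %in% c("AUC", "IC50"))
      !is.null(pair$study_a$sensitivity[[dt]]) &&
        !is.null(pair$study_b$sensitivity[[dt]])
    else
      !is.null(pair$study_a$profiles[[dt]]) &&
        !is.null(pair$study_b$profiles[[dt]])
    if (!present) next
    reports[[dt]] <- per_entity_consistency(pair, dt, cfg, min_pairs)
  }
  for (meas in names(studies$study_a$sensitivity)) {
    for (method in c("WATERFALL", "FIXED")) {
      ka <- calls[[paste("study_a", meas, method, sep = "_")]]
      kb <- calls[[paste("study_b", meas, method, sep = "_")]]
      if (is.null(ka) || is.null(kb)) next
      reports[[paste0("CALLS_", meas, "_", method)]] <-
        call_consistency(ka, kb, cfg, min_pairs)
    }
  }
  for (nm in names(reports)) {
    res <- reports[[nm]]$results
    utils::write.csv(res, file.path(out_dir,
                                    paste0("consistency_",
                                           tolower(nm), ".csv")),
                     row.names = FALSE, quote = FALSE)
    note(sprintf("consistency %s: %d entities, %d rho / %d kappa defined",
                 nm, reports[[nm]]$summary$n_entities,
                 reports[[nm]]$summary$n_rho_defined,
                 reports[[nm]]$summary$n_kappa_defined))
  }

  # genomic vs pharmacological consistency
  dt_cmp <- NULL
  genomic <- intersect(c("EXPRESSION", "CNV"), names(reports))
  pharm <- intersect(c("AUC", "IC50"), names(reports))
  if (length(genomic) && length(pharm)) {
    gv <- unlist(lapply(reports[genomic],
                        function(r) r$results$rho[!is.na(r$results$rho)]))
    pv <- unlist(lapply(reports[pharm],
                        function(r) r$results$rho[!is.na(r$results$rho)]))
    w <- wilcoxon_rank_sum(gv, pv, alternative = "greater")
    dt_cmp <- data.frame(comparison = "genomic_vs_pharmacological",
                         alternative = "greater",
                         statistic = w$statistic, p = w$p,
                         n_genomic = length(gv),
                         n_pharmacological = length(pv))
    utils::write.csv(dt_cmp, file.path(out_dir, "datatype_comparison.csv"),
                     row.names = FALSE, quote = FALSE)
    note(sprintf("datatype comparison (genomic > pharmacological): p = %g",
                 w$p))
  }

  # association designs on this pair
  design_single <- NULL
  has_mut <- !is.null(pair$study_a$profiles$MUTATION) &&
    !is.null(pair$study_b$profiles$MUTATION)
  has_both_measures <- all(c("AUC", "IC50") %in%
                             names(pair$study_a$sensitivity)) &&
    all(c("AUC", "IC50") %in% names(pair$study_b$sensitivity))
  if (has_mut && !is.null(pair$study_a$sensitivity$AUC)) {
    design_ids <- c("A", "B", if (has_both_measures) "C")
    design_single <- do.call(rbind, lapply(design_ids, function(id) {
      d <- design_spec(id)
      scr <- run_association_screen(pair, d)
      conc <- biomarker_concordance(scr$study_a, scr$study_b, sig_q = sig_q)
      data.frame(design_id = id, effect_rho = conc$effect_rho,
                 hit_kappa = conc$hit_kappa,
                 n_common_tests = conc$n_common_tests,
                 n_hits_a = conc$n_hits_a, n_hits_b = conc$n_hits_b,
                 measure_a = d$measure_a, measure_b = d$measure_b,
                 mutation_source = d$mutation_source)
    }))
    utils::write.csv(design_single, file.path(out_dir, "design_single.csv"),
                     row.names = FALSE, quote = FALSE)
    note("association designs on this pair: design_single.csv")
  }

  # replicated leak simulation (only when generating parameters are known)
  design_table <- NULL
  if (!is.null(params) && design_reps > 0L) {
    design_table <- run_design_comparison(params, n_reps = design_reps,
                                          seed = seed, sig_q = sig_q)
    utils::write.csv(design_table, file.path(out_dir,
                                             "design_comparison.csv"),
                     row.names = FALSE, quote = FALSE)
    note(sprintf("design comparison: %d replicates", design_reps))
  }

  # union of tests across sensitivity measures (never evidence of agreement)
  union <- NULL
  union_measures <- intersect(c("AUC", "IC50", "CALLS_AUC_WATERFALL",
                                "CALLS_IC50_WATERFALL"), names(reports))
  if (length(union_measures) >= 2L)
    union <- union_of_tests(reports[union_measures], cfg)

  summary <- list(
    thresholds = unclass(cfg),
    n_common = list(cell_lines = length(pair$common_cell_lines),
                    drugs = length(pair$common_drugs),
                    genes = length(pair$common_genes)),
    dropped = pair$dropped,
    consistency = lapply(reports, function(r) r$summary),
    datatype_comparison = if (!is.null(dt_cmp)) as.list(dt_cmp),
    design_single = design_single,
    design_means = if (!is.null(design_table))
      lapply(split(design_table, design_table$design_id), function(d)
        list(mean_effect_rho = mean(d$effect_rho, na.rm = TRUE),
             mean_hit_kappa = mean(d$hit_kappa, na.rm = TRUE))),
    union_of_tests = union)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  writeLines(render_summary_text(summary, cfg),
             file.path(out_dir, "summary.txt"))
  note("OK")
  invisible(list(pair = pair, calls = calls, consistency = reports,
                 datatype_comparison = dt_cmp,
                 design_single = design_single, design_table = design_table,
                 union = union, summary = summary))
}

#' @keywords internal
#' @noRd
render_summary_text <- function(summary, cfg) {
  lines <- c("Agreement assessment summary", "")
  for (nm in names(summary$consistency)) {
    s <- summary$consistency[[nm]]
    if (s$n_rho_defined > 0)
      lines <- c(lines, sprintf(
        "%s: median rho %.3f; rho > %.2f in %d/%d; rho >= %.2f in %d/%d",
        nm, s$median_rho, cfg$rho_reasonable,
        round(s$fraction_rho_gt_reasonable * s$n_rho_defined),
        s$n_rho_defined, cfg$rho_good,
        round(s$fraction_rho_ge_good * s$n_rho_defined), s$n_rho_defined))
    if (s$n_kappa_defined > 0)
      lines <- c(lines, sprintf(
        "%s: median kappa %.3f; kappa >= %.2f in %d/%d",
        nm, s$median_kappa, cfg$kappa_moderate_min,
        round(s$fraction_kappa_ge_moderate * s$n_kappa_defined),
        s$n_kappa_defined))
  }
  if (!is.null(summary$datatype_comparison))
    lines <- c(lines, "", sprintf(
      "Genomic vs pharmacological consistency (one-sided rank-sum): p = %g",
      summary$datatype_comparison$p))
  if (!is.null(summary$union_of_tests)) {
    u <- summary$union_of_tests
    lines <- c(lines, "", sprintf(
      "Union of consistency tests across measures: %.0f%% of %d entities pass at least one criterion.",
      100 * u$fraction_union, u$n_entities), paste(
      "  NON-EVIDENTIAL: the union fraction can only grow as measures are",
      "added and is not evidence of agreement; per-measure fractions are",
      "reported above."))
  }
  lines
}

# ---- command-line interface ------------------------------------------------

#' @keywords internal
#' @noRd
parse_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else {
      opts[[key]] <- args[[i + 1L]]; i <- i + 2L
    }
  }
  opts
}

#' @keywords internal
#' @noRd
params_from_yaml <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  allowed <- names(formals(simulation_params))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown simulation parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(raw$reliability)) raw$reliability <- unlist(raw$reliability)
  do.call(simulation_params, raw)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `pgxagree` script
#' (`inst/cli/pgxagree.R`). Subcommands: `simulate` (write a synthetic
#' fixture), `call` (binarize a sensitivity table), `compare` (per-entity
#' consistency for one datatype of a fixture pair), `screen` (association
#' screen under a design), `leaksim` (replicated design comparison) and
#' `report` (full assessment).
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status: 0 success, 2 usage/config error, 3 data
#'   error, 4 step failure.
#' @export
pgx_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pgxagree <simulate|call|compare|screen|leaksim|report> [--flags]",
    " simulate --out DIR [--config sim.yaml] [--seed N]",
    " call     --input m.csv --measure auc|ic50 --method waterfall|fixed --out calls.csv",
    " compare  --pair manifest.yaml --datatype auc|ic50|expression|cnv|mutation --out report.csv",
    " screen   --pair manifest.yaml --design a|b|c --out assoc.csv",
    " leaksim  --reps N --seed N --out designs.csv [--config sim.yaml]",
    " report   --pair manifest.yaml --out DIR | --simulate --out DIR [--seed N] [--reps N]",
    sep = "\n")
  if (!length(args)) { message(usage); return(2L) }
  cmd <- args[[1]]
  opts <- tryCatch(parse_flags(args[-1]),
                   error = function(e) { message(e$message); NULL })
  if (is.null(opts)) return(2L)
  need <- function(key) {
    v <- opts[[key]]
    if (is.null(v) || isTRUE(v))
      stop(errorCondition(paste0("missing --", key),
                          class = c("pgx_usage_error", "error")))
    v
  }
  run <- function(expr) {
    tryCatch({ expr; 0L },
             pgx_usage_error = function(e) { message(e$message); 2L },
             pgx_data_error = function(e) { message(e$message); 3L },
             error = function(e) { message("error: ", e$message); 4L })
  }
  as_usage <- function(expr) {
    tryCatch(expr, error = function(e)
      stop(errorCondition(conditionMessage(e),
                          class = c("pgx_usage_error", "error"))))
  }
  as_data <- function(expr) {
    tryCatch(expr, error = function(e)
      stop(errorCondition(paste0("data error: ", conditionMessage(e)),
                          class = c("pgx_data_error", "error"))))
  }
  switch(cmd,
    simulate = run({
      params <- as_usage(params_from_yaml(opts$config))
      if (!is.null(opts$seed)) params$seed <- as.integer(opts$seed)
      write_fixture(generate_pair(params), need("out"))
      message("fixture written to ", need("out"))
    }),
    call = run({
      measure <- toupper(as_usage(match.arg(need("measure"),
                                            c("auc", "ic50"))))
      method <- as_usage(match.arg(need("method"),
                                   c("waterfall", "fixed")))
      m <- as_data(read_sensitivity_table(need("input"), measure))
      cl <- if (method == "waterfall") call_waterfall(m) else call_fixed(m)
      write_matrix_csv(cl$calls, need("out"))
      utils::write.csv(data.frame(drug = names(cl$per_drug_cutoff),
                                  cutoff = unname(cl$per_drug_cutoff)),
                       paste0(need("out"), ".cutoffs.csv"),
                       row.names = FALSE, quote = FALSE)
    }),
    compare = run({
      dt <- toupper(as_usage(match.arg(need("datatype"),
                                       c("auc", "ic50", "expression",
                                         "cnv", "mutation"))))
      studies <- as_data(read_fixture(need("pair")))
      pair <- as_data(intersect_studies(studies$study_a, studies$study_b))
      rep <- per_entity_consistency(pair, dt)
      utils::write.csv(rep$results, need("out"), row.names = FALSE,
                       quote = FALSE)
    }),
    screen = run({
      d <- design_spec(toupper(as_usage(match.arg(need("design"),
                                                  c("a", "b", "c")))))
      studies <- as_data(read_fixture(need("pair")))
      pair <- as_data(intersect_studies(studies$study_a, studies$study_b))
      scr <- run_association_screen(pair, d)
      scr$study_a$study <- "study_a"; scr$study_b$study <- "study_b"
      utils::write.csv(rbind(scr$study_a, scr$study_b), need("out"),
                       row.names = FALSE, quote = FALSE)
    }),
    leaksim = run({
      params <- as_usage(params_from_yaml(opts$config))
      tab <- run_design_comparison(params,
                                   n_reps = as.integer(need("reps")),
                                   seed = as.integer(need("seed")))
      utils::write.csv(tab, need("out"), row.names = FALSE, quote = FALSE)
    }),
    report = run({
      seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else 1L
      reps <- if (!is.null(opts$reps)) as.integer(opts$reps) else 10L
      x <- if (isTRUE(opts$simulate)) {
        params <- as_usage(params_from_yaml(opts$config))
        params$seed <- seed
        generate_pair(params)
      } else need("pair")
      run_full_assessment(x, need("out"), design_reps = reps, seed = seed)
    }),
    { message("unknown subcommand: ", cmd, "\n", usage); 2L })
}
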