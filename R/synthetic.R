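#' Parameters for the paired-study generator
#'
#' Describes the latent-truth-plus-noise structure that the agreement
#' comparisons assume: a latent per-(cell line, drug) true sensitivity, two
#' studies observing it with independent noise of configurable reliability,
#' latent binary mutation status observed with a per-study flip probability,
#' continuous genomic features with their own reliability, a sparse set of
#' true gene-drug effects shifting sensitivity in mutants, and IC50 reported
#' only within a tested concentration range.
#'
#' Reliability is parameterized as the fraction of observed variance carried
#' by the latent signal, `R = var(latent) / var(observed)`, so the expected
#' inter-study correlation of a shared signal is exactly
#' `sqrt(R1 * R2)` ([expected_attenuation()]).
#'
#' @param n_cell_lines,n_drugs,n_genes Panel dimensions. Defaults: 400 cell
#'   lines (the order of the overlap between large public screens, and sized
#'   so the design-A screen has high per-pair power at `effect_beta = 1` —
#'   concordance of undetectable biomarkers is not measurable), 15 drugs
#'   (the size of a typical shared drug panel) and 50 genes.
#' @param reliability Named fractions per datatype. Defaults: AUC and IC50
#'   0.5 (same-protocol replicate screens reach rho ~ 0.5), EXPRESSION 0.8,
#'   CNV 0.9 (copy-number profiles replicate best).
#' @param mutation_prevalence Latent mutant fraction per gene (default 0.2).
#' @param mutation_flip_rate Per-study symmetric miscall probability
#'   (default 0.1).
#' @param n_causal_pairs Number of true gene-drug effects (default 15).
#' @param effect_beta Latent sensitivity shift in mutants, in latent SD
#'   units (default 1).
#' @param auc_ic50_link `"monotone_nonlinear"` (log-IC50 is a fixed
#'   decreasing nonlinear map of the noisily observed latent sensitivity) or
#'   `"none"` (IC50 derives from an independent latent trait carrying the
#'   same causal effects with opposite sign).
#' @param ic50_max_conc Top of the tested concentration range in micromolar
#'   (default 8); log-IC50 above `log10(ic50_max_conc)` is censored at the
#'   bound.
#' @param study_bias Additive shift applied to study B's latent
#'   observations (default 0: pure noise, no protocol offset).
#' @param seed Integer seed; all randomness derives from it through fixed
#'   per-component substreams, so adding a datatype never perturbs the
#'   others.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_cell_lines = 400L, n_drugs = 15L,
                              n_genes = 50L,
                              reliability = c(AUC = 0.5, IC50 = 0.5,
                                              EXPRESSION = 0.8, CNV = 0.9),
                              mutation_prevalence = 0.2,
                              mutation_flip_rate = 0.1,
                              n_causal_pairs = 15L,
                              effect_beta = 1,
                              auc_ic50_link = c("monotone_nonlinear",
                                                "none"),
                              ic50_max_conc = 8,
                              study_bias = 0,
                              seed = 1L) {
  auc_ic50_link <- match.arg(auc_ic50_link)
  rel <- c(AUC = 0.5, IC50 = 0.5, EXPRESSION = 0.8, CNV = 0.9)
  rel[names(reliability)] <- reliability
  stopifnot(n_cell_lines >= 2, n_drugs >= 1, n_genes >= 1,
            all(rel >= 0 & rel <= 1),
            mutation_prevalence >= 0, mutation_prevalence <= 1,
            mutation_flip_rate >= 0, mutation_flip_rate <= 1,
            n_causal_pairs >= 0,
            n_causal_pairs <= as.numeric(n_genes) * n_drugs,
            is.finite(effect_beta), ic50_max_conc > 0,
            is.finite(study_bias))
  structure(list(n_cell_lines = as.integer(n_cell_lines),
                 n_drugs = as.integer(n_drugs),
                 n_genes = as.integer(n_genes),
                 reliability = rel,
                 mutation_prevalence = mutation_prevalence,
                 mutation_flip_rate = mutation_flip_rate,
                 n_causal_pairs = as.integer(n_causal_pairs),
                 effect_beta = effect_beta,
                 auc_ic50_link = auc_ic50_link,
                 ic50_max_conc = ic50_max_conc,
                 study_bias = study_bias,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Expected inter-study correlation under measurement noise
#'
#' Closed-form attenuation law: two noisy observations of a shared latent
#' signal with reliabilities `r_a` and `r_b` correlate at `sqrt(r_a * r_b)`.
#' The generator is built so this holds exactly in expectation, which makes
#' the attenuation an oracle for the per-drug correlation distributions it
#' produces.
#'
#' @param r_a,r_b Reliabilities in \[0, 1\].
#' @return `sqrt(r_a * r_b)`.
#' @examples
#' expected_attenuation(0.64, 1)   # 0.8
#' expected_attenuation(0.5, 0.5)  # 0.5
#' @export
expected_attenuation <- function(r_a, r_b) {
  if (any(r_a < 0 | r_a > 1) || any(r_b < 0 | r_b > 1))
    stop("reliabilities must lie in [0, 1]")
  sqrt(r_a * r_b)
}

#' @keywords internal
#' @noRd
substream_seed <- function(seed, component) {
  as.integer((as.numeric(seed) %% 1e6 * 2039 +
                as.numeric(component) * 9973) %% 2147483399)
}

# squash scale for the latent -> AUC logistic map; mild enough that the
# Pearson correlation of squashed bivariate normals is preserved to < 0.002
AUC_SQUASH_SCALE <- 0.6

#' @keywords internal
#' @noRd
latent_to_auc <- function(z) {
  pmin(pmax(stats::plogis(AUC_SQUASH_SCALE * z), 0), 1)
}

#' @keywords internal
#' @noRd
latent_to_log_ic50 <- function(z) {
  # fixed decreasing nonlinear map: more sensitive (high z) -> lower log-IC50
  -(z + 0.15 * z^3)
}

#' Generate a paired synthetic pharmacogenomic study
#'
#' Draws the latent truth (sensitivity, mutations, causal gene-drug set) and
#' two studies' observations of it under the noise model of
#' [simulation_params()]:
#'
#' * latent sensitivity `s(c, d)` is standard normal plus
#'   `effect_beta * mut(c, g)` summed over causal pairs `(g, d)`;
#' * each study observes `sqrt(R) * s + sqrt(1 - R) * eps` with fresh
#'   standard-normal noise, then maps the observation to AUC through a fixed
#'   logistic squash into \[0, 1\], and to log10 IC50 through the configured
#'   link, censored at the tested concentration bound;
#' * latent mutations are Bernoulli(prevalence); each study observes them
#'   with independent symmetric flips;
#' * expression and copy number are independent latent gene features observed
#'   with their own reliabilities.
#'
#' Fully determined by `params$seed`.
#'
#' @param params A [simulation_params()] object.
#' @return An object of class `synthetic_study_pair`: `params`, `truth`
#'   (latent sensitivity, latent mutations, causal pair table), and
#'   `study_a` / `study_b` [study_collection()]s holding AUC, IC50,
#'   EXPRESSION, CNV and MUTATION matrices.
#' @export
generate_pair <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  pr <- params
  cells <- sprintf("CL%04d", seq_len(pr$n_cell_lines))
  drugs <- sprintf("DRUG%03d", seq_len(pr$n_drugs))
  genes <- sprintf("GENE%04d", seq_len(pr$n_genes))
  rnmat <- function(component, nr, nc) {
    set.seed(substream_seed(pr$seed, component))
    matrix(stats::rnorm(nr * nc), nr, nc)
  }
  # latent mutation status, genes x cells
  set.seed(substream_seed(pr$seed, 1L))
  mut_true <- matrix(stats::rbinom(pr$n_genes * pr$n_cell_lines, 1L,
                                   pr$mutation_prevalence),
                     pr$n_genes, pr$n_cell_lines,
                     dimnames = list(genes, cells))
  storage.mode(mut_true) <- "double"
  # causal gene-drug pairs
  set.seed(substream_seed(pr$seed, 2L))
  grid_n <- as.numeric(pr$n_genes) * pr$n_drugs
  causal_idx <- if (pr$n_causal_pairs > 0)
    sort(sample.int(grid_n, pr$n_causal_pairs)) else integer()
  causal <- data.frame(
    gene = genes[((causal_idx - 1L) %% pr$n_genes) + 1L],
    drug = drugs[((causal_idx - 1L) %/% pr$n_genes) + 1L],
    stringsAsFactors = FALSE)
  # latent sensitivity, cells x drugs
  s <- rnmat(3L, pr$n_cell_lines, pr$n_drugs)
  dimnames(s) <- list(cells, drugs)
  for (i in seq_len(nrow(causal)))
    s[, causal$drug[i]] <- s[, causal$drug[i]] +
      pr$effect_beta * mut_true[causal$gene[i], ]
  # independent latent trait for IC50 when the link is "none" (same causal
  # effects, opposite sign: mutants respond at lower concentrations)
  u <- rnmat(4L, pr$n_cell_lines, pr$n_drugs)
  dimnames(u) <- list(cells, drugs)
  for (i in seq_len(nrow(causal)))
    u[, causal$drug[i]] <- u[, causal$drug[i]] -
      pr$effect_beta * mut_true[causal$gene[i], ]
  # latent genomic features, genes x cells
  expr_true <- rnmat(5L, pr$n_genes, pr$n_cell_lines)
  cnv_true <- rnmat(6L, pr$n_genes, pr$n_cell_lines)
  dimnames(expr_true) <- dimnames(cnv_true) <- list(genes, cells)

  observe <- function(latent, r, component, bias = 0) {
    eps <- rnmat(component, nrow(latent), ncol(latent))
    out <- sqrt(r) * latent + sqrt(1 - r) * eps + bias
    dimnames(out) <- dimnames(latent)
    out
  }
  make_study <- function(study_id, base) {
    bias <- if (study_id == "study_b") pr$study_bias else 0
    z_auc <- observe(s, pr$reliability[["AUC"]], base + 1L, bias)
    auc <- sensitivity_matrix(latent_to_auc(z_auc), "AUC", study_id)
    ic50_latent <- if (pr$auc_ic50_link == "none") u else s
    z_ic <- observe(ic50_latent, pr$reliability[["IC50"]], base + 2L, bias)
    log_ic50 <- if (pr$auc_ic50_link == "none") z_ic
                else latent_to_log_ic50(z_ic)
    ic50 <- sensitivity_matrix(log_ic50, "IC50", study_id,
                               ic50_max_conc = pr$ic50_max_conc)
    expr <- molecular_profile(
      observe(expr_true, pr$reliability[["EXPRESSION"]], base + 3L, bias),
      "EXPRESSION", study_id)
    cnv <- molecular_profile(
      observe(cnv_true, pr$reliability[["CNV"]], base + 4L, bias),
      "CNV", study_id)
    set.seed(substream_seed(pr$seed, base + 5L))
    flips <- matrix(stats::rbinom(length(mut_true), 1L,
                                  pr$mutation_flip_rate),
                    nrow(mut_true), ncol(mut_true))
    mut_obs <- abs(mut_true - flips)
    dimnames(mut_obs) <- dimnames(mut_true)
    mut <- molecular_profile(mut_obs, "MUTATION", study_id)
    study_collection(auc, ic50, expr, cnv, mut, study_id = study_id)
  }
  structure(
    list(params = pr,
         truth = list(sensitivity = s, mutation = mut_true, causal = causal,
                      ic50_latent = if (pr$auc_ic50_link == "none") u
                                    else latent_to_log_ic50(s)),
         study_a = make_study("study_a", 10L),
         study_b = make_study("study_b", 20L)),
    class = "synthetic_study_pair")
}

#' @export
print.synthetic_study_pair <- function(x, ...) {
  pr <- x$params
  cat(sprintf("<synthetic_study_pair> %d cell lines x %d drugs x %d genes, %d causal pairs, seed %d\n",
              pr$n_cell_lines, pr$n_drugs, pr$n_genes, nrow(x$truth$causal),
              pr$seed))
  cat("  reliability:",
      paste(names(pr$reliability), sprintf("%.2f", pr$reliability),
            sep = "=", collapse = " "),
      sprintf("| flip %.2f, beta %.2f, link %s\n", pr$mutation_flip_rate,
              pr$effect_beta, pr$auc_ic50_link))
  invisible(x)
}

#' Write a synthetic pair as a CSV fixture with a manifest
#'
#' Writes every observed matrix in the delimited dialect of
#' [read_sensitivity_table()] / [read_profile_table()] plus a YAML manifest
#' describing paths, measures, datatypes and censoring bounds; the latent
#' truth goes to a `truth/` subdirectory. IC50 files are written on the
#' log10 scale (recorded in the manifest) so the round trip through the
#' readers is bit-exact. Rewriting with the same pair produces byte-identical
#' files.
#'
#' @param pair A [generate_pair()] result.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_fixture <- function(pair, dir) {
  stopifnot(inherits(pair, "synthetic_study_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create fixture directory ", dir)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  manifest <- list(studies = list(), ic50_scale = "log10",
                   seed = pair$params$seed)
  for (side in c("study_a", "study_b")) {
    st <- pair[[side]]
    dir.create(file.path(dir, side), showWarnings = FALSE)
    entries <- list()
    for (m in st$sensitivity) {
      fn <- file.path(side, paste0(tolower(m$measure), ".csv"))
      write_matrix_csv(m$values, file.path(dir, fn))
      entries[[m$measure]] <- list(
        path = fn, kind = "sensitivity", measure = m$measure,
        ic50_max_conc = m$ic50_max_conc)
    }
    for (m in st$profiles) {
      fn <- file.path(side, paste0(tolower(m$datatype), ".csv"))
      write_matrix_csv(m$values, file.path(dir, fn))
      entries[[m$datatype]] <- list(path = fn, kind = "profile",
                                    datatype = m$datatype)
    }
    manifest$studies[[side]] <- list(study_id = st$study_id,
                                     tables = entries)
  }
  write_matrix_csv(pair$truth$sensitivity,
                   file.path(dir, "truth", "sensitivity.csv"))
  write_matrix_csv(pair$truth$mutation,
                   file.path(dir, "truth", "mutation.csv"))
  utils::write.csv(pair$truth$causal,
                   file.path(dir, "truth", "causal_pairs.csv"),
                   row.names = FALSE, quote = FALSE)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @keywords internal
#' @noRd
write_matrix_csv <- function(values, path) {
  header <- paste(c("", colnames(values)), collapse = ",")
  rows <- vapply(seq_len(nrow(values)), function(i)
    paste(c(rownames(values)[i], format_cell(values[i, ])), collapse = ","),
    character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a fixture manifest back into study collections
#'
#' Inverse of [write_fixture()]: loads every table listed in the manifest
#' through the package readers and rebuilds the two [study_collection()]s.
#'
#' @param manifest_path Path to a `manifest.yaml` written by
#'   [write_fixture()] (or hand-written in the same schema).
#' @return Named list with `study_a` and `study_b` collections.
#' @export
read_fixture <- function(manifest_path) {
  manifest <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  log_scale <- identical(manifest$ic50_scale, "log10")
  out <- lapply(manifest$studies, function(st) {
    members <- lapply(st$tables, function(tb) {
      path <- file.path(base, tb$path)
      if (tb$kind == "sensitivity") {
        if (tb$measure == "IC50" && log_scale) {
          vals <- read_labelled_matrix(path)
          sensitivity_matrix(vals, "IC50", st$study_id,
                             ic50_max_conc = tb$ic50_max_conc)
        } else {
          read_sensitivity_table(path, tb$measure, st$study_id,
                                 ic50_max_conc = tb$ic50_max_conc)
        }
      } else {
        read_profile_table(path, tb$datatype, st$study_id)
      }
    })
    study_collection(unname(members), study_id = st$study_id)
  })
  out
}
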