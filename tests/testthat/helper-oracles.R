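# Independent oracles used across the suite. Each deliberately re-derives the
# quantity with a different method than the implementation under test.

# Brute-force waterfall cutoff: full 2D geometry with the cross-product
# point-to-line distance, scanning every point of the sorted curve.
bf_waterfall <- function(values, linearity_min = 0.95) {
  y <- sort(values[!is.na(values)], decreasing = TRUE)
  n <- length(y)
  if (stats::sd(y) == 0) return(y[1])
  if (abs(stats::cor(seq_len(n), y)) >= linearity_min)
    return(stats::median(y))
  t <- seq(0, 1, length.out = n)
  v <- (y - min(y)) / diff(range(y))
  p1 <- c(t[1], v[1]); p2 <- c(t[n], v[n])
  a <- p2 - p1
  d <- vapply(seq_len(n), function(i) {
    b <- c(t[i], v[i]) - p1
    abs(a[1] * b[2] - a[2] * b[1]) / sqrt(sum(a^2))
  }, numeric(1))
  y[which.max(d)]
}

# Exact rank-sum p by enumeration of all C(m+n, m) rank assignments.
# rank_combos may be precomputed (combn(m+n, m)) and reused.
enum_wilcoxon_p <- function(x, y, alternative, rank_combos = NULL) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  if (is.null(rank_combos)) rank_combos <- utils::combn(m + n, m)
  w_all <- colSums(matrix(seq_len(m + n)[rank_combos], nrow = m))
  p_less <- mean(w_all <= w_obs)
  p_greater <- mean(w_all >= w_obs)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two_sided = min(1, 2 * min(p_less, p_greater)))
}

# Exact permutation p for the two-group mean comparison, two-sided on |t|.
perm_t_p <- function(response, group) {
  n <- length(response)
  n1 <- sum(group == 1)
  tstat <- function(idx) {
    g1 <- response[idx]; g0 <- response[-idx]
    sp2 <- (sum((g1 - mean(g1))^2) + sum((g0 - mean(g0))^2)) / (n - 2)
    if (sp2 == 0) return(if (mean(g1) == mean(g0)) 0 else Inf)
    (mean(g1) - mean(g0)) / sqrt(sp2 * (1 / n1 + 1 / (n - n1)))
  }
  t_obs <- abs(tstat(which(group == 1)))
  perms <- utils::combn(n, n1)
  t_all <- abs(apply(perms, 2, tstat))
  mean(t_all >= t_obs - 1e-12)
}

# Small labelled sensitivity matrix for fixture-free tests.
toy_sensitivity <- function(values, measure = "AUC", study_id = "s",
                            cells = NULL, drugs = NULL, ...) {
  values <- as.matrix(values)
  if (is.null(cells))
    cells <- if (!is.null(rownames(values))) rownames(values)
             else sprintf("CL%02d", seq_len(nrow(values)))
  if (is.null(drugs))
    drugs <- if (!is.null(colnames(values))) colnames(values)
             else sprintf("D%02d", seq_len(ncol(values)))
  dimnames(values) <- list(cells, drugs)
  sensitivity_matrix(values, measure, study_id, ...)
}

# Random vectors with a mix of linear and elbow-shaped sorted curves.
random_waterfall_vector <- function(n) {
  shape <- sample(3, 1)
  if (shape == 1) stats::runif(n)
  else if (shape == 2) {
    k <- sample(seq_len(n - 1), 1)
    c(stats::runif(k, 0.7, 1), stats::runif(n - k, 0, 0.25))
  } else stats::rbeta(n, 0.4, 0.4)
}
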