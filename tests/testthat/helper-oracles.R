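# Independent oracles and small fixture builders shared across tests.

# Exhaustive search over every circular arc/complement split, mirroring the
# statistic definition but none of the search code: pooled mean-difference
# statistic with the interval-wide variance, ties broken toward the first
# (i ascending, j ascending) maximum.
oracle_max_split <- function(v, min_width = 2) {
  m <- length(v)
  best <- list(i = -1L, j = -1L, t = 0, found = FALSE)
  tot <- sum(v)
  s2 <- sum((v - tot / m)^2) / m
  if (m < 2 * min_width || s2 < 1e-20) return(best)
  cs <- c(0, cumsum(v))
  for (i in 0:(m - 1)) {
    jmin <- i + min_width
    jmax <- min(m, i + m - min_width)
    if (jmin > jmax) next
    for (j in jmin:jmax) {
      k <- j - i
      t <- abs((cs[j + 1] - cs[i + 1]) / k -
                 (tot - cs[j + 1] + cs[i + 1]) / (m - k)) /
        sqrt(s2 * (1 / k + 1 / (m - k)))
      if (t > best$t) best <- list(i = i, j = j, t = t, found = TRUE)
    }
  }
  best
}

# Normal-equations least squares: coefficients, standard errors and t for a
# full-column-rank design, computed without qr-based shortcuts.
oracle_ols <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- unname(sqrt(diag(solve(XtX)) * sigma2))
  list(beta = as.vector(beta), se = se, t = as.vector(beta) / se, df = df)
}

# simulate_cohort silencing the sqrt(PD) clamp warning that a handful of
# tail samples trigger at the default coefficients
sim_quiet <- function(cfg) suppressWarnings(simulate_cohort(cfg))

# A tiny hand-built panel: values supplied directly, one chromosome.
toy_panel <- function(lrr, baf = NULL, plate_id = NULL, n_chrom = 1) {
  n <- nrow(lrr)
  P <- ncol(lrr)
  if (is.null(baf)) baf <- matrix(0.5, n, P)
  pm <- data.frame(
    probe_id = sprintf("tp%04d", seq_len(P)),
    chromosome = as.character(rep(seq_len(n_chrom), each = ceiling(P / n_chrom))[seq_len(P)]),
    position = 1000L * (seq_len(P)),
    is_snp = rep(TRUE, P), stringsAsFactors = FALSE)
  # positions restart ordering per chromosome for map validity
  pm <- pm[order(pm$chromosome, pm$position), ]
  samples <- data.frame(sample_id = sprintf("T%03d", seq_len(n)),
                        plate_id = plate_id %||% rep("PL01", n),
                        stringsAsFactors = FALSE)
  new_intensity_panel(lrr, baf, samples, pm)
}

# A minimal phenotype table with fixed covariates.
toy_phenotypes <- function(n, pd = NULL, family_id = NULL, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("T%03d", seq_len(n)),
             percent_density = pd %||% runif(n, 5, 60),
             age = rnorm(n, 57, 10), bmi = runif(n, 18, 40),
             menopausal = rbinom(n, 1, 0.6),
             family_id = family_id %||% sprintf("F%03d", seq_len(n)),
             plate_id = "PL01", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expected BAF cluster centres per copy-number state (restated here rather
# than taken from the package, so cluster tests stay independent).
baf_clusters_for_test <- function(state) {
  switch(as.character(state),
         `1` = c(0, 1), `2` = c(0, 0.5, 1),
         `3` = c(0, 1 / 3, 2 / 3, 1),
         `4` = c(0, 0.25, 0.5, 0.75, 1))
}
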