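#' Region summary statistic
#'
#' The arithmetic mean of the absolute probe statistics across a segment —
#' the value a candidate region is assigned and that permutation inference
#' compares against.
#'
#' @param values Non-empty numeric vector of |t| values.
#' @return Their mean.
#' @export
region_statistic <- function(values) {
  if (length(values) == 0) stop("region statistic of an empty value set")
  mean(values)
}

#' Permutation p-value convention
#'
#' `(n_exceed + 1) / (B + 1)`: the add-one convention whose floor at
#' B = 10,000 is 1/10,001 when no permuted statistic reaches the observed
#' one, and whose ceiling is 1.
#'
#' @param n_exceed Permutations with statistic >= observed (ties count).
#' @param B Number of permutations.
#' @return The p-value.
#' @export
permutation_p <- function(n_exceed, B) {
  stopifnot(B >= 1, n_exceed >= 0, n_exceed <= B)
  (n_exceed + 1) / (B + 1)
}

#' Construct a probe-index region with its expansion
#'
#' Convenience constructor for a region row in the same layout
#' [expand_segments()] produces, for testing predefined windows.
#'
#' @param chromosome Chromosome label.
#' @param start_idx,end_idx 0-based half-open chromosome-local indices.
#' @param probe_map Probe map.
#' @param expand Expansion multiple per side (0 keeps the window as is).
#' @return One-row `expanded_regions` data frame.
#' @export
region_window <- function(chromosome, start_idx, end_idx, probe_map,
                          expand = 6) {
  seg <- data.frame(chromosome = as.character(chromosome),
                    start_idx = as.integer(start_idx),
                    end_idx = as.integer(end_idx),
                    n_probes = as.integer(end_idx - start_idx),
                    mean_abs_t = NA_real_,
                    start_pos = NA_integer_, end_pos = NA_integer_,
                    stringsAsFactors = FALSE)
  rows <- which(probe_map$chromosome == seg$chromosome)
  seg$start_pos <- probe_map$position[rows[seg$start_idx + 1]]
  seg$end_pos <- probe_map$position[rows[seg$end_idx]]
  class(seg) <- c("cnv_segments", "data.frame")
  expand_segments(seg, probe_map, expand)
}

# Best-segment statistic of one |t| track: CBS, then the maximal mean |t|
# among segments with >= min_probes probes; when CBS yields no qualifying
# segment the whole-track mean is used (conservative fallback).
best_segment_stat <- function(v, min_probes, alpha, n_split_permutations,
                              min_width) {
  cps <- .cbs_segment_cpp(v, alpha, as.integer(n_split_permutations),
                          as.integer(min_width))
  iv <- changepoints_to_intervals(cps, length(v))
  w <- iv$end_idx - iv$start_idx
  best <- -Inf
  for (k in which(w >= min_probes))
    best <- max(best, mean(v[(iv$start_idx[k] + 1):iv$end_idx[k]]))
  if (is.finite(best)) best else mean(v)
}

#' Region-level permutation test
#'
#' Assigns an expanded region a permutation p-value. Per iteration the
#' phenotype (percent density only; covariates travel with their sample) is
#' shuffled across the QC-passing samples, the probe models are refit for
#' the probes inside the expanded region, CBS is applied to the resulting
#' |t| values, and the statistic recorded is the mean |t| over the best
#' resulting segment (maximal mean among segments with at least
#' `min_probes` probes, falling back to the whole-region mean when CBS
#' yields none). The p-value is `(n_exceed + 1) / (B + 1)`, ties counting
#' as exceedances, with floor 1/10,001 at B = 10,000.
#'
#' @param region One-row `expanded_regions` data frame.
#' @param panel An `intensity_panel` (QC-excluded samples removed).
#' @param phenotypes Phenotype data frame.
#' @param spec A [model_spec()]; a conditioning SNP supplied via
#'   `condition` is added to the fixed covariates of every fit, observed
#'   and permuted alike.
#' @param B Number of permutations.
#' @param seed Seed driving both the phenotype shuffles and the CBS split
#'   tests.
#' @param observed_stat Observed region statistic (the identified segment's
#'   mean |t| from the genome scan); when `NULL` it is computed from the
#'   observed track with the same best-segment rule used for permutations.
#' @param condition Optional genotype vector named by sample id.
#' @param min_probes Minimum probes for a best segment.
#' @param alpha,n_split_permutations,min_width CBS parameters.
#' @param discovery_threshold,replication_threshold Significance levels for
#'   the discovery (default 1/10,000) and replication (default 0.05) rules.
#' @param permute `"phenotype"` (the default: shuffle sqrt percent density
#'   itself) or `"residual"` (shuffle the covariate-model residuals and add
#'   them back to the fitted values, preserving the phenotype-covariate
#'   association under the null).
#' @param within_family Restrict shuffles to within `family_id` groups
#'   instead of full exchangeability across samples.
#' @return A `region_result` one-row data frame.
#' @export
permute_region <- function(region, panel, phenotypes, spec = model_spec(),
                           B = 10000, seed = 1, observed_stat = NULL,
                           condition = NULL, min_probes = 3, alpha = 0.01,
                           n_split_permutations = 1000, min_width = 2,
                           discovery_threshold = 1 / 10000,
                           replication_threshold = 0.05,
                           permute = c("phenotype", "residual"),
                           within_family = FALSE) {
  permute <- match.arg(permute)
  stopifnot(inherits(panel, "intensity_panel"), nrow(region) == 1)
  if (B < 1) stop("B must be at least 1")
  if (!is.null(condition)) {
    if (is.null(names(condition)))
      stop("conditioning genotype must be named by sample_id")
    spec <- model_spec(mixed = spec$mixed,
                       extra = c(spec$extra, list(.cond_snp = condition)))
  }
  pm <- panel$probe_map
  rows <- which(pm$chromosome == region$chromosome)
  cols <- rows[(region$exp_start_idx + 1L):region$exp_end_idx]

  m <- match(panel$samples$sample_id, phenotypes$sample_id)
  if (anyNA(m)) stop("panel samples missing from phenotype table")
  ph <- phenotypes[m, , drop = FALSE]
  d <- build_design(ph, spec)
  ok <- stats::complete.cases(d$y, d$Z)
  y <- d$y[ok]
  Z <- d$Z[ok, , drop = FALSE]
  fam <- d$family_id[ok]
  X <- panel$lrr[ok, cols, drop = FALSE]
  n <- length(y)

  fast <- !spec$mixed && !anyNA(X)
  track_t <- if (fast) {
    qz <- qr(Z)
    Xres <- X - qr.fitted(qz, X)
    sxx <- colSums(Xres^2)
    degen <- sxx < 1e-10
    df <- n - qz$rank - 1L
    function(yy) {
      yres <- qr.resid(qz, yy)
      sxy <- as.vector(crossprod(Xres, yres))
      beta <- sxy / sxx
      rss <- sum(yres^2) - beta * sxy
      t <- beta / sqrt(pmax(rss, 0) / df / sxx)
      t[degen | !is.finite(t)] <- 0
      t
    }
  } else {
    function(yy) {
      vapply(seq_len(ncol(X)), function(j) {
        r <- fit_focal(yy, cbind(lrr = X[, j]), Z, fam, spec$mixed)
        if (is.finite(r$t)) r$t else 0
      }, 0)
    }
  }

  # draw_index(): one permutation of 1..n, optionally within families
  draw_index <- if (within_family) {
    groups <- split(seq_len(n), fam)
    function() {
      idx <- integer(n)
      for (g in groups) idx[g] <- g[sample.int(length(g))]
      idx
    }
  } else {
    function() sample.int(n)
  }
  # permuted_y(): phenotype shuffle, or covariate-fit residual shuffle
  if (permute == "residual") {
    cfit <- stats::lm.fit(Z, y)
    y_fit <- cfit$fitted.values
    y_res <- cfit$residuals
    permuted_y <- function() y_fit + y_res[draw_index()]
  } else {
    permuted_y <- function() y[draw_index()]
  }

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  if (is.null(observed_stat))
    observed_stat <- best_segment_stat(abs(track_t(y)), min_probes, alpha,
                                       n_split_permutations, min_width)
  n_exceed <- 0L
  for (b in seq_len(B)) {
    s <- best_segment_stat(abs(track_t(permuted_y())), min_probes,
                           alpha, n_split_permutations, min_width)
    if (s >= observed_stat) n_exceed <- n_exceed + 1L
  }
  p <- permutation_p(n_exceed, B)
  out <- region
  out$observed_stat <- observed_stat
  out$n_exceed <- n_exceed
  out$B <- as.integer(B)
  out$p_value <- p
  out$significant_discovery <- p < discovery_threshold
  out$significant_replication <- p < replication_threshold
  class(out) <- c("region_result", "data.frame")
  out
}

#' SNP-conditional region permutation test
#'
#' [permute_region()] with the region's most significant SNP as an extra
#' fixed covariate in every probe model, observed and permuted alike; used
#' to ask whether a candidate copy-number association survives adjustment
#' for a linked SNP.
#'
#' @inheritParams permute_region
#' @param genotype_column Genotypes (0/1/2) named by sample id — typically
#'   the minimum-p SNP inside the region from [select_top_snp()].
#' @return A `region_result` one-row data frame.
#' @export
conditional_region_test <- function(region, panel, phenotypes,
                                    genotype_column, spec = model_spec(),
                                    B = 10000, seed = 1, ...) {
  permute_region(region, panel, phenotypes, spec, B = B, seed = seed,
                 condition = genotype_column, ...)
}

#' Write region permutation results
#'
#' @param results A `region_result` data frame (rows may be rbind-ed).
#' @param path Output TSV path.
#' @export
write_region_results <- function(results, path) {
  d <- results[, c("chromosome", "start_pos", "end_pos", "n_probes",
                   "observed_stat", "n_exceed", "B", "p_value",
                   "significant_discovery", "significant_replication")]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
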