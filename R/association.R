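#' Specify the per-probe phenotype model
#'
#' The response is always the square root of percent density; covariates are
#' age, inverse BMI and menopausal status, optionally extended (e.g. by a
#' conditioning SNP) and optionally with one Gaussian random intercept per
#' family, fit by maximum likelihood.
#'
#' @param mixed Use a family random intercept (`lme4`); falls back to the
#'   ordinary model, with a flag, when the mixed fit cannot converge.
#' @param extra Named list of extra fixed covariate vectors, each named by
#'   `sample_id` (aligned automatically).
#' @return A `model_spec`.
#' @export
model_spec <- function(mixed = FALSE, extra = NULL) {
  if (!is.null(extra)) {
    stopifnot(is.list(extra), !is.null(names(extra)))
    for (v in extra) if (is.null(names(v)))
      stop("extra covariates must be named by sample_id")
  }
  structure(list(mixed = mixed, extra = extra), class = "model_spec")
}

# Covariate design (intercept, age, 1/bmi, menopausal, extras), response
# sqrt(percent density), and family labels — rows with any missing field
# dropped, the contract being complete-case per fit.
build_design <- function(phenotypes, spec) {
  validate_phenotypes(phenotypes)
  Z <- cbind(`(Intercept)` = 1, age = phenotypes$age,
             invbmi = 1 / phenotypes$bmi, meno = phenotypes$menopausal)
  if (!is.null(spec$extra)) {
    for (nm in names(spec$extra)) {
      v <- spec$extra[[nm]][phenotypes$sample_id]
      Z <- cbind(Z, stats::setNames(data.frame(v), nm))
    }
    Z <- as.matrix(Z)
  }
  list(y = sqrt(phenotypes$percent_density), Z = Z,
       family_id = phenotypes$family_id,
       sample_id = phenotypes$sample_id)
}

# Joint fit of y ~ W + Z (+ (1 | family) when mixed); returns one row per
# focal column of W. Degeneracies never raise: aliased or zero-variance
# focal columns come back flagged with t = 0, a zero-residual (perfect) fit
# with se = 0 and infinite t.
fit_focal <- function(y, W, Z, family_id, mixed = FALSE) {
  W <- as.matrix(W)
  keep <- stats::complete.cases(y, W, Z)
  y <- y[keep]
  W <- W[keep, , drop = FALSE]
  Z <- Z[keep, , drop = FALSE]
  family_id <- family_id[keep]
  n <- length(y)
  # covariates first: rank-deficiency pivoting then drops the focal column,
  # so a monomorphic focal predictor is the one reported degenerate
  X <- cbind(Z, W)
  focal <- ncol(Z) + seq_len(ncol(W))
  out <- data.frame(term = colnames(W) %||% paste0("x", focal),
                    beta = NA_real_, se = NA_real_, t = 0, p = 1,
                    n_used = n, flags = "", stringsAsFactors = FALSE)
  if (n < ncol(X) + 1) {
    out$flags <- "insufficient_data"
    return(out)
  }

  ols <- function(flag_extra = "") {
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients
    df <- n - fit$rank
    rss <- sum(fit$residuals^2)
    sigma2 <- if (df > 0) rss / df else NA_real_
    R <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
    R[lower.tri(R)] <- 0
    XtXinv_diag <- rep(NA_real_, ncol(X))
    XtXinv_diag[fit$qr$pivot[seq_len(fit$rank)]] <- diag(chol2inv(R))
    for (w in seq_along(focal)) {
      k <- focal[w]
      fl <- if (nzchar(flag_extra)) flag_extra else character()
      b <- unname(beta[k])
      if (is.na(b)) {  # aliased: zero variance given covariates
        out$t[w] <<- 0; out$p[w] <<- 1
        out$flags[w] <<- paste(c(fl, "degenerate_zero_variance"), collapse = ";")
        next
      }
      se <- sqrt(sigma2 * XtXinv_diag[k])
      if (!is.finite(se) || se < 1e-12) {
        out$beta[w] <<- b; out$se[w] <<- 0
        out$t[w] <<- if (abs(b) > 0) sign(b) * Inf else 0
        out$p[w] <<- 0
        out$flags[w] <<- paste(c(fl, "degenerate_zero_residual"), collapse = ";")
        next
      }
      tt <- b / se
      out$beta[w] <<- b; out$se[w] <<- se; out$t[w] <<- tt
      out$p[w] <<- 2 * stats::pt(-abs(tt), df)
      if (nzchar(flag_extra)) out$flags[w] <<- flag_extra
    }
    out
  }

  if (!mixed) return(ols())

  fit <- tryCatch({
    df_fit <- data.frame(.y = y, .fam = factor(family_id))
    m <- lme4::lmer(.y ~ 0 + X + (1 | .fam), data = df_fit, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore",
                                                check.scaleX = "ignore"))
    codes <- m@optinfo$conv$lme4$code
    if (!is.null(codes) && any(codes < 0)) NULL else m
  }, error = function(e) NULL)
  if (is.null(fit)) return(ols("mixed_fallback"))

  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  rank_fixed <- length(b)
  dfree <- n - rank_fixed
  # lmer drops rank-deficient columns; map back by name
  nm <- sub("^X", "", names(b))
  for (w in seq_along(focal)) {
    key <- colnames(X)[focal[w]]
    j <- match(key, nm)
    if (is.na(j)) {
      out$t[w] <- 0; out$p[w] <- 1
      out$flags[w] <- "degenerate_zero_variance"
      next
    }
    out$beta[w] <- unname(b[j])
    out$se[w] <- unname(se[j])
    if (se[j] < 1e-12) {
      out$t[w] <- if (abs(b[j]) > 0) sign(b[j]) * Inf else 0
      out$p[w] <- 0
      out$flags[w] <- "degenerate_zero_residual"
    } else {
      out$t[w] <- out$beta[w] / out$se[w]
      out$p[w] <- 2 * stats::pt(-abs(out$t[w]), dfree)
    }
  }
  out
}

#' Fit the phenotype model for one probe
#'
#' Regresses sqrt percent density on the probe's LRR plus age, inverse BMI
#' and menopausal status, returning the Wald statistic for the LRR
#' coefficient. With `spec$mixed`, one Gaussian random intercept per family
#' is fit by maximum likelihood; non-convergence falls back to the ordinary
#' model with a `mixed_fallback` flag. Samples with any missing field are
#' dropped (reflected in `n_used`); degenerate probes are flagged, never an
#' error.
#'
#' @param lrr_column Numeric vector aligned with `phenotypes` rows.
#' @param phenotypes Phenotype data frame.
#' @param spec A [model_spec()].
#' @return One-row data frame: `beta`, `se`, `t`, `p`, `n_used`, `flags`.
#' @export
fit_probe_model <- function(lrr_column, phenotypes, spec = model_spec()) {
  d <- build_design(phenotypes, spec)
  res <- fit_focal(d$y, cbind(lrr = lrr_column), d$Z, d$family_id, spec$mixed)
  res[, -1]
}

#' Fit the phenotype model for one SNP
#'
#' Same contract as [fit_probe_model()] with an additively coded genotype
#' (0/1/2) in place of LRR; monomorphic SNPs come back flagged degenerate.
#'
#' @param genotype_column Genotypes in \{0, 1, 2, NA\} aligned with
#'   `phenotypes` rows.
#' @inheritParams fit_probe_model
#' @return One-row data frame as in [fit_probe_model()].
#' @export
fit_snp_model <- function(genotype_column, phenotypes, spec = model_spec()) {
  if (!all(genotype_column %in% c(0, 1, 2, NA)))
    stop("genotypes must be coded 0, 1, 2 or NA")
  d <- build_design(phenotypes, spec)
  res <- fit_focal(d$y, cbind(snp = as.numeric(genotype_column)), d$Z,
                   d$family_id, spec$mixed)
  res[, -1]
}

#' Joint SNP-conditional probe model
#'
#' Fits sqrt percent density on LRR and a conditioning SNP together (plus
#' the standard covariates), returning the adjusted statistic for each.
#' Perfect LRR-genotype collinearity yields a flagged degenerate pair.
#'
#' @param lrr_column,genotype_column Focal predictors aligned with
#'   `phenotypes` rows.
#' @inheritParams fit_probe_model
#' @return Two-row data frame (`term` = `"lrr"`, `"snp"`).
#' @export
fit_conditional_model <- function(lrr_column, genotype_column, phenotypes,
                                  spec = model_spec()) {
  d <- build_design(phenotypes, spec)
  fit_focal(d$y, cbind(lrr = lrr_column, snp = as.numeric(genotype_column)),
            d$Z, d$family_id, spec$mixed)
}

# Vectorized ordinary-model scan over the columns of X sharing one
# covariate design: residualize y and X on Z (Frisch-Waugh), then the
# per-column slope t equals the full-model Wald t with df = n - ncol(Z) - 1.
scan_ols_fast <- function(y, X, Z) {
  qz <- qr(Z)
  yres <- stats::lm.fit(Z, y)$residuals
  Xres <- X - qr.fitted(qz, X)
  n <- length(y)
  df <- n - qz$rank - 1L
  sxx <- colSums(Xres^2)
  sxy <- as.vector(crossprod(Xres, yres))
  beta <- sxy / sxx
  rss <- sum(yres^2) - beta * sxy
  se <- sqrt(pmax(rss, 0) / df / sxx)
  t <- beta / se
  flags <- rep("", ncol(X))
  degen <- sxx < 1e-10
  zero_res <- !degen & se < 1e-12
  beta[degen] <- NA; se[degen] <- NA; t[degen] <- 0
  flags[degen] <- "degenerate_zero_variance"
  t[zero_res] <- 0  # perfect fit: zeroed so the |t| track stays finite
  flags[zero_res] <- "degenerate_zero_residual"
  p <- 2 * stats::pt(-abs(t), df)
  p[degen] <- 1
  p[zero_res] <- 0
  list(beta = beta, se = se, t = t, p = p, n_used = n, flags = flags, df = df)
}

#' Genome-wide per-probe association scan
#'
#' One [fit_probe_model()] result per probe, in probe-map order. For the
#' ordinary model the scan is computed by residualizing the phenotype and
#' all LRR columns on the shared covariate design, which is algebraically
#' identical to probe-by-probe fits; probes with missing LRR values and all
#' mixed-model fits take the per-probe path. QC-excluded samples must
#' already have been removed.
#'
#' @param panel An `intensity_panel`.
#' @param phenotypes Phenotype data frame covering the panel's samples.
#' @param spec A [model_spec()].
#' @return A `probe_stats` data frame: `probe_id`, `chromosome`, `position`,
#'   `beta`, `se`, `t`, `p`, `n_used`, `flags`.
#' @export
scan_probes <- function(panel, phenotypes, spec = model_spec()) {
  stopifnot(inherits(panel, "intensity_panel"))
  pm <- panel$probe_map
  m <- match(panel$samples$sample_id, phenotypes$sample_id)
  if (anyNA(m))
    stop("panel samples missing from phenotype table: ",
         paste(utils::head(panel$samples$sample_id[is.na(m)], 5), collapse = ", "))
  ph <- phenotypes[m, , drop = FALSE]
  P <- nrow(pm)
  out <- data.frame(probe_id = pm$probe_id, chromosome = pm$chromosome,
                    position = pm$position, beta = rep(NA_real_, P),
                    se = rep(NA_real_, P), t = rep(0, P), p = rep(1, P),
                    n_used = rep(NA_integer_, P), flags = rep("", P),
                    stringsAsFactors = FALSE)
  if (nrow(pm) == 0) {
    class(out) <- c("probe_stats", "data.frame")
    return(out)
  }
  d <- build_design(ph, spec)
  base_ok <- stats::complete.cases(d$y, d$Z)
  slow_cols <- integer()
  if (!spec$mixed) {
    X <- panel$lrr[base_ok, , drop = FALSE]
    col_ok <- colSums(is.na(X)) == 0
    if (any(col_ok)) {
      f <- scan_ols_fast(d$y[base_ok], X[, col_ok, drop = FALSE],
                         d$Z[base_ok, , drop = FALSE])
      out$beta[col_ok] <- f$beta; out$se[col_ok] <- f$se
      out$t[col_ok] <- f$t; out$p[col_ok] <- f$p
      out$n_used[col_ok] <- f$n_used; out$flags[col_ok] <- f$flags
    }
    slow_cols <- which(!col_ok)
  } else {
    slow_cols <- seq_len(nrow(pm))
  }
  for (j in slow_cols) {
    r <- fit_focal(d$y, cbind(lrr = panel$lrr[, j]), d$Z, d$family_id,
                   spec$mixed)
    out$beta[j] <- r$beta; out$se[j] <- r$se
    out$t[j] <- if (is.finite(r$t)) r$t else 0
    out$p[j] <- r$p; out$n_used[j] <- r$n_used; out$flags[j] <- r$flags
    if (!is.finite(r$t) && !nzchar(r$flags))
      out$flags[j] <- "degenerate_zero_residual"
  }
  class(out) <- c("probe_stats", "data.frame")
  out
}

#' Write a per-probe association TSV
#'
#' @param stats A `probe_stats` data frame.
#' @param path Output path.
#' @export
write_probe_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Most significant SNP within an expanded region
#'
#' Evaluates every genotyped SNP probe whose position falls inside the
#' expanded region with [fit_snp_model()] and returns the minimum-p SNP.
#'
#' @param genotypes Samples x SNPs matrix (rownames sample ids).
#' @param probe_map Probe map.
#' @param region One-row expanded region (from [expand_segments()]).
#' @param phenotypes Phenotype data frame.
#' @param spec A [model_spec()].
#' @return List `snp_id`, `p`, `stat` (the fitted row), or `NULL` when the
#'   region contains no genotyped SNP.
#' @export
select_top_snp <- function(genotypes, probe_map, region, phenotypes,
                           spec = model_spec()) {
  ids <- region_probe_ids(probe_map, region$chromosome,
                          region$exp_start_idx, region$exp_end_idx)
  ids <- intersect(ids, colnames(genotypes))
  if (length(ids) == 0) return(NULL)
  g <- genotypes[match(phenotypes$sample_id, rownames(genotypes)), ids,
                 drop = FALSE]
  best <- NULL
  for (id in ids) {
    r <- fit_snp_model(g[, id], phenotypes, spec)
    if (is.null(best) || r$p < best$p)
      best <- list(snp_id = id, p = r$p, stat = r)
  }
  best
}

# Probe ids for a chromosome-local 0-based half-open index window.
region_probe_ids <- function(probe_map, chromosome, start_idx, end_idx) {
  rows <- which(probe_map$chromosome == chromosome)
  probe_map$probe_id[rows[(start_idx + 1L):end_idx]]
}
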