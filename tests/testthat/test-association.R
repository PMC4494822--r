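test_that("ordinary probe model matches the normal-equations oracle", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(12:20, 1)
    ph <- toy_phenotypes(n, seed = rep)
    x <- rnorm(n)
    got <- fit_probe_model(x, ph)
    X <- cbind(x, 1, ph$age, 1 / ph$bmi, ph$menopausal)
    want <- oracle_ols(sqrt(ph$percent_density), X)
    expect_equal(got$beta, want$beta[1], tolerance = 1e-8)
    expect_equal(got$se, want$se[1], tolerance = 1e-8)
    expect_equal(got$t, want$t[1], tolerance = 1e-8)
    expect_equal(got$p, unname(2 * pt(-abs(want$t[1]), want$df)),
                 tolerance = 1e-10)
    expect_equal(got$n_used, n)
  }
})

test_that("scan matches per-probe fits and is invariant to sample order", {
  cfg <- scenario_deletion_config(seed = 8, n_families = 20)
  co <- sim_quiet(cfg)
  panel <- median_normalize_by_plate(co$panel)
  ps <- scan_probes(panel, co$phenotypes)
  for (j in c(1, 500, 501, 1700)) {
    single <- fit_probe_model(panel$lrr[, j], co$phenotypes)
    expect_equal(ps$t[j], single$t, tolerance = 1e-8)
  }
  set.seed(3)
  perm <- sample(nrow(panel$lrr))
  shuf <- panel
  shuf$lrr <- panel$lrr[perm, , drop = FALSE]
  shuf$baf <- panel$baf[perm, , drop = FALSE]
  shuf$samples <- panel$samples[perm, , drop = FALSE]
  ps2 <- scan_probes(shuf, co$phenotypes)
  expect_equal(ps2$t, ps$t, tolerance = 1e-10)
})

test_that("null scan t-statistics are standard-normal-like and calibrated", {
  set.seed(99)
  n <- 500
  ph <- toy_phenotypes(n, seed = 99)
  lrr <- matrix(rnorm(n * 1000, 0, 0.15), n, 1000)
  panel <- toy_panel(lrr)
  ps <- scan_probes(panel, ph)
  expect_lt(abs(mean(ps$t)), 0.1)
  expect_lt(abs(sd(ps$t) - 1), 0.1)
  frac <- mean(ps$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("degenerate probes are flagged, not fatal", {
  n <- 30
  ph <- toy_phenotypes(n, seed = 5)
  zero_var <- fit_probe_model(rep(0.3, n), ph)
  expect_equal(zero_var$t, 0)
  expect_equal(zero_var$p, 1)
  expect_match(zero_var$flags, "zero_variance")
  # exact linear relation, constant covariates: perfect-fit path
  x <- rnorm(6)
  ph6 <- data.frame(sample_id = sprintf("T%03d", 1:6),
                    percent_density = (2 + 0.5 * x)^2, age = 50, bmi = 25,
                    menopausal = 1, family_id = "F1", plate_id = "P1")
  perfect <- fit_probe_model(x, ph6)
  expect_equal(perfect$se, 0)
  expect_match(perfect$flags, "zero_residual")
  # inside a scan the degenerate column stays a finite 0 in the track
  lrr <- cbind(matrix(rnorm(n * 5), n), rep(1, n))
  ps <- scan_probes(toy_panel(lrr), ph)
  expect_equal(ps$t[6], 0)
  expect_match(ps$flags[6], "zero_variance")
  # empty probe set: vacuous scan
  empty <- scan_probes(toy_panel(matrix(0, n, 0),
                                 baf = matrix(0, n, 0)), ph)
  expect_equal(nrow(empty), 0)
})

test_that("mixed model equals GLS at the estimated variance components", {
  cfg <- scenario_deletion_config(seed = 15, gamma = 1, n_families = 12,
                                  family_size_range = c(6, 6))
  co <- sim_quiet(cfg)
  ph <- co$phenotypes
  x <- median_normalize_by_plate(co$panel)$lrr[, 500]
  got <- fit_probe_model(x, ph, model_spec(mixed = TRUE))
  y <- sqrt(ph$percent_density)
  X <- cbind(x, 1, ph$age, 1 / ph$bmi, ph$menopausal)
  fam <- factor(ph$family_id)
  m <- suppressWarnings(lme4::lmer(y ~ 0 + X + (1 | fam), REML = FALSE))
  vc <- lme4::VarCorr(m)
  V <- as.numeric(vc$fam) * tcrossprod(model.matrix(~ 0 + fam)) +
    attr(vc, "sc")^2 * diag(length(y))
  Vi <- solve(V)
  bgls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  expect_equal(got$beta, unname(bgls[1, 1]), tolerance = 1e-6)
  segls <- unname(sqrt(diag(solve(t(X) %*% Vi %*% X)))[1])
  expect_equal(got$se, segls, tolerance = 1e-6)
})

test_that("a single family collapses the mixed model to the ordinary one", {
  n <- 40
  ph <- toy_phenotypes(n, family_id = rep("F1", n), seed = 31)
  x <- rnorm(n)
  mixed <- fit_probe_model(x, ph, model_spec(mixed = TRUE))
  plain <- fit_probe_model(x, ph)
  expect_equal(mixed$beta, plain$beta, tolerance = 1e-8)
  expect_match(mixed$flags, "mixed_fallback")
})

test_that("SNP model obeys coding symmetry and flags monomorphic SNPs", {
  set.seed(44)
  n <- 500
  g <- rbinom(n, 2, 0.3)
  ph <- toy_phenotypes(n, seed = 4400)  # separate stream from g's
  ph$percent_density <- pmin(100, pmax(0, (sqrt(ph$percent_density) + 1.0 * g)^2))
  fit <- fit_snp_model(g, ph)
  expect_lt(abs(fit$beta - 1.0), 3 * fit$se)
  flipped <- fit_snp_model(2 - g, ph)
  expect_equal(flipped$beta, -fit$beta, tolerance = 1e-10)
  expect_equal(abs(flipped$t), abs(fit$t), tolerance = 1e-10)
  mono <- fit_snp_model(rep(2, n), ph)
  expect_match(mono$flags, "zero_variance")
  expect_error(fit_snp_model(c(3, rep(1, n - 1)), ph), "0, 1, 2")
})

test_that("conditional model adjusts away a SNP-driven LRR association", {
  set.seed(55)
  attenuated <- 0
  for (rep in 1:40) {
    n <- 300
    g <- rbinom(n, 1, 0.3)
    # LRR correlated with the SNP at roughly r2 = 0.8
    x <- 0.9 * g + rnorm(n, 0, 0.45 * sd(g))
    ph <- toy_phenotypes(n, seed = 1000 + rep)
    ph$percent_density <- pmin(100, pmax(0,
      (sqrt(ph$percent_density) + 1.2 * g)^2))
    un <- fit_probe_model(x, ph)
    both <- fit_conditional_model(x, g, ph)
    if (abs(both$t[both$term == "lrr"]) < abs(un$t)) {
      attenuated <- attenuated + 1
    }
  }
  expect_gte(attenuated, 38)  # >= 95% of replicates
})

test_that("conditional model handles degenerate genotype columns", {
  set.seed(66)
  n <- 100
  x <- rnorm(n)
  ph <- toy_phenotypes(n, seed = 66)
  un <- fit_probe_model(x, ph)
  both <- fit_conditional_model(x, rep(0, n), ph)
  lrr_row <- both[both$term == "lrr", ]
  expect_equal(lrr_row$t, un$t, tolerance = 1e-10)
  expect_match(both$flags[both$term == "snp"], "zero_variance")
  # perfectly collinear pair: flagged, no exception
  coll <- fit_conditional_model(x, x, ph)
  expect_true(any(grepl("degenerate", coll$flags)))
})

test_that("LRR-driven associations survive adjustment for an unrelated SNP", {
  set.seed(77)
  kept <- 0
  for (rep in 1:20) {
    n <- 300
    x <- rnorm(n, 0, 0.3)
    g <- rbinom(n, 2, 0.4)
    ph <- toy_phenotypes(n, seed = 2000 + rep)
    ph$percent_density <- pmin(100, pmax(0,
      (sqrt(ph$percent_density) + 2 * x)^2))
    both <- fit_conditional_model(x, g, ph)
    if (both$p[both$term == "lrr"] < 0.001) kept <- kept + 1
  }
  expect_gte(kept, 19)
})
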