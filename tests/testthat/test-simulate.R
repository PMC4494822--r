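test_that("null configuration yields diploid samples with near-zero mean LRR", {
  cfg <- simulation_config(n_families = 30, family_size_range = c(3, 5),
                           n_probes = 500, n_chromosomes = 1, seed = 5)
  co <- sim_quiet(cfg)
  expect_s3_class(co$panel, "intensity_panel")
  expect_equal(ncol(co$truth), 3)  # no cn columns without regions
  probe_means <- colMeans(co$panel$lrr)
  expect_lt(max(abs(probe_means)), 0.1)
  expect_lt(abs(mean(co$panel$lrr)), 0.05)
})

test_that("deletion-carrier fraction matches the configured frequency", {
  cfg <- scenario_deletion_config(seed = 17, n_families = 120,
                                  family_size_range = c(4, 6))
  co <- sim_quiet(cfg)
  n <- nrow(co$truth)
  expect_gte(n, 400)
  frac <- mean(co$truth$cn_region1 != 2)
  tol <- 3 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(frac - 0.3), tol)
  # carriers' LRR shifted in the region, diploids not
  reg_cols <- 496:505
  del1 <- co$truth$cn_region1 == 1
  expect_lt(mean(co$panel$lrr[del1, reg_cols]), -0.3)
  dip <- co$truth$cn_region1 == 2
  expect_lt(abs(mean(co$panel$lrr[dip, reg_cols])), 0.1)
})

test_that("identical seeds give bit-identical cohorts, different seeds differ", {
  cfg <- scenario_deletion_config(seed = 3, n_families = 10)
  a <- sim_quiet(cfg)
  b <- sim_quiet(cfg)
  expect_identical(a$panel$lrr, b$panel$lrr)
  expect_identical(a$panel$baf, b$panel$baf)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$genotypes, b$genotypes)
  c2 <- sim_quiet(scenario_deletion_config(seed = 4, n_families = 10))
  expect_false(identical(a$panel$lrr, c2$panel$lrr))
})

test_that("overlapping regions are rejected at validation", {
  r1 <- true_region("1", 10, 30, deletion_freq = 0.1)
  r2 <- true_region("1", 25, 40, deletion_freq = 0.1)
  expect_error(simulation_config(n_probes = 200, n_chromosomes = 1,
                                 cnv_regions = list(r1, r2)),
               "overlap")
  # same indices on different chromosomes are fine
  r3 <- true_region("2", 25, 40, deletion_freq = 0.1)
  expect_s3_class(simulation_config(n_probes = 200, n_chromosomes = 2,
                                    cnv_regions = list(r1, r3)),
                  "simulation_config")
})

test_that("region invariants are enforced", {
  expect_error(true_region("1", 10, 30, deletion_freq = 0.7,
                           duplication_freq = 0.5), "\\[0, 1\\]")
  bad_means <- c(`0` = -3.5, `1` = -0.45, `2` = 0, `3` = -0.1, `4` = 0.68)
  expect_error(true_region("1", 10, 30, lrr_means = bad_means), "increasing")
  off_diploid <- c(`0` = -3.5, `1` = -0.45, `2` = 0.1, `3` = 0.4, `4` = 0.68)
  expect_error(true_region("1", 10, 30, lrr_means = off_diploid), "diploid")
  reg <- true_region("1", 190, 220)
  expect_error(simulation_config(n_probes = 200, n_chromosomes = 1,
                                 cnv_regions = list(reg)), "beyond")
})

test_that("BAF cluster patterns follow the simulated copy number", {
  reg <- true_region("1", 50, 80, deletion_freq = 0.4,
                     duplication_freq = 0.3)
  cfg <- simulation_config(n_families = 80, family_size_range = c(4, 6),
                           n_probes = 300, n_chromosomes = 1,
                           cnv_regions = list(reg), seed = 9)
  co <- sim_quiet(cfg)
  cols <- 51:80
  cn <- co$truth$cn_region1
  baf_near <- function(b, centers, tol = 0.08)
    mean(vapply(b, function(x) any(abs(x - centers) < tol), NA))
  for (state in c(1, 2, 3, 4)) {
    rows <- which(cn == state)
    if (length(rows) == 0) next
    b <- as.vector(co$panel$baf[rows, cols])
    expect_gt(baf_near(b, baf_clusters_for_test(state)), 0.98)
  }
  # copy-zero BAF is uniform-ish: a mid band holds roughly its share of mass
  rows0 <- which(cn == 0)
  b0 <- as.vector(co$panel$baf[rows0, cols])
  expect_gt(mean(b0 > 0.3 & b0 < 0.7), 0.25)
})

test_that("phenotype generation conserves the configured coefficients", {
  cfg <- scenario_deletion_config(seed = 23, gamma = 0.8, n_families = 110,
                                  family_size_range = c(4, 6))
  co <- sim_quiet(cfg)
  tr <- co$truth
  ph <- co$phenotypes
  expect_gte(nrow(ph), 400)
  d <- data.frame(y = sqrt(ph$percent_density), age = ph$age,
                  invbmi = 1 / ph$bmi, meno = ph$menopausal,
                  dosage = tr$cn_region1 - 2)
  fit <- summary(lm(y ~ age + invbmi + meno + dosage, data = d))$coefficients
  true <- attr(tr, "pheno_coeffs")
  for (pair in list(c("(Intercept)", "intercept"), c("age", "age"),
                    c("invbmi", "invbmi"), c("meno", "meno"),
                    c("dosage", "cnv"))) {
    est <- fit[pair[1], "Estimate"]
    se <- fit[pair[1], "Std. Error"]
    expect_lt(abs(est - true[[pair[2]]]), 3 * se)
  }
})

test_that("QC failure injection perturbs only the designated samples", {
  cfg <- scenario_null_config(seed = 31, n_families = 3,
                              family_size_range = c(2, 2), n_probes = 2000)
  co <- sim_quiet(cfg)
  panel <- co$panel
  ids <- panel$samples$sample_id
  expect_identical(simulate_qc_failures(panel, list()), panel)
  expect_error(simulate_qc_failures(panel, list(list(sample = "nope",
                                                     type = "noisy_lrr"))),
               "unknown sample")
  set.seed(1)
  p2 <- simulate_qc_failures(panel, list(
    list(sample = ids[1], type = "noisy_lrr", magnitude = 0.5),
    list(sample = ids[2], type = "baf_drift")))
  expect_gt(sd(p2$lrr[1, ]), 0.35)
  drift <- mean((p2$baf[2, ] > 0.2 & p2$baf[2, ] < 0.25) |
                  (p2$baf[2, ] > 0.75 & p2$baf[2, ] < 0.8))
  expect_gt(drift, 0.0015)
  # untouched samples bitwise identical
  expect_identical(p2$lrr[3:6, ], panel$lrr[3:6, ])
  expect_identical(p2$baf[c(1, 3:6), ], panel$baf[c(1, 3:6), ])
})

test_that("linked SNP hits its target r2 across the LD range", {
  cfg <- scenario_deletion_config(seed = 41, gamma = 0, n_families = 125,
                                  family_size_range = c(4, 4))
  co <- sim_quiet(cfg)
  expect_gte(nrow(co$truth), 500)
  carrier <- as.integer(co$truth$cn_region1 != 2)
  set.seed(7)
  perfect <- simulate_linked_snp(co, 1, r2_target = 1)
  g1 <- perfect$genotypes[, perfect$linked_snps[[1]]$snp_id]
  expect_identical(unname(g1), carrier)
  set.seed(8)
  none <- simulate_linked_snp(co, 1, r2_target = 0)
  g0 <- none$genotypes[, none$linked_snps[[1]]$snp_id]
  expect_lt(abs(cor(g0, carrier)), 0.1)
  set.seed(9)
  mid <- simulate_linked_snp(co, 1, r2_target = 0.8)
  expect_lt(abs(mid$linked_snps[[1]]$realized_r2 - 0.8), 0.1)
})

test_that("linked SNP requires carriers", {
  cfg <- scenario_deletion_config(seed = 43, gamma = 0, n_families = 5,
                                  deletion_freq = 0)
  co <- sim_quiet(cfg)
  expect_error(simulate_linked_snp(co, 1, 0.8), "no carriers")
})
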