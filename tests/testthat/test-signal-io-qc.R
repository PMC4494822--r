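test_that("signal files round-trip and align to probe-map order", {
  cfg <- scenario_null_config(seed = 11, n_families = 2,
                              family_size_range = c(2, 2), n_probes = 120)
  co <- sim_quiet(cfg)
  dir <- withr::local_tempdir()
  paths <- write_signal_files(co$panel, dir)
  panel2 <- read_signal_files(paths, co$probe_map,
                              plate_ids = co$panel$samples$plate_id)
  expect_equal(panel2$lrr, co$panel$lrr)
  expect_equal(panel2$baf, co$panel$baf)

  # shuffle one file's rows: values must come back in map order
  d <- read.delim(paths[1], check.names = FALSE)
  set.seed(2)
  write.table(d[sample(nrow(d)), ], paths[1], sep = "\t", quote = FALSE,
              row.names = FALSE)
  panel3 <- read_signal_files(paths, co$probe_map)
  expect_equal(panel3$lrr[1, ], co$panel$lrr[1, ])

  # drop one probe: that cell missing, reported via message
  write.table(d[-5, ], paths[1], sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_message(panel4 <- read_signal_files(paths, co$probe_map),
                 "1 probe\\(s\\) absent")
  expect_true(is.na(panel4$lrr[1, 5]))
  expect_equal(panel4$lrr[1, -5], co$panel$lrr[1, -5])

  # duplicate probe and sparse coverage are errors
  write.table(rbind(d, d[3, ]), paths[1], sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_signal_files(paths, co$probe_map), "duplicate probe")
  write.table(d[1:30, ], paths[1], sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_signal_files(paths, co$probe_map), "fewer than half")
})

test_that("cohort tables round-trip through their text formats", {
  cfg <- scenario_deletion_config(seed = 13, n_families = 4)
  co <- sim_quiet(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  pm <- read_probe_map(file.path(dir, "probe_map.tsv"))
  expect_equal(pm, co$probe_map)
  ph <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  expect_equal(ph$sample_id, co$phenotypes$sample_id)
  expect_equal(ph$percent_density, co$phenotypes$percent_density,
               tolerance = 1e-12)
  g <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_equal(unname(g), unname(co$genotypes))
})

test_that("per-plate median normalization zeroes each plate and is idempotent", {
  set.seed(4)
  lrr <- matrix(rnorm(6 * 200), 6, 200)
  plate <- rep(c("A", "B"), each = 3)
  lrr[plate == "A", ] <- lrr[plate == "A", ] + 0.1
  lrr[plate == "B", ] <- lrr[plate == "B", ] - 0.3
  panel <- toy_panel(lrr, plate_id = plate)
  norm <- median_normalize_by_plate(panel)
  for (pl in c("A", "B"))
    expect_equal(median(norm$lrr[plate == pl, ]), 0)
  expect_equal(norm$baf, panel$baf)
  # pure location shift: every value moves by minus the plate median
  shift_a <- median(lrr[plate == "A", ])
  expect_equal(unname(norm$lrr[plate == "A", ]), lrr[plate == "A", ] - shift_a)
  # idempotent
  norm2 <- median_normalize_by_plate(norm)
  expect_equal(norm2$lrr, norm$lrr)
  # already-centred plate is unchanged
  centred <- lrr - median(lrr)
  p_one <- toy_panel(centred, plate_id = rep("A", 6))
  expect_equal(unname(median_normalize_by_plate(p_one)$lrr), centred)
})

test_that("QC metrics are exact on constructed samples", {
  P <- 2000
  lrr <- rbind(rep(0, P),                      # clean
               c(rep(0, 1000), rep(0.4, 1000)))  # strong half-genome shift
  baf <- rbind(rep(c(0, 0.5, 1), length.out = P),
               rep(c(0, 0.5, 1), length.out = P))
  panel <- toy_panel(lrr, baf)
  m <- compute_qc_metrics(panel)
  expect_equal(m$lrr_sd[1], 0)
  expect_equal(m$baf_drift[1], 0)
  expect_equal(m$wave_factor[1], 0)
  expect_equal(m$n_cnv_intervals[1], 0)
  # sample 2: two windows with medians 0 and 0.4 -> sd = 0.4/sqrt(2)*sqrt(2)
  expect_equal(m$wave_factor[2], sd(c(0, 0.4)))
  expect_equal(m$n_cnv_intervals[2], 1)
})

test_that("lrr_sd and baf_drift estimates recover constructed levels", {
  set.seed(6)
  P <- 10000
  lrr <- matrix(rnorm(2 * P, 0, 0.5), 2, P)
  baf <- matrix(rep(c(0, 0.5, 1), length.out = 2 * P), 2, P)
  idx <- sample.int(P, round(0.01 * P))
  baf[2, idx] <- 0.22
  m <- compute_qc_metrics(toy_panel(lrr, baf))
  expect_lt(abs(m$lrr_sd[1] - 0.5) / 0.5, 0.1)
  expect_equal(m$baf_drift[2], 0.01)
  expect_gt(m$baf_drift[2], 0.0015)
})

test_that("exclusion thresholds are strict and reasons enumerate violations", {
  base <- data.frame(sample_id = sprintf("S%d", 1:6),
                     lrr_sd = c(0.40, 0.35, 0.2, 0.2, 0.2, 0.5),
                     baf_drift = c(0, 0.0015, 0.002, 0, 0, 0.01),
                     wave_factor = c(0, 0.05, 0, 0.06, 0, 0),
                     n_cnv_intervals = c(0L, 500L, 0L, 0L, 501L, 0L),
                     excluded = FALSE, exclusion_reasons = "",
                     stringsAsFactors = FALSE)
  m <- apply_qc_exclusions(base)
  expect_equal(m$excluded, c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(m$exclusion_reasons[1], "lrr_sd")
  expect_equal(m$exclusion_reasons[2], "")  # all metrics exactly at threshold
  expect_equal(m$exclusion_reasons[3], "baf_drift")
  expect_equal(m$exclusion_reasons[4], "wave_factor")
  expect_equal(m$exclusion_reasons[5], "n_cnv_intervals")
  expect_equal(m$exclusion_reasons[6], "lrr_sd;baf_drift")
  expect_true(all(m$excluded == nzchar(m$exclusion_reasons)))
})

test_that("exclusion is monotone in lrr_sd", {
  base <- data.frame(sample_id = "S1", lrr_sd = 0.30, baf_drift = 0,
                     wave_factor = 0, n_cnv_intervals = 0L,
                     excluded = FALSE, exclusion_reasons = "",
                     stringsAsFactors = FALSE)
  was_excluded <- FALSE
  for (v in seq(0.30, 0.60, by = 0.05)) {
    base$lrr_sd <- v
    now <- apply_qc_exclusions(base)$excluded
    expect_false(was_excluded && !now)
    was_excluded <- now
  }
  expect_true(was_excluded)
})

test_that("QC metrics are invariant to within-chromosome probe shuffling plus re-sort", {
  cfg <- scenario_null_config(seed = 21, n_families = 2,
                              family_size_range = c(2, 2), n_probes = 1000,
                              n_chromosomes = 1)
  co <- sim_quiet(cfg)
  panel <- co$panel
  m1 <- compute_qc_metrics(panel)
  set.seed(3)
  perm <- sample(ncol(panel$lrr))
  shuffled <- panel
  shuffled$lrr <- panel$lrr[, perm]
  shuffled$baf <- panel$baf[, perm]
  shuffled$probe_map <- panel$probe_map[perm, ]
  back <- order(shuffled$probe_map$chromosome, shuffled$probe_map$position)
  shuffled$lrr <- shuffled$lrr[, back]
  shuffled$baf <- shuffled$baf[, back]
  shuffled$probe_map <- shuffled$probe_map[back, ]
  m2 <- compute_qc_metrics(shuffled)
  expect_equal(m1[, -1], m2[, -1])
})

test_that("too few probes auto-excludes with its own reason", {
  lrr <- matrix(NA_real_, 2, 300)
  lrr[1, ] <- rnorm(300, 0, 0.1)
  lrr[2, 1:50] <- rnorm(50, 0, 0.1)
  m <- compute_qc_metrics(toy_panel(lrr))
  expect_false(m$excluded[1])
  expect_true(m$excluded[2])
  expect_match(m$exclusion_reasons[2], "insufficient probes")
  expect_true(is.na(m$lrr_sd[2]))
})
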