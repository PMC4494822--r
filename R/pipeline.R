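#' Full-pipeline configuration
#'
#' Collects every stage parameter with its standard default: QC thresholds
#' (0.35 / 0.0015 / 0.05 / 500), segment retention (at least 3 probes and
#' mean |t| above 1), 6x expansion, B = 10,000 permutations with discovery significance
#' p < 1/10,000 and replication significance 0.05, and one global seed that
#' drives per-stage seed derivation.
#'
#' @param sim_config A [simulation_config()] to generate the cohort, or
#'   `NULL` to read one from `input_dir`.
#' @param input_dir Directory holding `signals/`, `probe_map.tsv`,
#'   `phenotypes.csv` and optionally `genotypes.tsv` (as written by
#'   [write_cohort()]).
#' @param out_dir Optional output directory for stage TSVs and the report.
#' @param mixed Use the family random-intercept model.
#' @param qc_thresholds Named QC cutoffs (see [apply_qc_exclusions()]).
#' @param min_probes,mean_t_threshold Segment retention rules.
#' @param expand Expansion multiple per side.
#' @param B Permutations per region.
#' @param alpha,n_split_permutations CBS split-test parameters.
#' @param discovery_threshold,replication_threshold Significance rules.
#' @param condition_snp `"none"`, or `"auto"` to adjust each region for its
#'   most significant SNP (when genotypes are available).
#' @param call_regions Force copy-number calls in each candidate region and
#'   test the deletion-carrier contrast.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim_config = NULL, input_dir = NULL,
                            out_dir = NULL, mixed = FALSE,
                            qc_thresholds = c(lrr_sd = 0.35,
                                              baf_drift = 0.0015,
                                              wave_factor = 0.05,
                                              n_cnv_intervals = 500),
                            min_probes = 3, mean_t_threshold = 1,
                            expand = 6, B = 10000, alpha = 0.01,
                            n_split_permutations = 1000,
                            discovery_threshold = 1 / 10000,
                            replication_threshold = 0.05,
                            condition_snp = c("none", "auto"),
                            call_regions = TRUE, seed = 1) {
  if (is.null(sim_config) && is.null(input_dir))
    stop("either sim_config or input_dir is required")
  structure(list(sim_config = sim_config, input_dir = input_dir,
                 out_dir = out_dir, mixed = mixed,
                 qc_thresholds = qc_thresholds, min_probes = min_probes,
                 mean_t_threshold = mean_t_threshold, expand = expand,
                 B = as.integer(B), alpha = alpha,
                 n_split_permutations = as.integer(n_split_permutations),
                 discovery_threshold = discovery_threshold,
                 replication_threshold = replication_threshold,
                 condition_snp = match.arg(condition_snp),
                 call_regions = call_regions, seed = as.integer(seed)),
            class = "pipeline_config")
}

read_cohort_inputs <- function(dir) {
  pm <- read_probe_map(file.path(dir, "probe_map.tsv"))
  ph <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  paths <- list.files(file.path(dir, "signals"), full.names = TRUE)
  panel <- read_signal_files(paths, pm)
  m <- match(panel$samples$sample_id, ph$sample_id)
  if (!anyNA(m)) panel$samples$plate_id <- ph$plate_id[m]
  gpath <- file.path(dir, "genotypes.tsv")
  genotypes <- if (file.exists(gpath)) read_genotypes(gpath) else NULL
  list(probe_map = pm, panel = panel, phenotypes = ph,
       genotypes = genotypes, truth = NULL)
}

#' Run the full probe-level CNV association pipeline
#'
#' Stages, in order: cohort simulation (or input reading), per-plate median
#' normalization, sample QC and exclusion, the per-probe association scan,
#' CBS candidate-segment identification and 6x expansion, region-level
#' permutation inference (optionally SNP-conditional), and forced
#' copy-number calling with a deletion-carrier association test in each
#' candidate region. With simulated input, recovery against the embedded
#' ground truth is reported. Identical configurations produce identical
#' reports.
#'
#' @param config A [pipeline_config()].
#' @return A `cnv_report` list; see its `print()` method for a summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 3)
  cohort <- if (!is.null(config$sim_config)) {
    simulate_cohort(config$sim_config)
  } else {
    read_cohort_inputs(config$input_dir)
  }
  spec <- model_spec(mixed = config$mixed)

  panel <- median_normalize_by_plate(cohort$panel)
  metrics <- compute_qc_metrics(panel)
  metrics <- apply_qc_exclusions(metrics, config$qc_thresholds)
  kept <- drop_excluded_samples(panel, cohort$phenotypes, metrics)

  stats <- scan_probes(kept$panel, kept$phenotypes, spec)
  segments <- identify_candidate_segments(
    stats, min_probes = config$min_probes,
    mean_t_threshold = config$mean_t_threshold, alpha = config$alpha,
    n_split_permutations = config$n_split_permutations, seed = seeds[1])
  regions <- expand_segments(segments, cohort$probe_map, config$expand)

  region_results <- NULL
  conditional_results <- NULL
  calls <- list()
  carrier <- NULL
  perm_seeds <- derive_seeds(seeds[2], max(1L, nrow(regions)))
  for (k in seq_len(nrow(regions))) {
    rr <- permute_region(regions[k, ], kept$panel, kept$phenotypes, spec,
                         B = config$B, seed = perm_seeds[k],
                         observed_stat = regions$mean_abs_t[k],
                         min_probes = config$min_probes,
                         alpha = config$alpha,
                         n_split_permutations = config$n_split_permutations,
                         discovery_threshold = config$discovery_threshold,
                         replication_threshold = config$replication_threshold)
    region_results <- rbind(region_results, rr)
    if (config$condition_snp == "auto" && !is.null(cohort$genotypes)) {
      top <- select_top_snp(cohort$genotypes, cohort$probe_map,
                            regions[k, ], kept$phenotypes, spec)
      if (!is.null(top)) {
        g <- stats::setNames(
          cohort$genotypes[, top$snp_id],
          rownames(cohort$genotypes))
        cr <- conditional_region_test(
          regions[k, ], kept$panel, kept$phenotypes, g, spec,
          B = config$B, seed = perm_seeds[k],
          min_probes = config$min_probes, alpha = config$alpha,
          n_split_permutations = config$n_split_permutations,
          discovery_threshold = config$discovery_threshold,
          replication_threshold = config$replication_threshold)
        cr$snp_id <- top$snp_id
        cr$snp_p <- top$p
        conditional_results <- rbind(conditional_results, cr)
      }
    }
    if (config$call_regions && regions$n_probes[k] >= 3) {
      cl <- call_region_copy_number(kept$panel, regions[k, ])
      calls[[k]] <- cl
      ca <- tryCatch(carrier_association(cl, kept$phenotypes, spec),
                     error = function(e) NULL)
      if (!is.null(ca)) {
        ca$chromosome <- regions$chromosome[k]
        ca$start_pos <- regions$start_pos[k]
        carrier <- rbind(carrier, ca)
      }
    }
  }

  recovery <- NULL
  if (!is.null(cohort$truth) && length(attr(cohort$truth, "regions"))) {
    tr <- attr(cohort$truth, "regions")
    recovery <- data.frame(
      region = seq_along(tr),
      chromosome = vapply(tr, `[[`, "", "chromosome"),
      identified = vapply(seq_along(tr), function(i) {
        r <- tr[[i]]
        any(segments$chromosome == r$chromosome &
              segments$start_idx < r$end_probe &
              segments$end_idx > r$start_probe)
      }, NA),
      stringsAsFactors = FALSE)
  }

  report <- structure(list(
    config = config, n_samples = nrow(cohort$phenotypes),
    n_excluded = sum(metrics$excluded),
    n_analyzed = nrow(kept$phenotypes), qc = metrics,
    probe_stats = stats, segments = segments, regions = regions,
    region_results = region_results,
    conditional_results = conditional_results,
    calls = calls, carrier = carrier, recovery = recovery,
    panel = kept$panel, phenotypes = kept$phenotypes,
    genotypes = cohort$genotypes, probe_map = cohort$probe_map,
    truth = cohort$truth), class = "cnv_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @method print cnv_report
#' @export
print.cnv_report <- function(x, ...) {
  cat("cnv_report\n")
  cat("  samples:", x$n_samples, "(", x$n_excluded, "excluded by QC,",
      x$n_analyzed, "analyzed )\n")
  cat("  probes scanned:", nrow(x$probe_stats), "\n")
  cat("  candidate regions:", nrow(x$segments), "\n")
  if (!is.null(x$region_results) && nrow(x$region_results)) {
    cat("  region permutation results:\n")
    d <- x$region_results
    for (k in seq_len(nrow(d)))
      cat(sprintf("    chr%s:%d-%d  n=%d  stat=%.2f  p=%.3g%s\n",
                  d$chromosome[k], d$start_pos[k], d$end_pos[k],
                  d$n_probes[k], d$observed_stat[k], d$p_value[k],
                  if (d$significant_discovery[k]) "  *discovery*" else ""))
  }
  if (!is.null(x$recovery))
    cat("  true regions identified:", sum(x$recovery$identified), "/",
        nrow(x$recovery), "\n")
  invisible(x)
}

#' Write all report artifacts to a directory
#'
#' @param report A `cnv_report`.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_qc_report(report$qc, file.path(dir, "qc_report.tsv"))
  write_probe_stats(report$probe_stats, file.path(dir, "probe_stats.tsv"))
  if (nrow(report$regions))
    write_regions(report$regions, file.path(dir, "regions.tsv"),
                  file.path(dir, "regions.bed"))
  if (!is.null(report$region_results))
    write_region_results(report$region_results,
                         file.path(dir, "region_results.tsv"))
  if (!is.null(report$carrier))
    utils::write.table(report$carrier,
                       file.path(dir, "carrier_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (k in seq_along(report$calls))
    if (!is.null(report$calls[[k]]))
      write_cnv_calls(report$calls[[k]],
                      file.path(dir, sprintf("calls_region%02d.tsv", k)))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' Compare a discovery report against a replication cohort
#'
#' For every candidate region of the discovery report, checks (i) whether
#' the CNV itself exists in the replication panel — by forced copy-number
#' calling over the region's probes, with presence defined as a non-diploid
#' carrier fraction of at least `presence_freq` — and (ii) whether the
#' association replicates, by rerunning the region permutation test on the
#' replication cohort at significance `replication_threshold`. This mirrors
#' the distinction between replicating a CNV and replicating its phenotype
#' association.
#'
#' @param report_discovery,report_replication `cnv_report` objects with
#'   overlapping probe maps.
#' @param B Permutations for the replication region tests.
#' @param presence_freq Minimum carrier fraction for CNV presence.
#' @param replication_threshold Replication significance level.
#' @param seed Seed for the replication permutation tests.
#' @return A concordance data frame, one row per discovery region.
#' @export
compare_cohorts <- function(report_discovery, report_replication, B = 999,
                            presence_freq = 0.01,
                            replication_threshold = 0.05, seed = 1) {
  pm_d <- report_discovery$probe_map
  pm_r <- report_replication$probe_map
  if (length(intersect(pm_d$probe_id, pm_r$probe_id)) == 0)
    stop("probe maps are disjoint; cohorts cannot be compared")
  regions <- report_discovery$regions
  res_d <- report_discovery$region_results
  out <- data.frame(chromosome = character(), start_pos = integer(),
                    end_pos = integer(), discovery_p = numeric(),
                    cnv_present = logical(), carrier_freq = numeric(),
                    replication_p = numeric(),
                    association_replicated = logical(),
                    stringsAsFactors = FALSE)
  if (nrow(regions) == 0) return(out)
  seeds <- derive_seeds(seed, nrow(regions))
  spec <- model_spec(mixed = report_replication$config$mixed)
  for (k in seq_len(nrow(regions))) {
    reg <- regions[k, ]
    rows_r <- which(pm_r$chromosome == reg$chromosome &
                    pm_r$position >= reg$start_pos &
                    pm_r$position <= reg$end_pos)
    present <- NA
    cf <- NA_real_
    if (length(rows_r) >= 3) {
      cl <- call_region_copy_number(
        report_replication$panel,
        list(chromosome = reg$chromosome, start_pos = reg$start_pos,
             end_pos = reg$end_pos))
      cf <- mean(cl$copy_number != 2L, na.rm = TRUE)
      present <- cf >= presence_freq
    }
    rep_p <- NA_real_
    replicated <- NA
    rows_exp <- which(pm_r$chromosome == reg$chromosome &
                      pm_r$position >= reg$exp_start_pos &
                      pm_r$position <= reg$exp_end_pos)
    if (length(rows_exp) >= 3) {
      chr_rows <- which(pm_r$chromosome == reg$chromosome)
      loc <- match(rows_exp, chr_rows)
      win <- region_window(reg$chromosome, min(loc) - 1L, max(loc),
                           pm_r, expand = 0)
      rr <- permute_region(win, report_replication$panel,
                           report_replication$phenotypes, spec, B = B,
                           seed = seeds[k],
                           replication_threshold = replication_threshold)
      rep_p <- rr$p_value
      replicated <- rr$significant_replication
    }
    out <- rbind(out, data.frame(
      chromosome = reg$chromosome, start_pos = reg$start_pos,
      end_pos = reg$end_pos,
      discovery_p = if (!is.null(res_d)) res_d$p_value[k] else NA_real_,
      cnv_present = present, carrier_freq = cf, replication_p = rep_p,
      association_replicated = replicated, stringsAsFactors = FALSE))
  }
  out
}
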