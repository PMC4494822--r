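#' Per-plate median normalization of LRR
#'
#' Subtracts, within each plate, the median of all non-missing LRR values
#' pooled over the plate's samples, so that every plate's pooled LRR median
#' is zero afterwards. BAF is untouched. The operation is idempotent.
#'
#' @param panel An `intensity_panel` with a plate assignment per sample.
#' @return The normalized panel.
#' @export
median_normalize_by_plate <- function(panel) {
  stopifnot(inherits(panel, "intensity_panel"))
  plate <- panel$samples$plate_id
  if (anyNA(plate)) stop("every sample needs a plate_id")
  for (pl in unique(plate)) {
    rows <- which(plate == pl)
    vals <- panel$lrr[rows, , drop = FALSE]
    if (all(is.na(vals))) stop("plate ", pl, " has no non-missing LRR values")
    panel$lrr[rows, ] <- vals - stats::median(vals, na.rm = TRUE)
  }
  panel
}

# Centered running mean of width 3 (ends treated as not exceeding).
running_mean3 <- function(x) {
  as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
}

# Count maximal runs of >= min_run consecutive probes whose width-3 running
# mean deviates from 0 by more than `dev` (per chromosome, summed).
count_cnv_intervals <- function(x, chromosome, dev = 0.25, min_run = 3L) {
  total <- 0L
  for (chr in unique(chromosome)) {
    sm <- running_mean3(x[chromosome == chr])
    hit <- !is.na(sm) & abs(sm) > dev
    r <- rle(hit)
    total <- total + sum(r$values & r$lengths >= min_run)
  }
  total
}

#' Compute per-sample intensity QC metrics
#'
#' Four desk-scale analogues of the standard array QC summaries:
#' `lrr_sd`, the SD of the sample's non-missing autosomal LRR; `baf_drift`,
#' the fraction of non-missing BAF values strictly inside (0.2, 0.25) or
#' (0.75, 0.8); `wave_factor`, the SD across consecutive `window`-probe
#' windows of the per-window median LRR (0 when fewer than two windows have
#' data); and `n_cnv_intervals`, the number of maximal runs of three or more
#' consecutive probes whose width-3 running-mean LRR deviates from 0 by more
#' than 0.25. Samples with fewer than `min_probes` non-missing LRR values
#' get undefined metrics and are auto-excluded.
#'
#' @param panel A normalized `intensity_panel`.
#' @param window Probes per wave-factor window.
#' @param min_probes Minimum non-missing probes for defined metrics.
#' @return A `qc_metrics` data frame, one row per sample, with `excluded`
#'   and `exclusion_reasons` columns (threshold exclusions are applied by
#'   [apply_qc_exclusions()]).
#' @export
compute_qc_metrics <- function(panel, window = 1000L, min_probes = 100L) {
  stopifnot(inherits(panel, "intensity_panel"))
  n <- nrow(panel$lrr)
  P <- ncol(panel$lrr)
  win_id <- rep(seq_len(ceiling(P / window)), each = window)[seq_len(P)]
  out <- data.frame(sample_id = panel$samples$sample_id,
                    lrr_sd = NA_real_, baf_drift = NA_real_,
                    wave_factor = NA_real_, n_cnv_intervals = NA_integer_,
                    excluded = FALSE, exclusion_reasons = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    x <- panel$lrr[i, ]
    if (sum(!is.na(x)) < min_probes) {
      out$excluded[i] <- TRUE
      out$exclusion_reasons[i] <- "insufficient probes"
      next
    }
    out$lrr_sd[i] <- stats::sd(x, na.rm = TRUE)
    b <- panel$baf[i, ]
    b <- b[!is.na(b)]
    out$baf_drift[i] <- if (length(b)) {
      mean((b > 0.2 & b < 0.25) | (b > 0.75 & b < 0.8))
    } else 0
    med <- tapply(x, win_id, stats::median, na.rm = TRUE)
    med <- med[!is.na(med)]
    out$wave_factor[i] <- if (length(med) >= 2) stats::sd(med) else 0
    out$n_cnv_intervals[i] <-
      count_cnv_intervals(x, panel$probe_map$chromosome)
  }
  class(out) <- c("qc_metrics", "data.frame")
  out
}

#' Apply sample-exclusion thresholds to QC metrics
#'
#' A sample is excluded when any metric strictly exceeds its threshold
#' (metric-equal samples are retained); all violated metrics are listed as
#' reasons. Defaults are the standard array-QC cutoffs: LRR SD 0.35, BAF
#' drift 0.0015, wave factor 0.05, 500 CNV intervals.
#'
#' @param metrics A `qc_metrics` data frame from [compute_qc_metrics()].
#' @param thresholds Named vector `(lrr_sd, baf_drift, wave_factor,
#'   n_cnv_intervals)`.
#' @return `metrics` with `excluded`/`exclusion_reasons` updated.
#' @export
apply_qc_exclusions <- function(metrics,
                                thresholds = c(lrr_sd = 0.35,
                                               baf_drift = 0.0015,
                                               wave_factor = 0.05,
                                               n_cnv_intervals = 500)) {
  need <- c("lrr_sd", "baf_drift", "wave_factor", "n_cnv_intervals")
  stopifnot(all(need %in% names(thresholds)))
  for (i in seq_len(nrow(metrics))) {
    reasons <- if (nzchar(metrics$exclusion_reasons[i])) {
      strsplit(metrics$exclusion_reasons[i], ";")[[1]]
    } else character()
    for (m in need) {
      v <- metrics[[m]][i]
      if (!is.na(v) && v > thresholds[[m]]) reasons <- c(reasons, m)
    }
    metrics$exclusion_reasons[i] <- paste(reasons, collapse = ";")
    metrics$excluded[i] <- length(reasons) > 0
  }
  metrics
}

#' Drop QC-excluded samples from a panel and phenotype table
#'
#' @param panel An `intensity_panel`.
#' @param phenotypes Phenotype data frame.
#' @param metrics A `qc_metrics` data frame with exclusions applied.
#' @return List with the filtered `panel` and `phenotypes`.
#' @export
drop_excluded_samples <- function(panel, phenotypes, metrics) {
  keep <- metrics$sample_id[!metrics$excluded]
  rows <- panel$samples$sample_id %in% keep
  panel$lrr <- panel$lrr[rows, , drop = FALSE]
  panel$baf <- panel$baf[rows, , drop = FALSE]
  panel$samples <- panel$samples[rows, , drop = FALSE]
  list(panel = panel,
       phenotypes = phenotypes[phenotypes$sample_id %in% keep, , drop = FALSE])
}

#' Write a QC report
#'
#' @param metrics A `qc_metrics` data frame.
#' @param path Output TSV path.
#' @export
write_qc_report <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
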