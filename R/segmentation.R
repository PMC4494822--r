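#' Circular binary segmentation of a numeric track
#'
#' Recursive change-point search: the current interval is arranged on a
#' circle and the pair of cut points maximizing the pooled two-sample
#' mean-difference statistic between the arc and its complement is located
#' (ties broken toward the leftmost start, then the shortest arc); the
#' split is accepted when its within-interval permutation p-value is at
#' most `alpha` (`n_split_permutations` shuffles, with early stopping once
#' rejection is certain), and the procedure recurses on the pieces.
#' Wrapping arcs are complements of non-wrapping ones and map back to the
#' same two linear cut points.
#'
#' @param values Finite numeric vector.
#' @param alpha Split-acceptance level.
#' @param n_split_permutations Shuffles per split test.
#' @param min_width Minimum piece width considered for an arc (>= 2);
#'   inputs shorter than `2 * min_width` return no change-points.
#' @param seed Optional seed for the shuffles (the enclosing RNG state is
#'   restored afterwards); with `NULL` the current RNG stream is used.
#' @return Sorted integer vector of 0-based interior boundaries: a
#'   change-point at `k` splits between `values[k]` and `values[k + 1]`
#'   (1-based indexing).
#' @export
cbs_segment <- function(values, alpha = 0.01, n_split_permutations = 1000,
                        min_width = 2, seed = NULL) {
  stopifnot(is.numeric(values), all(is.finite(values)),
            min_width >= 2, alpha > 0, alpha < 1, n_split_permutations >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  .cbs_segment_cpp(as.numeric(values), alpha,
                   as.integer(n_split_permutations), as.integer(min_width))
}

#' Maximal circular split of an interval
#'
#' The single best arc/complement split located by the CBS search, without
#' any acceptance testing — the building block [cbs_segment()] applies
#' recursively, exposed for diagnostics and for verification against
#' exhaustive search.
#'
#' @inheritParams cbs_segment
#' @return List with the 0-based arc bounds `i`, `j` (arc is
#'   `values[(i+1):j]` in 1-based terms), the statistic `t`, and `found`.
#' @export
cbs_max_split <- function(values, min_width = 2) {
  .cbs_max_split_cpp(as.numeric(values), as.integer(min_width))
}

# Intervals between consecutive change-points of one chromosome track.
changepoints_to_intervals <- function(cps, n) {
  bounds <- c(0L, cps, n)
  data.frame(start_idx = bounds[-length(bounds)], end_idx = bounds[-1])
}

#' Identify candidate segments from an absolute test-statistic track
#'
#' Runs [cbs_segment()] on |t| per chromosome, converts the change-points
#' into segments and retains those with at least `min_probes` probes and a
#' mean |t| strictly greater than `mean_t_threshold`. A guard additionally
#' drops any segment whose mean does not exceed the chromosome-wide mean
#' |t|, which prevents long flat tracks from qualifying as one
#' whole-chromosome segment (mean |t| under the null is about 0.8, close to
#' the retention threshold of 1).
#'
#' @param stats A `probe_stats` data frame from [scan_probes()].
#' @param min_probes Minimum probes per retained segment.
#' @param mean_t_threshold Retention threshold on the segment mean |t|.
#' @param chrom_mean_guard Apply the chromosome-mean guard.
#' @param alpha,n_split_permutations,min_width CBS parameters.
#' @param seed Seed for the CBS split tests.
#' @return A `cnv_segments` data frame with 0-based half-open
#'   chromosome-local `start_idx`/`end_idx`, probe counts, mean |t| and
#'   1-based inclusive genomic positions.
#' @export
identify_candidate_segments <- function(stats, min_probes = 3,
                                        mean_t_threshold = 1,
                                        chrom_mean_guard = TRUE,
                                        alpha = 0.01,
                                        n_split_permutations = 1000,
                                        min_width = 2, seed = 1) {
  out <- list()
  seeds <- derive_seeds(seed, max(1L, length(unique(stats$chromosome))))
  for (ci in seq_along(unique(stats$chromosome))) {
    chr <- unique(stats$chromosome)[ci]
    rows <- which(stats$chromosome == chr)
    v <- abs(stats$t[rows])
    cps <- cbs_segment(v, alpha, n_split_permutations, min_width,
                       seed = seeds[ci])
    iv <- changepoints_to_intervals(cps, length(v))
    iv$chromosome <- chr
    iv$n_probes <- iv$end_idx - iv$start_idx
    iv$mean_abs_t <- vapply(seq_len(nrow(iv)), function(k)
      mean(v[(iv$start_idx[k] + 1):iv$end_idx[k]]), 0)
    keep <- iv$n_probes >= min_probes & iv$mean_abs_t > mean_t_threshold
    if (chrom_mean_guard) keep <- keep & iv$mean_abs_t > mean(v)
    iv <- iv[keep, , drop = FALSE]
    if (nrow(iv)) {
      iv$start_pos <- stats$position[rows[iv$start_idx + 1]]
      iv$end_pos <- stats$position[rows[iv$end_idx]]
      out[[length(out) + 1]] <- iv
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start_idx = integer(), end_idx = integer(),
               chromosome = character(), n_probes = integer(),
               mean_abs_t = numeric(), start_pos = integer(),
               end_pos = integer())
  res <- res[, c("chromosome", "start_idx", "end_idx", "n_probes",
                 "mean_abs_t", "start_pos", "end_pos")]
  rownames(res) <- NULL
  class(res) <- c("cnv_segments", "data.frame")
  res
}

#' Expand a candidate segment by six times its probe count on each side
#'
#' An `n`-probe segment gains `expand * n` probes before its start and
#' after its end (so a 10-probe segment becomes a 130-probe region at the
#' default `expand = 6`), clipped at the chromosome bounds;
#' `n_total_probes` is reported after clipping.
#'
#' @param segment One-row segment (needs `start_idx`, `end_idx`).
#' @param chromosome_length Number of probes on the segment's chromosome.
#' @param expand Expansion multiple per side.
#' @return The row with `exp_start_idx`, `exp_end_idx` (0-based half-open)
#'   and `n_total_probes` added.
#' @export
expand_segment <- function(segment, chromosome_length, expand = 6) {
  n <- segment$end_idx - segment$start_idx
  segment$exp_start_idx <- as.integer(max(0, segment$start_idx - expand * n))
  segment$exp_end_idx <- as.integer(min(chromosome_length,
                                        segment$end_idx + expand * n))
  segment$n_total_probes <- segment$exp_end_idx - segment$exp_start_idx
  segment
}

#' Expand all candidate segments against a probe map
#'
#' @param segments A `cnv_segments` data frame.
#' @param probe_map The probe map defining chromosome lengths.
#' @param expand Expansion multiple per side.
#' @return An `expanded_regions` data frame (segments plus expansion
#'   columns and expansion genomic positions).
#' @export
expand_segments <- function(segments, probe_map, expand = 6) {
  lens <- table(probe_map$chromosome)
  out <- segments
  blank <- rep(NA_integer_, nrow(out))
  out$exp_start_idx <- out$exp_end_idx <- out$n_total_probes <- blank
  out$exp_start_pos <- out$exp_end_pos <- blank
  for (k in seq_len(nrow(segments))) {
    e <- expand_segment(segments[k, ], lens[[segments$chromosome[k]]], expand)
    out$exp_start_idx[k] <- e$exp_start_idx
    out$exp_end_idx[k] <- e$exp_end_idx
    out$n_total_probes[k] <- e$n_total_probes
    rows <- which(probe_map$chromosome == segments$chromosome[k])
    out$exp_start_pos[k] <- probe_map$position[rows[e$exp_start_idx + 1]]
    out$exp_end_pos[k] <- probe_map$position[rows[e$exp_end_idx]]
  }
  class(out) <- c("expanded_regions", class(segments))
  out
}

#' Write candidate regions as TSV and BED
#'
#' The TSV uses 1-based inclusive positions; the BED is 0-based half-open.
#'
#' @param regions An `expanded_regions` data frame.
#' @param tsv_path,bed_path Output paths (either may be `NULL`).
#' @export
write_regions <- function(regions, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    d <- regions[, c("chromosome", "start_pos", "end_pos", "n_probes",
                     "mean_abs_t", "exp_start_pos", "exp_end_pos")]
    utils::write.table(d, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = regions$chromosome,
                      chromStart = regions$start_pos - 1L,
                      chromEnd = regions$end_pos,
                      name = sprintf("region_%d", seq_len(nrow(regions))),
                      score = round(pmin(1000, 100 * regions$mean_abs_t)))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(regions)
}
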