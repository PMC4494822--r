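#' Likelihood parameters for forced copy-number calling
#'
#' Defaults are shared with the simulator (LRR state means from
#' [default_lrr_means()], LRR SD 0.15, BAF cluster SD 0.02) so that
#' recovery against simulated truth exercises a matched generative model.
#' A small uniform admixture keeps the BAF likelihood bounded away from
#' zero for values far from any cluster.
#'
#' @param lrr_means Named LRR state means for copy numbers 0..4.
#' @param lrr_sd LRR noise SD.
#' @param baf_sd BAF cluster SD.
#' @param baf_uniform_mix Uniform mixing weight in the BAF likelihood.
#' @return A `cn_model_params` list.
#' @export
cn_model_params <- function(lrr_means = default_lrr_means(), lrr_sd = 0.15,
                            baf_sd = 0.02, baf_uniform_mix = 0.01) {
  stopifnot(lrr_sd > 0, baf_sd > 0,
            baf_uniform_mix >= 0, baf_uniform_mix < 1)
  structure(list(lrr_means = lrr_means[as.character(0:4)], lrr_sd = lrr_sd,
                 baf_sd = baf_sd, baf_uniform_mix = baf_uniform_mix),
            class = "cn_model_params")
}

baf_clusters <- function(state) {
  switch(as.character(state),
         `0` = numeric(),          # no allele signal: uniform BAF
         `1` = c(0, 1),
         `2` = c(0, 0.5, 1),
         `3` = c(0, 1 / 3, 2 / 3, 1),
         `4` = c(0, 0.25, 0.5, 0.75, 1))
}

baf_loglik <- function(baf, state, params) {
  cl <- baf_clusters(state)
  if (length(cl) == 0) return(0)  # uniform on [0, 1]: log density 0
  dens <- rowMeans(vapply(cl, function(mu)
    stats::dnorm(baf, mu, params$baf_sd), numeric(length(baf))))
  sum(log((1 - params$baf_uniform_mix) * dens + params$baf_uniform_mix))
}

#' Force an integer copy-number call per sample in a known region
#'
#' For each sample, the LRR values of all probes inside the region are
#' scored under a Gaussian likelihood for each copy-number state's mean,
#' the BAF values under that state's cluster-mixture, and the call is the
#' state maximizing the summed log-likelihood. `call_score` is the
#' log-likelihood margin over the runner-up state. Deterministic; a sample
#' with no non-missing probe in the region gets a withheld (NA) call.
#'
#' @param panel An `intensity_panel`.
#' @param region List or one-row data frame with `chromosome`, `start_pos`,
#'   `end_pos` (1-based inclusive), or with chromosome-local `start_idx` /
#'   `end_idx`.
#' @param params A [cn_model_params()].
#' @return A `cnv_calls` data frame: `sample_id`, region coordinates,
#'   `copy_number` (0-4 or NA), `call_score`, `is_deletion_carrier`,
#'   `is_duplication_carrier`.
#' @export
call_region_copy_number <- function(panel, region,
                                    params = cn_model_params()) {
  stopifnot(inherits(panel, "intensity_panel"))
  pm <- panel$probe_map
  rows <- which(pm$chromosome == region$chromosome)
  if (!is.null(region$start_pos) && !is.na(region$start_pos %||% NA)) {
    cols <- rows[pm$position[rows] >= region$start_pos &
                 pm$position[rows] <= region$end_pos]
  } else {
    cols <- rows[(region$start_idx + 1L):region$end_idx]
  }
  if (length(cols) < 3) stop("region must contain at least 3 probes")
  states <- 0:4
  n <- nrow(panel$lrr)
  out <- data.frame(sample_id = panel$samples$sample_id,
                    chromosome = region$chromosome,
                    start_pos = min(pm$position[cols]),
                    end_pos = max(pm$position[cols]),
                    copy_number = NA_integer_, call_score = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    lrr <- panel$lrr[i, cols]
    baf <- panel$baf[i, cols]
    use_l <- !is.na(lrr)
    use_b <- !is.na(baf)
    if (!any(use_l) && !any(use_b)) {
      message(out$sample_id[i], ": all probes missing in region, call withheld")
      next
    }
    ll <- vapply(states, function(s) {
      v <- 0
      if (any(use_l))
        v <- v + sum(stats::dnorm(lrr[use_l],
                                  params$lrr_means[[as.character(s)]],
                                  params$lrr_sd, log = TRUE))
      if (any(use_b)) v <- v + baf_loglik(baf[use_b], s, params)
      v
    }, 0)
    ord <- order(ll, decreasing = TRUE)
    out$copy_number[i] <- states[ord[1]]
    out$call_score[i] <- ll[ord[1]] - ll[ord[2]]
  }
  out$is_deletion_carrier <- out$copy_number < 2L
  out$is_duplication_carrier <- out$copy_number > 2L
  class(out) <- c("cnv_calls", "data.frame")
  out
}

#' Carrier-status association with percent density
#'
#' Fits the standard sqrt-percent-density model with the carrier indicator
#' (deletion: copy number < 2; duplication: copy number > 2) in place of
#' LRR; with `spec$mixed` the family random intercept is honored.
#'
#' @param calls A `cnv_calls` data frame.
#' @param phenotypes Phenotype data frame.
#' @param spec A [model_spec()].
#' @param contrast `"deletion"` or `"duplication"`.
#' @return One-row data frame as in [fit_probe_model()], plus carrier
#'   counts.
#' @export
carrier_association <- function(calls, phenotypes, spec = model_spec(),
                                contrast = c("deletion", "duplication")) {
  contrast <- match.arg(contrast)
  m <- match(phenotypes$sample_id, calls$sample_id)
  carrier <- if (contrast == "deletion") {
    calls$is_deletion_carrier[m]
  } else {
    calls$is_duplication_carrier[m]
  }
  ok <- !is.na(carrier)
  n_car <- sum(carrier[ok])
  n_non <- sum(!carrier[ok])
  if (n_car == 0) stop("no ", contrast, " carriers: the contrast is undefined")
  if (n_non == 0) stop("every sample is a ", contrast,
                       " carrier: the contrast is undefined")
  ph <- phenotypes[ok, , drop = FALSE]
  res <- fit_probe_model(as.numeric(carrier[ok]), ph, spec)
  res$n_carriers <- n_car
  res$n_noncarriers <- n_non
  res$contrast <- contrast
  res
}

#' Write forced-call results
#'
#' @param calls A `cnv_calls` data frame.
#' @param path Output TSV path.
#' @export
write_cnv_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
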