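#' Default Log R Ratio cluster means per copy-number state
#'
#' Conventional SNP-array LRR cluster positions for integer copy numbers
#' 0 through 4 (diploid = 0 by construction). Shared between the simulator
#' and the forced-calling likelihood so that generative-model recovery is a
#' meaningful check.
#'
#' @return Named numeric vector with names `"0"`..`"4"`.
#' @export
default_lrr_means <- function() {
  c(`0` = -3.5, `1` = -0.45, `2` = 0, `3` = 0.4, `4` = 0.68)
}

#' Define a true CNV region for simulation
#'
#' Probe indices are 0-based, half-open and relative to the chromosome they
#' sit on, matching the segmentation module's internal convention.
#'
#' @param chromosome Chromosome label (character).
#' @param start_probe 0-based inclusive first probe index within the chromosome.
#' @param end_probe 0-based exclusive end probe index.
#' @param deletion_freq Probability that a sample carries a deletion
#'   (copy number 0 or 1) in the region.
#' @param duplication_freq Probability of a duplication (copy number 3 or 4).
#' @param lrr_means Named vector mapping copy-number states "0".."4" to LRR
#'   shifts; must be increasing with `lrr_means["2"] == 0`.
#' @return A `true_region` list.
#' @export
true_region <- function(chromosome, start_probe, end_probe,
                        deletion_freq = 0, duplication_freq = 0,
                        lrr_means = default_lrr_means()) {
  stopifnot(length(chromosome) == 1L, start_probe >= 0, end_probe > start_probe)
  if (deletion_freq < 0 || duplication_freq < 0 ||
      deletion_freq + duplication_freq > 1)
    stop("deletion_freq + duplication_freq must lie in [0, 1]")
  lrr_means <- lrr_means[as.character(0:4)]
  if (anyNA(lrr_means)) stop("lrr_means must name all states 0..4")
  if (any(diff(lrr_means) <= 0))
    stop("lrr_means must be strictly increasing in copy number")
  if (abs(lrr_means[["2"]]) > 1e-12)
    stop("lrr_means['2'] must be 0 (diploid reference)")
  structure(list(chromosome = as.character(chromosome),
                 start_probe = as.integer(start_probe),
                 end_probe = as.integer(end_probe),
                 deletion_freq = deletion_freq,
                 duplication_freq = duplication_freq,
                 lrr_means = lrr_means),
            class = "true_region")
}

#' Configuration for the synthetic SNP-array cohort generator
#'
#' Defaults emulate a multigenerational family study of mammographic density:
#' 89 families of 3-10 women (approx. 580 samples), 96-well plates with
#' plate-level LRR shifts, a low-amplitude genomic wave, and covariate
#' distributions with age around 57 (SD 11.6) years and BMI around 27
#' (SD 5.7) kg/m^2. Phenotype coefficients act on the square-root percent
#' density scale; `cnv` is the effect per copy-number unit away from diploid.
#'
#' @param n_families Number of families.
#' @param family_size_range Integer `(min, max)` of women per family.
#' @param n_probes Total autosomal probes across all chromosomes.
#' @param n_chromosomes Number of chromosomes the probes are spread over.
#' @param plate_size Samples per genotyping plate.
#' @param cnv_regions List of [true_region()] objects; must not overlap.
#' @param lrr_noise_sd Per-probe LRR noise SD.
#' @param wave_amplitude Mean amplitude of the per-sample genomic wave
#'   (sinusoid in probe index; a stand-in for GC waves).
#' @param wave_period Wave period in probes.
#' @param plate_shift_sd SD of per-plate LRR batch shifts.
#' @param baf_noise_sd SD of BAF noise around cluster centres.
#' @param pheno_coeffs Named vector `(intercept, age, invbmi, meno, cnv)` on
#'   the sqrt-percent-density scale (per year, per (kg/m^2)^-1, indicator,
#'   per copy).
#' @param family_sd SD of the family random intercept.
#' @param residual_sd Residual SD of sqrt percent density.
#' @param seed Master seed; drives a per-stage seed sequence.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_families = 89, family_size_range = c(3, 10),
                              n_probes = 2000, n_chromosomes = 2,
                              plate_size = 96, cnv_regions = list(),
                              lrr_noise_sd = 0.15, wave_amplitude = 0.01,
                              wave_period = 400, plate_shift_sd = 0.05,
                              baf_noise_sd = 0.02,
                              pheno_coeffs = c(intercept = 4, age = 0.01,
                                               invbmi = 20, meno = -0.3,
                                               cnv = 0),
                              family_sd = 0.7, residual_sd = 1.3, seed = 1) {
  cfg <- list(n_families = as.integer(n_families),
              family_size_range = as.integer(family_size_range),
              n_probes = as.integer(n_probes),
              n_chromosomes = as.integer(n_chromosomes),
              plate_size = as.integer(plate_size),
              cnv_regions = cnv_regions,
              lrr_noise_sd = lrr_noise_sd, wave_amplitude = wave_amplitude,
              wave_period = wave_period, plate_shift_sd = plate_shift_sd,
              baf_noise_sd = baf_noise_sd, pheno_coeffs = pheno_coeffs,
              family_sd = family_sd, residual_sd = residual_sd,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_families >= 1, n_probes >= 1, n_chromosomes >= 1,
              plate_size >= 1, length(family_size_range) == 2,
              family_size_range[1] >= 1,
              family_size_range[2] >= family_size_range[1],
              lrr_noise_sd >= 0, family_sd >= 0, residual_sd >= 0,
              wave_period >= 2)
    need <- c("intercept", "age", "invbmi", "meno", "cnv")
    if (!all(need %in% names(pheno_coeffs)))
      stop("pheno_coeffs must name: ", paste(need, collapse = ", "))
  })
  lens <- chromosome_lengths(cfg$n_probes, cfg$n_chromosomes)
  for (r in cfg$cnv_regions) {
    if (!inherits(r, "true_region")) stop("cnv_regions must be true_region objects")
    if (!r$chromosome %in% names(lens))
      stop("region chromosome '", r$chromosome, "' not in probe map")
    if (r$end_probe > lens[[r$chromosome]])
      stop("region extends beyond chromosome '", r$chromosome, "'")
  }
  # reject overlapping regions on the same chromosome
  if (length(cfg$cnv_regions) > 1) {
    rd <- data.frame(chr = vapply(cfg$cnv_regions, `[[`, "", "chromosome"),
                     s = vapply(cfg$cnv_regions, `[[`, 0L, "start_probe"),
                     e = vapply(cfg$cnv_regions, `[[`, 0L, "end_probe"))
    rd <- rd[order(rd$chr, rd$s), ]
    same <- rd$chr[-1] == rd$chr[-nrow(rd)]
    if (any(same & rd$s[-1] < rd$e[-nrow(rd)]))
      stop("cnv_regions must not overlap")
  }
  invisible(cfg)
}

chromosome_lengths <- function(n_probes, n_chromosomes) {
  base <- n_probes %/% n_chromosomes
  lens <- rep(base, n_chromosomes)
  extra <- n_probes %% n_chromosomes
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  stats::setNames(as.integer(lens), as.character(seq_len(n_chromosomes)))
}

# Global (probe-map row) column indices of a simulated region.
region_global_cols <- function(probe_map, region) {
  rows <- which(probe_map$chromosome == region$chromosome)
  rows[(region$start_probe + 1L):region$end_probe]
}

#' Simulate a SNP-array cohort with embedded CNV regions
#'
#' Generates a probe map, per-sample LRR/BAF intensities, SNP genotypes, a
#' percent-density phenotype table and the ground truth used to verify
#' recovery. LRR at probes inside a region with copy number c equals the
#' configured state mean plus a genomic wave, a plate shift and Gaussian
#' noise; BAF follows the cluster pattern implied by c (uniform at c = 0,
#' clusters {0,1}, {0,1/2,1}, {0,1/3,2/3,1}, {0,1/4,1/2,3/4,1} for c = 1..4).
#' Square-root percent density is generated from the covariate linear
#' predictor plus a family random intercept and residual noise, then squared
#' and clamped to \[0, 100\].
#'
#' Identical configurations (including the seed) produce bit-identical
#' cohorts.
#'
#' @param config A [simulation_config()].
#' @return A `cnv_cohort` list: `probe_map`, `panel` (an `intensity_panel`),
#'   `phenotypes`, `genotypes` (samples x SNP-probes matrix of 0/1/2),
#'   `truth` (per-sample copy numbers per region, with the generating
#'   coefficients as attributes) and `config`.
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  seeds <- derive_seeds(config$seed, 4)

  ## stage 1: probe map ------------------------------------------------
  set.seed(seeds[1])
  lens <- chromosome_lengths(config$n_probes, config$n_chromosomes)
  chrom <- rep(names(lens), lens)
  within <- unlist(lapply(lens, seq_len), use.names = FALSE)
  probe_map <- data.frame(
    probe_id = sprintf("p%s_%06d", chrom, within),
    chromosome = chrom,
    position = 4000L * within,
    is_snp = stats::runif(config$n_probes) > 0.05,
    stringsAsFactors = FALSE)
  for (r in config$cnv_regions)  # catalogue-style CNV-intensity probes
    probe_map$is_snp[region_global_cols(probe_map, r)] <- FALSE
  allele_freq <- stats::runif(config$n_probes, 0.05, 0.95)

  ## stage 2: families, plates, copy numbers ---------------------------
  set.seed(seeds[2])
  size_range <- seq(config$family_size_range[1], config$family_size_range[2])
  sizes <- if (length(size_range) == 1) {
    rep(size_range, config$n_families)  # sample(n, ...) would read n as 1:n
  } else {
    sample(size_range, config$n_families, replace = TRUE)
  }
  n <- sum(sizes)
  sample_id <- sprintf("S%04d", seq_len(n))
  family_id <- rep(sprintf("F%03d", seq_len(config$n_families)), sizes)
  plate_id <- sprintf("PL%02d", ceiling(seq_len(n) / config$plate_size))
  nreg <- length(config$cnv_regions)
  cn <- matrix(2L, n, max(1L, nreg))[, seq_len(nreg), drop = FALSE]
  for (k in seq_len(nreg)) {
    r <- config$cnv_regions[[k]]
    u <- stats::runif(n)
    del <- u < r$deletion_freq
    dup <- !del & u < r$deletion_freq + r$duplication_freq
    # deletion carriers split 1-copy : 0-copy = 2 : 1; duplications 3 : 4 = 2 : 1
    cn[del, k] <- ifelse(stats::runif(sum(del)) < 1 / 3, 0L, 1L)
    cn[dup, k] <- ifelse(stats::runif(sum(dup)) < 1 / 3, 4L, 3L)
  }

  ## stage 3: intensities and genotypes --------------------------------
  set.seed(seeds[3])
  P <- config$n_probes
  plates <- unique(plate_id)
  shift <- stats::setNames(stats::rnorm(length(plates), 0, config$plate_shift_sd), plates)
  lrr <- matrix(stats::rnorm(n * P, 0, config$lrr_noise_sd), n, P)
  lrr <- lrr + shift[plate_id]
  gidx <- seq_len(P)
  theta <- 2 * pi * gidx / config$wave_period
  amp <- config$wave_amplitude * stats::runif(n, 0.5, 1.5)
  phase <- stats::runif(n, 0, 2 * pi)
  lrr <- lrr + outer(amp * cos(phase), sin(theta)) +
    outer(amp * sin(phase), cos(theta))

  g2 <- matrix(stats::rbinom(n * P, 2L, rep(allele_freq, each = n)), n, P)
  baf <- g2 / 2 + stats::rnorm(n * P, 0, config$baf_noise_sd)

  for (k in seq_len(nreg)) {
    r <- config$cnv_regions[[k]]
    cols <- region_global_cols(probe_map, r)
    for (state in setdiff(sort(unique(cn[, k])), 2L)) {
      rows <- which(cn[, k] == state)
      lrr[rows, cols] <- lrr[rows, cols] + r$lrr_means[[as.character(state)]]
      if (state == 0L) {
        baf[rows, cols] <- stats::runif(length(rows) * length(cols))
      } else {
        p <- rep(allele_freq[cols], each = length(rows))
        g <- stats::rbinom(length(rows) * length(cols), state, p)
        baf[rows, cols] <- g / state +
          stats::rnorm(length(g), 0, config$baf_noise_sd)
      }
    }
  }
  baf <- pmin(pmax(baf, 0), 1)  # pmin/pmax take dims from the first argument
  dimnames(lrr) <- dimnames(baf) <- list(sample_id, probe_map$probe_id)
  genotypes <- g2[, probe_map$is_snp, drop = FALSE]
  dimnames(genotypes) <- list(sample_id, probe_map$probe_id[probe_map$is_snp])

  panel <- new_intensity_panel(
    lrr, baf, data.frame(sample_id = sample_id, plate_id = plate_id,
                         stringsAsFactors = FALSE), probe_map)

  ## stage 4: phenotype ------------------------------------------------
  set.seed(seeds[4])
  b <- config$pheno_coeffs
  age <- stats::rnorm(n, 57.2, 11.6)
  bmi <- pmax(15, stats::rnorm(n, 27.1, 5.7))
  meno <- as.integer(xor(age > 51, stats::runif(n) < 0.05))
  fam_eff <- stats::setNames(stats::rnorm(config$n_families, 0, config$family_sd),
                             unique(family_id))
  dosage <- if (nreg > 0) rowSums(cn - 2L) else numeric(n)
  sqrtpd <- b[["intercept"]] + b[["age"]] * age + b[["invbmi"]] / bmi +
    b[["meno"]] * meno + b[["cnv"]] * dosage +
    fam_eff[family_id] + stats::rnorm(n, 0, config$residual_sd)
  out_of_range <- sum(sqrtpd < 0 | sqrtpd > 10)
  if (out_of_range > 0)
    warning(out_of_range, " sample(s) had sqrt(PD) outside [0, 10]; ",
            "percent density clamped to [0, 100]")
  pd <- pmin(100, pmax(0, sqrtpd^2))

  phenotypes <- data.frame(sample_id = sample_id, percent_density = pd,
                           age = age, bmi = bmi, menopausal = meno,
                           family_id = family_id, plate_id = plate_id,
                           stringsAsFactors = FALSE)

  truth <- data.frame(sample_id = sample_id, family_id = family_id,
                      plate_id = plate_id, stringsAsFactors = FALSE)
  for (k in seq_len(nreg)) truth[[paste0("cn_region", k)]] <- cn[, k]
  attr(truth, "pheno_coeffs") <- b
  attr(truth, "regions") <- config$cnv_regions

  structure(list(probe_map = probe_map, panel = panel,
                 phenotypes = phenotypes, genotypes = genotypes,
                 truth = truth, config = config),
            class = "cnv_cohort")
}

#' Inject QC failures into simulated samples
#'
#' Perturbs the named samples so that they measurably exceed one of the
#' sample QC thresholds; all other samples are untouched. Failure types:
#' `"noisy_lrr"` (extra LRR noise of SD `magnitude`, default 0.45),
#' `"baf_drift"` (a `magnitude` fraction, default 0.01, of BAF values moved
#' into the drift windows (0.2, 0.25) and (0.75, 0.8)), `"wave"` (a strong
#' sinusoidal wave of amplitude `magnitude`, default 0.2, with period two QC
#' windows), and `"fragmented"` (the LRR track replaced by `magnitude`,
#' default 510, short high-amplitude intervals over low noise).
#'
#' @param panel An `intensity_panel`.
#' @param failure_spec List of `list(sample, type, magnitude = NULL)` entries.
#' @return The perturbed panel; an empty `failure_spec` returns it unchanged.
#' @export
simulate_qc_failures <- function(panel, failure_spec) {
  stopifnot(inherits(panel, "intensity_panel"))
  if (length(failure_spec) == 0) return(panel)
  P <- ncol(panel$lrr)
  for (f in failure_spec) {
    i <- match(f$sample, panel$samples$sample_id)
    if (is.na(i)) stop("unknown sample id: ", f$sample)
    type <- match.arg(f$type, c("noisy_lrr", "baf_drift", "wave", "fragmented"))
    mag <- f$magnitude
    switch(type,
      noisy_lrr = {
        panel$lrr[i, ] <- panel$lrr[i, ] + stats::rnorm(P, 0, mag %||% 0.45)
      },
      baf_drift = {
        frac <- mag %||% 0.01
        k <- max(1L, round(frac * P))
        j <- sample.int(P, k)
        lo <- stats::runif(k, 0.201, 0.249)
        hi <- stats::runif(k, 0.751, 0.799)
        panel$baf[i, j] <- ifelse(stats::runif(k) < 0.5, lo, hi)
      },
      wave = {
        amp <- mag %||% 0.2
        panel$lrr[i, ] <- panel$lrr[i, ] + amp * sin(2 * pi * seq_len(P) / 2000)
      },
      fragmented = {
        count <- mag %||% 510
        periods <- ceiling(count / 2)  # one +block and one -block per period
        need <- 10L * periods
        if (P < need)
          stop("panel has ", P, " probes; ", need,
               " needed to inject ", count, " CNV intervals")
        # zero-mean alternating blocks keep lrr_sd and wave_factor below
        # their thresholds while creating many short mean-shift intervals
        x <- stats::rnorm(P, 0, 0.05)
        block <- rep(rep(c(0.35, -0.35), each = 5), periods)
        x[seq_len(need)] <- x[seq_len(need)] + block
        panel$lrr[i, ] <- x
      })
  }
  panel
}

#' Add a SNP in linkage disequilibrium with a simulated CNV region
#'
#' Creates a biallelic SNP whose genotype correlates with the region's
#' carrier status (copy number different from 2) at approximately
#' `r2_target`, by copying the carrier indicator and re-drawing a fraction
#' `1 - sqrt(r2_target)` of samples from the carrier-frequency marginal.
#' The SNP is written into the genotype table at the SNP probe nearest the
#' region midpoint, so that SNP-conditional analyses can locate it by
#' position. The realized r^2 is recorded in the returned cohort.
#'
#' @param cohort A `cnv_cohort` with at least one simulated region.
#' @param region Index of the region in `cohort$config$cnv_regions`.
#' @param r2_target Target squared correlation in \[0, 1\].
#' @return The cohort with the genotype column replaced; the host probe id
#'   and realized r^2 are appended to `cohort$linked_snps`.
#' @export
simulate_linked_snp <- function(cohort, region = 1L, r2_target) {
  stopifnot(inherits(cohort, "cnv_cohort"),
            r2_target >= 0, r2_target <= 1)
  r <- cohort$config$cnv_regions[[region]]
  carrier <- cohort$truth[[paste0("cn_region", region)]] != 2L
  if (!any(carrier)) stop("region has no carriers; linkage is undefined")
  n <- length(carrier)
  g <- as.integer(carrier)
  pi_perturb <- 1 - sqrt(r2_target)
  redraw <- stats::runif(n) < pi_perturb
  g[redraw] <- stats::rbinom(sum(redraw), 1L, mean(carrier))
  realized <- if (stats::var(g) > 0) stats::cor(g, as.integer(carrier))^2 else 0

  pm <- cohort$probe_map
  on_chr <- which(pm$chromosome == r$chromosome & pm$is_snp)
  if (length(on_chr) == 0) stop("no SNP probe available on chromosome ", r$chromosome)
  chr_rows <- which(pm$chromosome == r$chromosome)
  mid_pos <- mean(pm$position[chr_rows[c(r$start_probe + 1L, r$end_probe)]])
  host <- on_chr[which.min(abs(pm$position[on_chr] - mid_pos))]
  host_id <- pm$probe_id[host]
  cohort$genotypes[, host_id] <- g
  cohort$linked_snps <- c(cohort$linked_snps,
                          list(list(snp_id = host_id, region = region,
                                    r2_target = r2_target,
                                    realized_r2 = realized)))
  cohort
}

#' Add a per-allele SNP effect to a simulated phenotype
#'
#' Shifts sqrt percent density by `beta` per allele of the named SNP and
#' re-squares (clamping to \[0, 100\]). Used to build scenarios where the
#' phenotype signal is carried by a SNP rather than the CNV itself.
#'
#' @param cohort A `cnv_cohort`.
#' @param snp_id Genotype column name.
#' @param beta Effect per allele on the sqrt-percent-density scale.
#' @return The cohort with `phenotypes$percent_density` updated.
#' @export
add_snp_phenotype_effect <- function(cohort, snp_id, beta) {
  g <- cohort$genotypes[, snp_id]
  ph <- cohort$phenotypes
  stopifnot(identical(rownames(cohort$genotypes), ph$sample_id))
  s <- sqrt(ph$percent_density) + beta * g
  cohort$phenotypes$percent_density <- pmin(100, pmax(0, s^2))
  cohort
}

#' Add a per-carrier phenotype shift for a simulated region
#'
#' @param cohort A `cnv_cohort`.
#' @param region Region index.
#' @param shift Shift of sqrt percent density for carriers (copy number != 2).
#' @return The updated cohort.
#' @export
add_carrier_phenotype_effect <- function(cohort, region = 1L, shift) {
  carrier <- cohort$truth[[paste0("cn_region", region)]] != 2L
  s <- sqrt(cohort$phenotypes$percent_density) + shift * carrier
  cohort$phenotypes$percent_density <- pmin(100, pmax(0, s^2))
  cohort
}
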