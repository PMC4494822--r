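#' Canonical simulation scenarios
#'
#' Fixed study conditions used throughout the package's calibration, power
#' and recovery experiments. Each returns a [simulation_config()] (or a
#' ready cohort) whose parameters are documented defaults, not tuning
#' knobs: cohort sizes approximate a family study of a few hundred women;
#' the "strong" CNV effect is 1.5 sqrt-percent-density units per copy
#' against a residual SD of 1.3.
#'
#' @name scenarios
NULL

#' @describeIn scenarios No CNV regions and no CNV effect: used for type-I
#'   calibration. About 200 samples in 50 families over `n_probes` probes.
#' @param seed Master seed.
#' @param n_families,family_size_range,n_probes,n_chromosomes Cohort shape.
#' @export
scenario_null_config <- function(seed, n_families = 50,
                                 family_size_range = c(3, 5),
                                 n_probes = 2000, n_chromosomes = 2) {
  simulation_config(n_families = n_families,
                    family_size_range = family_size_range,
                    n_probes = n_probes, n_chromosomes = n_chromosomes,
                    cnv_regions = list(), seed = seed)
}

#' @describeIn scenarios One deletion region (default 10 probes, carrier
#'   frequency 0.3) with a per-copy phenotype effect `gamma`; used for
#'   recovery/power experiments. About 150 samples in 38 families.
#' @param gamma CNV effect per copy on the sqrt-percent-density scale.
#' @param region_start,region_len 0-based region start and probe count.
#' @param deletion_freq,duplication_freq Carrier frequencies.
#' @export
scenario_deletion_config <- function(seed, gamma = 1.5, n_families = 38,
                                     family_size_range = c(3, 5),
                                     n_probes = 2000, n_chromosomes = 2,
                                     region_start = 495, region_len = 10,
                                     deletion_freq = 0.3,
                                     duplication_freq = 0) {
  reg <- true_region("1", region_start, region_start + region_len,
                     deletion_freq = deletion_freq,
                     duplication_freq = duplication_freq)
  coeffs <- c(intercept = 4, age = 0.01, invbmi = 20, meno = -0.3,
              cnv = gamma)
  simulation_config(n_families = n_families,
                    family_size_range = family_size_range,
                    n_probes = n_probes, n_chromosomes = n_chromosomes,
                    cnv_regions = list(reg), pheno_coeffs = coeffs,
                    seed = seed)
}

#' @describeIn scenarios Phenotype driven solely by a SNP in linkage
#'   disequilibrium (target r^2) with a phenotype-neutral deletion region:
#'   the setting in which SNP adjustment should remove the region's
#'   apparent copy-number association. Returns a simulated cohort with the
#'   linked SNP recorded in `cohort$linked_snps`.
#' @param r2 Target SNP-carrier squared correlation.
#' @param beta_snp SNP effect per allele on the sqrt-percent-density scale.
#' @export
scenario_snp_driven_cohort <- function(seed, r2 = 0.8, beta_snp = 1.5,
                                       n_families = 38,
                                       family_size_range = c(3, 5),
                                       n_probes = 2000,
                                       region_start = 495, region_len = 10,
                                       deletion_freq = 0.3) {
  cfg <- scenario_deletion_config(seed, gamma = 0, n_families = n_families,
                                  family_size_range = family_size_range,
                                  n_probes = n_probes, n_chromosomes = 2,
                                  region_start = region_start,
                                  region_len = region_len,
                                  deletion_freq = deletion_freq)
  cohort <- simulate_cohort(cfg)
  seeds <- derive_seeds(seed + 1L, 2)
  set.seed(seeds[1])
  cohort <- simulate_linked_snp(cohort, region = 1L, r2_target = r2)
  add_snp_phenotype_effect(cohort, cohort$linked_snps[[1]]$snp_id, beta_snp)
}

#' @describeIn scenarios A 20-probe region with both deletions and
#'   duplications and a carrier phenotype shift, for forced-calling and
#'   carrier-association recovery. About 200 samples.
#' @param carrier_shift Sqrt-percent-density shift applied to carriers.
#' @export
scenario_calling_cohort <- function(seed, region_len = 20,
                                    deletion_freq = 0.25,
                                    duplication_freq = 0.1,
                                    carrier_shift = -1.0,
                                    n_families = 50,
                                    family_size_range = c(3, 5),
                                    n_probes = 600) {
  cfg <- scenario_deletion_config(seed, gamma = 0, n_families = n_families,
                                  family_size_range = family_size_range,
                                  n_probes = n_probes, n_chromosomes = 1,
                                  region_start = 290,
                                  region_len = region_len,
                                  deletion_freq = deletion_freq,
                                  duplication_freq = duplication_freq)
  cohort <- simulate_cohort(cfg)
  if (carrier_shift != 0)
    cohort <- add_carrier_phenotype_effect(cohort, 1L, carrier_shift)
  cohort
}
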