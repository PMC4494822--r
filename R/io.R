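#' Construct an intensity panel
#'
#' Container for samples x probes LRR and BAF matrices plus the plate
#' assignment and the probe map the columns are aligned to.
#'
#' @param lrr,baf Numeric matrices (samples x probes); `NA` allowed. BAF
#'   must lie in \[0, 1\] where present.
#' @param samples Data frame with `sample_id` and `plate_id`.
#' @param probe_map Probe map data frame (see [read_probe_map()]).
#' @return An `intensity_panel`.
#' @export
new_intensity_panel <- function(lrr, baf, samples, probe_map) {
  validate_probe_map(probe_map)
  stopifnot(is.matrix(lrr), is.matrix(baf),
            nrow(lrr) == nrow(samples), ncol(lrr) == nrow(probe_map),
            identical(dim(lrr), dim(baf)),
            !anyDuplicated(samples$sample_id))
  if (length(baf)) {
    rng <- suppressWarnings(range(baf, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
      stop("BAF values must lie in [0, 1]")
  }
  rownames(lrr) <- rownames(baf) <- samples$sample_id
  colnames(lrr) <- colnames(baf) <- probe_map$probe_id
  structure(list(lrr = lrr, baf = baf, samples = samples,
                 probe_map = probe_map),
            class = "intensity_panel")
}

#' @method print intensity_panel
#' @export
print.intensity_panel <- function(x, ...) {
  cat("intensity_panel:", nrow(x$lrr), "samples x", ncol(x$lrr), "probes,",
      length(unique(x$samples$plate_id)), "plate(s)\n")
  invisible(x)
}

validate_probe_map <- function(pm) {
  need <- c("probe_id", "chromosome", "position", "is_snp")
  if (!all(need %in% names(pm)))
    stop("probe map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(pm$probe_id)) stop("probe ids must be unique")
  if (any(pm$position < 1)) stop("positions must be >= 1")
  o <- order(pm$chromosome, pm$position)
  if (!identical(o, seq_len(nrow(pm))))
    stop("probe map must be sorted by (chromosome, position)")
  invisible(pm)
}

#' Read / write a probe map
#'
#' Tab-delimited with columns `probe_id`, `chromosome`, `position`,
#' `is_snp`; sorted by (chromosome, position).
#'
#' @param path File path.
#' @return A validated probe-map data frame.
#' @export
read_probe_map <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chromosome = "character"))
  pm$is_snp <- as.logical(pm$is_snp)
  validate_probe_map(pm)
  pm
}

#' @rdname read_probe_map
#' @param probe_map Probe-map data frame.
#' @export
write_probe_map <- function(probe_map, path) {
  utils::write.table(probe_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Comma-separated with columns `sample_id`, `percent_density`, `age`,
#' `bmi`, `menopausal`, `family_id`, `plate_id`.
#'
#' @param path File path.
#' @return Phenotype data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character"))
  validate_phenotypes(ph)
  ph
}

#' @rdname read_phenotypes
#' @param phenotypes Phenotype data frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_phenotypes <- function(ph) {
  need <- c("sample_id", "percent_density", "age", "bmi", "menopausal",
            "family_id", "plate_id")
  if (!all(need %in% names(ph)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ph$sample_id)) stop("sample ids must be unique")
  if (any(ph$bmi <= 0, na.rm = TRUE)) stop("bmi must be positive")
  pd <- ph$percent_density
  if (any(pd < 0 | pd > 100, na.rm = TRUE))
    stop("percent_density must lie in [0, 100]")
  invisible(ph)
}

#' Read / write a genotype table
#'
#' Tab-delimited, samples in rows (first column `sample_id`), SNPs in
#' columns, values 0/1/2 or NA.
#'
#' @param path File path.
#' @return Samples x SNPs integer matrix with sample-id rownames.
#' @export
read_genotypes <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = c(sample_id = "character"))
  g <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- d$sample_id
  bad <- !(g %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA")
  g
}

#' @rdname read_genotypes
#' @param genotypes Samples x SNPs matrix.
#' @export
write_genotypes <- function(genotypes, path) {
  d <- data.frame(sample_id = rownames(genotypes), genotypes,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

signal_colnames <- function(sample_id) {
  c("Name", "Chr", "Position",
    paste0(sample_id, ".Log R Ratio"),
    paste0(sample_id, ".B Allele Freq"))
}

#' Write per-sample signal files
#'
#' One tab-delimited file per sample in the prevailing array-signal export
#' dialect: `Name  Chr  Position  <sample>.Log R Ratio  <sample>.B Allele
#' Freq`.
#'
#' @param panel An `intensity_panel`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_signal_files <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pm <- panel$probe_map
  paths <- character(nrow(panel$samples))
  for (i in seq_len(nrow(panel$samples))) {
    sid <- panel$samples$sample_id[i]
    d <- data.frame(pm$probe_id, pm$chromosome, pm$position,
                    panel$lrr[i, ], panel$baf[i, ],
                    stringsAsFactors = FALSE)
    names(d) <- signal_colnames(sid)
    paths[i] <- file.path(dir, paste0(sid, ".txt"))
    utils::write.table(d, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Read per-sample signal files into an intensity panel
#'
#' Probes are aligned to the probe-map order regardless of file order;
#' probes absent from a file become missing values (counts are reported via
#' `message()`). A file listing fewer than half of the map's probes, or any
#' probe twice, is an error.
#'
#' @param paths Character vector of signal-file paths.
#' @param probe_map Probe map the panel is aligned to.
#' @param plate_ids Optional plate assignment per file (defaults to a single
#'   plate `"PL01"`).
#' @return An `intensity_panel`.
#' @export
read_signal_files <- function(paths, probe_map, plate_ids = NULL) {
  validate_probe_map(probe_map)
  P <- nrow(probe_map)
  n <- length(paths)
  lrr <- matrix(NA_real_, n, P)
  baf <- matrix(NA_real_, n, P)
  sample_id <- character(n)
  for (i in seq_len(n)) {
    d <- utils::read.delim(paths[i], check.names = FALSE,
                           stringsAsFactors = FALSE)
    lcol <- grep("\\.Log R Ratio$", names(d), value = TRUE)
    bcol <- grep("\\.B Allele Freq$", names(d), value = TRUE)
    if (length(lcol) != 1 || length(bcol) != 1 || !"Name" %in% names(d))
      stop("malformed signal file: ", paths[i])
    sample_id[i] <- sub("\\.Log R Ratio$", "", lcol)
    if (anyDuplicated(d$Name))
      stop("duplicate probe within signal file: ", paths[i])
    idx <- match(probe_map$probe_id, d$Name)
    n_missing <- sum(is.na(idx))
    if (P - n_missing < P / 2)
      stop("signal file ", paths[i], " covers fewer than half of the probes")
    if (n_missing > 0)
      message(sample_id[i], ": ", n_missing, " probe(s) absent, set missing")
    lrr[i, ] <- d[[lcol]][idx]
    baf[i, ] <- d[[bcol]][idx]
  }
  if (is.null(plate_ids)) plate_ids <- rep("PL01", n)
  new_intensity_panel(lrr, baf,
                      data.frame(sample_id = sample_id, plate_id = plate_ids,
                                 stringsAsFactors = FALSE),
                      probe_map)
}

#' Write a simulated cohort to disk
#'
#' Emits the signal files, probe map, phenotype CSV, genotype TSV and
#' ground-truth TSV in the formats read back by the corresponding readers.
#'
#' @param cohort A `cnv_cohort`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_signal_files(cohort$panel, file.path(dir, "signals"))
  write_probe_map(cohort$probe_map, file.path(dir, "probe_map.tsv"))
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  if (!is.null(cohort$genotypes))
    write_genotypes(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
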