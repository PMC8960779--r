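#' Simulation configuration for a synthetic iCCA cohort
#'
#' Bundles and validates every parameter of the synthetic cohort generator.
#' The defaults describe the study conditions used throughout the package's
#' tests: a small two-subtype cohort (two tumors per subtype plus two
#' reference liver samples), chromosome-ordered genes with six broad copy
#' number segments in malignant cells, two mutually exclusive marker programs
#' (a perihilar-like "phl" program seeded by marker A and a peripheral
#' small-duct-like "pps" program seeded by marker B), negative-binomial counts
#' with dropout, and a dedicated mitochondrial contig so the QC filter is
#' exercisable.
#'
#' @param n_tumors_per_subtype Number of tumor samples per subtype (two
#'   subtypes are always generated).
#' @param n_ref_samples Number of reference (non-tumor liver) samples; their
#'   epithelial cells serve as the CNV centering reference.
#' @param cells_per_sample Cells simulated per sample.
#' @param malignant_fraction Fraction of cells in each tumor sample that are
#'   malignant (carry CNV segments and a marker program).
#' @param n_genes Number of nuclear genes, distributed evenly across
#'   chromosomes.
#' @param n_chromosomes Number of nuclear chromosomes.
#' @param n_mito Number of mitochondrial genes appended on a dedicated "MT"
#'   contig (13 mimics the human mitochondrial proteome).
#' @param cnv_segments `data.frame(chrom, start, end, shift)`: per-segment
#'   chromosome name, first and last gene index *within that chromosome*
#'   (1-based, inclusive) and log2 expression shift applied multiplicatively
#'   to malignant cells. `NULL` builds the default six alternating +/-0.5
#'   segments on chromosomes 1-6.
#' @param marker_program List with elements `seed_marker`, `alt_marker` (gene
#'   ids; `NULL` auto-selects the first two genes of the last nuclear
#'   chromosome), `program_size` (genes per subtype program), `marker_mean`
#'   (expected UMI count of a cell's own marker), `marker_bg_mean` (expected
#'   count of the opposite marker), and `program_log2fc` (log2 shift of
#'   program genes).
#' @param libsize_mean Expected UMIs per cell.
#' @param libsize_cv Coefficient of variation of the lognormal per-cell
#'   library size.
#' @param dropout_rate Independent per-entry Bernoulli dropout probability.
#' @param dispersion Negative-binomial dispersion (NB size = 1/dispersion).
#' @param mito_fraction_range Interval from which each cell's expected
#'   mitochondrial UMI fraction is drawn uniformly.
#' @param purity Tumor purity used when simulating mutation allele counts.
#' @param clonal_fraction Fraction of simulated mutations that are clonal
#'   (cancer cell fraction 1).
#' @param depth_mean Expected sequencing depth per mutation site.
#' @param n_mutations Mutations simulated per tumor.
#' @param subclonal_ccf_range Interval for subclonal cancer cell fractions.
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_tumors_per_subtype = 2L,
                       n_ref_samples = 2L,
                       cells_per_sample = 200L,
                       malignant_fraction = 0.6,
                       n_genes = 2400L,
                       n_chromosomes = 8L,
                       n_mito = 13L,
                       cnv_segments = NULL,
                       marker_program = list(),
                       libsize_mean = 20000,
                       libsize_cv = 0.3,
                       dropout_rate = 0.05,
                       dispersion = 0.15,
                       mito_fraction_range = c(0.01, 0.10),
                       purity = 0.8,
                       clonal_fraction = 0.6,
                       depth_mean = 500,
                       n_mutations = 200L,
                       subclonal_ccf_range = c(0.2, 0.6),
                       seed = 1L) {
  check_count(n_tumors_per_subtype, "n_tumors_per_subtype")
  check_count(n_ref_samples, "n_ref_samples", min = 0L)
  check_count(cells_per_sample, "cells_per_sample")
  check_count(n_genes, "n_genes")
  check_count(n_chromosomes, "n_chromosomes")
  check_count(n_mito, "n_mito", min = 0L)
  check_count(n_mutations, "n_mutations")
  check_fraction(malignant_fraction, "malignant_fraction")
  check_fraction(dropout_rate, "dropout_rate")
  check_fraction(clonal_fraction, "clonal_fraction")
  check_fraction(purity, "purity", lo = 1e-12)
  if (n_genes < n_chromosomes) stopf("`n_genes` must be >= `n_chromosomes`")
  if (libsize_mean <= 0) stopf("`libsize_mean` must be positive")
  if (depth_mean <= 0) stopf("`depth_mean` must be positive")
  if (dispersion < 0) stopf("`dispersion` must be non-negative")
  if (length(mito_fraction_range) != 2L ||
      any(mito_fraction_range < 0) || any(mito_fraction_range > 1) ||
      mito_fraction_range[1] > mito_fraction_range[2]) {
    stopf("`mito_fraction_range` must be an increasing interval within [0, 1]")
  }
  if (length(subclonal_ccf_range) != 2L ||
      any(subclonal_ccf_range <= 0) || any(subclonal_ccf_range >= 1) ||
      subclonal_ccf_range[1] > subclonal_ccf_range[2]) {
    stopf("`subclonal_ccf_range` must be an increasing interval within (0, 1)")
  }

  genes_per_chrom <- gene_counts_per_chrom(n_genes, n_chromosomes)
  if (is.null(cnv_segments)) {
    cnv_segments <- default_cnv_segments(genes_per_chrom)
  }
  validate_cnv_segments(cnv_segments, genes_per_chrom)

  mp_defaults <- list(seed_marker = NULL, alt_marker = NULL,
                      program_size = 20L, marker_mean = 8,
                      marker_bg_mean = 0.02, program_log2fc = 1)
  marker_program <- utils::modifyList(mp_defaults, as.list(marker_program))
  if (!is.null(marker_program$seed_marker) &&
      identical(marker_program$seed_marker, marker_program$alt_marker)) {
    stopf("the two marker genes must be distinct")
  }

  structure(list(
    n_tumors_per_subtype = as.integer(n_tumors_per_subtype),
    n_ref_samples = as.integer(n_ref_samples),
    cells_per_sample = as.integer(cells_per_sample),
    malignant_fraction = malignant_fraction,
    n_genes = as.integer(n_genes),
    n_chromosomes = as.integer(n_chromosomes),
    n_mito = as.integer(n_mito),
    cnv_segments = cnv_segments,
    marker_program = marker_program,
    libsize_mean = libsize_mean,
    libsize_cv = libsize_cv,
    dropout_rate = dropout_rate,
    dispersion = dispersion,
    mito_fraction_range = as.numeric(mito_fraction_range),
    purity = purity,
    clonal_fraction = clonal_fraction,
    depth_mean = depth_mean,
    n_mutations = as.integer(n_mutations),
    subclonal_ccf_range = as.numeric(subclonal_ccf_range),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# even split of nuclear genes over chromosomes; remainder to the first ones
gene_counts_per_chrom <- function(n_genes, n_chromosomes) {
  base <- n_genes %/% n_chromosomes
  extra <- n_genes %% n_chromosomes
  counts <- rep(base, n_chromosomes) + c(rep(1L, extra), rep(0L, n_chromosomes - extra))
  stats::setNames(as.integer(counts), paste0("chr", seq_len(n_chromosomes)))
}

# six broad alternating-gain/loss segments covering ~90% of chromosomes 1..6,
# leaving at least the last chromosome copy-neutral for marker genes
default_cnv_segments <- function(genes_per_chrom) {
  n_seg <- min(6L, max(1L, length(genes_per_chrom) - 1L))
  chroms <- names(genes_per_chrom)[seq_len(n_seg)]
  gpc <- genes_per_chrom[seq_len(n_seg)]
  data.frame(
    chrom = chroms,
    start = pmin(gpc, ceiling(0.05 * gpc) + 1L),
    end = pmax(1L, floor(0.95 * gpc)),
    shift = rep_len(c(0.5, -0.5), n_seg),
    stringsAsFactors = FALSE
  )
}

validate_cnv_segments <- function(segments, genes_per_chrom) {
  req <- c("chrom", "start", "end", "shift")
  if (!is.data.frame(segments) || !all(req %in% names(segments))) {
    stopf("`cnv_segments` must be a data.frame with columns %s",
          paste(req, collapse = ", "))
  }
  bad <- !segments$chrom %in% names(genes_per_chrom)
  if (any(bad)) stopf("cnv_segments reference unknown chromosome(s): %s",
                      paste(unique(segments$chrom[bad]), collapse = ", "))
  n <- genes_per_chrom[segments$chrom]
  if (any(segments$start < 1L) || any(segments$end > n) ||
      any(segments$start > segments$end)) {
    stopf("cnv_segments gene indices must satisfy 1 <= start <= end <= genes on chromosome")
  }
  invisible(segments)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic iCCA cohort configuration\n")
  cat(sprintf("  samples: %d tumors/subtype x 2 subtypes + %d reference\n",
              x$n_tumors_per_subtype, x$n_ref_samples))
  cat(sprintf("  %d cells/sample, %d nuclear genes on %d chromosomes (+%d MT)\n",
              x$cells_per_sample, x$n_genes, x$n_chromosomes, x$n_mito))
  cat(sprintf("  %d CNV segments, libsize %g, dropout %g, seed %d\n",
              nrow(x$cnv_segments), x$libsize_mean, x$dropout_rate, x$seed))
  invisible(x)
}
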