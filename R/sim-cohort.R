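#' Generate a chromosome-ordered synthetic gene table
#'
#' Builds a BED-like gene position table: `n_genes` nuclear genes split evenly
#' over `n_chromosomes` chromosomes, plus `n_mito` mitochondrial genes on a
#' dedicated `"MT"` contig flagged `is_mito` (these anchor the mitochondrial
#' QC filter). Within each chromosome, start coordinates are strictly
#' increasing and genes do not overlap; rows are ordered by (chromosome,
#' start), which is the global gene order used by the CNV sliding windows.
#' Coordinates are 0-based half-open as in BED.
#'
#' @param n_genes Number of nuclear genes (>= n_chromosomes).
#' @param n_chromosomes Number of nuclear chromosomes.
#' @param seed Integer seed; fixed seed gives byte-identical tables.
#' @param n_mito Number of genes on the "MT" contig (default 13).
#'
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `is_mito`, ordered by genomic location.
#' @export
#' @examples
#' gt <- generate_gene_table(300, 3, seed = 1)
#' table(gt$chrom)
generate_gene_table <- function(n_genes, n_chromosomes, seed = 1L, n_mito = 13L) {
  check_count(n_genes, "n_genes")
  check_count(n_chromosomes, "n_chromosomes")
  check_count(n_mito, "n_mito", min = 0L)
  if (n_genes < n_chromosomes) stopf("`n_genes` must be >= `n_chromosomes`")

  with_seed(seed, {
    gpc <- gene_counts_per_chrom(n_genes, n_chromosomes)
    chrom <- rep(names(gpc), gpc)
    # non-overlapping gene bodies: random widths and intergenic gaps
    widths <- sample(200:2000, n_genes, replace = TRUE)
    gaps <- sample(500:5000, n_genes, replace = TRUE)
    start <- integer(n_genes)
    end <- integer(n_genes)
    pos <- 0L
    last_chrom <- ""
    for (i in seq_len(n_genes)) {
      if (chrom[i] != last_chrom) {
        pos <- 0L
        last_chrom <- chrom[i]
      }
      start[i] <- pos + gaps[i]
      end[i] <- start[i] + widths[i]
      pos <- end[i]
    }
    nuclear <- data.frame(
      gene_id = sprintf("G%05d", seq_len(n_genes)),
      chrom = chrom, start = start, end = end,
      is_mito = FALSE, stringsAsFactors = FALSE
    )
    if (n_mito > 0L) {
      mw <- sample(200:1700, n_mito, replace = TRUE)
      ms <- cumsum(sample(50:400, n_mito, replace = TRUE) + c(0L, mw[-n_mito]))
      mito <- data.frame(
        gene_id = sprintf("MT-G%02d", seq_len(n_mito)),
        chrom = "MT", start = ms, end = ms + mw,
        is_mito = TRUE, stringsAsFactors = FALSE
      )
      nuclear <- rbind(nuclear, mito)
    }
    rownames(nuclear) <- NULL
    nuclear
  })
}

resolve_marker_program <- function(config, gene_table) {
  mp <- config$marker_program
  nuclear <- gene_table$gene_id[!gene_table$is_mito]
  chroms <- gene_table$chrom[!gene_table$is_mito]
  last_chrom <- chroms[length(chroms)]
  last_genes <- nuclear[chroms == last_chrom]
  if (is.null(mp$seed_marker)) mp$seed_marker <- last_genes[1L]
  if (is.null(mp$alt_marker)) mp$alt_marker <- last_genes[2L]
  if (!all(c(mp$seed_marker, mp$alt_marker) %in% gene_table$gene_id)) {
    stopf("marker genes %s / %s absent from the gene table",
          mp$seed_marker, mp$alt_marker)
  }
  if (identical(mp$seed_marker, mp$alt_marker)) {
    stopf("the two marker genes must be distinct")
  }
  if (is.null(mp$program_a) || is.null(mp$program_b)) {
    pool <- setdiff(last_genes, c(mp$seed_marker, mp$alt_marker))
    k <- min(mp$program_size, length(pool) %/% 2L)
    mp$program_a <- mp$program_a %||% pool[seq_len(k)]
    mp$program_b <- mp$program_b %||% pool[k + seq_len(k)]
  }
  mp
}

#' Generate a synthetic single-cell cohort with known ground truth
#'
#' Simulates a 10x-style UMI count matrix (genes x cells) for a two-subtype
#' tumor cohort. Counts are negative binomial around per-cell lognormal
#' library sizes with independent Bernoulli dropout. Malignant cells carry
#' multiplicative `2^shift` expression changes over the configured CNV
#' segments and express exactly one of two mutually exclusive marker programs
#' according to their sample's subtype; reference samples contain no
#' malignant cells. Each cell's expected mitochondrial UMI fraction is drawn
#' from the configured interval and realized on the "MT" contig genes. Truth
#' labels travel in the cell metadata under `truth_`-prefixed columns.
#'
#' @param config A [sim_config()] object.
#'
#' @return An object of class `"CellCohort"`: a list with `counts` (sparse
#'   dgCMatrix, genes x cells), `cell_meta` (data.frame with `cell_id`,
#'   `sample`, `tissue`, `cell_type`, `truth_malignant`, `truth_program`,
#'   `truth_subtype`), `gene_table`, and the resolved `marker_program`.
#' @export
generate_sc_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stopf("`config` must be a sim_config")

  gene_table <- generate_gene_table(config$n_genes, config$n_chromosomes,
                                    seed = derive_seed(config$seed, 1L),
                                    n_mito = config$n_mito)
  mp <- resolve_marker_program(config, gene_table)

  with_seed(derive_seed(config$seed, 2L), {
    n_tum <- 2L * config$n_tumors_per_subtype
    tumor_ids <- sprintf("T%02d", seq_len(n_tum))
    subtype <- rep(c("phl", "pps"), each = config$n_tumors_per_subtype)
    ref_ids <- if (config$n_ref_samples > 0L)
      sprintf("N%02d", seq_len(config$n_ref_samples)) else character()

    samples <- c(tumor_ids, ref_ids)
    tissue <- c(rep("tumor", n_tum), rep("normal", length(ref_ids)))
    sample_subtype <- c(subtype, rep(NA_character_, length(ref_ids)))

    cps <- config$cells_per_sample
    n_cells <- cps * length(samples)
    cell_sample <- rep(samples, each = cps)
    cell_tissue <- rep(tissue, each = cps)
    cell_subtype <- rep(sample_subtype, each = cps)

    n_mal <- round(config$malignant_fraction * cps)
    malignant <- rep(FALSE, n_cells)
    for (s in tumor_ids) {
      idx <- which(cell_sample == s)
      malignant[idx[seq_len(n_mal)]] <- TRUE
    }
    program <- ifelse(malignant, cell_subtype, "none")

    is_mito <- gene_table$is_mito
    nuc_ids <- gene_table$gene_id[!is_mito]
    n_nuc <- length(nuc_ids)
    n_mt <- sum(is_mito)

    # per-cohort baseline gene weights (relative expression propensities)
    w_base <- stats::rlnorm(n_nuc, meanlog = 0, sdlog = 0.5)
    w_mt <- if (n_mt > 0L) stats::rlnorm(n_mt, meanlog = 0, sdlog = 0.3) else numeric()
    base_sum <- sum(w_base)

    # CNV multipliers along the nuclear gene order
    shift_mult <- rep(1, n_nuc)
    nuc_chrom <- gene_table$chrom[!is_mito]
    for (k in seq_len(nrow(config$cnv_segments))) {
      seg <- config$cnv_segments[k, ]
      pos <- which(nuc_chrom == seg$chrom)
      shift_mult[pos[seg$start:seg$end]] <- 2^seg$shift
    }

    marker_w <- function(expected_count) expected_count * base_sum / config$libsize_mean
    ia <- match(mp$seed_marker, nuc_ids)
    ib <- match(mp$alt_marker, nuc_ids)
    ipa <- match(mp$program_a, nuc_ids)
    ipb <- match(mp$program_b, nuc_ids)
    if (anyNA(c(ia, ib))) stopf("marker genes must be nuclear genes")

    class_weights <- function(cls) {
      w <- w_base
      w[c(ia, ib)] <- marker_w(mp$marker_bg_mean)
      if (cls == "mal_phl") {
        w <- w * shift_mult
        w[ia] <- marker_w(mp$marker_mean)
        w[ipa] <- w[ipa] * 2^mp$program_log2fc
      } else if (cls == "mal_pps") {
        w <- w * shift_mult
        w[ib] <- marker_w(mp$marker_mean)
        w[ipb] <- w[ipb] * 2^mp$program_log2fc
      }
      w
    }
    W <- cbind(normal = class_weights("normal"),
               mal_phl = class_weights("mal_phl"),
               mal_pps = class_weights("mal_pps"))
    cls_idx <- ifelse(!malignant, 1L, ifelse(program == "phl", 2L, 3L))

    sdlog <- sqrt(log(1 + config$libsize_cv^2))
    libsize <- stats::rlnorm(n_cells, meanlog = log(config$libsize_mean) - sdlog^2 / 2,
                             sdlog = sdlog)
    mito_frac <- stats::runif(n_cells, config$mito_fraction_range[1],
                              config$mito_fraction_range[2])
    keep_p <- 1 - config$dropout_rate

    # expected counts; dropout-compensated so E[total UMIs] == libsize
    mu_nuc <- W[, cls_idx, drop = FALSE] / base_sum
    mu_nuc <- sweep(mu_nuc, 2L, libsize * (1 - mito_frac) / keep_p, `*`)
    size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
    draw <- function(mu) {
      n <- length(mu)
      x <- if (is.finite(size)) stats::rnbinom(n, mu = mu, size = size)
           else stats::rpois(n, lambda = mu)
      if (config$dropout_rate > 0) x <- x * stats::rbinom(n, 1L, keep_p)
      x
    }
    counts_nuc <- matrix(draw(mu_nuc), nrow = n_nuc, ncol = n_cells)
    if (n_mt > 0L) {
      mu_mt <- outer(w_mt / sum(w_mt), libsize * mito_frac / keep_p)
      counts_mt <- matrix(draw(mu_mt), nrow = n_mt, ncol = n_cells)
    }

    counts <- matrix(0L, nrow = nrow(gene_table), ncol = n_cells)
    counts[!is_mito, ] <- counts_nuc
    if (n_mt > 0L) counts[is_mito, ] <- counts_mt
    dimnames(counts) <- list(gene_table$gene_id,
                             sprintf("%s_C%04d", cell_sample,
                                     stats::ave(seq_len(n_cells), cell_sample,
                                                FUN = seq_along)))
    counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                      "generalMatrix"), "CsparseMatrix")

    cell_meta <- data.frame(
      cell_id = colnames(counts),
      sample = cell_sample,
      tissue = cell_tissue,
      cell_type = "epithelial",
      truth_malignant = malignant,
      truth_program = program,
      truth_subtype = cell_subtype,
      stringsAsFactors = FALSE
    )

    structure(list(counts = counts, cell_meta = cell_meta,
                   gene_table = gene_table, marker_program = mp,
                   config = config),
              class = "CellCohort")
  })
}

#' @export
print.CellCohort <- function(x, ...) {
  cat(sprintf("CellCohort: %d genes x %d cells over %d samples\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cell_meta$sample))))
  cat(sprintf("  %d malignant cells (truth); markers %s / %s\n",
              sum(x$cell_meta$truth_malignant),
              x$marker_program$seed_marker, x$marker_program$alt_marker))
  invisible(x)
}

#' Generate a synthetic bulk expression cohort with bimodal markers
#'
#' Emulates a bulk cholangiocarcinoma cohort in which two marker genes have
#' bimodal log2 expression across samples. Each sample belongs to one of four
#' classes (A+B-, A-B+, A-B-, A+B+) drawn from `subtype_mix`; its expression
#' of each marker is sampled from the high- or low-mean Gaussian component
#' according to the class. Decoy genes with unimodal expression are appended.
#'
#' @param n_samples Cohort size (>= 4; a two-component mixture is unfittable
#'   below that).
#' @param subtype_mix Length-4 vector of class probabilities in the order
#'   A+B-, A-B+, A-B-, A+B+; must sum to 1. Class counts are the rounded
#'   expectations, so the planted composition is deterministic.
#' @param component_means Length-2 vector `c(low, high)` of component means
#'   (log2 expression units), shared by both markers.
#' @param component_sds Length-2 vector of component standard deviations.
#' @param seed Integer seed.
#' @param marker_names Row names used for the two marker genes.
#' @param n_noise_genes Number of unimodal decoy genes appended.
#'
#' @return A list with `expr` (genes x samples matrix of log2 expression) and
#'   `truth` (data.frame with `sample` and planted four-way `class`).
#' @export
generate_bulk_cohort <- function(n_samples, subtype_mix = c(0.45, 0.45, 0.06, 0.04),
                                 component_means = c(4, 9),
                                 component_sds = c(1, 1),
                                 seed = 1L,
                                 marker_names = c("S100P", "SPP1"),
                                 n_noise_genes = 20L) {
  check_count(n_samples, "n_samples", min = 4L)
  if (length(subtype_mix) != 4L || any(subtype_mix < 0) ||
      abs(sum(subtype_mix) - 1) > 1e-8) {
    stopf("`subtype_mix` must be 4 non-negative probabilities summing to 1")
  }
  if (length(component_means) != 2L || component_means[1] == component_means[2]) {
    stopf("`component_means` must be two distinct values")
  }

  with_seed(seed, {
    # deterministic class counts: rounded cumulative allocation sums to n
    cum <- round(cumsum(subtype_mix) * n_samples)
    counts <- diff(c(0, cum))
    classes <- c("A+B-", "A-B+", "A-B-", "A+B+")
    cls <- rep(classes, counts)
    a_pos <- cls %in% c("A+B-", "A+B+")
    b_pos <- cls %in% c("A-B+", "A+B+")
    mlow <- component_means[1]; mhigh <- component_means[2]
    slow <- component_sds[1]; shigh <- component_sds[2]
    a <- stats::rnorm(n_samples, ifelse(a_pos, mhigh, mlow),
                      ifelse(a_pos, shigh, slow))
    b <- stats::rnorm(n_samples, ifelse(b_pos, mhigh, mlow),
                      ifelse(b_pos, shigh, slow))
    noise <- matrix(stats::rnorm(n_noise_genes * n_samples, mean = 5, sd = 1),
                    nrow = n_noise_genes)
    expr <- rbind(matrix(a, nrow = 1), matrix(b, nrow = 1), noise)
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    dimnames(expr) <- list(c(marker_names, sprintf("NOISE%03d", seq_len(n_noise_genes))),
                           sample_ids)
    cls_named <- markers_class_labels(cls, marker_names)
    list(expr = expr,
         truth = data.frame(sample = sample_ids, class = cls_named,
                            stringsAsFactors = FALSE))
  })
}

# "A+B-" style codes -> marker-named labels like "S100P+SPP1-"
markers_class_labels <- function(cls, marker_names) {
  map <- c("A+B-" = paste0(marker_names[1], "+", marker_names[2], "-"),
           "A-B+" = paste0(marker_names[1], "-", marker_names[2], "+"),
           "A-B-" = paste0(marker_names[1], "-", marker_names[2], "-"),
           "A+B+" = paste0(marker_names[1], "+", marker_names[2], "+"))
  unname(map[cls])
}

#' Generate a synthetic mutation table with known clonality
#'
#' Simulates per-mutation allele counts for one tumor. A configured fraction
#' of mutations is clonal (cancer cell fraction 1); the rest are subclonal
#' with CCF drawn uniformly from `subclonal_ccf_range`. Read depth is Poisson
#' around `depth_mean` (floored at 1) and alt counts are binomial at the
#' expected variant allele fraction \eqn{VAF = CCF \cdot p \cdot m /
#' (p \cdot CN_{tot} + 2(1 - p))} with multiplicity m = 1.
#'
#' @param n_mutations Number of mutations.
#' @param clonal_fraction Fraction of mutations that are clonal.
#' @param purity Tumor purity in (0, 1].
#' @param depth_mean Expected depth (> 0).
#' @param seed Integer seed.
#' @param sample_id Sample label written in the table.
#' @param total_cn,major_cn Local total and major copy number at each site.
#' @param subclonal_ccf_range Interval for subclonal CCFs.
#'
#' @return A list with `mutations` (data.frame: sample, chrom, pos, ref, alt,
#'   ref_count, alt_count, purity, total_cn, major_cn) and `truth`
#'   (data.frame with `clonal` flag and the planted `ccf_true`).
#' @export
generate_mutation_table <- function(n_mutations, clonal_fraction = 0.6,
                                    purity = 0.8, depth_mean = 500, seed = 1L,
                                    sample_id = "T01",
                                    total_cn = 2L, major_cn = 1L,
                                    subclonal_ccf_range = c(0.2, 0.6)) {
  check_count(n_mutations, "n_mutations")
  check_fraction(clonal_fraction, "clonal_fraction")
  check_fraction(purity, "purity", lo = 1e-12)
  if (depth_mean <= 0) stopf("`depth_mean` must be positive")

  with_seed(seed, {
    n_clonal <- round(clonal_fraction * n_mutations)
    clonal <- rep(FALSE, n_mutations)
    clonal[sample.int(n_mutations, n_clonal)] <- TRUE
    ccf <- ifelse(clonal, 1,
                  stats::runif(n_mutations, subclonal_ccf_range[1],
                               subclonal_ccf_range[2]))
    vaf <- ccf * purity * 1 / (purity * total_cn + (1 - purity) * 2)
    depth <- pmax(1L, stats::rpois(n_mutations, depth_mean))
    alt <- stats::rbinom(n_mutations, depth, vaf)
    bases <- c("A", "C", "G", "T")
    ref_allele <- sample(bases, n_mutations, replace = TRUE)
    alt_allele <- vapply(ref_allele,
                         function(r) sample(setdiff(bases, r), 1L), "")
    list(
      mutations = data.frame(
        sample = sample_id,
        chrom = paste0("chr", sample.int(22L, n_mutations, replace = TRUE)),
        pos = sample.int(1e8L, n_mutations),
        ref = ref_allele, alt = unname(alt_allele),
        ref_count = depth - alt, alt_count = alt,
        purity = purity, total_cn = as.integer(total_cn),
        major_cn = as.integer(major_cn),
        stringsAsFactors = FALSE
      ),
      truth = data.frame(clonal = clonal, ccf_true = ccf)
    )
  })
}
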