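# Independent brute-force reimplementations used as oracles. These are
# deliberately straight-line (loops, no shared code with the package).

oracle_windowed_means <- function(values, chrom, window_size, window_step) {
  out <- numeric(0)
  for (ch in unique(chrom)) {
    v <- values[chrom == ch]
    n <- length(v)
    if (n < window_size) {
      out <- c(out, mean(v))
    } else {
      starts <- seq(1, n - window_size + 1, by = window_step)
      for (s in starts) out <- c(out, mean(v[s:(s + window_size - 1)]))
    }
  }
  out
}

oracle_cnv_score <- function(cnvi_vec) {
  total <- 0
  for (w in seq_along(cnvi_vec)) total <- total + cnvi_vec[w]^2
  total / length(cnvi_vec)
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

oracle_positive_fraction <- function(counts_vec, min_count = 1) {
  hits <- 0
  for (v in counts_vec) if (v >= min_count) hits <- hits + 1
  hits / length(counts_vec)
}

oracle_ccf <- function(alt, ref, purity, total_cn, m) {
  vaf <- alt / (alt + ref)
  vaf * (purity * total_cn + (1 - purity) * 2) / (purity * m)
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
oracle_wilcoxon_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# small dense toy cohort with explicit mito gene, used by preprocess tests
toy_cohort <- function(umis = c(500, 1000, 2000, 3000, 4000),
                       mito_frac = rep(0.10, length(umis))) {
  n <- length(umis)
  mito <- round(umis * mito_frac)
  counts <- rbind(
    GENE1 = round((umis - mito) * 0.6),
    GENE2 = umis - mito - round((umis - mito) * 0.6),
    `MT-G01` = mito
  )
  colnames(counts) <- sprintf("cell%d", seq_len(n))
  gene_table <- data.frame(
    gene_id = rownames(counts), chrom = c("chr1", "chr1", "MT"),
    start = c(0, 2000, 0), end = c(1000, 3000, 1000),
    is_mito = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE
  )
  structure(list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    cell_meta = data.frame(cell_id = colnames(counts), sample = "S1",
                           tissue = "tumor", cell_type = "epithelial",
                           stringsAsFactors = FALSE),
    gene_table = gene_table
  ), class = "CellCohort")
}

# compact simulation settings for structural (non-recovery) tests
quick_config <- function(seed = 1, ...) {
  args <- list(n_tumors_per_subtype = 1L, n_ref_samples = 1L,
               cells_per_sample = 60L, n_genes = 600L, n_chromosomes = 3L,
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
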