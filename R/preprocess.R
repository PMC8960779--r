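#' Quality-control filter for single-cell count matrices
#'
#' Removes low-quality cells using the two standard droplet QC rules: a cell
#' is excluded if it has fewer than `min_umi` total UMIs or if more than
#' `max_mito_fraction` of its UMIs come from mitochondrial genes. Both
#' boundaries are strict ("less than" / "greater than"), so a cell with
#' exactly `min_umi` UMIs and exactly the maximal mitochondrial fraction is
#' retained. Mitochondrial genes are taken from the gene table's `is_mito`
#' flag when present, otherwise from the conventional `"MT-"` gene-id prefix.
#'
#' @param cohort A `CellCohort` (see [generate_sc_cohort()]), or any list with
#'   `counts` (genes x cells), `cell_meta`, and `gene_table` elements.
#' @param min_umi Minimum total UMIs per cell (default 1000).
#' @param max_mito_fraction Maximum mitochondrial UMI fraction (default 0.20).
#'
#' @return The filtered `CellCohort`, with a `qc_report` attribute: a
#'   per-sample data.frame of cells in/out and removal reasons.
#' @export
qc_filter <- function(cohort, min_umi = 1000, max_mito_fraction = 0.20) {
  counts <- cohort$counts
  check_fraction(max_mito_fraction, "max_mito_fraction")
  if (min_umi < 0) stopf("`min_umi` must be >= 0")

  mito <- mito_gene_flags(cohort$gene_table, rownames(counts))
  if (!any(mito) && max_mito_fraction < 1) {
    stopf(paste("no mitochondrial genes found (is_mito flag or 'MT-' prefix);",
                "cannot apply the mitochondrial fraction filter"))
  }
  total <- Matrix::colSums(counts)
  mito_frac <- if (any(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1)
  } else rep(0, length(total))

  low_umi <- total < min_umi
  high_mito <- mito_frac > max_mito_fraction
  keep <- !low_umi & !high_mito

  meta <- cohort$cell_meta
  report <- do.call(rbind, lapply(split(seq_along(keep), meta$sample), function(i) {
    data.frame(sample = meta$sample[i[1]],
               n_cells_in = length(i),
               n_cells_kept = sum(keep[i]),
               n_low_umi = sum(low_umi[i]),
               n_high_mito = sum(high_mito[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL

  out <- cohort
  out$counts <- counts[, keep, drop = FALSE]
  out$cell_meta <- meta[keep, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  attr(out, "qc_report") <- report
  out
}

mito_gene_flags <- function(gene_table, gene_ids) {
  if (!is.null(gene_table) && "is_mito" %in% names(gene_table)) {
    flags <- gene_table$is_mito[match(gene_ids, gene_table$gene_id)]
    flags[is.na(flags)] <- FALSE
    flags
  } else {
    startsWith(gene_ids, "MT-")
  }
}

#' Library-size normalization with log transformation
#'
#' Scales each cell's counts to a common total (`scale_factor`, default
#' 10,000) and applies `log1p`:
#' \eqn{x_{gc} = \log(1 + count_{gc} \cdot s / total_c)}. Natural log is
#' used; every downstream procedure in this package (ranks, centering,
#' mixtures fit on their own inputs) is insensitive to the base. Sparsity is
#' preserved.
#'
#' @param counts Sparse or dense genes x cells count matrix, or a
#'   `CellCohort` (its `counts` element is used).
#' @param scale_factor Per-cell target total (> 0).
#'
#' @return A sparse dgCMatrix of normalized log expression with the input's
#'   dimnames.
#' @export
normalize_counts <- function(counts, scale_factor = 10000) {
  if (inherits(counts, "CellCohort")) counts <- counts$counts
  if (scale_factor <= 0) stopf("`scale_factor` must be positive")
  total <- Matrix::colSums(counts)
  if (any(total == 0)) {
    stopf("some cells have zero total counts; run qc_filter() first")
  }
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / total)
  norm <- methods::as(methods::as(norm, "generalMatrix"), "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  norm
}
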