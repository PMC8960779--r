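#' Parameters of the inferred-CNV malignancy classifier
#'
#' @param window_size Genes per sliding window (default 100).
#' @param window_step Window advance in genes (default 1).
#' @param clip_limit Absolute bound applied to reference-centered expression
#'   before windowing (default 3); prevents single-gene outliers from
#'   dominating 100-gene window means.
#' @param top_fraction Fraction of a tumor's cells, ranked by CNV score, that
#'   define its reference CNV profile (default 0.03).
#' @param score_threshold Malignancy threshold on the CNV score (default
#'   0.04); a cell must be strictly above it.
#' @param corr_threshold Malignancy threshold on the Spearman CNV correlation
#'   (default 0.5); strictly above.
#' @param min_cells Samples with fewer scored cells than this are reported
#'   but not called (the top-fraction reference profile is meaningless;
#'   default 10).
#'
#' @return A list of class `"cnv_params"`.
#' @export
cnv_params <- function(window_size = 100L, window_step = 1L, clip_limit = 3,
                       top_fraction = 0.03, score_threshold = 0.04,
                       corr_threshold = 0.5, min_cells = 10L) {
  check_count(window_size, "window_size")
  check_count(window_step, "window_step")
  check_fraction(top_fraction, "top_fraction", lo = 1e-12, hi = 1 - 1e-12)
  if (!is.finite(clip_limit) || clip_limit <= 0) stopf("`clip_limit` must be positive")
  if (!is.finite(score_threshold) || !is.finite(corr_threshold)) {
    stopf("thresholds must be finite")
  }
  structure(list(window_size = as.integer(window_size),
                 window_step = as.integer(window_step),
                 clip_limit = clip_limit, top_fraction = top_fraction,
                 score_threshold = score_threshold,
                 corr_threshold = corr_threshold,
                 min_cells = as.integer(min_cells)),
            class = "cnv_params")
}

#' Reference-centered relative expression
#'
#' Subtracts, per gene, the mean normalized expression over a set of
#' reference cells (epithelial cells from non-tumor tissue) from each target
#' cell, then clips values to `[-clip_limit, +clip_limit]`. Genes with zero
#' expression in every reference cell are still centered (their reference
#' mean is 0), so an expressed target gene simply keeps its normalized value
#' up to the clip.
#'
#' @param norm Normalized log-expression matrix (genes x cells), e.g. from
#'   [normalize_counts()].
#' @param target_cells,reference_cells Column names or indices; the reference
#'   set must be non-empty and disjoint from the targets.
#' @param clip_limit Absolute clipping bound (default 3).
#'
#' @return A dense genes x target-cells matrix of clipped centered values.
#' @export
relative_expression <- function(norm, target_cells, reference_cells,
                                clip_limit = 3) {
  if (length(reference_cells) == 0L) stopf("reference cell set is empty")
  if (length(target_cells) == 0L) stopf("target cell set is empty")
  tgt <- resolve_cells(norm, target_cells)
  ref <- resolve_cells(norm, reference_cells)
  if (length(intersect(tgt, ref)) > 0L) {
    stopf("target and reference cell sets must be disjoint")
  }
  ref_mean <- Matrix::rowMeans(norm[, ref, drop = FALSE])
  centered <- as.matrix(norm[, tgt, drop = FALSE]) - ref_mean
  clamp(centered, -clip_limit, clip_limit)
}

resolve_cells <- function(m, cells) {
  if (is.character(cells)) {
    idx <- match(cells, colnames(m))
    if (anyNA(idx)) stopf("unknown cell id(s): %s",
                          paste(utils::head(cells[is.na(idx)], 3), collapse = ", "))
    idx
  } else as.integer(cells)
}

#' Sliding-window CNV profile (CNVi)
#'
#' Sorts genes by genomic location within each chromosome and averages the
#' centered relative expression over sliding windows of `window_size`
#' consecutive genes advancing by `window_step`; the i-th window's average is
#' the cell's CNVi. Windows never span chromosome boundaries; a chromosome
#' with fewer genes than `window_size` contributes a single whole-chromosome
#' window. Mitochondrial genes are excluded (the MT contig carries no
#' informative copy number signal).
#'
#' @param centered Genes x cells matrix from [relative_expression()].
#' @param gene_table Gene position table covering the matrix rows.
#' @param window_size,window_step Window geometry (defaults 100 / 1).
#' @param exclude_mito Drop `is_mito` genes before windowing (default TRUE).
#'
#' @return An object of class `"CnvProfile"`: list with `cnvi` (windows x
#'   cells matrix), `windows` (data.frame: chrom, first/last gene id and
#'   index), and `cells`.
#' @export
window_profile <- function(centered, gene_table, window_size = 100L,
                           window_step = 1L, exclude_mito = TRUE) {
  if (is.null(gene_table) || nrow(gene_table) == 0L) stopf("empty gene table")
  check_count(window_size, "window_size")
  check_count(window_step, "window_step")

  gt <- gene_table[gene_table$gene_id %in% rownames(centered), , drop = FALSE]
  if (exclude_mito && "is_mito" %in% names(gt)) gt <- gt[!gt$is_mito, , drop = FALSE]
  if (nrow(gt) == 0L) stopf("gene table covers no rows of the matrix")
  # gene_table row order is the genomic order (chrom, start)
  x <- centered[gt$gene_id, , drop = FALSE]

  chrom_rle <- rle(as.character(gt$chrom))
  offs <- cumsum(c(0L, chrom_rle$lengths))
  win_chrom <- character(); win_start <- integer(); win_end <- integer()
  cnvi_blocks <- vector("list", length(chrom_rle$values))
  for (ci in seq_along(chrom_rle$values)) {
    n <- chrom_rle$lengths[ci]
    rows <- offs[ci] + seq_len(n)
    if (n < window_size) {
      starts <- 1L; ends <- n
    } else {
      starts <- seq.int(1L, n - window_size + 1L, by = window_step)
      ends <- starts + window_size - 1L
    }
    block <- x[rows, , drop = FALSE]
    # each window is summed independently (plain column sums): windows that
    # are mathematically equal come out exactly equal, which matters for the
    # tie handling of the downstream Spearman ranks
    wmeans <- matrix(0, nrow = length(starts), ncol = ncol(block))
    for (wi in seq_along(starts)) {
      wmeans[wi, ] <- colSums(block[starts[wi]:ends[wi], , drop = FALSE]) /
        (ends[wi] - starts[wi] + 1L)
    }
    cnvi_blocks[[ci]] <- wmeans
    win_chrom <- c(win_chrom, rep(chrom_rle$values[ci], length(starts)))
    win_start <- c(win_start, offs[ci] + starts)
    win_end <- c(win_end, offs[ci] + ends)
  }
  cnvi <- do.call(rbind, cnvi_blocks)
  rownames(cnvi) <- sprintf("W%04d", seq_len(nrow(cnvi)))
  colnames(cnvi) <- colnames(centered)
  windows <- data.frame(window = rownames(cnvi), chrom = win_chrom,
                        first_gene = gt$gene_id[win_start],
                        last_gene = gt$gene_id[win_end],
                        n_genes = win_end - win_start + 1L,
                        stringsAsFactors = FALSE)
  structure(list(cnvi = cnvi, windows = windows, cells = colnames(centered)),
            class = "CnvProfile")
}

#' @export
print.CnvProfile <- function(x, ...) {
  cat(sprintf("CnvProfile: %d windows x %d cells over %d chromosomes\n",
              nrow(x$cnvi), ncol(x$cnvi), length(unique(x$windows$chrom))))
  invisible(x)
}

#' Per-cell CNV score
#'
#' The CNV score of a cell is the mean of its squared CNVi values across all
#' windows — a non-negative summary of how much inferred copy number signal
#' the cell carries.
#'
#' @param profile A `CnvProfile` (or a windows x cells CNVi matrix).
#' @return Named numeric vector of per-cell scores.
#' @export
cnv_score <- function(profile) {
  cnvi <- if (inherits(profile, "CnvProfile")) profile$cnvi else profile
  if (is.null(dim(cnvi)) || nrow(cnvi) < 1L) stopf("profile has no windows")
  colMeans(cnvi^2)
}

#' Per-cell CNV correlation against the top-score reference profile
#'
#' For each sample, the cells with the top `top_fraction` CNV scores (count =
#' `ceiling(top_fraction * n)`, minimum 1, exact-score ties broken by stable
#' input order) define a reference CNVi profile (window-wise mean). Each
#' cell's CNV correlation is the Spearman correlation between its CNVi vector
#' and its own sample's reference profile. Cells with a constant CNVi vector,
#' and all cells of samples smaller than `min_cells`, get `NA` (reported, not
#' called).
#'
#' @param profile A `CnvProfile`.
#' @param scores Per-cell CNV scores from [cnv_score()].
#' @param samples Per-cell sample labels (same order as profile cells).
#' @param top_fraction Fraction defining the reference set (default 0.03).
#' @param min_cells Minimum sample size to attempt correlation (default 10).
#'
#' @return Named numeric vector of per-cell Spearman correlations (NA where
#'   undefined).
#' @export
cnv_correlation <- function(profile, scores, samples, top_fraction = 0.03,
                            min_cells = 10L) {
  cnvi <- profile$cnvi
  n_cells <- ncol(cnvi)
  if (length(scores) != n_cells || length(samples) != n_cells) {
    stopf("`scores` and `samples` must match the profile's cells")
  }
  corr <- rep(NA_real_, n_cells)
  names(corr) <- colnames(cnvi)
  for (s in unique(samples)) {
    idx <- which(samples == s)
    if (length(idx) < min_cells) next
    k <- max(1L, ceiling(top_fraction * length(idx)))
    top <- idx[order(-scores[idx])[seq_len(k)]]  # stable order breaks ties
    ref <- rowMeans(cnvi[, top, drop = FALSE])
    if (stats::sd(ref) == 0) next
    sub <- cnvi[, idx, drop = FALSE]
    ok <- apply(sub, 2L, stats::sd) > 0
    if (any(ok)) {
      corr[idx[ok]] <- suppressWarnings(
        stats::cor(sub[, ok, drop = FALSE], ref, method = "spearman")[, 1L])
    }
  }
  corr
}

#' Threshold-based malignant cell call
#'
#' A cell is called malignant iff its CNV score is strictly above
#' `score_threshold` AND its CNV correlation is strictly above
#' `corr_threshold`. Cells with undefined correlation are called
#' non-malignant.
#'
#' @param scores,corrs Per-cell score and correlation vectors.
#' @param score_threshold,corr_threshold Call thresholds (defaults 0.04 / 0.5).
#' @return Logical vector of malignant calls.
#' @export
call_malignant <- function(scores, corrs, score_threshold = 0.04,
                           corr_threshold = 0.5) {
  call <- !is.na(corrs) & scores > score_threshold & corrs > corr_threshold
  names(call) <- names(scores)
  call
}

#' End-to-end inferred-CNV malignancy classification
#'
#' Runs the full classifier on a cohort: centers the normalized expression of
#' epithelial cells on the reference epithelial cells from non-tumor samples,
#' computes sliding-window CNVi profiles, CNV scores, per-sample top-fraction
#' Spearman correlations, and threshold calls. Reference-sample cells are
#' scored and correlated within their own sample but never contribute to a
#' tumor's reference profile.
#'
#' @param cohort A `CellCohort` that passed QC.
#' @param norm Normalized matrix from [normalize_counts()]; computed from the
#'   cohort counts when `NULL`.
#' @param params A [cnv_params()] object.
#' @param target_cell_type Metadata `cell_type` gating which cells are
#'   classified (default `"epithelial"`).
#'
#' @return A list of class `"cnv_result"`: `cells` (data.frame with cell_id,
#'   sample, tissue, cnv_score, cnv_corr, malignant), `profile` (the
#'   `CnvProfile`), and `summary` (per-sample cell and malignant counts).
#' @export
infer_malignant_cells <- function(cohort, norm = NULL, params = cnv_params(),
                                  target_cell_type = "epithelial") {
  meta <- cohort$cell_meta
  if (is.null(norm)) norm <- normalize_counts(cohort$counts)
  epi <- meta$cell_type == target_cell_type
  ref_cells <- meta$cell_id[epi & meta$tissue == "normal"]
  tgt_cells <- meta$cell_id[epi & meta$tissue != "normal"]
  if (length(ref_cells) == 0L) {
    stopf("no reference epithelial cells (normal tissue) available")
  }
  centered <- relative_expression(norm, tgt_cells, ref_cells,
                                  clip_limit = params$clip_limit)
  # score reference cells too (centered on the remaining reference cells is
  # unnecessary: they are reported against the same reference mean)
  centered_ref <- clamp(as.matrix(norm[, ref_cells, drop = FALSE]) -
                          Matrix::rowMeans(norm[, ref_cells, drop = FALSE]),
                        -params$clip_limit, params$clip_limit)
  all_centered <- cbind(centered, centered_ref)
  profile <- window_profile(all_centered, cohort$gene_table,
                            window_size = params$window_size,
                            window_step = params$window_step)
  scores <- cnv_score(profile)
  cell_samples <- meta$sample[match(colnames(all_centered), meta$cell_id)]
  corrs <- cnv_correlation(profile, scores, cell_samples,
                           top_fraction = params$top_fraction,
                           min_cells = params$min_cells)
  calls <- call_malignant(scores, corrs, params$score_threshold,
                          params$corr_threshold)

  cells <- data.frame(
    cell_id = colnames(all_centered),
    sample = cell_samples,
    tissue = meta$tissue[match(colnames(all_centered), meta$cell_id)],
    cnv_score = unname(scores),
    cnv_corr = unname(corrs),
    malignant = unname(calls),
    stringsAsFactors = FALSE
  )
  summary <- do.call(rbind, lapply(split(cells, cells$sample), function(d) {
    data.frame(sample = d$sample[1], n_cells = nrow(d),
               n_malignant = sum(d$malignant),
               frac_malignant = mean(d$malignant),
               called = nrow(d) >= params$min_cells,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(cells = cells, profile = profile, summary = summary,
                 params = params),
            class = "cnv_result")
}

#' @export
print.cnv_result <- function(x, ...) {
  cat(sprintf("cnv_result: %d cells, %d called malignant\n",
              nrow(x$cells), sum(x$cells$malignant)))
  print(x$summary)
  invisible(x)
}
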