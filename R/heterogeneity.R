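#' Cancer cell fraction (CCF) per mutation
#'
#' Maps each mutation's variant allele fraction to a cancer cell fraction
#' under the standard purity/copy-number model: the expected VAF of a
#' mutation present in a fraction f of tumor cells with multiplicity m is
#' \eqn{v(f) = f \cdot p \cdot m / (p \cdot CN_{tot} + 2 (1 - p))}, where p
#' is tumor purity and \eqn{CN_{tot}} the local total copy number. The point
#' estimate solves v(f) at the observed VAF and is clamped to `[0, 1.5]`; the
#' 95% interval maps the Clopper-Pearson binomial interval on the VAF
#' through the same formula. When `multiplicity` is absent it is estimated as
#' `max(1, round(VAF * (p*CNtot + 2(1-p)) / p))` capped at the major copy
#' number.
#'
#' @param mutations Data.frame with columns `ref_count`, `alt_count`,
#'   `purity`, `total_cn`, `major_cn` and optionally `multiplicity`.
#'
#' @return The input with columns `vaf`, `multiplicity`, `ccf`, `ccf_lower`,
#'   `ccf_upper` appended.
#' @export
compute_ccf <- function(mutations) {
  req <- c("ref_count", "alt_count", "purity", "total_cn", "major_cn")
  if (!all(req %in% names(mutations))) {
    stopf("`mutations` must have columns %s", paste(req, collapse = ", "))
  }
  if (any(mutations$purity <= 0)) stopf("purity must be > 0")
  depth <- mutations$ref_count + mutations$alt_count
  if (any(depth <= 0)) stopf("each mutation needs alt_count + ref_count > 0")

  vaf <- mutations$alt_count / depth
  denom <- mutations$purity * mutations$total_cn + (1 - mutations$purity) * 2
  m <- mutations$multiplicity %||%
    pmin(pmax(1, round(vaf * denom / mutations$purity)), mutations$major_cn)
  m <- pmax(1, m)

  to_ccf <- function(v) v * denom / (mutations$purity * m)
  # Clopper-Pearson 95% CI on the VAF
  lo <- stats::qbeta(0.025, mutations$alt_count, mutations$ref_count + 1)
  hi <- stats::qbeta(0.975, mutations$alt_count + 1, mutations$ref_count)
  out <- mutations
  out$vaf <- vaf
  out$multiplicity <- as.integer(m)
  out$ccf <- clamp(to_ccf(vaf), 0, 1.5)
  out$ccf_lower <- clamp(to_ccf(lo), 0, 1.5)
  out$ccf_upper <- clamp(to_ccf(hi), 0, 1.5)
  out
}

#' Clonality call per mutation
#'
#' A mutation is clonal iff the upper bound of its CCF 95% interval reaches 1
#' and its CCF point estimate exceeds `ccf_cutoff` (default 0.9); otherwise
#' subclonal.
#'
#' @param mutations Data.frame with `ccf` and `ccf_upper` (see
#'   [compute_ccf()]).
#' @param ccf_cutoff Point-estimate cutoff (default 0.9).
#' @return The input with a `clonality` column (`"clonal"`/`"subclonal"`).
#' @export
classify_clonality <- function(mutations, ccf_cutoff = 0.9) {
  if (!all(c("ccf", "ccf_upper") %in% names(mutations))) {
    stopf("run compute_ccf() first")
  }
  clonal <- mutations$ccf_upper >= 1 & mutations$ccf > ccf_cutoff
  mutations$clonality <- ifelse(clonal, "clonal", "subclonal")
  mutations
}

#' Genomic intratumor heterogeneity
#'
#' The proportion of a tumor's mutations classified subclonal.
#'
#' @param mutations Data.frame with a `clonality` column for one tumor.
#' @return A fraction in `[0, 1]`; `NA` for zero mutations (tumor excluded
#'   from comparisons).
#' @export
genomic_ith <- function(mutations) {
  if (nrow(mutations) == 0L) return(NA_real_)
  if (!"clonality" %in% names(mutations)) stopf("run classify_clonality() first")
  mean(mutations$clonality == "subclonal")
}

#' Transcriptomic intratumor heterogeneity
#'
#' Scores how dispersed a tumor's malignant cells are around their average
#' expression state: over the `n_top_genes` most variable genes in the
#' tumor's cells, the score is the mean over cells of one minus the Pearson
#' correlation between the cell and the tumor's mean expression vector.
#' Identical cells score 0; anti-correlated subpopulations push the score
#' toward 1.
#'
#' @param norm Normalized log-expression matrix (genes x cells).
#' @param cells Malignant cell ids/indices of one tumor (>= `min_cells`).
#' @param n_top_genes Number of most-variable genes used (default 1000).
#' @param min_cells Minimum number of cells (default 10); fewer is an error
#'   so the tumor can be excluded upstream with a warning.
#'
#' @return A single non-negative score.
#' @export
transcriptomic_ith <- function(norm, cells, n_top_genes = 1000L,
                               min_cells = 10L) {
  idx <- resolve_cells(norm, cells)
  if (length(idx) < min_cells) {
    stopf("transcriptomic ITH needs >= %d cells (got %d)", min_cells, length(idx))
  }
  sub <- as.matrix(norm[, idx, drop = FALSE])
  v <- apply(sub, 1L, stats::var)
  if (max(v) == 0) return(0)  # all cells identical
  top <- order(-v)[seq_len(min(n_top_genes, nrow(sub)))]
  m <- sub[top, , drop = FALSE]
  centroid <- rowMeans(m)
  r <- suppressWarnings(stats::cor(m, centroid)[, 1L])
  # constant cells over the top-variable genes carry no correlation signal;
  # they sit maximally far from the centroid in correlation terms
  r[is.na(r)] <- 0
  mean(1 - r)
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test between two groups of
#' per-tumor (or per-cell) values: exact when both groups have at most 20
#' observations and there are no ties, otherwise the normal approximation
#' with continuity and tie correction.
#'
#' @param x,y Numeric vectors for the two groups (both non-empty).
#' @return A list with `statistic` (W), `p_value`, `method`, `n` (group
#'   sizes), and group medians/quartiles.
#' @export
compare_groups <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 20L && length(y) <= 20L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  list(statistic = unname(wt$statistic),
       p_value = min(1, wt$p.value),
       method = if (exact) "exact" else "normal approximation",
       n = c(length(x), length(y)),
       quartiles_x = qs(x), quartiles_y = qs(y))
}

#' Per-tumor heterogeneity summary for a mutation table
#'
#' Runs [compute_ccf()] and [classify_clonality()] on a multi-tumor mutation
#' table and summarizes genomic ITH per tumor.
#'
#' @param mutations Mutation table with a `sample` column.
#' @param ccf_cutoff Clonality point-estimate cutoff (default 0.9).
#' @return A list with `mutations` (annotated table) and `per_tumor`
#'   (sample, n_mutations, n_subclonal, genomic_ith).
#' @export
summarize_genomic_ith <- function(mutations, ccf_cutoff = 0.9) {
  ann <- classify_clonality(compute_ccf(mutations), ccf_cutoff = ccf_cutoff)
  per_tumor <- do.call(rbind, lapply(split(ann, ann$sample), function(d) {
    data.frame(sample = d$sample[1], n_mutations = nrow(d),
               n_subclonal = sum(d$clonality == "subclonal"),
               genomic_ith = genomic_ith(d), stringsAsFactors = FALSE)
  }))
  rownames(per_tumor) <- NULL
  list(mutations = ann, per_tumor = per_tumor)
}
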