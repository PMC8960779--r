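#' Read gene signature sets from a TSV file
#'
#' Signature files are two-column TSVs (`signature`, `gene`), one gene per
#' row. The package ships editable default macrophage polarization lists
#' (pro_inflammatory, anti_inflammatory, m1_polarization, m2_polarization) in
#' `inst/extdata/macrophage_signatures.tsv`; users may substitute curated
#' lists of their own.
#'
#' @param path TSV path; defaults to the packaged macrophage polarization
#'   signatures.
#' @return A named list of duplicate-free gene-id vectors.
#' @export
read_signatures <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "macrophage_signatures.tsv",
                        package = "iccaSubtypes", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("signature", "gene") %in% names(tab))) {
    stopf("signature file needs columns 'signature' and 'gene'")
  }
  lapply(split(tab$gene, tab$signature), unique)
}

#' Per-cell gene-set signature score
#'
#' The score of a cell is the mean, over the signature genes, of the gene's
#' z-scored normalized expression, where the z-scoring is computed across the
#' scored cell set (genes with zero variance get z = 0). Scores therefore
#' average 0 over the scored cells by construction. Signature genes missing
#' from the matrix are dropped with a warning; a signature with no genes
#' present is an error.
#'
#' @param norm Normalized log-expression matrix (genes x cells).
#' @param cells Cell ids/indices to score (and to z-score across).
#' @param signature Character vector of gene ids (duplicates ignored).
#' @return Named numeric vector of per-cell scores.
#' @export
score_signature <- function(norm, cells, signature) {
  signature <- unique(signature)
  if (length(signature) == 0L) stopf("empty signature")
  idx <- resolve_cells(norm, cells)
  present <- signature[signature %in% rownames(norm)]
  if (length(present) == 0L) stopf("no signature genes present in the matrix")
  if (length(present) < length(signature)) {
    warning(sprintf("%d of %d signature genes absent from the matrix; dropped",
                    length(signature) - length(present), length(signature)),
            call. = FALSE)
  }
  m <- as.matrix(norm[present, idx, drop = FALSE])
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(sdv > 0, sdv, Inf)  # zero-variance genes -> z = 0
  scores <- colMeans(z)
  names(scores) <- colnames(m)
  scores
}

#' Compare signature scores between two cell subsets
#'
#' Two-sided Wilcoxon rank-sum comparison of per-cell scores between two
#' labeled subsets (e.g. two macrophage populations), reporting medians,
#' quartiles, the W statistic and p-value. All-ties degenerate inputs (zero
#' variance in both subsets) are reported as non-significant with a warning.
#'
#' @param scores Named per-cell score vector.
#' @param labels Factor/character of the same length with exactly two levels
#'   used; cells with other labels are ignored.
#' @param groups Optional length-2 character vector selecting and ordering
#'   the two labels to compare.
#' @return As [compare_groups()], plus the group labels.
#' @export
compare_subsets <- function(scores, labels, groups = NULL) {
  labels <- as.character(labels)
  if (is.null(groups)) groups <- unique(labels)[seq_len(2L)]
  if (length(groups) != 2L || anyNA(groups)) stopf("need exactly two groups")
  x <- scores[labels == groups[1]]
  y <- scores[labels == groups[2]]
  if (length(x) == 0L || length(y) == 0L) stopf("both subsets must be non-empty")
  if (stats::sd(c(x, y)) == 0) {
    warning("all scores identical in both subsets; comparison is degenerate",
            call. = FALSE)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate (all ties)", n = c(length(x), length(y)),
                groups = groups,
                quartiles_x = rep(x[1], 3), quartiles_y = rep(y[1], 3)))
  }
  out <- compare_groups(x, y)
  out$groups <- groups
  out
}
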