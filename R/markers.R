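#' Fraction of cells positive for a gene
#'
#' A cell is positive when its raw count reaches `min_count` (default 1), a
#' dropout-aware, scale-free positivity rule.
#'
#' @param counts Genes x cells count matrix (sparse or dense), or a
#'   `CellCohort`.
#' @param gene Gene id (row name).
#' @param cells Cell ids or indices; must be non-empty.
#' @param min_count Positivity threshold on raw counts (default 1).
#' @return A single fraction in `[0, 1]`.
#' @export
positive_fraction <- function(counts, gene, cells, min_count = 1) {
  if (inherits(counts, "CellCohort")) counts <- counts$counts
  if (length(cells) == 0L) stopf("`cells` must be non-empty")
  if (!gene %in% rownames(counts)) stopf("gene '%s' not in matrix", gene)
  idx <- resolve_cells(counts, cells)
  x <- counts[gene, idx]
  mean(x >= min_count)
}

#' Mutual-exclusivity marker screen
#'
#' Splits the malignant cells into seed-marker-positive and seed-negative
#' subsets and, for every gene, computes the fraction of positive cells in
#' each subset. Candidate markers for the seed-negative subtype are genes
#' rarely expressed among seed-positive cells (`frac_pos_seedpos <=
#' max_pos_seedpos`) yet extensively expressed among seed-negative cells
#' (`frac_pos_seedneg >= min_pos_seedneg`). Genes are ranked by
#' `frac_pos_seedneg - frac_pos_seedpos`, descending, ties broken by gene id.
#'
#' @param counts Genes x cells count matrix or `CellCohort`.
#' @param seed_gene Seed marker gene id defining the partition.
#' @param malignant_cells Cell ids/indices of malignant cells.
#' @param min_pos_seedneg Candidate threshold on the seed-negative fraction
#'   (default 0.5).
#' @param max_pos_seedpos Candidate threshold on the seed-positive fraction
#'   (default 0.2).
#' @param min_count Positivity rule (default raw count >= 1).
#'
#' @return A data.frame (gene, frac_pos_seedpos, frac_pos_seedneg, delta,
#'   candidate, exclusivity_rank) sorted by rank; candidates first.
#' @export
exclusivity_screen <- function(counts, seed_gene, malignant_cells,
                               min_pos_seedneg = 0.5, max_pos_seedpos = 0.2,
                               min_count = 1) {
  if (inherits(counts, "CellCohort")) counts <- counts$counts
  idx <- resolve_cells(counts, malignant_cells)
  if (!seed_gene %in% rownames(counts)) stopf("seed gene '%s' not in matrix", seed_gene)
  seed_pos <- counts[seed_gene, idx] >= min_count
  if (all(seed_pos) || !any(seed_pos)) {
    stopf("seed gene '%s' splits the malignant cells degenerately (all %s)",
          seed_gene, if (all(seed_pos)) "positive" else "negative")
  }
  pos <- counts[, idx, drop = FALSE] >= min_count
  frac_pos <- Matrix::rowMeans(pos[, seed_pos, drop = FALSE])
  frac_neg <- Matrix::rowMeans(pos[, !seed_pos, drop = FALSE])
  delta <- frac_neg - frac_pos
  out <- data.frame(gene = rownames(counts),
                    frac_pos_seedpos = unname(frac_pos),
                    frac_pos_seedneg = unname(frac_neg),
                    delta = unname(delta),
                    candidate = unname(frac_pos <= max_pos_seedpos &
                                         frac_neg >= min_pos_seedneg),
                    stringsAsFactors = FALSE)
  ord <- order(-out$delta, out$gene)
  out <- out[ord, , drop = FALSE]
  out$exclusivity_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Four-way two-marker classification of malignant cells
#'
#' Assigns every malignant cell to one of four classes by its positivity for
#' two markers (A+B-, A-B+, A-B-, A+B+, labeled with the marker names) and
#' tabulates global and per-tumor class proportions.
#'
#' @param counts Genes x cells count matrix or `CellCohort`.
#' @param markerA,markerB Marker gene ids.
#' @param malignant_cells Cell ids/indices of the malignant cells.
#' @param samples Per-cell sample labels aligned with `malignant_cells`;
#'   taken from the cohort metadata when `counts` is a `CellCohort` and
#'   `samples` is NULL.
#' @param min_count Positivity rule (default raw count >= 1).
#'
#' @return A list of class `"marker_calls"`: `cells` (cell_id, sample, posA,
#'   posB, class), `global` (named class proportions), `per_tumor` (class
#'   proportion matrix, rows = tumors), and the marker names.
#' @export
classify_cells_two_markers <- function(counts, markerA, markerB,
                                       malignant_cells, samples = NULL,
                                       min_count = 1) {
  if (inherits(counts, "CellCohort")) {
    if (is.null(samples)) {
      samples <- counts$cell_meta$sample[match(malignant_cells,
                                               counts$cell_meta$cell_id)]
    }
    counts <- counts$counts
  }
  for (g in c(markerA, markerB)) {
    if (!g %in% rownames(counts)) stopf("marker '%s' not in matrix", g)
  }
  idx <- resolve_cells(counts, malignant_cells)
  if (is.null(samples)) samples <- rep("all", length(idx))
  posA <- counts[markerA, idx] >= min_count
  posB <- counts[markerB, idx] >= min_count
  lv <- c(paste0(markerA, "+", markerB, "-"), paste0(markerA, "-", markerB, "+"),
          paste0(markerA, "-", markerB, "-"), paste0(markerA, "+", markerB, "+"))
  cls <- ifelse(posA & !posB, lv[1],
                ifelse(!posA & posB, lv[2], ifelse(!posA & !posB, lv[3], lv[4])))
  cls <- factor(cls, levels = lv)
  cells <- data.frame(cell_id = colnames(counts)[idx], sample = samples,
                      posA = unname(posA), posB = unname(posB),
                      class = cls, stringsAsFactors = FALSE)
  global <- prop.table(table(cells$class))
  per_tumor <- prop.table(table(cells$sample, cells$class), margin = 1L)
  structure(list(cells = cells, global = global,
                 per_tumor = as.matrix(per_tumor),
                 markers = c(A = markerA, B = markerB)),
            class = "marker_calls")
}

#' @export
print.marker_calls <- function(x, ...) {
  cat(sprintf("marker_calls: %d cells, markers %s / %s\n",
              nrow(x$cells), x$markers["A"], x$markers["B"]))
  print(round(x$global, 4))
  invisible(x)
}

#' Tumor-level subtype assignment from marker class proportions
#'
#' A tumor is labeled with a concordant class (A+B-, the perihilar-like
#' subtype, or A-B+, the peripheral-small-duct-like subtype) when that
#' class's cell proportion strictly exceeds `dominance_threshold`; otherwise
#' it is reported as `"ambiguous"` rather than forced.
#'
#' @param calls A `"marker_calls"` object from
#'   [classify_cells_two_markers()].
#' @param dominance_threshold Proportion a concordant class must exceed
#'   (default 0.5).
#'
#' @return A data.frame (sample, subtype, prop_A, prop_B) where `subtype` is
#'   the dominant concordant class label or `"ambiguous"`.
#' @export
assign_tumor_subtype <- function(calls, dominance_threshold = 0.5) {
  pt <- calls$per_tumor
  lv <- colnames(pt)
  propA <- pt[, 1L]
  propB <- pt[, 2L]
  subtype <- ifelse(propA > dominance_threshold, lv[1L],
                    ifelse(propB > dominance_threshold, lv[2L], "ambiguous"))
  data.frame(sample = rownames(pt), subtype = unname(subtype),
             prop_concordant_A = unname(propA), prop_concordant_B = unname(propB),
             stringsAsFactors = FALSE)
}
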