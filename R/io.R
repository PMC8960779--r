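#' Write a cohort as a 10x-style MTX triplet plus metadata
#'
#' Writes `matrix.mtx` (MatrixMarket sparse counts, genes x cells),
#' `features.tsv` (gene_id, gene_id, "Gene Expression"), `barcodes.tsv`, a
#' cell-metadata TSV (including any `truth_` columns), and a BED-like gene
#' position table (chrom, start, end, gene_id, is_mito; 0-based half-open).
#' All files are uncompressed text.
#'
#' @param cohort A `CellCohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_10x_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(cohort$counts, mtx)
  feat <- data.frame(id = rownames(cohort$counts), name = rownames(cohort$counts),
                     type = "Gene Expression")
  utils::write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(cohort$counts), file.path(dir, "barcodes.tsv"))
  write_tsv(cohort$cell_meta, file.path(dir, "cell_metadata.tsv"))
  bed <- cohort$gene_table[, c("chrom", "start", "end", "gene_id", "is_mito")]
  write_tsv(bed, file.path(dir, "gene_positions.tsv"))
  invisible(file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                             "cell_metadata.tsv", "gene_positions.tsv")))
}

#' Read a cohort written by [write_10x_cohort()]
#'
#' @param dir Directory holding the triplet and metadata files.
#' @return A `CellCohort` (without simulation config or marker program).
#' @export
read_10x_cohort <- function(dir) {
  counts <- methods::as(methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                                    "generalMatrix"), "CsparseMatrix")
  features <- utils::read.delim(file.path(dir, "features.tsv"), header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(features[[1]], barcodes)
  meta <- utils::read.delim(file.path(dir, "cell_metadata.tsv"),
                            stringsAsFactors = FALSE)
  bed <- utils::read.delim(file.path(dir, "gene_positions.tsv"),
                           stringsAsFactors = FALSE)
  gene_table <- bed[, c("gene_id", "chrom", "start", "end", "is_mito")]
  structure(list(counts = counts, cell_meta = meta, gene_table = gene_table),
            class = "CellCohort")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' Records the package version, global seed, stage parameters and an
#' md5 hash per output file, as deterministic JSON (no wall-clock fields, so
#' identical runs produce byte-identical manifests).
#'
#' @param path Manifest path.
#' @param seed Global seed of the run.
#' @param params Named list of stage parameters.
#' @param files Character vector of output file paths (hashed relative to
#'   their basename).
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, seed, params, files) {
  files <- files[file.exists(files)]
  hashes <- tools::md5sum(files)
  names(hashes) <- basename(files)
  manifest <- list(
    tool = "iccaSubtypes",
    version = as.character(utils::packageVersion("iccaSubtypes")),
    seed = as.integer(seed),
    parameters = params,
    files = as.list(hashes)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
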