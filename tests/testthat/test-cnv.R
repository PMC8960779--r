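test_that("relative expression centers, clips, and validates its inputs", {
  # 6-gene, 4-cell toy: two reference cells, two targets, hand-computed
  vals <- matrix(c(1, 2, 0, 4, 5, 9,
                   3, 2, 2, 4, 1, 9,
                   2, 0, 1, 8, 3, 0,
                   6, 2, 1, 0, 3, 9), nrow = 6,
                 dimnames = list(paste0("g", 1:6), paste0("c", 1:4)))
  m <- Matrix::Matrix(vals, sparse = TRUE)
  centered <- relative_expression(m, c("c3", "c4"), c("c1", "c2"), clip_limit = 3)
  ref_mean <- (vals[, 1] + vals[, 2]) / 2
  hand <- pmin(pmax(vals[, 3:4] - ref_mean, -3), 3)
  expect_equal(centered, hand, tolerance = 1e-12)
  # value 10 against reference mean 4 clips at +3
  m2 <- Matrix::Matrix(matrix(c(4, 4, 10), 1, dimnames = list("g", c("r1", "r2", "t"))),
                       sparse = TRUE)
  expect_equal(unname(relative_expression(m2, "t", c("r1", "r2"), 3)[1, 1]), 3)

  expect_error(relative_expression(m, "c1", character()), "empty")
  expect_error(relative_expression(m, c("c1", "c2"), c("c2", "c3")), "disjoint")
})

test_that("centering a sample of the reference distribution gives near-zero means", {
  set.seed(11)
  m <- matrix(rpois(200 * 100, 5), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("c%03d", 1:100)))
  norm <- normalize_counts(Matrix::Matrix(m, sparse = TRUE))
  centered <- relative_expression(norm, 1:50, 51:100, clip_limit = 3)
  # target mean minus reference mean: SE = sd * sqrt(1/50 + 1/50); with 200
  # genes a 4.5-SE band holds with overwhelming probability
  se <- apply(as.matrix(norm), 1, sd) * sqrt(2 / 50)
  expect_true(all(abs(rowMeans(centered)) < 4.5 * pmax(se, 1e-8) + 1e-8))
})

test_that("window profiles follow the sliding-window contract", {
  gt <- data.frame(gene_id = paste0("g", 1:5), chrom = "chr1",
                   start = 1:5 * 100, end = 1:5 * 100 + 50, is_mito = FALSE)
  m <- matrix(c(1, 2, 3, 4, 5), ncol = 1, dimnames = list(gt$gene_id, "c1"))
  prof <- window_profile(m, gt, window_size = 3, window_step = 1)
  expect_equal(unname(prof$cnvi[, 1]), c(2, 3, 4))
  expect_equal(unname(prof$cnvi[, 1]),
               oracle_windowed_means(m[, 1], gt$chrom, 3, 1))

  # constant input: one chromosome, 300 genes, all values c -> 201 equal windows
  gt2 <- data.frame(gene_id = sprintf("g%03d", 1:300), chrom = "chr1",
                    start = 1:300, end = 1:300, is_mito = FALSE)
  m2 <- matrix(0.7, nrow = 300, ncol = 2, dimnames = list(gt2$gene_id, c("a", "b")))
  prof2 <- window_profile(m2, gt2, window_size = 100)
  expect_equal(nrow(prof2$cnvi), 201L)
  expect_true(all(abs(prof2$cnvi - 0.7) < 1e-12))

  # windows never span chromosome boundaries
  gt3 <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    chrom = rep(c("chr1", "chr2"), each = 100),
                    start = rep(1:100, 2), end = rep(1:100, 2) + 1, is_mito = FALSE)
  m3 <- matrix(rnorm(400), nrow = 200, dimnames = list(gt3$gene_id, c("a", "b")))
  prof3 <- window_profile(m3, gt3, window_size = 100)
  expect_equal(nrow(prof3$cnvi), 2L)
  expect_equal(prof3$windows$chrom, c("chr1", "chr2"))

  # a chromosome shorter than the window yields one whole-chromosome window
  gt4 <- data.frame(gene_id = sprintf("g%03d", 1:130),
                    chrom = rep(c("chr1", "chr2"), c(100, 30)),
                    start = c(1:100, 1:30), end = c(1:100, 1:30) + 1, is_mito = FALSE)
  prof4 <- window_profile(m3[1:130, , drop = FALSE], gt4, window_size = 100)
  expect_equal(prof4$windows$n_genes, c(100L, 30L))

  expect_error(window_profile(m3, gt3[0, ]), "empty")
})

test_that("CNV scores equal the mean of squared window values", {
  expect_equal(unname(cnv_score(matrix(0, 3, 1))), 0)
  expect_equal(unname(cnv_score(matrix(c(0.1, -0.1, 0.2), 3, 1))), 0.02)

  set.seed(4)
  cnvi <- matrix(rnorm(40 * 50, sd = 0.2), nrow = 40,
                 dimnames = list(NULL, sprintf("c%02d", 1:50)))
  scores <- cnv_score(cnvi)
  brute <- vapply(seq_len(50), function(j) oracle_cnv_score(cnvi[, j]), 0)
  expect_equal(unname(scores), brute, tolerance = 1e-12)

  # quadratic scaling: k * CNVi -> k^2 * score
  expect_equal(unname(cnv_score(3 * cnvi)), 9 * unname(cnv_score(cnvi)),
               tolerance = 1e-12)
})

test_that("CNV correlation matches a rank-then-Pearson oracle", {
  set.seed(6)
  base <- rnorm(30)
  cnvi <- sapply(1:20, function(i) base * runif(1, 0.5, 2) + rnorm(30, sd = 0.3))
  colnames(cnvi) <- sprintf("c%02d", 1:20)
  prof <- structure(list(cnvi = cnvi), class = "CnvProfile")
  scores <- cnv_score(cnvi)
  samples <- rep("T1", 20)
  corr <- cnv_correlation(prof, scores, samples, top_fraction = 0.1, min_cells = 5)

  k <- ceiling(0.1 * 20)
  top <- order(-scores)[seq_len(k)]
  ref <- rowMeans(cnvi[, top, drop = FALSE])
  for (j in c(1, 7, 20)) {
    expect_equal(unname(corr[j]), oracle_spearman(cnvi[, j], ref), tolerance = 1e-12)
  }

  # Spearman is invariant to strictly increasing transforms of a cell's CNVi
  warped <- cnvi
  warped[, 3] <- exp(cnvi[, 3])
  prof_w <- structure(list(cnvi = warped), class = "CnvProfile")
  corr_w <- cnv_correlation(prof_w, scores, samples, top_fraction = 0.1, min_cells = 5)
  if (!3 %in% top) expect_equal(unname(corr_w[3]), unname(corr[3]), tolerance = 1e-12)
})

test_that("correlation edge cases: self-profile, negation, constant cells", {
  v <- c(1, -2, 3, -1, 2, 0.5, -0.3, 1.2, -0.8, 0.1)
  # all top cells share one profile: a top cell correlates at exactly 1
  cnvi <- cbind(a = v, b = v, c = -v, d = rep(0.5, 10))
  scores <- cnv_score(cnvi)
  corr <- cnv_correlation(structure(list(cnvi = cnvi), class = "CnvProfile"),
                          scores, rep("T1", 4), top_fraction = 0.5, min_cells = 2)
  expect_equal(unname(corr["a"]), 1)
  expect_equal(unname(corr["c"]), -1)
  expect_true(is.na(corr["d"]))  # zero-variance CNVi vector
  # and a constant cell is never called malignant
  expect_false(call_malignant(scores, corr)["d"])
})

test_that("malignancy thresholds are strict conjunctions", {
  expect_true(call_malignant(0.05, 0.6))
  expect_false(call_malignant(0.04, 0.9))   # strictly above required
  expect_false(call_malignant(0.10, 0.4))
  expect_false(call_malignant(0.05, 0.5))
})

test_that("the pipeline is equivariant to cell permutation", {
  co <- generate_sc_cohort(quick_config(seed = 13, cells_per_sample = 50L))
  res <- infer_malignant_cells(co, params = cnv_params(window_size = 50, min_cells = 5))

  perm <- rev(seq_len(ncol(co$counts)))
  shuffled <- co
  shuffled$counts <- co$counts[, perm]
  shuffled$cell_meta <- co$cell_meta[perm, ]
  res2 <- infer_malignant_cells(shuffled,
                                params = cnv_params(window_size = 50, min_cells = 5))
  ord <- match(res$cells$cell_id, res2$cells$cell_id)
  expect_equal(res$cells$cnv_score, res2$cells$cnv_score[ord], tolerance = 1e-12)
  expect_equal(res$cells$cnv_corr, res2$cells$cnv_corr[ord], tolerance = 1e-12)
  expect_equal(res$cells$malignant, res2$cells$malignant[ord])
})

test_that("every intermediate matches a straight-line brute-force run (<=50 cells)", {
  co <- generate_sc_cohort(sim_config(n_tumors_per_subtype = 1L, n_ref_samples = 1L,
                                      cells_per_sample = 15L, n_genes = 200L,
                                      n_chromosomes = 2L, seed = 77))
  norm <- normalize_counts(co$counts)
  meta <- co$cell_meta
  params <- cnv_params(window_size = 30, min_cells = 5)
  res <- infer_malignant_cells(co, norm, params)

  # brute force: loops only
  nm <- as.matrix(norm)
  ref_cells <- meta$cell_id[meta$tissue == "normal"]
  tgt_cells <- meta$cell_id[meta$tissue == "tumor"]
  ref_mean <- rowMeans(nm[, ref_cells])
  centered <- cbind(nm[, tgt_cells] - ref_mean, nm[, ref_cells] - ref_mean)
  centered <- pmin(pmax(centered, -3), 3)
  keep <- !co$gene_table$is_mito
  gt <- co$gene_table[keep, ]
  centered <- centered[gt$gene_id, ]

  cells <- colnames(centered)
  cnvi <- sapply(cells, function(cl)
    oracle_windowed_means(centered[, cl], gt$chrom, 30, 1))
  scores <- vapply(cells, function(cl) oracle_cnv_score(cnvi[, cl]), 0)
  expect_equal(unname(scores[res$cells$cell_id]), res$cells$cnv_score,
               tolerance = 1e-9)

  samples <- meta$sample[match(cells, meta$cell_id)]
  for (s in unique(samples)) {
    idx <- which(samples == s)
    k <- max(1, ceiling(0.03 * length(idx)))
    top <- idx[order(-scores[idx])[seq_len(k)]]
    ref <- rowMeans(cnvi[, top, drop = FALSE])
    for (j in idx) {
      expected <- oracle_spearman(cnvi[, j], ref)
      got <- res$cells$cnv_corr[match(cells[j], res$cells$cell_id)]
      expect_equal(got, expected, tolerance = 1e-9)
    }
  }
})

test_that("caller recovers planted malignancy on the default study conditions", {
  co <- generate_sc_cohort(sim_config(seed = 101))
  res <- infer_malignant_cells(co)
  truth <- co$cell_meta$truth_malignant[match(res$cells$cell_id,
                                              co$cell_meta$cell_id)]
  expect_gte(mean(res$cells$malignant[truth]), 0.95)   # sensitivity
  expect_gte(mean(!res$cells$malignant[!truth]), 0.95) # specificity
})
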