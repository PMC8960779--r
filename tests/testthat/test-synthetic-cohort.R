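test_that("gene table has the forced layout, ordering, and MT contig", {
  gt <- generate_gene_table(300, 3, seed = 1)
  expect_equal(as.integer(table(gt$chrom)[paste0("chr", 1:3)]), rep(100L, 3))
  expect_equal(sum(gt$is_mito), 13L)
  expect_true(all(gt$chrom[gt$is_mito] == "MT"))
  # strictly increasing, non-overlapping within each chromosome
  for (ch in unique(gt$chrom)) {
    g <- gt[gt$chrom == ch, ]
    expect_true(all(diff(g$start) > 0))
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    expect_true(all(g$end > g$start))
  }
  # global order is (chromosome, start)
  expect_equal(gt$gene_id, gt$gene_id[order(match(gt$chrom, unique(gt$chrom)), gt$start)])
})

test_that("gene table handles the degenerate single-gene case and bad input", {
  gt <- generate_gene_table(1, 1, seed = 0, n_mito = 0)
  expect_equal(nrow(gt), 1L)
  expect_error(generate_gene_table(0, 1), "n_genes")
  expect_error(generate_gene_table(5, 10), ">=")
})

test_that("gene table is byte-identical under a fixed seed", {
  expect_identical(generate_gene_table(300, 3, seed = 1),
                   generate_gene_table(300, 3, seed = 1))
  expect_false(identical(generate_gene_table(300, 3, seed = 1),
                         generate_gene_table(300, 3, seed = 2)))
})

test_that("sc cohort is deterministic and respects truth-label invariants", {
  cfg <- quick_config(seed = 42)
  a <- generate_sc_cohort(cfg)
  b <- generate_sc_cohort(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$cell_meta, b$cell_meta)

  meta <- a$cell_meta
  # malignant cells only in tumor tissue; programs only on malignant cells
  expect_true(all(meta$tissue[meta$truth_malignant] == "tumor"))
  expect_true(all(meta$truth_program[!meta$truth_malignant] == "none"))
  expect_true(all(meta$truth_program[meta$truth_malignant] %in% c("phl", "pps")))
  # mutual exclusivity: program equals the sample subtype, never both
  mal <- meta[meta$truth_malignant, ]
  expect_true(all(mal$truth_program == mal$truth_subtype))
  # counts are non-negative integers
  expect_true(all(a$counts@x >= 0))
  expect_true(all(a$counts@x == floor(a$counts@x)))
})

test_that("per-cell UMI totals and mito fractions track the configuration", {
  cfg <- quick_config(seed = 3, cells_per_sample = 150L)
  co <- generate_sc_cohort(cfg)
  totals <- Matrix::colSums(co$counts)
  expect_lt(abs(mean(totals) / cfg$libsize_mean - 1), 0.10)
  mito <- Matrix::colSums(co$counts[co$gene_table$is_mito, ]) / totals
  rng <- cfg$mito_fraction_range
  # realized fractions carry count-level sampling noise (sd ~ 0.01) around
  # the per-cell expectation drawn from the configured range
  expect_true(all(mito > rng[1] - 0.06 & mito < rng[2] + 0.06))
  expect_gt(mean(mito > rng[1] - 0.02 & mito < rng[2] + 0.02), 0.95)
  expect_true(mean(mito) > rng[1] && mean(mito) < rng[2])
})

test_that("zero CNV shift leaves malignant and normal expression exchangeable", {
  cfg <- quick_config(seed = 5, cells_per_sample = 120L)
  cfg$cnv_segments$shift <- 0
  co <- generate_sc_cohort(cfg)
  meta <- co$cell_meta
  seg_genes <- setdiff(rownames(co$counts)[!co$gene_table$is_mito],
                       c(co$marker_program$seed_marker, co$marker_program$alt_marker,
                         co$marker_program$program_a, co$marker_program$program_b))
  # normalize within the compared gene set so neither per-cell depth nor the
  # marker-program contribution to the totals enters the contrast
  sub <- as.matrix(co$counts[seg_genes, ])
  frac <- t(t(sub) / colSums(sub))
  mal_mean <- rowMeans(frac[, meta$truth_malignant])
  nor_mean <- rowMeans(frac[, !meta$truth_malignant])
  expect_lt(abs(mean(mal_mean) / mean(nor_mean) - 1), 0.02)
})

test_that("unknown marker genes are rejected", {
  cfg <- quick_config(marker_program = list(seed_marker = "NOT_A_GENE",
                                            alt_marker = "G00002"))
  expect_error(generate_sc_cohort(cfg), "absent")
  expect_error(quick_config(marker_program = list(seed_marker = "G00001",
                                                  alt_marker = "G00001")),
               "distinct")
})

test_that("bulk cohort honors the planted mixture and is deterministic", {
  b1 <- generate_bulk_cohort(100, c(0.5, 0.3, 0.1, 0.1), seed = 9)
  b2 <- generate_bulk_cohort(100, c(0.5, 0.3, 0.1, 0.1), seed = 9)
  expect_identical(b1, b2)
  expect_equal(as.integer(table(b1$truth$class)[unique(b1$truth$class)]),
               c(50L, 30L, 10L, 10L))

  one <- generate_bulk_cohort(10, c(1, 0, 0, 0), seed = 1)
  expect_true(all(one$truth$class == "S100P+SPP1-"))
  expect_error(generate_bulk_cohort(3, c(1, 0, 0, 0)), "n_samples")
  expect_error(generate_bulk_cohort(10, c(0.5, 0.4, 0, 0)), "summing")
})

test_that("mutation tables encode the purity/CCF model correctly", {
  # all-clonal limit: genomic ITH vanishes up to the CI-rule's finite-depth
  # miss rate (a clonal site ~2 binomial SDs below VAF 0.5 can fail the
  # CI-reaches-1 requirement)
  mt <- generate_mutation_table(100, clonal_fraction = 1, purity = 1,
                                depth_mean = 800, seed = 2)
  ann <- classify_clonality(compute_ccf(mt$mutations))
  expect_lte(genomic_ith(ann), 0.05)

  # halving purity halves the expected VAF at diploid sites
  hi <- generate_mutation_table(2000, clonal_fraction = 1, purity = 1,
                                depth_mean = 500, seed = 3)
  lo <- generate_mutation_table(2000, clonal_fraction = 1, purity = 0.5,
                                depth_mean = 500, seed = 3)
  vaf <- function(m) mean(m$mutations$alt_count /
                            (m$mutations$alt_count + m$mutations$ref_count))
  expect_lt(abs(vaf(lo) / vaf(hi) - 0.5), 0.02)

  expect_error(generate_mutation_table(10, depth_mean = 0), "depth_mean")
})
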