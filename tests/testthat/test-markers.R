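make_counts <- function(m) {
  Matrix::Matrix(m, sparse = TRUE)
}

test_that("positive fractions count cells at the raw-count rule", {
  m <- make_counts(matrix(c(0, 1, 0, 2,
                            0, 0, 0, 0), nrow = 2, byrow = TRUE,
                          dimnames = list(c("gA", "gB"), paste0("c", 1:4))))
  expect_equal(positive_fraction(m, "gA", paste0("c", 1:4)), 0.5)
  expect_equal(positive_fraction(m, "gB", paste0("c", 1:4)), 0)
  expect_equal(positive_fraction(m, "gA", paste0("c", 1:4), min_count = 2), 0.25)
  expect_error(positive_fraction(m, "gA", character()), "non-empty")
  expect_error(positive_fraction(m, "nope", "c1"), "not in matrix")

  # planted expressing cells recovered exactly
  set.seed(21)
  planted <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  mm <- make_counts(matrix(as.numeric(planted), nrow = 1,
                           dimnames = list("g", sprintf("c%03d", 1:100))))
  expect_equal(positive_fraction(mm, "g", sprintf("c%03d", 1:100)),
               oracle_positive_fraction(as.numeric(planted)))
})

test_that("positive fractions are monotone in the threshold and mixture-consistent", {
  set.seed(31)
  m <- make_counts(matrix(rpois(300, 1.5), nrow = 3,
                          dimnames = list(c("g1", "g2", "g3"),
                                          sprintf("c%03d", 1:100))))
  cells <- sprintf("c%03d", 1:100)
  for (g in rownames(m)) {
    f <- vapply(1:4, function(k) positive_fraction(m, g, cells, min_count = k), 0)
    expect_true(all(diff(f) <= 0))
  }
  # union fraction is the cell-count-weighted mean of partition fractions
  part1 <- cells[1:30]; part2 <- cells[31:100]
  f_all <- positive_fraction(m, "g1", cells)
  f1 <- positive_fraction(m, "g1", part1)
  f2 <- positive_fraction(m, "g1", part2)
  expect_equal(f_all, (30 * f1 + 70 * f2) / 100, tolerance = 1e-12)
})

test_that("exclusivity screen ranks a planted mutually exclusive gene first", {
  co <- generate_sc_cohort(quick_config(seed = 17, n_genes = 1200L,
                                        cells_per_sample = 150L))
  mal <- co$cell_meta$cell_id[co$cell_meta$truth_malignant]
  screen <- exclusivity_screen(co, co$marker_program$seed_marker, mal)
  expect_equal(screen$gene[1], co$marker_program$alt_marker)
  expect_true(screen$candidate[1])
  # the seed gene defines the partition: positive fraction 1 in seed-positive
  seed_row <- screen[screen$gene == co$marker_program$seed_marker, ]
  expect_equal(seed_row$frac_pos_seedpos, 1)
  expect_false(seed_row$candidate)
})

test_that("exclusivity screen is invariant to gene order and rejects degenerate seeds", {
  co <- generate_sc_cohort(quick_config(seed = 19))
  mal <- co$cell_meta$cell_id[co$cell_meta$truth_malignant]
  s1 <- exclusivity_screen(co$counts, co$marker_program$seed_marker, mal)
  perm <- sample(nrow(co$counts))
  s2 <- exclusivity_screen(co$counts[perm, ], co$marker_program$seed_marker, mal)
  expect_equal(s1, s2)

  allpos <- make_counts(matrix(5, 2, 10, dimnames = list(c("s", "g"),
                                                         paste0("c", 1:10))))
  expect_error(exclusivity_screen(allpos, "s", paste0("c", 1:10)), "degenerate")
})

test_that("four-way classification enumerates the marker combinations", {
  m <- make_counts(matrix(c(3, 0, 0, 2,
                            0, 4, 0, 1), nrow = 2, byrow = TRUE,
                          dimnames = list(c("A", "B"), paste0("c", 1:4))))
  mc <- classify_cells_two_markers(m, "A", "B", paste0("c", 1:4))
  expect_equal(as.character(mc$cells$class),
               c("A+B-", "A-B+", "A-B-", "A+B+"))
  expect_equal(unname(as.numeric(mc$global)), rep(0.25, 4))
  expect_equal(sum(mc$global), 1, tolerance = 1e-9)
})

test_that("synthetic cohorts are classified concordantly with planted programs", {
  co <- generate_sc_cohort(quick_config(seed = 23, cells_per_sample = 200L))
  meta <- co$cell_meta
  mal <- meta$cell_id[meta$truth_malignant]
  mp <- co$marker_program
  mc <- classify_cells_two_markers(co, mp$seed_marker, mp$alt_marker, mal)
  lv <- levels(mc$cells$class)
  # discordant classes are bounded by the dropout-driven miss rates
  discordant <- mean(mc$cells$class %in% lv[3:4])
  expect_lt(discordant, 3 * co$config$dropout_rate + 0.05)
  # cells in concordant classes recover the planted program
  truth <- meta$truth_program[match(mc$cells$cell_id, meta$cell_id)]
  conc <- mc$cells$class %in% lv[1:2]
  predicted <- ifelse(mc$cells$class == lv[1], "phl", "pps")
  expect_gte(mean(predicted[conc] == truth[conc]), 0.95)
})

test_that("tumor subtype assignment follows class dominance", {
  co <- generate_sc_cohort(quick_config(seed = 29, cells_per_sample = 150L))
  meta <- co$cell_meta
  mal <- meta$cell_id[meta$truth_malignant]
  mp <- co$marker_program
  mc <- classify_cells_two_markers(co, mp$seed_marker, mp$alt_marker, mal)
  subtypes <- assign_tumor_subtype(mc)
  truth_map <- unique(meta[meta$tissue == "tumor", c("sample", "truth_subtype")])
  expected <- ifelse(truth_map$truth_subtype[match(subtypes$sample,
                                                   truth_map$sample)] == "phl",
                     levels(mc$cells$class)[1], levels(mc$cells$class)[2])
  expect_equal(subtypes$subtype, expected)

  # hand-built proportion cases: 91% dominant -> labeled; 40/40 -> ambiguous
  fake <- list(per_tumor = matrix(c(0.91, 0.03, 0.04, 0.02,
                                    0.40, 0.40, 0.10, 0.10), nrow = 2,
                                  byrow = TRUE,
                                  dimnames = list(c("T1", "T2"),
                                                  c("A+B-", "A-B+", "A-B-", "A+B+"))))
  out <- assign_tumor_subtype(fake)
  expect_equal(out$subtype, c("A+B-", "ambiguous"))
})
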