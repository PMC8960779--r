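#' Pipeline configuration
#'
#' Builds the nested configuration consumed by [run_pipeline()]. Every stage
#' block mirrors the corresponding module's parameters; a global seed fans
#' out to per-stage seeds through a counter-based derivation so re-running a
#' stage alone reproduces its output regardless of execution order.
#'
#' @param seed Global integer seed.
#' @param sim A [sim_config()] for the simulate stage (its own seed is
#'   overridden by the derived stage seed).
#' @param qc List: `min_umi`, `max_mito_fraction`.
#' @param normalize List: `scale_factor`.
#' @param cnv A [cnv_params()] object.
#' @param screen List: `min_pos_seedneg`, `max_pos_seedpos`, `min_count`.
#' @param subtype List: `dominance_threshold`.
#' @param ith List: `ccf_cutoff`, `n_top_genes`, `min_cells`.
#' @param score List: `signature_file` (TSV path or NULL to score the
#'   simulated subtype programs).
#' @param bulk List: `n_samples`, `subtype_mix`, `component_means`,
#'   `component_sds`, `marker_names`.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(),
                            qc = list(min_umi = 1000, max_mito_fraction = 0.20),
                            normalize = list(scale_factor = 10000),
                            cnv = cnv_params(),
                            screen = list(min_pos_seedneg = 0.5,
                                          max_pos_seedpos = 0.2, min_count = 1),
                            subtype = list(dominance_threshold = 0.5),
                            ith = list(ccf_cutoff = 0.9, n_top_genes = 1000L,
                                       min_cells = 10L),
                            score = list(signature_file = NULL),
                            bulk = list(n_samples = 108L,
                                        subtype_mix = c(0.45, 0.45, 0.06, 0.04),
                                        component_means = c(4, 9),
                                        component_sds = c(1, 1),
                                        marker_names = c("S100P", "SPP1"))) {
  structure(list(seed = as.integer(seed), sim = sim, qc = qc,
                 normalize = normalize, cnv = cnv, screen = screen,
                 subtype = subtype, ith = ith, score = score, bulk = bulk),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; absent keys
#' keep their defaults. The `sim` block is passed to [sim_config()] and the
#' `cnv` block to [cnv_params()].
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  args <- list()
  args$seed <- raw$seed %||% defaults$seed
  args$sim <- if (is.null(raw$sim)) defaults$sim else do.call(sim_config, raw$sim)
  args$cnv <- if (is.null(raw$cnv)) defaults$cnv else do.call(cnv_params, raw$cnv)
  for (k in c("qc", "normalize", "screen", "subtype", "ith", "score", "bulk")) {
    args[[k]] <- utils::modifyList(defaults[[k]], raw[[k]] %||% list())
  }
  do.call(pipeline_config, args)
}

PIPELINE_STAGES <- c("simulate", "qc", "cnv", "subtype_sc", "ith", "score",
                     "subtype_bulk")

require_stage_file <- function(path, stage, needed_by) {
  if (!file.exists(path)) {
    stopf("stage '%s' requires output of stage '%s' (missing: %s); run it first",
          needed_by, stage, path)
  }
  path
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order (simulate -> qc -> cnv ->
#' subtype_sc -> ith / score; subtype_bulk depends only on simulate), writing
#' each stage's artifacts under `out_dir` and a deterministic `manifest.json`
#' listing every output file with its md5 hash, the parameters and the seed.
#' Stage inputs are never mutated; a missing upstream output raises a
#' dependency error naming the absent stage. Progress is logged to stderr
#' with stage, timestamp and level.
#'
#' @param config A `"pipeline_config"` (or YAML path).
#' @param out_dir Output directory.
#' @param stages Character vector of stages, or `"all"`.
#' @param quiet Suppress log lines (default FALSE).
#'
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = "all", quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) stopf("invalid pipeline config")
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_line <- function(stage, msg, level = "INFO") {
    if (!quiet) message(sprintf("[%s] %s %s: %s",
                                format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                level, stage, msg))
  }
  files <- character()
  add <- function(f) files <<- c(files, f)
  p <- function(...) file.path(out_dir, ...)

  for (stage in stages) {
    log_line(stage, "started")
    stage_seed <- derive_seed(config$seed, match(stage, PIPELINE_STAGES))
    switch(stage,
      simulate = {
        sim <- config$sim
        sim$seed <- stage_seed
        cohort <- generate_sc_cohort(sim)
        add(write_10x_cohort(cohort, p("sim")))
        jsonlite::write_json(cohort$marker_program, p("sim", "markers.json"),
                             auto_unbox = TRUE, digits = NA)
        add(p("sim", "markers.json"))
        tumors <- unique(cohort$cell_meta$sample[cohort$cell_meta$tissue == "tumor"])
        muts <- do.call(rbind, lapply(seq_along(tumors), function(i) {
          mt <- generate_mutation_table(
            sim$n_mutations, clonal_fraction = sim$clonal_fraction,
            purity = sim$purity, depth_mean = sim$depth_mean,
            seed = derive_seed(stage_seed, i), sample_id = tumors[i],
            subclonal_ccf_range = sim$subclonal_ccf_range)
          cbind(mt$mutations, truth_clonal = mt$truth$clonal,
                truth_ccf = mt$truth$ccf_true)
        }))
        add(write_tsv(muts, p("sim", "mutations.tsv")))
        bulk <- do.call(generate_bulk_cohort,
                        c(config$bulk[c("n_samples", "subtype_mix",
                                        "component_means", "component_sds",
                                        "marker_names")],
                          list(seed = derive_seed(stage_seed, 99L))))
        expr_df <- data.frame(gene = rownames(bulk$expr), bulk$expr,
                              check.names = FALSE)
        add(write_tsv(expr_df, p("sim", "bulk_expression.tsv")))
        add(write_tsv(bulk$truth, p("sim", "bulk_truth.tsv")))
      },
      qc = {
        require_stage_file(p("sim", "matrix.mtx"), "simulate", "qc")
        cohort <- read_10x_cohort(p("sim"))
        filtered <- qc_filter(cohort, min_umi = config$qc$min_umi,
                              max_mito_fraction = config$qc$max_mito_fraction)
        add(write_10x_cohort(filtered, p("qc")))
        add(write_tsv(attr(filtered, "qc_report"), p("qc", "qc_report.tsv")))
        norm <- normalize_counts(filtered, config$normalize$scale_factor)
        Matrix::writeMM(norm, p("qc", "normalized.mtx"))
        add(p("qc", "normalized.mtx"))
      },
      cnv = {
        require_stage_file(p("qc", "matrix.mtx"), "qc", "cnv")
        cohort <- read_10x_cohort(p("qc"))
        res <- infer_malignant_cells(cohort, params = config$cnv)
        add(write_tsv(res$cells, p("cnv_calls.tsv")))
        add(write_tsv(res$summary, p("cnv_summary.tsv")))
        win <- data.frame(res$profile$windows,
                          round(res$profile$cnvi, 4), check.names = FALSE)
        add(write_tsv(win, p("cnv_windows.tsv")))
      },
      subtype_sc = {
        require_stage_file(p("cnv_calls.tsv"), "cnv", "subtype_sc")
        cohort <- read_10x_cohort(p("qc"))
        calls <- read_tsv(p("cnv_calls.tsv"))
        markers <- jsonlite::read_json(p("sim", "markers.json"),
                                       simplifyVector = TRUE)
        mal <- calls$cell_id[calls$malignant]
        screen <- exclusivity_screen(cohort$counts, markers$seed_marker, mal,
                                     min_pos_seedneg = config$screen$min_pos_seedneg,
                                     max_pos_seedpos = config$screen$max_pos_seedpos,
                                     min_count = config$screen$min_count)
        add(write_tsv(screen, p("exclusivity_screen.tsv")))
        mc <- classify_cells_two_markers(
          cohort$counts, markers$seed_marker, markers$alt_marker, mal,
          samples = calls$sample[calls$malignant],
          min_count = config$screen$min_count)
        add(write_tsv(mc$cells, p("cell_classes.tsv")))
        subtypes <- assign_tumor_subtype(mc, config$subtype$dominance_threshold)
        add(write_tsv(subtypes, p("tumor_subtypes.tsv")))
      },
      ith = {
        require_stage_file(p("sim", "mutations.tsv"), "simulate", "ith")
        require_stage_file(p("tumor_subtypes.tsv"), "subtype_sc", "ith")
        muts <- read_tsv(p("sim", "mutations.tsv"))
        gsum <- summarize_genomic_ith(muts, ccf_cutoff = config$ith$ccf_cutoff)
        add(write_tsv(gsum$mutations, p("mutation_ccf.tsv")))
        cohort <- read_10x_cohort(p("qc"))
        norm <- normalize_counts(cohort)
        calls <- read_tsv(p("cnv_calls.tsv"))
        subtypes <- read_tsv(p("tumor_subtypes.tsv"))
        tith <- vapply(gsum$per_tumor$sample, function(s) {
          cells <- calls$cell_id[calls$malignant & calls$sample == s]
          if (length(cells) < config$ith$min_cells) return(NA_real_)
          transcriptomic_ith(norm, cells, n_top_genes = config$ith$n_top_genes,
                             min_cells = config$ith$min_cells)
        }, 0)
        per_tumor <- merge(gsum$per_tumor,
                           data.frame(sample = gsum$per_tumor$sample,
                                      transcriptomic_ith = unname(tith)),
                           by = "sample")
        per_tumor <- merge(per_tumor, subtypes[, c("sample", "subtype")],
                           by = "sample", all.x = TRUE)
        add(write_tsv(per_tumor, p("ith_per_tumor.tsv")))
        grp <- split(per_tumor, per_tumor$subtype)
        cmp <- if (length(grp) >= 2L) {
          g <- grp[seq_len(2L)]
          list(groups = names(g),
               genomic = compare_groups(g[[1]]$genomic_ith, g[[2]]$genomic_ith),
               transcriptomic = compare_groups(
                 stats::na.omit(g[[1]]$transcriptomic_ith),
                 stats::na.omit(g[[2]]$transcriptomic_ith)))
        } else list(note = "fewer than two subtype groups; no comparison")
        jsonlite::write_json(cmp, p("ith_comparison.json"), auto_unbox = TRUE,
                             digits = NA)
        add(p("ith_comparison.json"))
      },
      score = {
        require_stage_file(p("qc", "matrix.mtx"), "qc", "score")
        require_stage_file(p("cell_classes.tsv"), "subtype_sc", "score")
        cohort <- read_10x_cohort(p("qc"))
        norm <- normalize_counts(cohort)
        sigs <- if (!is.null(config$score$signature_file)) {
          read_signatures(config$score$signature_file)
        } else {
          markers <- jsonlite::read_json(p("sim", "markers.json"),
                                         simplifyVector = TRUE)
          list(program_phl = unlist(markers$program_a),
               program_pps = unlist(markers$program_b))
        }
        classes <- read_tsv(p("cell_classes.tsv"))
        score_tab <- data.frame(cell_id = classes$cell_id,
                                sample = classes$sample, class = classes$class,
                                stringsAsFactors = FALSE)
        cmp <- list()
        for (nm in names(sigs)) {
          sc <- score_signature(norm, classes$cell_id, sigs[[nm]])
          score_tab[[nm]] <- unname(sc)
          two <- names(sort(table(classes$class), decreasing = TRUE))[1:2]
          cmp[[nm]] <- compare_subsets(sc, classes$class, groups = two)
        }
        add(write_tsv(score_tab, p("signature_scores.tsv")))
        jsonlite::write_json(cmp, p("score_comparison.json"), auto_unbox = TRUE,
                             digits = NA)
        add(p("score_comparison.json"))
      },
      subtype_bulk = {
        require_stage_file(p("sim", "bulk_expression.tsv"), "simulate",
                           "subtype_bulk")
        expr_df <- read_tsv(p("sim", "bulk_expression.tsv"))
        expr <- as.matrix(expr_df[, -1, drop = FALSE])
        rownames(expr) <- expr_df$gene
        mn <- config$bulk$marker_names
        res <- subtype_bulk_cohort(expr, mn[1], mn[2], seed = stage_seed)
        add(write_tsv(res$samples, p("bulk_sample_calls.tsv")))
        out <- list(
          fits = list(markerA = res$fitA[c("means", "sds", "weights", "seed")],
                      markerB = res$fitB[c("means", "sds", "weights", "seed")]),
          counts = as.list(res$counts),
          concordant_fraction = res$concordant_fraction)
        jsonlite::write_json(out, p("bulk_summary.json"), auto_unbox = TRUE,
                             digits = NA)
        add(p("bulk_summary.json"))
      }
    )
    log_line(stage, "done")
  }

  manifest <- write_manifest(p("manifest.json"), config$seed,
                             params = list(stages = stages,
                                           qc = config$qc,
                                           cnv = unclass(config$cnv),
                                           screen = config$screen,
                                           subtype = config$subtype,
                                           ith = config$ith,
                                           bulk = config$bulk),
                             files = unique(files))
  invisible(manifest)
}
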