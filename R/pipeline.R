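## End-to-end driver: process -> aggregate -> enrich, with resolved
## configuration written next to the outputs.

#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis with the defaults used
#' genome-wide: convergence cutoff d = 0.004 nats; 10% FDR for test
#' significance; 20% empirical FDR for enrichment reporting; minimum set
#' size 11 (i.e. categories mapped to more than 10 genes; the sparser
#' phenotype annotation uses 6); elim removal level 0.01; 100 permutations
#' for the empirical FDR; 10000 randomisations for targeted set tests;
#' finite-population variance mode.
#'
#' @param d_cutoff convergence cutoff (nats).
#' @param fdr_threshold q-value threshold for per-test significance.
#' @param report_fdr empirical-FDR threshold for enrichment reporting.
#' @param min_set_size smallest testable gene set.
#' @param elim_alpha elim removal level.
#' @param fdr_perms permutations for the empirical FDR.
#' @param settest_perms randomisations for targeted set tests.
#' @param mode SUMSTAT variance mode, `"fpc"` or `"iid"`.
#' @param branch_set lineage branches for score aggregation (default the
#'   13 ant branches).
#' @param seed seed for every stochastic stage.
#' @return object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(d_cutoff = 0.004, fdr_threshold = 0.10,
                            report_fdr = 0.20, min_set_size = 11L,
                            elim_alpha = 0.01, fdr_perms = 100L,
                            settest_perms = 10000L,
                            mode = c("fpc", "iid"),
                            branch_set = ant_branch_labels("ant"),
                            seed = 1L) {
  mode <- match.arg(mode)
  structure(list(d_cutoff = d_cutoff, fdr_threshold = fdr_threshold,
                 report_fdr = report_fdr,
                 min_set_size = as.integer(min_set_size),
                 elim_alpha = elim_alpha, fdr_perms = as.integer(fdr_perms),
                 settest_perms = as.integer(settest_perms), mode = mode,
                 branch_set = branch_set, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_config <- function(config, path) {
  flat <- vapply(config, function(v) paste(v, collapse = ","), "")
  writeLines(paste0(names(flat), " = ", flat), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes test post-processing, lineage score aggregation and SUMSTAT
#' enrichment on a dataset (either a [simulate_dataset()] object or a
#' directory of input files in the formats of [write_dataset()]), writing
#' every intermediate table plus the resolved configuration to `out_dir`.
#' Stage counts (tests read, excluded, clamped, significant; families
#' scored; terms tested and reported) are logged via `message()`.
#'
#' @param input `sim_dataset` object or input directory path.
#' @param out_dir output directory.
#' @param config [pipeline_config()].
#' @return list with `records`, `scores`, `enrichment`
#'   (a [sumstat_enrich()] object) and `tabulation`, invisibly.
#' @export
run_pipeline <- function(input, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  if (inherits(input, "sim_dataset")) {
    runs <- input$replicate_runs
    graph <- input$ontology
    annotations <- input$annotations
  } else {
    runs <- read_replicate_runs(file.path(input, "replicate_runs.tsv"))
    graph <- read_obo(file.path(input, "ontology.obo"))
    annotations <- read_associations(file.path(input, "associations.tsv"))
  }
  message("pipeline: ", nrow(runs) / 6L, " tests read")

  records <- process_tests(runs, d_cutoff = config$d_cutoff,
                           fdr_threshold = config$fdr_threshold)
  write_test_records(records, file.path(out_dir, "test_records.tsv"))

  scores_df <- lineage_scores(records, config$branch_set)
  message("pipeline: ", nrow(scores_df), " families scored over the lineage")
  write_family_scores(scores_df, file.path(out_dir, "family_scores.tsv"))
  scores <- score_vector(scores_df)

  collection <- filter_sets(propagate(graph, annotations),
                            min_size = config$min_set_size,
                            background = names(scores))
  message("pipeline: ", length(collection$members), " testable gene sets")

  enr <- sumstat_enrich(scores, collection, graph,
                        elim_alpha = config$elim_alpha, mode = config$mode,
                        fdr_perms = config$fdr_perms,
                        report_fdr = config$report_fdr)
  message("pipeline: ", sum(enr$results$reported), " sets reported at ",
          "empirical FDR < ", config$report_fdr)
  write_enrichment(enr$results[order(enr$results$p_enrich), ],
                   file.path(out_dir, "enrichment.tsv"))
  if (!is.null(enr$fdr_table))
    write_tsv(enr$fdr_table, file.path(out_dir, "fdr_table.tsv"))

  tab <- tabulate_selection(records,
                            lineages = list(ant = config$branch_set))
  write_tsv(tab$branches, file.path(out_dir, "branch_counts.tsv"))
  write_config(config, file.path(out_dir, "config.txt"))

  invisible(list(records = records, scores = scores_df, enrichment = enr,
                 tabulation = tab))
}
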