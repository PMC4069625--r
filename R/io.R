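## Tab-separated file formats for every pipeline stage. All tables carry a
## header line; '#' lines are comments; floats are written with 10
## significant digits so a rerun with the same seed is byte-identical.
## Column layouts are documented in inst/FORMATS.md.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 10))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, required = NULL) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss))
      stop(path, " lacks required column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Read and write pipeline tables
#'
#' Readers validate the required columns and fail naming the file and the
#' missing column. `read_replicate_runs()` additionally rejects rows with
#' a non-numeric log-likelihood, citing the first offending line.
#'
#' @param path file path.
#' @param x table to write (format-specific data frame).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_replicate_runs <- function(path) {
  df <- read_tsv(path, c("family_id", "branch_id", "hypothesis", "run", "lnl"))
  if (!is.numeric(df$lnl)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$lnl))))[1L]
    stop(path, ": non-numeric lnl value at data row ", bad)
  }
  df
}

#' @rdname pipeline_io
#' @export
write_replicate_runs <- function(x, path) write_tsv(x, path)

#' @rdname pipeline_io
#' @export
read_test_records <- function(path) {
  df <- read_tsv(path, c("family_id", "branch_id", "delta_lnl", "lrt", "d"))
  class(df) <- c("test_records", "data.frame")
  df
}

#' @rdname pipeline_io
#' @export
write_test_records <- function(x, path) write_tsv(as.data.frame(x), path)

#' @rdname pipeline_io
#' @export
read_family_scores <- function(path)
  read_tsv(path, c("family_id", "n_branches_used", "mean_lrt", "transformed"))

#' @rdname pipeline_io
#' @export
write_family_scores <- function(x, path) write_tsv(x, path)

#' @rdname pipeline_io
#' @export
read_associations <- function(path) {
  df <- read_tsv(path, c("gene", "term"))
  df[c("gene", "term")]
}

#' @rdname pipeline_io
#' @export
write_associations <- function(x, path) write_tsv(x, path)

#' Read gene-set definitions (name TAB comma-separated gene ids)
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad)) stop(path, ": malformed gene-set line ", bad[1L])
  setNames(lapply(parts, function(p) strsplit(p[2L], ",", fixed = TRUE)[[1L]]),
           vapply(parts, `[`, "", 1L))
}

#' @rdname read_gene_sets
#' @param sets named list of character vectors to write.
#' @export
write_gene_sets <- function(sets, path) {
  writeLines(paste(names(sets),
                   vapply(sets, paste, "", collapse = ","), sep = "\t"),
             path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
write_enrichment <- function(x, path) {
  if (inherits(x, "sumstat_enrichment")) x <- x$results
  write_tsv(x, path)
}

#' Write a synthetic dataset to a directory
#'
#' Produces the on-disk form of every generator output: replicate-runs
#' TSV, per-family newick trees (two-column TSV `family_id`, `newick`),
#' OBO-subset ontology, gene-term association TSV, and truth-label TSVs.
#'
#' @param dataset [simulate_dataset()] output.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_replicate_runs(dataset$replicate_runs,
                       file.path(dir, "replicate_runs.tsv"))
  write_tsv(data.frame(family_id = names(dataset$family_trees),
                       newick = unname(dataset$family_trees),
                       stringsAsFactors = FALSE),
            file.path(dir, "family_trees.tsv"))
  writeLines(dataset$obo, file.path(dir, "ontology.obo"))
  write_associations(dataset$annotations, file.path(dir, "associations.tsv"))
  write_tsv(dataset$truth$tests, file.path(dir, "truth_tests.tsv"))
  write_tsv(dataset$truth$terms, file.path(dir, "truth_terms.tsv"))
  invisible(dir)
}
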