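#' Write / read a cell matrix as Matrix-Market plus TSV metadata
#'
#' The on-disk layout is the 10x-style triplet: `matrix.mtx` (sparse
#' counts), `genes.tsv` (one gene id per line) and `cells.tsv` (per-cell
#' metadata, tab-separated with header).
#'
#' @param m A [cell_matrix()].
#' @param dir Output directory (created if needed).
#' @return `write_cell_matrix` returns `dir` invisibly; `read_cell_matrix`
#'   returns a [cell_matrix()].
#' @export
write_cell_matrix <- function(m, dir) {
  stopifnot(inherits(m, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "genes.tsv"))
  write.table(m$cell_meta, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cell_matrix
#' @export
read_cell_matrix <- function(dir) {
  counts <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  meta <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  rownames(counts) <- genes
  colnames(counts) <- meta$cell_id
  cell_matrix(counts, meta)
}

#' Write / read a segment matrix as CSV counts plus TSV metadata
#'
#' @param s A [segment_matrix()].
#' @param dir Output directory (created if needed); files are `counts.csv`
#'   (genes x segments, first column gene id) and `segments.tsv`.
#' @return `write_segment_matrix` returns `dir` invisibly;
#'   `read_segment_matrix` returns a [segment_matrix()].
#' @export
write_segment_matrix <- function(s, dir) {
  stopifnot(inherits(s, "segment_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(gene = rownames(s$counts), s$counts,
                       check.names = FALSE),
            file.path(dir, "counts.csv"), row.names = FALSE, quote = FALSE)
  write.table(s$segment_meta, file.path(dir, "segments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_segment_matrix
#' @export
read_segment_matrix <- function(dir) {
  tab <- read.csv(file.path(dir, "counts.csv"), check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$gene
  meta <- read.delim(file.path(dir, "segments.tsv"), stringsAsFactors = FALSE)
  segment_matrix(counts, meta)
}

#' Write a simulation ground-truth table as JSON
#'
#' @param truth The `truth` element returned by [simulate_cells()] or
#'   [simulate_segments()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Write an analysis report bundle
#'
#' Writes every data.frame in `sections` as a CSV under `dir` and a
#' `report.json` summary holding the package version, the seed (if given),
#' a manifest of written and missing sections and the MD5 checksum of each
#' CSV. Output is byte-stable for identical inputs.
#'
#' @param sections Named list; data.frame entries are written as
#'   `<name>.csv`, scalar/list entries are embedded in the JSON summary,
#'   `NULL` entries are listed in the manifest as missing.
#' @param dir Output directory (created if needed).
#' @param seed Optional integer recorded in the summary.
#' @return Path of `report.json`, invisibly.
#' @export
write_report <- function(sections, dir, seed = NULL) {
  if (is.null(names(sections)) && length(sections))
    stop("sections must be a named list")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  missing <- character(0)
  inline <- list()
  for (nm in names(sections)) {
    x <- sections[[nm]]
    if (is.null(x)) {
      missing <- c(missing, nm)
    } else if (is.data.frame(x)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      write.csv(x, f, row.names = FALSE, quote = FALSE)
      written <- c(written, nm)
    } else {
      inline[[nm]] <- x
    }
  }
  files <- file.path(dir, paste0(written, ".csv"))
  summary <- list(
    package = "nichecompare",
    version = as.character(utils::packageVersion("nichecompare")),
    seed = seed,
    manifest = list(written = as.list(written),
                    missing = as.list(missing)),
    checksums = as.list(setNames(unname(tools::md5sum(files)), written)),
    results = inline)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "report.json"))
}
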