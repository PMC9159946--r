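# Readers and writers for the on-disk formats: TSV tables, Matrix Market
# count matrices, FASTQ, JSON truth and YAML configuration. All writers
# emit deterministic column and row order.

write_fastq <- function(reads, ids, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a character vector
#'
#' @param path FASTQ path (gzip transparently supported).
#' @return character vector of read sequences.
#' @export
read_fastq <- function(path) {
  unname(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
}

#' Read a bulk barcode count table and its sample sheet
#'
#' The count table is a TSV whose first column (`barcode`) holds barcode
#' ids and whose remaining columns are sample counts; the sample sheet is
#' a TSV with columns `sample_id`, `mouse_id`, `compartment`, `age_group`,
#' `sex`. Validation failures name the offending row or column.
#'
#' @param counts_path,samples_path input TSV paths.
#' @return a [barcode_count_table()].
#' @export
read_barcode_table <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"barcode" %in% names(df)) {
    stop_validation("count table must have a 'barcode' first column")
  }
  if (anyDuplicated(df$barcode)) {
    stop_validation("duplicated barcode id: '%s'",
                    df$barcode[duplicated(df$barcode)][1])
  }
  counts <- as.matrix(df[, setdiff(names(df), "barcode"), drop = FALSE])
  rownames(counts) <- df$barcode
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  barcode_count_table(counts, samples)
}

#' Write a bulk barcode count table and its sample sheet
#'
#' @param table a [barcode_count_table()].
#' @param counts_path,samples_path output TSV paths.
#' @return invisibly, the count table path.
#' @export
write_barcode_table <- function(table, counts_path, samples_path) {
  df <- data.frame(barcode = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Read / write a clone assignment table
#'
#' TSV with columns `cell_id`, `barcode_1`, `barcode_2`, `population`
#' (empty `barcode_2` becomes `NA`).
#'
#' @param path TSV path.
#' @return data frame of clone assignments.
#' @export
read_clone_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("cell_id", "barcode_1", "population")
  if (!all(req %in% names(df))) {
    stop_validation("clone table must have columns %s", paste(req, collapse = ", "))
  }
  if (!"barcode_2" %in% names(df)) df$barcode_2 <- NA_character_
  df$barcode_2 <- as.character(df$barcode_2)
  df
}

#' @rdname read_clone_table
#' @param clones clone assignment data frame.
#' @export
write_clone_table <- function(clones, path) {
  utils::write.table(clones, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a count matrix as Matrix Market plus id files
#'
#' Writes `matrix.mtx`, `genes.tsv` and `cells.tsv` into a directory and
#' reads them back into a dense genes x cells integer matrix.
#'
#' @param dir directory holding (or to hold) the three files.
#' @return genes x cells matrix.
#' @export
read_count_matrix <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "cells.tsv"))
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_count_matrix
#' @param counts genes x cells matrix.
#' @export
write_count_matrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read / write simulator ground truth as JSON
#'
#' @param truth the `truth` data frame of a simulated cohort.
#' @param path JSON path.
#' @return the truth data frame.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", na = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  if ("barcode_2" %in% names(df)) df$barcode_2 <- as.character(df$barcode_2)
  df
}
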