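#' Bulk barcode count table
#'
#' Container for scar-barcode read counts across sorted bulk TEC samples,
#' the input to the rare-barcode co-occurrence and background-frequency
#' computations. Rows are barcodes, columns are samples; a companion sample
#' sheet carries mouse identity, compartment, age group and sex.
#'
#' @param counts integer matrix (barcode x sample) of non-negative read
#'   counts with unique row names (barcode ids) and column names matching
#'   `samples$sample_id`.
#' @param samples data frame with columns `sample_id`, `mouse_id`,
#'   `compartment` (one of `"cTEC"`, `"mTEC"`), `age_group` and `sex`.
#' @return an object of class `barcode_count_table`.
#' @examples
#' counts <- matrix(c(5L, 0L, 2L, 1L), 2, 2,
#'                  dimnames = list(c("b1", "b2"), c("s1", "s2")))
#' samples <- data.frame(sample_id = c("s1", "s2"), mouse_id = "m1",
#'                       compartment = c("cTEC", "mTEC"),
#'                       age_group = "P14", sex = "male")
#' barcode_count_table(counts, samples)
#' @export
barcode_count_table <- function(counts, samples) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_validation("counts must be a matrix with barcode row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    stop_validation("duplicated barcode id in count table: '%s'", dup)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    stop_validation("counts must be non-negative integers (offending barcode '%s', sample '%s')",
                    rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  req <- c("sample_id", "mouse_id", "compartment", "age_group", "sex")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    stop_validation("sample sheet lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  samples <- as.data.frame(samples)[, req]
  if (!setequal(samples$sample_id, colnames(counts)) ||
      anyDuplicated(samples$sample_id)) {
    stop_validation("sample sheet ids must match count table columns exactly")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$compartment %in% c("cTEC", "mTEC"))) {
    stop_validation("compartment must be 'cTEC' or 'mTEC'")
  }
  tab <- table(samples$mouse_id, samples$compartment)
  if (any(tab > 1)) {
    bad <- which(tab > 1, arr.ind = TRUE)[1, ]
    stop_validation("mouse '%s' contributes more than one %s sample",
                    rownames(tab)[bad[1]], colnames(tab)[bad[2]])
  }
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop_validation("sample '%s' has zero total count", colnames(counts)[zero][1])
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples),
            class = "barcode_count_table")
}

#' @export
print.barcode_count_table <- function(x, ...) {
  cat(sprintf("barcode_count_table: %d barcodes x %d samples (%d mice)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$mouse_id))))
  cat(sprintf("  compartments: %s\n",
              paste(sprintf("%s=%d", names(table(x$samples$compartment)),
                            table(x$samples$compartment)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.barcode_count_table <- function(x) dim(x$counts)

# sample ids belonging to one mouse, named by compartment
mouse_samples <- function(table, mouse) {
  s <- table$samples[table$samples$mouse_id == mouse, ]
  stats::setNames(s$sample_id, s$compartment)
}
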