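#' Extract the scar window from amplicon sequences
#'
#' Locates the forward extraction primer and the reverse-complemented
#' reverse primer in each sequence (each anchor tolerating at most
#' `max_mismatch` substitutions, no indels) and returns the subsequence
#' between them, the scar window. Orientation is normalised: sequences in
#' which the anchors are not found are retried as their reverse
#' complement. Absence of either anchor yields `NA`, not an error.
#'
#' @param sequences character vector of read or amplicon sequences.
#' @param max_mismatch mismatches tolerated per anchor (default 1).
#' @return character vector of scar windows, `NA` where no scar was found;
#'   attribute `"reason"` holds per-element diagnostics (`"ok"`,
#'   `"no_scar"`, `"ambiguous_base"`).
#' @examples
#' extract_scar_region(paste0("ACGATC", "GCTCGAGATGTCATGAAGG",
#'                            germline_scar_window(),
#'                            "AAGAACTTATAGCCCCCC", "AGTTGA"))
#' @export
extract_scar_region <- function(sequences, max_mismatch = 1) {
  if (!length(sequences)) {
    return(structure(character(0), reason = character(0)))
  }
  scar <- rep(NA_character_, length(sequences))
  reason <- rep("no_scar", length(sequences))

  hit <- scan_strand(sequences, max_mismatch)
  miss <- is.na(hit)
  if (any(miss)) {
    hit[miss] <- scan_strand(revcomp(sequences[miss]), max_mismatch)
  }
  ok <- !is.na(hit)
  scar[ok] <- hit[ok]
  reason[ok] <- "ok"
  amb <- ok & grepl("[^ACGT]", scar)
  scar[amb] <- NA_character_
  reason[amb] <- "ambiguous_base"
  structure(scar, reason = reason)
}

# One-strand anchor scan; NA where either anchor (or their ordering) fails.
scan_strand <- function(sequences, max_mismatch) {
  x <- Biostrings::DNAStringSet(sequences)
  f <- Biostrings::vmatchPattern(HPRT_FORWARD_PRIMER, x,
                                 max.mismatch = max_mismatch, fixed = TRUE)
  r <- Biostrings::vmatchPattern(revcomp(HPRT_REVERSE_PRIMER), x,
                                 max.mismatch = max_mismatch, fixed = TRUE)
  fe <- Biostrings::endIndex(f)
  rs <- Biostrings::startIndex(r)
  out <- rep(NA_character_, length(sequences))
  for (i in seq_along(out)) {
    if (is.null(fe[[i]]) || is.null(rs[[i]])) next
    a <- min(fe[[i]])
    b <- rs[[i]][rs[[i]] > a]
    if (!length(b)) next
    out[i] <- substr(sequences[i], a + 1L, min(b) - 1L)
  }
  out
}

#' Parse paired-end single-cell scar reads
#'
#' Decomposes each left mate into its 6-nt UMI, 6-nt cell barcode and scar
#' region, extracts the scar independently from the right mate, and keeps
#' a read pair only when the identical scar sequence appears in both mates.
#'
#' @param left,right character vectors of mate sequences (same length).
#' @param max_mismatch anchor mismatch tolerance, see
#'   [extract_scar_region()].
#' @return data frame with one row per input pair: `umi`, `cell_barcode`,
#'   `scar` (NA unless accepted) and `status` (`"ok"`, `"too_short"`,
#'   `"no_scar"`, `"ambiguous_base"`, `"mate_mismatch"`).
#' @export
parse_read_pairs <- function(left, right, max_mismatch = 1) {
  if (length(left) != length(right)) {
    stop_invalid("left and right mates must have equal length")
  }
  n <- length(left)
  status <- rep("ok", n)
  umi <- substr(left, 1L, 6L)
  cbc <- substr(left, 7L, 12L)
  scar <- rep(NA_character_, n)

  short <- nchar(left) <= 12L | nchar(right) == 0L
  status[short] <- "too_short"
  idx <- which(!short)
  if (length(idx)) {
    sl <- extract_scar_region(substring(left[idx], 13L), max_mismatch)
    sr <- extract_scar_region(right[idx], max_mismatch)
    rl <- attr(sl, "reason")
    rr <- attr(sr, "reason")
    bad <- rl != "ok" | rr != "ok"
    # ambiguous bases dominate over plain anchor absence in the report
    reason <- ifelse(rl == "ambiguous_base" | rr == "ambiguous_base",
                     "ambiguous_base", "no_scar")
    status[idx[bad]] <- reason[bad]
    both <- !bad
    agree <- both & sl == sr
    status[idx[both & !agree]] <- "mate_mismatch"
    keep <- which(both & agree)
    scar[idx[keep]] <- sl[keep]
  }
  data.frame(umi = umi, cell_barcode = cbc, scar = scar, status = status,
             stringsAsFactors = FALSE)
}

#' Parse a single read pair
#'
#' Scalar convenience wrapper around [parse_read_pairs()].
#'
#' @param left,right single mate sequences.
#' @param max_mismatch anchor mismatch tolerance.
#' @return one-row data frame, see [parse_read_pairs()].
#' @export
parse_read_pair <- function(left, right, max_mismatch = 1) {
  parse_read_pairs(left, right, max_mismatch)
}

#' Call scar alleles per cell
#'
#' Groups accepted reads by cell barcode, ranks distinct scar sequences by
#' read support (optionally UMI-collapsed: support is the number of
#' distinct UMI-scar combinations, which protects the allele-fraction rule
#' from PCR jackpots) and applies the single-cell filtering rules: a cell
#' passes only with at least `min_reads` usable reads; male cells are
#' excluded when a second scar reaches `allele_frac` of the major scar's
#' support; female cells are excluded when a third scar reaches
#' `allele_frac` of the second's. In passing female cells the second
#' allele is reported only when it reaches `allele_frac` of the major
#' allele, otherwise it is treated as noise.
#'
#' @param parsed data frame from [parse_read_pairs()].
#' @param sex `"male"` or `"female"`.
#' @param min_reads minimum usable (two-mate agreeing) reads per cell.
#' @param allele_frac detection threshold for secondary alleles, as a
#'   fraction of the support of the next-ranked allele; the published rule
#'   is "at least 10%", so a fraction of exactly 0.10 triggers detection.
#' @param umi_collapse collapse read support to distinct (UMI, scar)
#'   pairs before ranking (recommended for UMI-tagged libraries).
#' @return data frame with one row per cell: `cell_barcode`, `allele_1`,
#'   `allele_2`, `support_1`, `support_2`, `total_reads`, `status`
#'   (`"pass"`/`"filtered"`) and `filter_reason` (`"none"`, `"low_reads"`,
#'   `"excess_alleles_male"`, `"excess_alleles_female"`).
#' @export
call_cell_scars <- function(parsed, sex, min_reads = 200, allele_frac = 0.10,
                            umi_collapse = TRUE) {
  if (length(sex) != 1 || !sex %in% c("male", "female")) {
    stop_invalid("sex must be 'male' or 'female'")
  }
  assert_count(min_reads, "min_reads")
  assert_fraction(allele_frac, "allele_frac")
  ok <- parsed[parsed$status == "ok", , drop = FALSE]
  cells <- unique(parsed$cell_barcode)
  rows <- lapply(cells, function(cb) {
    p <- ok[ok$cell_barcode == cb, , drop = FALSE]
    total <- nrow(p)
    support <- if (umi_collapse) {
      u <- unique(p[, c("umi", "scar")])
      table(u$scar)
    } else {
      table(p$scar)
    }
    support <- sort(support, decreasing = TRUE)
    # deterministic tie-break on sequence
    support <- support[order(-as.integer(support), names(support))]
    s <- as.integer(support)
    sq <- names(support)
    res <- data.frame(cell_barcode = cb,
                      allele_1 = NA_character_, allele_2 = NA_character_,
                      support_1 = NA_integer_, support_2 = NA_integer_,
                      total_reads = total,
                      status = "filtered", filter_reason = "none",
                      stringsAsFactors = FALSE)
    if (total < min_reads) {
      res$filter_reason <- "low_reads"
      return(res)
    }
    if (sex == "male") {
      if (length(s) >= 2 && s[2] >= allele_frac * s[1]) {
        res$filter_reason <- "excess_alleles_male"
        return(res)
      }
      res$status <- "pass"
      res$allele_1 <- sq[1]
      res$support_1 <- s[1]
      return(res)
    }
    # female
    if (length(s) >= 3 && s[2] >= allele_frac * s[1] && s[3] >= allele_frac * s[2]) {
      res$filter_reason <- "excess_alleles_female"
      return(res)
    }
    res$status <- "pass"
    res$allele_1 <- sq[1]
    res$support_1 <- s[1]
    if (length(s) >= 2 && s[2] >= allele_frac * s[1]) {
      res$allele_2 <- sq[2]
      res$support_2 <- s[2]
    }
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count scar barcodes in bulk amplicon reads
#'
#' Bulk libraries carry no UMI or cell-barcode structure; both mates span
#' the scar. Reads are kept when the identical scar is extracted from both
#' mates, and read counts per distinct scar sequence are returned
#' (read-level counting; bulk amplicon primers carry no UMIs).
#'
#' @param left,right character vectors of mate sequences.
#' @param max_mismatch anchor mismatch tolerance.
#' @return data frame sorted by decreasing count: `barcode` (scar
#'   sequence), `count`, `is_germline`.
#' @export
count_bulk_barcodes <- function(left, right, max_mismatch = 1) {
  if (!length(left)) {
    warning("no input reads; returning empty barcode counts")
    return(data.frame(barcode = character(0), count = integer(0),
                      is_germline = logical(0)))
  }
  sl <- extract_scar_region(left, max_mismatch)
  sr <- extract_scar_region(right, max_mismatch)
  keep <- !is.na(sl) & !is.na(sr) & sl == sr
  tab <- sort(table(sl[keep]), decreasing = TRUE)
  data.frame(barcode = names(tab), count = as.integer(tab),
             is_germline = names(tab) == germline_scar_window(),
             stringsAsFactors = FALSE, row.names = NULL)
}
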