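# Sequence-level model of the scar amplicon.
#
# Anchor primers and the sgRNA target (with PAM) are the published assay
# sequences; the short flanks padding the scar window are synthetic
# placeholders, not genomic Hprt exon-3 context.
HPRT_FORWARD_PRIMER <- "GCTCGAGATGTCATGAAGG"
HPRT_REVERSE_PRIMER <- "GGGGGGCTATAAGTTCTT"
SGRNA_TARGET <- "GATGGGAGGCCATCACATTGG"
SCAR_WINDOW_5P <- "ACCTCT"
SCAR_WINDOW_3P <- "AGTCTA"
# Constant segment between the cell barcode and the scar region in the
# single-cell barcoding primer.
SC_PRIMER_CONST <- "CCAGTTAAAGTTGAGAGATCATCTCC"
# Cas9 blunt cut 3 nt upstream of the PAM: after base 21 of the window.
CUT_POSITION <- 21L

#' Germline (unedited) scar window
#'
#' The unedited target window returned by [extract_scar_region()] on a
#' germline amplicon: the sgRNA target (PAM included) with short synthetic
#' flanks inside the primer anchors.
#'
#' @return single character string.
#' @export
germline_scar_window <- function() {
  paste0(SCAR_WINDOW_5P, SGRNA_TARGET, SCAR_WINDOW_3P)
}

encode_base4 <- function(n, width) {
  alphabet <- c("A", "C", "G", "T")
  vapply(n, function(k) {
    digits <- integer(width)
    for (i in seq_len(width)) {
      digits[i] <- k %% 4L
      k <- k %/% 4L
    }
    paste(alphabet[rev(digits) + 1L], collapse = "")
  }, character(1))
}

#' Scar sequence of a simulated barcode
#'
#' Deterministic map from simulator barcode ids to scar nucleotide
#' sequences: each outcome deletes up to six bases around the cut site and
#' inserts a nine-base tag that encodes the outcome index, so distinct
#' outcome ids always yield distinct sequences while identical outcomes
#' drawn in different mice share one sequence (barcode collisions happen at
#' the outcome level, as in real repair-outcome distributions).
#'
#' @param barcode_ids character vector of simulator ids (`"b000017"`);
#'   the special id `"germline"` maps to [germline_scar_window()].
#' @return character vector of scar sequences.
#' @export
scar_sequence <- function(barcode_ids) {
  w <- germline_scar_window()
  out <- character(length(barcode_ids))
  germ <- barcode_ids == "germline"
  out[germ] <- w
  if (any(!germ)) {
    n <- as.integer(sub("^b", "", barcode_ids[!germ]))
    if (anyNA(n)) {
      stop_invalid("malformed barcode id(s): %s",
                   paste(utils::head(barcode_ids[!germ][is.na(n)], 3), collapse = ", "))
    }
    del <- n %% 7L
    del_l <- del %/% 2L
    del_r <- del - del_l
    ins <- encode_base4(n, 9L)
    out[!germ] <- paste0(substring(w, 1L, CUT_POSITION - del_l), ins,
                         substring(w, CUT_POSITION + 1L + del_r))
  }
  out
}

sc_amplicon <- function(scar) {
  paste0(SC_PRIMER_CONST, HPRT_FORWARD_PRIMER, scar,
         revcomp(HPRT_REVERSE_PRIMER), "CATCTG")
}

bulk_amplicon <- function(scar) {
  paste0("ACGATC", HPRT_FORWARD_PRIMER, scar, revcomp(HPRT_REVERSE_PRIMER), "AGTTGA")
}

# distinct deterministic 6-mers for cell barcodes
cell_barcode_kmers <- function(n) {
  if (n > 4096) stop_invalid("at most 4096 distinct 6-nt cell barcodes exist")
  encode_base4(seq_len(n) - 1L, 6L)
}

#' Synthesize single-cell scar amplicon reads
#'
#' Emits paired-end reads for a set of barcoded cells following the
#' single-cell barcoding library structure: the left mate carries a 6-nt
#' UMI, then a 6-nt cell barcode, then the constant primer segment and the
#' scar region framed by the extraction primer anchors; the right mate
#' carries the same scar region reverse-complemented. Substitution errors
#' are applied uniformly at `error_rate` per base.
#'
#' @param cells data frame with columns `cell_id`, `barcode_1` and
#'   optionally `barcode_2` (NA for single-allele cells), e.g. the
#'   `clones` element of a simulated single-cell dataset.
#' @param reads_per_cell reads emitted per cell (>= 1).
#' @param error_rate per-base substitution probability in `[0, 0.05]`.
#' @param seed integer seed.
#' @param left,right optional output FASTQ paths (gzip-compressed when
#'   ending in `.gz`); when `NULL` the reads are returned in memory.
#' @return invisibly (or visibly when `left` is `NULL`) a list with
#'   `left`/`right` read vectors or file paths and a `cells` data frame
#'   mapping `cell_id` to its 6-nt `cell_barcode`.
#' @seealso [parse_read_pairs()], [call_cell_scars()]
#' @export
synthesize_fastq <- function(cells, reads_per_cell = 300, error_rate = 0,
                             seed = 1L, left = NULL, right = NULL) {
  assert_count(reads_per_cell, "reads_per_cell")
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 0.05) {
    stop_invalid("error_rate must be in [0, 0.05]")
  }
  if (!all(c("cell_id", "barcode_1") %in% names(cells))) {
    stop_invalid("cells must have columns cell_id and barcode_1")
  }
  n_cells <- nrow(cells)
  cbc <- cell_barcode_kmers(n_cells)
  b2 <- if ("barcode_2" %in% names(cells)) cells$barcode_2 else rep(NA_character_, n_cells)

  res <- with_seed(seed, {
    lefts <- vector("list", n_cells)
    rights <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      alleles <- c(cells$barcode_1[i], b2[i])
      alleles <- alleles[!is.na(alleles)]
      pick <- if (length(alleles) == 1) {
        rep(alleles, reads_per_cell)
      } else {
        sample(alleles, reads_per_cell, replace = TRUE)
      }
      scar <- scar_sequence(pick)
      umi <- random_dna(rep(6L, reads_per_cell))
      core <- sc_amplicon(scar)
      lefts[[i]] <- paste0(umi, cbc[i], core)
      rights[[i]] <- revcomp(core)
    }
    lv <- unlist(lefts)
    rv <- unlist(rights)
    if (error_rate > 0) {
      lv <- mutate_reads(lv, error_rate)
      rv <- mutate_reads(rv, error_rate)
    }
    list(left = lv, right = rv)
  })
  ids <- sprintf("read%07d", seq_along(res$left))
  out <- list(left = res$left, right = res$right,
              cells = data.frame(cell_id = cells$cell_id, cell_barcode = cbc,
                                 stringsAsFactors = FALSE))
  if (!is.null(left)) {
    write_fastq(res$left, ids, left)
    write_fastq(res$right, ids, right)
    out$left <- left
    out$right <- right
    return(invisible(out))
  }
  out
}

#' Synthesize bulk scar amplicon reads
#'
#' Paired-end bulk amplicon reads (no UMI or cell-barcode structure) with
#' the requested number of reads per barcode.
#'
#' @param barcode_counts named integer vector: reads to emit per barcode id
#'   (ids as accepted by [scar_sequence()]).
#' @param error_rate per-base substitution probability in `[0, 0.05]`.
#' @param seed integer seed (reads are shuffled and errors drawn from it).
#' @return list with `left` and `right` read vectors.
#' @export
synthesize_bulk_fastq <- function(barcode_counts, error_rate = 0, seed = 1L) {
  if (is.null(names(barcode_counts))) {
    stop_invalid("barcode_counts must be named by barcode id")
  }
  ids <- rep(names(barcode_counts), barcode_counts)
  with_seed(seed, {
    ids <- sample(ids)
    core <- bulk_amplicon(scar_sequence(ids))
    lv <- core
    rv <- revcomp(core)
    if (error_rate > 0) {
      lv <- mutate_reads(lv, error_rate)
      rv <- mutate_reads(rv, error_rate)
    }
    list(left = lv, right = rv)
  })
}
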