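fwd <- "GCTCGAGATGTCATGAAGG"
rev_rc <- as.character(Biostrings::reverseComplement(
  Biostrings::DNAString("GGGGGGCTATAAGTTCTT")))

test_that("the germline amplicon yields the unedited target window", {
  amp <- paste0("ACGATC", fwd, germline_scar_window(), rev_rc, "AGTTGA")
  scar <- extract_scar_region(amp)
  expect_equal(as.character(scar), germline_scar_window())
  expect_true(grepl("GATGGGAGGCCATCACATTGG", scar, fixed = TRUE))
  # orientation is normalised: the reverse complement extracts identically
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(amp)))
  expect_equal(as.character(extract_scar_region(rc)), germline_scar_window())
})

test_that("anchor matching tolerates one substitution but not two", {
  w <- germline_scar_window()
  mutate_at <- function(anchor, pos) {
    ch <- strsplit(anchor, "")[[1]]
    ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
    paste(ch, collapse = "")
  }
  # every single-substitution variant of the forward anchor still matches
  for (pos in seq_len(nchar(fwd))) {
    amp <- paste0("ACGATC", mutate_at(fwd, pos), w, rev_rc, "AGTTGA")
    expect_false(is.na(extract_scar_region(amp)), info = paste("pos", pos))
  }
  # two substitutions break the anchor
  f2 <- mutate_at(mutate_at(fwd, 3), 11)
  amp2 <- paste0("ACGATC", f2, w, rev_rc, "AGTTGA")
  expect_true(is.na(extract_scar_region(amp2)))
  # a missing forward anchor gives NA, not an error
  expect_true(is.na(extract_scar_region(paste0("ACGT", w, rev_rc))))
})

test_that("read pairs decompose into UMI, cell barcode and a two-mate-verified scar", {
  cells <- data.frame(cell_id = c("c1", "c2"),
                      barcode_1 = c("b000005", "b000123"),
                      stringsAsFactors = FALSE)
  fq <- synthesize_fastq(cells, reads_per_cell = 5, error_rate = 0, seed = 2)
  parsed <- parse_read_pairs(fq$left, fq$right)
  expect_true(all(parsed$status == "ok"))
  expect_true(all(nchar(parsed$umi) == 6), all(nchar(parsed$cell_barcode) == 6))
  expect_setequal(unique(parsed$scar), scar_sequence(cells$barcode_1))
  expect_setequal(unique(parsed$cell_barcode), fq$cells$cell_barcode)

  # mates carrying different scars are rejected
  swapped <- parse_read_pairs(fq$left[1], fq$right[6])
  expect_equal(swapped$status, "mate_mismatch")
  # truncation before the scar region
  expect_equal(parse_read_pair(substr(fq$left[1], 1, 10), fq$right[1])$status,
               "too_short")
  expect_equal(parse_read_pair(substr(fq$left[1], 1, 30), fq$right[1])$status,
               "no_scar")
  # ambiguous bases inside the scar are dropped
  amb <- fq$left[1]
  substr(amb, 60, 60) <- "N"
  expect_equal(parse_read_pair(amb, fq$right[1])$status, "ambiguous_base")
})

make_parsed <- function(scar_reads) {
  # scar_reads: named vector scar -> number of reads, one cell "AAAAAA"
  do.call(rbind, lapply(names(scar_reads), function(s) {
    n <- scar_reads[[s]]
    data.frame(umi = sprintf("UMI%03d_%s", seq_len(n), substr(s, 1, 2)),
               cell_barcode = "AAAAAA", scar = s, status = "ok",
               stringsAsFactors = FALSE)
  }))
}

test_that("allele calling applies the read-support and allele-fraction rules", {
  # male, one scar, ample reads: pass with a single allele
  p <- make_parsed(c(SCARX = 300))
  res <- call_cell_scars(p, "male")
  expect_equal(res$status, "pass")
  expect_equal(res$allele_1, "SCARX")
  expect_true(is.na(res$allele_2))

  # male with a second sequence at 12% of the major: excluded
  p <- make_parsed(c(MAJOR = 250, MINOR = 30))
  res <- call_cell_scars(p, "male")
  expect_equal(res$status, "filtered")
  expect_equal(res$filter_reason, "excess_alleles_male")

  # a second sequence at exactly 10.0% triggers exclusion ("at least 10%")
  p <- make_parsed(c(MAJOR = 250, MINOR = 25))
  expect_equal(call_cell_scars(p, "male")$filter_reason, "excess_alleles_male")
  # just below 10%: noise, cell passes
  p <- make_parsed(c(MAJOR = 250, MINOR = 24))
  expect_equal(call_cell_scars(p, "male")$status, "pass")

  # female 200/60/5: third is 8.3% of the second, cell passes with 2 alleles
  p <- make_parsed(c(A1 = 200, A2 = 60, A3 = 5))
  res <- call_cell_scars(p, "female")
  expect_equal(res$status, "pass")
  expect_equal(res$allele_1, "A1")
  expect_equal(res$allele_2, "A2")
  # third at 10% of the second: excluded
  p <- make_parsed(c(A1 = 200, A2 = 60, A3 = 6))
  expect_equal(call_cell_scars(p, "female")$filter_reason, "excess_alleles_female")

  # below the read threshold every cell is filtered
  p <- make_parsed(c(SCARX = 150))
  expect_equal(call_cell_scars(p, "male")$filter_reason, "low_reads")

  expect_error(call_cell_scars(p, "unknown"), class = "clonescar_invalid_config")
})

test_that("raising the read threshold never converts a filtered cell to pass", {
  p <- rbind(make_parsed(c(S1 = 220)),
             within(make_parsed(c(S2 = 180)), cell_barcode <- "CCCCCC"),
             within(make_parsed(c(S3 = 260, S4 = 40)), cell_barcode <- "GGGGGG"))
  status_at <- function(thr) {
    r <- call_cell_scars(p, "male", min_reads = thr)
    stats::setNames(r$status == "pass", r$cell_barcode)
  }
  prev <- status_at(100)
  for (thr in c(150, 200, 250, 300)) {
    cur <- status_at(thr)
    expect_true(all(cur[prev == FALSE] == FALSE))
    prev <- cur
  }
})

test_that("UMI collapsing protects the allele fraction rule from PCR jackpots", {
  # second scar has many reads but all share one UMI: a PCR jackpot
  p <- rbind(make_parsed(c(MAJOR = 250)),
             data.frame(umi = "JACKPOT", cell_barcode = "AAAAAA",
                        scar = "MINOR", status = "ok")[rep(1, 50), ])
  expect_equal(call_cell_scars(p, "male", umi_collapse = TRUE)$status, "pass")
  expect_equal(call_cell_scars(p, "male", umi_collapse = FALSE)$filter_reason,
               "excess_alleles_male")
})

test_that("bulk barcode counting reproduces read counts per scar", {
  fqb <- synthesize_bulk_fastq(c(b000005 = 50, b000017 = 30, b000123 = 20), seed = 4)
  counts <- count_bulk_barcodes(fqb$left, fqb$right)
  expect_equal(counts$count, c(50, 30, 20))
  expect_setequal(counts$barcode, scar_sequence(c("b000005", "b000017", "b000123")))

  # all-germline input collapses to the single germline row
  fqg <- synthesize_bulk_fastq(c(germline = 40), seed = 4)
  cg <- count_bulk_barcodes(fqg$left, fqg$right)
  expect_equal(nrow(cg), 1)
  expect_true(cg$is_germline)

  expect_warning(empty <- count_bulk_barcodes(character(0), character(0)),
                 "no input reads")
  expect_equal(nrow(empty), 0)
})

test_that("no read is counted toward two cells or two scars", {
  cells <- data.frame(cell_id = c("c1", "c2"), barcode_1 = c("b000005", "b000009"))
  fq <- synthesize_fastq(cells, reads_per_cell = 20, error_rate = 0, seed = 8)
  parsed <- parse_read_pairs(fq$left, fq$right)
  # each read row has exactly one cell barcode and one scar
  expect_equal(nrow(parsed), length(fq$left))
  expect_equal(sum(table(parsed$cell_barcode)), nrow(parsed))
  calls <- call_cell_scars(parsed, "male", min_reads = 10)
  expect_equal(sum(calls$total_reads), nrow(parsed))
})
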