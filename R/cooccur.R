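#' Rare-barcode sets per sample
#'
#' A barcode is *rare* when it is observed no more than `threshold` times
#' in all samples together (default 2); because independently generated
#' collisions of rare repair outcomes are improbable, rare barcodes are the
#' informative ones for clonal sharing. `B_i`, the rare set of sample `i`,
#' contains every rare barcode with at least one count in that sample.
#'
#' @param table a [barcode_count_table()].
#' @param threshold maximum total count (or number of positive samples,
#'   see `count_mode`) for a barcode to qualify as rare.
#' @param count_mode `"reads"` (default) counts total read copies across
#'   all samples; `"samples"` counts the number of samples in which the
#'   barcode appears.
#' @return object of class `rare_barcode_sets`: list with `sets` (named
#'   list of barcode-id vectors per sample), `threshold`, `count_mode`.
#' @export
rare_barcode_sets <- function(table, threshold = 2, count_mode = c("reads", "samples")) {
  count_mode <- match.arg(count_mode)
  if (!inherits(table, "barcode_count_table")) {
    stop_invalid("table must be a barcode_count_table")
  }
  assert_count(threshold, "threshold")
  totals <- if (count_mode == "reads") {
    rowSums(table$counts)
  } else {
    rowSums(table$counts > 0)
  }
  rare <- totals >= 1 & totals <= threshold
  sets <- lapply(seq_len(ncol(table$counts)), function(i) {
    rownames(table$counts)[rare & table$counts[, i] > 0]
  })
  names(sets) <- colnames(table$counts)
  structure(list(sets = sets, threshold = threshold, count_mode = count_mode,
                 samples = table$samples),
            class = "rare_barcode_sets")
}

#' @export
print.rare_barcode_sets <- function(x, ...) {
  cat(sprintf("rare_barcode_sets: %d samples, threshold %d (%s); |B_i| median %d\n",
              length(x$sets), x$threshold, x$count_mode,
              as.integer(stats::median(lengths(x$sets)))))
  invisible(x)
}

#' Co-occurrence probability of rare barcodes
#'
#' Fraction of sample `i`'s rare barcodes that are also present in sample
#' `j`'s rare set: `P_ij = |B_i intersect B_j| / |B_i|`. `P_ii` is 1
#' whenever `B_i` is non-empty. When `B_i` is empty the value is
#' undefined (`NA`), to be excluded from downstream averages.
#'
#' @param sets a [rare_barcode_sets()] object.
#' @param i,j sample ids (names) or indices.
#' @return probability in `[0, 1]`, or `NA` when `B_i` is empty.
#' @export
cooccurrence_probability <- function(sets, i, j) {
  bi <- sets$sets[[i]]
  if (is.null(bi)) stop_invalid("unknown sample '%s'", as.character(i))
  if (!length(bi)) {
    message(sprintf("P_ij undefined: rare set of sample '%s' is empty", as.character(i)))
    return(NA_real_)
  }
  length(intersect(bi, sets$sets[[j]])) / length(bi)
}

#' Full matrix of rare-barcode co-occurrence probabilities
#'
#' @param sets a [rare_barcode_sets()] object.
#' @return numeric sample x sample matrix of `P_ij` (rows index `i`);
#'   rows with empty `B_i` are `NA`.
#' @export
cooccurrence_matrix <- function(sets) {
  ids <- names(sets$sets)
  sizes <- lengths(sets$sets)
  P <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in seq_along(ids)) {
    if (!sizes[a]) next
    P[a, ] <- vapply(seq_along(ids), function(b) {
      length(intersect(sets$sets[[a]], sets$sets[[b]])) / sizes[a]
    }, numeric(1))
  }
  P
}

#' Per-mouse enrichment of same-mouse rare-barcode co-occurrence
#'
#' Quantifies how much more often the rare barcodes of a mouse's cTEC
#' sample co-occur in the *same* mouse's mTEC sample (and vice versa) than
#' in samples of other animals. For mouse `m` with samples `m_cTEC` and
#' `m_mTEC`, each directional ratio divides `P(m_cTEC, m_mTEC)` by the
#' mean of `P(m_cTEC, j)` over all samples `j` from other animals (and
#' analogously with the mTEC sample as reference); the enrichment `E_m` is
#' the maximum of the two ratios. Values above 1 indicate a shared clonal
#' origin of the two compartments. Undefined `P` values (empty rare sets)
#' are excluded from the denominator mean; a zero denominator with a
#' positive numerator yields `Inf` (flagged, still usable by rank
#' statistics).
#'
#' @param sets a [rare_barcode_sets()] object (carries the sample sheet).
#' @param mouse mouse id.
#' @return one-row data frame: `mouse_id`, `E_m`, `ratio_cTEC_ref`,
#'   `ratio_mTEC_ref`, `status` (`"ok"`, `"undefined"`, `"infinite"`).
#' @export
enrichment_value <- function(sets, mouse) {
  P <- cooccurrence_matrix(sets)
  enrichment_from_matrix(P, sets$samples, mouse)
}

#' Enrichment value from a precomputed co-occurrence matrix
#'
#' The computational core of [enrichment_value()], operating directly on a
#' sample-by-sample matrix of co-occurrence probabilities (rows index the
#' reference sample `i` of `P_ij`). Useful when the `P` matrix is already
#' available or comes from elsewhere.
#'
#' @param P numeric sample x sample matrix with dimnames; `NA` entries are
#'   treated as undefined and excluded from denominator means.
#' @param samples sample sheet with `sample_id`, `mouse_id`,
#'   `compartment`.
#' @param mouse mouse id.
#' @return one-row data frame, see [enrichment_value()].
#' @export
enrichment_from_matrix <- function(P, samples, mouse) {
  s <- samples[samples$sample_id %in% rownames(P), ]
  own <- s$sample_id[s$mouse_id == mouse]
  comp <- s$compartment[s$mouse_id == mouse]
  if (length(own) < 2) {
    return(data.frame(mouse_id = mouse, E_m = NA_real_,
                      ratio_cTEC_ref = NA_real_, ratio_mTEC_ref = NA_real_,
                      status = "undefined", stringsAsFactors = FALSE))
  }
  ic <- own[comp == "cTEC"]
  im <- own[comp == "mTEC"]
  others <- s$sample_id[s$mouse_id != mouse]
  dir_ratio <- function(ref, target) {
    num <- P[ref, target]
    if (is.na(num)) return(NA_real_)
    dvals <- P[ref, others]
    dvals <- dvals[!is.na(dvals)]
    if (!length(dvals)) return(NA_real_)
    den <- mean(dvals)
    if (den == 0) {
      if (num == 0) NA_real_ else Inf
    } else {
      num / den
    }
  }
  r1 <- dir_ratio(ic, im)
  r2 <- dir_ratio(im, ic)
  e <- if (all(is.na(c(r1, r2)))) NA_real_ else max(r1, r2, na.rm = TRUE)
  status <- if (is.na(e)) "undefined" else if (is.infinite(e)) "infinite" else "ok"
  data.frame(mouse_id = mouse, E_m = e, ratio_cTEC_ref = r1, ratio_mTEC_ref = r2,
             status = status, stringsAsFactors = FALSE)
}

#' Enrichment values for all mice of a cohort table
#'
#' @param table a [barcode_count_table()].
#' @param threshold rarity threshold, see [rare_barcode_sets()].
#' @param count_mode see [rare_barcode_sets()].
#' @return data frame with one row per mouse, see [enrichment_value()].
#' @export
enrichment_values <- function(table, threshold = 2, count_mode = "reads") {
  sets <- rare_barcode_sets(table, threshold, count_mode)
  P <- cooccurrence_matrix(sets)
  mice <- unique(table$samples$mouse_id)
  out <- do.call(rbind, lapply(mice, function(m) {
    enrichment_from_matrix(P, table$samples, m)
  }))
  rownames(out) <- NULL
  out
}

#' One-sided rank-sum comparison of enrichment values between age groups
#'
#' Tests whether the enrichment values of the older group tend to be
#' larger than those of the younger group with a one-sided Wilcoxon
#' rank-sum test. For a combined sample size of at most 25 the exact
#' permutation distribution of the rank sum is used (computed by dynamic
#' programming over midranks, so ties are handled exactly); larger
#' samples fall back to the normal approximation with tie correction.
#' The reported P value is `P(W >= observed)` under random assignment.
#'
#' @param older,younger numeric vectors of enrichment values (at least 3
#'   defined values each; `NA` is dropped, `Inf` is allowed and ranks
#'   highest).
#' @return list with `statistic` (rank sum of the older group),
#'   `p.value` and `method`.
#' @export
compare_age_groups <- function(older, younger) {
  older <- older[!is.na(older)]
  younger <- younger[!is.na(younger)]
  if (length(older) < 3 || length(younger) < 3) {
    stop_invalid("each group needs at least 3 defined enrichment values")
  }
  n1 <- length(older)
  n <- n1 + length(younger)
  r <- rank(c(older, younger))
  W <- sum(r[seq_len(n1)])
  if (n <= 25) {
    p <- ranksum_exact_upper(r, n1, W)
    method <- "exact rank-sum (midrank permutation distribution)"
  } else {
    p <- stats::wilcox.test(older, younger, alternative = "greater",
                            exact = FALSE, correct = TRUE)$p.value
    method <- "Wilcoxon rank-sum, normal approximation with tie correction"
  }
  list(statistic = W, p.value = p, method = method)
}

# P(W >= w_obs) where W is the sum of n1 ranks drawn without replacement
# from the midrank vector r. Exact count by dynamic programming over
# doubled midranks (integers even with ties).
ranksum_exact_upper <- function(r, n1, w_obs) {
  ir <- as.integer(round(2 * r))
  smax <- sum(sort(ir, decreasing = TRUE)[seq_len(n1)])
  # f[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  f <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  f[1, 1] <- 1
  for (v in ir) {
    for (k in rev(seq_len(n1))) {
      cols <- seq_len(smax + 1 - v)
      f[k + 1, cols + v] <- f[k + 1, cols + v] + f[k, cols]
    }
  }
  total <- sum(f[n1 + 1, ])
  w2 <- as.integer(round(2 * w_obs))
  sum(f[n1 + 1, seq(w2 + 1, smax + 1)]) / total
}
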