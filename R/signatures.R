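#' Convert observed UMI counts to transcript counts
#'
#' With a UMI space of `K` distinct tags (4096 for 6-nt UMIs), several
#' transcripts can draw the same tag, so the number of observed distinct
#' UMIs `k` underestimates the number of transcripts. Under uniform random
#' tagging the expected relationship inverts in closed form to
#' `t = -K * log(1 - k / K)`. The conversion is monotone and convex, is
#' the identity at 0, and diverges at saturation; `k = K` is therefore
#' guarded as `k = K - 0.5`.
#'
#' @param k observed distinct UMI count(s), `0 <= k <= K`.
#' @param K UMI space size (default `4^6 = 4096`).
#' @return estimated transcript counts (numeric, vectorised).
#' @examples
#' umi_to_transcripts(c(0, 1, 2048), K = 4096)
#' @export
umi_to_transcripts <- function(k, K = 4096) {
  assert_count(K, "K")
  if (any(k < 0) || any(k > K)) {
    stop_invalid("k must satisfy 0 <= k <= K")
  }
  k <- ifelse(k == K, K - 0.5, k)
  -K * log(1 - k / K)
}

#' Quality-control filter for cells
#'
#' Applies the per-dataset cell filters: cells whose transcript total is
#' below `min_total` are discarded, as are cells in which the low-quality
#' marker gene (`Kcnq1ot1`) exceeds `max_marker_frac` of the
#' transcriptome. Retained cells are then normalised by downscaling: each
#' cell is downsampled without replacement (multivariate hypergeometric)
#' to the minimum retained total, which preserves the integer, count
#' nature of the data and within-cell proportions in expectation.
#'
#' @param counts genes x cells matrix of non-negative counts with row and
#'   column names.
#' @param min_total minimum transcript total per cell.
#' @param max_marker_frac maximum tolerated fraction of `marker_gene`
#'   transcripts (default 0.02; the rule is strict: fractions above the
#'   threshold are removed).
#' @param marker_gene low-quality marker gene id (default `"Kcnq1ot1"`;
#'   silently skipped when absent from the matrix).
#' @param normalize `"downsample"` (default), `"scale"` (divide by total
#'   and rescale to the minimum total; faster, non-integer) or `"none"`.
#' @param seed seed for the downsampling draws.
#' @return filtered (and normalised) matrix; attribute `"removed"` is a
#'   data frame of removed cells and reasons.
#' @export
qc_filter_cells <- function(counts, min_total, max_marker_frac = 0.02,
                            marker_gene = "Kcnq1ot1",
                            normalize = c("downsample", "scale", "none"),
                            seed = 1L) {
  normalize <- match.arg(normalize)
  assert_count(min_total, "min_total", min = 1)
  totals <- colSums(counts)
  low <- totals < min_total
  marker <- rep(FALSE, ncol(counts))
  if (marker_gene %in% rownames(counts)) {
    marker <- counts[marker_gene, ] / pmax(totals, 1) > max_marker_frac
  }
  removed <- data.frame(
    cell = colnames(counts)[low | marker],
    reason = ifelse(marker[low | marker], "marker_fraction", "low_total"),
    stringsAsFactors = FALSE
  )
  keep <- !(low | marker)
  if (!any(keep)) {
    stop_validation("all %d cells removed by QC (min_total=%d)", ncol(counts), min_total)
  }
  out <- counts[, keep, drop = FALSE]
  if (normalize == "downsample") {
    target <- min(colSums(out))
    out <- with_seed(seed, apply_downsample(out, target))
  } else if (normalize == "scale") {
    target <- min(colSums(out))
    out <- sweep(out, 2, colSums(out), "/") * target
  }
  attr(out, "removed") <- removed
  out
}

# Exact without-replacement downsampling of every column to `target`,
# sequential multivariate hypergeometric per cell.
apply_downsample <- function(counts, target) {
  out <- counts
  for (j in seq_len(ncol(counts))) {
    v <- counts[, j]
    tot <- sum(v)
    if (tot <= target) next
    left <- target
    rest <- tot
    nz <- which(v > 0)
    new <- integer(length(v))
    for (g in nz) {
      rest <- rest - v[g]
      x <- stats::rhyper(1, v[g], rest, left)
      new[g] <- x
      left <- left - x
      if (left == 0) break
    }
    out[, j] <- new
  }
  out
}

#' Quality-control filter for genes
#'
#' Removes the low-quality marker gene itself, every gene whose Pearson
#' correlation with it (across cells) exceeds `corr_threshold`,
#' mitochondrial genes, the barcoding locus `Hprt`, and any configured
#' exclusion patterns (immediate-early genes, predicted-gene identifiers,
#' and optionally `Malat1`/`Xist`/`Neat1`).
#'
#' @param counts genes x cells matrix.
#' @param marker_gene anchor gene for the correlation filter; when absent
#'   the correlation step is skipped with a warning.
#' @param corr_threshold Pearson correlation above which a gene is
#'   removed (default 0.65, strict).
#' @param exclude_patterns regular expressions for ids to drop.
#' @return filtered matrix; attribute `"removed"` names dropped genes.
#' @export
qc_filter_genes <- function(counts, marker_gene = "Kcnq1ot1",
                            corr_threshold = 0.65,
                            exclude_patterns = c("^mt-", "^Hprt$", "^Jun$",
                                                 "^Fos$", "^Gm\\d",
                                                 "^Malat1$", "^Xist$", "^Neat1$")) {
  drop <- rep(FALSE, nrow(counts))
  names(drop) <- rownames(counts)
  if (marker_gene %in% rownames(counts)) {
    anchor <- counts[marker_gene, ]
    if (stats::sd(anchor) > 0) {
      sds <- apply(counts, 1, stats::sd)
      cc <- rep(0, nrow(counts))
      ok <- sds > 0
      cc[ok] <- suppressWarnings(stats::cor(t(counts[ok, , drop = FALSE]), anchor))
      drop[cc > corr_threshold] <- TRUE
    }
    drop[marker_gene] <- TRUE
  } else {
    warning(sprintf("marker gene '%s' absent; correlation filter skipped", marker_gene))
  }
  for (pat in exclude_patterns) {
    drop[grepl(pat, rownames(counts))] <- TRUE
  }
  out <- counts[!drop, , drop = FALSE]
  attr(out, "removed") <- names(drop)[drop]
  out
}

# Quadratic mean-variance background: v(m) = m + a * m^2, least squares
# over genes with positive mean. Returns the dispersion coefficient a.
fit_dispersion_trend <- function(counts) {
  m <- rowMeans(counts)
  v <- apply(counts, 1, stats::var)
  use <- m > 0
  m <- m[use]
  v <- v[use]
  a <- sum(m^2 * (v - m)) / sum(m^4)
  max(a, 1e-6)
}

#' Negative-binomial differential expression between two cell groups
#'
#' For each gene, models the total count in each group as a negative
#' binomial whose mean follows the pooled per-cell mean and whose
#' variance follows a background mean-variance trend `v(m) = m + a m^2`
#' fitted by least squares across all genes of the matrix (so the
#' dispersion reflects dataset-wide technical plus biological
#' variability, not the per-gene sample variance). The focal group
#' (`group_b`) total is compared against its expectation under the pooled
#' mean; the two-sided P value doubles the smaller tail (capped at 1) and
#' is BH-adjusted across tested genes.
#'
#' @param counts genes x cells matrix (normalised counts).
#' @param group_a,group_b disjoint character vectors of column (cell) ids,
#'   each of at least 5 cells; `group_b` is the focal group whose
#'   deviation is tested, so positive fold changes mean higher in
#'   `group_b`.
#' @param pseudocount added to both group means for the fold change.
#' @return data frame: `gene`, `mean_a`, `mean_b`, `log2_fc`
#'   (positive = higher in `group_b`), `p`, `p_adj`.
#' @export
diffexp_nb <- function(counts, group_a, group_b, pseudocount = 0.1) {
  if (length(group_a) < 5 || length(group_b) < 5) {
    stop_invalid("both groups need at least 5 cells")
  }
  if (!all(c(group_a, group_b) %in% colnames(counts))) {
    stop_invalid("group cell ids must be columns of the count matrix")
  }
  a <- fit_dispersion_trend(counts)
  A <- counts[, group_a, drop = FALSE]
  B <- counts[, group_b, drop = FALSE]
  nA <- ncol(A)
  nB <- ncol(B)
  sA <- rowSums(A)
  sB <- rowSums(B)
  m0 <- (sA + sB) / (nA + nB)

  mu <- nB * m0
  size <- nB / a
  lo <- stats::pnbinom(sB, mu = mu, size = size)
  hi <- stats::pnbinom(sB - 1, mu = mu, size = size, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lo, hi))
  zero <- sA + sB == 0
  p[zero] <- 1
  mean_a <- sA / nA
  mean_b <- sB / nB
  lfc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  lfc[zero] <- 0
  data.frame(gene = rownames(counts), mean_a = mean_a, mean_b = mean_b,
             log2_fc = lfc, p = p, p_adj = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive population-specific gene sets
#'
#' One-vs-rest differential expression for each of the four TEC
#' populations over the configured cluster map; genes with adjusted
#' P below `max_p_adj` and log2 fold change strictly above `min_log2_fc`
#' enter the population's set. Predicted-gene identifiers (`Gm*`,
#' `*Rik`) and heat-shock family genes are excluded, and genes shared by
#' the early-progenitor and cTEC sets are removed from the
#' early-progenitor set (they mark the cortical lineage, not progenitor
#' state).
#'
#' @param counts genes x cells matrix (QC-filtered, normalised).
#' @param clusters named cluster label per cell (names = column ids).
#' @param cluster_map named list mapping population names (`EP`, `PP`,
#'   `cTEC`, `mTEC`) to cluster labels.
#' @param max_p_adj,min_log2_fc inclusion thresholds (defaults 0.01 and
#'   1; the fold-change rule is strict, so exactly 1 is excluded).
#' @param id_exclude_patterns identifier patterns never admitted to sets.
#' @param heatshock_patterns heat-shock families excluded from all sets.
#' @return object of class `gene_set_collection`: named list of gene id
#'   vectors for `EP`, `PP`, `cTEC`, `mTEC`.
#' @export
derive_gene_sets <- function(counts, clusters, cluster_map,
                             max_p_adj = 0.01, min_log2_fc = 1,
                             id_exclude_patterns = c("^Gm\\d", "Rik$"),
                             heatshock_patterns = c("^Hspa", "^Hspb", "^Dnaj")) {
  pops <- c("EP", "PP", "cTEC", "mTEC")
  if (!all(pops %in% names(cluster_map))) {
    stop_invalid("cluster_map must name all of %s", paste(pops, collapse = ", "))
  }
  if (is.null(names(clusters))) {
    stop_invalid("clusters must be named by cell id")
  }
  cells <- colnames(counts)
  clusters <- clusters[cells]
  sets <- lapply(pops, function(pop) {
    inside <- cells[clusters %in% cluster_map[[pop]]]
    outside <- setdiff(cells, inside)
    de <- diffexp_nb(counts, group_a = outside, group_b = inside)
    hits <- de$gene[de$p_adj < max_p_adj & de$log2_fc > min_log2_fc]
    for (pat in c(id_exclude_patterns, heatshock_patterns)) {
      hits <- hits[!grepl(pat, hits)]
    }
    hits
  })
  names(sets) <- pops
  sets$EP <- setdiff(sets$EP, sets$cTEC)
  if (!all(lengths(sets) > 0)) {
    warning(sprintf("empty gene set(s): %s",
                    paste(names(sets)[lengths(sets) == 0], collapse = ", ")))
  }
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:\n")
  for (nm in names(x)) cat(sprintf("  %-5s %d genes\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Population signature scores per cell
#'
#' Each cell's score for a population is the plain sum of its transcript
#' counts over the population's gene set.
#'
#' @param counts genes x cells matrix.
#' @param sets a [derive_gene_sets()] collection (or named list of gene
#'   id vectors).
#' @return data frame: `cell`, one numeric score column per set.
#' @export
score_cells <- function(counts, sets) {
  if (!all(lengths(sets) >= 0) || is.null(names(sets))) {
    stop_invalid("sets must be a named list of gene id vectors")
  }
  out <- data.frame(cell = colnames(counts), stringsAsFactors = FALSE)
  for (nm in names(sets)) {
    genes <- intersect(sets[[nm]], rownames(counts))
    out[[nm]] <- if (length(genes)) {
      colSums(counts[genes, , drop = FALSE])
    } else {
      rep(0, ncol(counts))
    }
  }
  out
}

#' Cluster coordinates in progenitor/mature ratio space
#'
#' Summarises each cluster of each dataset by two log2 ratios of
#' aggregated signature scores: early- vs postnatal-progenitor
#' (`EP/PP`) and cortical vs medullary (`C/M`), with a pseudocount
#' `eps` guarding empty aggregates. Coordinates are centred so that the
#' reference dataset's clusters average to the origin, making all other
#' datasets readable as displacements relative to the reference state;
#' the relative cell fraction of each cluster is reported for dot sizing.
#'
#' @param scores per-cell score table from [score_cells()] with columns
#'   `EP`, `PP`, `cTEC`, `mTEC`.
#' @param clusters cluster label per cell (aligned with `scores` rows).
#' @param datasets dataset id per cell (aligned with `scores` rows).
#' @param reference dataset id used for centring.
#' @param eps pseudocount (transcripts) added to every aggregate.
#' @param exclude_clusters cluster labels dropped before centring (e.g.
#'   thymic-nurse-cell-like or parathyroid-like clusters).
#' @return data frame: `dataset`, `cluster`, `n_cells`, `fraction`,
#'   `ep_pp_log2`, `c_m_log2` (centred), plus uncentred `.raw` columns.
#' @export
cluster_ratio_coordinates <- function(scores, clusters, datasets, reference,
                                      eps = 1, exclude_clusters = NULL) {
  if (!all(c("EP", "PP", "cTEC", "mTEC") %in% names(scores))) {
    stop_invalid("scores must have EP, PP, cTEC, mTEC columns")
  }
  if (!reference %in% datasets) {
    stop_invalid("reference dataset '%s' not present", as.character(reference))
  }
  keep <- !(clusters %in% exclude_clusters)
  df <- data.frame(dataset = datasets[keep], cluster = clusters[keep],
                   scores[keep, c("EP", "PP", "cTEC", "mTEC")],
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(df[, c("EP", "PP", "cTEC", "mTEC")],
                          by = df[, c("dataset", "cluster")], FUN = sum)
  sizes <- stats::aggregate(list(n_cells = rep(1, nrow(df))),
                            by = df[, c("dataset", "cluster")], FUN = sum)
  agg <- merge(agg, sizes, by = c("dataset", "cluster"))
  ds_tot <- tapply(agg$n_cells, agg$dataset, sum)
  agg$fraction <- agg$n_cells / as.numeric(ds_tot[agg$dataset])
  agg$ep_pp_log2.raw <- log2((agg$EP + eps) / (agg$PP + eps))
  agg$c_m_log2.raw <- log2((agg$cTEC + eps) / (agg$mTEC + eps))
  ref <- agg$dataset == reference
  agg$ep_pp_log2 <- agg$ep_pp_log2.raw - mean(agg$ep_pp_log2.raw[ref])
  agg$c_m_log2 <- agg$c_m_log2.raw - mean(agg$c_m_log2.raw[ref])
  zero <- with(agg, EP == 0 & PP == 0 | cTEC == 0 & mTEC == 0)
  agg$degenerate <- zero
  agg[order(agg$dataset, agg$cluster),
      c("dataset", "cluster", "n_cells", "fraction",
        "ep_pp_log2", "c_m_log2", "ep_pp_log2.raw", "c_m_log2.raw",
        "degenerate")]
}
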