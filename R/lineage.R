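#' Background barcode frequencies from bulk samples
#'
#' The background frequency `f_b` of barcode `b` is the unweighted mean of
#' its per-sample relative frequencies over all contributing bulk samples:
#' each sample's counts are first normalised to sum to 1, then averaged.
#' This estimates how often a barcode is generated and sampled in an
#' arbitrary TEC population, the reference against which single-cell
#' over-representation is judged.
#'
#' @param bulk a [barcode_count_table()] or a non-negative count matrix
#'   (barcodes x samples) with positive column sums.
#' @return object of class `background_frequencies`: list with `f` (named
#'   frequency vector), `n_samples` and `sample_ids`.
#' @export
background_frequency <- function(bulk) {
  counts <- if (inherits(bulk, "barcode_count_table")) bulk$counts else bulk
  if (is.null(dim(counts)) || nrow(counts) == 0 || ncol(counts) == 0) {
    stop_validation("empty bulk table: cannot derive background frequencies")
  }
  tot <- colSums(counts)
  if (any(tot <= 0)) {
    stop_validation("sample '%s' has non-positive total count",
                    colnames(counts)[tot <= 0][1])
  }
  freq <- sweep(counts, 2, tot, "/")
  structure(list(f = rowMeans(freq), n_samples = ncol(counts),
                 sample_ids = colnames(counts)),
            class = "background_frequencies")
}

#' @export
print.background_frequencies <- function(x, ...) {
  cat(sprintf("background_frequencies: %d barcodes over %d samples\n",
              length(x$f), x$n_samples))
  invisible(x)
}

#' Right tail of the binomial distribution
#'
#' `P(X >= c)` for `X ~ Binomial(C, f)`, the probability of observing at
#' least `c` cells with a barcode among `C` barcode-carrying cells when
#' the barcode's background frequency is `f`. Computed via the survival
#' function (`pbinom(..., lower.tail = FALSE)`) so that small tail
#' probabilities do not lose precision to cancellation.
#'
#' @param c observed count(s), `0 <= c <= C`.
#' @param C number of trials.
#' @param f success probability in `[0, 1]`.
#' @return tail probability, vectorised over the inputs.
#' @examples
#' binomial_right_tail(4, 4, 0.5)   # 0.5^4
#' binomial_right_tail(0, 100, 0.3) # 1: the whole mass
#' @export
binomial_right_tail <- function(c, C, f) {
  if (any(c < 0) || any(C < 0) || any(c > C)) {
    stop_invalid("need 0 <= c <= C")
  }
  if (any(f < 0) || any(f > 1)) {
    stop_invalid("f must be in [0, 1]")
  }
  stats::pbinom(c - 1, C, f, lower.tail = FALSE)
}

canonical_barcode_key <- function(b1, b2) {
  ifelse(is.na(b2) | b2 == "", b1,
         paste(pmin(b1, b2), pmax(b1, b2), sep = "+"))
}

#' Test barcodes for over-representation in single-cell populations
#'
#' For every barcode (or barcode pair) observed in a single-cell dataset
#' and every TEC population, computes the right-tailed binomial
#' probability of seeing at least the observed number of cells `c_b,i`
#' among the population's `C_i` barcode-carrying cells, with success
#' probability equal to the bulk background frequency `f_b` (for barcode
#' pairs, the product of the two singleton frequencies). P values are
#' Benjamini-Hochberg corrected jointly across all (barcode, population)
#' tests of the dataset; a barcode is called significantly
#' over-represented at adjusted P below `alpha`.
#'
#' Barcodes seen in single cells but absent from every bulk sample have no
#' defined background and are excluded from testing (reported in the
#' `"bulk_unseen"` attribute).
#'
#' @param clones data frame with columns `cell_id`, `barcode_1`,
#'   `barcode_2` (NA for single-allele cells) and `population`.
#' @param bg a [background_frequency()] object.
#' @param alpha significance threshold on the adjusted P value
#'   (default 0.001).
#' @param family `"joint"` (default) adjusts over all barcode x population
#'   tests of the dataset; `"per_population"` adjusts within each
#'   population separately (sensitivity analysis).
#' @return data frame of class `lineage_call_matrix`: `barcode`,
#'   `population`, `cells`, `total_cells`, `background_f`, `p`, `p_adj`,
#'   `neg_log10_p_adj`, `significant`. Attributes: `"bulk_unseen"`
#'   (excluded barcode keys), `"alpha"`.
#' @export
barcode_population_tests <- function(clones, bg, alpha = 0.001,
                                     family = c("joint", "per_population")) {
  family <- match.arg(family)
  if (!inherits(bg, "background_frequencies")) {
    stop_invalid("bg must be a background_frequencies object")
  }
  assert_fraction(alpha, "alpha")
  req <- c("cell_id", "barcode_1", "population")
  if (!all(req %in% names(clones))) {
    stop_invalid("clones must have columns %s", paste(req, collapse = ", "))
  }
  b2 <- if ("barcode_2" %in% names(clones)) clones$barcode_2 else NA_character_
  carrying <- !is.na(clones$barcode_1) & clones$barcode_1 != ""
  cl <- clones[carrying, , drop = FALSE]
  b2 <- b2[carrying]
  key <- canonical_barcode_key(cl$barcode_1, b2)

  # background per key; pairs multiply their singleton frequencies
  f_of <- function(k) {
    parts <- strsplit(k, "+", fixed = TRUE)
    vapply(parts, function(p) {
      fv <- bg$f[p]
      if (anyNA(fv) || any(fv == 0)) NA_real_ else prod(fv)
    }, numeric(1))
  }
  keys <- sort(unique(key))
  fk <- f_of(keys)
  unseen <- keys[is.na(fk)]
  if (length(unseen)) {
    warning(sprintf("%d barcode key(s) absent from bulk background excluded from testing",
                    length(unseen)))
  }
  keep_cell <- key %in% keys[!is.na(fk)]
  pops <- sort(unique(cl$population))
  totals <- table(factor(cl$population, levels = pops))  # all barcode-carrying cells
  cl2 <- cl[keep_cell, , drop = FALSE]
  key2 <- key[keep_cell]
  counts <- table(factor(key2, levels = keys[!is.na(fk)]),
                  factor(cl2$population, levels = pops))

  grid <- expand.grid(barcode = rownames(counts), population = pops,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$cells <- as.integer(counts[cbind(grid$barcode, grid$population)])
  grid$total_cells <- as.integer(totals[grid$population])
  grid$background_f <- fk[match(grid$barcode, keys)]
  grid$p <- binomial_right_tail(grid$cells, grid$total_cells, grid$background_f)
  grid$p_adj <- if (family == "joint") {
    stats::p.adjust(grid$p, method = "BH")
  } else {
    stats::ave(grid$p, grid$population,
               FUN = function(p) stats::p.adjust(p, method = "BH"))
  }
  grid$neg_log10_p_adj <- -log10(grid$p_adj)
  grid$significant <- grid$p_adj < alpha
  attr(grid, "bulk_unseen") <- unseen
  attr(grid, "alpha") <- alpha
  class(grid) <- c("lineage_call_matrix", class(grid))
  grid
}

#' Classify barcodes by their significance pattern across populations
#'
#' Deterministic interpretation of a lineage call matrix: which
#' populations a barcode is significantly over-represented in determines
#' its clonal behaviour label.
#'
#' \describe{
#'   \item{early/postnatal bipotent}{significant in a progenitor
#'     population (EP, or PP without EP) and in both mature
#'     compartments.}
#'   \item{mature bipotent}{both mature compartments, no progenitor.}
#'   \item{early/postnatal cTEC- or mTEC-biased}{a progenitor population
#'     plus exactly one mature compartment.}
#'   \item{cTEC-/mTEC-private}{exactly one mature compartment, no
#'     progenitor.}
#'   \item{dormant}{progenitor population(s) only: a clone with no
#'     significant mature progeny.}
#'   \item{none}{no significant population.}
#' }
#'
#' @param calls a `lineage_call_matrix` from
#'   [barcode_population_tests()].
#' @param ep,pp,ctec,mtec population labels used in `calls`.
#' @return data frame: `barcode`, the four significance flags, `pattern`.
#' @export
classify_barcode_patterns <- function(calls, ep = "EP", pp = "PP",
                                      ctec = "cTEC", mtec = "mTEC") {
  flag <- function(pop) {
    x <- calls[calls$population == pop, ]
    stats::setNames(x$significant, x$barcode)
  }
  barcodes <- sort(unique(calls$barcode))
  g <- function(v) {
    out <- stats::setNames(rep(FALSE, length(barcodes)), barcodes)
    out[names(v)] <- v
    out
  }
  fe <- g(flag(ep)); fp <- g(flag(pp)); fc <- g(flag(ctec)); fm <- g(flag(mtec))
  prog <- fe | fp
  prefix <- ifelse(fe, "early", "postnatal")
  pattern <- rep("none", length(barcodes))
  pattern[prog & fc & fm] <- paste(prefix[prog & fc & fm], "bipotent")
  pattern[!prog & fc & fm] <- "mature bipotent"
  pattern[prog & fc & !fm] <- paste(prefix[prog & fc & !fm], "cTEC-biased")
  pattern[prog & !fc & fm] <- paste(prefix[prog & !fc & fm], "mTEC-biased")
  pattern[!prog & fc & !fm] <- "cTEC-private"
  pattern[!prog & !fc & fm] <- "mTEC-private"
  pattern[prog & !fc & !fm] <- "dormant"
  data.frame(barcode = barcodes, EP = fe, PP = fp, cTEC = fc, mTEC = fm,
             pattern = pattern, row.names = NULL, stringsAsFactors = FALSE)
}
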