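#' Barcode-generation (repair outcome) distribution
#'
#' Probability of each distinct Cas9 repair outcome under a truncated
#' power-law (Zipf-like) model: outcome `k` has probability proportional to
#' `k^-outcome_skew`. A skew of 0 gives the uniform distribution; positive
#' skew concentrates mass on the first outcomes, reproducing the monotone
#' rank-frequency profile of scar barcodes, in which frequently generated
#' barcodes recur independently in different mice while tail outcomes are
#' effectively private. The distribution is a deterministic function of its
#' parameters and is shared by all mice of a cohort.
#'
#' @param n_outcomes number of distinct repair outcomes (>= 2).
#' @param outcome_skew power-law exponent (>= 0).
#' @param seed accepted for interface symmetry with the other generator
#'   operations; the closed-form distribution involves no randomness.
#' @return numeric probability vector of length `n_outcomes`, decreasing,
#'   summing to 1, named by barcode id.
#' @examples
#' p <- draw_outcome_distribution(2000, 1.1)
#' head(p)
#' @export
draw_outcome_distribution <- function(n_outcomes, outcome_skew, seed = NULL) {
  assert_count(n_outcomes, "n_outcomes", min = 2)
  assert_number(outcome_skew, "outcome_skew", min = 0)
  p <- seq_len(n_outcomes)^(-outcome_skew)
  p <- p / sum(p)
  names(p) <- barcode_id(seq_len(n_outcomes))
  p
}

barcode_id <- function(k) sprintf("b%06d", k)

# Per-mouse ground truth: one row per founder clone.
sim_mouse_truth <- function(config, probs, mouse_id) {
  f <- config$founders_per_mouse
  bc <- sample.int(config$n_outcomes, f, replace = TRUE, prob = probs)
  bc2 <- if (config$sex == "female") {
    sample.int(config$n_outcomes, f, replace = TRUE, prob = probs)
  } else {
    rep(NA_integer_, f)
  }
  size <- pmax(1L, as.integer(round(stats::rlnorm(
    f, config$clone_size_log_mean, config$clone_size_log_sd))))
  is_ep <- stats::runif(f) < config$frac_early_progenitor
  n_prog <- stats::rbinom(f, size, config$frac_progenitor_state)
  mature <- size - n_prog
  p_ctec <- ifelse(is_ep, config$bias_early_to_cTEC, 1 - config$bias_postnatal_to_mTEC)
  n_ctec <- stats::rbinom(f, mature, p_ctec)
  data.frame(
    mouse_id = mouse_id,
    founder = sprintf("%s_f%04d", mouse_id, seq_len(f)),
    barcode = barcode_id(bc),
    barcode_2 = ifelse(is.na(bc2), NA_character_, barcode_id(bc2)),
    progenitor_type = ifelse(is_ep, "EP", "PP"),
    clone_size = size,
    n_EP = ifelse(is_ep, n_prog, 0L),
    n_PP = ifelse(is_ep, 0L, n_prog),
    n_cTEC = n_ctec,
    n_mTEC = mature - n_ctec,
    stringsAsFactors = FALSE
  )
}

# Cell abundance of each barcode in one compartment of one mouse.
# For female mice both alleles of a clone are counted at the DNA level.
compartment_abundance <- function(truth_m, column) {
  n <- truth_m[[column]]
  bc <- truth_m$barcode
  if (any(!is.na(truth_m$barcode_2))) {
    bc <- c(bc, truth_m$barcode_2)
    n <- c(n, n)
    keep <- !is.na(bc)
    bc <- bc[keep]
    n <- n[keep]
  }
  a <- rowsum(as.numeric(n), bc)
  stats::setNames(a[, 1], rownames(a))
}

sample_bulk_column <- function(abundance, reads) {
  pos <- abundance[abundance > 0]
  draw <- stats::rmultinom(1, reads, pos)[, 1]
  draw[draw > 0]
}

#' Simulate a clonally barcoded mouse cohort
#'
#' Generates a full synthetic cohort with known ground truth: per mouse,
#' `founders_per_mouse` founder cells each draw a barcode from the shared
#' outcome distribution (two independent barcodes per founder in females),
#' expand into a log-normally sized clone whose mature descendants are
#' allocated to the cTEC or mTEC compartment according to the founder's
#' progenitor type, and are then read out by (i) bulk amplicon sequencing
#' of each sorted compartment (multinomial read sampling at
#' `bulk_reads_per_sample`) and (ii) single-cell datasets that sample cells
#' uniformly and attach population labels, per-cell barcode calls and,
#' optionally, a negative-binomial expression matrix over a panel with four
#' planted population signatures.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `clonescar_cohort` with elements
#' \describe{
#'   \item{truth}{data frame, one row per founder clone: barcode(s),
#'     progenitor type, clone size and per-compartment descendant counts.}
#'   \item{bulk}{a [barcode_count_table()] with one cTEC and one mTEC
#'     sample per mouse.}
#'   \item{sc}{list of single-cell datasets (first `n_sc_datasets` mice),
#'     each with a `clones` data frame (`cell_id`, `barcode_1`,
#'     `barcode_2`, `population`, `founder`) and a genes x cells `counts`
#'     matrix when `make_counts` is set.}
#'   \item{outcome_probs}{the shared outcome distribution.}
#' }
#' @examples
#' cohort <- simulate_cohort(sim_config(n_mice = 2, founders_per_mouse = 50,
#'                                      bulk_reads_per_sample = 2000,
#'                                      cells_per_sc_dataset = 50,
#'                                      n_sc_datasets = 1, seed = 7))
#' cohort$bulk
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_invalid("config must be a sim_config object")
  }
  probs <- draw_outcome_distribution(config$n_outcomes, config$outcome_skew)
  n <- config$n_mice
  seeds <- derive_seeds(config$seed, 3L * n + 1L)
  mouse_ids <- sprintf("m%02d", seq_len(n))

  truth <- do.call(rbind, lapply(seq_len(n), function(m) {
    with_seed(seeds[m], sim_mouse_truth(config, probs, mouse_ids[m]))
  }))

  cols <- vector("list", 2L * n)
  sample_ids <- character(2L * n)
  meta <- vector("list", 2L * n)
  for (m in seq_len(n)) {
    tm <- truth[truth$mouse_id == mouse_ids[m], ]
    with_seed(seeds[n + m], {
      cols[[2 * m - 1]] <- sample_bulk_column(
        compartment_abundance(tm, "n_cTEC"), config$bulk_reads_per_sample)
      cols[[2 * m]] <- sample_bulk_column(
        compartment_abundance(tm, "n_mTEC"), config$bulk_reads_per_sample)
    })
    sample_ids[2 * m - 1] <- sprintf("%s_cTEC", mouse_ids[m])
    sample_ids[2 * m] <- sprintf("%s_mTEC", mouse_ids[m])
    meta[[2 * m - 1]] <- data.frame(sample_id = sample_ids[2 * m - 1],
                                    mouse_id = mouse_ids[m], compartment = "cTEC",
                                    age_group = config$age_group, sex = config$sex)
    meta[[2 * m]] <- data.frame(sample_id = sample_ids[2 * m],
                                mouse_id = mouse_ids[m], compartment = "mTEC",
                                age_group = config$age_group, sex = config$sex)
  }
  bulk <- assemble_count_table(cols, sample_ids, do.call(rbind, meta))

  sc <- lapply(seq_len(config$n_sc_datasets), function(m) {
    tm <- truth[truth$mouse_id == mouse_ids[m], ]
    with_seed(seeds[2L * n + m], sim_sc_dataset(tm, config, mouse_ids[m]))
  })
  names(sc) <- mouse_ids[seq_len(config$n_sc_datasets)]

  structure(list(config = config, truth = truth, bulk = bulk, sc = sc,
                 outcome_probs = probs, null = FALSE),
            class = "clonescar_cohort")
}

assemble_count_table <- function(cols, sample_ids, meta) {
  all_bc <- sort(unique(unlist(lapply(cols, names))))
  counts <- matrix(0L, length(all_bc), length(cols),
                   dimnames = list(all_bc, sample_ids))
  for (i in seq_along(cols)) {
    counts[names(cols[[i]]), i] <- as.integer(cols[[i]])
  }
  barcode_count_table(counts, meta)
}

# One single-cell dataset: uniform sampling of cells from the mouse's pool,
# population labels from the cell state, barcode exposure per X-inactivation.
sim_sc_dataset <- function(truth_m, config, mouse_id) {
  states <- c("EP", "PP", "cTEC", "mTEC")
  pool <- as.vector(t(as.matrix(truth_m[, c("n_EP", "n_PP", "n_cTEC", "n_mTEC")])))
  total <- sum(pool)
  n_cells <- min(config$cells_per_sc_dataset, total)
  idx <- sort(sample(total, n_cells))
  cum <- cumsum(pool)
  cat_idx <- findInterval(idx - 0.5, c(0, cum))
  founder_row <- (cat_idx - 1L) %/% 4L + 1L
  population <- states[(cat_idx - 1L) %% 4L + 1L]

  b1 <- truth_m$barcode[founder_row]
  b2 <- rep(NA_character_, n_cells)
  if (config$sex == "female") {
    alt <- truth_m$barcode_2[founder_row]
    both <- stats::runif(n_cells) < config$relaxed_xi_prob
    use_alt <- stats::runif(n_cells) < 0.5
    b2[both] <- alt[both]
    swap <- !both & use_alt
    b1[swap] <- alt[swap]
  }
  ord <- sample(n_cells)
  clones <- data.frame(
    cell_id = sprintf("%s_c%04d", mouse_id, seq_len(n_cells)),
    barcode_1 = b1[ord],
    barcode_2 = b2[ord],
    population = population[ord],
    founder = truth_m$founder[founder_row][ord],
    stringsAsFactors = FALSE
  )
  counts <- NULL
  if (config$make_counts) {
    counts <- sim_count_matrix(clones$population, config, clones$cell_id)
  }
  list(clones = clones, counts = counts)
}

#' Simulated expression gene panel
#'
#' The fixed panel used for simulated count matrices: four disjoint
#' signature sets of 50 genes (early progenitor, postnatal progenitor,
#' cTEC, mTEC) plus 800 background genes. The background includes a small
#' group of conventionally named QC genes (`Kcnq1ot1`, `Hprt`,
#' mitochondrial genes, `Jun`, `Fos`, `Malat1`, `Xist`, and a few `Gm`/
#' `Rik`-style predicted-gene identifiers) so that the quality-control and
#' identifier-exclusion rules of the signature module can be exercised
#' end to end on synthetic data.
#'
#' @return list with `genes` (character vector of panel gene names) and
#'   `sets` (named list of the four planted signature gene sets).
#' @export
sim_gene_panel <- function() {
  sets <- list(
    EP = sprintf("EpSig%02d", 1:50),
    PP = sprintf("PpSig%02d", 1:50),
    cTEC = sprintf("CtSig%02d", 1:50),
    mTEC = sprintf("MtSig%02d", 1:50)
  )
  qc <- c("Kcnq1ot1", "Hprt", "mt-Co1", "mt-Nd1", "Jun", "Fos",
          "Malat1", "Xist", "Gm10076", "Gm42418", "2900097C17Rik", "5430405H02Rik")
  bg <- c(qc, sprintf("Bg%03d", seq_len(800 - length(qc))))
  list(genes = c(unlist(sets, use.names = FALSE), bg), sets = sets)
}

# NB counts for one dataset; per-gene base means are a deterministic
# function of the panel (fixed across cohorts), population signature genes
# are elevated sc_signal_fold-fold in cells of that population.
sim_count_matrix <- function(populations, config, cell_ids) {
  panel <- sim_gene_panel()
  g <- length(panel$genes)
  base <- with_seed(760817L, stats::rlnorm(g, meanlog = 0, sdlog = 1))
  names(base) <- panel$genes
  base["Kcnq1ot1"] <- 0.6  # modest expression; QC fraction rule needs real mass
  mu <- matrix(base, nrow = g, ncol = length(populations),
               dimnames = list(panel$genes, cell_ids))
  for (pop in names(panel$sets)) {
    cells <- populations == pop
    if (any(cells)) {
      mu[panel$sets[[pop]], cells] <- mu[panel$sets[[pop]], cells] * config$sc_signal_fold
    }
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$sc_dispersion),
                   nrow = g, dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a null cohort with sample-exchangeable barcode allocation
#'
#' Generates clones exactly as [simulate_cohort()] but severs the link
#' between clone identity and compartment/sample at readout: all clones of
#' the cohort are pooled, every bulk sample draws its reads from the pooled
#' barcode abundance, single-cell datasets draw cell barcodes from the same
#' pool, and population labels are assigned independently of barcode. All
#' samples are therefore exchangeable, so rare-barcode co-occurrence is the
#' same within and across mice (enrichment values scatter around 1) and no
#' barcode is over-represented in any population beyond sampling noise.
#' This is the calibration null for type-I-error tests of the co-occurrence
#' and lineage statistics.
#'
#' @param config a [sim_config()] object.
#' @return a `clonescar_cohort` object (element `null` set to `TRUE`).
#' @seealso [simulate_cohort()]
#' @export
simulate_null_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_invalid("config must be a sim_config object")
  }
  probs <- draw_outcome_distribution(config$n_outcomes, config$outcome_skew)
  n <- config$n_mice
  seeds <- derive_seeds(config$seed, 3L * n + 1L)
  mouse_ids <- sprintf("m%02d", seq_len(n))

  truth <- do.call(rbind, lapply(seq_len(n), function(m) {
    with_seed(seeds[m], sim_mouse_truth(config, probs, mouse_ids[m]))
  }))

  # pooled cohort abundance: compartment allocation independent of barcode
  pool_df <- truth
  pool_df$n_all <- truth$clone_size
  pool <- compartment_abundance(pool_df, "n_all")
  pop_prop <- c(EP = sum(truth$n_EP), PP = sum(truth$n_PP),
                cTEC = sum(truth$n_cTEC), mTEC = sum(truth$n_mTEC))
  pop_prop <- pop_prop / sum(pop_prop)

  cols <- vector("list", 2L * n)
  sample_ids <- character(2L * n)
  meta <- vector("list", 2L * n)
  for (m in seq_len(n)) {
    with_seed(seeds[n + m], {
      cols[[2 * m - 1]] <- sample_bulk_column(pool, config$bulk_reads_per_sample)
      cols[[2 * m]] <- sample_bulk_column(pool, config$bulk_reads_per_sample)
    })
    sample_ids[2 * m - 1] <- sprintf("%s_cTEC", mouse_ids[m])
    sample_ids[2 * m] <- sprintf("%s_mTEC", mouse_ids[m])
    meta[[2 * m - 1]] <- data.frame(sample_id = sample_ids[2 * m - 1],
                                    mouse_id = mouse_ids[m], compartment = "cTEC",
                                    age_group = config$age_group, sex = config$sex)
    meta[[2 * m]] <- data.frame(sample_id = sample_ids[2 * m],
                                mouse_id = mouse_ids[m], compartment = "mTEC",
                                age_group = config$age_group, sex = config$sex)
  }
  bulk <- assemble_count_table(cols, sample_ids, do.call(rbind, meta))

  sc <- lapply(seq_len(config$n_sc_datasets), function(m) {
    with_seed(seeds[2L * n + m], {
      n_cells <- config$cells_per_sc_dataset
      bc <- sample(names(pool), n_cells, replace = TRUE, prob = pool)
      population <- sample(names(pop_prop), n_cells, replace = TRUE, prob = pop_prop)
      clones <- data.frame(
        cell_id = sprintf("%s_c%04d", mouse_ids[m], seq_len(n_cells)),
        barcode_1 = bc,
        barcode_2 = NA_character_,
        population = population,
        founder = NA_character_,
        stringsAsFactors = FALSE
      )
      counts <- if (config$make_counts) {
        sim_count_matrix(clones$population, config, clones$cell_id)
      }
      list(clones = clones, counts = counts)
    })
  })
  names(sc) <- mouse_ids[seq_len(config$n_sc_datasets)]

  structure(list(config = config, truth = truth, bulk = bulk, sc = sc,
                 outcome_probs = probs, null = TRUE),
            class = "clonescar_cohort")
}

#' @export
print.clonescar_cohort <- function(x, ...) {
  cat(sprintf("clonescar_cohort (%s): %d mice, %d founders/mouse, %d sc dataset(s)\n",
              if (x$null) "null" else "fate-biased",
              x$config$n_mice, x$config$founders_per_mouse, length(x$sc)))
  print(x$bulk)
  invisible(x)
}
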