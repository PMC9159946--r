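# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small but fully featured biased cohort for unit tests.
fx_small_cohort <- function() {
  fixture("small_cohort", function() {
    simulate_cohort(sim_config(n_mice = 4, founders_per_mouse = 300,
                               n_outcomes = 2000, bulk_reads_per_sample = 20000,
                               cells_per_sc_dataset = 600, n_sc_datasets = 2,
                               seed = 11))
  })
}

# Study-scale biased cohort with deep single-cell sampling (recovery tests).
fx_recovery_cohort <- function() {
  fixture("recovery_cohort", function() {
    simulate_cohort(sim_config(seed = 42, cells_per_sc_dataset = 2000))
  })
}

# A hand-sized barcode count table: 2 mice x 2 compartments.
fx_tiny_table <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(5L, 3L, 1L, 0L,
                       0L, 2L, 1L, 4L,
                       1L, 1L, 0L, 0L,
                       2L, 0L, 0L, 2L), nrow = 4, byrow = TRUE,
                     dimnames = list(paste0("bc", 1:4),
                                     c("m1_c", "m1_m", "m2_c", "m2_m")))
  }
  samples <- data.frame(sample_id = c("m1_c", "m1_m", "m2_c", "m2_m"),
                        mouse_id = rep(c("m1", "m2"), each = 2),
                        compartment = rep(c("cTEC", "mTEC"), 2),
                        age_group = "P14", sex = "male",
                        stringsAsFactors = FALSE)
  barcode_count_table(counts, samples[samples$sample_id %in% colnames(counts), ])
}

# Independent brute-force re-implementation of rare sets / P_ij / E_m used
# as the oracle against the package's vectorised versions.
oracle_rare_sets <- function(counts, threshold = 2) {
  sets <- list()
  for (s in colnames(counts)) {
    members <- character(0)
    for (b in rownames(counts)) {
      total <- 0
      for (s2 in colnames(counts)) total <- total + counts[b, s2]
      if (total >= 1 && total <= threshold && counts[b, s] > 0) {
        members <- c(members, b)
      }
    }
    sets[[s]] <- members
  }
  sets
}

oracle_P <- function(sets, i, j) {
  if (length(sets[[i]]) == 0) return(NA_real_)
  sum(sets[[i]] %in% sets[[j]]) / length(sets[[i]])
}

oracle_Em <- function(sets, samples, mouse) {
  ic <- samples$sample_id[samples$mouse_id == mouse & samples$compartment == "cTEC"]
  im <- samples$sample_id[samples$mouse_id == mouse & samples$compartment == "mTEC"]
  others <- samples$sample_id[samples$mouse_id != mouse]
  ratio <- function(ref, tgt) {
    num <- oracle_P(sets, ref, tgt)
    if (is.na(num)) return(NA_real_)
    dv <- c()
    for (j in others) {
      pj <- oracle_P(sets, ref, j)
      if (!is.na(pj)) dv <- c(dv, pj)
    }
    if (!length(dv)) return(NA_real_)
    den <- mean(dv)
    if (den == 0) { if (num == 0) NA_real_ else Inf } else num / den
  }
  r <- c(ratio(ic, im), ratio(im, ic))
  if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
}

# Random small count tables with a realistic mix of rare and common barcodes.
random_fixture_table <- function(n_mice = 3, n_barcodes = 30) {
  ids <- paste0("b", seq_len(n_barcodes))
  samples <- data.frame(
    sample_id = as.vector(outer(c("c", "m"), paste0("ms", seq_len(n_mice)),
                                function(a, b) paste0(b, "_", a))),
    mouse_id = rep(paste0("ms", seq_len(n_mice)), each = 2),
    compartment = rep(c("cTEC", "mTEC"), n_mice),
    age_group = "P14", sex = "male", stringsAsFactors = FALSE)
  repeat {
    counts <- matrix(stats::rpois(n_barcodes * 2 * n_mice, 0.6),
                     nrow = n_barcodes,
                     dimnames = list(ids, samples$sample_id))
    counts[1:3, ] <- counts[1:3, ] + 5L  # a few common barcodes
    storage.mode(counts) <- "integer"
    if (all(colSums(counts) > 0)) break
  }
  barcode_count_table(counts, samples)
}
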