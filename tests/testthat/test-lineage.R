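test_that("background frequencies average per-sample relative frequencies", {
  counts <- matrix(c(1L, 3L,
                     9L, 7L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("b", "other"), c("s1", "s2")))
  bg <- background_frequency(counts)
  expect_equal(unname(bg$f["b"]), mean(c(0.1, 0.3)))
  expect_equal(sum(bg$f), 1)

  # a barcode present in 1 of 33 samples at 33% has f = 1%
  m <- matrix(0L, 2, 33, dimnames = list(c("b", "o"), paste0("s", 1:33)))
  m["o", ] <- 100L
  m["b", 1] <- 49L  # 49/149 = 0.33 within sample 1
  m["o", 1] <- 100L
  bg2 <- background_frequency(m)
  expect_equal(unname(bg2$f["b"]), (49 / 149) / 33, tolerance = 1e-12)

  expect_error(background_frequency(matrix(numeric(0), 0, 0)),
               class = "clonescar_validation_error")
})

test_that("bulk frequencies recover the generating outcome distribution", {
  # with equal clone sizes, barcode abundance is proportional to the
  # generation probability, so f recovers it up to multinomial noise
  co <- simulate_cohort(sim_config(n_mice = 4, founders_per_mouse = 2000,
                                   n_outcomes = 500, clone_size_log_mean = 2,
                                   clone_size_log_sd = 0,
                                   bulk_reads_per_sample = 50000,
                                   n_sc_datasets = 0, seed = 23))
  bg <- background_frequency(co$bulk)
  truth_p <- co$outcome_probs[names(bg$f)]
  common <- names(bg$f)[bg$f > 0.002]
  expect_gt(length(common), 50)
  expect_gt(stats::cor(bg$f[common], truth_p[common], method = "spearman"), 0.8)
})

test_that("binomial right tail matches enumeration and is monotone", {
  expect_equal(binomial_right_tail(0, 10, 0.3), 1)
  expect_equal(binomial_right_tail(4, 4, 0.5), 0.0625)
  # enumeration oracle for c = 3, C = 10, f = 0.1
  oracle <- sum(choose(10, 3:10) * 0.1^(3:10) * 0.9^(10 - (3:10)))
  expect_equal(binomial_right_tail(3, 10, 0.1), oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 4), 0.0702)

  # monotone decreasing in c, increasing in f
  p_by_c <- binomial_right_tail(0:10, 10, 0.2)
  expect_true(all(diff(p_by_c) < 0))
  fs <- seq(0.05, 0.95, by = 0.05)
  p_by_f <- binomial_right_tail(3, 10, fs)
  expect_true(all(diff(p_by_f) > 0))

  expect_error(binomial_right_tail(5, 4, 0.5), class = "clonescar_invalid_config")
  expect_error(binomial_right_tail(1, 4, 1.5), class = "clonescar_invalid_config")
})

make_bg <- function(f) {
  structure(list(f = f, n_samples = 10, sample_ids = paste0("s", 1:10)),
            class = "background_frequencies")
}

test_that("population tests follow the binomial model with joint BH correction", {
  bg <- make_bg(c(common = 0.5, rare = 0.001, pairA = 0.01, pairB = 0.02))
  clones <- data.frame(
    cell_id = sprintf("c%03d", 1:120),
    barcode_1 = c(rep("common", 58), rep("rare", 30), rep("pairA", 32)),
    barcode_2 = c(rep(NA, 88), rep("pairB", 32)),
    population = rep(c("cTEC", "mTEC"), 60),
    stringsAsFactors = FALSE)
  calls <- barcode_population_tests(clones, bg)

  # a barcode at its expected frequency is not significant
  common_row <- calls[calls$barcode == "common" & calls$population == "cTEC", ]
  expect_gt(common_row$p_adj, 0.5)
  expect_false(common_row$significant)

  # raw P equals the binomial right tail with C_i = barcode-carrying cells
  expect_equal(common_row$p,
               binomial_right_tail(common_row$cells, 60, 0.5))

  # pair background is the product of the singleton frequencies
  pair_row <- calls[calls$barcode == "pairA+pairB" & calls$population == "cTEC", ]
  expect_equal(pair_row$background_f, 0.01 * 0.02)

  # a rare barcode carried by a quarter of the cells is flagged
  rare_row <- calls[calls$barcode == "rare" & calls$population == "cTEC", ]
  expect_true(rare_row$significant)

  # BH never lowers a P value and preserves order
  expect_true(all(calls$p_adj >= calls$p - 1e-15))
  o <- order(calls$p)
  expect_true(all(diff(calls$p_adj[o]) >= -1e-15))
  expect_equal(calls$significant, calls$p_adj < 0.001)
})

test_that("BH adjustment equals the textbook step-up rule", {
  set.seed(7)
  bg <- make_bg(stats::setNames(rep(0.02, 20), paste0("b", 1:20)))
  clones <- data.frame(cell_id = sprintf("c%03d", 1:200),
                       barcode_1 = sample(paste0("b", 1:20), 200, replace = TRUE),
                       barcode_2 = NA_character_,
                       population = sample(c("EP", "PP", "cTEC", "mTEC"), 200,
                                           replace = TRUE),
                       stringsAsFactors = FALSE)
  calls <- barcode_population_tests(clones, bg)
  # independent step-up implementation
  p <- calls$p
  n <- length(p)
  o <- order(p)
  stepped <- rev(cummin(rev(p[o] * n / seq_len(n))))
  want <- pmin(1, stepped)[match(seq_len(n), o)]
  expect_equal(calls$p_adj, want, tolerance = 1e-12)
})

test_that("bulk-unseen barcodes are excluded with a warning", {
  bg <- make_bg(c(seen = 0.1))
  clones <- data.frame(cell_id = c("c1", "c2", "c3"),
                       barcode_1 = c("seen", "ghost", "seen"),
                       barcode_2 = NA_character_,
                       population = "cTEC", stringsAsFactors = FALSE)
  expect_warning(calls <- barcode_population_tests(clones, bg), "absent from bulk")
  expect_false("ghost" %in% calls$barcode)
  expect_equal(attr(calls, "bulk_unseen"), "ghost")
  # C_i still counts every barcode-carrying cell, including excluded ones
  expect_equal(unique(calls$total_cells), 3L)
})

test_that("significance patterns map to lineage labels", {
  mk <- function(barcode, sig) {
    data.frame(barcode = barcode, population = c("EP", "PP", "cTEC", "mTEC"),
               significant = sig, stringsAsFactors = FALSE)
  }
  calls <- rbind(mk("b1", c(TRUE, FALSE, TRUE, TRUE)),    # early bipotent
                 mk("b2", c(FALSE, TRUE, FALSE, TRUE)),   # postnatal mTEC-biased
                 mk("b3", c(FALSE, FALSE, TRUE, FALSE)),  # cTEC-private
                 mk("b4", c(TRUE, TRUE, FALSE, FALSE)),   # dormant
                 mk("b5", c(FALSE, FALSE, FALSE, FALSE))) # none
  pat <- classify_barcode_patterns(calls)
  lab <- stats::setNames(pat$pattern, pat$barcode)
  expect_equal(unname(lab["b1"]), "early bipotent")
  expect_equal(unname(lab["b2"]), "postnatal mTEC-biased")
  expect_equal(unname(lab["b3"]), "cTEC-private")
  expect_equal(unname(lab["b4"]), "dormant")
  expect_equal(unname(lab["b5"]), "none")
})

test_that("flagged barcodes reflect true clone fate biases", {
  # among flagged barcodes, the observed compartment fraction in the
  # single-cell data should rank-correlate with the true clone bias
  co <- fx_recovery_cohort()
  bg <- background_frequency(co$bulk)
  est_all <- truth_all <- c()
  for (mname in names(co$sc)) {
    calls <- suppressWarnings(barcode_population_tests(co$sc[[mname]]$clones, bg))
    sig <- calls[calls$significant & calls$population %in% c("cTEC", "mTEC"), ]
    tm <- co$truth[co$truth$mouse_id == mname, ]
    true_c <- tapply(tm$n_cTEC, tm$barcode, sum)
    true_m <- tapply(tm$n_mTEC, tm$barcode, sum)
    bcs <- setdiff(intersect(unique(sig$barcode), names(true_c)),
                   grep("\\+", unique(sig$barcode), value = TRUE))
    est <- vapply(bcs, function(b) {
      x <- calls[calls$barcode == b, ]
      x$cells[x$population == "cTEC"] / max(1, sum(x$cells))
    }, numeric(1))
    est_all <- c(est_all, est)
    truth_all <- c(truth_all, true_c[bcs] / (true_c[bcs] + true_m[bcs]))
  }
  expect_gt(length(est_all), 50)
  expect_gt(stats::cor(est_all, truth_all, method = "spearman"), 0.8)
})
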