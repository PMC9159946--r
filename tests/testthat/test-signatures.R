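test_that("UMI collision correction has the closed form's fixed points and shape", {
  expect_equal(umi_to_transcripts(0), 0)
  expect_equal(umi_to_transcripts(1, 4096), 1.000122, tolerance = 1e-6)
  expect_equal(umi_to_transcripts(2048, 4096), 4096 * log(2), tolerance = 1e-12)
  k <- 0:4000
  t <- umi_to_transcripts(k, 4096)
  expect_true(all(diff(t) > 0))            # monotone
  expect_true(all(diff(diff(t)) > 0))      # convex
  expect_true(all(t[-1] >= k[-1]))         # collisions only inflate
  expect_true(is.finite(umi_to_transcripts(4096, 4096)))  # saturation guard
  expect_error(umi_to_transcripts(5000, 4096), class = "clonescar_invalid_config")
})

test_that("cell QC removes exactly the constructed violators and equalises totals", {
  set.seed(31)
  genes <- c("Kcnq1ot1", paste0("g", 1:49))
  counts <- matrix(rpois(50 * 100, 30), nrow = 50,
                   dimnames = list(genes, paste0("cell", 1:100)))
  counts["Kcnq1ot1", ] <- rpois(100, 2)
  # violators: 5 low-total cells, 4 marker-heavy cells
  low <- paste0("cell", 1:5)
  counts[, low] <- 0L
  counts[2:10, low] <- 10L
  marker <- paste0("cell", 11:14)
  counts["Kcnq1ot1", marker] <- 200L
  storage.mode(counts) <- "integer"

  f <- qc_filter_cells(counts, min_total = 1000, seed = 9)
  removed <- attr(f, "removed")
  expect_setequal(removed$cell, c(low, marker))
  expect_setequal(removed$reason[removed$cell %in% marker], "marker_fraction")
  expect_length(unique(colSums(f)), 1)          # downscaled to common total
  expect_true(all(f <= counts[, colnames(f)]))  # subsampling never adds counts

  # a cell at 3% marker fraction is removed; one at 2% is kept
  counts2 <- counts[, 20:30]
  tot <- colSums(counts2)
  counts2["Kcnq1ot1", 1] <- as.integer(ceiling(0.031 * tot[1]))
  f2 <- qc_filter_cells(counts2, min_total = 100, normalize = "none")
  expect_true(colnames(counts2)[1] %in% attr(f2, "removed")$cell)

  expect_error(qc_filter_cells(counts, min_total = 1e6),
               class = "clonescar_validation_error")
})

test_that("gene QC removes the anchor, correlated genes and configured ids", {
  set.seed(32)
  n <- 60
  anchor <- rpois(n, 20)
  # construct genes at exact correlations to the anchor
  at_cor <- function(r) {
    e <- stats::residuals(stats::lm(rnorm(n) ~ anchor))
    z <- r * scale(anchor)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
    round(50 + 10 * z)
  }
  counts <- rbind(Kcnq1ot1 = anchor,
                  twin = anchor,             # r = 1
                  hi = at_cor(0.70),
                  lo = at_cor(0.60),
                  Hprt = rpois(n, 10),
                  `mt-Co1` = rpois(n, 10),
                  Jun = rpois(n, 10),
                  Gm12345 = rpois(n, 10),
                  keep1 = rpois(n, 10),
                  keep2 = rpois(n, 10))
  colnames(counts) <- paste0("c", 1:n)
  expect_equal(unname(cor(counts["hi", ], counts["Kcnq1ot1", ])), 0.7,
               tolerance = 0.02)
  g <- qc_filter_genes(counts)
  expect_setequal(rownames(g), c("lo", "keep1", "keep2"))

  expect_warning(qc_filter_genes(counts[-1, , drop = FALSE]), "absent")
})

test_that("NB differential expression is powered for planted signals and calibrated on nulls", {
  set.seed(33)
  n_per <- 50
  n_genes <- 400
  true_up <- 1:200  # genes 1..200 elevated 4-fold in group B
  muA <- rep(2, n_genes)
  muB <- muA
  muB[true_up] <- muA[true_up] * 4
  counts <- cbind(
    matrix(rnbinom(n_genes * n_per, mu = muA, size = 10), nrow = n_genes),
    matrix(rnbinom(n_genes * n_per, mu = muB, size = 10), nrow = n_genes))
  rownames(counts) <- paste0("g", seq_len(n_genes))
  colnames(counts) <- paste0("c", seq_len(2 * n_per))
  ga <- colnames(counts)[1:n_per]
  gb <- colnames(counts)[(n_per + 1):(2 * n_per)]
  de <- diffexp_nb(counts, ga, gb)
  hit <- de$p_adj < 0.01 & abs(de$log2_fc) > 1
  expect_gte(mean(hit[true_up]), 0.95)                  # power
  expect_lte(mean(hit[-true_up]), 0.01)                 # type-I control
  expect_true(all(de$log2_fc[true_up][hit[true_up]] > 0))

  # identical groups: duplicated cells, no gene should move
  dup <- cbind(counts[, ga], counts[, ga])
  colnames(dup) <- paste0("d", seq_len(2 * n_per))
  de0 <- diffexp_nb(dup, colnames(dup)[1:n_per], colnames(dup)[-(1:n_per)])
  expect_gt(min(de0$p_adj), 0.5)

  # all-zero gene convention
  z <- counts
  z["g1", ] <- 0L
  dez <- diffexp_nb(z, ga, gb)
  expect_equal(dez$p[dez$gene == "g1"], 1)
  expect_equal(dez$log2_fc[dez$gene == "g1"], 0)

  expect_error(diffexp_nb(counts, ga[1:3], gb), class = "clonescar_invalid_config")
})

test_that("gene sets recover the planted signatures with identifier exclusions", {
  co <- fx_small_cohort()
  mat <- co$sc[[1]]$counts
  cl <- co$sc[[1]]$clones
  clusters <- stats::setNames(cl$population, cl$cell_id)
  cmap <- list(EP = "EP", PP = "PP", cTEC = "cTEC", mTEC = "mTEC")
  panel <- sim_gene_panel()

  # plant a predicted-gene identifier onto a cTEC signature gene
  mat2 <- mat
  rownames(mat2)[rownames(mat2) == "CtSig01"] <- "Gm12345"
  sets <- derive_gene_sets(mat2, clusters, cmap)
  expect_false("Gm12345" %in% unlist(sets))
  for (pop in names(panel$sets)) {
    recall <- mean(setdiff(panel$sets[[pop]], "CtSig01") %in% sets[[pop]])
    expect_gte(recall, 0.9)
    # no cross-population contamination from other planted sets
    others <- unlist(panel$sets[setdiff(names(panel$sets), pop)])
    expect_length(intersect(sets[[pop]], others), 0)
  }
  expect_length(intersect(sets$EP, sets$cTEC), 0)

  # the fold-change rule is strict: a gene at exactly the threshold is out
  de <- diffexp_nb(mat, cl$cell_id[cl$population != "EP"],
                   cl$cell_id[cl$population == "EP"])
  gene <- de$gene[de$p_adj < 0.01 & de$log2_fc > 1][1]
  lfc <- de$log2_fc[de$gene == gene]
  at <- derive_gene_sets(mat, clusters, cmap, min_log2_fc = lfc)
  below <- derive_gene_sets(mat, clusters, cmap, min_log2_fc = lfc - 1e-9)
  expect_false(gene %in% at$EP)
  expect_true(gene %in% below$EP)
})

test_that("signature scores are sums over set genes and predict population", {
  co <- fx_small_cohort()
  mat <- co$sc[[1]]$counts
  cl <- co$sc[[1]]$clones
  panel <- sim_gene_panel()
  sc <- score_cells(mat, panel$sets)
  expect_equal(sc$EP, unname(colSums(mat[panel$sets$EP, ])))

  # additivity over an arbitrary partition of a set
  half1 <- panel$sets$EP[1:25]
  half2 <- panel$sets$EP[26:50]
  parts <- score_cells(mat, list(a = half1, b = half2))
  expect_equal(parts$a + parts$b, sc$EP)

  # zero-count cell scores zero
  mat0 <- mat
  mat0[, 1] <- 0L
  expect_equal(unlist(score_cells(mat0, panel$sets)[1, -1]),
               c(EP = 0, PP = 0, cTEC = 0, mTEC = 0))

  # argmax score predicts the simulated population
  pred <- names(panel$sets)[max.col(as.matrix(sc[, names(panel$sets)]))]
  expect_gte(mean(pred == cl$population), 0.9)
})

test_that("ratio coordinates centre the reference at the origin and order cohorts", {
  co <- fx_small_cohort()
  panel <- sim_gene_panel()
  emb <- simulate_cohort(sim_config(n_mice = 1, founders_per_mouse = 300,
                                    n_outcomes = 2000,
                                    frac_early_progenitor = 0.95,
                                    bulk_reads_per_sample = 5000,
                                    cells_per_sc_dataset = 600,
                                    n_sc_datasets = 1, seed = 44))
  score_of <- function(cohort, id) {
    d <- cohort$sc[[1]]
    s <- score_cells(d$counts, panel$sets)
    s$cluster <- d$clones$population[match(s$cell, d$clones$cell_id)]
    s$dataset <- id
    s
  }
  sc <- rbind(score_of(co, "ref"), score_of(emb, "embryonic"))
  coords <- cluster_ratio_coordinates(sc, sc$cluster, sc$dataset, reference = "ref")
  ref <- coords[coords$dataset == "ref", ]
  expect_equal(mean(ref$ep_pp_log2), 0, tolerance = 1e-12)
  expect_equal(mean(ref$c_m_log2), 0, tolerance = 1e-12)

  # an embryonic-like cohort (EP-dominated, cTEC-biased) sits in the
  # EP-high / C-high quadrant relative to the reference
  em <- coords[coords$dataset == "embryonic", ]
  expect_gt(mean(em$ep_pp_log2), 0)
  expect_gt(mean(em$c_m_log2), 0)

  # doubling the pseudocount changes no quadrant assignment
  coords2 <- cluster_ratio_coordinates(sc, sc$cluster, sc$dataset,
                                       reference = "ref", eps = 2)
  expect_equal(sign(coords2$ep_pp_log2[coords2$dataset == "embryonic"]),
               sign(em$ep_pp_log2))

  # cluster exclusion and fraction bookkeeping
  coords3 <- cluster_ratio_coordinates(sc, sc$cluster, sc$dataset,
                                       reference = "ref",
                                       exclude_clusters = "EP")
  expect_false("EP" %in% coords3$cluster)
  expect_equal(as.numeric(tapply(coords$fraction, coords$dataset, sum)),
               c(1, 1), tolerance = 1e-12)
})
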