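#' Configuration for the clonal-barcoding simulator
#'
#' Bundles all parameters of the synthetic cohort generator. The defaults
#' describe a post-weaning male mouse cohort: a thymic rudiment of ~4,000
#' founder epithelial cells per mouse, a shared heavy-tailed (Zipf-like)
#' distribution of Cas9 repair outcomes, log-normal clonal expansion with
#' fate bias towards the cortical (early progenitors) or medullary
#' (postnatal progenitors) compartment, bulk amplicon sequencing at
#' ~250,000 reads per sorted sample, and single-cell readout of 1,000 cells
#' per profiled mouse.
#'
#' @param n_mice number of mice in the cohort.
#' @param founders_per_mouse marked founder cells per thymic rudiment.
#' @param n_outcomes size of the repair-outcome (barcode) space.
#' @param outcome_skew exponent of the truncated power-law outcome
#'   distribution; 0 gives a uniform distribution.
#' @param frac_early_progenitor fraction of founders that behave as early
#'   (cTEC-biased) progenitors; the rest are postnatal (mTEC-biased).
#' @param bias_early_to_cTEC probability that a mature descendant of an
#'   early progenitor ends up in the cTEC compartment.
#' @param bias_postnatal_to_mTEC probability that a mature descendant of a
#'   postnatal progenitor ends up in the mTEC compartment.
#' @param clone_size_log_mean,clone_size_log_sd meanlog/sdlog of the
#'   log-normal clone-size distribution (cells per founder clone).
#' @param frac_progenitor_state fraction of a clone's cells that remain in
#'   the progenitor state (labelled EP or PP at single-cell readout).
#' @param bulk_reads_per_sample amplicon reads per bulk cTEC/mTEC sample.
#' @param cells_per_sc_dataset cells sampled per single-cell dataset.
#' @param n_sc_datasets number of mice (taken from the start of the cohort)
#'   that receive a single-cell dataset.
#' @param relaxed_xi_prob probability that a female cell exposes both X
#'   alleles at readout instead of the inactivation-selected one.
#' @param sc_signal_fold fold elevation of a population's signature genes
#'   in the simulated expression panel.
#' @param sc_dispersion negative-binomial dispersion (1/size) of simulated
#'   transcript counts.
#' @param make_counts logical; generate per-cell expression matrices for
#'   the single-cell datasets (clone maps are always generated).
#' @param age_group age label attached to every sample of the cohort.
#' @param sex `"male"` (one barcode per founder) or `"female"` (two
#'   independent barcodes per founder, one X expressed per cell).
#' @param seed master seed; all randomness flows from it through per-mouse
#'   substreams, so identical config + seed reproduces the cohort exactly.
#' @return a validated object of class `sim_config`.
#' @seealso [simulate_cohort()], [simulate_null_cohort()]
#' @export
sim_config <- function(n_mice = 18,
                       founders_per_mouse = 4000,
                       n_outcomes = 20000,
                       outcome_skew = 1.1,
                       frac_early_progenitor = 0.5,
                       bias_early_to_cTEC = 0.85,
                       bias_postnatal_to_mTEC = 0.85,
                       clone_size_log_mean = 1.0,
                       clone_size_log_sd = 3.0,
                       frac_progenitor_state = 0.1,
                       bulk_reads_per_sample = 250000,
                       cells_per_sc_dataset = 1000,
                       n_sc_datasets = 4,
                       relaxed_xi_prob = 0.02,
                       sc_signal_fold = 4,
                       sc_dispersion = 0.1,
                       make_counts = TRUE,
                       age_group = "P14",
                       sex = c("male", "female"),
                       seed = 1L) {
  sex <- match.arg(sex)
  assert_count(n_mice, "n_mice")
  assert_count(founders_per_mouse, "founders_per_mouse")
  assert_count(n_outcomes, "n_outcomes", min = 2)
  assert_number(outcome_skew, "outcome_skew", min = 0)
  assert_fraction(frac_early_progenitor, "frac_early_progenitor")
  assert_fraction(bias_early_to_cTEC, "bias_early_to_cTEC")
  assert_fraction(bias_postnatal_to_mTEC, "bias_postnatal_to_mTEC")
  assert_number(clone_size_log_mean, "clone_size_log_mean")
  assert_number(clone_size_log_sd, "clone_size_log_sd", min = 0)
  assert_fraction(frac_progenitor_state, "frac_progenitor_state")
  assert_count(bulk_reads_per_sample, "bulk_reads_per_sample")
  assert_count(cells_per_sc_dataset, "cells_per_sc_dataset")
  assert_count(n_sc_datasets, "n_sc_datasets", min = 0)
  assert_fraction(relaxed_xi_prob, "relaxed_xi_prob")
  assert_number(sc_signal_fold, "sc_signal_fold", min = 1)
  assert_number(sc_dispersion, "sc_dispersion", min = 1e-8)
  assert_count(seed, "seed")
  if (n_sc_datasets > n_mice) {
    stop_invalid("n_sc_datasets (%d) cannot exceed n_mice (%d)", n_sc_datasets, n_mice)
  }
  if (cells_per_sc_dataset > 4096) {
    stop_invalid("cells_per_sc_dataset cannot exceed the 6-nt cell barcode space (4096)")
  }
  structure(list(
    n_mice = as.integer(n_mice),
    founders_per_mouse = as.integer(founders_per_mouse),
    n_outcomes = as.integer(n_outcomes),
    outcome_skew = as.numeric(outcome_skew),
    frac_early_progenitor = frac_early_progenitor,
    bias_early_to_cTEC = bias_early_to_cTEC,
    bias_postnatal_to_mTEC = bias_postnatal_to_mTEC,
    clone_size_log_mean = clone_size_log_mean,
    clone_size_log_sd = clone_size_log_sd,
    frac_progenitor_state = frac_progenitor_state,
    bulk_reads_per_sample = as.integer(bulk_reads_per_sample),
    cells_per_sc_dataset = as.integer(cells_per_sc_dataset),
    n_sc_datasets = as.integer(n_sc_datasets),
    relaxed_xi_prob = relaxed_xi_prob,
    sc_signal_fold = sc_signal_fold,
    sc_dispersion = sc_dispersion,
    make_counts = isTRUE(make_counts),
    age_group = as.character(age_group),
    sex = sex,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
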