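---
title: "Models and methods behind clonescar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonescar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescar)
```

`clonescar` analyses CRISPR–Cas9 scar barcoding of thymic epithelial
cells (TECs). This vignette explains the underlying models, the
assumptions they make, the tunable parameters and their defaults, what
the built-in simulator does and does not emulate, and the numerical and
design choices made where the problem was genuinely open.

## The barcoding system

Cas9, expressed in epithelial cells of the embryonic thymic rudiment as
soon as the epithelial program switches on, cuts a fixed target in exon 3
of the X-linked *Hprt* gene. Error-prone repair produces a sequence
outcome — a *scar* or *barcode* — that is inherited by all progeny of the
founder cell. Three properties of the system drive all downstream
statistics:

1. **Founder bound.** The rudiment contains roughly 4,000 epithelial
   cells at the time of marking, an upper bound on barcode diversity per
   animal.
2. **Outcome recurrence.** Repair outcomes are far from uniform: the
   observed number of distinct barcodes per thymus is three- to four-fold
   below the founder bound because frequent outcomes arise independently
   in many founders (and in different mice). Only *rare* outcomes are
   reliable clone labels.
3. **X linkage.** Males carry one barcode per cell. Females carry two,
   but dosage compensation exposes a single allele per cell at the
   transcript level; occasionally relaxed X inactivation reveals both.
   Bulk DNA analysis is therefore restricted to males, while single-cell
   RNA readout works for both sexes.

## Rare-barcode co-occurrence and enrichment

Sample `i`'s rare set `B_i` holds every barcode with at least one count
in `i` and at most `threshold` (default 2) counts summed over *all* bulk
samples. The co-occurrence probability `P_ij` is the fraction of `B_i`
also present in `B_j`. The per-mouse enrichment `E_m` divides the
same-mouse `P` (in each direction) by the mean of the corresponding
cross-mouse values over all `N - 2` samples from other animals and takes
the maximum of the two ratios.

Choices worth stating explicitly:

* **Rarity counts read copies**, not sample occurrences, by default; a
  `count_mode = "samples"` flag switches to occurrence counting. Read
  depth is high enough that the distinction matters only for borderline
  barcodes.
* **Undefined values propagate.** An empty `B_i` makes `P_ij` undefined
  (`NA`); undefined values are excluded from denominator means rather
  than treated as zeros. A zero denominator with positive numerator
  yields `Inf`, which is kept because the downstream comparison is
  rank-based.
* **Age-group comparisons** use a one-sided Wilcoxon rank-sum test. For
  combined sample sizes up to 25 the exact permutation distribution of
  the rank sum is computed by dynamic programming over midranks (ties
  handled exactly); beyond that the normal approximation with tie
  correction is used. The reported value is `P(W >= observed)`; for
  heavily tied data this convention is conservative (it tends to 1, not
  0.5, for identical groups).

## Binomial lineage inference

The background frequency `f_b` of a barcode is the unweighted mean of its
per-sample relative frequencies across bulk samples. The unweighted mean
(rather than pooling counts) keeps deeply sequenced samples from
dominating the background. A barcode carried by `c` of the `C`
barcode-carrying cells of a single-cell population is tested with the
right tail of `Binomial(C, f_b)`, computed through the survival function
so that small tails do not suffer cancellation. P values are BH-corrected
in one joint family across all barcode-by-population tests of a dataset
(a `per_population` family is available for sensitivity analysis), and
significance is called at adjusted P < 0.001 — the threshold applies to
the adjusted values.

The model assumes binomial sampling of cells given the background
frequency; it deliberately ignores overdispersion between animals, which
is conservative for mouse-private clones because their cross-cohort
background is diluted by all other samples. Two further rules:

* **Barcode pairs** (two-allele cells) are tested as a unit with the
  product of the singleton backgrounds — the null hypothesis that the
  two alleles co-occur by independent generation.
* **Bulk-unseen barcodes** (observed in single cells, never in bulk)
  have no defined background; a zero-background binomial is degenerate,
  so they are excluded from testing and reported separately. They still
  count towards `C`.

Pattern labels ("early bipotent", "dormant", …) are a deterministic
reading of the significance flags across the four populations and are
documented in `?classify_barcode_patterns`.

## UMI conversion, QC and signatures

With 6-nt UMIs there are `K = 4096` tags; the number of distinct observed
tags `k` understates the number of transcripts `t` because of
collisions. Under uniform random tagging `E[k] = K(1 - e^{-t/K})`, which
inverts to `t = -K log(1 - k/K)`; saturation (`k = K`) is guarded as
`k = K - 0.5`. The closed form is validated in the test suite against a
Monte-Carlo collision simulation.

Cell QC removes cells below a per-dataset transcript minimum and cells in
which the low-quality marker `Kcnq1ot1` exceeds 2% of transcripts.
Remaining cells are normalised by *downscaling*: exact multivariate
hypergeometric subsampling of every cell to the minimum retained total,
which keeps counts integral and preserves within-cell proportions in
expectation (a `scale` mode performs plain rescaling when speed matters).
Gene QC removes the marker gene, genes correlating with it above Pearson
0.65, mitochondrial genes, *Hprt* (the barcoding locus itself),
immediate-early genes, and configurable identifier patterns.

Differential expression uses a negative-binomial model whose variance
follows a quadratic mean–variance trend `v(m) = m + a m^2` fitted by
least squares across all genes of the dataset; under this law the NB size
of a group total is `n/a`, independent of the mean. The focal group's
total is compared with its expectation under the pooled mean, two-sided.
Using a dataset-wide trend rather than per-gene variances stabilises the
test at single-cell sample sizes; testing the focal group keeps power
symmetric across very unbalanced one-vs-rest splits. Gene sets take genes
with adjusted P < 0.01 and log2 fold change strictly greater than 1,
exclude `Gm*`/`*Rik` predicted-gene identifiers and heat-shock families
(`Hspa*`, `Hspb*`, `Dnaj*` by default — these genes separate progenitors
from mature cells without distinguishing the two progenitor states), and
remove genes shared between the early-progenitor and cTEC sets from the
early-progenitor set, since those mark cortical identity rather than
progenitor state.

Cluster summaries use two log2 ratios of summed signature scores —
early/postnatal progenitor and cortical/medullary — with a pseudocount of
one transcript guarding empty aggregates. Coordinates are centred so that
the *reference dataset's clusters average to the origin*. The reference
normalisation is interpretive: only "a reference time point" is specified
by the analysis design, and mean-centring in log space is the weakest
transform that makes other datasets readable as displacements from the
reference state. Scores are computed on downscaled counts by default
(flag to use raw).

## The simulator: what it emulates, and what it does not

`simulate_cohort()` generates, per mouse: founder barcodes drawn from a
shared truncated power-law (Zipf) outcome distribution; log-normal clone
sizes; a progenitor-state fraction per clone; allocation of mature cells
to compartments by the founder's fate bias; multinomial bulk read
sampling per sorted compartment; uniform single-cell sampling with
population labels and X-inactivation-aware barcode exposure; and
negative-binomial expression over a 1,000-gene panel with four planted
50-gene signatures.

Default parameters and their provenance:

| parameter | default | why |
|---|---|---|
| `founders_per_mouse` | 4000 | size of the marked founder pool |
| `bulk_reads_per_sample` | 250000 | typical bulk amplicon depth |
| `n_mice` | 18 | bulk cohort size per age group |
| `n_outcomes`, `outcome_skew` | 20000, 1.1 | calibrated once so that observed distinct barcodes per thymus (~800), same-mouse rare sharing (~5%) and cross-mouse sharing (~0.25%) match the magnitudes reported for real cohorts |
| `clone_size_log_mean/sd` | 1.0, 3.0 | heavy-tailed clonal expansion: most founder clones stay small or die out while a few dominate, the regime that produces both rare barcodes and high-power clones |
| `bias_early_to_cTEC`, `bias_postnatal_to_mTEC` | 0.85 | strong but incomplete fate bias of the two progenitor states |
| `frac_progenitor_state` | 0.1 | fraction of cells remaining progenitor-like at readout |
| `cells_per_sc_dataset` | 1000 | order of a real single-cell dataset (≤ 4096, the cell-barcode space) |
| `relaxed_xi_prob` | 0.02 | rare two-allele readout in females |

The functional form of the outcome distribution is a modelling choice —
the real repair-outcome distribution is not published — and the power law
was chosen because one parameter reproduces the monotone rank-frequency
profile. The simulator does **not** model: spatial structure (medullary
islets), age-dependent transcriptome drift, PCR or sequencing chimeras,
doublets, or the recruitment of late founders into the epithelial
lineage. Consequently, passing recovery tests demonstrates correctness of
the statistics under the stated generative assumptions, not robustness to
every artefact of real libraries.

`simulate_null_cohort()` is the calibration null. Allocating compartments
independently of clone identity *within* each mouse would not suffice:
clones are mouse-private, so same-mouse samples would still share rare
barcodes heavily. The null therefore makes all samples exchangeable —
every bulk sample and every single cell draws from the pooled cohort-wide
barcode abundance, and population labels are drawn independently of
barcode. Under this null the enrichment values scatter around 1 and the
lineage test's false-positive rate is far below its nominal level (the
binomial right tail is conservative for discrete counts).

Determinism: one cohort seed drives per-mouse substreams (derived with a
seeded draw, all below 2^31), so identical configuration and seed
reproduce every table byte for byte, and expression matrices can be
switched off (`make_counts = FALSE`) without changing any barcode-level
output, because they are drawn after the clone map within each substream.

## Scar extraction

Reads are anchored by the published extraction primers; each 18–19-nt
anchor tolerates at most one substitution and no indels (one mismatch
absorbs sequencer error without making the match ambiguous at this
length). The scar is the literal sequence between the anchors — no
realignment to the germline, since barcodes are sequence identities —
orientation is normalised by retrying the reverse complement, reads with
ambiguous bases inside the scar are dropped, and a read pair counts only
when both mates yield the identical scar. Per-cell allele calling ranks
scars by support — by default the number of distinct (UMI, scar)
combinations, which stops PCR jackpots from inflating a noise allele past
the 10% rule — and applies the filters: at least 200 usable reads; males
fail if a second scar reaches 10% of the major (the rule is "at least
10%", so exactly 10.0% excludes); females fail if a third scar reaches
10% of the second, and report a second allele only at ≥ 10% of the
major. The read threshold is applied to two-mate-agreeing reads, i.e.
after the agreement filter. Bulk counting is read-level, as the bulk
amplicon primers carry no UMIs. The synthetic amplicon used by the
simulator embeds the real primer and target sequences in short synthetic
flanks; it is labelled as such and exercises extraction end to end.

## Problem sizes used by tests and the acceptance script

Unit tests run on small cohorts (hundreds of founders). Calibration and
recovery use study-scale cohorts: 50 null cohorts of 18 mice for the
enrichment calibration, 10 for the lineage false-positive rate, and one
fate-biased cohort with 2,000-cell single-cell datasets for bipotent
recovery (deeper single-cell sampling raises the binomial power, so the
"testable" clone set — both-compartment clones with detection power
above 0.99 on each side — is non-empty). These sizes were chosen as the
smallest that make the quantities statistically stable.

## Known limitations

* The enrichment estimator is a ratio of small counts; with few rare
  barcodes per sample its distribution is heavy-tailed, and single-mouse
  values should be read through the rank-based group comparison, not
  individually.
* The NB differential-expression test conditions on the pooled mean and
  a global dispersion trend; genes whose dispersion deviates strongly
  from the trend will be mis-calibrated in either direction.
* Barcode-pair tests assume independent generation of the two alleles;
  linked repair events would inflate their significance.
* The binomial lineage test detects over-representation, not hierarchy:
  it cannot order progenitors and progeny in time.
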