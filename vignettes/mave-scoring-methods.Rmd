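---
title: "Scoring and calibrating multiplexed assays of variant effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and calibrating multiplexed assays of variant effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mavescorer` implements the computational pipeline behind saturation-mutagenesis
variant-effect maps of a voltage-gated potassium channel subunit (676 residues,
~14,200 possible single amino-acid changes), read out by barcode sequencing in
four assay contexts: cell-surface abundance and channel function, each measured
variant-only and in a heterozygous (wild-type co-expressed) background. This
vignette records the models, the parameters that matter, and the design choices
made where the methods left room.

```{r setup}
library(mavescorer)
```

## The measurement model

**Subassembly.** Each plasmid in the mutagenesis library carries one variant
and a random 18-nt barcode. Deep sequencing of barcode-plus-mutant-region
amplicons links barcodes to variants. The computational steps are: (1)
extraction of the barcode between exact matches of 5-6 nt constant flanks;
(2) a minimum-frequency threshold placed at the trough of the bimodal
log10 barcode-frequency histogram (genuine barcodes form the high mode,
sequencing-error barcodes the low mode); (3) removal of the lower-frequency
member of any barcode pair within Hamming distance 2 (substitutions only —
barcodes are fixed-length and flank-anchored, so indels present as flank
failures, not shifted barcodes); (4) per-barcode consensus calling against
the reference coding sequence, retaining barcodes whose consensus carries
exactly one changed codon (missense, nonsense or synonymous) and rejecting
fully wild-type, multi-codon, and ambiguous or low-coverage barcodes, and any
barcode observed at two loci. Short-read alignment is replaced by positional
comparison of fixed-length amplicons whose reference start coordinate travels
in the read header; an external aligner is glue, not part of the method.

Defaults that the methods leave implicit are explicit parameters here: the
trough is found on a 25-bin histogram smoothed with a 3-bin moving average;
consensus calls require coverage of at least 3 reads and a per-position
majority fraction of at least 0.6. Collapse order is deterministic: barcodes
are processed by descending count, ties broken lexicographically.

**Abundance (sort-seq).** Cells are sorted into four fluorescence bins at
population quartiles (~25% of cells per bin) and each bin is sequenced. The
raw score is the weighted bin average of a variant's reads-per-million,

$$W = \frac{0\,F_{1} + 1\,F_{2} + 2\,F_{3} + 3\,F_{4}}{F_{1}+F_{2}+F_{3}+F_{4}} \in [0,3].$$

**Function (drug selection).** Channel activity is made a fitness cost by two
channel activators plus ouabain ("triple-drug" selection), so active channels
deplete and loss-of-function variants enrich over 28 days. The raw score is
the pseudocounted log-ratio

$$R_{28} = \log_2\frac{F_{28}+10}{F_{0}+10},$$

with $F_x$ the variant's reads-per-million at day $x$. The pseudocount of 10
RPM keeps the score finite for variants depleted to zero.

**Filters.** Per replicate, abundance scores require a mean of at least 25
RPM across the four bins and function scores at least 15 RPM at day 0; both
thresholds are strict (`< 25`, `< 15`) exactly as worded in the source
protocol. After replicate averaging, variants whose standard error of the
mean exceeds a cutoff (default 0.5 on the normalized scale; the protocol does
not print its value) are removed.

**Normalization.** Raw scores are affinely rescaled per replicate so the
median synonymous variant scores 1 and a null anchor scores 0. The null
anchor is the median nonsense variant over residues 1-610, except: (a) the
function assays exclude nonsense variants at residues 239-307, where cryptic
stop-codon readthrough inflates apparent function; (b) the heterozygous
abundance assay, which measures the wild-type allele and where nonsense
variants are not reduced, anchors 0 at the lowest possible raw score
(all reads in bin 1, $W = 0$). The variant-only abundance assay is normalized
per mutagenesis zone (residues 1-236, 237-394, 395-676) and then merged,
because some replicates were sorted one zone at a time. Replicates are
averaged unweighted (weighting by depth is not specified in the source
protocol) and the merged scores re-anchored to (0, 1).

**Categories.** The normal range is the empirical 2.5th-97.5th percentile
interval of the synonymous score distribution. The printed description of
this range contains an internal inconsistency ("higher than the 2.5th
percentile or higher than the 97.5th percentile"); we implement the interval
reading, which is the only one consistent with the accompanying "within the
95% confidence interval" sentence and which produces non-degenerate gain and
partial-loss ranges. Scores above the interval are gain; below it but at or
above 0.25, partial loss; strictly below 0.25, loss ("below 0.25" is the
printed wording, hence the strict inequality and the convention that exactly
0.25 is partial loss). Missense variants at the six activator-drug binding
residues (248, 251, 255, 267, 335, 339) are excluded from function score sets
only, since their function scores conflate drug response with channel
function.

**Dominant negatives.** A tetrameric channel lets a mutant subunit poison
complexes containing wild-type subunits. Complete missense variants with
scores below 0.25, 0.25, 0.25 and 0 in the abundance, function, heterozygous
abundance and heterozygous function assays are counted; all four below is a
severe dominant negative, three of four a strong one. The heterozygous
function cutoff of 0 — not 0.25 — reflects that assay's normalization: 0 is
the haploinsufficient (nonsense) level, so only scores *below* it implicate
the wild-type allele.

**Clustering and classifiers.** Mechanism structure is summarized by PCA and
k-means (k = 6) on the standardized four-assay matrix of complete variants.
k-means uses 50 random restarts under a fixed seed; the selection of k = 6 in
the source analysis was made by visual inspection, and is a configurable
parameter here. Cluster names are a pure function of centroid profiles
(thresholds: centroid < 0.25 is "low", within the synonymous interval
"normal", above it "gain"), so renaming never depends on the seed beyond the
clustering itself. Classifier combination trains logistic regression, random
forest and Gaussian naive Bayes with leave-one-out cross-validation; whether
the source analysis standardized inputs is unstated, so the scale-sensitive
models (LR, GNB) use standardized scores and the random forest raw scores.

## Clinical calibration

Truth sets follow fixed rules: pathogenic controls are ClinVar P/LP variants
(protein-level deduplication keeps the more definitive classification);
benign controls are ClinVar B/LB supplemented by frequency rules — maximum
filtering allele frequency above 0.004 (BA1), between 0.0004 and 0.004 (BS1),
or between 0.000134 and 0.0004 with zero reported disease cases. The floor of
0.000134 is double the allele frequency of the most common pathogenic
missense control.

Three calibrations are implemented:

* **ROC/AUC** by the Mann-Whitney rank statistic with midranks, oriented so
  lower scores indicate pathogenicity.
* **Binary OddsPath**: with prior $P_1$ the proportion pathogenic in the
  truth set and $P_2$ the proportion pathogenic among abnormal (or normal)
  scores, $\mathrm{OddsPath} = \frac{P_2/(1-P_2)}{P_1/(1-P_1)}$. An empty
  contingency cell receives one pseudo-variant of its own label before
  computing $P_2$ (the zero-cell extension); $P_1$ uses the uncorrected
  totals. OddsPath is reported on the odds scale — the scale on which the
  published values (23.1, 0.177) live — even though the framework's prose
  sometimes calls it a log-likelihood ratio.
* **Continuous kernel LLR**: Gaussian kernel density estimates of the
  pathogenic and benign score distributions (bandwidth 0.2 in score units =
  the kernel's standard deviation; scores outside (-0.3, 1.5) trimmed as
  outliers), evaluated on a 0.001-step grid with densities floored at 1e-12,
  giving $\mathrm{llr}(s) = \ln f_P(s)/f_B(s)$ and, by interpolation, an
  odds value for any score.

Evidence strengths map odds onto the points-based thresholds underlying the
ClinGen recommendations — 18.7 (strong), 4.33 (moderate), 2.08 (supporting),
with reciprocals toward benignity and benign evidence capped at moderate.
The calibration methods state only the resulting categories; the thresholds
are configurable.

From the published function-assay classification counts (204 P/LP controls,
168 abnormal; 28 B/LB, 0 abnormal), the pipeline computes:

```{r}
op <- oddspath_from_counts(204, 168, 28, 0)
signif(op$oddspath_pathogenic, 3)
round(op$oddspath_benign, 3)
```

Note that the benign value computed from these counts,
$(36/28)/(204/28) = 36/204 = 0.17647$, rounds to 0.176; the published
rounding is 0.177.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which every downstream stage is validated. Each simulated variant draws an
effect archetype (wild-type-like, early/late nonsense, missense loss/
partial/gain, dominant-negative, haploinsufficient) and four latent effects
on a scale where 1 is wild-type and 0 complete loss, jittered (sd 0.06)
around archetype means and clipped to [0, 1.5]. Key emulated conditions:

* library of 2,000 variants by default (scaled down from ~14,200 for
  tractable test and example runs; the archetype mix — ~4% synonymous, ~5%
  nonsense, ~7% dominant-negative among all variants — mirrors the observed
  composition), mean 19.5 barcodes per variant, 18-nt barcodes;
* FACS: per-cell fluorescence log-normal around the latent abundance with
  configurable spread (sigma_cell = 0.6; flow-cytometry noise is
  conventionally log-normal, and the protocol gives no value), bins at
  population quartiles, Poisson read noise, reads-per-million output;
* selection: exponential growth with per-day fitness cost
  `selection_strength x latent activity` (clipped at 0) — the simplest model
  consistent with a monotone fitness defect. The default strength
  0.0633/day is derived from the published day-28 wild-type competitive
  index of 17% under triple-drug treatment: $e^{-s \cdot 28} = 0.17$;
* sequencing: Poisson shot noise at 25M reads per sample (the stated depth),
  substitution-only barcode errors at 0.005/base;
* replicates: 3 by default, with log-normal latent jitter (sd 0.05)
  between replicates.

Per-variant cell counts entering the sorter are not published beyond a
lower bound, so the simulator exposes the total (default 4M cells, ~2,000
per variant) as a parameter.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: induction kinetics and integration efficiency,
beta-subunit co-expression, stop-codon readthrough in the 239-307 window
(simulated nonsense variants there are true nulls; the *anchor exclusion* is
still applied and tested), codon-level biases, index hopping, and
replicate-specific batch structure beyond scalar jitter. Recovery statistics
(Spearman rho >= 0.9 between normalized function scores and latent function;
>= 90% of simulated dominant negatives called severe/strong) therefore
validate the arithmetic and the filtering logic, not assay chemistry.

```{r, eval = FALSE}
cfg <- sim_config()            # 2,000 variants, 3 replicates, seed 1
truth <- simulate_truth(cfg)
counts <- simulate_facs(truth, cfg, replicate = 1, assay = "abundance")
scores <- score_assay(counts, truth, "abundance")
```

## Numerical choices and degenerate inputs

* Trough detection falls back to a fixed threshold (default 2) with a
  warning when the histogram is unimodal; all-equal counts are degenerate
  and use the fallback directly.
* Collapse ties (equal counts) remove the lexicographically larger barcode;
  the greedy pass runs in descending count order, so the result matches the
  brute-force pairwise oracle and is idempotent.
* Variants with zero reads in all four bins have undefined W and are
  dropped, not scored 0. The R28 pseudocount makes the all-zero selection
  case exactly 0.
* Normalization refuses to run when an anchor class is absent or when the
  two anchors coincide; categorization refuses a synonymous lower bound at
  or below 0.25 (the category scheme would be degenerate).
* OddsPath requires both strata non-empty; the LLR calibration requires at
  least 5 controls per label after trimming.
* k-means naming is deterministic given centroids; two normal-profile
  clusters are numbered by size.
* All simulation streams derive 32-bit sub-seeds from one base seed;
  identical configuration and seed reproduce byte-identical outputs, and
  the pipeline manifest records md5 checksums to make this checkable.

## Problem sizes used in checks

The packaged tests run the full simulation-to-calls loop at 600 variants
(shared fixture) and the recovery checks at the default 2,000 variants with
3 replicates; the pipeline integration test runs 400 variants with a richer
synonymous fraction (0.25) so that anchor percentiles are stable at that
scale. These sizes are the package's choices for fast, deterministic
validation of the arithmetic; the machinery is the same at full library
scale.

## Known limitations

* The consensus caller assumes fixed-length amplicons with known reference
  offsets; it is not a general-purpose aligner and does not handle indels
  within the mutant region.
* Replicate averaging is unweighted; no shrinkage or count-based weighting
  (e.g. Enrich2-style scoring) is applied.
* The kernel LLR uses a fixed global bandwidth; no boundary correction is
  applied at the trim edges, where the density floor bounds the curve
  instead.
* Scores are amino-acid-level; codon-level effects and splice effects are
  out of scope (the splice-disruption aggregation utility consumes
  precomputed predictor scores).
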