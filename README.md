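# mavescorer

Scoring, integration and clinical calibration of **multiplexed assays of
variant effect (MAVEs)** for ion-channel saturation mutagenesis screens —
from barcoded sequencing counts to normalized variant scores,
dominant-negative calls, and ACMG/ClinGen functional evidence.

## The problem

Saturation mutagenesis of a disease gene — here modeled on a 676-residue
voltage-gated potassium channel subunit whose loss-of-function variants cause
long QT syndrome — produces thousands of variants assayed in one pooled
experiment. Each variant is tagged with random 18-nt barcodes; cells carrying
one variant each are either FACS-sorted into four bins by surface-protein
staining (sort-seq, measuring **abundance**) or grown for 28 days under drug
selection that makes channel activity a fitness cost (measuring
**function**), in both variant-only and heterozygous (wild-type co-expressed)
contexts. Sequencing barcode counts per bin or timepoint yields, after
normalization, four scores per variant on a scale where 1 is wild-type and 0
is complete loss. The package is aimed at analysts of such screens: it
implements every computational stage, plus a synthetic-data generator so the
whole pipeline is testable without sequencing data.

## The core quantities

* Subassembly maps barcodes to variants: flank-anchored extraction, a
  minimum-frequency threshold at the trough of the bimodal barcode-frequency
  histogram, Hamming-distance-2 collapse of sequencing-error barcodes, and
  per-barcode consensus calls retaining single-codon variants.
* Raw abundance score (weighted bin average over the four FACS bins):
  `W = (0·F1 + 1·F2 + 2·F3 + 3·F4) / (F1 + F2 + F3 + F4)`.
* Raw function score (pseudocounted log-ratio of day-28 to day-0 RPM):
  `R28 = log2((F28 + 10) / (F0 + 10))`.
* Scores are filtered (≥25 RPM mean bin depth; ≥15 RPM at day 0), rescaled so
  the median synonymous variant is 1 and the median early-nonsense variant is
  0, averaged across replicates with an SEM noise filter, and categorized
  against the synonymous 2.5th–97.5th percentile interval (loss < 0.25 ≤
  partial loss < normal ≤ gain).
* Dominant negatives: complete missense variants below cutoffs
  (0.25, 0.25, 0.25, 0) in the abundance, function, heterozygous-abundance
  and heterozygous-function assays — all four below is a **severe DN**,
  three of four a **strong DN**.
* Calibration: ROC/AUC, binary OddsPath
  `[P2/(1−P2)] / [P1/(1−P1)]` with the Fayer zero-cell correction, and a
  continuous Gaussian-kernel log-likelihood-ratio curve (bandwidth 0.2,
  outliers outside (−0.3, 1.5) trimmed) mapped onto ACMG evidence strengths
  (PS3_strong / moderate / supporting; BS3 capped at moderate).

## Worked example

Simulate a 1,000-variant library with three replicates, score the four
assays, call dominant negatives and calibrate:

```r
library(mavescorer)

cfg    <- sim_config(n_variants = 1000, seed = 2026)
truth  <- simulate_truth(cfg)
counts <- lapply(setNames(nm = c("abundance", "function",
                                 "het_abundance", "het_function")),
  function(a) do.call(rbind, lapply(1:3, function(r)
    if (a %in% c("abundance", "het_abundance"))
      simulate_facs(truth, cfg, r, a)
    else simulate_selection(truth, cfg, r, a))))
scores <- lapply(names(counts), function(a) score_assay(counts[[a]], truth, a))
names(scores) <- names(counts)

scores[["function"]]
#> <score_set> function assay: 988 variants
#>   synonymous normal range: [0.871, 1.119]
#>
#>         gain         loss       normal partial_loss
#>           69          335          473          111

dn <- call_dominant_negative(assemble_matrix(scores))
table(dn$label)
#>      none severe_dn strong_dn
#>       918        75         7
```

988 of 1,000 variants survive the depth filters; 335 score as
loss-of-function (normalized score < 0.25), and 82 missense variants reduce
function in at least three of the four assay contexts, the signature of a
dominant-negative subunit in a tetrameric channel. Calibrating the function
scores against the simulated benign/pathogenic control labels:

```r
ts  <- mavescorer:::truth_set_from_archetypes(truth)
roc_auc(scores[["function"]], ts)$auc       # 1 on this clean simulation
cal <- llr_kernel(scores[["function"]], ts)
ev  <- assign_evidence(cal, scores[["function"]])
attr(ev, "tally")
#>     PS3_strong   PS3_moderate PS3_supporting           none BS3_supporting
#>            336             21             20             43              9
#>   BS3_moderate
#>            559
```

So 336 variants receive strong pathogenic functional evidence and 559
moderate benign evidence; intermediate scores get graded support, exactly
the behaviour the continuous log-likelihood-ratio calibration is for.

The whole chain is also available as one call with on-disk outputs and a
checksummed manifest:

```r
man <- run_pipeline(run_config(sim = cfg), outdir = "run1")
```

## Package layout

| Area | Functions |
| --- | --- |
| Simulation | `sim_config`, `simulate_truth`, `simulate_barcode_library`, `simulate_subassembly_reads`, `simulate_facs`, `simulate_selection` |
| Subassembly | `extract_barcodes`, `threshold_barcodes`, `collapse_barcodes`, `call_consensus`, `subassemble` |
| Scoring | `aggregate_to_variants`, `abundance_raw`, `function_raw`, `filter_low_coverage`, `normalize_replicate`, `merge_replicates`, `categorize`, `exclude_drug_residues`, `score_assay`, `competitive_index` |
| Integration | `assemble_matrix`, `call_dominant_negative`, `pca_kmeans`, `combine_classifiers` |
| Calibration | `build_truth_set`, `roc_auc`, `oddspath_from_counts`, `oddspath_binary`, `llr_kernel`, `assign_evidence` |
| Clinical | `risk_ratio`, `spliceai_aggregate`, `spliceai_aggregate_max` |
| Pipeline | `run_config`, `run_pipeline`, `write_run_config`, `read_run_config`, `write_score_set`, `read_score_set` |

See `vignettes/mave-scoring-methods.Rmd` for the models, parameter defaults
and design decisions.
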