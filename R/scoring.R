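# Per-variant score calculation for the four MAVE assays.
#
# Abundance (sort-seq): raw score W is the weighted average of a variant's
# read frequencies over the four fluorescence bins,
#   W = (0*F1 + 1*F2 + 2*F3 + 3*F4) / (F1 + F2 + F3 + F4),  W in [0, 3].
# Function (selection): raw score is the pseudocounted log-ratio of day-28 to
# day-0 reads per million, R28 = log2((F28 + 10) / (F0 + 10)).
# Raw scores are filtered on read depth, linearly rescaled per replicate so
# the median synonymous variant is 1 and the null anchor is 0, averaged over
# replicates with an SEM noise filter, renormalized, and categorized against
# the synonymous score distribution.

ASSAYS <- c("abundance", "function", "het_abundance", "het_function")

RPM_FILTER_ABUNDANCE <- 25   # mean RPM across the four bins, strict <
RPM_FILTER_FUNCTION <- 15    # day-0 RPM, strict <
FUNCTION_PSEUDOCOUNT <- 10
LOSS_CUTOFF <- 0.25

#' Pool barcode counts to variant counts
#'
#' Sums reads-per-million over each variant's accepted barcodes within every
#' (sample, replicate) column, then renormalizes columns to one million.
#' Counted barcodes absent from the map are dropped and tallied in the
#' `dropped_barcodes` attribute.
#'
#' @param counts Barcode-level count table.
#' @param map A `barcode_map` (only `status == "accepted"` rows are used) or
#'   any data frame with `barcode` and `variant_id` columns.
#' @return Variant-level count table.
#' @export
aggregate_to_variants <- function(counts, map) {
  if ("status" %in% names(map)) map <- map[map$status == "accepted", ]
  idx <- match(counts$entity_id, map$barcode)
  dropped <- unique(counts$entity_id[is.na(idx)])
  keep <- !is.na(idx)
  if (!any(keep)) stop2("no counted barcode is present in the map")
  df <- counts[keep, , drop = FALSE]
  df$entity_id <- map$variant_id[idx[keep]]
  agg <- stats::aggregate(rpm ~ entity_id + sample_id + replicate, df, sum)
  out <- normalize_rpm(count_table(agg$entity_id, agg$sample_id,
                                   agg$replicate, agg$rpm))
  attr(out, "dropped_barcodes") <- dropped
  out
}

# Reshape a long count table to a variants x samples matrix per replicate.
counts_wide <- function(counts, samples, replicate) {
  sub <- counts[counts$replicate == replicate & counts$sample_id %in% samples, ]
  ids <- sort(unique(sub$entity_id))
  m <- matrix(0, nrow = length(ids), ncol = length(samples),
              dimnames = list(ids, samples))
  m[cbind(match(sub$entity_id, ids), match(sub$sample_id, samples))] <- sub$rpm
  m
}

#' Raw abundance score: weighted bin average
#'
#' @param counts Variant-level count table with bin samples
#'   `"bin1"`..`"bin4"`.
#' @return `data.frame` with `variant_id`, `replicate`, `value` (W in
#'   `[0, 3]`), `mean_rpm` (mean RPM over the four bins). Variants with zero
#'   reads in all four bins are dropped.
#' @export
abundance_raw <- function(counts) {
  if (any(counts$rpm < 0)) stop2("negative counts")
  bins <- paste0("bin", 1:4)
  if (!all(bins %in% counts$sample_id)) stop2("four bin columns required")
  out <- lapply(sort(unique(counts$replicate)), function(r) {
    m <- counts_wide(counts, bins, r)
    tot <- rowSums(m)
    keep <- tot > 0
    data.frame(
      variant_id = rownames(m)[keep],
      replicate = r,
      value = as.numeric(m[keep, ] %*% 0:3) / tot[keep],
      mean_rpm = tot[keep] / 4,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Raw function score: pseudocounted log-ratio of final to initial frequency
#'
#' @param counts Variant-level count table with at least `"day0"` and
#'   `"day28"` samples.
#' @param final_day Final timepoint (default 28).
#' @return `data.frame` with `variant_id`, `replicate`, `value` (R28) and
#'   `mean_rpm` (day-0 RPM).
#' @export
function_raw <- function(counts, final_day = 28L) {
  days <- c("day0", paste0("day", final_day))
  if (!all(days %in% counts$sample_id)) stop2("day-0 and day-", final_day,
                                              " columns required")
  out <- lapply(sort(unique(counts$replicate)), function(r) {
    m <- counts_wide(counts, days, r)
    data.frame(
      variant_id = rownames(m),
      replicate = r,
      value = log2((m[, 2] + FUNCTION_PSEUDOCOUNT) /
                     (m[, 1] + FUNCTION_PSEUDOCOUNT)),
      mean_rpm = m[, 1],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Remove low-coverage raw scores
#'
#' Per replicate: abundance scores with mean bin RPM strictly below 25 are
#' removed; function scores with day-0 RPM strictly below 15 are removed.
#'
#' @param raw Output of [abundance_raw()] or [function_raw()].
#' @param assay One of `"abundance"`, `"function"`, `"het_abundance"`,
#'   `"het_function"`.
#' @param min_rpm Override for the default threshold.
#' @return Filtered raw-score table.
#' @export
filter_low_coverage <- function(raw, assay, min_rpm = NULL) {
  assay <- match.arg(assay, ASSAYS)
  thr <- min_rpm %||% if (assay %in% c("abundance", "het_abundance")) {
    RPM_FILTER_ABUNDANCE
  } else {
    RPM_FILTER_FUNCTION
  }
  raw[raw$mean_rpm >= thr, , drop = FALSE]
}

# Anchor pair (null, wild-type-like) for one replicate's raw scores.
replicate_anchors <- function(raw_sub, variants, assay) {
  vi <- variants[match(raw_sub$variant_id, variants$variant_id), ]
  syn <- raw_sub$value[vi$consequence == "synonymous"]
  if (!length(syn)) stop2("no synonymous variants available as anchor")
  a1 <- stats::median(syn)
  if (assay == "het_abundance") {
    a0 <- 0  # lowest possible weighted bin score: 100% of reads in bin 1
  } else {
    anchor_pos <- nonsense_anchor_positions(assay)
    non <- raw_sub$value[vi$consequence == "nonsense" & vi$position %in% anchor_pos]
    if (!length(non)) stop2("no anchor nonsense variants available")
    a0 <- stats::median(non)
  }
  c(a0 = a0, a1 = a1)
}

#' Normalize raw scores per replicate against synonymous and null anchors
#'
#' Applies the affine map sending the null anchor to 0 and the median
#' synonymous raw score to 1, per replicate. The null anchor is the median
#' nonsense raw score over residues 1-610 (abundance) or residues 1-238 and
#' 308-610 (function assays, excluding the stop-readthrough window), except
#' for the heterozygous abundance assay where the anchor is the lowest
#' possible raw score (all reads in bin 1, W = 0). For the variant-only
#' abundance assay, normalization can be performed per mutagenesis zone and
#' merged, matching replicates sorted one zone at a time.
#'
#' @param raw Filtered raw-score table.
#' @param variants Variant identity table (e.g. simulation truth or an
#'   accepted `barcode_map`), with `variant_id`, `position`, `consequence`,
#'   `zone`.
#' @param assay Assay name.
#' @param by_zone Normalize per zone then merge (default: only for the
#'   variant-only abundance assay).
#' @return `raw` with a `score` column added.
#' @export
normalize_replicate <- function(raw, variants, assay,
                                by_zone = identical(assay, "abundance")) {
  assay <- match.arg(assay, ASSAYS)
  vi <- variants[match(raw$variant_id, variants$variant_id), ]
  grp <- if (by_zone) {
    interaction(raw$replicate, vi$zone, drop = TRUE)
  } else {
    factor(raw$replicate)
  }
  raw$score <- NA_real_
  for (g in levels(grp)) {
    sel <- grp == g
    an <- replicate_anchors(raw[sel, ], variants, assay)
    if (an["a1"] == an["a0"]) stop2("degenerate anchors: synonymous and null medians coincide")
    raw$score[sel] <- (raw$value[sel] - an["a0"]) / (an["a1"] - an["a0"])
  }
  raw
}

#' Average normalized scores across replicates
#'
#' Computes the unweighted mean and standard error of the mean across
#' surviving replicates, removes noisy variants whose SEM exceeds
#' `sem_cutoff`, and renormalizes with a final affine transformation so the
#' median synonymous and median anchor-nonsense scores are exactly 1 and 0.
#'
#' @param normalized Output of [normalize_replicate()].
#' @param variants Variant identity table.
#' @param assay Assay name.
#' @param sem_cutoff SEM noise filter on the normalized scale.
#' @return A `score_set`: `data.frame` with `variant_id`, `position`, `wt`,
#'   `alt`, `consequence`, `score`, `sem`, `n_reps`; attribute `assay`.
#' @export
merge_replicates <- function(normalized, variants, assay, sem_cutoff = 0.5) {
  assay <- match.arg(assay, ASSAYS)
  sp <- split(normalized$score, normalized$variant_id)
  n <- lengths(sp)
  mean_s <- vapply(sp, mean, numeric(1))
  sem <- vapply(sp, function(x) {
    if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  }, numeric(1))
  keep <- is.na(sem) | sem <= sem_cutoff
  out <- data.frame(variant_id = names(sp)[keep],
                    score = mean_s[keep], sem = sem[keep],
                    n_reps = as.integer(n[keep]),
                    stringsAsFactors = FALSE)
  # Final renormalization: re-anchor medians to (0, 1) on the merged scores.
  vi <- variants[match(out$variant_id, variants$variant_id), ]
  tmp <- data.frame(variant_id = out$variant_id, value = out$score,
                    stringsAsFactors = FALSE)
  an <- replicate_anchors(tmp, variants, assay)
  out$score <- (out$score - an["a0"]) / (an["a1"] - an["a0"])
  out$sem <- out$sem / abs(an["a1"] - an["a0"])
  out <- cbind(out, vi[, c("position", "wt", "alt", "consequence")])
  rownames(out) <- NULL
  out <- out[, c("variant_id", "position", "wt", "alt", "consequence",
                 "score", "sem", "n_reps")]
  structure(out, assay = assay, class = c("score_set", "data.frame"))
}

#' Categorize scores against the synonymous distribution
#'
#' The normal range is the empirical 2.5th-97.5th percentile interval of the
#' synonymous score distribution. Scores above it are gain; scores below it
#' but at or above 0.25 are partial loss; scores strictly below 0.25 are
#' loss.
#'
#' @param scores A `score_set`.
#' @param syn_scores Synonymous scores defining the normal range; defaults to
#'   the synonymous variants inside `scores`.
#' @param min_synonymous Minimum synonymous scores required for stable
#'   percentiles.
#' @return `scores` with a `category` column (`loss`, `partial_loss`,
#'   `normal`, `gain`) and attribute `normal_range`.
#' @export
categorize <- function(scores, syn_scores = NULL, min_synonymous = 20L) {
  if (is.null(syn_scores)) {
    syn_scores <- scores$score[scores$consequence == "synonymous"]
  }
  if (length(syn_scores) < min_synonymous) {
    stop2("need at least ", min_synonymous, " synonymous scores; got ",
          length(syn_scores))
  }
  bounds <- stats::quantile(syn_scores, c(0.025, 0.975), names = FALSE)
  if (bounds[1] <= LOSS_CUTOFF) {
    stop2("synonymous lower bound (", signif(bounds[1], 3),
          ") is at or below the loss cutoff 0.25; category scheme degenerate")
  }
  s <- scores$score
  scores$category <- ifelse(s > bounds[2], "gain",
    ifelse(s >= bounds[1], "normal",
      ifelse(s >= LOSS_CUTOFF, "partial_loss", "loss")))
  attr(scores, "normal_range") <- bounds
  scores
}

#' Exclude missense variants at activator-drug binding residues
#'
#' The function assays rely on channel activator compounds; missense changes
#' at the six residues critical for activator binding (248, 251, 255, 267,
#' 335, 339) are removed from function score sets because their scores
#' conflate drug response with channel function. Synonymous and nonsense
#' changes at those positions are retained, and abundance assays are never
#' touched.
#'
#' @param scores A `score_set`.
#' @param assay Assay name; only `"function"`/`"het_function"` are filtered.
#' @return Filtered `score_set`.
#' @export
exclude_drug_residues <- function(scores, assay = attr(scores, "assay")) {
  if (!assay %in% c("function", "het_function")) return(scores)
  drop <- scores$consequence == "missense" &
    scores$position %in% DRUG_BINDING_RESIDUES
  keep_attrs <- attributes(scores)[c("assay", "normal_range")]
  scores <- scores[!drop, , drop = FALSE]
  attr(scores, "assay") <- keep_attrs$assay
  if (!is.null(keep_attrs$normal_range)) {
    attr(scores, "normal_range") <- keep_attrs$normal_range
  }
  scores
}

#' Score one assay end to end
#'
#' Convenience wrapper: raw score, coverage filter, per-replicate
#' normalization, replicate merge, categorization and (for function assays)
#' drug-residue exclusion.
#'
#' @param counts Variant-level count table.
#' @param variants Variant identity table.
#' @param assay Assay name.
#' @param sem_cutoff SEM noise filter.
#' @param by_zone Per-zone normalization (variant-only abundance default).
#' @return A categorized `score_set`.
#' @export
score_assay <- function(counts, variants, assay, sem_cutoff = 0.5,
                        by_zone = identical(assay, "abundance")) {
  assay <- match.arg(assay, ASSAYS)
  raw <- if (assay %in% c("abundance", "het_abundance")) {
    abundance_raw(counts)
  } else {
    function_raw(counts)
  }
  raw <- filter_low_coverage(raw, assay)
  norm <- normalize_replicate(raw, variants, assay, by_zone = by_zone)
  merged <- merge_replicates(norm, variants, assay, sem_cutoff = sem_cutoff)
  merged <- categorize(merged)
  exclude_drug_residues(merged, assay)
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> %s assay: %d variants\n",
              attr(x, "assay") %||% "?", nrow(x)))
  if (!is.null(attr(x, "normal_range"))) {
    nr <- attr(x, "normal_range")
    cat(sprintf("  synonymous normal range: [%.3f, %.3f]\n", nr[1], nr[2]))
  }
  if ("category" %in% names(x)) print(table(x$category))
  invisible(x)
}

#' Competitive index of wild-type versus empty vector
#'
#' Percentage change in wild-type cell abundance relative to empty-vector
#' cells between day 0 and day `day`:
#' `100 * (A_WT,day / A_WT,0) / (A_empty,day / A_empty,0)`.
#'
#' @param abundances `data.frame` with columns `condition` (`"WT"`,
#'   `"empty"`), `day`, `abundance`.
#' @param day Evaluation timepoint.
#' @return Competitive index as a percentage.
#' @export
competitive_index <- function(abundances, day) {
  get_a <- function(cond, d) {
    v <- abundances$abundance[abundances$condition == cond & abundances$day == d]
    if (length(v) != 1) stop2("need exactly one abundance for ", cond, " day ", d)
    v
  }
  a_wt0 <- get_a("WT", 0); a_e0 <- get_a("empty", 0)
  if (a_wt0 == 0 || a_e0 == 0) stop2("zero day-0 abundance")
  100 * (get_a("WT", day) / a_wt0) / (get_a("empty", day) / a_e0)
}
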