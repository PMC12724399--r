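# ACMG functional-evidence calibration against benign/pathogenic truth sets:
# ROC/AUC, binary OddsPath per the ClinGen sequence-variant-interpretation
# framework (with the Fayer zero-cell correction), and a continuous
# kernel-density log-likelihood-ratio curve mapping scores to evidence
# strengths (PS3/BS3 at supporting/moderate/strong).

# Allele-frequency cutoffs for frequency-based benign controls: BA1
# stand-alone, BS1 strong, and the semi-rare band whose floor is double the
# allele frequency of the most common pathogenic missense variant.
MAF_BA1 <- 0.004
MAF_BS1 <- 0.0004
MAF_SEMIRARE_FLOOR <- 0.000134

# Evidence-strength thresholds on the odds-of-pathogenicity scale
# (points-based strengths underlying the ClinGen recommendations).
EVIDENCE_THRESHOLDS <- c(strong = 18.7, moderate = 4.33, supporting = 2.08)

#' Build a benign/pathogenic truth set
#'
#' Pathogenic controls are ClinVar P/LP variants (protein-level,
#' deduplicated keeping the more definitive classification). Benign controls
#' are ClinVar B/LB variants, optionally supplemented ("plus" mode) by
#' frequency rules: maximum filtering allele frequency above the BA1 cutoff
#' (0.004), in the BS1 band (0.0004-0.004), or semi-rare
#' (0.000134-0.0004) with zero reported disease cases.
#'
#' @param clinvar `data.frame` with `variant_id`, `classification` (strings
#'   containing `"pathogenic"`, `"benign"`, `"uncertain"`/`"VUS"`, matched
#'   case-insensitively, with "likely" variants folded in).
#' @param freq Optional `data.frame` with `variant_id`, `maf` (maximum
#'   filtering allele frequency across ancestry groups).
#' @param cases Optional `data.frame` with `variant_id`, `n_cases` (reported
#'   disease cases).
#' @param variants Optional variant identity table used to restrict by
#'   consequence.
#' @param scope `"missense"` (default) or `"all"` consequences.
#' @param plus Include the frequency-based benign supplements (the "plus"
#'   truth-set flavors).
#' @return `data.frame` of class `truth_set` with `variant_id`, `label`
#'   (`P_LP`/`B_LB`), `source`.
#' @export
build_truth_set <- function(clinvar, freq = NULL, cases = NULL,
                            variants = NULL, scope = c("missense", "all"),
                            plus = TRUE) {
  scope <- match.arg(scope)
  cls <- tolower(clinvar$classification)
  rank <- ifelse(grepl("pathogenic", cls) & !grepl("conflict", cls), 3L,
          ifelse(grepl("benign", cls), 2L, 1L))
  # Protein-level dedup keeping the more definitive classification.
  ord <- order(clinvar$variant_id, -rank)
  cv <- clinvar[ord, ][!duplicated(clinvar$variant_id[ord]), ]
  cls <- tolower(cv$classification)
  p_ids <- cv$variant_id[grepl("pathogenic", cls) & !grepl("conflict", cls)]
  b_ids <- cv$variant_id[grepl("benign", cls)]
  src_p <- rep("clinvar", length(p_ids))
  src_b <- rep("clinvar", length(b_ids))

  if (plus && !is.null(freq)) {
    maf <- freq$maf
    n_cases <- if (is.null(cases)) rep(0, nrow(freq)) else {
      nc <- cases$n_cases[match(freq$variant_id, cases$variant_id)]
      ifelse(is.na(nc), 0, nc)
    }
    ba1 <- freq$variant_id[maf > MAF_BA1]
    bs1 <- freq$variant_id[maf > MAF_BS1 & maf <= MAF_BA1]
    semi <- freq$variant_id[maf > MAF_SEMIRARE_FLOOR & maf <= MAF_BS1 & n_cases == 0]
    for (grp in list(list(ba1, "BA1_freq"), list(bs1, "BS1_freq"),
                     list(semi, "semirare_no_cases"))) {
      new <- setdiff(grp[[1]], c(b_ids, p_ids))
      b_ids <- c(b_ids, new)
      src_b <- c(src_b, rep(grp[[2]], length(new)))
    }
  }
  both <- intersect(p_ids, b_ids)
  if (length(both)) {
    stop2("variants labeled both pathogenic and benign: ",
          paste(both, collapse = ", "))
  }
  out <- data.frame(
    variant_id = c(p_ids, b_ids),
    label = c(rep("P_LP", length(p_ids)), rep("B_LB", length(b_ids))),
    source = c(src_p, src_b),
    stringsAsFactors = FALSE
  )
  if (!is.null(variants) && scope == "missense") {
    cons <- variants$consequence[match(out$variant_id, variants$variant_id)]
    out <- out[!is.na(cons) & cons == "missense", , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("truth_set", "data.frame")
  out
}

# Join scores with a truth set; returns score/label vectors.
match_truth <- function(scores, truth) {
  m <- match(truth$variant_id, scores$variant_id)
  ok <- !is.na(m)
  list(score = scores$score[m[ok]], label = truth$label[ok],
       variant_id = truth$variant_id[ok])
}

#' ROC curve and AUC for a functional assay against a truth set
#'
#' AUC is computed from the Mann-Whitney rank statistic with midranks for
#' ties; orientation is fixed so that lower scores indicate pathogenicity
#' (AUC = probability that a random benign variant scores above a random
#' pathogenic one).
#'
#' @param scores `data.frame` with `variant_id`, `score`.
#' @param truth A `truth_set`.
#' @return List with `auc` and `curve` (`data.frame` of FPR/TPR points).
#' @export
roc_auc <- function(scores, truth) {
  mt <- match_truth(scores, truth)
  if (length(unique(mt$label)) < 2) stop2("both labels must be represented")
  s <- mt$score
  path <- mt$label == "P_LP"
  r <- rank(s)
  n1 <- sum(path); n0 <- sum(!path)
  auc <- (sum(r[!path]) - n0 * (n0 + 1) / 2) / (n0 * n1)
  # Curve: classify pathogenic when score < t, over all thresholds.
  ts <- c(-Inf, sort(unique(s)), Inf)
  curve <- t(vapply(ts, function(t) {
    c(fpr = mean(s[!path] < t), tpr = mean(s[path] < t))
  }, c(fpr = 0, tpr = 0)))
  list(auc = auc, curve = as.data.frame(curve))
}

#' OddsPath from a 2x2 truth-set contingency
#'
#' Core OddsPath computation from counts: `P1` is the prior proportion
#' pathogenic in the truth set; `P2` the proportion pathogenic in the
#' abnormal-score stratum (pathogenic evidence) or the normal-score stratum
#' (benign evidence); OddsPath = odds(P2) / odds(P1). An empty cell receives
#' one pseudo-variant of its own label before computing P2 (the Fayer
#' zero-cell correction); P1 is computed from the uncorrected totals.
#'
#' @param n_path,n_benign Truth-set sizes.
#' @param n_path_abnormal,n_benign_abnormal Counts with abnormal scores.
#' @return List with `oddspath_pathogenic`, `oddspath_benign`, `prior_p1`,
#'   and the (corrected) contingency.
#' @export
oddspath_from_counts <- function(n_path, n_path_abnormal,
                                 n_benign, n_benign_abnormal) {
  stopifnot(n_path_abnormal <= n_path, n_benign_abnormal <= n_benign)
  p1 <- n_path / (n_path + n_benign)
  ab_p <- n_path_abnormal; ab_b <- n_benign_abnormal
  no_p <- n_path - n_path_abnormal; no_b <- n_benign - n_benign_abnormal
  if ((ab_p + ab_b) == 0 || (no_p + no_b) == 0) {
    stop2("empty abnormal or normal stratum")
  }
  # Fayer correction: +1 of the cell's own label in any empty cell.
  cab_p <- max(ab_p, 1); cab_b <- max(ab_b, 1)
  cno_p <- max(no_p, 1); cno_b <- max(no_b, 1)
  p2_path <- cab_p / (cab_p + cab_b)
  p2_ben <- cno_p / (cno_p + cno_b)
  odds <- function(p) p / (1 - p)
  list(
    oddspath_pathogenic = odds(p2_path) / odds(p1),
    oddspath_benign = odds(p2_ben) / odds(p1),
    prior_p1 = p1,
    contingency = c(abnormal_path = ab_p, abnormal_benign = ab_b,
                    normal_path = no_p, normal_benign = no_b)
  )
}

#' Binary OddsPath calibration of assay scores
#'
#' Dichotomizes scores at `cutoff` (abnormal = score strictly below) and
#' computes OddsPath values from the truth-set contingency via
#' [oddspath_from_counts()]. The default cutoff placement is the lower bound
#' of the synonymous normal range stored on the score set.
#'
#' @param scores A `score_set` (or `data.frame` with `variant_id`, `score`).
#' @param truth A `truth_set`.
#' @param cutoff Abnormal/normal score boundary.
#' @return Object of class `mave_calibration` (binary mode) with the
#'   contingency, OddsPath values and cutoff.
#' @export
oddspath_binary <- function(scores, truth,
                            cutoff = attr(scores, "normal_range")[1]) {
  if (is.null(cutoff) || is.na(cutoff)) stop2("no cutoff available")
  mt <- match_truth(scores, truth)
  rng <- range(mt$score)
  if (cutoff < rng[1] || cutoff > rng[2]) {
    stop2("cutoff ", signif(cutoff, 3), " outside score range")
  }
  path <- mt$label == "P_LP"
  abn <- mt$score < cutoff
  op <- oddspath_from_counts(sum(path), sum(path & abn),
                             sum(!path), sum(!path & abn))
  structure(c(op, list(mode = "binary", cutoff = cutoff,
                       n = length(mt$score))),
            class = "mave_calibration")
}

#' Continuous kernel-density log-likelihood-ratio calibration
#'
#' Fits Gaussian kernel density estimates (bandwidth = sd of the kernel) to
#' the pathogenic and benign score distributions after trimming outliers
#' outside `trim`, and returns the natural-log likelihood ratio
#' `llr(s) = log fP(s) / fB(s)` evaluated on a fixed grid, with linear
#' interpolation for arbitrary scores. Densities are floored at `floor` to
#' keep the curve finite.
#'
#' @param scores A `score_set` or `data.frame` with `variant_id`, `score`.
#' @param truth A `truth_set`.
#' @param bandwidth Gaussian kernel standard deviation (score units).
#' @param trim Score range retained, default `c(-0.3, 1.5)`.
#' @param grid_step Evaluation grid step.
#' @param floor Density floor.
#' @param min_per_label Minimum trimmed variants required per label.
#' @return Object of class `mave_calibration` (llr mode) with `grid`, `llr`,
#'   the component densities, and an interpolating function `llr_fun`.
#' @export
llr_kernel <- function(scores, truth, bandwidth = 0.2, trim = c(-0.3, 1.5),
                       grid_step = 0.001, floor = 1e-12, min_per_label = 5L) {
  if (bandwidth <= 0) stop2("bandwidth must be positive")
  mt <- match_truth(scores, truth)
  keep <- mt$score >= trim[1] & mt$score <= trim[2]
  s <- mt$score[keep]; lab <- mt$label[keep]
  sp <- s[lab == "P_LP"]; sb <- s[lab == "B_LB"]
  if (length(sp) < min_per_label || length(sb) < min_per_label) {
    stop2("need at least ", min_per_label, " variants per label after trimming")
  }
  grid <- seq(trim[1], trim[2], by = grid_step)
  fp <- gaussian_kde(grid, sp, bandwidth)
  fb <- gaussian_kde(grid, sb, bandwidth)
  llr <- log(pmax(fp, floor) / pmax(fb, floor))
  structure(list(
    mode = "llr", grid = grid, llr = llr, f_pathogenic = fp, f_benign = fb,
    bandwidth = bandwidth, trim = trim,
    n = c(pathogenic = length(sp), benign = length(sb)),
    llr_fun = stats::approxfun(grid, llr, rule = 2)
  ), class = "mave_calibration")
}

# Gaussian kernel density estimate evaluated at `at` (bw = kernel sd).
gaussian_kde <- function(at, x, bw) {
  vapply(at, function(a) mean(stats::dnorm(a - x, sd = bw)), numeric(1))
}

#' Assign ACMG evidence strengths from a calibration
#'
#' Maps each variant's odds of pathogenicity — `exp(llr(score))` for a
#' continuous calibration, or the stratum OddsPath for a binary one — onto
#' symmetric evidence thresholds (18.7 strong, 4.33 moderate, 2.08
#' supporting; reciprocals toward benignity). Benign evidence is capped at
#' moderate.
#'
#' @param calibration A `mave_calibration`.
#' @param scores A `score_set` or `data.frame` with `variant_id`, `score`.
#' @param thresholds Named odds thresholds.
#' @return `data.frame` with `variant_id`, `score`, `odds_path`, `evidence`
#'   (one of `PS3_strong`, `PS3_moderate`, `PS3_supporting`, `none`,
#'   `BS3_supporting`, `BS3_moderate`); attribute `tally` with per-category
#'   counts.
#' @export
assign_evidence <- function(calibration, scores,
                            thresholds = EVIDENCE_THRESHOLDS) {
  stopifnot(inherits(calibration, "mave_calibration"))
  s <- scores$score
  odds <- if (identical(calibration$mode, "llr")) {
    exp(calibration$llr_fun(pmin(pmax(s, calibration$trim[1]),
                                 calibration$trim[2])))
  } else {
    ifelse(s < calibration$cutoff,
           calibration$oddspath_pathogenic,
           calibration$oddspath_benign)
  }
  ev <- evidence_from_odds(odds, thresholds)
  out <- data.frame(variant_id = scores$variant_id, score = s,
                    odds_path = odds, evidence = ev,
                    stringsAsFactors = FALSE)
  lv <- c("PS3_strong", "PS3_moderate", "PS3_supporting", "none",
          "BS3_supporting", "BS3_moderate")
  attr(out, "tally") <- table(factor(ev, levels = lv))
  out
}

evidence_from_odds <- function(odds, thresholds) {
  ifelse(odds >= thresholds["strong"], "PS3_strong",
  ifelse(odds >= thresholds["moderate"], "PS3_moderate",
  ifelse(odds >= thresholds["supporting"], "PS3_supporting",
  ifelse(odds <= 1 / thresholds["moderate"], "BS3_moderate",
  ifelse(odds <= 1 / thresholds["supporting"], "BS3_supporting",
         "none")))))
}

#' @export
print.mave_calibration <- function(x, ...) {
  if (identical(x$mode, "binary")) {
    cat("<mave_calibration> binary OddsPath at cutoff",
        signif(x$cutoff, 4), "\n")
    cat(sprintf("  prior P1 = %.4f (n = %d)\n", x$prior_p1, x$n))
    print(x$contingency)
    cat(sprintf("  OddsPath: pathogenic %.3f, benign %.3f\n",
                x$oddspath_pathogenic, x$oddspath_benign))
  } else {
    cat("<mave_calibration> kernel LLR, bandwidth", x$bandwidth, "\n")
    cat(sprintf("  %d pathogenic / %d benign controls in [%.2g, %.2g]\n",
                x$n["pathogenic"], x$n["benign"], x$trim[1], x$trim[2]))
    cat(sprintf("  llr range on grid: [%.2f, %.2f]\n",
                min(x$llr), max(x$llr)))
  }
  invisible(x)
}

#' @export
plot.mave_calibration <- function(x, ...) {
  if (!identical(x$mode, "llr")) {
    stop2("plotting is defined for continuous (llr) calibrations")
  }
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  graphics::plot(x$grid, x$f_pathogenic, type = "l", col = "firebrick",
                 xlab = "score", ylab = "density", ...)
  graphics::lines(x$grid, x$f_benign, col = "steelblue")
  graphics::legend("topleft", legend = c("pathogenic", "benign"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  graphics::plot(x$grid, x$llr, type = "l", xlab = "score",
                 ylab = "log likelihood ratio")
  graphics::abline(h = log(c(EVIDENCE_THRESHOLDS,
                             1 / EVIDENCE_THRESHOLDS[c("moderate", "supporting")])),
                   lty = 3, col = "grey50")
  invisible(x)
}
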