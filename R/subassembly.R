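# Subassembly: convert raw barcode-bearing reads into a validated
# barcode -> variant map. Four stages: flank-anchored barcode extraction,
# trough thresholding of the bimodal barcode-frequency distribution,
# Hamming-distance collapse of sequencing-error barcodes, and per-barcode
# consensus calling against the reference coding sequence.

#' Extract barcodes anchored by constant flanks
#'
#' Counts the fixed-length substring found between exact matches of the
#' constant prefix and suffix. Reads lacking either flank are dropped and
#' tallied in the `dropped` attribute.
#'
#' @param reads A `read_set` (or any data frame with a `seq` column).
#' @param prefix,suffix Constant flanking sequences, 5-6 nt each.
#' @param barcode_length Barcode length in nt.
#' @return `data.frame` with columns `barcode`, `count`, ordered by
#'   decreasing count; attribute `dropped` holds the number of flank-failing
#'   reads and attribute `read_barcode` the per-read barcode (NA if dropped),
#'   used later to group reads per barcode.
#' @export
extract_barcodes <- function(reads, prefix, suffix, barcode_length = 18L) {
  if (!(nchar(prefix) %in% 5:6) || !(nchar(suffix) %in% 5:6)) {
    stop2("prefix/suffix must be 5-6 nt")
  }
  if (nrow(reads) == 0) {
    out <- data.frame(barcode = character(), count = integer())
    attr(out, "dropped") <- 0L
    attr(out, "read_barcode") <- character()
    return(out)
  }
  pat <- paste0(prefix, "([ACGTN]{", barcode_length, "})", suffix)
  m <- regexpr(pat, reads$seq)
  bc <- rep(NA_character_, nrow(reads))
  ok <- m != -1L
  bc[ok] <- substr(regmatches(reads$seq, m), nchar(prefix) + 1L,
                   nchar(prefix) + barcode_length)
  tab <- table(bc[ok])
  out <- data.frame(barcode = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$barcode), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!ok)
  attr(out, "read_barcode") <- bc
  out
}

#' Threshold barcodes at the trough of a bimodal frequency distribution
#'
#' Builds a histogram of log10(count), smooths it with a moving average, and
#' places the threshold at the histogram minimum between the two largest
#' local maxima — mechanizing the visual trough choice that separates genuine
#' high-frequency barcodes from sequencing-error barcodes. A unimodal
#' histogram falls back to `fallback` with a warning.
#'
#' @param counts `data.frame` with columns `barcode`, `count`.
#' @param n_bins Histogram bins over the log10(count) range.
#' @param smooth_window Moving-average window (odd).
#' @param fallback Fixed threshold used when no trough is found.
#' @return List with `counts` (rows with `count >= threshold`) and
#'   `threshold`.
#' @export
threshold_barcodes <- function(counts, n_bins = 25L, smooth_window = 3L,
                               fallback = 2L) {
  if (nrow(counts) == 0) return(list(counts = counts, threshold = fallback))
  lx <- log10(counts$count)
  if (length(unique(counts$count)) < 2 || diff(range(lx)) == 0) {
    warning("degenerate count distribution; using fallback threshold")
    return(list(counts = counts[counts$count >= fallback, , drop = FALSE],
                threshold = fallback))
  }
  h <- graphics::hist(lx, breaks = seq(min(lx), max(lx), length.out = n_bins + 1),
                      plot = FALSE)
  dens <- smooth_ma(h$counts, smooth_window)
  peaks <- which(diff(sign(diff(c(-Inf, dens, -Inf)))) == -2)
  if (length(peaks) < 2) {
    warning("unimodal barcode-frequency histogram; using fallback threshold")
    return(list(counts = counts[counts$count >= fallback, , drop = FALSE],
                threshold = fallback))
  }
  top2 <- peaks[order(-dens[peaks])][1:2]
  lo <- min(top2); hi <- max(top2)
  trough <- lo + which.min(dens[lo:hi]) - 1L
  threshold <- ceiling(10^h$mids[trough])
  list(counts = counts[counts$count >= threshold, , drop = FALSE],
       threshold = threshold)
}

smooth_ma <- function(x, window) {
  if (window <= 1) return(x)
  k <- rep(1 / window, window)
  as.numeric(stats::filter(x, k, sides = 2, circular = FALSE)) -> s
  s[is.na(s)] <- x[is.na(s)]
  s
}

#' Collapse barcodes within Hamming distance 2
#'
#' For every pair of equal-length barcodes within two substitutions of each
#' other, the lower-count member is removed (greedy by descending count;
#' count ties broken by removing the lexicographically larger barcode). This
#' removes low-frequency barcodes that are sequencing errors of genuine ones.
#'
#' @param counts `data.frame` with columns `barcode`, `count`.
#' @param max_dist Maximum Hamming distance collapsed (default 2).
#' @return The surviving rows, ordered by decreasing count.
#' @export
collapse_barcodes <- function(counts, max_dist = 2L) {
  n <- nrow(counts)
  if (n <= 1) return(counts)
  len <- unique(nchar(counts$barcode))
  if (length(len) != 1) stop2("barcodes must be equal length")
  ord <- order(-counts$count, counts$barcode)
  counts <- counts[ord, , drop = FALSE]
  rownames(counts) <- NULL
  pairs <- candidate_pairs(counts$barcode, max_dist)
  keep <- rep(TRUE, n)
  if (nrow(pairs)) {
    # pairs are (i, j) with i < j in priority order: j is removed when i kept
    ordp <- order(pairs[, 1])
    pairs <- pairs[ordp, , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (keep[i] && keep[j]) keep[j] <- FALSE
    }
  }
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pigeonhole candidate generation: any pair within Hamming distance <= 2 of
# length-L barcodes agrees exactly on at least one of three L/3 segments.
candidate_pairs <- function(bc, max_dist) {
  n <- length(bc)
  L <- nchar(bc[1])
  nseg <- max_dist + 1L
  cut <- floor(seq(0, L, length.out = nseg + 1))
  m <- matrix(charToRaw(paste(bc, collapse = "")), nrow = L)
  seen <- new.env(hash = TRUE)
  out <- list()
  for (s in seq_len(nseg)) {
    seg <- substr(bc, cut[s] + 1L, cut[s + 1L])
    grp <- split(seq_len(n), seg)
    grp <- grp[lengths(grp) > 1]
    for (g in grp) {
      cmb <- utils::combn(g, 2)
      for (k in seq_len(ncol(cmb))) {
        i <- cmb[1, k]; j <- cmb[2, k]
        key <- paste0(i, "_", j)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        if (sum(m[, i] != m[, j]) <= max_dist) {
          out[[length(out) + 1L]] <- c(i, j)
        }
      }
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 2))
  do.call(rbind, out)
}

#' Call per-barcode consensus sequences and build the barcode -> variant map
#'
#' Groups reads by barcode, piles amplicons onto reference coordinates using
#' the start position carried in the read name, calls a per-position majority
#' base (majority fraction >= `majority`, coverage >= `min_coverage`), and
#' classifies each barcode by its consensus against the reference: exactly
#' one changed codon is accepted as a single amino-acid variant; fully
#' wild-type, multi-codon and ambiguous/low-coverage barcodes are rejected.
#' A barcode observed at more than one amplicon locus (the analogue of one
#' barcode appearing in two mutagenesis zones) is rejected as ambiguous.
#'
#' @param reads A `read_set` of subassembly reads.
#' @param reference_cds Reference coding sequence (in frame).
#' @param barcodes Character vector of barcodes to call (typically the
#'   thresholded, collapsed set). Defaults to all extracted barcodes.
#' @param prefix,suffix,barcode_length Flank/barcode geometry, as in
#'   [extract_barcodes()].
#' @param min_coverage Minimum reads per barcode.
#' @param majority Minimum majority fraction per position.
#' @return `data.frame` of class `barcode_map`: `barcode`, `variant_id`,
#'   `position`, `wt`, `alt`, `consequence`, `support`, `status` (one of
#'   `accepted`, `rejected_wt`, `rejected_multi`, `rejected_ambiguous`).
#' @export
call_consensus <- function(reads, reference_cds, barcodes = NULL,
                           prefix = "AGGAC", suffix = "CTCGA",
                           barcode_length = 18L,
                           min_coverage = 3L, majority = 0.6) {
  ext <- extract_barcodes(reads, prefix, suffix, barcode_length)
  read_bc <- attr(ext, "read_barcode")
  if (is.null(barcodes)) barcodes <- ext$barcode
  pos_m <- regmatches(reads$id, regexpr("pos=\\d+", reads$id))
  ref_start <- as.integer(sub("pos=", "", pos_m))
  amp_start <- nchar(prefix) + barcode_length + nchar(suffix) + 1L
  amplicon <- substr(reads$seq, amp_start, nchar(reads$seq))
  ok <- !is.na(read_bc) & read_bc %in% barcodes
  grp <- split(which(ok), read_bc[ok])

  rows <- lapply(names(grp), function(b) {
    ii <- grp[[b]]
    call_one_barcode(b, amplicon[ii], ref_start[ii], reference_cds,
                     min_coverage, majority)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(barcode = character(), variant_id = character(),
                      position = integer(), wt = character(),
                      alt = character(), consequence = character(),
                      support = integer(), status = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("barcode_map", "data.frame")
  out
}

call_one_barcode <- function(barcode, amps, starts, cds, min_coverage, majority) {
  res <- function(status, variant = NULL) {
    data.frame(
      barcode = barcode,
      variant_id = if (is.null(variant)) NA_character_ else variant$variant_id,
      position = if (is.null(variant)) NA_integer_ else variant$position,
      wt = if (is.null(variant)) NA_character_ else variant$wt,
      alt = if (is.null(variant)) NA_character_ else variant$alt,
      consequence = if (is.null(variant)) NA_character_ else variant$consequence,
      support = length(amps),
      status = status,
      stringsAsFactors = FALSE
    )
  }
  if (length(amps) < min_coverage) return(res("rejected_ambiguous"))
  if (length(unique(starts)) > 1) return(res("rejected_ambiguous"))
  w <- unique(nchar(amps))
  if (length(w) != 1) return(res("rejected_ambiguous"))
  start <- starts[1]
  ref_win <- substr(cds, start, start + w - 1L)
  if (nchar(ref_win) != w) return(res("rejected_ambiguous"))
  m <- matrix(charToRaw(paste(amps, collapse = "")), nrow = w)
  bases <- charToRaw("ACGT")
  cnt <- vapply(seq_along(bases), function(k) rowSums(m == bases[k]),
                numeric(w))
  best <- max.col(cnt, ties.method = "first")
  frac <- cnt[cbind(seq_len(w), best)] / length(amps)
  if (any(frac < majority)) return(res("rejected_ambiguous"))
  cons <- rawToChar(bases[best])
  ref_chars <- ref_win
  diffs <- which(charToRaw(cons) != charToRaw(ref_chars))
  if (!length(diffs)) return(res("rejected_wt"))
  # Map differing nt positions to codon indices on the reference frame.
  nt_pos <- start + diffs - 1L
  codons <- unique((nt_pos - 1L) %/% 3L + 1L)
  if (length(codons) > 1) return(res("rejected_multi"))
  cpos <- codons
  c0 <- 3L * (cpos - 1L) + 1L
  off <- c0 - start
  if (off < 0 || off + 3L > w) return(res("rejected_ambiguous"))
  alt_codon <- substr(cons, off + 1L, off + 3L)
  ref_codon <- cds_codon(cds, cpos)
  wt_aa <- codon_to_aa(ref_codon)
  alt_aa <- codon_to_aa(alt_codon)
  v <- variant_table(cpos, wt_aa, alt_aa)
  res("accepted", v)
}

#' Run the full subassembly pipeline on a read set
#'
#' Extraction, trough thresholding, Hamming collapse and consensus calling,
#' in order, returning the accepted and rejected barcode calls plus a drop
#' log.
#'
#' @inheritParams call_consensus
#' @param threshold_fallback Fallback count threshold when the barcode
#'   frequency histogram has no trough.
#' @return A `barcode_map` with attribute `log` (a list with counts of
#'   dropped reads and removed barcodes at each stage).
#' @export
subassemble <- function(reads, reference_cds,
                        prefix = "AGGAC", suffix = "CTCGA",
                        barcode_length = 18L, min_coverage = 3L,
                        majority = 0.6, threshold_fallback = 2L) {
  ext <- extract_barcodes(reads, prefix, suffix, barcode_length)
  thr <- threshold_barcodes(ext, fallback = threshold_fallback)
  coll <- collapse_barcodes(thr$counts)
  map <- call_consensus(reads, reference_cds, barcodes = coll$barcode,
                        prefix = prefix, suffix = suffix,
                        barcode_length = barcode_length,
                        min_coverage = min_coverage, majority = majority)
  attr(map, "log") <- list(
    reads_dropped_no_flank = attr(ext, "dropped"),
    barcodes_extracted = nrow(ext),
    threshold = thr$threshold,
    barcodes_below_threshold = nrow(ext) - nrow(thr$counts),
    barcodes_collapsed = nrow(thr$counts) - nrow(coll),
    barcodes_called = nrow(map),
    accepted = sum(map$status == "accepted")
  )
  map
}
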