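# Shared fixtures, built once on first use and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# Small simulated study: 600 variants, 3 replicates, 4 assays, scored.
fixture_study <- function() {
  if (!is.null(.fixture_env$study)) return(.fixture_env$study)
  cfg <- sim_config(n_variants = 600, n_cells = 6e5, reads_per_sample = 3e6,
                    seed = 42)
  truth <- simulate_truth(cfg)
  counts <- lapply(setNames(nm = c("abundance", "function",
                                   "het_abundance", "het_function")),
    function(a) {
      do.call(rbind, lapply(seq_len(cfg$n_replicates), function(r) {
        if (a %in% c("abundance", "het_abundance")) {
          simulate_facs(truth, cfg, replicate = r, assay = a)
        } else {
          simulate_selection(truth, cfg, replicate = r, assay = a)
        }
      }))
    })
  scores <- lapply(names(counts), function(a) score_assay(counts[[a]], truth, a))
  names(scores) <- names(counts)
  .fixture_env$study <- list(cfg = cfg, truth = truth, counts = counts,
                             scores = scores)
  .fixture_env$study
}

# Brute-force O(n^2) oracle for barcode collapse: greedy by descending count,
# ties broken lexicographically, remove the lower member of any pair within
# Hamming distance <= max_dist of a kept barcode.
collapse_oracle <- function(counts, max_dist = 2L) {
  ord <- order(-counts$count, counts$barcode)
  counts <- counts[ord, , drop = FALSE]
  n <- nrow(counts)
  hamming <- function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  }
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (j <= i || !keep[j]) next
      if (hamming(counts$barcode[i], counts$barcode[j]) <= max_dist) {
        keep[j] <- FALSE
      }
    }
  }
  counts[keep, , drop = FALSE]
}

# Direct-arithmetic oracles for the two raw scores.
w_oracle <- function(f) sum((0:3) * f) / sum(f)
r28_oracle <- function(f0, f28) log2((f28 + 10) / (f0 + 10))

# Category oracle following the stated rules.
category_oracle <- function(score, lower, upper) {
  if (score > upper) "gain"
  else if (score >= lower) "normal"
  else if (score >= 0.25) "partial_loss"
  else "loss"
}

random_counts <- function(n, len = 8L, max_count = 1000L) {
  repeat {
    bc <- apply(matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
                       nrow = n), 1, paste0, collapse = "")
    if (!anyDuplicated(bc)) break
  }
  data.frame(barcode = bc, count = sample.int(max_count, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
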