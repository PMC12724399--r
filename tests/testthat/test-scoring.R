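bin_table <- function(rpm_by_bin, variant = "A1V", replicate = 1L) {
  data.frame(entity_id = variant, sample_id = paste0("bin", 1:4),
             replicate = replicate, rpm = rpm_by_bin,
             stringsAsFactors = FALSE)
}

day_table <- function(f0, f28, variant = "A1V", replicate = 1L) {
  data.frame(entity_id = variant, sample_id = c("day0", "day28"),
             replicate = replicate, rpm = c(f0, f28),
             stringsAsFactors = FALSE)
}

test_that("weighted bin score W matches its arithmetic definition", {
  expect_equal(abundance_raw(bin_table(c(10, 0, 0, 0)))$value, 0)
  expect_equal(abundance_raw(bin_table(c(0, 0, 0, 10)))$value, 3)
  expect_equal(abundance_raw(bin_table(c(1, 2, 3, 4)))$value, 2.0)
  expect_error(abundance_raw(bin_table(c(-1, 2, 3, 4))), "negative")
  # All-zero variants are dropped, not scored
  tab <- rbind(bin_table(c(0, 0, 0, 0), "A2V"), bin_table(c(1, 1, 1, 1)))
  expect_equal(abundance_raw(tab)$variant_id, "A1V")
})

test_that("function score R28 applies the pseudocount log-ratio", {
  expect_equal(function_raw(day_table(100, 100))$value, 0)
  expect_equal(function_raw(day_table(0, 0))$value, 0)
  expect_equal(function_raw(day_table(30, 150))$value, 2.0)
  expect_equal(function_raw(day_table(30, 150))$mean_rpm, 30)
})

test_that("W and R28 match brute-force arithmetic on random tables", {
  set.seed(101)
  for (i in 1:200) {
    f <- runif(4, 0, 1000)
    expect_equal(abundance_raw(bin_table(f))$value, w_oracle(f))
    f0 <- runif(1, 0, 2000); f28 <- runif(1, 0, 2000)
    expect_equal(function_raw(day_table(f0, f28))$value, r28_oracle(f0, f28))
  }
})

test_that("upward bin-mass shifts never decrease W", {
  set.seed(7)
  for (i in 1:100) {
    f <- runif(4, 0, 100)
    from <- sample(1:3, 1)
    to <- if (from == 3) 4L else sample((from + 1):4, 1)
    g <- f
    moved <- runif(1, 0, f[from])
    g[from] <- g[from] - moved
    g[to] <- g[to] + moved
    expect_gte(w_oracle(g), w_oracle(f) - 1e-12)
  }
})

test_that("barcode counts pool to variants and renormalize", {
  counts <- data.frame(entity_id = c("bc1", "bc2", "bc3"),
                       sample_id = "bin1", replicate = 1L,
                       rpm = c(5, 7, 12), stringsAsFactors = FALSE)
  map <- data.frame(barcode = c("bc1", "bc2", "bc3"),
                    variant_id = c("A1V", "A1V", "B2C"),
                    stringsAsFactors = FALSE)
  out <- aggregate_to_variants(counts, map)
  v <- out$rpm[out$entity_id == "A1V"]
  expect_equal(v, 12 / 24 * 1e6)  # 5 + 7 pooled, then renormalized
  one <- aggregate_to_variants(counts, map[1:2, ])
  expect_equal(one$rpm, 1e6)
  expect_error(aggregate_to_variants(counts,
                 data.frame(barcode = "zz", variant_id = "X1Y")), "map")
})

test_that("pooling matches a group-by oracle on simulated data", {
  st <- fixture_study()
  lib <- simulate_barcode_library(st$truth, st$cfg)
  counts <- simulate_facs(st$truth, st$cfg, replicate = 1, barcode_lib = lib)
  got <- aggregate_to_variants(counts, lib)
  key <- lib$variant_id[match(counts$entity_id, lib$barcode)]
  oracle <- tapply(counts$rpm[counts$sample_id == "bin2"],
                   key[counts$sample_id == "bin2"], sum)
  oracle <- setNames(as.numeric(oracle) / sum(oracle) * 1e6, names(oracle))
  got2 <- got$rpm[got$sample_id == "bin2"]
  names(got2) <- got$entity_id[got$sample_id == "bin2"]
  expect_equal(got2[names(oracle)], oracle[names(oracle)])
})

test_that("coverage filters use strict thresholds exactly as stated", {
  raw <- data.frame(variant_id = c("a", "b", "c"), replicate = 1L,
                    value = 1, mean_rpm = c(24.9, 25, 26))
  out <- filter_low_coverage(raw, "abundance")
  expect_setequal(out$variant_id, c("b", "c"))
  rawf <- data.frame(variant_id = c("a", "b"), replicate = 1L,
                     value = 0, mean_rpm = c(14.99, 15))
  outf <- filter_low_coverage(rawf, "function")
  expect_equal(outf$variant_id, "b")
  # brute-force oracle on a random mixed table
  set.seed(3)
  tab <- data.frame(variant_id = paste0("v", 1:200), replicate = 1L,
                    value = 0, mean_rpm = runif(200, 0, 50))
  expect_setequal(filter_low_coverage(tab, "abundance")$variant_id,
                  tab$variant_id[tab$mean_rpm >= 25])
})

anchor_fixture <- function(n_syn = 21, n_non = 21, syn_at = 2.4, non_at = 0.3,
                           extra = NULL) {
  pos_syn <- seq_len(n_syn)
  pos_non <- seq(30, 29 + n_non)
  v <- variant_table(c(pos_syn, pos_non), rep("A", n_syn + n_non),
                     c(rep("A", n_syn), rep("*", n_non)))
  raw <- data.frame(variant_id = v$variant_id, replicate = 1L,
                    value = c(rep(syn_at, n_syn), rep(non_at, n_non)),
                    mean_rpm = 100, stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    v2 <- variant_table(extra$position, extra$wt, extra$alt)
    v <- rbind(v, v2)
    raw <- rbind(raw, data.frame(variant_id = v2$variant_id, replicate = 1L,
                                 value = extra$value, mean_rpm = 100))
  }
  list(variants = v, raw = raw)
}

test_that("normalization maps the anchors to exactly 0 and 1", {
  fx <- anchor_fixture(extra = list(position = 100, wt = "A", alt = "V",
                                    value = 1.35))
  norm <- normalize_replicate(fx$raw, fx$variants, "function",
                              by_zone = FALSE)
  vs <- setNames(norm$score, norm$variant_id)
  expect_equal(unname(vs["A100V"]), 0.5)  # (1.35-0.3)/(2.4-0.3)
  expect_equal(unname(vs["A1="]), 1)
  expect_equal(unname(vs["A30*"]), 0)
})

test_that("normalization is invariant to positive affine maps of raw scores", {
  fx <- anchor_fixture(extra = list(position = c(100, 101), wt = c("A", "A"),
                                    alt = c("V", "W"), value = c(1.0, 0.6)))
  n1 <- normalize_replicate(fx$raw, fx$variants, "function", by_zone = FALSE)
  fx$raw$value <- 3.7 * fx$raw$value + 11
  n2 <- normalize_replicate(fx$raw, fx$variants, "function", by_zone = FALSE)
  expect_equal(n1$score, n2$score)
})

test_that("heterozygous abundance anchors to the all-bin-1 score of zero", {
  fx <- anchor_fixture(syn_at = 1.6, extra = list(position = 100, wt = "A",
                                                  alt = "V", value = 0.8))
  norm <- normalize_replicate(fx$raw, fx$variants, "het_abundance")
  vs <- setNames(norm$score, norm$variant_id)
  expect_equal(unname(vs["A100V"]), 0.5)  # 0.8 / 1.6
})

test_that("function-assay nonsense anchor excludes the readthrough window", {
  # nonsense at 250 (inside 239-307) must not contribute to the anchor
  v <- variant_table(c(1:21, 250, 400:420), rep("A", 43),
                     c(rep("A", 21), "*", rep("*", 21)))
  raw <- data.frame(variant_id = v$variant_id, replicate = 1L,
                    value = c(rep(2, 21), 99, rep(0.5, 21)), mean_rpm = 100)
  norm <- normalize_replicate(raw, v, "function", by_zone = FALSE)
  vs <- setNames(norm$score, norm$variant_id)
  expect_equal(unname(vs["A400*"]), 0)  # anchor from 400-420 only
  expect_gt(unname(vs["A250*"]), 1)     # readthrough-window variant excluded
})

test_that("replicate merging averages, filters noise and re-anchors", {
  fx <- anchor_fixture()
  raw2 <- fx$raw; raw2$replicate <- 2L
  target <- variant_table(c(100, 101), c("A", "A"), c("V", "W"))
  v <- rbind(fx$variants, target)
  tr <- data.frame(variant_id = rep(target$variant_id, 2),
                   replicate = rep(1:2, each = 2),
                   value = c(0.3 + 2.1 * 0.9, 0.3 + 2.1 * 0,
                             0.3 + 2.1 * 1.1, 0.3 + 2.1 * 2),
                   mean_rpm = 100)
  norm <- normalize_replicate(rbind(fx$raw, raw2, tr), v, "function",
                              by_zone = FALSE)
  merged <- merge_replicates(norm, v, "function", sem_cutoff = 0.5)
  ms <- setNames(merged$score, merged$variant_id)
  expect_equal(unname(ms["A100V"]), 1.0)          # mean of 0.9 and 1.1
  expect_equal(merged$sem[merged$variant_id == "A100V"], 0.1)
  expect_false("A101W" %in% merged$variant_id)    # SEM 1 > 0.5 removed
  # anchoring invariant after merge
  syn <- merged$score[merged$consequence == "synonymous"]
  non <- merged$score[merged$consequence == "nonsense"]
  expect_equal(median(syn), 1, tolerance = 1e-9)
  expect_equal(median(non), 0, tolerance = 1e-9)
})

test_that("merged simulated replicates keep anchor medians at 0 and 1", {
  st <- fixture_study()
  for (a in c("function", "abundance")) {
    s <- st$scores[[a]]
    syn <- s$score[s$consequence == "synonymous"]
    anchor_pos <- mavescorer:::nonsense_anchor_positions(a)
    non <- s$score[s$consequence == "nonsense" & s$position %in% anchor_pos]
    expect_equal(median(syn), 1, tolerance = 1e-9)
    expect_equal(median(non), 0, tolerance = 1e-9)
  }
})

test_that("categorization follows the synonymous interval and 0.25 cutoffs", {
  syn <- seq(0.7, 1.3, length.out = 41)  # 2.5th/97.5th at 0.706/1.294
  sc <- structure(
    data.frame(variant_id = paste0("A", 1:5, "V"), position = 1:5,
               wt = "A", alt = "V", consequence = "missense",
               score = c(1.0, 1.5, 0.5, 0.1, 0.25), sem = 0.01, n_reps = 3L),
    assay = "function", class = c("score_set", "data.frame"))
  out <- categorize(sc, syn_scores = syn)
  expect_equal(out$category,
               c("normal", "gain", "partial_loss", "loss", "partial_loss"))
  bounds <- attr(out, "normal_range")
  set.seed(5)
  for (i in 1:100) {
    s <- runif(1, -0.5, 2)
    sc1 <- sc; sc1$score[1] <- s
    expect_equal(categorize(sc1, syn_scores = syn)$category[1],
                 category_oracle(s, bounds[1], bounds[2]))
  }
  expect_error(categorize(sc, syn_scores = syn[1:5]), "at least")
  expect_error(categorize(sc, syn_scores = runif(41, 0, 0.2)), "degenerate")
})

test_that("drug-binding residues are excluded from function assays only", {
  sc <- structure(
    data.frame(variant_id = c("W248L", "F335=", "A10V"),
               position = c(248, 335, 10), wt = c("W", "F", "A"),
               alt = c("L", "F", "V"),
               consequence = c("missense", "synonymous", "missense"),
               score = 1, sem = 0.01, n_reps = 3L),
    assay = "function", class = c("score_set", "data.frame"))
  out <- exclude_drug_residues(sc, "function")
  expect_setequal(out$variant_id, c("F335=", "A10V"))
  ab <- sc; attr(ab, "assay") <- "abundance"
  expect_equal(nrow(exclude_drug_residues(ab, "abundance")), 3)
})

test_that("competitive index follows the WT-vs-empty ratio formula", {
  tab <- function(wt0, wt28, e0, e28) {
    data.frame(condition = c("WT", "WT", "empty", "empty"),
               day = c(0, 28, 0, 28), abundance = c(wt0, wt28, e0, e28))
  }
  expect_equal(competitive_index(tab(100, 100, 50, 50), 28), 100)
  expect_equal(competitive_index(tab(100, 50, 50, 50), 28), 50)
  expect_equal(competitive_index(tab(200, 60, 100, 90), 28), 100 * 0.3 / 0.9)
  expect_error(competitive_index(tab(0, 50, 50, 50), 28), "zero")
})

test_that("scores recover latent function on simulated data", {
  st <- fixture_study()
  fs <- st$scores[["function"]]
  lat <- st$truth$latent_function[match(fs$variant_id, st$truth$variant_id)]
  expect_gt(cor(fs$score, lat, method = "spearman"), 0.9)
})
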