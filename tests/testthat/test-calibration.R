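test_that("truth sets follow ClinVar and allele-frequency rules", {
  clinvar <- data.frame(
    variant_id = c("A1V", "A2V", "A3V", "A3V", "A4V"),
    classification = c("Pathogenic", "Likely benign",
                       "Uncertain significance", "Likely pathogenic",
                       "Uncertain significance"))
  freq <- data.frame(variant_id = c("A5V", "A6V", "A7V", "A8V", "A9V"),
                     maf = c(0.005, 0.001, 0.0002, 0.0002, 0.0001))
  cases <- data.frame(variant_id = "A8V", n_cases = 3)
  ts <- build_truth_set(clinvar, freq, cases)
  lab <- setNames(ts$label, ts$variant_id)
  src <- setNames(ts$source, ts$variant_id)
  expect_equal(unname(lab["A1V"]), "P_LP")
  expect_equal(unname(lab["A2V"]), "B_LB")
  expect_equal(unname(lab["A3V"]), "P_LP")     # dedup keeps more definitive
  expect_false("A4V" %in% ts$variant_id)       # VUS excluded
  expect_equal(unname(src["A5V"]), "BA1_freq")        # MAF > 0.004
  expect_equal(unname(src["A6V"]), "BS1_freq")        # 0.0004 < MAF < 0.004
  expect_equal(unname(src["A7V"]), "semirare_no_cases")
  expect_false("A8V" %in% ts$variant_id)       # semi-rare but has cases
  expect_false("A9V" %in% ts$variant_id)       # below the semi-rare floor
  # plain ClinVar flavor drops the frequency supplements
  ts2 <- build_truth_set(clinvar, freq, cases, plus = FALSE)
  expect_false(any(ts2$source != "clinvar"))
})

test_that("conflicting labels and scope restriction are handled", {
  clinvar <- data.frame(variant_id = "A1V", classification = "Pathogenic")
  freq <- data.frame(variant_id = "A1V", maf = 0.01)
  ts <- build_truth_set(clinvar, freq)   # P/LP wins; BA1 not applied on top
  expect_equal(ts$label, "P_LP")
  v <- variant_table(c(1, 2), c("A", "A"), c("V", "A"))
  clinvar2 <- data.frame(variant_id = v$variant_id,
                         classification = c("Pathogenic", "Benign"))
  ts3 <- build_truth_set(clinvar2, variants = v, scope = "missense")
  expect_equal(ts3$variant_id, "A1V")    # synonymous dropped in missense scope
})

test_that("AUC matches brute-force pair counting and a reference package", {
  sc <- data.frame(variant_id = paste0("v", 1:6),
                   score = c(0.1, 0.2, 0.4, 0.3, 0.9, 1.0))
  ts <- data.frame(variant_id = sc$variant_id,
                   label = c("P_LP", "P_LP", "P_LP", "B_LB", "B_LB", "B_LB"))
  expect_equal(roc_auc(sc, ts)$auc, 8 / 9)
  expect_error(roc_auc(sc, ts[ts$label == "P_LP", ]), "both labels")
  skip_if_not_installed("pROC")
  set.seed(19)
  sc2 <- data.frame(variant_id = paste0("v", 1:100), score = runif(100))
  ts2 <- data.frame(variant_id = sc2$variant_id,
                    label = sample(c("P_LP", "B_LB"), 100, replace = TRUE))
  ours <- roc_auc(sc2, ts2)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = ts2$label == "B_LB", predictor = sc2$score,
    quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(23)
  sc <- data.frame(variant_id = paste0("v", 1:2000), score = runif(2000))
  ts <- data.frame(variant_id = sc$variant_id,
                   label = sample(c("P_LP", "B_LB"), 2000, replace = TRUE))
  expect_lt(abs(roc_auc(sc, ts)$auc - 0.5), 0.05)
})

test_that("OddsPath reproduces the hand-computed contingency values", {
  op <- oddspath_from_counts(204, 168, 28, 0)
  # (168/1) / (204/28) with the +1 zero-cell correction
  expect_equal(op$oddspath_pathogenic, (168 / 1) / (204 / 28))
  expect_equal(signif(op$oddspath_pathogenic, 3), 23.1)
  expect_equal(op$oddspath_benign, (36 / 28) / (204 / 28))
  expect_equal(op$prior_p1, 204 / 232)
  sym <- oddspath_from_counts(100, 50, 100, 50)  # P1 = P2 = 0.5
  expect_equal(sym$oddspath_pathogenic, 1)
  expect_error(oddspath_from_counts(10, 0, 10, 0), "empty")
})

test_that("pathogenic OddsPath is monotone in the abnormal-pathogenic count", {
  vals <- sapply(150:204, function(k) {
    oddspath_from_counts(204, k, 28, 1)$oddspath_pathogenic
  })
  expect_true(all(diff(vals) >= 0))
})

test_that("binary calibration dichotomizes scores at the cutoff", {
  sc <- data.frame(variant_id = paste0("v", 1:8),
                   score = c(0.1, 0.2, 0.3, 0.35, 0.8, 0.9, 1.0, 1.1))
  ts <- data.frame(variant_id = sc$variant_id,
                   label = c(rep("P_LP", 4), rep("B_LB", 4)))
  cal <- oddspath_binary(sc, ts, cutoff = 0.5)
  expect_equal(unname(cal$contingency),
               c(4, 0, 0, 4))
  expect_gt(cal$oddspath_pathogenic, 1)
  expect_lt(cal$oddspath_benign, 1)
  expect_error(oddspath_binary(sc, ts, cutoff = 5), "outside")
})

test_that("kernel LLR is zero for identical distributions", {
  sc <- data.frame(variant_id = paste0("v", 1:40),
                   score = rep(seq(0, 1, length.out = 20), 2))
  ts <- data.frame(variant_id = sc$variant_id,
                   label = rep(c("P_LP", "B_LB"), each = 20))
  cal <- llr_kernel(sc, ts)
  expect_lt(max(abs(cal$llr)), 1e-10)
  expect_error(llr_kernel(sc, ts, bandwidth = 0), "positive")
})

test_that("kernel LLR separates well-separated score distributions", {
  set.seed(41)
  sc <- data.frame(variant_id = paste0("v", 1:400),
                   score = c(rnorm(200, 0, 0.1), rnorm(200, 1, 0.1)))
  ts <- data.frame(variant_id = sc$variant_id,
                   label = rep(c("P_LP", "B_LB"), each = 200))
  cal <- llr_kernel(sc, ts)
  expect_gt(cal$llr_fun(0), 0)
  expect_lt(cal$llr_fun(1), 0)
  # density-ratio consistency on the grid
  idx <- cal$f_benign > 1e-6 & cal$f_pathogenic > 1e-6
  expect_lt(max(abs(exp(cal$llr[idx]) * cal$f_benign[idx] -
                      cal$f_pathogenic[idx])), 1e-9)
})

test_that("LLR is invariant to duplicating every control", {
  set.seed(43)
  base <- data.frame(variant_id = paste0("v", 1:60),
                     score = c(rnorm(30, 0.2, 0.15), rnorm(30, 1, 0.15)))
  ts1 <- data.frame(variant_id = base$variant_id,
                    label = rep(c("P_LP", "B_LB"), each = 30))
  dup <- base; dup$variant_id <- paste0("w", 1:60)
  sc2 <- rbind(base, dup)
  ts2 <- rbind(ts1, within(ts1, variant_id <- paste0("w", 1:60)))
  c1 <- llr_kernel(base, ts1)
  c2 <- llr_kernel(sc2, ts2)
  expect_equal(c1$llr, c2$llr, tolerance = 1e-12)
})

test_that("evidence strengths follow the symmetric odds thresholds", {
  odds <- c(25, 19, 5, 2.5, 1.0, 0.45, 0.18, 0.01)
  ev <- mavescorer:::evidence_from_odds(odds,
          c(strong = 18.7, moderate = 4.33, supporting = 2.08))
  expect_equal(unname(ev),
               c("PS3_strong", "PS3_strong", "PS3_moderate", "PS3_supporting",
                 "none", "BS3_supporting", "BS3_moderate", "BS3_moderate"))
  # benign evidence is capped at moderate, never strong
  expect_false(any(grepl("BS3_strong", ev)))
})

test_that("evidence tallies are invariant to score-table row order", {
  set.seed(47)
  sc <- data.frame(variant_id = paste0("v", 1:300),
                   score = c(rnorm(150, 0.1, 0.1), rnorm(150, 1, 0.1)))
  ts <- data.frame(variant_id = sc$variant_id,
                   label = rep(c("P_LP", "B_LB"), each = 150))
  cal <- llr_kernel(sc, ts)
  t1 <- attr(assign_evidence(cal, sc), "tally")
  t2 <- attr(assign_evidence(cal, sc[sample(nrow(sc)), ]), "tally")
  expect_equal(t1, t2)
})
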