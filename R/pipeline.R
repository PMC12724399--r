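# Pipeline orchestration: simulate -> subassemble -> score -> integrate ->
# calibrate as one reproducible run with a serializable config, per-stage
# outputs on disk, and a manifest of paths, checksums and parameters.

#' Pipeline run configuration
#'
#' Bundles stage toggles and per-stage parameters. All scientific defaults
#' live in [sim_config()] and the stage functions; this object only selects
#' and forwards them, and round-trips losslessly through YAML.
#'
#' @param sim A [sim_config()] (or arguments for one, as a list).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "subassemble", "score", "integrate", "calibrate")`.
#' @param sem_cutoff SEM noise-filter cutoff for replicate merging.
#' @param k Cluster count for the PCA/k-means stage.
#' @param llr_bandwidth Kernel bandwidth for the continuous calibration.
#' @param llr_trim Score trimming range for the continuous calibration.
#' @param seed Run seed; overrides the simulation seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       stages = c("simulate", "subassemble", "score",
                                  "integrate", "calibrate"),
                       sem_cutoff = 0.5,
                       k = 6L,
                       llr_bandwidth = 0.2,
                       llr_trim = c(-0.3, 1.5),
                       seed = 1L) {
  if (is.list(sim) && !inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  stages <- match.arg(stages, several.ok = TRUE,
                      choices = c("simulate", "subassemble", "score",
                                  "integrate", "calibrate"))
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, stages = stages, sem_cutoff = sem_cutoff,
                 k = as.integer(k), llr_bandwidth = llr_bandwidth,
                 llr_trim = llr_trim, seed = as.integer(seed)),
            class = "run_config")
}

#' Read and write run configurations as YAML
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$archetype_props <- as.list(x$sim$archetype_props)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$sim$archetype_props <- unlist(x$sim$archetype_props)
  sim <- do.call(sim_config, x$sim)
  run_config(sim = sim, stages = x$stages, sem_cutoff = x$sem_cutoff,
             k = x$k, llr_bandwidth = x$llr_bandwidth,
             llr_trim = unlist(x$llr_trim), seed = x$seed)
}

#' Run the MAVE analysis pipeline
#'
#' Executes the selected stages in order, writing each stage's tables under
#' `outdir` as TSV (scores in a MaveDB-compatible wide layout) and returning
#' a manifest of file paths, md5 checksums, the parameter echo and a log.
#' Later stages consume earlier outputs from memory when available, or from
#' `outdir` when re-run. The calibration stage labels controls from the
#' simulation archetypes: wild-type-like missense variants are the benign
#' controls and loss-of-function/dominant-negative missense archetypes the
#' pathogenic controls.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return List of class `run_manifest`: `files` (named paths), `checksums`,
#'   `config`, `stages_run`, `skipped`, `log`, plus in-memory `results`.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("mave_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("simulate", "subassemble", "score", "integrate", "calibrate")
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  files <- list()
  res <- list()
  sim <- config$sim

  need <- function(what, stage) {
    if (is.null(res[[what]])) {
      stop2("stage '", stage, "' requires output '", what,
            "' from an earlier stage; enable it or provide outputs")
    }
    res[[what]]
  }

  if ("simulate" %in% config$stages) {
    note("simulate: n_variants=", sim$n_variants, " seed=", sim$seed)
    res$truth <- simulate_truth(sim)
    res$barcode_lib <- simulate_barcode_library(res$truth, sim)
    counts <- list()
    for (assay in ASSAYS) {
      tabs <- lapply(seq_len(sim$n_replicates), function(r) {
        if (assay %in% c("abundance", "het_abundance")) {
          simulate_facs(res$truth, sim, replicate = r, assay = assay)
        } else {
          simulate_selection(res$truth, sim, replicate = r, assay = assay)
        }
      })
      counts[[assay]] <- do.call(rbind, tabs)
    }
    res$counts <- counts
    files$truth <- write_tsv(res$truth, file.path(outdir, "truth.tsv"))
    files$barcode_lib <- write_tsv(res$barcode_lib,
                                   file.path(outdir, "barcode_library.tsv"))
    for (assay in ASSAYS) {
      files[[paste0("counts_", assay)]] <-
        write_tsv(counts[[assay]], file.path(outdir, paste0("counts_", assay, ".tsv")))
    }
  } else note("simulate: skipped")

  if ("subassemble" %in% config$stages) {
    truth <- need("truth", "subassemble")
    reads <- simulate_subassembly_reads(truth, sim, barcode_lib = res$barcode_lib)
    files$reads <- write_fastq(reads, file.path(outdir, "subassembly.fastq"))
    map <- subassemble(reads, make_reference_cds(),
                       prefix = sim$prefix, suffix = sim$suffix,
                       barcode_length = sim$barcode_length)
    res$barcode_map <- map
    files$barcode_map <- write_tsv(map, file.path(outdir, "barcode_map.tsv"))
    lg <- attr(map, "log")
    note("subassemble: ", lg$accepted, "/", lg$barcodes_called,
         " barcodes accepted (threshold ", lg$threshold, ")")
  } else note("subassemble: skipped")

  if ("score" %in% config$stages) {
    truth <- need("truth", "score")
    counts <- need("counts", "score")
    res$scores <- list()
    for (assay in ASSAYS) {
      res$scores[[assay]] <- score_assay(counts[[assay]], truth, assay,
                                         sem_cutoff = config$sem_cutoff)
      files[[paste0("scores_", assay)]] <- write_score_set(
        res$scores[[assay]], file.path(outdir, paste0("scores_", assay, ".tsv")))
      note("score: ", assay, " -> ", nrow(res$scores[[assay]]), " variants")
    }
  } else note("score: skipped")

  if ("integrate" %in% config$stages) {
    scores <- need("scores", "integrate")
    res$matrix <- assemble_matrix(scores)
    res$dn_calls <- call_dominant_negative(res$matrix)
    nr <- attr(scores[["function"]], "normal_range")
    res$clusters <- pca_kmeans(res$matrix, k = config$k, seed = config$seed,
                               normal_bounds = nr)
    files$assay_matrix <- write_tsv(res$matrix, file.path(outdir, "assay_matrix.tsv"))
    files$dn_calls <- write_tsv(res$dn_calls, file.path(outdir, "dn_calls.tsv"))
    files$clusters <- write_tsv(res$clusters$assignments,
                                file.path(outdir, "clusters.tsv"))
    note("integrate: ", sum(res$dn_calls$label == "severe_dn"), " severe / ",
         sum(res$dn_calls$label == "strong_dn"), " strong DN")
  } else note("integrate: skipped")

  if ("calibrate" %in% config$stages) {
    truth <- need("truth", "calibrate")
    scores <- need("scores", "calibrate")
    ts <- truth_set_from_archetypes(truth)
    fs <- scores[["function"]]
    res$roc <- roc_auc(fs, ts)
    res$oddspath <- oddspath_binary(fs, ts)
    res$llr <- llr_kernel(fs, ts, bandwidth = config$llr_bandwidth,
                          trim = config$llr_trim)
    res$evidence <- assign_evidence(res$llr, fs)
    files$evidence <- write_tsv(res$evidence, file.path(outdir, "evidence.tsv"))
    files$llr_curve <- write_tsv(
      data.frame(score = res$llr$grid, llr = res$llr$llr),
      file.path(outdir, "llr_curve.tsv"))
    calib <- list(auc = res$roc$auc,
                  oddspath_pathogenic = res$oddspath$oddspath_pathogenic,
                  oddspath_benign = res$oddspath$oddspath_benign,
                  prior_p1 = res$oddspath$prior_p1,
                  contingency = as.list(res$oddspath$contingency),
                  cutoff = res$oddspath$cutoff,
                  evidence_tally = as.list(attr(res$evidence, "tally")))
    files$calibration <- file.path(outdir, "calibration.json")
    jsonlite::write_json(calib, files$calibration, auto_unbox = TRUE, digits = NA)
    note("calibrate: AUC=", round(res$roc$auc, 3),
         " OddsPath_path=", round(res$oddspath$oddspath_pathogenic, 2))
  } else note("calibrate: skipped")

  files <- lapply(files, normalizePath)
  manifest <- list(
    files = files,
    checksums = vapply(files, function(f) unname(tools::md5sum(f)), ""),
    config = config,
    stages_run = intersect(all_stages, config$stages),
    skipped = setdiff(all_stages, config$stages),
    log = log,
    results = res
  )
  class(manifest) <- "run_manifest"
  manifest_out <- manifest[c("files", "checksums", "stages_run", "skipped", "log")]
  manifest_out$seed <- config$seed
  jsonlite::write_json(manifest_out, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

# Benign/pathogenic control labels derived from simulation archetypes.
truth_set_from_archetypes <- function(truth) {
  path_arch <- c("missense_lof", "dominant_negative", "haploinsufficient")
  miss <- truth$consequence == "missense"
  p <- truth$variant_id[miss & truth$archetype %in% path_arch]
  b <- truth$variant_id[miss & truth$archetype == "synonymous_like"]
  out <- data.frame(
    variant_id = c(p, b),
    label = c(rep("P_LP", length(p)), rep("B_LB", length(b))),
    source = "simulated_archetype",
    stringsAsFactors = FALSE
  )
  class(out) <- c("truth_set", "data.frame")
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> stages:", paste(x$stages_run, collapse = ", "), "\n")
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a score set as a MaveDB-style TSV
#'
#' Columns: `hgvs_p` (compact variant string), `position`, `wt_aa`, `alt_aa`,
#' `consequence`, `assay`, `score`, `sem`, `n_reps`, `category`.
#'
#' @param scores A `score_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_score_set <- function(scores, path) {
  out <- data.frame(
    hgvs_p = scores$variant_id,
    position = scores$position,
    wt_aa = scores$wt,
    alt_aa = scores$alt,
    consequence = scores$consequence,
    assay = attr(scores, "assay") %||% NA_character_,
    score = scores$score,
    sem = scores$sem,
    n_reps = scores$n_reps,
    category = if ("category" %in% names(scores)) scores$category else NA,
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
  invisible(path)
}

#' Read a score set written by [write_score_set()]
#' @param path TSV path.
#' @return A `score_set`.
#' @export
read_score_set <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(
    variant_id = df$hgvs_p, position = df$position, wt = df$wt_aa,
    alt = df$alt_aa, consequence = df$consequence, score = df$score,
    sem = df$sem, n_reps = df$n_reps,
    stringsAsFactors = FALSE
  )
  if ("category" %in% names(df)) out$category <- df$category
  structure(out, assay = df$assay[1], class = c("score_set", "data.frame"))
}
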