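# Synthetic-data generator: ground-truth variant effects plus every raw
# input the pipeline consumes (subassembly reads, FACS bin counts, selection
# timecourses). Latent effects are on a dimensionless scale where 1 is
# wild-type and 0 is complete loss.

# Archetype latent means: columns are variant-only abundance, variant-only
# function, heterozygous (WT-allele) abundance, heterozygous function.
# Early nonsense variants lose abundance/function of their own allele but
# leave the wild-type allele intact (haploinsufficiency: het_abundance ~ 1,
# het_function ~ 0.5 of a two-allele dose). Dominant negatives drag all four
# down, including the wild-type allele's surface abundance.
ARCHETYPE_MEANS <- rbind(
  synonymous_like   = c(1.00, 1.00, 1.00, 1.00),
  early_nonsense    = c(0.05, 0.03, 1.00, 0.50),
  late_nonsense_gof = c(1.00, 1.30, 1.00, 1.15),
  missense_lof      = c(0.15, 0.08, 0.95, 0.60),
  missense_partial  = c(0.60, 0.50, 0.97, 0.75),
  missense_gof      = c(1.05, 1.30, 1.00, 1.15),
  dominant_negative = c(0.06, 0.04, 0.08, 0.05),
  haploinsufficient = c(0.08, 0.06, 1.00, 0.60)
)
colnames(ARCHETYPE_MEANS) <- c("latent_abundance", "latent_function",
                               "het_abundance", "het_function")

# Default archetype mix (proportions of the library).
DEFAULT_ARCHETYPE_PROPS <- c(
  synonymous_like   = 0.53,
  early_nonsense    = 0.06,
  late_nonsense_gof = 0.01,
  missense_lof      = 0.10,
  missense_partial  = 0.12,
  missense_gof      = 0.03,
  dominant_negative = 0.07,
  haploinsufficient = 0.08
)

#' Simulation configuration
#'
#' Collects every tunable parameter of the synthetic MAVE. Defaults are the
#' study conditions: a saturation-mutagenesis library with a mean of 19.5
#' barcodes per variant, 18-nt barcodes, four FACS bins holding ~25% of cells
#' each, a 28-day drug-selection timecourse sampled weekly, and a selection
#' strength reproducing the observed day-28 wild-type fitness of 17% under
#' triple-drug treatment (exp(-s * 28) = 0.17).
#'
#' @param n_variants Number of coding variants in the library.
#' @param archetype_props Named proportions over the eight effect archetypes.
#' @param p_synonymous Probability that a synonymous-like variant is a true
#'   synonymous change (the rest are wild-type-like missense).
#' @param barcodes_per_variant_mean Mean barcodes tagging each variant.
#' @param reads_per_barcode_mean Mean subassembly reads per barcode
#'   (log-normal across barcodes).
#' @param reads_sdlog Log-sd of the per-barcode read abundance.
#' @param barcode_length Barcode length in nt.
#' @param seq_error_rate Per-base substitution error probability.
#' @param prefix,suffix Constant flanks (5-6 nt) anchoring the barcode.
#' @param amplicon_length Length of the mutant-region amplicon carried by
#'   each subassembly read.
#' @param n_bins Number of FACS bins.
#' @param n_cells Cells entering the sorter per replicate.
#' @param reads_per_sample Sequencing reads per post-assay sample.
#' @param sigma_cell Log-scale cell-to-cell fluorescence spread.
#' @param selection_strength Fitness cost per unit latent channel activity
#'   per day under triple-drug selection.
#' @param timepoints Collection days, ascending from 0.
#' @param n_replicates Biological replicates per assay.
#' @param replicate_noise_sd Log-scale replicate-to-replicate jitter on
#'   latent effects.
#' @param seed Integer seed; all simulation streams derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 2000L,
                       archetype_props = DEFAULT_ARCHETYPE_PROPS,
                       p_synonymous = 0.08,
                       barcodes_per_variant_mean = 19.5,
                       reads_per_barcode_mean = 20,
                       reads_sdlog = 0.5,
                       barcode_length = 18L,
                       seq_error_rate = 0.005,
                       prefix = "AGGAC",
                       suffix = "CTCGA",
                       amplicon_length = 33L,
                       n_bins = 4L,
                       n_cells = 4e6,
                       reads_per_sample = 25e6,
                       sigma_cell = 0.6,
                       selection_strength = log(1 / 0.17) / 28,
                       timepoints = c(0L, 7L, 14L, 21L, 28L),
                       n_replicates = 3L,
                       replicate_noise_sd = 0.05,
                       seed = 1L) {
  if (n_variants <= 0) stop2("n_variants must be positive")
  if (barcodes_per_variant_mean <= 0 || reads_per_barcode_mean <= 0 ||
      n_cells <= 0 || reads_per_sample <= 0) {
    stop2("all rates and depths must be positive")
  }
  if (!(nchar(prefix) %in% 5:6) || !(nchar(suffix) %in% 5:6)) {
    stop2("prefix/suffix must be 5-6 nt")
  }
  if (is.unsorted(timepoints, strictly = TRUE) || timepoints[1] != 0) {
    stop2("timepoints must be sorted ascending and start at 0")
  }
  stopifnot(abs(sum(archetype_props) - 1) < 1e-8,
            all(names(archetype_props) %in% rownames(ARCHETYPE_MEANS)))
  structure(list(
    n_variants = as.integer(n_variants),
    archetype_props = archetype_props,
    p_synonymous = p_synonymous,
    barcodes_per_variant_mean = barcodes_per_variant_mean,
    reads_per_barcode_mean = reads_per_barcode_mean,
    reads_sdlog = reads_sdlog,
    barcode_length = as.integer(barcode_length),
    seq_error_rate = seq_error_rate,
    prefix = prefix,
    suffix = suffix,
    amplicon_length = as.integer(amplicon_length),
    n_bins = as.integer(n_bins),
    n_cells = n_cells,
    reads_per_sample = reads_per_sample,
    sigma_cell = sigma_cell,
    selection_strength = selection_strength,
    timepoints = as.integer(timepoints),
    n_replicates = as.integer(n_replicates),
    replicate_noise_sd = replicate_noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate ground-truth variant effects
#'
#' Draws one variant per library slot: an amino-acid change (with its codon
#' change on the synthetic reference), an effect archetype, and four latent
#' effects (variant-only and heterozygous abundance/function) jittered around
#' the archetype means and clipped to `[0, 1.5]`.
#'
#' @param config A [sim_config()].
#' @param reference_cds Reference coding sequence; defaults to
#'   [make_reference_cds()].
#' @return `data.frame` of class `variant_truth`: variant identity columns
#'   plus `archetype`, the four latent columns, `ref_codon`, `alt_codon`,
#'   `codon_start` (nt position of the mutated codon).
#' @export
simulate_truth <- function(config, reference_cds = make_reference_cds()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_variants
  with_seed(sub_seed(config$seed, 1L), {
    arche <- sample(names(config$archetype_props), n, replace = TRUE,
                    prob = config$archetype_props)
    df <- draw_variant_identities(arche, config, reference_cds)
    # Reject duplicate (position, alt) draws and redraw.
    for (i in 1:25) {
      dup <- duplicated(df$variant_id)
      if (!any(dup)) break
      df[dup, ] <- draw_variant_identities(arche[dup], config, reference_cds)
    }
    if (anyDuplicated(df$variant_id)) {
      df <- df[!duplicated(df$variant_id), ]
    }
    sd <- 0.06
    lat <- ARCHETYPE_MEANS[df$archetype, , drop = FALSE]
    lat <- lat + matrix(stats::rnorm(length(lat), 0, sd), nrow = nrow(lat))
    lat <- pmin(pmax(lat, 0), 1.5)
    out <- cbind(df, as.data.frame(lat))
    rownames(out) <- NULL
    class(out) <- c("variant_truth", "data.frame")
    out
  })
}

# Draw variant identities (position + codon change) consistent with each
# archetype's consequence class.
draw_variant_identities <- function(arche, config, cds) {
  n <- length(arche)
  n_res <- nchar(cds) %/% 3L
  consequence <- rep("missense", n)
  is_syn_arch <- arche == "synonymous_like"
  consequence[is_syn_arch] <- ifelse(
    stats::runif(sum(is_syn_arch)) < config$p_synonymous,
    "synonymous", "missense")
  consequence[arche %in% c("early_nonsense", "late_nonsense_gof")] <- "nonsense"

  position <- integer(n)
  position[arche == "early_nonsense"] <-
    sample(seq(EARLY_NONSENSE_RANGE[1], EARLY_NONSENSE_RANGE[2]),
           sum(arche == "early_nonsense"), replace = TRUE)
  position[arche == "late_nonsense_gof"] <-
    sample(seq(LATE_NONSENSE_RANGE[1], LATE_NONSENSE_RANGE[2]),
           sum(arche == "late_nonsense_gof"), replace = TRUE)
  rest <- position == 0L
  position[rest] <- sample.int(n_res, sum(rest), replace = TRUE)

  ref_codon <- cds_codon(cds, position)
  wt <- codon_to_aa(ref_codon)

  # Synonymous changes need a codon with a synonym; shift position if not.
  gc <- Biostrings::GENETIC_CODE
  syn_ok <- function(codon) {
    aa <- gc[codon]
    sum(gc == aa & gc != "*") > 1
  }
  need <- which(consequence == "synonymous")
  for (i in need) {
    tries <- 0
    while (!syn_ok(ref_codon[i]) && tries < 50) {
      position[i] <- sample.int(n_res, 1)
      ref_codon[i] <- cds_codon(cds, position[i])
      tries <- tries + 1
    }
  }
  wt <- codon_to_aa(ref_codon)

  alt_codon <- character(n)
  alt <- character(n)
  sense <- sense_codons()
  stops <- stop_codons()
  for (i in seq_len(n)) {
    if (consequence[i] == "nonsense") {
      alt_codon[i] <- sample(stops, 1)
      alt[i] <- "*"
    } else if (consequence[i] == "synonymous") {
      cands <- sense[gc[sense] == wt[i] & sense != ref_codon[i]]
      alt_codon[i] <- sample(cands, 1)
      alt[i] <- wt[i]
    } else {
      cands <- sense[gc[sense] != wt[i]]
      alt_codon[i] <- sample(cands, 1)
      alt[i] <- unname(gc[alt_codon[i]])
    }
  }
  df <- variant_table(position, wt, alt)
  df$archetype <- arche
  df$ref_codon <- ref_codon
  df$alt_codon <- alt_codon
  df$codon_start <- 3L * (df$position - 1L) + 1L
  df
}

#' Assign random barcodes to variants
#'
#' Each variant receives `1 + Poisson(mean - 1)` distinct random barcodes of
#' the configured length, mirroring a barcoded plasmid library.
#'
#' @param truth Output of [simulate_truth()].
#' @param config A [sim_config()].
#' @return `data.frame` with columns `barcode`, `variant_id`.
#' @export
simulate_barcode_library <- function(truth, config) {
  with_seed(sub_seed(config$seed, 2L), {
    n_bc <- 1L + stats::rpois(nrow(truth), config$barcodes_per_variant_mean - 1)
    total <- sum(n_bc)
    repeat {
      bc <- random_barcodes(total, config$barcode_length)
      if (!anyDuplicated(bc)) break
    }
    data.frame(
      barcode = bc,
      variant_id = rep(truth$variant_id, n_bc),
      stringsAsFactors = FALSE
    )
  })
}

random_barcodes <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate subassembly reads linking barcodes to mutations
#'
#' Emits one FASTQ-like record per read: constant prefix, barcode, constant
#' suffix, then a fixed-length amplicon of the mutant region. Per-barcode
#' read abundance is log-normal around `reads_per_barcode_mean`; per-base
#' substitution errors at `seq_error_rate` create spurious low-frequency
#' barcodes. The amplicon's reference start coordinate travels in the read
#' name (the role a SAM POS field would play after alignment).
#'
#' @param truth Output of [simulate_truth()].
#' @param config A [sim_config()].
#' @param barcode_lib Output of [simulate_barcode_library()]; generated if
#'   `NULL`.
#' @param reference_cds Reference coding sequence.
#' @return `data.frame` of class `read_set` with columns `id`, `seq`, `qual`.
#' @export
simulate_subassembly_reads <- function(truth, config, barcode_lib = NULL,
                                       reference_cds = make_reference_cds()) {
  if (nrow(truth) == 0) stop2("truth must be nonempty")
  if (is.null(barcode_lib)) barcode_lib <- simulate_barcode_library(truth, config)
  with_seed(sub_seed(config$seed, 3L), {
    idx <- match(barcode_lib$variant_id, truth$variant_id)
    alen <- config$amplicon_length
    cds_len <- nchar(reference_cds)
    start <- pmin(pmax(truth$codon_start[idx] - (alen - 3L) %/% 2L, 1L),
                  cds_len - alen + 1L)
    amplicon <- substring(reference_cds, start, start + alen - 1L)
    off <- truth$codon_start[idx] - start  # 0-based codon offset in amplicon
    substr(amplicon, off + 1L, off + 3L) <- truth$alt_codon[idx]

    mu <- log(config$reads_per_barcode_mean) - config$reads_sdlog^2 / 2
    n_reads <- pmax(1L, as.integer(round(
      stats::rlnorm(nrow(barcode_lib), mu, config$reads_sdlog))))
    rid <- rep(seq_len(nrow(barcode_lib)), n_reads)
    seqs <- paste0(config$prefix, barcode_lib$barcode[rid], config$suffix,
                   amplicon[rid])
    seqs <- add_substitution_errors(seqs, config$seq_error_rate)
    ids <- sprintf("read%07d pos=%d", seq_along(seqs), start[rid])
    out <- data.frame(id = ids, seq = seqs,
                      qual = strrep("I", nchar(seqs[1])),
                      stringsAsFactors = FALSE)
    class(out) <- c("read_set", "data.frame")
    out
  })
}

# Apply iid per-base substitution errors to equal-length sequences.
add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  len <- nchar(seqs[1])
  k <- stats::rbinom(length(seqs), len, rate)
  hit <- which(k > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(len, k[i])
    s <- seqs[i]
    for (p in pos) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(bases, cur), 1)
    }
    seqs[i] <- s
  }
  seqs
}

#' Simulate FACS sorting into four fluorescence bins
#'
#' Cells are assigned to variants (weighted by barcode multiplicity when a
#' barcode library is supplied), given log-normal fluorescence around the
#' latent surface abundance, sorted into `n_bins` bins at population
#' quartiles, and sequenced with Poisson read noise. Counts are reported as
#' reads per million within each bin.
#'
#' @param truth Output of [simulate_truth()].
#' @param config A [sim_config()].
#' @param replicate Replicate index (drives the replicate jitter stream).
#' @param assay `"abundance"` (variant-only) or `"het_abundance"`
#'   (wild-type-allele abundance in the heterozygous context).
#' @param barcode_lib Optional barcode library; if supplied the count table
#'   is at barcode level, otherwise at variant level.
#' @return A count table (`entity_id`, `sample_id` = `"bin1"`..`"bin4"`,
#'   `replicate`, `rpm`).
#' @export
simulate_facs <- function(truth, config, replicate = 1L,
                          assay = c("abundance", "het_abundance"),
                          barcode_lib = NULL) {
  assay <- match.arg(assay)
  latent <- if (assay == "abundance") truth$latent_abundance else truth$het_abundance
  with_seed(sub_seed(config$seed, 100L * replicate + (assay == "het_abundance") * 7L + 4L), {
    n <- nrow(truth)
    a_rep <- latent * exp(stats::rnorm(n, 0, config$replicate_noise_sd))
    mu <- log(pmax(a_rep, 0.02))
    w <- if (is.null(barcode_lib)) rep(1, n) else {
      as.numeric(table(factor(barcode_lib$variant_id, levels = truth$variant_id)))
    }
    v <- sample.int(n, config$n_cells, replace = TRUE, prob = w)
    logf <- stats::rnorm(config$n_cells, mu[v], config$sigma_cell)
    qs <- stats::quantile(logf, probs = seq_len(config$n_bins - 1) / config$n_bins)
    bin <- findInterval(logf, qs) + 1L
    cells <- matrix(tabulate(v + (bin - 1L) * n, nbins = n * config$n_bins),
                    nrow = n)
    depth <- config$reads_per_sample / config$n_bins
    counts_to_table(cells, depth, truth, barcode_lib,
                    paste0("bin", seq_len(config$n_bins)), replicate)
  })
}

#' Simulate a drug-selection timecourse
#'
#' Variant frequencies evolve by exponential growth with a per-day fitness
#' cost `selection_strength * latent_function` (clipped at zero), so
#' wild-type-like activity depletes, loss-of-function enriches relatively,
#' and gain-of-function depletes fastest. Each timepoint is sequenced with
#' Poisson noise and renormalized to reads per million.
#'
#' @inheritParams simulate_facs
#' @param assay `"function"` or `"het_function"`.
#' @return A count table with `sample_id` = `"day0"`, `"day7"`, ...
#' @export
simulate_selection <- function(truth, config, replicate = 1L,
                               assay = c("function", "het_function"),
                               barcode_lib = NULL) {
  assay <- match.arg(assay)
  latent <- if (assay == "function") truth$latent_function else truth$het_function
  with_seed(sub_seed(config$seed, 100L * replicate + (assay == "het_function") * 7L + 5L), {
    n <- nrow(truth)
    f_rep <- pmax(latent * exp(stats::rnorm(n, 0, config$replicate_noise_sd)), 0)
    w0 <- if (is.null(barcode_lib)) rep(1, n) else {
      as.numeric(table(factor(barcode_lib$variant_id, levels = truth$variant_id)))
    }
    wt_mat <- vapply(config$timepoints, function(t) {
      w <- w0 * exp(-config$selection_strength * f_rep * t)
      w / sum(w)
    }, numeric(n))
    expected <- wt_mat * config$reads_per_sample
    counts <- matrix(stats::rpois(length(expected), expected), nrow = n)
    counts_to_table(counts, NULL, truth, barcode_lib,
                    paste0("day", config$timepoints), replicate)
  })
}

# Convert a variants x samples count matrix into a long RPM table, optionally
# scattering each variant's reads over its barcodes (Poisson thinning), and
# renormalizing each sample column to 1e6 RPM.
counts_to_table <- function(mat, depth, truth, barcode_lib, sample_ids, replicate) {
  n <- nrow(mat)
  if (!is.null(depth)) {
    # mat holds sorted-cell counts; convert to Poisson read counts per bin.
    reads <- vapply(seq_len(ncol(mat)), function(j) {
      tot <- sum(mat[, j])
      lam <- if (tot > 0) mat[, j] / tot * depth else rep(0, n)
      stats::rpois(n, lam)
    }, numeric(n))
  } else {
    reads <- mat
  }
  if (is.null(barcode_lib)) {
    tab <- count_table(
      entity_id = rep(truth$variant_id, ncol(reads)),
      sample_id = rep(sample_ids, each = n),
      replicate = replicate,
      rpm = as.numeric(reads)
    )
  } else {
    idx <- match(barcode_lib$variant_id, truth$variant_id)
    nbc <- tabulate(idx, nbins = n)
    lam_bc <- reads[idx, , drop = FALSE] / nbc[idx]
    bc_reads <- matrix(stats::rpois(length(lam_bc), lam_bc), nrow = nrow(barcode_lib))
    tab <- count_table(
      entity_id = rep(barcode_lib$barcode, ncol(bc_reads)),
      sample_id = rep(sample_ids, each = nrow(barcode_lib)),
      replicate = replicate,
      rpm = as.numeric(bc_reads)
    )
  }
  normalize_rpm(tab)
}

#' Write reads to a FASTQ file
#' @param reads A `read_set` (columns `id`, `seq`, `qual`).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file into a read set
#' @param path FASTQ path.
#' @return A `read_set` data frame.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  out <- data.frame(id = names(x), seq = as.character(x),
                    qual = as.character(S4Vectors::mcols(x)$qualities),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}
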