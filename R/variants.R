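# Variant identity: a single amino-acid change (position, wt, alt,
# consequence). The compact string form "A341V" / "R518*" / "L123=" is the
# universal join key across count tables, score sets and truth sets.

# Channel geometry constants (positions on the 676-residue subunit).
KCNQ1_N_RESIDUES <- 676L
ZONE_BOUNDARIES <- c(0L, 236L, 394L, 676L)
EARLY_NONSENSE_RANGE <- c(1L, 610L)
LATE_NONSENSE_RANGE <- c(611L, 676L)
# Mid-gene nonsense window excluded from the function-assay null anchor
# (stop-codon readthrough inflates apparent function there).
FUNCTION_NONSENSE_EXCLUDE <- c(239L, 307L)
# Residues critical for activator-drug binding; missense changes here are
# excluded from function score sets because drug response confounds function.
DRUG_BINDING_RESIDUES <- c(248L, 251L, 255L, 267L, 335L, 339L)

#' Build a variant identity table
#'
#' @param position Integer residue positions (1-based).
#' @param wt,alt Single-letter amino acids; `alt` is `"*"` for nonsense and
#'   equal to `wt` for synonymous changes.
#' @return `data.frame` with columns `variant_id`, `position`, `wt`, `alt`,
#'   `consequence` (one of `"synonymous"`, `"missense"`, `"nonsense"`) and
#'   `zone` (mutagenesis zone 1-3).
#' @export
variant_table <- function(position, wt, alt) {
  position <- as.integer(position)
  consequence <- ifelse(alt == "*", "nonsense",
    ifelse(alt == wt, "synonymous", "missense"))
  id_alt <- ifelse(consequence == "synonymous", "=", alt)
  data.frame(
    variant_id = paste0(wt, position, id_alt),
    position = position,
    wt = wt,
    alt = alt,
    consequence = consequence,
    zone = variant_zone(position),
    stringsAsFactors = FALSE
  )
}

#' Mutagenesis zone of a residue position
#' @param position Integer residue positions.
#' @return Integer zone index (1, 2 or 3).
#' @export
variant_zone <- function(position) {
  findInterval(position, ZONE_BOUNDARIES[2:3] + 0.5) + 1L
}

# Positions eligible as the nonsense null anchor for a given assay.
nonsense_anchor_positions <- function(assay) {
  pos <- seq(EARLY_NONSENSE_RANGE[1], EARLY_NONSENSE_RANGE[2])
  if (assay %in% c("function", "het_function")) {
    pos <- pos[pos < FUNCTION_NONSENSE_EXCLUDE[1] | pos > FUNCTION_NONSENSE_EXCLUDE[2]]
  }
  pos
}

# Genetic code lookup (standard code, via Biostrings).
codon_to_aa <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"]
}

#' Deterministic synthetic reference coding sequence
#'
#' Generates a synthetic in-frame coding sequence (no internal stop codons)
#' used as the alignment reference for simulated subassembly reads. It stands
#' in for the real cDNA, which is not shipped; residue numbering and zone
#' boundaries follow the 676-residue channel subunit.
#'
#' @param n_residues Number of codons.
#' @param seed RNG seed; fixed default so the reference is reproducible.
#' @return A single character string of length `3 * n_residues`.
#' @export
make_reference_cds <- function(n_residues = KCNQ1_N_RESIDUES, seed = 676L) {
  with_seed(seed, {
    codons <- sample(sense_codons(), n_residues, replace = TRUE)
    paste0(codons, collapse = "")
  })
}

# Extract codon `i` (1-based residue index) from a CDS string.
cds_codon <- function(cds, i) {
  substring(cds, 3L * (i - 1L) + 1L, 3L * i)
}
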