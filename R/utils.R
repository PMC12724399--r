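# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so simulation calls do not perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a distinct 32-bit sub-seed from a base seed and a stream label.
sub_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 1000003L * as.integer(stream)) %% 2147483647L
}

stop2 <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Renormalize counts to reads per million within each sample
#'
#' Rescales the `rpm` column of a count table so that every
#' (sample, replicate) column sums to exactly one million, the unit in which
#' all downstream scores are computed.
#'
#' @param counts A count table: `data.frame` with columns `entity_id`,
#'   `sample_id`, `replicate`, `rpm`.
#' @return The same table with `rpm` rescaled.
#' @export
normalize_rpm <- function(counts) {
  stopifnot(all(c("entity_id", "sample_id", "replicate", "rpm") %in% names(counts)))
  key <- interaction(counts$sample_id, counts$replicate, drop = TRUE)
  tot <- tapply(counts$rpm, key, sum)
  counts$rpm <- counts$rpm / as.numeric(tot[key]) * 1e6
  counts
}

# Constructor for the long-format count table used throughout the package.
count_table <- function(entity_id, sample_id, replicate, rpm) {
  data.frame(
    entity_id = as.character(entity_id),
    sample_id = as.character(sample_id),
    replicate = as.integer(replicate),
    rpm = as.numeric(rpm),
    stringsAsFactors = FALSE
  )
}
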