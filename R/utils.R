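#' @importFrom methods is
#' @importFrom stats sd rbinom rnbinom runif rnorm rlnorm pchisq setNames
#' @importFrom utils read.table write.table combn head
NULL

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded operations stay pure functions of (inputs, seed).
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

cd_log <- function(..., level = "INFO") {
  msg <- paste0(...)
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"), msg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("%s must be a single finite number", name))
  }
}

# Overlap helpers on a unified seqlevel set: queries and subjects from
# different files routinely carry disjoint chromosome sets, which is not an
# error for >= 1 bp overlap semantics.
same_levels <- function(query, subject) {
  sl <- union(GenomeInfoDb::seqlevels(query), GenomeInfoDb::seqlevels(subject))
  GenomeInfoDb::seqlevels(query) <- sl
  GenomeInfoDb::seqlevels(subject) <- sl
  list(query = query, subject = subject)
}

ov_any <- function(query, subject) {
  h <- same_levels(query, subject)
  IRanges::overlapsAny(h$query, h$subject, ignore.strand = TRUE)
}

ov_count <- function(query, subject) {
  h <- same_levels(query, subject)
  GenomicRanges::countOverlaps(h$query, h$subject, ignore.strand = TRUE)
}

ov_hits <- function(query, subject) {
  h <- same_levels(query, subject)
  GenomicRanges::findOverlaps(h$query, h$subject, ignore.strand = TRUE)
}
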