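#' Binary element states, three-timepoint trajectories and random controls
#'
#' An element's state at a timepoint is positive when it overlaps a peak of
#' the assay by at least one base (accessibility for ATAC, activity for
#' H3K27ac) or, for RNA, when its RPM is strictly positive. A three-timepoint
#' trajectory is consistent_positive when all three states are positive
#' (consistently accessible / active / expressed), consistent_negative when
#' all three are negative, and dynamic otherwise.
#'
#' @name states
NULL

#' Construct a peak set
#'
#' @param peaks `GRanges` of called peaks.
#' @param assay one of ATAC, H3K27ac, p53.
#' @param timepoint 0h/8h/16h, or "static" (p53 only).
#' @return list of class `credyn_peak_set`.
#' @export
peak_set <- function(peaks, assay = "ATAC", timepoint = "0h") {
  if (timepoint == "static" && assay != "p53") {
    stop("timepoint 'static' is reserved for p53 peak sets")
  }
  structure(list(peaks = peaks, assay = assay, timepoint = timepoint),
            class = "credyn_peak_set")
}

#' Per-element binary state from peak overlap
#'
#' @param elements `GRanges`.
#' @param peaks peak set from [peak_set()] (or a bare `GRanges`).
#' @return logical vector: TRUE iff the element shares >= 1 base with a peak.
#' @export
overlap_state <- function(elements, peaks) {
  pk <- if (inherits(peaks, "credyn_peak_set")) peaks$peaks else peaks
  ov_any(elements, pk)
}

#' Trajectory category from a binary state triple
#'
#' @param states logical vector of length 3 (ordered timepoints), or a
#'   3-column logical matrix (one row per element).
#' @return character: consistent_positive (all TRUE), consistent_negative
#'   (all FALSE), otherwise dynamic.
#' @export
trajectory_category <- function(states) {
  if (is.matrix(states)) {
    if (ncol(states) != 3L) stop("state matrix must have exactly 3 columns")
    npos <- rowSums(states)
    return(ifelse(npos == 3L, "consistent_positive",
                  ifelse(npos == 0L, "consistent_negative", "dynamic")))
  }
  if (length(states) != 3L) stop("exactly 3 states required")
  trajectory_category(matrix(as.logical(states), nrow = 1))[1]
}

#' Expression trajectory category from an RPM triple
#'
#' @param rpms numeric vector of length 3 (0h, 8h, 16h), or a 3-column matrix;
#'   all values must be >= 0.
#' @return character: consistent_positive (all > 0), consistent_negative
#'   (all = 0), otherwise dynamic.
#' @export
expression_trajectory <- function(rpms) {
  if (any(rpms < 0)) stop("RPM values must be non-negative")
  if (is.matrix(rpms)) {
    if (ncol(rpms) != 3L) stop("RPM matrix must have exactly 3 columns")
    return(trajectory_category(rpms > 0))
  }
  if (length(rpms) != 3L) stop("exactly 3 RPM values required")
  trajectory_category(rpms > 0)
}

#' Trajectory table for a catalog against three peak sets
#'
#' @param elements `GRanges` with ids as names.
#' @param peaks_by_tp list of three peak sets (ordered timepoints).
#' @param assay assay label for the output.
#' @return data.frame: element_id, assay, state_0h, state_8h, state_16h,
#'   category.
#' @export
state_trajectories <- function(elements, peaks_by_tp, assay = "ATAC") {
  if (length(peaks_by_tp) != 3L) stop("exactly 3 timepoint peak sets required")
  st <- vapply(peaks_by_tp, function(p) overlap_state(elements, p),
               logical(length(elements)))
  st <- matrix(st, ncol = 3)
  data.frame(element_id = names(elements) %||% paste0("el", seq_along(elements)),
             assay = assay,
             state_0h = st[, 1], state_8h = st[, 2], state_16h = st[, 3],
             category = trajectory_category(st),
             stringsAsFactors = FALSE)
}

#' Sample random fixed-length regions across the genome
#'
#' Chromosomes are chosen with probability proportional to their length
#' (among those long enough to hold a region) and start positions uniformly,
#' so placement is uniform per base. Regions may overlap each other and any
#' annotated element; no exclusion is applied.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param n number of regions (default 10000).
#' @param length region length in bp (default 2000).
#' @param seed RNG seed; output is a pure function of (inputs, seed).
#' @return `GRanges` of `n` regions, each fully inside its chromosome.
#' @export
random_regions <- function(chrom_sizes, n = 10000, length = 2000, seed = 1) {
  ok <- chrom_sizes >= length
  if (!any(ok)) stop("no chromosome is long enough to hold a region")
  sizes <- chrom_sizes[ok]
  with_local_seed(seed, {
    chr <- sample(names(sizes), n, replace = TRUE, prob = sizes / sum(sizes))
    start0 <- floor(runif(n) * (sizes[chr] - length + 1))
    bed_to_gr(chr, start0, start0 + length,
              id = paste0("rand", seq_len(n)))
  })
}

#' Sample random accessible regions from a peak set
#'
#' Draws peaks uniformly without replacement from those having zero overlap
#' with any catalog element; region lengths are the peaks' own lengths. When
#' fewer than `n` peaks are eligible, all eligible peaks are returned and the
#' result carries `attr(, "truncated") = TRUE`.
#'
#' @param peaks peak set or `GRanges` of accessible (e.g. ATAC) peaks.
#' @param elements `GRanges` of catalog elements to exclude.
#' @param n number of regions requested.
#' @param seed RNG seed.
#' @return `GRanges` (peaks verbatim), with attribute `truncated`.
#' @export
random_accessible_regions <- function(peaks, elements, n, seed = 1) {
  pk <- if (inherits(peaks, "credyn_peak_set")) peaks$peaks else peaks
  eligible <- pk[!ov_any(pk, elements)]
  truncated <- length(eligible) < n
  if (truncated) {
    warning(sprintf("only %d eligible peaks for %d requested regions",
                    length(eligible), n))
    out <- eligible
  } else {
    out <- with_local_seed(seed, eligible[sample(length(eligible), n)])
  }
  attr(out, "truncated") <- truncated
  out
}
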