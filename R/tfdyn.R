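#' TF footprint activity variability and p53 partitioning
#'
#' Transcription-factor footprints carry a protection score (cleavage
#' depletion in the footprint versus its flanks) and a tag count. Per-TF
#' binding activity at each timepoint is the mean of the chosen metric over
#' that TF's footprints; TFs are ranked by the sample standard deviation of
#' their activity across the three timepoints, and the most variable TFs of
#' two element classes are compared by exact name intersection ("::" complex
#' names are never split). Elements are partitioned into p53-bound and
#' p53-free classes by peak overlap.
#'
#' @name tfdyn
NULL

#' Read a TF footprint table
#'
#' @param path TSV with header tf_name, chrom, start, end, protection_score,
#'   tag_count, timepoint (coordinates 0-based half-open).
#' @return data.frame of footprint records.
#' @export
read_footprints <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("tf_name", "chrom", "start", "end", "protection_score",
            "tag_count", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("footprint table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$tag_count < 0)) stop("tag_count must be >= 0")
  if (any(!nzchar(df$tf_name))) stop("tf_name must be non-empty")
  df
}

#' Restrict footprints to those inside catalog elements
#'
#' @param footprints footprint data.frame from [read_footprints()].
#' @param elements `GRanges` of catalog elements.
#' @return list with `subset` (footprints overlapping >= 1 base with any
#'   element) and `counts` (per-timepoint table of retained footprints).
#' @export
footprints_in_elements <- function(footprints, elements) {
  if (nrow(footprints) == 0) {
    return(list(subset = footprints, counts = table(character(0))))
  }
  fp_gr <- bed_to_gr(footprints$chrom, footprints$start, footprints$end)
  hit <- ov_any(fp_gr, elements)
  subset <- footprints[hit, , drop = FALSE]
  rownames(subset) <- NULL
  list(subset = subset, counts = table(subset$timepoint))
}

#' Aggregate footprints into a TF x timepoint activity table
#'
#' Activity of a TF at a timepoint is the mean of the chosen metric over that
#' TF's footprints at that timepoint. The combined metric is the mean of
#' min-max-normalised protection score and tag count, each normalised across
#' the whole footprint table. TFs missing any of the three timepoints are
#' dropped (reasons in the `dropped` attribute).
#'
#' @param footprints footprint data.frame.
#' @param metric one of "protection", "tag_count", "combined" (default).
#' @param timepoints ordered timepoint labels.
#' @return matrix (TF x timepoint) with attribute `metric`.
#' @export
build_activity_table <- function(footprints, metric = c("combined", "protection", "tag_count"),
                                 timepoints = c("0h", "8h", "16h")) {
  metric <- match.arg(metric)
  minmax <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(0.5, length(x)))
    (x - r[1]) / (r[2] - r[1])
  }
  score <- switch(metric,
    protection = footprints$protection_score,
    tag_count = footprints$tag_count,
    combined = (minmax(footprints$protection_score) + minmax(footprints$tag_count)) / 2)
  agg <- tapply(score, list(footprints$tf_name, footprints$timepoint), mean)
  miss_tp <- setdiff(timepoints, colnames(agg))
  if (length(miss_tp)) {
    agg <- cbind(agg, matrix(NA_real_, nrow(agg), length(miss_tp),
                             dimnames = list(NULL, miss_tp)))
  }
  agg <- agg[, timepoints, drop = FALSE]
  complete <- rowSums(is.na(agg)) == 0
  dropped <- rownames(agg)[!complete]
  out <- agg[complete, , drop = FALSE]
  attr(out, "metric") <- metric
  attr(out, "dropped") <- if (length(dropped)) {
    data.frame(tf_name = dropped, reason = "missing_timepoint",
               stringsAsFactors = FALSE)
  } else NULL
  out
}

#' Rank TFs by cross-timepoint activity standard deviation
#'
#' Uses the sample standard deviation (divisor n - 1) of each TF's activity
#' triple, sorted in descending order; ties are broken lexicographically by
#' TF name for determinism.
#'
#' @param table activity matrix from [build_activity_table()].
#' @param top_n number of TFs to return (default 30).
#' @return character vector of the first `min(top_n, nrow)` TF names.
#' @export
rank_by_sd <- function(table, top_n = 30) {
  if (top_n < 1) stop("top_n must be >= 1")
  sds <- apply(table, 1, sd)
  ord <- order(-sds, rownames(table))
  head(rownames(table)[ord], min(top_n, nrow(table)))
}

#' Intersection of two top-TF lists
#'
#' Complex names joined with "::" are compared verbatim, never split into
#' their components.
#'
#' @param top_a,top_b character vectors of TF names.
#' @return list with `shared` (sorted names) and `count`.
#' @export
top_overlap <- function(top_a, top_b) {
  shared <- sort(intersect(top_a, top_b))
  list(shared = shared, count = length(shared))
}

#' Partition elements by p53 peak overlap
#'
#' Enhancers/promoters overlapping a p53 peak by >= 1 base are p53-bound
#' (p53BER / p53BPR); the rest are p53-free (p53FER / p53FPR). Bound and
#' free sets partition each class exactly.
#'
#' @param elements `GRanges` with ids as names and an `element_class`
#'   metadata column in {enhancer, promoter}.
#' @param p53_peaks p53 peak set from [peak_set()] (assay must be "p53") or
#'   a bare `GRanges`.
#' @return list of id vectors: p53BER, p53FER, p53BPR, p53FPR.
#' @export
partition_by_p53 <- function(elements, p53_peaks) {
  if (inherits(p53_peaks, "credyn_peak_set") && p53_peaks$assay != "p53") {
    stop("p53 partition requires a p53 peak set")
  }
  cls <- S4Vectors::mcols(elements)$element_class
  if (is.null(cls)) stop("elements must carry an element_class metadata column")
  bound <- overlap_state(elements, p53_peaks)
  ids <- names(elements) %||% paste0("el", seq_along(elements))
  part <- list(p53BER = ids[cls == "enhancer" & bound],
               p53FER = ids[cls == "enhancer" & !bound],
               p53BPR = ids[cls == "promoter" & bound],
               p53FPR = ids[cls == "promoter" & !bound])
  stopifnot(length(part$p53BER) + length(part$p53FER) == sum(cls == "enhancer"),
            length(part$p53BPR) + length(part$p53FPR) == sum(cls == "promoter"))
  part
}

#' Compare signal between two element groups (two-sample KS test)
#'
#' @param group_a,group_b element-id vectors.
#' @param values named numeric vector of per-element signal at one timepoint.
#' @return a [ks2()] test result (D statistic, p-value, stars).
#' @export
group_signal_compare <- function(group_a, group_b, values) {
  xa <- values[intersect(group_a, names(values))]
  xb <- values[intersect(group_b, names(values))]
  if (length(xa) == 0 || length(xb) == 0) {
    stop("both groups must be non-empty after matching to values")
  }
  ks2(as.numeric(xa), as.numeric(xb))
}
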