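#' Signal quantification: region RPM and center-anchored profile matrices
#'
#' Per-element expression/accessibility/activity is quantified as reads per
#' million (RPM): the number of fragments overlapping the element by at least
#' one base, divided by the library's total mapped fragments, times 1e6.
#' Profile matrices hold per-base coverage around element centers, binned,
#' CPM-normalised, and mean-smoothed, with minus-strand rows reversed so bins
#' run 5' to 3'.
#'
#' @name signal
NULL

#' Construct a fragment set
#'
#' @param fragments `GRanges` of sequenced fragments.
#' @param total_count total mapped fragments in the library (>= 1; may exceed
#'   the fragments listed, e.g. when only a region subset is loaded).
#' @param assay one of RNA, ATAC, H3K27ac.
#' @param timepoint sample timepoint label (e.g. "0h").
#' @param label sample name.
#' @return list of class `credyn_fragment_set`.
#' @export
fragment_set <- function(fragments, total_count, assay = "RNA",
                         timepoint = "0h", label = "") {
  stopifnot_scalar_number(total_count, "total_count")
  if (total_count < 1) stop("total_count must be >= 1")
  if (total_count < length(fragments)) {
    stop("total_count cannot be smaller than the number of fragments listed")
  }
  structure(list(fragments = fragments, total_count = as.numeric(total_count),
                 assay = assay, timepoint = timepoint, label = label),
            class = "credyn_fragment_set")
}

#' Read a fragment manifest and its BED fragment files
#'
#' The manifest is a TSV with header `sample, assay, timepoint, path,
#' total_count`; paths are resolved relative to the manifest's directory.
#'
#' @param path manifest path.
#' @return named list of fragment sets (names = sample labels).
#' @export
read_fragment_manifest <- function(path) {
  man <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "assay", "timepoint", "path", "total_count")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  base <- dirname(path)
  out <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    fragment_set(read_bed(p), man$total_count[i], assay = man$assay[i],
                 timepoint = man$timepoint[i], label = man$sample[i])
  })
  names(out) <- man$sample
  out
}

#' Read a bedGraph file as per-base coverage intervals
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open).
#' @return `GRanges` with metadata column `score`.
#' @export
read_bedgraph <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 4) stop("bedGraph requires 4 columns")
  gr <- bed_to_gr(df[[1]], df[[2]], df[[3]])
  S4Vectors::mcols(gr)$score <- as.numeric(df[[4]])
  gr
}

#' Reads-per-million signal of regions
#'
#' Counts fragments overlapping each region by at least one base and scales
#' to the library size: `count / total_count * 1e6`.
#'
#' @param frags fragment set from [fragment_set()].
#' @param regions `GRanges` of query regions.
#' @return numeric RPM vector, one value per region.
#' @export
region_rpm <- function(frags, regions) {
  if (frags$total_count <= 0) stop("total_count must be positive")
  counts <- ov_count(regions, frags$fragments)
  as.numeric(counts) / frags$total_count * 1e6
}

#' Expressed flag from baseline RPM
#'
#' An element is expressed when its untreated (0 h) RPM is strictly positive.
#'
#' @param rpm_t0 RPM value(s) at 0 h; must be >= 0.
#' @return logical vector.
#' @export
expressed_flag <- function(rpm_t0) {
  if (any(rpm_t0 < 0)) stop("RPM must be non-negative")
  rpm_t0 > 0
}

#' Binned, smoothed signal profiles around element centers
#'
#' Per-base coverage is computed in `[center - flank, center + flank)`
#' (center = `floor((start + end) / 2)`, 0-based; bases outside the
#' chromosome count as zero), averaged within `bin`-bp bins, normalised to
#' counts per million of `total_count`, then mean-smoothed: each bin becomes
#' the unweighted mean of all bins overlapping the `smooth`-bp window centred
#' on it, truncated at the matrix edges. Rows of minus-strand elements are
#' reversed.
#'
#' @param frags fragment set.
#' @param elements stranded `GRanges` with ids as names.
#' @param flank half-window in bp (default 1000); must be a multiple of `bin`.
#' @param bin bin width in bp (default 50).
#' @param smooth smoothing window in bp (default 60); 0 disables smoothing.
#' @return list of class `credyn_signal_matrix` with element_ids, bin_edges
#'   (bin start offsets relative to center), values (elements x bins), params.
#' @export
profile_matrix <- function(frags, elements, flank = 1000, bin = 50, smooth = 60) {
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  if (smooth < 0) stop("smooth must be >= 0")
  nb <- as.integer(2 * flank / bin)
  ids <- names(elements) %||% paste0("el", seq_along(elements))
  cov <- GenomicRanges::coverage(frags$fragments)
  centers <- interval_midpoint0(elements)
  chroms <- as.character(GenomicRanges::seqnames(elements))
  vals <- matrix(0, nrow = length(elements), ncol = nb)
  for (i in seq_along(elements)) {
    base_cov <- numeric(2 * flank)
    w0 <- centers[i] - flank            # 0-based window start
    if (chroms[i] %in% names(cov)) {
      rle <- cov[[chroms[i]]]
      lo1 <- max(1, w0 + 1)             # 1-based clip to [1, length(rle)]
      hi1 <- min(length(rle), w0 + 2 * flank)
      if (hi1 >= lo1) {
        seg <- as.numeric(S4Vectors::window(rle, lo1, hi1))
        base_cov[(lo1 - w0):(hi1 - w0)] <- seg
      }
    }
    vals[i, ] <- colMeans(matrix(base_cov, nrow = bin))
  }
  vals <- vals * 1e6 / frags$total_count
  if (smooth > 0 && nb > 1) {
    max_off <- floor(smooth / (2 * bin) + 0.5 - 1e-9)
    if (max_off > 0) {
      sm <- matrix(0, nrow = nrow(vals), ncol = nb)
      cnt <- integer(nb)
      for (off in -max_off:max_off) {
        src <- seq_len(nb) + off
        ok <- src >= 1 & src <= nb
        sm[, ok] <- sm[, ok, drop = FALSE] + vals[, src[ok], drop = FALSE]
        cnt[ok] <- cnt[ok] + 1L
      }
      vals <- sweep(sm, 2, cnt, "/")
    }
  }
  neg <- as.character(GenomicRanges::strand(elements)) == "-"
  if (any(neg)) vals[neg, ] <- vals[neg, nb:1, drop = FALSE]
  structure(list(element_ids = ids,
                 bin_edges = seq(-flank, flank - bin, by = bin),
                 values = vals,
                 params = list(flank = flank, bin = bin, smooth = smooth)),
            class = "credyn_signal_matrix")
}

#' Subtract a control signal matrix from a treatment matrix
#'
#' @param treatment,control signal matrices from [profile_matrix()] built on
#'   identical elements and parameters.
#' @return signal matrix of elementwise differences (negatives permitted).
#' @export
subtract_tracks <- function(treatment, control) {
  if (!identical(treatment$element_ids, control$element_ids) ||
      !identical(treatment$bin_edges, control$bin_edges) ||
      !identical(treatment$params, control$params)) {
    stop("signal matrices differ in elements, bins or parameters")
  }
  out <- treatment
  out$values <- treatment$values - control$values
  out
}

#' Export a signal matrix as TSV
#'
#' @param mat signal matrix.
#' @param path output path.
#' @export
write_signal_matrix <- function(mat, path) {
  df <- data.frame(id = mat$element_ids, mat$values)
  names(df) <- c("id", paste0("bin_", mat$bin_edges))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
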