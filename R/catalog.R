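#' Element curation: exclusion rules and distal/proximal classification
#'
#' Candidate enhancers are removed when they overlap a known coding region —
#' approximated as the full gene span extended by `pad` (default 1 kb) on both
#' sides — or any blacklist interval. Surviving enhancers are classified by
#' their strand-aware upstream distance to the nearest gene TSS: between 1 kb
#' and 2 kb upstream is proximal, more than 2 kb is distal.
#'
#' @name catalog
NULL

#' Filter candidate enhancers against coding regions and a blacklist
#'
#' An enhancer is removed iff it shares at least one base with any gene
#' interval extended by `pad` on both sides, or with any blacklist interval.
#' When both apply, the coding-overlap reason is reported.
#'
#' @param enhancers `GRanges` of candidate enhancers (ids as names).
#' @param genes gene model data.frame from [read_genes()]; an empty/NULL gene
#'   list removes nothing for coding overlap.
#' @param blacklist `GRanges` of excluded regions (may be empty or NULL).
#' @param pad extension in bp applied to each gene span (default 1000).
#' @return list with `kept` (GRanges) and `removed` (GRanges with metadata
#'   column `reason` in {coding_overlap, blacklist}); the two partition the
#'   input.
#' @export
filter_enhancers <- function(enhancers, genes = NULL, blacklist = NULL, pad = 1000) {
  if (pad < 0) stop("pad must be >= 0")
  n <- length(enhancers)
  reason <- rep(NA_character_, n)
  if (!is.null(blacklist) && length(blacklist) > 0) {
    hit <- ov_any(enhancers, blacklist)
    reason[hit] <- "blacklist"
  }
  if (!is.null(genes) && nrow(genes) > 0) {
    ext <- bed_to_gr(genes$chrom, pmax(0, genes$start - pad), genes$end + pad)
    hit <- ov_any(enhancers, ext)
    reason[hit] <- "coding_overlap"
  }
  removed <- enhancers[!is.na(reason)]
  if (length(removed)) S4Vectors::mcols(removed)$reason <- reason[!is.na(reason)]
  list(kept = enhancers[is.na(reason)], removed = removed)
}

#' Classify enhancers as proximal or distal by upstream TSS distance
#'
#' The reference point is the enhancer midpoint, `floor((start + end) / 2)` in
#' 0-based coordinates. For each gene on the same chromosome the enhancer is
#' upstream when the midpoint precedes the TSS in the gene's 5' direction;
#' `d` is the minimum upstream distance over genes, falling back to the
#' unsigned distance to the nearest TSS when the enhancer is downstream of
#' every gene. `1000 < d <= 2000` is proximal, `d > 2000` distal, `d <= 1000`
#' excluded (such enhancers should not survive [filter_enhancers()] with the
#' default pad).
#'
#' @param enhancers `GRanges` of enhancers.
#' @param genes gene model data.frame from [read_genes()]; must be non-empty.
#' @return character vector in {proximal, distal, excluded}, one per enhancer.
#' @export
classify_enhancer_distance <- function(enhancers, genes) {
  if (is.null(genes) || nrow(genes) == 0) stop("gene list must be non-empty")
  mids <- interval_midpoint0(enhancers)
  chroms <- as.character(GenomicRanges::seqnames(enhancers))
  by_chr <- split(seq_len(nrow(genes)), genes$chrom)
  out <- character(length(enhancers))
  for (i in seq_along(enhancers)) {
    gi <- by_chr[[chroms[i]]]
    if (is.null(gi)) {
      stop(sprintf("no gene models on chromosome %s", chroms[i]))
    }
    tss <- genes$tss[gi]
    plus <- genes$strand[gi] == "+"
    m <- mids[i]
    upstream <- ifelse(plus, m < tss, m > tss)
    d <- if (any(upstream)) min(abs(tss[upstream] - m)) else min(abs(tss - m))
    out[i] <- if (d <= 1000) "excluded" else if (d <= 2000) "proximal" else "distal"
  }
  out
}

#' Annotate promoter strand from the nearest gene TSS
#'
#' Each promoter takes the strand of the gene whose TSS lies closest to the
#' promoter midpoint (same chromosome); exact distance ties are broken by the
#' lexicographically smaller gene id. Promoters on chromosomes without gene
#' models keep strand `*`.
#'
#' @param promoters `GRanges`.
#' @param genes gene model data.frame from [read_genes()]; must be non-empty.
#' @return `GRanges` with strand set and metadata column `nearest_gene`.
#' @export
annotate_promoter_strand <- function(promoters, genes) {
  if (is.null(genes) || nrow(genes) == 0) stop("gene list must be non-empty")
  mids <- interval_midpoint0(promoters)
  chroms <- as.character(GenomicRanges::seqnames(promoters))
  ord <- order(genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  by_chr <- split(seq_len(nrow(genes)), genes$chrom)
  str_out <- rep("*", length(promoters))
  gene_out <- rep(NA_character_, length(promoters))
  for (i in seq_along(promoters)) {
    gi <- by_chr[[chroms[i]]]
    if (is.null(gi)) next
    d <- abs(genes$tss[gi] - mids[i])
    j <- gi[which.min(d)]  # genes pre-sorted by id, so which.min applies the tie-break
    str_out[i] <- genes$strand[j]
    gene_out[i] <- genes$gene_id[j]
  }
  GenomicRanges::strand(promoters) <- str_out
  S4Vectors::mcols(promoters)$nearest_gene <- gene_out
  promoters
}

#' Build the curated element catalog
#'
#' Applies [filter_enhancers()], classifies surviving enhancers with
#' [classify_enhancer_distance()], and annotates promoter strand with
#' [annotate_promoter_strand()]. Removed enhancers are retained in the table
#' with their removal reason so the partition is auditable.
#'
#' @param enhancers,promoters `GRanges` with unique ids as names.
#' @param genes gene model data.frame from [read_genes()].
#' @param blacklist `GRanges` or NULL.
#' @param pad coding-region extension in bp.
#' @param provenance free-text source description.
#' @return data.frame (class `credyn_catalog`) with columns id, chrom, start,
#'   end, strand, element_class, subclass, removal_reason, nearest_gene;
#'   coordinates 0-based half-open.
#' @export
build_catalog <- function(enhancers, promoters, genes, blacklist = NULL,
                          pad = 1000, provenance = "") {
  if (is.null(names(enhancers)) || is.null(names(promoters))) {
    stop("enhancers and promoters must carry unique ids as names")
  }
  if (anyDuplicated(c(names(enhancers), names(promoters)))) {
    stop("element ids must be unique across the catalog")
  }
  flt <- filter_enhancers(enhancers, genes, blacklist, pad = pad)
  kept <- flt$kept
  sub <- if (length(kept)) classify_enhancer_distance(kept, genes) else character(0)
  prom <- annotate_promoter_strand(promoters, genes)

  row_of <- function(gr, class, subclass, reason, nearest) {
    df <- gr_to_bed(gr)
    data.frame(id = df$id, chrom = df$chrom, start = df$start, end = df$end,
               strand = df$strand, element_class = class, subclass = subclass,
               removal_reason = reason, nearest_gene = nearest,
               stringsAsFactors = FALSE)
  }
  parts <- list()
  if (length(kept)) {
    parts$kept <- row_of(kept, "enhancer", sub, NA_character_, NA_character_)
  }
  if (length(flt$removed)) {
    parts$removed <- row_of(flt$removed, "enhancer", "not_applicable",
                            S4Vectors::mcols(flt$removed)$reason, NA_character_)
  }
  if (length(prom)) {
    parts$prom <- row_of(prom, "promoter", "not_applicable", NA_character_,
                         S4Vectors::mcols(prom)$nearest_gene)
  }
  cat_df <- do.call(rbind, parts)
  rownames(cat_df) <- NULL
  attr(cat_df, "provenance") <- provenance
  class(cat_df) <- c("credyn_catalog", "data.frame")
  cat_df
}

#' Retained elements of a catalog as a GRanges
#'
#' @param catalog catalog data.frame from [build_catalog()] (or a compatible
#'   table with id/chrom/start/end/strand/element_class/subclass columns).
#' @param classes restrict to element classes (e.g. "enhancer"); NULL for all.
#' @param subclasses restrict to enhancer subclasses (e.g. "distal").
#' @param kept_only drop rows carrying a removal reason (default TRUE).
#' @return `GRanges` with mcols element_class, subclass.
#' @export
catalog_gr <- function(catalog, classes = NULL, subclasses = NULL,
                       kept_only = TRUE) {
  df <- as.data.frame(catalog)
  if (kept_only && "removal_reason" %in% names(df)) {
    df <- df[is.na(df$removal_reason), , drop = FALSE]
  }
  if (!is.null(classes)) df <- df[df$element_class %in% classes, , drop = FALSE]
  if (!is.null(subclasses)) df <- df[df$subclass %in% subclasses, , drop = FALSE]
  if (nrow(df) == 0) return(GenomicRanges::GRanges())
  gr <- bed_to_gr(df$chrom, df$start, df$end, strand = df$strand, id = df$id)
  S4Vectors::mcols(gr)$element_class <- df$element_class
  S4Vectors::mcols(gr)$subclass <- df$subclass
  gr
}

#' Write / read a catalog TSV
#'
#' @param catalog catalog data.frame.
#' @param path output path.
#' @export
write_catalog <- function(catalog, path) {
  write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  class(df) <- c("credyn_catalog", "data.frame")
  df
}
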