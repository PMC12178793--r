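#' Genomic interval I/O and conversion helpers
#'
#' Intervals on disk follow the BED convention: 0-based, half-open
#' `[start, end)`. In memory they are held as [GenomicRanges::GRanges]
#' (1-based, closed), so a BED record `start end` maps to
#' `IRanges(start + 1, end)`. Overlap always means at least one shared base.
#'
#' @name interval-io
NULL

#' Convert BED-style coordinate columns to a GRanges
#'
#' @param chrom,start,end vectors of chromosome names and 0-based half-open
#'   coordinates.
#' @param strand optional strand vector (`"+"`, `"-"` or `"*"`).
#' @param id optional unique labels, stored as names.
#' @return A `GRanges`.
#' @export
bed_to_gr <- function(chrom, start, end, strand = NULL, id = NULL) {
  if (any(start < 0) || any(end <= start)) {
    stop("invalid interval: require 0 <= start < end")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.numeric(start) + 1, end = as.numeric(end)),
    strand = if (is.null(strand)) rep("*", length(chrom)) else strand
  )
  if (!is.null(id)) {
    if (anyDuplicated(id)) stop("interval ids must be unique within a collection")
    names(gr) <- id
  }
  gr
}

#' Extract BED-style (0-based) coordinates from a GRanges
#'
#' @param gr A `GRanges`.
#' @return data.frame with columns chrom, start, end, id, strand
#'   (start/end 0-based half-open).
#' @export
gr_to_bed <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    id = if (is.null(names(gr))) rep(NA_character_, length(gr)) else names(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Read a BED3/BED6 file
#'
#' Lines starting with `track`, `browser` or `#` and blank lines are skipped.
#' Coordinates are validated per record; a malformed line (non-integer
#' coordinates or `start >= end`) raises an error naming the line number.
#' Extra columns beyond the sixth (e.g. narrowPeak statistics) are ignored.
#'
#' @param path file path.
#' @param stranded if `TRUE`, take strand from column 6 where present.
#' @return `GRanges` in file order; column 4, when present, becomes interval
#'   ids (names).
#' @export
read_bed <- function(path, stranded = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  ncols <- vapply(fields, length, integer(1))
  bad <- which(ncols < 3L)
  if (length(bad)) {
    stop(sprintf("line %d: expected >= 3 columns, got %d", idx[bad[1]], ncols[bad[1]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s_chr <- vapply(fields, `[[`, character(1), 2L)
  e_chr <- vapply(fields, `[[`, character(1), 3L)
  start <- suppressWarnings(as.numeric(s_chr))
  end <- suppressWarnings(as.numeric(e_chr))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad)) {
    stop(sprintf("line %d: non-integer coordinates '%s %s'",
                 idx[bad[1]], s_chr[bad[1]], e_chr[bad[1]]))
  }
  bad <- which(start < 0 | end <= start)
  if (length(bad)) {
    stop(sprintf("line %d: invalid interval [%s, %s) (require 0 <= start < end)",
                 idx[bad[1]], s_chr[bad[1]], e_chr[bad[1]]))
  }
  id <- ifelse(ncols >= 4L, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, character(1)), NA_character_)
  strand <- rep("*", length(idx))
  if (stranded) {
    has6 <- ncols >= 6L
    s6 <- vapply(fields, function(f) if (length(f) >= 6) f[[6]] else "*", character(1))
    strand[has6 & s6 %in% c("+", "-")] <- s6[has6 & s6 %in% c("+", "-")]
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end), strand = strand)
  if (!all(is.na(id))) names(gr) <- ifelse(is.na(id), paste0("iv", seq_along(id)), id)
  gr
}

#' Write intervals to a BED file
#'
#' @param gr `GRanges` to write.
#' @param path output path.
#' @param stranded include name/score/strand columns (BED6).
#' @export
write_bed <- function(gr, path, stranded = FALSE) {
  df <- gr_to_bed(gr)
  if (stranded) {
    out <- data.frame(df$chrom, df$start, df$end,
                      ifelse(is.na(df$id), ".", df$id), 0L, df$strand)
  } else if (!all(is.na(df$id))) {
    out <- data.frame(df$chrom, df$start, df$end, df$id)
  } else {
    out <- data.frame(df$chrom, df$start, df$end)
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# 0-based midpoint of each interval: floor((start0 + end0) / 2).
interval_midpoint0 <- function(gr) {
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)
  floor((start0 + end0) / 2)
}

#' Read gene models
#'
#' Accepts a TSV with header columns `gene_id, chrom, start, end, strand`
#' (coordinates 0-based half-open) or a BED6 file whose name column carries
#' the gene id. Strand is mandatory: the transcription start site (TSS) is the
#' 0-based `start` for `+` genes and `end - 1` for `-` genes.
#'
#' @param path file path.
#' @return data.frame with columns gene_id, chrom, start, end, strand, tss
#'   (0-based).
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  if (grepl("gene_id", first)) {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("gene table missing columns: ", paste(miss, collapse = ", "))
    df <- df[need]
  } else {
    gr <- read_bed(path, stranded = TRUE)
    df <- gr_to_bed(gr)
    df <- data.frame(gene_id = df$id, chrom = df$chrom, start = df$start,
                     end = df$end, strand = df$strand, stringsAsFactors = FALSE)
  }
  if (any(!df$strand %in% c("+", "-"))) {
    stop("gene models require explicit strand (+ or -)")
  }
  if (any(df$start >= df$end)) stop("gene models require start < end")
  if (anyDuplicated(df$gene_id)) stop("gene ids must be unique")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df
}

genes_to_gr <- function(genes) {
  bed_to_gr(genes$chrom, genes$start, genes$end, strand = genes$strand,
            id = genes$gene_id)
}
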