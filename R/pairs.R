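#' Enhancer target-gene assignment and coordinated-pair detection
#'
#' Targets are assigned two ways: a basal-plus-extension regulatory-domain
#' model (nearest-gene style: 5 kb upstream / 1 kb downstream basal region
#' around each TSS, extended up to 1 Mb but never past a neighbouring basal
#' region or the chromosome edge) and chromatin-loop anchors joining an
#' enhancer to a promoter. A pair is coordinated when enhancer RPM and target
#' gene expression move strictly in the same direction across both timepoint
#' steps.
#'
#' @name pairs
NULL

#' Read a differential-expression table
#'
#' @param path TSV with header gene_id, log2fc, fdr.
#' @param contrast contrast label (e.g. "8h_vs_0h").
#' @return data.frame with attribute `contrast`.
#' @export
read_de_table <- function(path, contrast = "") {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("DE table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$fdr < 0 | df$fdr > 1)) stop("fdr values must lie in [0, 1]")
  if (anyDuplicated(df$gene_id)) stop("one row per gene required")
  attr(df, "contrast") <- contrast
  df
}

#' Genes consistently up- or down-regulated in both contrasts
#'
#' A gene is consistently up when `log2fc > lfc_min` and `fdr < fdr_max`
#' (strict inequalities) in both the 8h-vs-0h and 16h-vs-0h contrasts, and
#' consistently down with `log2fc < -lfc_min` in both. Genes absent from a
#' contrast fail that contrast.
#'
#' @param de_8v0,de_16v0 DE tables (data.frames with gene_id, log2fc, fdr).
#' @param lfc_min absolute log2 fold-change threshold (default 1).
#' @param fdr_max FDR threshold (default 0.05).
#' @return list with character vectors `up` and `down` (disjoint).
#' @export
consistent_de_genes <- function(de_8v0, de_16v0, lfc_min = 1, fdr_max = 0.05) {
  if (nrow(de_8v0) == 0 || nrow(de_16v0) == 0) stop("DE tables must be non-empty")
  pass <- function(df, dir) {
    sig <- df$fdr < fdr_max
    hit <- if (dir > 0) df$log2fc > lfc_min else df$log2fc < -lfc_min
    df$gene_id[sig & hit]
  }
  up <- intersect(pass(de_8v0, 1), pass(de_16v0, 1))
  down <- intersect(pass(de_8v0, -1), pass(de_16v0, -1))
  list(up = sort(up), down = sort(down))
}

#' Build basal-plus-extension regulatory domains
#'
#' Each gene receives a strand-oriented basal region covering `basal_up` bp
#' upstream through `basal_down` bp downstream of its TSS. The basal region
#' is then extended in both directions up to `max_ext` bp, stopping at the
#' nearest non-overlapping neighbouring basal region boundary and at
#' chromosome edges. Domains overlap neighbouring basal regions only where
#' the basal regions themselves overlap.
#'
#' @param genes gene model data.frame from [read_genes()] (stranded).
#' @param basal_up,basal_down basal extent upstream/downstream of the TSS
#'   (defaults 5000 / 1000 bp).
#' @param max_ext maximum extension per side (default 1e6 bp).
#' @param chrom_sizes named vector of chromosome lengths; domains are clipped
#'   to `[0, size)`. Chromosomes absent from the mapping are unclipped on the
#'   right.
#' @return data.frame: gene_id, chrom, start, end, basal_start, basal_end
#'   (0-based half-open).
#' @export
build_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                          max_ext = 1e6, chrom_sizes = NULL) {
  if (any(!genes$strand %in% c("+", "-"))) stop("genes must be stranded")
  plus <- genes$strand == "+"
  # 0-based half-open basal region covering [tss - up, tss + down) in the
  # gene's own orientation; the +1 shifts account for the minus-strand TSS
  # sitting at end - 1.
  b_start <- ifelse(plus, genes$tss - basal_up, genes$tss - basal_down + 1)
  b_end <- ifelse(plus, genes$tss + basal_down, genes$tss + basal_up + 1)
  b_start <- pmax(0, b_start)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[genes$chrom]
    b_end <- ifelse(is.na(lim), b_end, pmin(b_end, lim))
  }
  d_start <- numeric(nrow(genes))
  d_end <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    same <- which(genes$chrom == genes$chrom[i])
    same <- same[same != i]
    left_lim <- 0
    right_lim <- if (!is.null(chrom_sizes) && genes$chrom[i] %in% names(chrom_sizes)) {
      chrom_sizes[[genes$chrom[i]]]
    } else Inf
    if (length(same)) {
      le <- b_end[same][b_end[same] <= b_start[i]]
      if (length(le)) left_lim <- max(left_lim, max(le))
      rs <- b_start[same][b_start[same] >= b_end[i]]
      if (length(rs)) right_lim <- min(right_lim, min(rs))
    }
    d_start[i] <- max(b_start[i] - max_ext, left_lim)
    d_end[i] <- min(b_end[i] + max_ext, right_lim)
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = d_start, end = d_end,
             basal_start = b_start, basal_end = b_end,
             stringsAsFactors = FALSE)
}

#' Assign enhancers to genes by regulatory-domain membership
#'
#' An enhancer is assigned every gene whose domain contains the enhancer
#' midpoint (0-based `floor((start + end) / 2)`).
#'
#' @param enhancers `GRanges` with ids as names.
#' @param domains domain table from [build_domains()].
#' @return data.frame: enhancer_id, gene_id, evidence = "domain" (zero rows
#'   when nothing is assigned).
#' @export
assign_by_domain <- function(enhancers, domains) {
  mids <- interval_midpoint0(enhancers)
  chroms <- as.character(GenomicRanges::seqnames(enhancers))
  ids <- names(enhancers) %||% paste0("el", seq_along(enhancers))
  res <- lapply(seq_along(enhancers), function(i) {
    hit <- domains$chrom == chroms[i] &
      domains$start <= mids[i] & mids[i] < domains$end
    if (!any(hit)) return(NULL)
    data.frame(enhancer_id = ids[i], gene_id = domains$gene_id[hit],
               evidence = "domain", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(enhancer_id = character(0), gene_id = character(0),
                      evidence = character(0), stringsAsFactors = FALSE)
  }
  res
}

#' Read a BEDPE-like loop file
#'
#' @param path 6-column TSV: chrom1, start1, end1, chrom2, start2, end2
#'   (0-based half-open anchors).
#' @return list with `anchor1` and `anchor2` GRanges of equal length.
#' @export
read_loops <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 6) stop("loop file requires >= 6 columns")
  list(anchor1 = bed_to_gr(df[[1]], df[[2]], df[[3]]),
       anchor2 = bed_to_gr(df[[4]], df[[5]], df[[6]]))
}

#' Assign enhancers to genes through chromatin-loop anchors
#'
#' A pair (enhancer, gene) is emitted when some loop has one anchor
#' overlapping the enhancer (>= 1 base) and the other anchor overlapping the
#' gene's promoter; both anchor orientations are considered and duplicate
#' pairs are collapsed.
#'
#' @param enhancers `GRanges` with ids as names.
#' @param promoters `GRanges` with ids as names and a `gene_id` metadata
#'   column mapping each promoter to its gene.
#' @param loops loop list from [read_loops()].
#' @return data.frame: enhancer_id, gene_id, evidence = "loop".
#' @export
assign_by_loops <- function(enhancers, promoters, loops) {
  if (is.null(S4Vectors::mcols(promoters)$gene_id)) {
    stop("promoters must carry a gene_id metadata column")
  }
  one_side <- function(a_enh, a_prom) {
    he <- ov_hits(a_enh, enhancers)
    hp <- ov_hits(a_prom, promoters)
    es <- split(S4Vectors::subjectHits(he), S4Vectors::queryHits(he))
    ps <- split(S4Vectors::subjectHits(hp), S4Vectors::queryHits(hp))
    common <- intersect(names(es), names(ps))
    if (!length(common)) return(NULL)
    do.call(rbind, lapply(common, function(l) {
      expand.grid(enhancer_id = names(enhancers)[es[[l]]],
                  gene_id = S4Vectors::mcols(promoters)$gene_id[ps[[l]]],
                  stringsAsFactors = FALSE)
    }))
  }
  res <- rbind(one_side(loops$anchor1, loops$anchor2),
               one_side(loops$anchor2, loops$anchor1))
  if (is.null(res) || nrow(res) == 0) {
    return(data.frame(enhancer_id = character(0), gene_id = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  res <- unique(res)
  res$evidence <- "loop"
  rownames(res) <- NULL
  res[order(res$enhancer_id, res$gene_id), , drop = FALSE]
}

#' Merge domain- and loop-based pair evidence
#'
#' @param domain_pairs,loop_pairs pair tables from [assign_by_domain()] /
#'   [assign_by_loops()].
#' @return pair table with evidence in {domain, loop, both}.
#' @export
merge_pair_evidence <- function(domain_pairs, loop_pairs) {
  key_d <- paste(domain_pairs$enhancer_id, domain_pairs$gene_id)
  key_l <- paste(loop_pairs$enhancer_id, loop_pairs$gene_id)
  all_keys <- union(key_d, key_l)
  if (!length(all_keys)) {
    return(data.frame(enhancer_id = character(0), gene_id = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(all_keys, " "))
  ev <- ifelse(all_keys %in% key_d & all_keys %in% key_l, "both",
               ifelse(all_keys %in% key_d, "domain", "loop"))
  out <- data.frame(enhancer_id = parts[, 1], gene_id = parts[, 2],
                    evidence = ev, stringsAsFactors = FALSE)
  out[order(out$enhancer_id, out$gene_id), , drop = FALSE]
}

#' Detect direction-coordinated enhancer-gene pairs
#'
#' A pair is coordinated-down when both the enhancer RPM triple and the gene
#' expression triple decrease strictly at both steps (`v0 - v1 > eps` and
#' `v1 - v2 > eps`); coordinated-up symmetrically. All other pairs are
#' dropped, as are pairs missing expression for either member (recorded in
#' the `dropped` attribute with a reason).
#'
#' @param pairs pair table (enhancer_id, gene_id, evidence).
#' @param enh_rpm matrix of enhancer RPM triples (rownames = enhancer ids,
#'   3 ordered timepoint columns).
#' @param gene_expr matrix of gene expression triples (rownames = gene ids).
#' @param eps minimum step change (default 0, i.e. strict monotonicity).
#' @return pair table with a `direction` column in {up, down}; attribute
#'   `dropped` lists discarded pairs and reasons.
#' @export
coordinated_pairs <- function(pairs, enh_rpm, gene_expr, eps = 0) {
  dir3 <- function(v) {
    if (v[1] - v[2] > eps && v[2] - v[3] > eps) return("down")
    if (v[2] - v[1] > eps && v[3] - v[2] > eps) return("up")
    NA_character_
  }
  keep <- logical(nrow(pairs))
  direction <- character(nrow(pairs))
  drop_reason <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    e <- pairs$enhancer_id[i]
    g <- pairs$gene_id[i]
    if (!e %in% rownames(enh_rpm)) { drop_reason[i] <- "missing_enhancer_expression"; next }
    if (!g %in% rownames(gene_expr)) { drop_reason[i] <- "missing_gene_expression"; next }
    de <- dir3(as.numeric(enh_rpm[e, ]))
    dg <- dir3(as.numeric(gene_expr[g, ]))
    if (is.na(de) || is.na(dg) || de != dg) { drop_reason[i] <- "not_coordinated"; next }
    keep[i] <- TRUE
    direction[i] <- de
  }
  out <- pairs[keep, , drop = FALSE]
  out$direction <- direction[keep]
  rownames(out) <- NULL
  dropped <- pairs[!keep, , drop = FALSE]
  dropped$reason <- drop_reason[!keep]
  rownames(dropped) <- NULL
  attr(out, "dropped") <- dropped
  out
}
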