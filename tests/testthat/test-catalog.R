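test_that("read_bed maps fields, preserves order, and rejects malformed lines", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chr1\t100\t200\te1", "# comment",
               "chr2\t0\t50\te2", "chr1\t5\t6\te3"), path)
  gr <- read_bed(path)
  expect_equal(length(gr), 3L)
  expect_equal(names(gr), c("e1", "e2", "e3"))
  df <- gr_to_bed(gr)
  expect_equal(df$chrom, c("chr1", "chr2", "chr1"))
  expect_equal(df$start, c(100, 0, 5))
  expect_equal(df$end, c(200, 50, 6))

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), bad)
  expect_error(read_bed(bad), "line 2")
  writeLines(c("chr1\t1.5\t7"), bad)
  expect_error(read_bed(bad), "non-integer")
  writeLines(c("chr1\t100"), bad)
  expect_error(read_bed(bad), ">= 3 columns")
})

test_that("filter_enhancers applies the pad-extended coding and blacklist rules", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 6000, end = 9000,
                      strand = "+", tss = 6000)
  enh <- bed_to_gr(c("chr1", "chr1", "chr2"),
                   c(5000, 3000, 1000), c(5400, 3500, 1500),
                   id = c("a", "b", "c"))
  bl <- bed_to_gr("chr1", 3400, 3600)
  res <- filter_enhancers(enh, genes, bl, pad = 1000)
  expect_equal(names(res$kept), "c")
  rem <- S4Vectors::mcols(res$removed)$reason
  names(rem) <- names(res$removed)
  expect_equal(rem[["a"]], "coding_overlap")  # extended gene [5000,10000)
  expect_equal(rem[["b"]], "blacklist")
  # empty gene list removes nothing for coding
  res2 <- filter_enhancers(enh, NULL, bl, pad = 1000)
  expect_equal(sort(names(res2$kept)), c("a", "c"))
  expect_error(filter_enhancers(enh, genes, bl, pad = -1), "pad")
})

test_that("filter_enhancers partitions its input exactly, matching a per-base oracle", {
  set.seed(42)
  for (rep in 1:25) {
    enh <- rand_intervals(12)
    gn <- rand_intervals(4)
    bl <- rand_intervals(3)
    genes <- data.frame(gene_id = paste0("g", seq_len(nrow(gn))),
                        chrom = gn$chrom, start = gn$start, end = gn$end,
                        strand = "+", tss = gn$start)
    pad <- sample(c(0, 10, 50), 1)
    res <- filter_enhancers(df_to_gr(enh, id = paste0("e", 1:12)), genes,
                            df_to_gr(bl), pad = pad)
    gn_ext <- data.frame(chrom = gn$chrom, start = pmax(0, gn$start - pad),
                         end = gn$end + pad)
    want_removed <- bf_overlaps_any(enh, gn_ext) | bf_overlaps_any(enh, bl)
    expect_setequal(names(res$removed), paste0("e", 1:12)[want_removed])
    expect_setequal(c(names(res$kept), names(res$removed)), paste0("e", 1:12))
    expect_length(intersect(names(res$kept), names(res$removed)), 0)
  }
})

test_that("upstream-distance classification follows the 1-2 kb / >2 kb rule", {
  genes <- data.frame(gene_id = "g1", chrom = "c1", start = 10000, end = 20000,
                      strand = "+", tss = 10000)
  enh <- bed_to_gr(c("c1", "c1"), c(8400, 6900), c(8600, 7100))
  expect_equal(classify_enhancer_distance(enh, genes),
               c("proximal", "distal"))  # midpoints 8500 (d=1500), 7000 (d=3000)

  # minimum upstream distance over genes: upstream of the minus-strand gene
  genes2 <- rbind(genes,
                  data.frame(gene_id = "g2", chrom = "c1", start = 11000,
                             end = 12601, strand = "-", tss = 12600))
  enh2 <- bed_to_gr("c1", 11400, 11600)  # midpoint 11500
  # by hand: + gene tss 10000, midpoint downstream; - gene tss 12600,
  # upstream at d = 1100 -> proximal
  expect_equal(classify_enhancer_distance(enh2, genes2), "proximal")
  expect_equal(classify_enhancer_distance(bed_to_gr("c1", 9400, 9600), genes),
               "excluded")
  expect_error(classify_enhancer_distance(enh, genes[0, ]), "non-empty")
})

test_that("distance classification is invariant under translation and renaming", {
  set.seed(7)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c1",
                      start = c(50000, 90000), end = c(60000, 95000),
                      strand = c("+", "-"), tss = c(50000, 94999))
  mids <- sample(30000:100000, 40)
  enh <- bed_to_gr("c1", mids - 100, mids + 100)
  base <- classify_enhancer_distance(enh, genes)
  shift <- 12345
  genes_s <- transform(genes, start = start + shift, end = end + shift,
                       tss = tss + shift, chrom = "other")
  enh_s <- bed_to_gr("other", mids - 100 + shift, mids + 100 + shift)
  expect_equal(classify_enhancer_distance(enh_s, genes_s), base)
})

test_that("promoter strand comes from the nearest TSS with lexicographic ties", {
  genes <- data.frame(gene_id = c("B", "A"), chrom = "c1",
                      start = c(5000, 7000), end = c(6000, 8001),
                      strand = c("-", "+"), tss = c(5999, 7000))
  # promoter midpoint 5020: nearest TSS is B at 5999? no - distance 979;
  # A at 7000 distance 1980 -> strand of B (-)
  p1 <- annotate_promoter_strand(bed_to_gr("c1", 4920, 5120), genes)
  expect_equal(as.character(GenomicRanges::strand(p1)), "-")
  # equidistant midpoint between the two TSSs: (5999+7000)/2 = 6499.5;
  # use tss values 5000 and 7000 with midpoint 6000 for an exact tie
  genes2 <- data.frame(gene_id = c("A", "B"), chrom = "c1",
                       start = c(5000, 6000), end = c(5500, 7001),
                       strand = c("+", "-"), tss = c(5000, 7000))
  pt <- annotate_promoter_strand(bed_to_gr("c1", 5900, 6100), genes2)
  expect_equal(as.character(GenomicRanges::strand(pt)), "+")  # id tie-break

  # brute force: each promoter to its nearest TSS
  set.seed(11)
  mids <- sample(1000:20000, 30)
  prom <- bed_to_gr("c1", mids - 50, mids + 50)
  gn <- data.frame(gene_id = sprintf("g%02d", 1:5), chrom = "c1",
                   start = seq(2000, 18000, length.out = 5),
                   end = seq(2000, 18000, length.out = 5) + 500,
                   strand = rep(c("+", "-"), length.out = 5))
  gn$tss <- ifelse(gn$strand == "+", gn$start, gn$end - 1)
  res <- annotate_promoter_strand(prom, gn)
  want <- vapply(mids, function(m) {
    d <- abs(gn$tss - m)
    cand <- which(d == min(d))
    gn$strand[cand[order(gn$gene_id[cand])][1]]
  }, character(1))
  expect_equal(as.character(GenomicRanges::strand(res)), want)
})

test_that("build_catalog keeps no enhancer violating the exclusion rules", {
  cfg <- noise_free(small_synth())
  b <- generate_bundle(cfg)
  cat_df <- build_catalog(b$enhancers, b$promoters, b$genes, b$blacklist)
  kept_enh <- cat_df[cat_df$element_class == "enhancer" &
                       is.na(cat_df$removal_reason), ]
  # kept enhancers never touch pad-extended gene spans or the blacklist
  kept_gr <- bed_to_gr(kept_enh$chrom, kept_enh$start, kept_enh$end)
  ext <- bed_to_gr(b$genes$chrom, pmax(0, b$genes$start - 1000),
                   b$genes$end + 1000)
  expect_false(any(IRanges::overlapsAny(kept_gr, ext)))
  expect_false(any(IRanges::overlapsAny(kept_gr, b$blacklist)))
  # planted decoys are removed with the planted reason
  removed <- cat_df[!is.na(cat_df$removal_reason), ]
  expect_setequal(removed$id, b$truth$removed_enhancers$id)
  expect_equal(removed$removal_reason[match(b$truth$removed_enhancers$id,
                                            removed$id)],
               b$truth$removed_enhancers$reason)
  # planted subclasses recovered
  expect_equal(kept_enh$subclass,
               b$truth$elements$subclass[match(kept_enh$id, b$truth$elements$id)])
})
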