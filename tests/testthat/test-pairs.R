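de_row <- function(gene, lfc, fdr) {
  data.frame(gene_id = gene, log2fc = lfc, fdr = fdr, stringsAsFactors = FALSE)
}

test_that("consistent DE genes require passing both contrasts with the same sign", {
  de8 <- rbind(de_row("up", 2.0, 0.01), de_row("flip", 2.0, 0.01),
               de_row("edge", 1.0, 0.01), de_row("dn", -2, 0.001),
               de_row("only8", 3, 0.001))
  de16 <- rbind(de_row("up", 1.5, 0.001), de_row("flip", -2.0, 0.01),
                de_row("edge", 1.0, 0.01), de_row("dn", -1.5, 0.01))
  res <- consistent_de_genes(de8, de16)
  expect_equal(res$up, "up")
  expect_equal(res$down, "dn")           # sign must agree in both
  expect_false("edge" %in% res$up)       # strict inequality at lfc = 1
  expect_false("only8" %in% res$up)      # absent contrast fails
  expect_length(intersect(res$up, res$down), 0)
})

test_that("regulatory domains extend to neighbours and chromosome edges", {
  sizes <- c(cA = 1e6)
  g1 <- data.frame(gene_id = "g1", chrom = "cA", start = 100000, end = 110000,
                   strand = "+", tss = 100000)
  d <- build_domains(g1, chrom_sizes = sizes)
  # single gene: basal [95000, 101000), extension 1 Mb clipped at the edges
  expect_equal(d$basal_start, 95000)
  expect_equal(d$basal_end, 101000)
  expect_equal(d$start, 0)
  expect_equal(d$end, 1e6)

  g2 <- rbind(g1, data.frame(gene_id = "g2", chrom = "cA", start = 102000,
                             end = 109000, strand = "+", tss = 102000))
  d2 <- build_domains(g2, chrom_sizes = sizes)
  # g1's downstream extension stops at g2's basal start (97000); here the
  # basal regions overlap ([95000,101000) vs [97000,103000)) so no clipping
  # between them applies and both extend to the free side only
  expect_equal(d2$start[1], 0)
  expect_equal(d2$end[2], 1e6)
  # non-overlapping neighbours clip each other's extension
  g3 <- rbind(g1, data.frame(gene_id = "g3", chrom = "cA", start = 200000,
                             end = 210000, strand = "+", tss = 200000))
  d3 <- build_domains(g3, chrom_sizes = sizes)
  expect_equal(d3$end[1], 195000)   # g3 basal start
  expect_equal(d3$start[2], 101000) # g1 basal end

  # basal clipped at position 0
  g0 <- data.frame(gene_id = "g0", chrom = "cA", start = 2000, end = 3000,
                   strand = "+", tss = 2000)
  expect_equal(build_domains(g0, chrom_sizes = sizes)$basal_start, 0)
})

test_that("domains cover basal regions and grow monotonically in max_ext", {
  set.seed(17)
  tss <- sort(sample(10000:900000, 15))
  gn <- data.frame(gene_id = sprintf("g%02d", 1:15), chrom = "cA",
                   start = tss, end = tss + 5000,
                   strand = sample(c("+", "-"), 15, replace = TRUE))
  gn$tss <- ifelse(gn$strand == "+", gn$start, gn$end - 1)
  sizes <- c(cA = 1e6)
  small <- build_domains(gn, max_ext = 10000, chrom_sizes = sizes)
  large <- build_domains(gn, max_ext = 1e6, chrom_sizes = sizes)
  expect_true(all(small$start <= small$basal_start & small$end >= small$basal_end))
  expect_true(all(small$start >= 0 & small$end <= 1e6))
  expect_true(all(large$start <= small$start & large$end >= small$end))
})

test_that("domain assignment matches a brute-force midpoint membership scan", {
  set.seed(19)
  tss <- sort(sample(5000:95000, 8))
  gn <- data.frame(gene_id = sprintf("g%d", 1:8), chrom = "cA",
                   start = tss, end = tss + 2000, strand = "+", tss = tss)
  dom <- build_domains(gn, max_ext = 20000, chrom_sizes = c(cA = 1e5))
  mids <- sample(0:99999, 50)
  enh <- bed_to_gr("cA", pmax(0, mids - 100), mids + 100,
                   id = sprintf("e%02d", 1:50))
  got <- assign_by_domain(enh, dom)
  for (i in 1:50) {
    m <- floor((pmax(0, mids[i] - 100) + mids[i] + 100) / 2)
    want <- dom$gene_id[dom$start <= m & m < dom$end]
    expect_setequal(got$gene_id[got$enhancer_id == sprintf("e%02d", i)], want)
  }
})

test_that("loop assignment requires one anchor on each side", {
  enh <- bed_to_gr("cA", 1000, 1400, id = "e1")
  prom <- bed_to_gr("cA", 50000, 50600, id = "p1")
  S4Vectors::mcols(prom)$gene_id <- "g1"
  hit <- list(anchor1 = bed_to_gr("cA", 900, 1500),
              anchor2 = bed_to_gr("cA", 49900, 50100))
  expect_equal(assign_by_loops(enh, prom, hit)[, c("enhancer_id", "gene_id")],
               data.frame(enhancer_id = "e1", gene_id = "g1"))
  both_enh <- list(anchor1 = bed_to_gr("cA", 900, 1500),
                   anchor2 = bed_to_gr("cA", 1000, 1200))
  expect_equal(nrow(assign_by_loops(enh, prom, both_enh)), 0L)
  # swapped anchor orientation also pairs, duplicates collapse
  swap <- list(anchor1 = bed_to_gr(c("cA", "cA"), c(49900, 900), c(50100, 1500)),
               anchor2 = bed_to_gr(c("cA", "cA"), c(900, 49900), c(1500, 50100)))
  expect_equal(nrow(assign_by_loops(enh, prom, swap)), 1L)
})

test_that("loop assignment matches a brute-force double overlap scan", {
  set.seed(23)
  enh_df <- rand_intervals(10, chroms = "cA")
  prom_df <- rand_intervals(6, chroms = "cA")
  a1 <- rand_intervals(12, chroms = "cA")
  a2 <- rand_intervals(12, chroms = "cA")
  enh <- df_to_gr(enh_df, id = sprintf("e%d", 1:10))
  prom <- df_to_gr(prom_df, id = sprintf("p%d", 1:6))
  S4Vectors::mcols(prom)$gene_id <- sprintf("g%d", 1:6)
  got <- assign_by_loops(enh, prom, list(anchor1 = df_to_gr(a1),
                                         anchor2 = df_to_gr(a2)))
  want <- unique(do.call(rbind, lapply(1:12, function(l) {
    out <- NULL
    for (ei in 1:10) for (pi in 1:6) {
      fwd <- bf_pair_overlaps(a1[l, ], enh_df[ei, ]) &&
        bf_pair_overlaps(a2[l, ], prom_df[pi, ])
      rev <- bf_pair_overlaps(a2[l, ], enh_df[ei, ]) &&
        bf_pair_overlaps(a1[l, ], prom_df[pi, ])
      if (fwd || rev) {
        out <- rbind(out, data.frame(enhancer_id = sprintf("e%d", ei),
                                     gene_id = sprintf("g%d", pi)))
      }
    }
    out
  })))
  expect_setequal(paste(got$enhancer_id, got$gene_id),
                  if (is.null(want)) character(0) else paste(want$enhancer_id, want$gene_id))
})

test_that("coordinated pairs require strict shared monotone direction", {
  pairs <- data.frame(enhancer_id = c("e1", "e2", "e3"),
                      gene_id = c("g1", "g2", "g3"),
                      evidence = "both", stringsAsFactors = FALSE)
  enh_rpm <- rbind(e1 = c(3, 2, 1), e2 = c(3, 2, 1), e3 = c(1, 2, 1.5))
  gene_expr <- rbind(g1 = c(30, 20, 10), g2 = c(10, 20, 30), g3 = c(1, 2, 1.5))
  res <- coordinated_pairs(pairs, enh_rpm, gene_expr)
  expect_equal(res$enhancer_id, "e1")
  expect_equal(res$direction, "down")
  dropped <- attr(res, "dropped")
  expect_setequal(dropped$enhancer_id, c("e2", "e3"))
  expect_true(all(dropped$reason == "not_coordinated"))

  # missing expression drops the pair with a logged reason
  res2 <- coordinated_pairs(pairs, enh_rpm[1:2, ], gene_expr)
  expect_equal(attr(res2, "dropped")$reason[attr(res2, "dropped")$enhancer_id == "e3"],
               "missing_enhancer_expression")

  # invariance under uniform rescaling of all expression values
  res3 <- coordinated_pairs(pairs, enh_rpm * 1000, gene_expr * 1000)
  expect_equal(res3$enhancer_id, res$enhancer_id)
  expect_equal(res3$direction, res$direction)
})

test_that("planted coordinated pairs are recovered from a noise-free bundle", {
  b <- generate_bundle(noise_free(small_synth(seed = 9)))
  cat_df <- build_catalog(b$enhancers, b$promoters, b$genes, b$blacklist)
  enh <- catalog_gr(cat_df, classes = "enhancer")
  prom <- b$promoters
  lp <- assign_by_loops(enh, prom, b$loops)
  rpm <- vapply(c("RNA_0h", "RNA_8h", "RNA_16h"),
                function(s) region_rpm(b$fragments[[s]], enh),
                numeric(length(enh)))
  rownames(rpm) <- names(enh)
  coord <- coordinated_pairs(lp, rpm, b$gene_expr)
  got <- paste(coord$enhancer_id, coord$gene_id, coord$direction)
  want <- paste(b$truth$pairs$enhancer_id, b$truth$pairs$gene_id,
                b$truth$pairs$direction)
  expect_setequal(got, want)
})
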