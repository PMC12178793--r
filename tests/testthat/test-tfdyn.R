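fp_row <- function(tf, chrom, start, prot, tc, tp) {
  data.frame(tf_name = tf, chrom = chrom, start = start, end = start + 20,
             protection_score = prot, tag_count = tc, timepoint = tp,
             stringsAsFactors = FALSE)
}

test_that("footprint extraction keeps only element-overlapping records", {
  fp <- rbind(fp_row("A", "c1", 110, 5, 10, "0h"),
              fp_row("B", "cZ", 110, 5, 10, "0h"))
  els <- bed_to_gr("c1", 100, 200)
  res <- footprints_in_elements(fp, els)
  expect_equal(res$subset$tf_name, "A")
  expect_equal(as.integer(res$counts[["0h"]]), 1L)

  set.seed(31)
  fps <- rand_intervals(40)
  fp2 <- do.call(rbind, lapply(seq_len(40), function(i) {
    fp_row(paste0("T", i), fps$chrom[i], fps$start[i], 1, 1,
           sample(c("0h", "8h", "16h"), 1))
  }))
  fp2$end <- fps$end
  els2 <- rand_intervals(8)
  got <- footprints_in_elements(fp2, df_to_gr(els2))
  expect_equal(got$subset$tf_name, fp2$tf_name[bf_overlaps_any(fps, els2)])
})

test_that("activity aggregation is the per-(TF, timepoint) mean with min-max fusion", {
  fp <- rbind(fp_row("A", "c", 0, 1, 100, "0h"), fp_row("A", "c", 0, 3, 300, "0h"),
              fp_row("A", "c", 0, 2, 200, "8h"), fp_row("A", "c", 0, 4, 400, "16h"),
              fp_row("B", "c", 0, 4, 0, "0h"), fp_row("B", "c", 0, 4, 0, "8h"))
  tab <- build_activity_table(fp, metric = "protection")
  expect_equal(unname(tab["A", ]), c(2, 2, 4))  # mean of 1,3 at 0h
  expect_false("B" %in% rownames(tab))
  expect_equal(attr(tab, "dropped")$tf_name, "B")  # missing 16h -> dropped

  # combined = mean of table-wide min-max normalised components
  tabc <- build_activity_table(fp, metric = "combined")
  pr <- (fp$protection_score - 1) / 3
  tc <- fp$tag_count / 400
  comb <- (pr + tc) / 2
  expect_equal(unname(tabc["A", "0h"]), mean(comb[1:2]))

  set.seed(33)
  fp3 <- do.call(rbind, lapply(sprintf("TF%d", 1:6), function(tf) {
    do.call(rbind, lapply(c("0h", "8h", "16h"), function(t) {
      k <- sample(1:4, 1)
      fp_row(rep(tf, k), "c", 0, rnorm(k), rpois(k, 5), rep(t, k))
    }))
  }))
  tab3 <- build_activity_table(fp3, metric = "tag_count")
  for (tf in rownames(tab3)) {
    for (t in c("0h", "8h", "16h")) {
      expect_equal(tab3[tf, t],
                   mean(fp3$tag_count[fp3$tf_name == tf & fp3$timepoint == t]))
    }
  }
})

test_that("SD ranking is descending with lexicographic ties and SD invariances", {
  tab <- rbind(flat = c(1, 1, 1), spread = c(0, 2, 4), mid = c(1, 2, 3))
  expect_equal(sd(tab["spread", ]), 2.0)
  expect_equal(rank_by_sd(tab, top_n = 3), c("spread", "mid", "flat"))
  expect_equal(rank_by_sd(tab, top_n = 1), "spread")
  expect_error(rank_by_sd(tab, top_n = 0), "top_n")

  set.seed(37)
  big <- matrix(rnorm(300), 100, 3,
                dimnames = list(sprintf("t%03d", 1:100), NULL))
  got <- rank_by_sd(big, top_n = 100)
  sds <- apply(big, 1, sd)
  want <- rownames(big)[order(-sds, rownames(big))]
  expect_equal(got, want)
  # row permutation invariance
  perm <- big[sample(100), ]
  expect_equal(rank_by_sd(perm, top_n = 100), got)
  # translation invariance of each row
  shifted <- big + matrix(rnorm(100), 100, 3)[, c(1, 1, 1)]
  expect_equal(rank_by_sd(shifted, top_n = 100), got)
})

test_that("top-list overlap compares complex names verbatim", {
  expect_equal(top_overlap(c("A", "B"), c("A", "B"))$count, 2)
  expect_equal(top_overlap(c("A"), c("B"))$count, 0)
  res <- top_overlap(c("JUNB", "FOSL1::JUN"), c("FOSL1::JUN", "JUN"))
  expect_equal(res$shared, "FOSL1::JUN")
  expect_equal(res$count, 1)
})

test_that("p53 partition is exact and sizes always sum by class", {
  els <- bed_to_gr(c("c1", "c1", "c1", "c1"), c(0, 100, 200, 300),
                   c(50, 150, 250, 350), id = c("e1", "e2", "p1", "p2"))
  S4Vectors::mcols(els)$element_class <- c("enhancer", "enhancer",
                                           "promoter", "promoter")
  pk <- peak_set(bed_to_gr("c1", c(40, 210), c(60, 220)), assay = "p53",
                 timepoint = "static")
  part <- partition_by_p53(els, pk)
  expect_equal(part$p53BER, "e1")
  expect_equal(part$p53FER, "e2")
  expect_equal(part$p53BPR, "p1")
  expect_equal(part$p53FPR, "p2")
  expect_error(partition_by_p53(els, peak_set(bed_to_gr("c1", 0, 1),
                                              assay = "ATAC")), "p53")

  set.seed(41)
  eldf <- rand_intervals(40)
  pkdf <- rand_intervals(10)
  gr <- df_to_gr(eldf, id = sprintf("x%02d", 1:40))
  S4Vectors::mcols(gr)$element_class <- sample(c("enhancer", "promoter"), 40,
                                               replace = TRUE)
  got <- partition_by_p53(gr, df_to_gr(pkdf))
  bound <- bf_overlaps_any(eldf, pkdf)
  cls <- S4Vectors::mcols(gr)$element_class
  expect_setequal(got$p53BER, names(gr)[cls == "enhancer" & bound])
  expect_setequal(got$p53FPR, names(gr)[cls == "promoter" & !bound])
})

test_that("high-variance TFs planted with >=5x separation top the ranking", {
  b <- generate_bundle(small_synth(seed = 13))
  tab <- build_activity_table(b$footprints, metric = "protection")
  k <- length(b$truth$hi_var_tfs)
  expect_setequal(rank_by_sd(tab, top_n = k), b$truth$hi_var_tfs)
  # the combined metric preserves the separation
  tabc <- build_activity_table(b$footprints, metric = "combined")
  expect_setequal(rank_by_sd(tabc, top_n = k), b$truth$hi_var_tfs)
})

test_that("group signal comparison delegates to the KS contract", {
  vals <- setNames(c(1, 2, 3, 4, 10, 11, 12, 13), paste0("e", 1:8))
  same <- group_signal_compare(paste0("e", 1:4), paste0("e", 1:4), vals)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disj <- group_signal_compare(paste0("e", 1:4), paste0("e", 5:8), vals)
  expect_equal(disj$statistic, 1)
  expect_error(group_signal_compare("missing", paste0("e", 1:4), vals),
               "non-empty")
})
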