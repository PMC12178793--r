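#' Seeded synthetic multi-omics bundle with planted temporal structure
#'
#' Generates a complete processed-data bundle — genome sizes, gene models,
#' candidate enhancers and promoters, a blacklist, per-assay/timepoint
#' fragment sets with a manifest, peak calls, a TF footprint table, DE
#' tables, a gene-expression table, chromatin loops and p53 peaks — together
#' with a ground-truth ledger of the planted classes, state trajectories,
#' coordinated pairs, high-variance TFs and p53-bound elements. Every file
#' parses through the package's own readers and the whole bundle is a pure
#' function of the configuration (including its seed).
#'
#' The genome is laid out in fixed-width gene slots; enhancers sit at known
#' upstream offsets of their gene's TSS so the distal (> 2 kb) / proximal
#' (1-2 kb) classes are planted by construction. Class-level multiplicative
#' temporal profiles emulate the qualitative patterns of the damage
#' response: distal-enhancer signal drops at 8 h and rebounds above baseline
#' at 16 h, while promoter RNA declines monotonically.
#'
#' @name synthdata
NULL

#' Default synthetic-bundle configuration
#'
#' @param seed RNG seed driving the whole bundle.
#' @param n_genes number of gene slots (one promoter per gene).
#' @param n_distal,n_proximal counts of planted distal/proximal enhancers.
#' @param class_profiles per-(element group, assay) multiplicative temporal
#'   triples (0h, 8h, 16h).
#' @param baseline_rate expected fragments per element at 0 h.
#' @param dispersion negative-binomial overdispersion (counts are drawn with
#'   `size = 1/dispersion`); 0 gives deterministic counts.
#' @param frac_silent fraction of elements with zero RNA at all timepoints.
#' @param n_coordinated_pairs,n_distractor_pairs planted coordinated
#'   enhancer-gene pairs and loop-connected distractor pairs.
#' @param n_tf,n_hi_var_tf footprint-table shape: total TFs and planted
#'   high-variance TFs (activity variance separation well above 5x).
#' @param p53_bound_frac fraction of elements given a p53 peak.
#' @param jitter_frac peak-boundary jitter as a fraction of element length.
#' @param pair_noise_sd lognormal noise SD on planted pair expression
#'   triples; 0 gives noise-free monotone triples.
#' @param n_decoy_coding,n_decoy_blacklist candidate enhancers planted to be
#'   removed by the exclusion rules.
#' @return configuration list of class `credyn_synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_genes = 800,
                         n_distal = 900,
                         n_proximal = 300,
                         class_profiles = list(
                           distal = list(RNA = c(1.0, 0.6, 1.2),
                                         ATAC = c(1.0, 0.7, 1.1),
                                         H3K27ac = c(1.0, 0.6, 1.2)),
                           proximal = list(RNA = c(1.0, 0.7, 0.5),
                                           ATAC = c(1.0, 0.7, 1.1),
                                           H3K27ac = c(1.0, 0.6, 1.2)),
                           promoter = list(RNA = c(1.0, 0.7, 0.5),
                                           ATAC = c(1.0, 0.8, 1.0),
                                           H3K27ac = c(1.0, 0.6, 1.2))),
                         baseline_rate = 20,
                         dispersion = 0.3,
                         frac_silent = 0.15,
                         n_coordinated_pairs = 40,
                         n_distractor_pairs = 40,
                         n_tf = 40,
                         n_hi_var_tf = 5,
                         p53_bound_frac = 0.3,
                         jitter_frac = 0.05,
                         pair_noise_sd = 0.1,
                         n_decoy_coding = 50,
                         n_decoy_blacklist = 20) {
  cfg <- list(seed = seed, n_genes = n_genes, n_distal = n_distal,
              n_proximal = n_proximal, n_promoters = n_genes,
              class_profiles = class_profiles, baseline_rate = baseline_rate,
              dispersion = dispersion, frac_silent = frac_silent,
              n_coordinated_pairs = n_coordinated_pairs,
              n_distractor_pairs = n_distractor_pairs,
              n_tf = n_tf, n_hi_var_tf = n_hi_var_tf,
              p53_bound_frac = p53_bound_frac, jitter_frac = jitter_frac,
              pair_noise_sd = pair_noise_sd,
              n_decoy_coding = n_decoy_coding,
              n_decoy_blacklist = n_decoy_blacklist,
              slot_width = 25000, enh_width = 400, prom_width = 600,
              library_size = 1e6, timepoints = c("0h", "8h", "16h"))
  stopifnot(frac_silent >= 0, frac_silent <= 1, baseline_rate > 0,
            all(unlist(class_profiles) > 0))
  n_slots <- n_genes
  n1 <- ceiling(n_slots * 0.75)
  cfg$chrom_sizes <- c(chr1 = n1 * cfg$slot_width,
                       chr2 = max(1, n_slots - n1) * cfg$slot_width)
  class(cfg) <- c("credyn_synth_config", "list")
  cfg
}

# Deterministic slot layout: gene, promoter, and enhancer anchor positions.
synth_layout <- function(cfg) {
  n <- cfg$n_genes
  n1 <- ceiling(n * 0.75)
  chrom <- c(rep("chr1", n1), rep("chr2", n - n1))
  slot <- c(seq_len(n1), seq_len(n - n1)) - 1
  S <- slot * cfg$slot_width
  strand <- rep(c("+", "+", "+", "-"), length.out = n)
  g_start <- ifelse(strand == "+", S + 12000, S + 10000)
  g_end <- ifelse(strand == "+", S + 15000, S + 13000)
  tss <- ifelse(strand == "+", g_start, g_end - 1)
  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(n)), chrom = chrom,
                      start = g_start, end = g_end, strand = strand,
                      tss = tss, slot_start = S, stringsAsFactors = FALSE)
  genes
}

# Upstream midpoint -> 0-based element interval of width w.
element_at <- function(genes, idx, upstream_d, w) {
  mid <- ifelse(genes$strand[idx] == "+",
                genes$tss[idx] - upstream_d, genes$tss[idx] + upstream_d)
  data.frame(chrom = genes$chrom[idx], start = mid - w / 2, end = mid + w / 2,
             gene_id = genes$gene_id[idx], stringsAsFactors = FALSE)
}

plant_state_triples <- function(n, p_pos = 0.70, p_neg = 0.15) {
  cat_draw <- sample(c("consistent_positive", "consistent_negative", "dynamic"),
                     n, replace = TRUE, prob = c(p_pos, p_neg, 1 - p_pos - p_neg))
  mixed <- rbind(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                 c(FALSE, FALSE, TRUE), c(TRUE, TRUE, FALSE),
                 c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE))
  st <- matrix(TRUE, n, 3)
  st[cat_draw == "consistent_negative", ] <- FALSE
  dyn <- which(cat_draw == "dynamic")
  if (length(dyn)) st[dyn, ] <- mixed[sample(6, length(dyn), replace = TRUE), ]
  st
}

nb_counts <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(round(rep_len(mu, n)))
  rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Generate a synthetic input bundle
#'
#' @param cfg configuration from [synth_config()].
#' @param out_dir directory to write the bundle files to; NULL keeps the
#'   bundle in memory only.
#' @return list of class `credyn_bundle` with the in-memory inputs (genes,
#'   enhancers, promoters, blacklist, fragment sets, peak sets, footprints,
#'   DE tables, gene expression, loops, p53 peaks), the `truth` ledger and
#'   the configuration. When `out_dir` is given, files are also written and
#'   their paths recorded in `$files`.
#' @export
generate_bundle <- function(cfg = synth_config(), out_dir = NULL) {
  with_local_seed(cfg$seed, generate_bundle_impl(cfg, out_dir))
}

generate_bundle_impl <- function(cfg, out_dir) {
  genes <- synth_layout(cfg)
  if (any(genes$end > cfg$chrom_sizes[genes$chrom])) {
    stop("elements do not fit in chrom_sizes")
  }
  tp <- cfg$timepoints

  # --- elements ---------------------------------------------------------
  distal_gene <- rep(seq_len(cfg$n_genes), length.out = cfg$n_distal)
  distal_off <- 3000 + 1500 * ((seq_len(cfg$n_distal) - 1) %/% cfg$n_genes)
  if (any(distal_off > 9000)) stop("too many distal enhancers per gene slot")
  prox_gene <- seq_len(min(cfg$n_proximal, cfg$n_genes))
  if (cfg$n_proximal > cfg$n_genes) stop("at most one proximal enhancer per gene")
  enh_df <- rbind(
    cbind(element_at(genes, distal_gene, distal_off, cfg$enh_width),
          subclass = "distal"),
    cbind(element_at(genes, prox_gene, 1500, cfg$enh_width),
          subclass = "proximal"))
  enh_df$id <- sprintf("enh%04d", seq_len(nrow(enh_df)))

  prom_mid <- genes$tss
  prom_df <- data.frame(chrom = genes$chrom,
                        start = prom_mid - cfg$prom_width / 2,
                        end = prom_mid + cfg$prom_width / 2,
                        gene_id = genes$gene_id,
                        id = sprintf("prom%04d", seq_len(cfg$n_genes)),
                        stringsAsFactors = FALSE)

  # decoy candidate enhancers: inside gene bodies / on blacklist intervals
  plus_slots <- which(genes$strand == "+")
  dec_cod_slots <- plus_slots[seq_len(min(cfg$n_decoy_coding, length(plus_slots)))]
  decoy_coding <- data.frame(chrom = genes$chrom[dec_cod_slots],
                             start = genes$slot_start[dec_cod_slots] + 13000,
                             end = genes$slot_start[dec_cod_slots] + 13000 + cfg$enh_width,
                             stringsAsFactors = FALSE)
  dec_bl_slots <- plus_slots[length(plus_slots) + 1 -
                               seq_len(min(cfg$n_decoy_blacklist, length(plus_slots)))]
  decoy_bl <- data.frame(chrom = genes$chrom[dec_bl_slots],
                         start = genes$slot_start[dec_bl_slots] + 18000,
                         end = genes$slot_start[dec_bl_slots] + 18000 + cfg$enh_width,
                         stringsAsFactors = FALSE)
  blacklist <- bed_to_gr(decoy_bl$chrom, decoy_bl$start - 100, decoy_bl$end + 100)
  decoys <- rbind(decoy_coding, decoy_bl)
  decoys$id <- sprintf("dec%04d", seq_len(nrow(decoys)))
  decoy_reason <- c(rep("coding_overlap", nrow(decoy_coding)),
                    rep("blacklist", nrow(decoy_bl)))

  enhancers <- bed_to_gr(c(enh_df$chrom, decoys$chrom),
                         c(enh_df$start, decoys$start),
                         c(enh_df$end, decoys$end),
                         id = c(enh_df$id, decoys$id))
  promoters <- bed_to_gr(prom_df$chrom, prom_df$start, prom_df$end,
                         id = prom_df$id)
  S4Vectors::mcols(promoters)$gene_id <- prom_df$gene_id

  el_df <- rbind(
    data.frame(id = enh_df$id, chrom = enh_df$chrom, start = enh_df$start,
               end = enh_df$end, element_class = "enhancer",
               subclass = enh_df$subclass, gene_id = enh_df$gene_id,
               stringsAsFactors = FALSE),
    data.frame(id = prom_df$id, chrom = prom_df$chrom, start = prom_df$start,
               end = prom_df$end, element_class = "promoter",
               subclass = "not_applicable", gene_id = prom_df$gene_id,
               stringsAsFactors = FALSE))
  ne <- nrow(el_df)
  group <- ifelse(el_df$element_class == "promoter", "promoter", el_df$subclass)

  # --- planted states and RNA counts ------------------------------------
  st_atac <- plant_state_triples(ne)
  st_k27 <- plant_state_triples(ne)
  silent <- runif(ne) < cfg$frac_silent

  prof <- function(assay) t(vapply(group, function(g) cfg$class_profiles[[g]][[assay]],
                                   numeric(3)))
  counts <- list()
  counts$RNA <- matrix(0L, ne, 3)
  pr <- prof("RNA")
  for (t in 1:3) {
    mu <- cfg$baseline_rate * pr[, t]
    counts$RNA[, t] <- ifelse(silent, 0L, nb_counts(ne, mu, cfg$dispersion))
  }
  for (assay in c("ATAC", "H3K27ac")) {
    pa <- prof(assay)
    st <- if (assay == "ATAC") st_atac else st_k27
    m <- matrix(0L, ne, 3)
    for (t in 1:3) {
      mu <- cfg$baseline_rate * pa[, t] * ifelse(st[, t], 1, 0.05)
      m[, t] <- nb_counts(ne, mu, cfg$dispersion)
    }
    counts[[assay]] <- m
  }

  # --- coordinated pairs: override enhancer RNA counts, set gene TPM ----
  n_pair <- cfg$n_coordinated_pairs
  distal_ids <- which(el_df$subclass == "distal")
  if (n_pair + cfg$n_distractor_pairs > length(distal_ids)) {
    stop("not enough distal enhancers for the requested pairs")
  }
  pair_enh_idx <- distal_ids[seq_len(n_pair)]
  pair_gene <- el_df$gene_id[pair_enh_idx]
  pair_dir <- rep(c("down", "up"), length.out = n_pair)
  shape <- list(down = c(2.2, 1.3, 0.6), up = c(0.6, 1.3, 2.2))
  gene_expr <- matrix(rlnorm(cfg$n_genes * 3, log(50), 0.2),
                      cfg$n_genes, 3,
                      dimnames = list(genes$gene_id, paste0("tpm_", tp)))
  # flat genes must not form monotone triples by chance: pin the middle
  gene_expr[, 2] <- pmax(gene_expr[, 1], gene_expr[, 3]) * 1.05
  for (i in seq_len(n_pair)) {
    noise <- exp(rnorm(3, 0, cfg$pair_noise_sd))
    counts$RNA[pair_enh_idx[i], ] <-
      pmax(1, round(cfg$baseline_rate * shape[[pair_dir[i]]] * noise))
    silent[pair_enh_idx[i]] <- FALSE
    gnoise <- exp(rnorm(3, 0, cfg$pair_noise_sd))
    gene_expr[pair_gene[i], ] <- 50 * shape[[pair_dir[i]]] * gnoise
  }
  # distractor pairs: loop-connected but with non-monotone gene expression
  n_dis <- cfg$n_distractor_pairs
  dis_enh_idx <- distal_ids[n_pair + seq_len(n_dis)]
  dis_gene <- el_df$gene_id[dis_enh_idx]

  truth_pairs <- data.frame(enhancer_id = el_df$id[pair_enh_idx],
                            gene_id = pair_gene, direction = pair_dir,
                            stringsAsFactors = FALSE)

  # --- fragments ---------------------------------------------------------
  frag_len <- 50
  frags <- list()
  for (assay in c("RNA", "ATAC", "H3K27ac")) {
    for (t in 1:3) {
      cnt <- counts[[assay]][, t]
      tot <- sum(cnt)
      if (tot > 0) {
        idx <- rep.int(seq_len(ne), cnt)
        u <- runif(tot)
        fs <- el_df$start[idx] + floor(u * (el_df$end[idx] - el_df$start[idx] - frag_len))
        gr <- bed_to_gr(el_df$chrom[idx], fs, fs + frag_len)
      } else {
        gr <- GenomicRanges::GRanges()
      }
      lab <- paste0(assay, "_", tp[t])
      # each library's total mapped fragments is dominated by genome-wide
      # background outside the catalog, so the per-million denominator is a
      # fixed library size rather than the element-restricted count
      frags[[lab]] <- fragment_set(gr, max(cfg$library_size, tot),
                                   assay = assay, timepoint = tp[t],
                                   label = lab)
    }
  }

  # --- peaks from planted states (boundary jitter only) ------------------
  peaks <- list()
  for (assay in c("ATAC", "H3K27ac")) {
    st <- if (assay == "ATAC") st_atac else st_k27
    for (t in 1:3) {
      on <- which(st[, t])
      w <- el_df$end[on] - el_df$start[on]
      j <- floor(cfg$jitter_frac * w)
      ps <- el_df$start[on] + floor(runif(length(on), -1, 1) * j)
      pe <- el_df$end[on] + floor(runif(length(on), -1, 1) * j)
      keep <- pe > ps
      peaks[[paste0(assay, "_", tp[t])]] <-
        peak_set(bed_to_gr(el_df$chrom[on][keep], pmax(0, ps[keep]), pe[keep]),
                 assay = assay, timepoint = tp[t])
    }
  }

  # --- p53 peaks ---------------------------------------------------------
  p53_idx <- sort(sample(ne, round(cfg$p53_bound_frac * ne)))
  p53_peaks <- peak_set(bed_to_gr(el_df$chrom[p53_idx],
                                  pmax(0, el_df$start[p53_idx] - 50),
                                  el_df$end[p53_idx] + 50),
                        assay = "p53", timepoint = "static")

  # --- footprints --------------------------------------------------------
  base_names <- sprintf("TF%02d", seq_len(cfg$n_tf))
  n_cx <- min(3, cfg$n_tf %/% 10)
  if (n_cx > 0) {
    cx <- seq_len(n_cx)
    base_names[cx] <- paste0(base_names[cx], "::", sprintf("CX%02d", cx))
  }
  hi_var <- base_names[seq_len(cfg$n_hi_var_tf)]
  fp_rows <- list()
  for (ti in seq_along(base_names)) {
    tf <- base_names[ti]
    hi <- tf %in% hi_var
    means <- if (hi) c(5, 15, 25) + runif(1, -1, 1) else rep(10 + runif(1, -1, 1), 3)
    for (t in 1:3) {
      k <- 5
      host <- sample(ne, k, replace = TRUE)
      fp_s <- el_df$start[host] + 10
      prot <- rnorm(k, means[t], 0.3)
      tc <- pmax(0, round(rnorm(k, means[t] * 10, 3)))
      fp_rows[[length(fp_rows) + 1]] <- data.frame(
        tf_name = tf, chrom = el_df$chrom[host], start = fp_s, end = fp_s + 20,
        protection_score = prot, tag_count = tc, timepoint = tp[t],
        stringsAsFactors = FALSE)
    }
  }
  footprints <- do.call(rbind, fp_rows)

  # --- DE tables ---------------------------------------------------------
  bg <- setdiff(genes$gene_id, c(pair_gene, dis_gene))
  n_bg_up <- min(40, floor(length(bg) / 2))
  n_bg_down <- min(20, floor(length(bg) / 4))
  up_genes <- sort(unique(c(pair_gene[pair_dir == "up"], bg[seq_len(n_bg_up)])))
  down_genes <- sort(unique(c(pair_gene[pair_dir == "down"],
                              bg[n_bg_up + seq_len(n_bg_down)])))
  de_tab <- function(jit) {
    lfc <- rnorm(cfg$n_genes, 0, 0.3)
    fdr <- runif(cfg$n_genes, 0.1, 1)
    iu <- match(up_genes, genes$gene_id)
    idn <- match(down_genes, genes$gene_id)
    lfc[iu] <- rnorm(length(iu), 2.5, 0.4) + jit
    lfc[idn] <- rnorm(length(idn), -2.5, 0.4) - jit
    fdr[c(iu, idn)] <- runif(length(iu) + length(idn), 1e-8, 1e-3)
    data.frame(gene_id = genes$gene_id, log2fc = lfc, fdr = fdr,
               stringsAsFactors = FALSE)
  }
  de <- list(`8h_vs_0h` = de_tab(0), `16h_vs_0h` = de_tab(0.2))

  # --- loops -------------------------------------------------------------
  loop_enh <- c(pair_enh_idx, dis_enh_idx)
  loop_gene <- c(pair_gene, dis_gene)
  pi <- match(loop_gene, prom_df$gene_id)
  loops_df <- data.frame(chrom1 = el_df$chrom[loop_enh],
                         start1 = el_df$start[loop_enh] - 100,
                         end1 = el_df$end[loop_enh] + 100,
                         chrom2 = prom_df$chrom[pi],
                         start2 = prom_df$start[pi],
                         end2 = prom_df$end[pi],
                         stringsAsFactors = FALSE)
  loops <- list(anchor1 = bed_to_gr(loops_df$chrom1, loops_df$start1, loops_df$end1),
                anchor2 = bed_to_gr(loops_df$chrom2, loops_df$start2, loops_df$end2))

  # --- truth ledger ------------------------------------------------------
  truth_elements <- data.frame(
    id = el_df$id, element_class = el_df$element_class,
    subclass = el_df$subclass, gene_id = el_df$gene_id,
    rna_category = expression_trajectory(counts$RNA),
    atac_category = trajectory_category(st_atac),
    k27_category = trajectory_category(st_k27),
    p53_bound = seq_len(ne) %in% p53_idx,
    stringsAsFactors = FALSE)
  truth <- list(elements = truth_elements,
                pairs = truth_pairs,
                hi_var_tfs = sort(hi_var),
                p53_bound = el_df$id[p53_idx],
                removed_enhancers = data.frame(id = decoys$id,
                                               reason = decoy_reason,
                                               stringsAsFactors = FALSE),
                de_up = sort(up_genes), de_down = sort(down_genes),
                counts = counts)

  bundle <- list(config = cfg, chrom_sizes = cfg$chrom_sizes,
                 genes = genes[c("gene_id", "chrom", "start", "end", "strand", "tss")],
                 enhancers = enhancers, promoters = promoters,
                 blacklist = blacklist, fragments = frags, peaks = peaks,
                 p53_peaks = p53_peaks, footprints = footprints, de = de,
                 gene_expr = gene_expr, loops = loops, loops_df = loops_df,
                 truth = truth)
  class(bundle) <- c("credyn_bundle", "list")
  if (!is.null(out_dir)) bundle$files <- write_bundle(bundle, out_dir)
  bundle
}

#' Write a bundle to disk in the formats the pipeline readers accept
#'
#' @param bundle bundle from [generate_bundle()].
#' @param out_dir output directory (created if needed).
#' @return named list of file paths.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  files <- list()
  tsv <- function(df, path, col.names = TRUE) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = col.names)
    path
  }
  files$genes <- tsv(bundle$genes[c("gene_id", "chrom", "start", "end", "strand")],
                     p("genes.tsv"))
  files$enhancers <- write_bed(bundle$enhancers, p("enhancers.bed"))
  files$promoters <- write_bed(bundle$promoters, p("promoters.bed"))
  files$blacklist <- write_bed(bundle$blacklist, p("blacklist.bed"))
  files$chrom_sizes <- tsv(data.frame(chrom = names(bundle$chrom_sizes),
                                      size = as.numeric(bundle$chrom_sizes)),
                           p("chrom_sizes.tsv"))
  man <- list()
  for (lab in names(bundle$fragments)) {
    fs <- bundle$fragments[[lab]]
    fpath <- p(paste0("frags_", lab, ".bed"))
    write_bed(fs$fragments, fpath)
    man[[lab]] <- data.frame(sample = lab, assay = fs$assay,
                             timepoint = fs$timepoint,
                             path = basename(fpath),
                             total_count = fs$total_count,
                             stringsAsFactors = FALSE)
  }
  files$manifest <- tsv(do.call(rbind, man), p("fragments_manifest.tsv"))
  for (lab in names(bundle$peaks)) {
    files[[paste0("peaks_", lab)]] <-
      write_bed(bundle$peaks[[lab]]$peaks, p(paste0("peaks_", lab, ".bed")))
  }
  files$p53 <- write_bed(bundle$p53_peaks$peaks, p("p53_peaks.bed"))
  files$footprints <- tsv(bundle$footprints, p("footprints.tsv"))
  files$de_8v0 <- tsv(bundle$de[["8h_vs_0h"]], p("de_8h_vs_0h.tsv"))
  files$de_16v0 <- tsv(bundle$de[["16h_vs_0h"]], p("de_16h_vs_0h.tsv"))
  files$gene_expr <- tsv(data.frame(gene_id = rownames(bundle$gene_expr),
                                    bundle$gene_expr), p("gene_expr.tsv"))
  files$loops <- tsv(bundle$loops_df, p("loops.bedpe"), col.names = FALSE)
  files$truth_elements <- tsv(bundle$truth$elements, p("truth_elements.tsv"))
  files$truth_pairs <- tsv(bundle$truth$pairs, p("truth_pairs.tsv"))
  files$truth_tfs <- tsv(data.frame(tf_name = bundle$truth$hi_var_tfs),
                         p("truth_tfs.tsv"))
  files
}

#' Recovery metrics of pipeline outputs against the planted truth
#'
#' @param truth truth ledger from a bundle (`bundle$truth`).
#' @param outputs list with any of: `trajectories` (data.frame element_id,
#'   assay, category), `pairs` (enhancer_id, gene_id, direction), `top_tfs`
#'   (character), `p53_partition` (list from [partition_by_p53()]).
#' @return data.frame: stage, metric, value.
#' @export
truth_report <- function(truth, outputs) {
  rows <- list()
  add <- function(stage, metric, value) {
    rows[[length(rows) + 1]] <<- data.frame(stage = stage, metric = metric,
                                            value = value,
                                            stringsAsFactors = FALSE)
  }
  if (!is.null(outputs$trajectories)) {
    tr <- outputs$trajectories
    bad <- setdiff(tr$element_id, truth$elements$id)
    if (length(bad)) {
      stop("trajectory ids not in truth: ", paste(head(bad, 5), collapse = ", "))
    }
    key <- c(RNA = "rna_category", ATAC = "atac_category",
             H3K27ac = "k27_category")
    for (assay in unique(tr$assay)) {
      sub <- tr[tr$assay == assay, ]
      want <- truth$elements[[key[[assay]]]][match(sub$element_id, truth$elements$id)]
      add("trajectory", paste0(assay, "_recovery"), mean(sub$category == want))
    }
  }
  if (!is.null(outputs$pairs)) {
    got <- paste(outputs$pairs$enhancer_id, outputs$pairs$gene_id,
                 outputs$pairs$direction)
    want <- paste(truth$pairs$enhancer_id, truth$pairs$gene_id,
                  truth$pairs$direction)
    prec <- if (length(got)) mean(got %in% want) else NA_real_
    rec <- if (length(want)) mean(want %in% got) else NA_real_
    add("pairs", "precision", prec)
    add("pairs", "recall", rec)
  }
  if (!is.null(outputs$top_tfs)) {
    add("tfdyn", "top_tf_recall",
        mean(truth$hi_var_tfs %in% outputs$top_tfs))
  }
  if (!is.null(outputs$p53_partition)) {
    pp <- outputs$p53_partition
    got_bound <- c(pp$p53BER, pp$p53BPR)
    all_ids <- truth$elements$id
    bad <- setdiff(c(got_bound, pp$p53FER, pp$p53FPR), all_ids)
    if (length(bad)) {
      stop("p53 partition ids not in truth: ", paste(head(bad, 5), collapse = ", "))
    }
    want_bound <- truth$elements$id[truth$elements$p53_bound]
    acc <- mean(all_ids %in% got_bound == all_ids %in% want_bound)
    add("p53", "partition_accuracy", acc)
  }
  do.call(rbind, rows)
}
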