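#' Stage orchestration: curate, quantify, states, pairs, tfdyn, compare,
#' simulate, report
#'
#' Each stage reads its inputs (files named in the run configuration, or the
#' outputs of the `simulate` stage when no explicit paths are given), writes
#' its module's TSV outputs plus a machine-readable `manifest.json` (inputs,
#' parameter values, seed, row counts) under `<out_dir>/<stage>/`, and is
#' idempotent: rerunning with identical inputs reproduces identical outputs.
#'
#' @name pipeline
NULL

pipeline_defaults <- function() {
  list(pad = 1000, lfc_min = 1, fdr_max = 0.05, top_n = 30, eps = 0,
       activity_metric = "combined", flank = 1000, bin = 50, smooth = 60,
       n_random_regions = 1000, random_region_length = 2000,
       timepoints = c("0h", "8h", "16h"))
}

#' Read a run configuration (YAML)
#'
#' Recognised keys: `seed`, `out_dir`, `inputs` (named file paths, resolved
#' relative to the config file), `params` (threshold overrides) and `synth`
#' (overrides for [synth_config()]).
#'
#' @param path YAML file path.
#' @return run-config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  if (!is.null(cfg$inputs)) {
    cfg$inputs <- lapply(cfg$inputs, function(p) {
      if (file.exists(p)) p else file.path(base, p)
    })
  }
  run_config(seed = cfg$seed %||% 1, out_dir = cfg$out_dir %||% "credyn_out",
             inputs = cfg$inputs, params = cfg$params, synth = cfg$synth)
}

#' Build a run configuration in code
#'
#' @param seed integer seed for all seeded stages.
#' @param out_dir output directory.
#' @param inputs named list of input file paths; when NULL, stages fall back
#'   to the outputs of the `simulate` stage under `out_dir`.
#' @param params named list overriding [pipeline_defaults()].
#' @param synth named list of [synth_config()] overrides for `simulate`.
#' @return run-config list of class `credyn_run_config`.
#' @export
run_config <- function(seed = 1, out_dir = "credyn_out", inputs = NULL,
                       params = NULL, synth = NULL) {
  p <- pipeline_defaults()
  for (k in names(params)) p[[k]] <- params[[k]]
  structure(list(seed = seed, out_dir = out_dir, inputs = inputs,
                 params = p, synth = synth),
            class = c("credyn_run_config", "list"))
}

stage_dir <- function(config, stage) file.path(config$out_dir, stage)

need_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact %s: run stage '%s' first", path, stage))
  }
  path
}

# Resolve an input path: explicit config entry, else the simulate output.
input_path <- function(config, key, default_file) {
  p <- config$inputs[[key]]
  if (!is.null(p)) {
    if (!file.exists(p)) stop(sprintf("input '%s' not found: %s", key, p))
    return(p)
  }
  need_artifact(file.path(config$out_dir, "simulate", default_file), "simulate")
}

write_manifest <- function(dir, stage, config, inputs, outputs) {
  counts <- lapply(outputs, function(p) {
    if (file.exists(p)) length(readLines(p)) else NA_integer_
  })
  # record paths relative to the run directory so identical runs in
  # different locations yield byte-identical manifests
  rel <- function(paths) lapply(paths, function(p) {
    file.path(stage, basename(as.character(p)))
  })
  man <- list(stage = stage, seed = config$seed, params = config$params,
              inputs = lapply(inputs, function(p) basename(as.character(p))),
              outputs = rel(outputs), row_counts = counts,
              package_version = as.character(utils::packageVersion("credyn")))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

tsv_out <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write a synthetic bundle), `curate` (element catalog),
#' `quantify` (per-element RPM per assay/timepoint), `states` (trajectory
#' table and random-region controls), `pairs` (target assignment, consistent
#' DE genes, coordinated pairs), `tfdyn` (TF activity ranking and p53
#' partition), `compare` (Friedman trend tests per element group and KS
#' comparisons between p53 classes), `report` (recovery metrics against the
#' simulated truth).
#'
#' @param stage stage name.
#' @param config run-config from [run_config()] or [read_run_config()].
#' @return invisibly, a named list of written file paths.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, c("simulate", "curate", "quantify", "states",
                              "pairs", "tfdyn", "compare", "report"))
  dir <- stage_dir(config, stage)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- get(paste0("stage_", stage), envir = asNamespace("credyn"))
  out <- fn(config, dir)
  invisible(out)
}

stage_simulate <- function(config, dir) {
  args <- c(list(seed = config$seed), config$synth)
  cfg <- do.call(synth_config, args)
  bundle <- generate_bundle(cfg, out_dir = dir)
  write_manifest(dir, "simulate", config, inputs = list(),
                 outputs = lapply(bundle$files, as.character))
  bundle$files
}

load_catalog_inputs <- function(config) {
  list(genes = read_genes(input_path(config, "genes", "genes.tsv")),
       enhancers = read_bed(input_path(config, "enhancers", "enhancers.bed")),
       promoters = read_bed(input_path(config, "promoters", "promoters.bed")),
       blacklist = read_bed(input_path(config, "blacklist", "blacklist.bed")))
}

stage_curate <- function(config, dir) {
  inp <- load_catalog_inputs(config)
  cat_df <- build_catalog(inp$enhancers, inp$promoters, inp$genes,
                          inp$blacklist, pad = config$params$pad,
                          provenance = "credyn curate stage")
  out <- list(catalog = tsv_out(as.data.frame(cat_df), file.path(dir, "catalog.tsv")))
  write_manifest(dir, "curate", config,
                 inputs = list(genes = input_path(config, "genes", "genes.tsv")),
                 outputs = out)
  out
}

pipeline_catalog <- function(config) {
  read_catalog(need_artifact(file.path(config$out_dir, "curate", "catalog.tsv"),
                             "curate"))
}

pipeline_elements <- function(config) {
  cat_df <- pipeline_catalog(config)
  catalog_gr(cat_df)
}

stage_quantify <- function(config, dir) {
  elements <- pipeline_elements(config)
  man_path <- input_path(config, "manifest", "fragments_manifest.tsv")
  frags <- read_fragment_manifest(man_path)
  tps <- config$params$timepoints
  out <- list()
  for (assay in unique(vapply(frags, `[[`, "", "assay"))) {
    cols <- lapply(tps, function(t) {
      fs <- Filter(function(f) f$assay == assay && f$timepoint == t, frags)
      if (length(fs) == 0) stop(sprintf("no %s fragments at %s in manifest", assay, t))
      region_rpm(fs[[1]], elements)
    })
    df <- data.frame(id = names(elements), stringsAsFactors = FALSE)
    for (i in seq_along(tps)) df[[paste0("rpm_", tps[i])]] <- cols[[i]]
    if (assay == "RNA") df$expressed <- expressed_flag(df[[paste0("rpm_", tps[1])]])
    out[[assay]] <- tsv_out(df, file.path(dir, paste0("rpm_", assay, ".tsv")))
  }
  write_manifest(dir, "quantify", config, inputs = list(manifest = man_path),
                 outputs = out)
  out
}

read_rpm_table <- function(config, assay) {
  path <- need_artifact(file.path(config$out_dir, "quantify",
                                  paste0("rpm_", assay, ".tsv")), "quantify")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

stage_states <- function(config, dir) {
  elements <- pipeline_elements(config)
  tps <- config$params$timepoints
  traj <- list()
  for (assay in c("ATAC", "H3K27ac")) {
    pk <- lapply(tps, function(t) {
      key <- paste0("peaks_", assay, "_", t)
      read_bed(input_path(config, key, paste0("peaks_", assay, "_", t, ".bed")))
    })
    traj[[assay]] <- state_trajectories(elements, pk, assay = assay)
  }
  rna <- read_rpm_table(config, "RNA")
  rpm_mat <- as.matrix(rna[paste0("rpm_", tps)])
  traj$RNA <- data.frame(element_id = rna$id, assay = "RNA",
                         state_0h = rpm_mat[, 1] > 0,
                         state_8h = rpm_mat[, 2] > 0,
                         state_16h = rpm_mat[, 3] > 0,
                         category = expression_trajectory(rpm_mat),
                         stringsAsFactors = FALSE)
  traj_df <- do.call(rbind, traj)
  rownames(traj_df) <- NULL
  cs <- read.table(input_path(config, "chrom_sizes", "chrom_sizes.tsv"),
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  sizes <- setNames(cs$size, cs$chrom)
  rr <- random_regions(sizes, n = config$params$n_random_regions,
                       length = config$params$random_region_length,
                       seed = config$seed)
  atac0 <- read_bed(input_path(config, "peaks_ATAC_0h", "peaks_ATAC_0h.bed"))
  rar <- suppressWarnings(
    random_accessible_regions(atac0, elements,
                              n = config$params$n_random_regions,
                              seed = config$seed))
  out <- list(trajectories = tsv_out(traj_df, file.path(dir, "trajectories.tsv")),
              random_regions = write_bed(rr, file.path(dir, "random_regions.bed")),
              random_accessible = write_bed(rar, file.path(dir, "random_accessible_regions.bed")))
  write_manifest(dir, "states", config, inputs = list(), outputs = out)
  out
}

stage_pairs <- function(config, dir) {
  cat_df <- pipeline_catalog(config)
  enh <- catalog_gr(cat_df, classes = "enhancer")
  prom <- catalog_gr(cat_df, classes = "promoter")
  kept <- cat_df[is.na(cat_df$removal_reason) & cat_df$element_class == "promoter", ]
  S4Vectors::mcols(prom)$gene_id <- kept$nearest_gene[match(names(prom), kept$id)]
  genes <- read_genes(input_path(config, "genes", "genes.tsv"))
  cs <- read.table(input_path(config, "chrom_sizes", "chrom_sizes.tsv"),
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  domains <- build_domains(genes, chrom_sizes = setNames(cs$size, cs$chrom))
  dom_pairs <- assign_by_domain(enh, domains)
  loops <- read_loops(input_path(config, "loops", "loops.bedpe"))
  loop_pairs <- assign_by_loops(enh, prom, loops)
  all_pairs <- merge_pair_evidence(dom_pairs, loop_pairs)

  de8 <- read_de_table(input_path(config, "de_8v0", "de_8h_vs_0h.tsv"), "8h_vs_0h")
  de16 <- read_de_table(input_path(config, "de_16v0", "de_16h_vs_0h.tsv"), "16h_vs_0h")
  de_cons <- consistent_de_genes(de8, de16, lfc_min = config$params$lfc_min,
                                 fdr_max = config$params$fdr_max)
  de_df <- rbind(
    data.frame(gene_id = de_cons$up, direction = "up", stringsAsFactors = FALSE),
    data.frame(gene_id = de_cons$down, direction = "down", stringsAsFactors = FALSE))

  rna <- read_rpm_table(config, "RNA")
  tps <- config$params$timepoints
  enh_rpm <- as.matrix(rna[paste0("rpm_", tps)])
  rownames(enh_rpm) <- rna$id
  ge <- read.table(input_path(config, "gene_expr", "gene_expr.tsv"),
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  gene_expr <- as.matrix(ge[, -1, drop = FALSE])
  rownames(gene_expr) <- ge$gene_id
  coord <- coordinated_pairs(all_pairs, enh_rpm, gene_expr,
                             eps = config$params$eps)
  out <- list(pairs = tsv_out(all_pairs, file.path(dir, "pairs.tsv")),
              coordinated = tsv_out(coord, file.path(dir, "coordinated_pairs.tsv")),
              de_genes = tsv_out(de_df, file.path(dir, "consistent_de_genes.tsv")))
  write_manifest(dir, "pairs", config, inputs = list(), outputs = out)
  out
}

stage_tfdyn <- function(config, dir) {
  elements <- pipeline_elements(config)
  fp <- read_footprints(input_path(config, "footprints", "footprints.tsv"))
  inside <- footprints_in_elements(fp, elements)
  act <- build_activity_table(inside$subset,
                              metric = config$params$activity_metric,
                              timepoints = config$params$timepoints)
  ranked <- rank_by_sd(act, top_n = config$params$top_n)
  sds <- apply(act, 1, sd)
  ranked_df <- data.frame(rank = seq_along(ranked), tf_name = ranked,
                          activity_sd = as.numeric(sds[ranked]),
                          stringsAsFactors = FALSE)
  # per-class top lists and their intersection
  enh_fp <- footprints_in_elements(fp, elements[S4Vectors::mcols(elements)$element_class == "enhancer"])
  prom_fp <- footprints_in_elements(fp, elements[S4Vectors::mcols(elements)$element_class == "promoter"])
  tops <- lapply(list(enh = enh_fp, prom = prom_fp), function(sub) {
    if (nrow(sub$subset) == 0) return(character(0))
    rank_by_sd(build_activity_table(sub$subset,
                                    metric = config$params$activity_metric,
                                    timepoints = config$params$timepoints),
               top_n = config$params$top_n)
  })
  shared <- top_overlap(tops$enh, tops$prom)
  p53 <- read_bed(input_path(config, "p53_peaks", "p53_peaks.bed"))
  part <- partition_by_p53(elements, peak_set(p53, assay = "p53", timepoint = "static"))
  part_df <- do.call(rbind, lapply(names(part), function(k) {
    if (!length(part[[k]])) return(NULL)
    data.frame(element_id = part[[k]], p53_class = k, stringsAsFactors = FALSE)
  }))
  out <- list(ranked = tsv_out(ranked_df, file.path(dir, "ranked_tfs.tsv")),
              shared = tsv_out(data.frame(tf_name = shared$shared),
                               file.path(dir, "shared_top_tfs.tsv")),
              partition = tsv_out(part_df, file.path(dir, "p53_partition.tsv")))
  write_manifest(dir, "tfdyn", config, inputs = list(), outputs = out)
  out
}

stage_compare <- function(config, dir) {
  cat_df <- pipeline_catalog(config)
  tps <- config$params$timepoints
  rpm_cols <- paste0("rpm_", tps)
  kept <- cat_df[is.na(cat_df$removal_reason), ]
  grp <- ifelse(kept$element_class == "promoter", "promoter", kept$subclass)
  trend <- list()
  comparisons <- list()
  for (assay in c("RNA", "ATAC", "H3K27ac")) {
    rpm <- tryCatch(read_rpm_table(config, assay), error = function(e) NULL)
    if (is.null(rpm)) next
    m <- as.matrix(rpm[rpm_cols])
    rownames(m) <- rpm$id
    for (g in c("distal", "proximal", "promoter")) {
      ids <- kept$id[grp == g]
      sub <- m[rownames(m) %in% ids, , drop = FALSE]
      if (nrow(sub) < 2) next
      ft <- friedman(sub)
      mean_tp <- colMeans(sub)
      trend[[paste(assay, g)]] <- data.frame(
        assay = assay, group = g, n = nrow(sub),
        mean_0h = mean_tp[1], mean_8h = mean_tp[2], mean_16h = mean_tp[3],
        statistic = ft$statistic, p_value = ft$p_value, method = ft$method,
        stars = ft$stars, stringsAsFactors = FALSE)
    }
    # p53-bound vs p53-free distributions per class and timepoint
    part_path <- file.path(config$out_dir, "tfdyn", "p53_partition.tsv")
    if (file.exists(part_path)) {
      part <- read.table(part_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
      for (pair in list(c("p53BER", "p53FER"), c("p53BPR", "p53FPR"))) {
        a <- part$element_id[part$p53_class == pair[1]]
        b <- part$element_id[part$p53_class == pair[2]]
        for (i in seq_along(tps)) {
          vals <- setNames(m[, i], rownames(m))
          if (!length(intersect(a, names(vals))) ||
              !length(intersect(b, names(vals)))) next
          ks <- group_signal_compare(a, b, vals)
          comparisons[[paste(assay, pair[1], tps[i])]] <- data.frame(
            group_a = pair[1], group_b = pair[2], assay = assay,
            timepoint = tps[i], D = ks$statistic, p = ks$p_value,
            stars = ks$stars, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- list(trend = tsv_out(do.call(rbind, trend), file.path(dir, "trend_tests.tsv")),
              comparisons = tsv_out(do.call(rbind, comparisons),
                                    file.path(dir, "p53_comparisons.tsv")))
  write_manifest(dir, "compare", config, inputs = list(), outputs = out)
  out
}

stage_report <- function(config, dir) {
  truth_el_path <- need_artifact(file.path(config$out_dir, "simulate",
                                           "truth_elements.tsv"), "simulate")
  truth_elements <- read.table(truth_el_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  truth_pairs <- read.table(file.path(config$out_dir, "simulate", "truth_pairs.tsv"),
                            header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  truth_tfs <- read.table(file.path(config$out_dir, "simulate", "truth_tfs.tsv"),
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  truth <- list(elements = truth_elements, pairs = truth_pairs,
                hi_var_tfs = truth_tfs$tf_name)
  traj <- read.table(need_artifact(file.path(config$out_dir, "states",
                                             "trajectories.tsv"), "states"),
                     header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  coord <- read.table(need_artifact(file.path(config$out_dir, "pairs",
                                              "coordinated_pairs.tsv"), "pairs"),
                      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  # recovery scores loop-anchored pairs: the truth ledger plants pair
  # identity through loops, while domain-only pairs may co-vary with
  # class-wide profiles by design
  coord <- coord[coord$evidence %in% c("loop", "both"), , drop = FALSE]
  ranked <- read.table(need_artifact(file.path(config$out_dir, "tfdyn",
                                               "ranked_tfs.tsv"), "tfdyn"),
                       header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  part_tab <- read.table(file.path(config$out_dir, "tfdyn", "p53_partition.tsv"),
                         header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  part <- split(part_tab$element_id, factor(part_tab$p53_class,
                                            c("p53BER", "p53FER", "p53BPR", "p53FPR")))
  rep_df <- truth_report(truth, list(
    trajectories = traj, pairs = coord,
    top_tfs = head(ranked$tf_name, length(truth$hi_var_tfs)),
    p53_partition = part))
  out <- list(recovery = tsv_out(rep_df, file.path(dir, "recovery.tsv")))
  write_manifest(dir, "report", config, inputs = list(), outputs = out)
  out
}

#' Run the full pipeline end to end
#'
#' Convenience wrapper running `simulate` (when no explicit inputs are
#' configured) followed by curate, quantify, states, pairs, tfdyn, compare
#' and report.
#'
#' @param config run-config.
#' @return invisibly, list of per-stage output paths.
#' @export
run_pipeline <- function(config) {
  stages <- c("curate", "quantify", "states", "pairs", "tfdyn", "compare")
  res <- list()
  if (is.null(config$inputs)) {
    res$simulate <- run_stage("simulate", config)
    stages <- c(stages, "report")
  }
  for (s in stages) res[[s]] <- run_stage(s, config)
  invisible(res)
}
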