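# Brute-force oracles, independent of the GRanges-backed implementation.
# All coordinates here are 0-based half-open data.frames (chrom, start, end).

# per-base overlap: do intervals a and b share >= 1 base?
bf_pair_overlaps <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  ab <- seq(a$start, a$end - 1)
  bb <- seq(b$start, b$end - 1)
  any(ab %in% bb)
}

# for each row of `query`, TRUE iff it overlaps any row of `subject`
bf_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(vapply(seq_len(nrow(subject)), function(j) {
      bf_pair_overlaps(query[i, ], subject[j, ])
    }, logical(1)))
  }, logical(1))
}

rand_intervals <- function(n, chroms = c("cA", "cB"), max_pos = 400,
                           max_len = 60) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

df_to_gr <- function(df, id = NULL) {
  bed_to_gr(df$chrom, df$start, df$end, id = id)
}

# Exhaustive Friedman permutation oracle: p over all (k!)^n within-row
# value permutations, statistic recomputed from scratch for every one.
bf_all_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- bf_all_perms(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1)))
  }
  out
}

bf_friedman_q <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  r <- t(apply(mat, 1, rank))
  ties <- sum(unlist(apply(mat, 1, function(v) {
    tt <- table(v)
    sum(tt^3 - tt)
  })))
  C <- 1 - ties / (n * k * (k^2 - 1))
  if (C <= 0) return(0)
  Rj <- colSums(r)
  ((12 / (n * k * (k + 1))) * sum(Rj^2) - 3 * n * (k + 1)) / C
}

bf_friedman_exact_p <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  perms <- bf_all_perms(k)
  q_obs <- bf_friedman_q(mat)
  idx <- rep(list(seq_len(nrow(perms))), n)
  grid <- expand.grid(idx)
  qs <- apply(grid, 1, function(g) {
    permuted <- t(vapply(seq_len(n), function(i) mat[i, perms[g[i], ]],
                         numeric(k)))
    bf_friedman_q(permuted)
  })
  mean(qs >= q_obs - 1e-9)
}

bf_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# Exhaustive two-sample KS p: every C(m+n, n) assignment of the pooled
# values to the two samples.
bf_ks_exact_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  d_obs <- bf_ks_d(x, y)
  picks <- combn(length(pooled), m)
  ds <- apply(picks, 2, function(ix) bf_ks_d(pooled[ix], pooled[-ix]))
  mean(ds >= d_obs - 1e-12)
}

# tiny fast synthetic configuration for unit tests
small_synth <- function(seed = 1, ...) {
  args <- list(seed = seed, n_genes = 60, n_distal = 70, n_proximal = 30,
               n_coordinated_pairs = 10, n_distractor_pairs = 10,
               n_tf = 12, n_hi_var_tf = 3, n_decoy_coding = 10,
               n_decoy_blacklist = 5)
  over <- list(...)
  for (k in names(over)) args[[k]] <- over[[k]]
  do.call(synth_config, args)
}

noise_free <- function(cfg) {
  cfg$dispersion <- 0
  cfg$jitter_frac <- 0
  cfg$pair_noise_sd <- 0
  cfg
}
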