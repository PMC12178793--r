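#' Nonparametric test battery: paired Friedman and two-sample KS
#'
#' Significance across the three paired timepoints uses the Friedman rank
#' test with tie correction; group-versus-group signal distributions use the
#' unpaired two-sample Kolmogorov-Smirnov test. Both provide exact
#' small-sample p-values (exhaustive within-row permutation enumeration for
#' Friedman; lattice-path counting over all orderings for KS) and standard
#' large-sample approximations, with the method used recorded in the result.
#'
#' @name teststats
NULL

# All permutations of 1..k, one per row.
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1))
  }))
}

friedman_q <- function(ranks, C) {
  n <- nrow(ranks)
  k <- ncol(ranks)
  Rj <- colSums(ranks)
  ((12 / (n * k * (k + 1))) * sum(Rj^2) - 3 * n * (k + 1)) / C
}

#' Paired Friedman rank test
#'
#' Rows are subjects (elements), columns the `k` paired conditions
#' (timepoints). Within-row ranks use mid-ranks for ties; the statistic is
#' the tie-corrected
#' `Q = [(12 / (n k (k+1))) * sum_j R_j^2 - 3 n (k+1)] / C` with
#' `C = 1 - sum(t^3 - t) / (n k (k^2 - 1))` over within-row tie groups.
#' When `n <= exact_n_max` the p-value is exact, from exhaustive enumeration
#' of all `(k!)^n` within-row value permutations; otherwise it is the
#' chi-square upper tail with `k - 1` degrees of freedom. If every row is
#' fully tied, `Q = 0` and `p = 1` by convention.
#'
#' @param data numeric matrix (n x k), no missing values, n >= 2.
#' @param exact_n_max largest n for which the exact permutation distribution
#'   is enumerated (default 6).
#' @return list of class `credyn_test`: statistic, p_value, df, method
#'   (friedman_exact or friedman_chi2), stars.
#' @export
friedman <- function(data, exact_n_max = 6) {
  data <- as.matrix(data)
  if (any(is.na(data))) stop("missing values not allowed")
  n <- nrow(data)
  k <- ncol(data)
  if (n < 2) stop("need at least 2 rows")
  if (k < 2) stop("need at least 2 columns")
  ranks <- t(apply(data, 1, rank))
  tie_term <- sum(apply(data, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  C <- 1 - tie_term / (n * k * (k^2 - 1))
  if (C <= 0) {
    # every row fully tied: no information, no departure from the null
    res <- list(statistic = 0, p_value = 1, df = k - 1,
                method = if (n <= exact_n_max) "friedman_exact" else "friedman_chi2")
    res$stars <- stars(res$p_value)
    class(res) <- "credyn_test"
    return(res)
  }
  Q <- friedman_q(ranks, C)
  if (n <= exact_n_max) {
    perms <- all_permutations(k)
    kf <- nrow(perms)
    # per-row ranks of each permuted value vector: n x k! x k
    rank_arr <- array(0, c(n, kf, k))
    for (i in seq_len(n)) {
      for (p in seq_len(kf)) {
        rank_arr[i, p, ] <- rank(data[i, perms[p, ]])
      }
    }
    grid <- as.matrix(expand.grid(rep(list(seq_len(kf)), n)))
    Rj <- matrix(0, nrow(grid), k)
    for (i in seq_len(n)) {
      Rj <- Rj + matrix(rank_arr[i, grid[, i], , drop = FALSE], ncol = k)
    }
    Qs <- (((12 / (n * k * (k + 1))) * rowSums(Rj^2)) - 3 * n * (k + 1)) / C
    p <- mean(Qs >= Q - 1e-9)
    method <- "friedman_exact"
  } else {
    p <- pchisq(Q, df = k - 1, lower.tail = FALSE)
    method <- "friedman_chi2"
  }
  res <- list(statistic = Q, p_value = min(1, max(0, p)), df = k - 1,
              method = method)
  res$stars <- stars(res$p_value)
  class(res) <- "credyn_test"
  res
}

ks_asymptotic_p <- function(D, m, n) {
  if (D <= 0) return(1)
  en <- sqrt(m * n / (m + n))
  e <- (en + 0.12 + 0.11 / en) * D
  p <- 0
  for (j in 1:200) {
    term <- 2 * (-1)^(j - 1) * exp(-2 * j^2 * e^2)
    p <- p + term
    if (abs(term) < 1e-10) break
  }
  min(1, max(0, p))
}

# Exact two-sided KS p by counting the lattice paths (all C(m+n, n)
# orderings of the pooled sample) whose empirical-CDF deviation stays
# strictly below the observed D.
ks_exact_p <- function(D, m, n) {
  if (D <= 1e-12) return(1)
  A <- matrix(0, m + 1, n + 1)
  A[1, 1] <- 1
  for (i in 0:m) {
    for (j in 0:n) {
      if (i == 0 && j == 0) next
      if (abs(i / m - j / n) >= D - 1e-12) next
      A[i + 1, j + 1] <-
        (if (i > 0) A[i, j + 1] else 0) + (if (j > 0) A[i + 1, j] else 0)
    }
  }
  1 - A[m + 1, n + 1] / choose(m + n, n)
}

#' Unpaired two-sample Kolmogorov-Smirnov test
#'
#' The statistic is `D = sup |F_x - F_y|` over the pooled observed points
#' (right-continuous empirical CDFs). When the pooled size is at most
#' `exact_total_max` and the samples share no value, the p-value is exact
#' over all `C(m+n, n)` orderings; otherwise the asymptotic two-sided series
#' with the small-sample effective-size correction
#' `e = (sqrt(mn/(m+n)) + 0.12 + 0.11 / sqrt(mn/(m+n))) * D` is used
#' (cross-sample ties force the asymptotic path, noted in the result).
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_total_max largest pooled size for the exact path (default 20).
#' @return list of class `credyn_test`: statistic (D), p_value, method
#'   (ks_exact or ks_asymptotic), stars, note.
#' @export
ks2 <- function(x, y, exact_total_max = 20) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  m <- length(x)
  n <- length(y)
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) sum(x <= t), numeric(1)) / m
  Fy <- vapply(pts, function(t) sum(y <= t), numeric(1)) / n
  D <- max(abs(Fx - Fy))
  ties <- length(intersect(x, y)) > 0
  note <- NULL
  if (!ties && m + n <= exact_total_max) {
    p <- ks_exact_p(D, m, n)
    method <- "ks_exact"
  } else {
    p <- ks_asymptotic_p(D, m, n)
    method <- "ks_asymptotic"
    if (ties) note <- "cross-sample ties: exact enumeration skipped"
  }
  res <- list(statistic = D, p_value = min(1, max(0, p)), df = NA_integer_,
              method = method, note = note)
  res$stars <- stars(res$p_value)
  class(res) <- "credyn_test"
  res
}

#' Significance stars for a p-value
#'
#' Strict thresholds: `p < 0.0001` gives `****`, `< 0.001` `***`, `< 0.01`
#' `**`, `< 0.05` `*`, otherwise `ns`.
#'
#' @param p p-value in \[0, 1\].
#' @return character star label.
#' @export
stars <- function(p) {
  if (any(p < 0 | p > 1)) stop("p-value must lie in [0, 1]")
  vapply(p, function(pi) {
    if (pi < 0.0001) "****"
    else if (pi < 0.001) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' @export
print.credyn_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g %s\n",
              x$method, x$statistic, x$p_value, x$stars))
  invisible(x)
}
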