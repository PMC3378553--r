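#' Configuration for the SAM two-class unpaired test
#'
#' Defaults reproduce the parameterisation of the classic SAM analysis of
#' two-class microarray data: 100 label permutations, automatic estimation of
#' the exchangeability constant s0, a fixed random seed, and no array-wise
#' median centering.
#'
#' @param n_permutations Number of label permutations for the null
#'   distribution (>= 1).
#' @param s0_mode `"automatic"` (estimate s0 from the data, see
#'   [estimate_s0()]) or `"fixed"`.
#' @param s0_fixed Non-negative s0 used when `s0_mode = "fixed"`.
#' @param seed Integer seed for the permutation sampler.
#' @param median_center If `TRUE`, median-center each array first. Off by
#'   default, matching the analysis this package reproduces.
#' @return A list of class `sam_config`.
#' @export
sam_config <- function(n_permutations = 100, s0_mode = c("automatic", "fixed"),
                       s0_fixed = 0, seed = 1234567, median_center = FALSE) {
  s0_mode <- match.arg(s0_mode)
  check_scalar_number(n_permutations, "n_permutations", lower = 1)
  check_scalar_number(s0_fixed, "s0_fixed", lower = 0)
  structure(list(n_permutations = as.integer(n_permutations),
                 s0_mode = s0_mode, s0_fixed = s0_fixed,
                 seed = as.integer(seed),
                 median_center = isTRUE(median_center)),
            class = "sam_config")
}

#' SAM relative difference and gene-specific scatter
#'
#' For each gene the relative difference is
#' \deqn{d = \frac{\bar x_2 - \bar x_1}{s + s_0}, \qquad
#'       s = \sqrt{\left(\frac{1}{n_1}+\frac{1}{n_2}\right)
#'                 \frac{SS_1 + SS_2}{n_1 + n_2 - 2}}}
#' where \eqn{SS_g} is the within-group sum of squared deviations. With
#' \eqn{s_0 = 0}, d is the classical pooled-variance two-sample t statistic.
#'
#' @param x1 Numeric matrix (genes x samples) of the reference group, or a
#'   numeric vector for a single gene.
#' @param x2 Same for the comparison group (same genes, same order).
#' @param s0 Exchangeability constant added to the scatter (>= 0).
#' @return List with numeric vectors `d` and `s`, one entry per gene.
#' @export
relative_difference <- function(x1, x2, s0 = 0) {
  if (is.vector(x1)) x1 <- matrix(x1, nrow = 1)
  if (is.vector(x2)) x2 <- matrix(x2, nrow = 1)
  stopifnot(nrow(x1) == nrow(x2))
  check_scalar_number(s0, "s0", lower = 0)
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2 || n2 < 2)
    stop_rs("each group needs at least 2 samples (got %d and %d)", n1, n2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(d = (m2 - m1) / (s + s0), s = s)
}

#' Automatic estimate of the SAM exchangeability constant s0
#'
#' Candidates are the percentiles 0, 5, ..., 100 of the gene-specific
#' scatters s (plus 0 itself). For each candidate the genes are split into
#' up to 100 windows by percentiles of s; the criterion is the coefficient
#' of variation, across windows, of the median absolute deviation of the
#' d statistics recomputed with that candidate. The candidate minimising the
#' criterion is returned; ties (including a completely flat criterion, as in
#' homoscedastic data) resolve to the smallest candidate.
#'
#' @param s Numeric vector of gene-specific scatters (>= 20 genes).
#' @param d_at Function of one argument: `d_at(s0)` returns the per-gene d
#'   statistics computed with that s0.
#' @return The selected s0 (a single non-negative number).
#' @export
estimate_s0 <- function(s, d_at) {
  if (length(s) < 20)
    stop_rs("s0 estimation needs at least 20 genes (got %d)", length(s))
  candidates <- sort(unique(c(0, stats::quantile(s, probs = seq(0, 1, by = 0.05),
                                                 names = FALSE))))
  br <- unique(stats::quantile(s, probs = seq(0, 1, length.out = 101),
                               names = FALSE))
  win <- if (length(br) > 2)
    cut(s, br, labels = FALSE, include.lowest = TRUE)
  else rep(1L, length(s))
  cv <- vapply(candidates, function(s0) {
    d <- d_at(s0)
    mads <- tapply(d, win, stats::mad)
    m <- mean(mads, na.rm = TRUE)
    if (!is.finite(m) || m == 0) return(NA_real_)
    stats::sd(mads, na.rm = TRUE) / m
  }, 0)
  if (all(!is.finite(cv))) return(candidates[1])
  candidates[which.min(cv)]  # which.min takes the first (smallest) on ties
}

#' Linear-scale fold change between two groups of log2 values
#'
#' `fc = 2^(mean_log2(x2) - mean_log2(x1))`, the geometric-mean ratio of
#' group 2 (e.g. tumor) over group 1 (reference). With
#' `method = "arithmetic"` the ratio of arithmetic means of unlogged values
#' is used instead (sensitivity analysis only).
#'
#' @inheritParams relative_difference
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @return Numeric vector of positive fold changes, one per gene.
#' @export
fold_change <- function(x1, x2, method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (is.vector(x1)) x1 <- matrix(x1, nrow = 1)
  if (is.vector(x2)) x2 <- matrix(x2, nrow = 1)
  stopifnot(nrow(x1) == nrow(x2))
  if (ncol(x1) == 0 || ncol(x2) == 0) stop_rs("empty group in fold_change")
  if (method == "geometric")
    2^(rowMeans(x2) - rowMeans(x1))
  else
    rowMeans(2^x2) / rowMeans(2^x1)
}

# distinct random two-group label assignments (column index sets for group 1),
# identity excluded; all assignments enumerated when few enough
sample_permutations <- function(n, n1, b) {
  total <- choose(n, n1)
  identity_key <- paste(seq_len(n1), collapse = ",")
  if (total - 1 <= b) {
    all_idx <- utils::combn(n, n1, simplify = FALSE)
    keys <- vapply(all_idx, paste, "", collapse = ",")
    return(all_idx[keys != identity_key])
  }
  seen <- new.env(hash = TRUE)
  out <- vector("list", b)
  got <- 0
  while (got < b) {
    idx <- sort(sample.int(n, n1))
    key <- paste(idx, collapse = ",")
    if (key == identity_key || !is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    got <- got + 1
    out[[got]] <- idx
  }
  out
}

# SAM q-values by the delta sweep over asymmetric cutoffs.
# d: observed statistics; d_perm: genes x B permuted statistics.
sam_qvalues <- function(d, d_perm) {
  p <- length(d)
  ord <- order(d)
  ds <- d[ord]
  dbar <- rowMeans(apply(d_perm, 2, sort))
  res <- ds - dbar
  # pi0: fraction of observed d inside the interquartile range of the
  # permuted d, divided by 0.5 (null genes fill that range uniformly in rank)
  qq <- stats::quantile(d_perm, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, max(0, sum(d > qq[1] & d < qq[2]) / (0.5 * p)))
  i0 <- which.min(abs(dbar))  # index where the expected statistic crosses 0
  deltas <- sort(unique(abs(res)))
  q_sorted <- rep(100, p)
  for (delta in deltas) {
    up <- which(res[i0:p] >= delta)
    cutup <- if (length(up)) ds[i0 + up[1] - 1] else Inf
    lo <- which(res[seq_len(i0)] <= -delta)
    cutlow <- if (length(lo)) ds[lo[length(lo)]] else -Inf
    called <- ds >= cutup | ds <= cutlow
    ncalled <- sum(called)
    if (ncalled == 0) next
    false_med <- stats::median(colSums(d_perm >= cutup) +
                               colSums(d_perm <= cutlow))
    fdr <- min(100, max(0, 100 * pi0 * false_med / ncalled))
    q_sorted[called] <- pmin(q_sorted[called], fdr)
  }
  q <- numeric(p)
  q[ord] <- q_sorted
  list(q = q, pi0 = pi0)
}

#' Run the SAM two-class unpaired test
#'
#' Computes, per gene, the relative difference d, the gene-specific scatter
#' s, the fold change, and a permutation-based q-value (in percent): the
#' lowest estimated false discovery rate among the asymmetric
#' delta-thresholds at which the gene is called. The FDR at a threshold is
#' pi0 times the median, over label permutations, of the number of permuted
#' d beyond the cutoffs, divided by the observed number called; pi0 is
#' estimated from the fraction of observed d inside the interquartile range
#' of the permuted statistics. Group means are compared in the direction
#' `group_b` minus `group_a`, so `group_a` is the reference (normal)
#' group. Runs with equal configuration and seed are bit-identical.
#'
#' @param mat Numeric matrix (genes x samples), log2 scale, no missing
#'   values (impute first, see [impute_knn()]).
#' @param samples_a Column names (or indices) of the reference group.
#' @param samples_b Column names (or indices) of the comparison group.
#' @param config A [sam_config()].
#' @return Data frame of class `sam_result` with columns `gene`, `d`, `s`,
#'   `fc`, `q` (percent), and attributes `s0`, `pi0`, `n1`, `n2`.
#' @export
run_sam <- function(mat, samples_a, samples_b, config = sam_config()) {
  stopifnot(is.matrix(mat), inherits(config, "sam_config"))
  if (anyNA(mat[, c(samples_a, samples_b)]))
    stop_rs("expression matrix has missing values; run impute_knn() first")
  if (config$median_center)
    mat <- sweep(mat, 2, apply(mat, 2, stats::median))
  x1 <- mat[, samples_a, drop = FALSE]
  x2 <- mat[, samples_b, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  rd <- relative_difference(x1, x2, s0 = 0)
  s0 <- if (config$s0_mode == "automatic") {
    estimate_s0(rd$s, function(cand)
      relative_difference(x1, x2, s0 = cand)$d)
  } else config$s0_fixed
  d <- relative_difference(x1, x2, s0 = s0)$d
  pooled <- cbind(x1, x2)
  perms <- with_seed(config$seed,
                     sample_permutations(n1 + n2, n1, config$n_permutations))
  d_perm <- vapply(perms, function(idx) {
    relative_difference(pooled[, idx, drop = FALSE],
                        pooled[, -idx, drop = FALSE], s0 = s0)$d
  }, numeric(nrow(mat)))
  if (is.vector(d_perm)) d_perm <- matrix(d_perm, nrow = 1)
  qv <- sam_qvalues(d, d_perm)
  out <- data.frame(gene = rownames(mat), d = d, s = rd$s,
                    fc = fold_change(x1, x2), q = qv$q,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "s0") <- s0
  attr(out, "pi0") <- qv$pi0
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  class(out) <- c("sam_result", "data.frame")
  out
}
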