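#' Exact one-sided binomial upper tail
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, computed by exact summation of the
#' binomial probability mass over the upper support. This is the one-sided
#' ("greater") binomial test used to ask whether the deregulated fraction in
#' a gene cluster exceeds the overall deregulated fraction.
#'
#' @param k Number of successes observed (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success probability in \[0, 1\].
#' @return The p-value `P(X >= k)` (1 when `k = 0`).
#' @examples
#' binomial_upper_tail(2, 15, 2 / 269)   # 0.005442...
#' @export
binomial_upper_tail <- function(k, n, p0) {
  check_scalar_number(k, "k", lower = 0)
  check_scalar_number(n, "n", lower = 0)
  check_scalar_number(p0, "p0", lower = 0, upper = 1)
  if (k > n) stop_rs("k (%g) exceeds n (%g)", k, n)
  if (k <= 0) return(1)
  sum(stats::dbinom(seq(k, n), size = n, prob = p0))
}

#' Binomial enrichment of deregulated genes in one Rab cluster
#'
#' Tests whether the fraction of deregulated genes among the
#' platform-present members of a cluster (`k` of `n`) is greater than the
#' overall fraction among all platform-present catalog genes (`K` of `N`),
#' using the exact binomial upper tail with `p0 = K/N`. Genes belonging to
#' several clusters count in each cluster's `k` and `n` but only once in
#' `K` and `N`; general-machinery genes contribute to `K`/`N` only.
#'
#' @param calls A `dereg_calls` data frame for one tumor group, covering the
#'   platform-present catalog genes.
#' @param cluster Cluster name.
#' @param platform A `platform_catalog` (see [restrict_to_platform()]).
#' @param alpha Significance threshold on the p-value (default 0.01).
#' @return One-row data frame: `cluster`, `k`, `n`, `K`, `N`, `p0`,
#'   `p_value`, `significant`.
#' @export
enrich_cluster <- function(calls, cluster, platform, alpha = 0.01) {
  stopifnot(inherits(calls, "dereg_calls"),
            inherits(platform, "platform_catalog"))
  members <- platform_cluster_members(platform, cluster)
  n <- length(members)
  if (n == 0) stop_rs("cluster %s has no platform-present members", cluster)
  dereg <- intersect(called_genes(calls), platform$present)
  k <- length(intersect(dereg, members))
  K <- length(dereg)
  N <- platform$N
  p0 <- K / N
  p <- binomial_upper_tail(k, n, p0)
  data.frame(cluster = cluster, k = k, n = n, K = K, N = N, p0 = p0,
             p_value = p, significant = p < alpha, stringsAsFactors = FALSE)
}

#' Cluster enrichment across all clusters and tumor groups
#'
#' Applies [enrich_cluster()] to every Rab cluster within every supplied
#' tumor group. No multiple-testing correction is applied; the per-test
#' threshold is `alpha`.
#'
#' @param calls_by_group Named list mapping group name to a `dereg_calls`
#'   data frame.
#' @inheritParams enrich_cluster
#' @param clusters Cluster names to test (default: all clusters in the
#'   catalog). Duplicated names are an error.
#' @return Data frame with one row per (cluster, group).
#' @export
enrich_all <- function(calls_by_group, platform, alpha = 0.01,
                       clusters = cluster_names(platform$catalog)) {
  stopifnot(inherits(platform, "platform_catalog"))
  if (anyDuplicated(clusters)) stop_rs("duplicate cluster names")
  rows <- list()
  for (grp in names(calls_by_group)) {
    for (cl in clusters) {
      members <- platform_cluster_members(platform, cl)
      if (length(members) == 0) next
      r <- enrich_cluster(calls_by_group[[grp]], cl, platform, alpha)
      r <- cbind(group = grp, r, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- r
    }
  }
  do.call(rbind, rows)
}
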