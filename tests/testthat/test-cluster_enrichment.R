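test_that("binomial upper tail reproduces the published cluster p-values", {
  # Rab27 cluster, n = 15 platform-present members, per-group k against
  # the overall deregulated fraction K/269
  expect_equal(signif(binomial_upper_tail(2, 15, 2 / 269), 4), 0.005442)
  expect_equal(signif(binomial_upper_tail(3, 15, 16 / 269), 4), 0.05592)
  expect_equal(signif(binomial_upper_tail(5, 15, 24 / 269), 4), 0.007908)
  expect_equal(signif(binomial_upper_tail(4, 15, 20 / 269), 4), 0.02145)
  expect_equal(signif(binomial_upper_tail(2, 15, 11 / 269), 4), 0.1235)
  expect_equal(signif(binomial_upper_tail(4, 15, 10 / 269), 4), 0.001874)
})

test_that("binomial upper tail agrees with independent oracles for all n <= 30", {
  # oracle 1: direct log-binomial-coefficient summation
  tail_direct <- function(k, n, p) {
    if (k == 0) return(1)
    i <- k:n
    sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
  }
  for (n in c(1:10, 15, 20, 30)) {
    for (p0 in c(0.0074, 0.1, 0.5, 0.9)) {
      for (k in unique(c(0, 1, floor(n / 2), n))) {
        got <- binomial_upper_tail(k, n, p0)
        expect_equal(got, tail_direct(k, n, p0), tolerance = 1e-10)
        # oracle 2: the standard exact binomial test
        if (k >= 1)
          expect_equal(got,
                       binom.test(k, n, p0, alternative = "greater")$p.value,
                       tolerance = 1e-10)
      }
    }
  }
})

test_that("binomial tail is monotone and handles degenerate corners", {
  expect_equal(binomial_upper_tail(0, 15, 0.3), 1)
  expect_equal(binomial_upper_tail(0, 0, 0.5), 1)
  # non-increasing in k, non-decreasing in p0
  p_by_k <- sapply(0:10, binomial_upper_tail, n = 10, p0 = 0.2)
  expect_true(all(diff(p_by_k) <= 0))
  p_by_p0 <- sapply(seq(0.05, 0.95, 0.1), function(p)
    binomial_upper_tail(4, 10, p))
  expect_true(all(diff(p_by_p0) >= 0))
  expect_error(binomial_upper_tail(5, 4, 0.1), "exceeds")
  expect_error(binomial_upper_tail(1, 4, 1.5), "p0")
})

# calls for one group: the given cluster genes plus filler catalog genes
# outside the cluster, deregulated to reach a total of K
group_calls <- function(platform, cluster_genes, K) {
  symbols <- platform$present
  filler <- setdiff(symbols, platform_cluster_members(platform, "RAB27"))
  dereg <- c(cluster_genes, filler[seq_len(K - length(cluster_genes))])
  call_deregulated(data.frame(gene = symbols,
                              fc = ifelse(symbols %in% dereg, 0.4, 1),
                              q = 1))
}

test_that("cluster enrichment reproduces the published Rab27 significance pattern", {
  platform <- fixture_platform()
  stats <- rab27_cohort_stats()
  K_by_group <- c(TaG3_nonmut = 2, T1_nonmut = 16, T24_nonmut = 24,
                  TaG1G2_mut = 20, T1_mut = 11, T24_mut = 10)
  calls <- lapply(names(K_by_group), function(g)
    group_calls(platform, called_genes(call_deregulated(stats[[g]])),
                K_by_group[[g]]))
  names(calls) <- names(K_by_group)
  res <- enrich_all(calls, platform, clusters = "RAB27")
  res <- res[match(names(K_by_group), res$group), ]
  expect_equal(res$n, rep(15, 6))
  expect_equal(res$N, rep(269, 6))
  expect_equal(res$k, c(2, 3, 5, 4, 2, 4))
  expect_equal(res$K, unname(K_by_group))
  expect_equal(signif(res$p_value, 4),
               c(0.005442, 0.05592, 0.007908, 0.02145, 0.1235, 0.001874))
  # p < 1% only for TaG3 non-mutated and the two muscle-invasive groups
  expect_equal(res$group[res$significant],
               c("TaG3_nonmut", "T24_nonmut", "T24_mut"))
})

test_that("cluster enrichment handles degenerate call sets", {
  platform <- fixture_platform()
  symbols <- platform$present
  none <- call_deregulated(data.frame(gene = symbols, fc = 1, q = 100))
  r0 <- enrich_cluster(none, "RAB27", platform)
  expect_equal(r0$k, 0)
  expect_equal(r0$p_value, 1)
  expect_false(r0$significant)
  all_called <- call_deregulated(data.frame(gene = symbols, fc = 0.1, q = 0))
  r1 <- enrich_cluster(all_called, "RAB27", platform)
  expect_equal(r1$p0, 1)
  expect_equal(r1$p_value, 1)
  expect_error(enrich_all(list(g = none), platform,
                          clusters = c("RAB27", "RAB27")),
               "duplicate cluster")
})

test_that("multi-cluster genes count per cluster but once overall", {
  platform <- fixture_platform()
  catalog <- platform$catalog
  shared <- catalog$symbol[lengths(catalog$clusters) > 1 & catalog$present][1]
  cls <- catalog$clusters[[match(shared, catalog$symbol)]]
  calls <- group_calls(platform, shared, 1)
  res <- enrich_all(list(g = calls), platform, clusters = cls)
  expect_true(all(res$k == 1))   # contributes to every owning cluster
  expect_true(all(res$K == 1))   # but only once to the overall count
})
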