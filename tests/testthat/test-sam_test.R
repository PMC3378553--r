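test_that("relative difference matches the hand-evaluated formula", {
  # x1 = (1,2,3), x2 = (4,5,6), s0 = 0:
  # m1 = 2, m2 = 5, SS1 = SS2 = 2, s = sqrt((1/3+1/3)*4/4) = sqrt(2/3)
  rd <- relative_difference(c(1, 2, 3), c(4, 5, 6), s0 = 0)
  expect_equal(rd$s, sqrt(2 / 3))
  expect_equal(rd$d, 3 / sqrt(2 / 3))
  # with s0 > 0 only the denominator changes
  rd2 <- relative_difference(c(1, 2, 3), c(4, 5, 6), s0 = 0.5)
  expect_equal(rd2$d, 3 / (sqrt(2 / 3) + 0.5))
  expect_equal(rd2$s, rd$s)
  # identical groups: d = 0
  expect_equal(relative_difference(c(1, 2, 5), c(1, 2, 5), 0)$d, 0)
  expect_error(relative_difference(1, c(1, 2), 0), "at least 2 samples")
})

test_that("with s0 = 0 the statistic equals the pooled-variance t statistic", {
  set.seed(11)
  for (i in 1:5) {
    x1 <- rnorm(sample(3:8, 1)); x2 <- rnorm(sample(3:8, 1))
    d <- relative_difference(x1, x2, s0 = 0)$d
    tt <- t.test(x2, x1, var.equal = TRUE)$statistic
    expect_equal(d, unname(tt))
  }
})

test_that("relative difference is antisymmetric under group swap", {
  set.seed(12)
  x1 <- matrix(rnorm(40), 10); x2 <- matrix(rnorm(50), 10)
  a <- relative_difference(x1, x2, s0 = 0.2)
  b <- relative_difference(x2, x1, s0 = 0.2)
  expect_equal(a$d, -b$d)
  expect_equal(a$s, b$s)
  expect_equal(fold_change(x1, x2), 1 / fold_change(x2, x1))
})

test_that("fold change converts log2 group means to linear ratios", {
  x1 <- matrix(c(5, 5, 7, 7), 2)
  expect_equal(fold_change(x1, x1), c(1, 1))
  expect_equal(fold_change(x1, x1 + 1), c(2, 2))
  expect_equal(round(fold_change(x1, x1 - log2(1.5)), 3), c(0.667, 0.667))
  expect_error(fold_change(x1, x1[, 0]), "empty group")
})

test_that("automatic s0 equals an exhaustive grid-search of the CV criterion", {
  set.seed(21)
  n_genes <- 120
  # heteroscedastic: scatter grows with the mean
  mu <- runif(n_genes, 5, 10)
  x1 <- sapply(1:6, function(i) rnorm(n_genes, mu, 0.1 + 0.2 * (mu - 5)))
  x2 <- sapply(1:6, function(i) rnorm(n_genes, mu, 0.1 + 0.2 * (mu - 5)))
  s <- relative_difference(x1, x2, 0)$s
  d_at <- function(s0) relative_difference(x1, x2, s0)$d
  got <- estimate_s0(s, d_at)
  # independent brute-force evaluation over the same candidate grid
  candidates <- sort(unique(c(0, quantile(s, seq(0, 1, 0.05), names = FALSE))))
  br <- unique(quantile(s, seq(0, 1, length.out = 101), names = FALSE))
  win <- cut(s, br, labels = FALSE, include.lowest = TRUE)
  crit <- sapply(candidates, function(s0) {
    mads <- tapply(d_at(s0), win, mad)
    sd(mads, na.rm = TRUE) / mean(mads, na.rm = TRUE)
  })
  expect_equal(got, candidates[which.min(crit)])
})

test_that("s0 selection degenerates sensibly", {
  # homoscedastic toy: all scatters equal -> flat criterion -> smallest candidate
  x1 <- matrix(rep(c(0, 0, 0, 1, 1, 1), 25), nrow = 25, byrow = TRUE)
  x2 <- x1 + 1
  s <- relative_difference(x1, x2, 0)$s
  expect_true(sd(s) < 1e-12)
  expect_equal(estimate_s0(s, function(s0) relative_difference(x1, x2, s0)$d), 0)
  expect_error(estimate_s0(s[1:5], identity), "at least 20 genes")
})

test_that("run_sam ranks a planted shift first and is seed-reproducible", {
  set.seed(31)
  n <- 201
  mat <- matrix(rnorm(n * 20, 8, 0.5), n,
                dimnames = list(sprintf("g%03d", 1:n), sprintf("s%02d", 1:20)))
  mat[1, 11:20] <- mat[1, 11:20] + 3   # large planted shift
  cfg <- sam_config(n_permutations = 50, seed = 99)
  res <- run_sam(mat, paste0("s", sprintf("%02d", 1:10)),
                 paste0("s", sprintf("%02d", 11:20)), cfg)
  expect_equal(res$gene[which.max(abs(res$d))], "g001")
  expect_equal(res$gene[which.min(res$q)], "g001")
  expect_true(all(res$q >= 0 & res$q <= 100))
  expect_true(attr(res, "pi0") >= 0 && attr(res, "pi0") <= 1)
  # identical config + seed -> bit-identical output
  res2 <- run_sam(mat, paste0("s", sprintf("%02d", 1:10)),
                  paste0("s", sprintf("%02d", 11:20)), cfg)
  expect_identical(res, res2)
  # q-values are monotone in |d| within each tail
  up <- res[res$d > 0, ]; up <- up[order(up$d), ]
  expect_true(all(diff(up$q) <= 1e-12))
  dn <- res[res$d < 0, ]; dn <- dn[order(dn$d, decreasing = TRUE), ]
  expect_true(all(diff(dn$q) <= 1e-12))
})

test_that("run_sam validates its inputs", {
  mat <- matrix(rnorm(40), 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  expect_error(run_sam(mat, "s1", c("s2", "s3"), sam_config()),
               "at least 2 samples")
  mat[1, 1] <- NA
  expect_error(run_sam(mat, c("s1", "s2"), c("s3", "s4"), sam_config()),
               "missing values")
  expect_error(sam_config(n_permutations = 0), "n_permutations")
})
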