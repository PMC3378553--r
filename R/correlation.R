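#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: equal lengths of at least
#' 3, no missing values, non-zero variance in both vectors.
#'
#' @param x,y Numeric vectors.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_rs("x and y must have equal length")
  if (length(x) < 3) stop_rs("need at least 3 paired values")
  if (anyNA(x) || anyNA(y)) stop_rs("missing values in correlation input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_rs("constant vector: correlation undefined")
  stats::cor(x, y)
}

#' Two-tailed p-value of a Pearson correlation
#'
#' Uses the exact-null transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' referred to a t distribution with `n - 2` degrees of freedom, doubling
#' the tail. For `|r| = 1` the statistic degenerates; 0 is returned with
#' attribute `degenerate = TRUE`.
#'
#' @param r Correlation coefficient.
#' @param n Number of paired observations (>= 3).
#' @return The two-tailed p-value.
#' @export
pearson_pvalue <- function(r, n) {
  check_scalar_number(r, "r", lower = -1, upper = 1)
  check_scalar_number(n, "n", lower = 3)
  if (abs(r) == 1) return(structure(0, degenerate = TRUE))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Critical |r| on a fixed decimal grid
#'
#' The smallest correlation magnitude, on the grid of `decimals` decimal
#' places, whose two-tailed p-value (via [pearson_pvalue()]) is strictly
#' below `alpha`. This grid definition reproduces the conventional printed
#' thresholds (e.g. 0.479 at n = 28 and 0.323 at n = 63 for alpha = 0.01),
#' whereas naive inversion of the t quantile can round the wrong way.
#'
#' @param n Number of paired observations (>= 4).
#' @param alpha Two-tailed significance level (default 0.01).
#' @param decimals Grid resolution (default 3).
#' @return The critical |r| (single number).
#' @examples
#' critical_r(28)  # 0.479
#' critical_r(63)  # 0.323
#' @export
critical_r <- function(n, alpha = 0.01, decimals = 3) {
  check_scalar_number(n, "n", lower = 4)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  step <- 10^(-decimals)
  grid <- seq(step, 1 - step, by = step)
  p <- vapply(grid, pearson_pvalue, 0, n = n)
  hit <- which(p < alpha)
  if (!length(hit)) return(1)
  grid[hit[1]]
}

#' Association verdict from per-group correlations
#'
#' The dual-group rule: a gene is `correlated` with a marker when its
#' correlation magnitude exceeds the group-specific critical value in both
#' reference groups with positive sign in both, `inversely_correlated` when
#' both pass with negative sign, and `none` otherwise (including sign
#' disagreement when `require_sign` is `TRUE`).
#'
#' @param r_a,r_b Pearson correlations in groups A and B.
#' @param crit_a,crit_b Group-specific critical |r| values.
#' @param require_sign Require a consistent sign across groups
#'   (default `TRUE`).
#' @return `"correlated"`, `"inversely_correlated"` or `"none"`.
#' @export
association_verdict <- function(r_a, r_b, crit_a, crit_b,
                                require_sign = TRUE) {
  pass <- abs(r_a) > crit_a && abs(r_b) > crit_b
  if (!pass) return("none")
  if (r_a > 0 && r_b > 0) return("correlated")
  if (r_a < 0 && r_b < 0) return("inversely_correlated")
  if (require_sign) "none" else if (r_a > 0) "correlated" else "inversely_correlated"
}

#' Correlation of one gene with one marker across two reference groups
#'
#' Computes the Pearson correlation between a gene and a marker (e.g. the
#' proliferation marker MKI67 or a urothelial differentiation marker such as
#' a uroplakin) separately in two tumor groups, compares each against the
#' group's critical |r| at level `alpha`, and issues the dual-group verdict.
#'
#' @param gene_expr,marker_expr Named numeric vectors of log2 expression
#'   indexed by sample id (or vectors aligned with the sample arguments).
#' @param samples_a,samples_b Sample ids of the two reference groups
#'   (each >= 4 samples).
#' @param alpha Two-tailed significance level (default 0.01).
#' @param require_sign Passed to [association_verdict()].
#' @return One-row data frame: `r_a`, `r_b`, `crit_a`, `crit_b`, `verdict`.
#' @export
marker_association <- function(gene_expr, marker_expr, samples_a, samples_b,
                               alpha = 0.01, require_sign = TRUE) {
  if (length(samples_a) < 4 || length(samples_b) < 4)
    stop_rs("each reference group needs at least 4 samples")
  r_a <- pearson_r(gene_expr[samples_a], marker_expr[samples_a])
  r_b <- pearson_r(gene_expr[samples_b], marker_expr[samples_b])
  crit_a <- critical_r(length(samples_a), alpha)
  crit_b <- critical_r(length(samples_b), alpha)
  data.frame(r_a = r_a, r_b = r_b, crit_a = crit_a, crit_b = crit_b,
             verdict = association_verdict(r_a, r_b, crit_a, crit_b,
                                           require_sign),
             stringsAsFactors = FALSE)
}

#' Gene-by-marker association table
#'
#' Applies [marker_association()] to every (gene, marker) pair, mirroring a
#' correlation report table: one row per pair with the per-group r values
#' and the verdict.
#'
#' @param mat Log2 expression matrix (genes x samples) containing both the
#'   query genes and the markers.
#' @param genes Query gene symbols.
#' @param markers Marker gene symbols. Defaults: proliferation is usually
#'   `MKI67`; differentiation `c("UPK1A","UPK1B","UPK2","UPK3A","UPK3B",
#'   "GRHL3","FOXA1")`.
#' @inheritParams marker_association
#' @return Data frame with columns `gene`, `marker`, `r_a`, `r_b`,
#'   `crit_a`, `crit_b`, `verdict`.
#' @export
marker_association_table <- function(mat, genes, markers, samples_a,
                                     samples_b, alpha = 0.01,
                                     require_sign = TRUE) {
  missing <- setdiff(c(genes, markers), rownames(mat))
  if (length(missing))
    stop_rs("gene(s) absent from matrix: %s", paste(missing, collapse = ", "))
  rows <- list()
  for (g in genes) for (m in markers) {
    r <- marker_association(mat[g, ], mat[m, ], samples_a, samples_b,
                            alpha, require_sign)
    rows[[length(rows) + 1]] <- cbind(gene = g, marker = m, r,
                                      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Welch's unequal-variance t-test p-value
#'
#' Two-tailed p-value of the two-sample t-test without the equal-variance
#' assumption, as used to compare marker expression between tumor groups.
#'
#' @param a,b Numeric vectors (each >= 2 values; unequal sizes allowed).
#' @return The two-tailed p-value.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_rs("each sample needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop_rs("zero variance in both samples")
  stats::t.test(a, b, var.equal = FALSE)$p.value
}
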