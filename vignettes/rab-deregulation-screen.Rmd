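---
title: "Methods: screening Rab-family gene sets for transcriptional deregulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening Rab-family gene sets for transcriptional deregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rabscreen)
```

# The screen

`rabscreen` asks a focused question: within a curated family of genes — the
Rab GTPases together with their exchange factors (GEFs), GTPase-activating
proteins (GAPs) and effectors — which genes, and which Rab-centred gene
sets, change transcriptionally along the two recognised progression
pathways of bladder cancer? The package takes already-normalised log2
expression (one value per gene per sample, RMA-style), a sample annotation
table (tissue, stage, grade, *FGFR3* mutation status) and the bundled gene
catalog, and runs a fixed sequence of analyses: group assignment, SAM
differential tests against normal urothelium, fold-change/q-value calls,
stromal filtering, pathway-specificity testing, cluster-level binomial
enrichment, and marker-correlation association.

## The two-pathway model

Samples are stratified before any testing. Tumors carrying an *FGFR3*
mutation form the Ta-like pathway with stage groups TaG1G2, T1 and T2–4;
tumors without the mutation form the carcinoma-in-situ-like pathway with
groups TaG3, T1 and T2–4. Two tumor constellations fit neither pathway —
TaG3 with an *FGFR3* mutation, and TaG1/G2 without one — and are assigned
to an explicit `excluded` group rather than dropped, so sample accounting
is always total. Normal urothelium is the shared reference for every
comparison. Group assignment is deterministic and order-independent.

# The SAM test

Each tumor group is compared to the normal group with a from-scratch
implementation of the SAM two-class unpaired test. For gene *i* with group
means $\bar x_{1i}$ (reference) and $\bar x_{2i}$:

$$d_i = \frac{\bar x_{2i} - \bar x_{1i}}{s_i + s_0}, \qquad
  s_i = \sqrt{\left(\tfrac{1}{n_1} + \tfrac{1}{n_2}\right)
        \frac{SS_{1i} + SS_{2i}}{n_1 + n_2 - 2}}$$

With $s_0 = 0$, $d_i$ is the pooled-variance t statistic; $s_0$ regularises
the denominator so that low-scatter genes cannot dominate the ranking.

**Automatic s0.** Candidates are the percentiles 0, 5, …, 100 of the
per-gene scatters $s$, plus 0 itself. For each candidate the genes are cut
into up to 100 percentile windows of $s$; the criterion is the coefficient
of variation, across windows, of the median absolute deviation of the
recomputed $d$. The candidate minimising the criterion wins; ties — and the
fully degenerate case of a flat criterion, as with exactly homoscedastic
data — resolve to the smallest candidate. This keeps the selection
deterministic.

**Permutations and q-values.** The null distribution comes from
`n_permutations` (default 100) random reassignments of the group labels:
distinct assignments, identity excluded, enumerated exhaustively when there
are no more than the requested number, otherwise sampled without
replacement. All randomness flows from the single integer seed in
`sam_config()` (default 1234567), so repeated runs are bit-identical.
q-values follow the classic SAM delta sweep: observed statistics are sorted
against the mean permuted order statistics $\bar d_{(i)}$; for each
threshold $\Delta$ the asymmetric cutoffs are the first sorted $d$ whose
residual $d_{(i)} - \bar d_{(i)}$ exceeds $\Delta$ above the centre (and
falls below $-\Delta$ beneath it); the estimated FDR at $\Delta$ is

$$\widehat{FDR}(\Delta) = \pi_0 \cdot
  \frac{\mathrm{median}_b\,\#\{d^{*b} \text{ beyond the cutoffs}\}}
       {\#\{d \text{ beyond the cutoffs}\}},$$

and a gene's q-value is the smallest FDR over all thresholds at which it is
called, clamped to [0, 100] percent. $\pi_0$ is the fraction of observed
$d$ inside the interquartile range of the pooled permuted statistics,
divided by 0.5 and clamped to [0, 1]. Because the called sets are nested in
$\Delta$, q-values are automatically monotone in $|d|$ within each tail.

**Missing values.** SAM requires a complete matrix, so missing entries are
first filled by gene-wise k-nearest-neighbour imputation (default k = 10):
neighbours are the genes observed at the target sample, ranked by Euclidean
distance over co-observed samples (scaled to the full sample count so
distances computed over different numbers of co-observed samples are
comparable), with ties broken by row order. The module imputes on the full
matrix before any group subsetting; whether the original analyses imputed
before or after subsetting is not documented, and imputing once on the full
matrix is the simpler, deterministic choice.

# Calls, lists and filters

**Thresholds.** A gene is called up-regulated when FC > 1.5 and q < 5%,
down-regulated when FC < 1/1.5 ≈ 0.667 with the same q condition. The
fold-change and q inequalities are strict — a gene sitting exactly on a
threshold is not called — because that is the direction in which the
thresholds are stated. The stromal filter's 2-fold rule, by contrast, is
stated as a drawn threshold line, and is applied inclusively (≥ 1 log2
unit above the NHU mean in at least one cell line retains the gene). Fold
changes are geometric-mean ratios, $2^{\Delta \overline{\log_2}}$, since
all stored values are log2; an arithmetic-mean variant exists behind a
switch for sensitivity analysis only.

**Pathway lists.** A pathway's list is the union of genes passing in at
least one of its three stage groups. A gene called in both directions
within one pathway is surfaced as an error, not silently resolved.

**Cross-dataset validation.** A call is validated in an independent cohort
when at least one threshold passes there *in the same direction*: the
fold-change criterion alone suffices, and the q criterion alone suffices
only when the second-cohort fold change is on the same side of 1. The
direction requirement is deliberate: "at least one threshold passed" could
be read as direction-blind, but then an opposite-direction hit could count
as validation; requiring direction agreement turns "no discordant result"
into a checked condition. A call passing both thresholds in the opposite
direction is reported as `discordant`.

**Specificity.** Candidates deregulated in exactly one pathway are
confirmed by SAM comparisons of the candidate pathway's stage group against
the same-stage group of opposite mutation status, at the same FC/q
thresholds and in the same direction.

# Cluster enrichment

For each Rab cluster, with `k` deregulated genes among its `n`
platform-present members, against `K` deregulated among all `N`
platform-present catalog genes, the exact binomial upper tail
$P(X \ge k)$, $X \sim \mathrm{Bin}(n, K/N)$, is summed directly from the
probability mass function. Reporting threshold: p < 1%, with no
multiple-testing correction (none is part of the screen's definition; the
table of all cluster × group p-values is returned so users can correct if
they wish). Genes belonging to several clusters count in each cluster's
`k` and `n` but once in `K` and `N`; the six general-machinery genes common
to all Rabs are in the catalog denominator but in no cluster.

# Marker association

Correlations are computed in the two largest homogeneous tumor groups
(defaults TaG1G2-mutated, n = 28, and T2–4 non-mutated, n = 63).
Significance uses the t transform $t = r\sqrt{n-2}/\sqrt{1-r^2}$ with
$n-2$ degrees of freedom, two-tailed. The per-group critical value is
defined on a three-decimal grid: the smallest |r| whose p-value is strictly
below 1%. This grid definition is deliberate — it yields 0.479 at n = 28
*and* 0.323 at n = 63, whereas rounding the inverted t quantile gives
0.322 at n = 63. A gene–marker pair earns a verdict only when |r| exceeds
the critical value in *both* groups with a consistent sign (`correlated`
positive, `inversely_correlated` negative). The sign-consistency
requirement is a design choice: the dual-p criterion alone would also
accept sign-flipping pairs, which have no coherent biological reading; it
can be relaxed via `require_sign = FALSE`.

# The synthetic cohort generator

Because the screen's reference cohorts are not publicly downloadable, the
generator provides data with exactly the structure the pipeline assumes:

* additive Gaussian noise on the log2 scale (default SD 0.5, a typical
  residual spread for RMA-summarised arrays) around a per-gene baseline
  drawn uniformly from 6–10 log2 units; an optional heteroscedastic mode
  ties the SD to the baseline to exercise s0 estimation;
* default group sizes 4 normal / 28, 13, 9 / 3, 25, 63 tumors, mirroring a
  realistic first-cohort composition and deliberately including a 3-sample
  group;
* planted per-group mean shifts recorded as true fold changes ($2^{shift}$);
* latent factors: a standard-normal per-sample score multiplied into named
  gene loadings, inducing marker co-expression with population correlation
  $\lambda_g \lambda_m / \sqrt{(\lambda_g^2+\sigma^2)(\lambda_m^2+\sigma^2)}$;
* stroma-only genes: up-shifted in tumor profiles but left at baseline in
  every simulated cell line, so the stromal filter must catch them;
* platform-absent genes and uniform missingness (each gene keeps at least
  one observed value).

What passing tests on this generator do **not** show: robustness to
intensity-dependent variance beyond the simple heteroscedastic mode, batch
effects, probe-level artefacts, non-Gaussian heavy tails, or correlated
noise between genes other than through the declared factors. Results on
real arrays depend on normalisation quality in ways the simulator does not
model.

# Numerical choices and degenerate inputs

* Binomial tails are exact pmf sums (no normal approximation) and agree
  with brute-force summation to at least 10 significant digits for all
  n ≤ 30 (tested).
* `k = 0` gives p = 1 by convention (the whole support).
* Empty platform intersections, all-deregulated call sets (`p0 = 1`),
  constant vectors in correlations, all-missing gene rows, and groups with
  fewer than two samples are all explicit errors or defined degenerate
  results rather than silent NaNs.
* s0 candidates, KNN neighbours and permutation sampling all have stated
  deterministic tie-breaks; the pipeline run is byte-identical for a fixed
  seed, and the JSON manifest records thresholds, SAM parameters and group
  sizes.

# Problem sizes in the test suite

The property tests run the full screen at the default cohort size (269
genes × 145 samples, 100 permutations) across 20 seeds for null
calibration and planted-effect recovery (sensitivity ≥ 90% and null-call
rate ≤ 10% at fold change 2, noise SD 0.5), and smaller instances
(20–200 genes) for the formula-level oracles. These sizes keep the whole
suite under a minute while leaving the recovery properties statistically
meaningful.

# Known limitations

* The q-value algorithm follows the classic SAM manual; minor revisions
  across historical versions of the tool mean q-values from specific
  published tables are matched qualitatively, not bit-exactly.
* The catalog's per-cluster membership is exact only where published
  (the Rab27 cluster); other interactors are placeholders (symbols prefixed
  `SYN`, documented as synthetic) that reproduce the per-cluster role
  counts, so cluster-level arithmetic is faithful while individual synthetic
  symbols carry no biological meaning.
* Gene symbols are used verbatim; no alias resolution is attempted.
* Only the two-class unpaired SAM variant is provided (no paired,
  multiclass or survival designs, and no local-FDR).
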