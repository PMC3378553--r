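#' Configuration for the synthetic bladder-cohort simulator
#'
#' Describes a synthetic study with the statistical structure the screening
#' pipeline assumes: additive Gaussian noise on the log2 scale around a
#' per-gene baseline, group-specific planted mean shifts (true fold
#' changes), latent factors inducing marker co-expression, stroma-only
#' up-regulation (present in tumor profiles but not in cell lines),
#' platform-absent genes and missing values. Default group sizes mirror a
#' typical first-cohort composition (4 normal urothelium references, 28
#' TaG1G2 mutated, 13 T1 mutated, 9 T2-4 mutated, 3 TaG3 non-mutated, 25 T1
#' non-mutated, 63 T2-4 non-mutated), deliberately including the degenerate
#' 3-sample group.
#'
#' @param seed Integer seed; every random draw of the simulator flows from
#'   it.
#' @param n_genes Number of genes (symbols default to `SIM0001`, ...).
#' @param genes Optional explicit gene symbols (overrides `n_genes`).
#' @param group_sizes Named integer vector of samples per analysis group.
#' @param baseline_range Range of the per-gene baseline log2 level.
#' @param noise_sd Standard deviation of the log2-scale Gaussian noise
#'   (default 0.5, a typical residual spread for RMA-summarised arrays).
#' @param heteroscedastic If `TRUE`, the noise SD of each gene scales with
#'   its baseline (exercises s0 estimation).
#' @param planted_effects Data frame with columns `gene`, `group`,
#'   `log2_shift`: mean shifts added to the named group's samples.
#' @param latent_factors List of factors, each a list with `name`,
#'   `loadings` (named numeric vector, gene -> loading) and `groups`
#'   (character vector); each sample in those groups draws a standard-normal
#'   factor score shared by all loaded genes.
#' @param stromal_genes Genes whose tumor up-shift is stromal: present in
#'   the study matrix but absent from every simulated cancer cell line.
#' @param missing_rate Fraction of cells set missing (in \[0, 1)); each gene
#'   always keeps at least one observed value.
#' @param platform_absent Genes excluded from the study matrix (platform
#'   restriction).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genes = 269, genes = NULL,
                       group_sizes = c(normal = 4, TaG1G2_mut = 28,
                                       T1_mut = 13, T24_mut = 9,
                                       TaG3_nonmut = 3, T1_nonmut = 25,
                                       T24_nonmut = 63),
                       baseline_range = c(6, 10), noise_sd = 0.5,
                       heteroscedastic = FALSE,
                       planted_effects = NULL, latent_factors = list(),
                       stromal_genes = character(), missing_rate = 0,
                       platform_absent = character()) {
  if (is.null(genes)) genes <- sprintf("SIM%04d", seq_len(n_genes))
  check_scalar_number(missing_rate, "missing_rate", lower = 0, upper = 1 - 1e-9)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (is.null(planted_effects))
    planted_effects <- data.frame(gene = character(), group = character(),
                                  log2_shift = numeric(),
                                  stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "group", "log2_shift") %in% names(planted_effects)),
            all(is.finite(planted_effects$log2_shift)))
  bad <- setdiff(planted_effects$gene, genes)
  if (length(bad))
    stop_rs("planted gene(s) not in gene list: %s", paste(bad, collapse = ", "))
  bad <- setdiff(c(stromal_genes, platform_absent), genes)
  if (length(bad))
    stop_rs("unknown gene(s) in config: %s", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), genes = genes,
                 group_sizes = group_sizes, baseline_range = baseline_range,
                 noise_sd = noise_sd, heteroscedastic = isTRUE(heteroscedastic),
                 planted_effects = planted_effects,
                 latent_factors = latent_factors,
                 stromal_genes = stromal_genes, missing_rate = missing_rate,
                 platform_absent = platform_absent),
            class = "sim_config")
}

sim_annotation_row <- function(group, sample) {
  spec <- switch(group,
    normal        = c("normal_urothelium", "NA", "NA", "NA"),
    TaG1G2_mut    = c("tumor", "Ta", "G1", "mutated"),
    T1_mut        = c("tumor", "T1", "G2", "mutated"),
    T24_mut       = c("tumor", "T2_4", "G3", "mutated"),
    TaG3_nonmut   = c("tumor", "Ta", "G3", "non_mutated"),
    T1_nonmut     = c("tumor", "T1", "G3", "non_mutated"),
    T24_nonmut    = c("tumor", "T2_4", "G3", "non_mutated"),
    TaG3_mut      = c("tumor", "Ta", "G3", "mutated"),
    TaG1G2_nonmut = c("tumor", "Ta", "G2", "non_mutated"),
    stop_rs("unknown group in group_sizes: %s", group))
  data.frame(sample = sample, tissue = spec[1], stage = spec[2],
             grade = spec[3], fgfr3 = spec[4], stringsAsFactors = FALSE)
}

#' Simulate a synthetic bladder-cohort study
#'
#' Draws a log2 expression matrix, matching sample annotations and a
#' ground-truth record from a [sim_config()]. Values are
#' `baseline + planted group shift + latent-factor contribution + noise`;
#' missing entries are then injected at `missing_rate` and platform-absent
#' genes dropped from the matrix (the truth keeps them). Identical seeds
#' give identical output.
#'
#' @param config A [sim_config()].
#' @return List with elements `expression` (matrix), `annotations`
#'   (data frame), and `truth` (list: `fc` matrix of true linear fold
#'   changes gene x group, `baseline`, `stromal_genes`, `config`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  small <- config$group_sizes < 2
  if (any(small))
    warning(sprintf("group(s) with < 2 samples: %s",
                    paste(names(config$group_sizes)[small], collapse = ", ")))
  genes <- config$genes
  groups <- names(config$group_sizes)
  with_seed(config$seed, {
    baseline <- stats::runif(length(genes), config$baseline_range[1],
                             config$baseline_range[2])
    names(baseline) <- genes
    sd_gene <- if (config$heteroscedastic)
      config$noise_sd * (0.5 + (baseline - min(baseline)) /
                           max(1e-9, diff(range(baseline))))
    else rep(config$noise_sd, length(genes))
    shift <- matrix(0, length(genes), length(groups),
                    dimnames = list(genes, groups))
    pe <- config$planted_effects
    for (i in seq_len(nrow(pe))) {
      if (!pe$group[i] %in% groups)
        stop_rs("planted effect for unknown group: %s", pe$group[i])
      shift[pe$gene[i], pe$group[i]] <- shift[pe$gene[i], pe$group[i]] +
        pe$log2_shift[i]
    }
    cols <- list(); ann <- list()
    for (grp in groups) {
      n <- config$group_sizes[[grp]]
      if (n == 0) next
      ids <- sprintf("%s_%02d", grp, seq_len(n))
      block <- baseline + shift[, grp] +
        matrix(stats::rnorm(length(genes) * n, sd = sd_gene),
               length(genes), n)
      for (f in config$latent_factors) {
        if (!grp %in% f$groups) next
        load <- rep(0, length(genes)); names(load) <- genes
        load[names(f$loadings)] <- f$loadings
        block <- block + outer(load, stats::rnorm(n))
      }
      colnames(block) <- ids
      cols[[grp]] <- block
      ann[[grp]] <- do.call(rbind, lapply(ids, function(id)
        sim_annotation_row(grp, id)))
    }
    mat <- do.call(cbind, cols)
    rownames(mat) <- genes
    annotations <- do.call(rbind, ann)
    rownames(annotations) <- NULL
    if (config$missing_rate > 0) {
      holes <- which(stats::runif(length(mat)) < config$missing_rate)
      mat[holes] <- NA
      # guarantee at least one observed value per gene
      lost <- which(rowSums(!is.na(mat)) == 0)
      for (g in lost) mat[g, 1] <- baseline[g]
    }
    keep <- setdiff(genes, config$platform_absent)
    truth <- list(fc = 2^shift, baseline = baseline,
                  stromal_genes = config$stromal_genes, config = config)
    list(expression = mat[keep, , drop = FALSE], annotations = annotations,
         truth = truth)
  })
}

#' Simulate the cell-line / NHU validation panel
#'
#' Generates log2 expression for 7 cancer cell lines and NHU culture
#' replicates consistent with a study's ground truth: genes planted as
#' up-regulated in tumors are raised by at least their planted shift
#' (minimum one log2 unit) in at least one cell line, except stromal genes,
#' which stay at the NHU baseline in every line. This is the panel the
#' stromal filter ([stroma_filter()]) interrogates.
#'
#' @param config The [sim_config()] used for the study.
#' @param truth The `truth` element returned by [simulate_study()].
#' @param lines Cell-line names (default the 7-line panel
#'   KK47, MGHU3, RT112, RT4, SCaBER, SD48, T24).
#' @param n_nhu Number of NHU replicates (default 3).
#' @param line_noise_sd Log2 noise SD for the panel (default 0.15).
#' @return List with matrices `cell_lines` (genes x lines) and `nhu`
#'   (genes x replicates).
#' @export
simulate_cell_lines <- function(config, truth,
                                lines = c("KK47", "MGHU3", "RT112", "RT4",
                                          "SCaBER", "SD48", "T24"),
                                n_nhu = 3, line_noise_sd = 0.15) {
  stopifnot(inherits(config, "sim_config"))
  genes <- config$genes
  baseline <- truth$baseline
  up_shift <- apply(log2(truth$fc), 1, max)  # strongest planted up-shift
  with_seed(config$seed + 104729L, {
    nhu <- baseline + matrix(stats::rnorm(length(genes) * n_nhu,
                                          sd = line_noise_sd),
                             length(genes), n_nhu,
                             dimnames = list(genes,
                                             sprintf("NHU_%02d", seq_len(n_nhu))))
    cl <- baseline + matrix(stats::rnorm(length(genes) * length(lines),
                                         sd = line_noise_sd),
                            length(genes), length(lines),
                            dimnames = list(genes, lines))
    up <- names(up_shift)[up_shift > 0]
    up <- setdiff(up, truth$stromal_genes)
    for (i in seq_along(up)) {
      line <- lines[(i - 1) %% length(lines) + 1]
      # margin above the 2-fold rule so panel noise cannot mask the signal
      cl[up[i], line] <- baseline[up[i]] + max(1.5, up_shift[up[i]])
    }
    list(cell_lines = cl, nhu = nhu)
  })
}
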