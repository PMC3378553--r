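#' Run the full Rab deregulation screening pipeline
#'
#' Orchestrates the whole screen on one study: group assignment, KNN
#' imputation, a SAM comparison of every tumor group against the shared
#' normal-urothelium reference, fold-change/q-value deregulation calls,
#' per-pathway union, optional cross-dataset validation, the stromal filter
#' on up-regulated genes (when a cell-line/NHU panel is supplied),
#' pathway-specificity testing via same-stage cross-pathway SAM
#' comparisons, cluster-level binomial enrichment, and marker-correlation
#' association. Stages log gene counts in and out; any stage error aborts
#' the run with the stage name, and partially written outputs are removed.
#'
#' @param expression Log2 expression matrix (genes x samples) or a path to
#'   an expression TSV (see [read_expression()]).
#' @param annotations Annotation data frame or path to an annotation TSV.
#' @param catalog A `rab_catalog` or path to a catalog TSV.
#' @param cell_lines,nhu Optional log2 matrices (or TSV paths) for the
#'   stromal filter.
#' @param expression2,annotations2 Optional second, independent dataset for
#'   cross-dataset validation of the calls.
#' @param present_genes Genes measurable on the platform (default: the rows
#'   of `expression`).
#' @param fc_up,fc_down,q_max Deregulation thresholds
#'   (see [call_deregulated()]).
#' @param cluster_alpha Binomial enrichment threshold (default 0.01).
#' @param corr_alpha Correlation significance level (default 0.01).
#' @param sam SAM parameters, a [sam_config()].
#' @param proliferation_markers,differentiation_markers Marker panels for
#'   the association step; markers absent from the matrix are skipped.
#' @param corr_groups The two reference groups for marker correlation.
#' @param out_dir Optional directory: per-stage TSV tables and a JSON run
#'   manifest are written there, deterministically for a fixed seed.
#' @return Invisibly, a list ("report bundle"): `groups`, `sam` (per
#'   group), `calls` (per group), `pathways`, `stroma`, `specific`,
#'   `enrichment`, `associations`, `log`, `manifest`.
#' @export
run_pipeline <- function(expression, annotations, catalog,
                         cell_lines = NULL, nhu = NULL,
                         expression2 = NULL, annotations2 = NULL,
                         present_genes = NULL,
                         fc_up = 1.5, fc_down = 1 / 1.5, q_max = 5,
                         cluster_alpha = 0.01, corr_alpha = 0.01,
                         sam = sam_config(),
                         proliferation_markers = "MKI67",
                         differentiation_markers = c("UPK1A", "UPK1B", "UPK2",
                                                     "UPK3A", "UPK3B",
                                                     "GRHL3", "FOXA1"),
                         corr_groups = c("TaG1G2_mut", "T24_nonmut"),
                         out_dir = NULL) {
  if (is.character(expression)) expression <- read_expression(expression)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  if (is.character(catalog)) catalog <- load_catalog(catalog)
  if (is.character(cell_lines)) cell_lines <- read_expression(cell_lines)
  if (is.character(nhu)) nhu <- read_expression(nhu)
  if (is.character(expression2)) expression2 <- read_expression(expression2)
  if (is.character(annotations2)) annotations2 <- read_annotations(annotations2)
  if (is.null(present_genes)) present_genes <- rownames(expression)

  written <- character()
  log_lines <- character()
  note <- function(fmt, ...) {
    log_lines[[length(log_lines) + 1]] <<- sprintf(fmt, ...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      for (f in written) unlink(f)
      stop_rs("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  emit <- function(obj, file) {
    if (is.null(out_dir)) return(invisible())
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    path <- file.path(out_dir, file)
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }

  tumor_groups <- c("TaG1G2_mut", "T1_mut", "T24_mut",
                    "TaG3_nonmut", "T1_nonmut", "T24_nonmut")

  groups <- stage("assign_groups", {
    g <- assign_groups(annotations)
    g <- g[g$sample %in% colnames(expression), , drop = FALSE]
    note("groups: %d samples mapped, %d excluded",
         nrow(g), sum(g$group == "excluded"))
    g
  })

  all_markers <- c(proliferation_markers, differentiation_markers)
  mat_full <- stage("impute", {
    keep <- intersect(rownames(expression),
                      union(intersect(catalog$symbol, present_genes),
                            all_markers))
    m <- expression[keep, , drop = FALSE]
    n_miss <- sum(is.na(m))
    if (n_miss > 0) m <- impute_knn(m)
    note("impute: %d genes retained (catalog + markers), %d cells imputed",
         nrow(m), n_miss)
    m
  })
  # SAM, calls and enrichment run on the catalog genes only
  mat <- mat_full[intersect(rownames(mat_full), catalog$symbol), ,
                  drop = FALSE]

  normal <- group_samples(groups, "normal")
  active <- tumor_groups[vapply(tumor_groups, function(g)
    length(group_samples(groups, g)) >= 2, TRUE)]

  sam_results <- stage("sam", {
    res <- lapply(active, function(grp)
      run_sam(mat, normal, group_samples(groups, grp), sam))
    names(res) <- active
    note("sam: %d group-vs-normal comparisons (s0 per group: %s)",
         length(res),
         paste(signif(vapply(res, attr, 0, "s0"), 3), collapse = ", "))
    res
  })

  calls <- stage("call_deregulated", {
    cl <- lapply(sam_results, call_deregulated,
                 fc_up = fc_up, fc_down = fc_down, q_max = q_max)
    note("calls: %s",
         paste(sprintf("%s=%d", names(cl),
                       vapply(cl, function(x) length(called_genes(x)), 0L)),
               collapse = ", "))
    cl
  })

  if (!is.null(expression2) && !is.null(annotations2)) {
    calls <- stage("cross_dataset_validate", {
      groups2 <- assign_groups(annotations2)
      keep2 <- intersect(rownames(expression2), catalog$symbol)
      mat2 <- expression2[keep2, , drop = FALSE]
      if (anyNA(mat2)) mat2 <- impute_knn(mat2)
      normal2 <- group_samples(groups2, "normal")
      out <- calls
      for (grp in names(out)) {
        s2 <- group_samples(groups2, grp)
        if (length(s2) < 2 || length(normal2) < 2) next
        sam2 <- run_sam(mat2, normal2, s2, sam)
        out[[grp]] <- cross_dataset_validate(out[[grp]], sam2, keep2,
                                             fc_up, fc_down, q_max)
      }
      n_val <- sum(vapply(out, function(x)
        sum((x$validation %||% "untested") == "validated"), 0L))
      note("validation: %d calls validated in second dataset", n_val)
      out
    })
  }

  pathways <- stage("pathway_union", {
    pw <- list(mutated = intersect(c("TaG1G2_mut", "T1_mut", "T24_mut"), active),
               non_mutated = intersect(c("TaG3_nonmut", "T1_nonmut",
                                         "T24_nonmut"), active))
    pw <- pw[lengths(pw) > 0]
    u <- pathway_union(calls, pw)
    note("pathways: %s",
         paste(sprintf("%s %d up / %d down", names(u),
                       lengths(lapply(u, `[[`, "up")),
                       lengths(lapply(u, `[[`, "down"))), collapse = "; "))
    u
  })

  stroma <- NULL
  if (!is.null(cell_lines) && !is.null(nhu)) {
    stroma <- stage("stroma_filter", {
      up_all <- sort(unique(unlist(lapply(unclass(pathways), `[[`, "up"))))
      sf <- stroma_filter(up_all, cell_lines, nhu)
      note("stroma: %d of %d up-regulated genes retained",
           sum(sf$retained), nrow(sf))
      # flagged genes leave the pathway up-lists
      flagged <- sf$gene[!sf$retained]
      for (p in names(pathways))
        pathways[[p]]$up <- setdiff(pathways[[p]]$up, flagged)
      sf
    })
  }

  specific <- stage("pathway_specific", {
    stage_pairs <- list(c("TaG3_nonmut", "TaG1G2_mut"),
                        c("T1_nonmut", "T1_mut"),
                        c("T24_nonmut", "T24_mut"))
    out <- list()
    for (pw in names(pathways)) {
      acc <- list(up = character(), down = character())
      for (pair in stage_pairs) {
        own <- if (pw == "non_mutated") pair[1] else pair[2]
        opp <- if (pw == "non_mutated") pair[2] else pair[1]
        s_own <- group_samples(groups, own)
        s_opp <- group_samples(groups, opp)
        if (length(s_own) < 2 || length(s_opp) < 2) next
        cross <- run_sam(mat, s_opp, s_own, sam)
        sp <- pathway_specific(pathways, cross, pw, fc_up, fc_down, q_max)
        acc$up <- union(acc$up, sp$up)
        acc$down <- union(acc$down, sp$down)
      }
      out[[pw]] <- acc
    }
    note("specific: %s",
         paste(sprintf("%s %d up / %d down", names(out),
                       lengths(lapply(out, `[[`, "up")),
                       lengths(lapply(out, `[[`, "down"))), collapse = "; "))
    out
  })

  enrichment <- stage("cluster_enrichment", {
    platform <- restrict_to_platform(catalog, rownames(mat))
    en <- enrich_all(calls, platform, alpha = cluster_alpha)
    note("enrichment: %d cluster x group tests, %d significant at %g",
         nrow(en), sum(en$significant), cluster_alpha)
    en
  })

  associations <- stage("marker_correlation", {
    markers <- intersect(all_markers, rownames(mat_full))
    ga <- group_samples(groups, corr_groups[1])
    gb <- group_samples(groups, corr_groups[2])
    if (length(markers) == 0 || length(ga) < 4 || length(gb) < 4) {
      note("associations: skipped (markers or reference groups unavailable)")
      NULL
    } else {
      dereg <- sort(unique(unlist(lapply(unclass(pathways),
                                         function(l) c(l$up, l$down)))))
      dereg <- setdiff(dereg, markers)
      at <- marker_association_table(mat_full, dereg, markers, ga, gb,
                                     corr_alpha)
      note("associations: %d gene x marker pairs, %d non-null verdicts",
           nrow(at), sum(at$verdict != "none"))
      at
    }
  })

  manifest <- list(
    thresholds = list(fc_up = fc_up, fc_down = fc_down, q_max = q_max,
                      cluster_alpha = cluster_alpha, corr_alpha = corr_alpha),
    sam = unclass(sam),
    n_genes = nrow(mat), n_samples = ncol(mat),
    groups = as.list(table(groups$group)),
    markers = list(proliferation = proliferation_markers,
                   differentiation = differentiation_markers))

  stage("write_outputs", {
    if (!is.null(out_dir)) {
      for (grp in names(sam_results))
        emit(sam_results[[grp]], sprintf("sam_%s.tsv", grp))
      all_calls <- do.call(rbind, lapply(names(calls), function(g)
        cbind(group = g, calls[[g]], stringsAsFactors = FALSE)))
      emit(all_calls, "deregulation_calls.tsv")
      pw_df <- do.call(rbind, lapply(names(pathways), function(p) {
        l <- pathways[[p]]
        if (length(l$up) + length(l$down) == 0) return(NULL)
        data.frame(pathway = p,
                   gene = c(l$up, l$down),
                   direction = rep(c("up", "down"),
                                   c(length(l$up), length(l$down))),
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(pw_df)) emit(pw_df, "pathway_lists.tsv")
      if (!is.null(stroma)) emit(stroma, "stroma_filter.tsv")
      sp_df <- do.call(rbind, lapply(names(specific), function(p) {
        l <- specific[[p]]
        if (length(l$up) + length(l$down) == 0) return(NULL)
        data.frame(pathway = p, gene = c(l$up, l$down),
                   direction = rep(c("up", "down"),
                                   c(length(l$up), length(l$down))),
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(sp_df) && nrow(sp_df))
        emit(sp_df, "pathway_specific.tsv")
      emit(enrichment, "cluster_enrichment.tsv")
      if (!is.null(associations)) emit(associations, "marker_associations.tsv")
      manifest_path <- file.path(out_dir, "manifest.json")
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      written <<- c(written, manifest_path)
      writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
    }
  })

  invisible(list(groups = groups, sam = sam_results, calls = calls,
                 pathways = pathways, stroma = stroma, specific = specific,
                 enrichment = enrichment, associations = associations,
                 log = log_lines, manifest = manifest))
}
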