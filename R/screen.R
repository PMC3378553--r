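#' Call up- and down-regulated genes from a SAM result
#'
#' Applies the study thresholds: a gene is called up-regulated when its fold
#' change strictly exceeds `fc_up` and its q-value is strictly below `q_max`
#' percent, and down-regulated when the fold change is strictly below
#' `fc_down` with the same q condition. Everything else is `none`. A fold
#' change sitting exactly on a threshold is therefore not called.
#'
#' @param sam A `sam_result` (see [run_sam()]) or any data frame with
#'   columns `gene`, `fc` and `q`.
#' @param fc_up Upper fold-change threshold (default 1.5).
#' @param fc_down Lower fold-change threshold (default 1/1.5 = 0.667).
#' @param q_max Maximum q-value in percent (default 5).
#' @return Data frame of class `dereg_calls` with columns `gene`, `fc`,
#'   `q`, `direction` (`up`/`down`/`none`).
#' @export
call_deregulated <- function(sam, fc_up = 1.5, fc_down = 1 / 1.5, q_max = 5) {
  stopifnot(all(c("gene", "fc", "q") %in% names(sam)))
  check_scalar_number(fc_up, "fc_up", lower = 0)
  check_scalar_number(fc_down, "fc_down", lower = 0)
  check_scalar_number(q_max, "q_max", lower = 0)
  if (!(fc_down < 1 && 1 < fc_up))
    stop_rs("need fc_down < 1 < fc_up (got %g, %g)", fc_down, fc_up)
  direction <- rep("none", nrow(sam))
  direction[sam$fc > fc_up & sam$q < q_max] <- "up"
  direction[sam$fc < fc_down & sam$q < q_max] <- "down"
  out <- data.frame(gene = sam$gene, fc = sam$fc, q = sam$q,
                    direction = direction, stringsAsFactors = FALSE)
  class(out) <- c("dereg_calls", "data.frame")
  out
}

#' Genes called in a set of calls
#' @param calls A `dereg_calls` data frame.
#' @param direction `"up"`, `"down"`, or `"any"`.
#' @return Character vector of gene symbols.
#' @export
called_genes <- function(calls, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "any") calls$direction != "none"
          else calls$direction == direction
  calls$gene[keep]
}

#' Per-pathway union of deregulation calls
#'
#' A pathway's deregulated-gene list is the union of the genes passing the
#' thresholds in at least one of its stage groups; the direction comes from
#' the passing calls. A gene called up in one group and down in another of
#' the same pathway is a conflict and raises an error.
#'
#' @param calls Named list mapping group name to a `dereg_calls` data frame.
#' @param pathways Named list mapping pathway name to the character vector
#'   of its group names; defaults to the two-pathway bladder model.
#' @return A list of class `pathway_lists`: per pathway, a list with
#'   character vectors `up` and `down` (sorted).
#' @export
pathway_union <- function(calls,
                          pathways = list(
                            mutated = c("TaG1G2_mut", "T1_mut", "T24_mut"),
                            non_mutated = c("TaG3_nonmut", "T1_nonmut",
                                            "T24_nonmut"))) {
  missing_groups <- setdiff(unlist(pathways), names(calls))
  if (length(missing_groups))
    stop_rs("calls missing for group(s): %s",
            paste(missing_groups, collapse = ", "))
  out <- lapply(pathways, function(groups) {
    up <- sort(unique(unlist(lapply(calls[groups], called_genes, "up"))))
    down <- sort(unique(unlist(lapply(calls[groups], called_genes, "down"))))
    conflict <- intersect(up, down)
    if (length(conflict))
      stop_rs("gene(s) up in one group and down in another of the same pathway: %s",
              paste(conflict, collapse = ", "))
    list(up = up, down = down)
  })
  class(out) <- "pathway_lists"
  out
}

#' Cross-dataset validation of deregulation calls
#'
#' A call from the first dataset is `validated` in a second, independent
#' dataset when at least one threshold passes there in the same direction:
#' either the second-dataset fold change passes the fold-change threshold in
#' the call's direction, or the second-dataset q-value is below `q_max` with
#' the fold change on the same side of 1. It is `discordant` when the second
#' dataset passes both thresholds in the opposite direction,
#' `not_significant` when neither criterion holds, and `untested` for genes
#' absent from the second platform. Uncalled genes (direction `none`) are
#' left `untested`.
#'
#' @param calls A `dereg_calls` data frame from the first dataset.
#' @param sam2 SAM result for the matching comparison in the second dataset.
#' @param genes_present2 Symbols measurable on the second platform.
#' @inheritParams call_deregulated
#' @return `calls` with an added `validation` column.
#' @export
cross_dataset_validate <- function(calls, sam2, genes_present2,
                                   fc_up = 1.5, fc_down = 1 / 1.5, q_max = 5) {
  stopifnot(inherits(calls, "dereg_calls"),
            all(c("gene", "fc", "q") %in% names(sam2)))
  validation <- rep("untested", nrow(calls))
  idx2 <- match(calls$gene, sam2$gene)
  for (i in seq_len(nrow(calls))) {
    dir <- calls$direction[i]
    if (dir == "none" || !(calls$gene[i] %in% genes_present2)) next
    if (is.na(idx2[i]))
      stop_rs("gene %s present on second platform but absent from sam2",
              calls$gene[i])
    fc2 <- sam2$fc[idx2[i]]; q2 <- sam2$q[idx2[i]]
    fc_pass_same <- if (dir == "up") fc2 > fc_up else fc2 < fc_down
    q_pass_same <- q2 < q_max && (if (dir == "up") fc2 > 1 else fc2 < 1)
    fc_pass_opp <- if (dir == "up") fc2 < fc_down else fc2 > fc_up
    validation[i] <-
      if (fc_pass_same || q_pass_same) "validated"
      else if (fc_pass_opp && q2 < q_max) "discordant"
      else "not_significant"
  }
  calls$validation <- validation
  calls
}

#' Stromal filter for up-regulated genes
#'
#' Tumor biopsies contain stroma, so apparent tumor up-regulation can come
#' from stromal rather than tumor cells. A gene is retained as
#' tumor-cell-intrinsic when at least one pure cancer cell line expresses it
#' at `min_fold` times (default 2, i.e. >= 1 log2 unit, inclusive) the mean
#' level of cultured normal human urothelial (NHU) cells; otherwise it is
#' flagged as potentially stromal. Only up-regulated genes need this filter;
#' down-regulated calls bypass it.
#'
#' @param up_genes Character vector of up-regulated gene symbols.
#' @param cell_lines Log2 expression matrix (genes x cancer cell lines).
#' @param nhu Log2 expression matrix (genes x NHU culture samples); the
#'   reference level per gene is the mean over its columns.
#' @param min_fold Linear fold threshold (default 2).
#' @return Data frame with columns `gene`, `max_log2_ratio` (best cell line
#'   vs NHU reference) and `retained` (logical; `FALSE` = stromal-flagged).
#' @export
stroma_filter <- function(up_genes, cell_lines, nhu, min_fold = 2) {
  stopifnot(is.matrix(cell_lines), is.matrix(nhu))
  missing_cl <- setdiff(up_genes, rownames(cell_lines))
  if (length(missing_cl))
    stop_rs("gene(s) missing from cell-line matrix: %s",
            paste(missing_cl, collapse = ", "))
  missing_nhu <- setdiff(up_genes, rownames(nhu))
  if (length(missing_nhu))
    stop_rs("gene(s) missing from NHU matrix: %s",
            paste(missing_nhu, collapse = ", "))
  ref <- rowMeans(nhu[up_genes, , drop = FALSE])
  best <- apply(cell_lines[up_genes, , drop = FALSE] - ref, 1, max)
  data.frame(gene = up_genes, max_log2_ratio = unname(best),
             retained = unname(best >= log2(min_fold)),
             stringsAsFactors = FALSE)
}

#' Genes specifically deregulated in one pathway
#'
#' Two-step specificity test. Step 1 keeps candidates deregulated in exactly
#' one pathway (per direction). Step 2 keeps a candidate only if the direct
#' SAM comparison of the candidate pathway's tumor group against the
#' same-stage group of opposite FGFR3 status also passes the fold-change and
#' q thresholds in the same direction.
#'
#' @param lists A `pathway_lists` (see [pathway_union()]).
#' @param cross_sam SAM result (or data frame with `gene`, `fc`, `q`) for
#'   the cross-pathway comparison, oriented so the candidate pathway is
#'   group 2 (its fold change is candidate-pathway over opposite-pathway).
#' @param pathway Name of the candidate pathway within `lists`.
#' @inheritParams call_deregulated
#' @return List with character vectors `up` and `down` of specific genes.
#' @export
pathway_specific <- function(lists, cross_sam, pathway,
                             fc_up = 1.5, fc_down = 1 / 1.5, q_max = 5) {
  stopifnot(inherits(lists, "pathway_lists"), pathway %in% names(lists))
  other <- setdiff(names(lists), pathway)
  other_genes <- unlist(lapply(unclass(lists)[other],
                               function(l) c(l$up, l$down)))
  cross_calls <- call_deregulated(cross_sam, fc_up, fc_down, q_max)
  keep <- function(genes, dir) {
    cand <- setdiff(genes, other_genes)   # step 1: unique to this pathway
    intersect(cand, called_genes(cross_calls, dir))  # step 2: cross passes
  }
  list(up = keep(lists[[pathway]]$up, "up"),
       down = keep(lists[[pathway]]$down, "down"))
}
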