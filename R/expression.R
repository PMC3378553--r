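#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' symbols. Cells hold log2-scale expression values; empty cells and the
#' literal `NA` mark missing values (to be filled by [impute_knn()]).
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix (genes x samples) with dimnames.
#' @seealso [write_expression()] for the lossless inverse.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = NULL)
  if (ncol(df) < 2) stop_rs("expression file needs a gene column plus samples")
  genes <- df[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop_rs("duplicate gene row(s): %s", paste(unique(dup), collapse = ", "))
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) stop_rs("duplicate sample column names")
  vals <- as.matrix(df[, -1, drop = FALSE])
  missing <- vals == "" | vals == "NA"
  num <- suppressWarnings(as.numeric(vals))
  bad <- !missing & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_rs("non-numeric cell '%s' at gene %s, sample %s",
            vals[bad][1], genes[idx[1]], samples[idx[2]])
  }
  num[missing] <- NA_real_
  matrix(num, nrow = length(genes), dimnames = list(genes, samples))
}

#' Write a log2 expression matrix as TSV
#'
#' Missing entries are written as empty cells; [read_expression()] round-trips
#' the result losslessly (values are written with full precision).
#'
#' @param mat Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  txt <- format(mat, digits = 17, trim = TRUE, scientific = FALSE)
  txt[is.na(mat)] <- ""
  df <- data.frame(gene = rownames(mat), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ANALYSIS_GROUPS <- c("TaG1G2_mut", "T1_mut", "T24_mut",
                     "TaG3_nonmut", "T1_nonmut", "T24_nonmut",
                     "normal", "excluded")

#' Read and validate a sample annotation table
#'
#' Columns: `sample`, `tissue` (`normal_urothelium`, `tumor`,
#' `cancer_cell_line`, `nhu_culture`), `stage` (`Ta`, `T1`, `T2_4` or `NA`),
#' `grade` (`G1`, `G2`, `G3` or `NA`), `fgfr3` (`mutated`, `non_mutated`, `NA`).
#' Tumor samples must have stage, grade and FGFR3 status set.
#'
#' @param path Path to annotation TSV.
#' @return Validated annotation data frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_annotations(df)
}

#' @rdname read_annotations
#' @param annotations An annotation data frame to validate in place.
#' @export
validate_annotations <- function(annotations) {
  required <- c("sample", "tissue", "stage", "grade", "fgfr3")
  if (!all(required %in% names(annotations)))
    stop_rs("annotations need columns %s", paste(required, collapse = ", "))
  df <- annotations[required]
  for (col in required) df[[col]] <- as.character(df[[col]])
  df[is.na(df)] <- "NA"
  if (anyDuplicated(df$sample)) stop_rs("duplicate sample id in annotations")
  vocab <- list(
    tissue = c("normal_urothelium", "tumor", "cancer_cell_line", "nhu_culture"),
    stage = c("Ta", "T1", "T2_4", "NA"),
    grade = c("G1", "G2", "G3", "NA"),
    fgfr3 = c("mutated", "non_mutated", "NA"))
  for (col in names(vocab)) {
    bad <- setdiff(unique(df[[col]]), vocab[[col]])
    if (length(bad))
      stop_rs("invalid %s value(s): %s", col, paste(bad, collapse = ", "))
  }
  tum <- df$tissue == "tumor"
  incomplete <- tum & (df$stage == "NA" | df$grade == "NA" | df$fgfr3 == "NA")
  if (any(incomplete))
    stop_rs("tumor sample(s) with missing stage/grade/fgfr3: %s",
            paste(df$sample[incomplete], collapse = ", "))
  df
}

#' Assign samples to the six analysis groups of the two-pathway model
#'
#' Bladder tumors are stratified by FGFR3 mutation status into two
#' progression pathways, each split by stage: the FGFR3-mutated (Ta-like)
#' pathway with groups TaG1G2, T1 and T2-4, and the FGFR3-non-mutated
#' (carcinoma-in-situ-like) pathway with groups TaG3, T1 and T2-4. Normal
#' urothelium forms the shared reference group. TaG3 mutated and TaG1/G2
#' non-mutated tumors fit neither pathway and are marked `excluded`
#' (never silently dropped); cell-line and NHU-culture samples are also
#' `excluded` from tumor-group analysis.
#'
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @return Data frame with columns `sample` and `group`; `group` is one of
#'   `TaG1G2_mut`, `T1_mut`, `T24_mut`, `TaG3_nonmut`, `T1_nonmut`,
#'   `T24_nonmut`, `normal`, `excluded`.
#' @export
assign_groups <- function(annotations) {
  df <- validate_annotations(annotations)
  group <- rep("excluded", nrow(df))
  group[df$tissue == "normal_urothelium"] <- "normal"
  tum <- df$tissue == "tumor"
  mut <- df$fgfr3 == "mutated"
  group[tum & mut & df$stage == "Ta" & df$grade %in% c("G1", "G2")] <- "TaG1G2_mut"
  group[tum & mut & df$stage == "T1"] <- "T1_mut"
  group[tum & mut & df$stage == "T2_4"] <- "T24_mut"
  group[tum & !mut & df$stage == "Ta" & df$grade == "G3"] <- "TaG3_nonmut"
  group[tum & !mut & df$stage == "T1"] <- "T1_nonmut"
  group[tum & !mut & df$stage == "T2_4"] <- "T24_nonmut"
  # Ta G3 mutated and Ta G1/G2 non-mutated stay "excluded"
  data.frame(sample = df$sample, group = group, stringsAsFactors = FALSE)
}

#' Sample ids belonging to one analysis group
#' @param groups Output of [assign_groups()].
#' @param group Group name.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(groups, group) {
  groups$sample[groups$group == group]
}

#' K-nearest-neighbour imputation of missing expression values
#'
#' Gene-wise KNN imputation in the style of the imputer bundled with the SAM
#' Excel add-in: for a missing entry (gene g, sample j), the k genes nearest
#' to g in Euclidean distance (computed over the samples where both genes are
#' observed, scaled to the full sample count) among genes observed at sample
#' j donate their values at j, and the mean fills the hole. Observed entries
#' are never modified. Distance ties are broken by matrix row order, making
#' the result deterministic.
#'
#' @param mat Numeric matrix, genes x samples, possibly with `NA` entries.
#' @param k Number of neighbour genes (default 10).
#' @return The matrix with all missing entries filled.
#' @export
impute_knn <- function(mat, k = 10) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  check_scalar_number(k, "k", lower = 1)
  miss <- is.na(mat)
  if (!any(miss)) return(mat)
  all_missing <- rowSums(!miss) == 0
  if (any(all_missing))
    stop_rs("gene(s) with all values missing: %s",
            paste(rownames(mat)[all_missing], collapse = ", "))
  out <- mat
  nsamp <- ncol(mat)
  for (g in which(rowSums(miss) > 0)) {
    for (j in which(miss[g, ])) {
      cand <- which(!miss[, j] & seq_len(nrow(mat)) != g)
      # scaled Euclidean distance over co-observed samples
      d <- vapply(cand, function(h) {
        co <- !miss[g, ] & !miss[h, ]
        if (!any(co)) return(Inf)
        sqrt(sum((mat[g, co] - mat[h, co])^2) * nsamp / sum(co))
      }, 0)
      cand <- cand[is.finite(d)]
      d <- d[is.finite(d)]
      if (length(cand) < k)
        stop_rs("k = %d exceeds the %d usable neighbour genes for %s at %s",
                k, length(cand), rownames(mat)[g], colnames(mat)[j])
      nb <- cand[order(d)[seq_len(k)]]
      out[g, j] <- mean(mat[nb, j])
    }
  }
  out
}
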