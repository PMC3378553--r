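# shared fixture builders and loaders

extdata <- function(file) {
  path <- system.file("extdata", file, package = "rabscreen")
  if (!nzchar(path)) stop("missing extdata fixture: ", file)
  path
}

fixture_catalog <- function() load_catalog(extdata("rab_catalog.tsv"))

fixture_platform <- function(catalog = fixture_catalog()) {
  absent <- readLines(extdata("u133_absent_genes.txt"))
  restrict_to_platform(catalog, setdiff(catalog$symbol, absent))
}

# the first bladder cohort: 4 normal urothelium + 152 tumors
first_cohort_annotation <- function() {
  blocks <- list(
    list(n = 4,  tissue = "normal_urothelium", stage = "NA", grade = "NA", fgfr3 = "NA"),
    list(n = 28, tissue = "tumor", stage = "Ta", grade = "G1", fgfr3 = "mutated"),
    list(n = 2,  tissue = "tumor", stage = "Ta", grade = "G3", fgfr3 = "mutated"),
    list(n = 13, tissue = "tumor", stage = "T1", grade = "G2", fgfr3 = "mutated"),
    list(n = 9,  tissue = "tumor", stage = "T2_4", grade = "G3", fgfr3 = "mutated"),
    list(n = 9,  tissue = "tumor", stage = "Ta", grade = "G2", fgfr3 = "non_mutated"),
    list(n = 3,  tissue = "tumor", stage = "Ta", grade = "G3", fgfr3 = "non_mutated"),
    list(n = 25, tissue = "tumor", stage = "T1", grade = "G3", fgfr3 = "non_mutated"),
    list(n = 63, tissue = "tumor", stage = "T2_4", grade = "G3", fgfr3 = "non_mutated"))
  rows <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    data.frame(sample = sprintf("S%02d_%02d", i, seq_len(b$n)),
               tissue = b$tissue, stage = b$stage, grade = b$grade,
               fgfr3 = b$fgfr3, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# cohort reference FC/q tables reshaped to one sam-like data frame per group
cohort_group_stats <- function(file, groups) {
  df <- utils::read.delim(extdata(file), stringsAsFactors = FALSE)
  out <- lapply(groups, function(g)
    data.frame(gene = df$gene,
               fc = df[[paste0("fc_", g)]],
               q = df[[paste0("q_", g)]],
               stringsAsFactors = FALSE))
  names(out) <- groups
  out
}

nonmut_cohort_stats <- function()
  cohort_group_stats("bladder_nonmut_pathway_sam.tsv",
                     c("TaG3_nonmut", "T1_nonmut", "T24_nonmut"))

mut_cohort_stats <- function()
  cohort_group_stats("bladder_mut_pathway_sam.tsv",
                     c("TaG1G2_mut", "T1_mut", "T24_mut"))

rab27_cohort_stats <- function()
  cohort_group_stats("rab27_cluster_sam.tsv",
                     c("TaG3_nonmut", "T1_nonmut", "T24_nonmut",
                       "TaG1G2_mut", "T1_mut", "T24_mut"))

# per-group deregulation calls from the printed cohort tables (both pathways)
cohort_calls <- function() {
  lapply(c(nonmut_cohort_stats(), mut_cohort_stats()), call_deregulated)
}
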