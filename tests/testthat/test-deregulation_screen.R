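test_that("thresholding the Rab27 cluster reference statistics reproduces the published call pattern", {
  stats <- rab27_cohort_stats()
  counts <- vapply(stats, function(s) length(called_genes(call_deregulated(s))), 0L)
  expect_equal(unname(counts[c("TaG3_nonmut", "T1_nonmut", "T24_nonmut",
                               "TaG1G2_mut", "T1_mut", "T24_mut")]),
               c(2, 3, 5, 4, 2, 4))
  t24 <- call_deregulated(stats$T24_nonmut)
  expect_setequal(called_genes(t24, "down"),
                  c("GCC2", "MLPH", "RPH3AL", "SYTL1", "SYTL2"))
  # RAB27B in that group fails on q (0.506 / 5.43) despite passing FC
  expect_equal(t24$direction[t24$gene == "RAB27B"], "none")
})

test_that("deregulation thresholds use strict inequalities", {
  sam <- data.frame(gene = c("a", "b", "c", "d"),
                    fc = c(1.5, 1.5001, 1 / 1.5, 0.666),
                    q = c(0, 0, 0, 0))
  calls <- call_deregulated(sam)
  expect_equal(calls$direction, c("none", "up", "none", "down"))
  # q exactly at the threshold is not called
  sam2 <- data.frame(gene = "e", fc = 3, q = 5)
  expect_equal(call_deregulated(sam2)$direction, "none")
  expect_error(call_deregulated(sam, fc_up = 0.9), "fc_down < 1 < fc_up")
})

test_that("calling is monotone in the thresholds", {
  set.seed(5)
  sam <- data.frame(gene = sprintf("g%02d", 1:50),
                    fc = 2^rnorm(50), q = runif(50, 0, 20))
  base <- called_genes(call_deregulated(sam))
  wide <- called_genes(call_deregulated(sam, fc_up = 1.2, fc_down = 0.8,
                                        q_max = 10))
  expect_true(all(base %in% wide))
})

test_that("pathway union reproduces the published per-pathway gene lists", {
  calls <- cohort_calls()
  lists <- pathway_union(calls)
  expect_equal(length(lists$non_mutated$down), 19)
  expect_equal(length(lists$non_mutated$up), 12)
  expect_equal(length(lists$mutated$down), 21)
  expect_equal(length(lists$mutated$up), 4)
  # overall: 30 down, 13 up; 13 genes common to both pathways (10 down, 3 up)
  expect_equal(length(union(lists$non_mutated$down, lists$mutated$down)), 30)
  expect_equal(length(union(lists$non_mutated$up, lists$mutated$up)), 13)
  common_down <- intersect(lists$non_mutated$down, lists$mutated$down)
  common_up <- intersect(lists$non_mutated$up, lists$mutated$up)
  expect_equal(length(common_down), 10)
  expect_setequal(common_up, c("CAV1", "ITGA5", "MICAL1"))
  # invariant to group ordering
  expect_identical(pathway_union(rev(calls)), lists)
})

test_that("pathway union surfaces within-pathway direction conflicts", {
  mk <- function(gene, dir) {
    df <- data.frame(gene = gene, fc = if (dir == "up") 2 else 0.5, q = 1)
    call_deregulated(df)
  }
  calls <- list(TaG3_nonmut = mk("X", "up"), T1_nonmut = mk("X", "down"),
                T24_nonmut = mk("Y", "up"))
  expect_error(pathway_union(calls, list(non_mutated = names(calls))),
               "up in one group and down in another")
  expect_error(pathway_union(calls[1:2], list(non_mutated = c("TaG3_nonmut",
                                                              "missing"))),
               "missing")
})

test_that("cross-dataset validation applies the one-threshold rule", {
  call1 <- call_deregulated(data.frame(gene = c("A", "B", "C", "D", "E"),
                                       fc = c(0.4, 0.4, 0.4, 2.2, 0.4),
                                       q = c(1, 1, 1, 1, 1)))
  sam2 <- data.frame(gene = c("A", "B", "C", "D"),
                     fc = c(0.60, 0.90, 1.80, 0.95),
                     q = c(20, 50, 2, 3))
  out <- cross_dataset_validate(call1, sam2, genes_present2 = c("A", "B", "C", "D"))
  v <- setNames(out$validation, out$gene)
  expect_equal(v[["A"]], "validated")        # FC passes, q does not
  expect_equal(v[["B"]], "not_significant")  # neither criterion
  expect_equal(v[["C"]], "discordant")       # both pass in reverse
  expect_equal(v[["E"]], "untested")         # absent from second platform
  # q-only pass requires the FC on the same side of 1: D called up, fc2 < 1
  expect_equal(v[["D"]], "not_significant")
  # q-only pass with agreeing side validates
  sam3 <- data.frame(gene = "A", fc = 0.9, q = 2)
  out3 <- cross_dataset_validate(call1[call1$gene == "A", ], sam3, "A")
  expect_equal(out3$validation, "validated")
})

test_that("stromal filter retains genes 2-fold above NHU in any line", {
  genes <- c("CAV1", "ITGA5", "KIF20A", "LEPRE1", "MICAL1", "MICAL2",
             "RAB23", "RAB31", "RABAC1", "SDC1", "STXBP1", "TMEM22", "ZWINT")
  stromal <- c("MICAL1", "RABAC1", "SDC1")
  nhu <- matrix(8, length(genes), 2,
                dimnames = list(genes, c("NHU_1", "NHU_2")))
  lines <- matrix(8, length(genes), 7,
                  dimnames = list(genes, paste0("CL", 1:7)))
  for (g in setdiff(genes, stromal)) lines[g, sample(7, 1)] <- 9.7
  for (g in stromal) lines[g, ] <- 8 + runif(7, -0.5, 0.9)  # all below 2x
  res <- stroma_filter(genes, lines, nhu)
  expect_setequal(res$gene[!res$retained], stromal)
  expect_equal(sum(res$retained), 10)
  # boundary: exactly 2-fold retains (inclusive threshold)
  one <- stroma_filter("CAV1",
                       matrix(9, 1, 1, dimnames = list("CAV1", "L1")),
                       matrix(8, 1, 2, dimnames = list("CAV1", c("n1", "n2"))))
  expect_true(one$retained)
  # all lines below NHU: flagged
  low <- stroma_filter("CAV1",
                       matrix(7, 1, 3, dimnames = list("CAV1", paste0("L", 1:3))),
                       matrix(8, 1, 2, dimnames = list("CAV1", c("n1", "n2"))))
  expect_false(low$retained)
  # adding a line that never exceeds the current maximum changes nothing
  lines2 <- cbind(lines, extra = lines[, 1] - 1)
  expect_equal(stroma_filter(genes, lines2, nhu)$retained, res$retained)
  expect_error(stroma_filter(c(genes, "NOPE"), lines, nhu), "NOPE")
})

test_that("pathway specificity keeps candidates confirmed by the cross-pathway comparison", {
  calls <- cohort_calls()
  lists <- pathway_union(calls)
  cross <- utils::read.delim(extdata("bladder_pathway_specific_sam.tsv"))
  cross_sam <- data.frame(gene = cross$gene, fc = cross$fc_cross,
                          q = cross$q_cross)
  sp <- pathway_specific(lists, cross_sam, "non_mutated")
  expect_setequal(sp$down, "SYTL1")
  expect_setequal(sp$up, c("LEPRE1", "MICAL2", "RAB23", "STXBP1"))
  # genes deregulated in both pathways are excluded at step 1 regardless
  both <- intersect(lists$non_mutated$up, lists$mutated$up)
  fake_cross <- data.frame(gene = both, fc = 10, q = 0)
  expect_equal(pathway_specific(lists, fake_cross, "non_mutated")$up,
               character())
  # candidates failing the cross comparison vanish
  sp_mut <- pathway_specific(lists, cross_sam, "mutated")
  expect_equal(sp_mut$up, character())
  expect_equal(sp_mut$down, character())
})
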