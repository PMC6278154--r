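csi_fixture <- function(seed = 31, presence = 1, jitter = 0L,
                        start = 21, end = 45) {
  truth <- synthetic_truth(70, c(E = 40, T = 40),
                           csis = list(list(clade = "E", col_start = start,
                                            col_end = end,
                                            presence = presence,
                                            length_jitter = jitter)),
                           conserved_frac = 0)
  generate_msa(truth, seed)
}

test_that("a clean planted insert is recovered with exact boundaries", {
  g <- csi_fixture()
  calls <- call_csis(g$alignment, g$groups)
  expect_length(calls, 1)
  expect_equal(calls[[1]]$clade, "E")
  expect_equal(calls[[1]]$col_start, 21)
  expect_equal(calls[[1]]$col_end, 45)
  expect_equal(calls[[1]]$occupancy_in, 1)
  expect_equal(calls[[1]]$occupancy_out_max, 0)
  # every clade member carries the full 25 residues
  expect_true(all(calls[[1]]$per_sequence_length == 25))
  rec <- truth_compare(calls, g$truth, "csi")
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$precision, 1)
  expect_equal(rec$boundary_error, 0)
})

test_that("a longer subclade-only insert is recovered at default thresholds", {
  g <- csi_fixture(seed = 8, presence = 0.7, start = 16, end = 55)
  calls <- call_csis(g$alignment, g$groups)
  expect_length(calls, 1)
  expect_equal(calls[[1]]$col_start, 16)
  expect_equal(calls[[1]]$col_end, 55)
})

test_that("columns occupied across clades are never called", {
  aln <- mk_aln(rep("ACDEFGHIKL", 8), paste0("s", 1:8))
  ga <- group_assignment(list(E = paste0("s", 1:4), T = paste0("s", 5:8)))
  expect_length(call_csis(aln, ga), 0)
})

test_that("noisy insert boundaries stay within the gap-run tolerance", {
  g <- csi_fixture(seed = 12, jitter = 3L)
  calls <- call_csis(g$alignment, g$groups)
  rec <- truth_compare(calls, g$truth, "csi")
  expect_equal(rec$sensitivity, 1)
  expect_lte(rec$boundary_error, 2) # the default max_gap_run
})

test_that("calls are invariant to row order and to non-focal relabeling", {
  g <- csi_fixture(seed = 40)
  calls <- call_csis(g$alignment, g$groups)
  set.seed(1)
  ord <- sample(length(g$alignment$ids))
  aln_p <- mk_aln(apply(g$alignment$mat[ord, ], 1, paste, collapse = ""),
                  g$alignment$ids[ord])
  ga2 <- group_assignment(list(E = g$groups$groups$E,
                               OTHER = g$groups$groups$T))
  calls2 <- call_csis(aln_p, ga2)
  expect_equal(calls2[[1]]$col_start, calls[[1]]$col_start)
  expect_equal(calls2[[1]]$col_end, calls[[1]]$col_end)
  nm <- sort(names(calls[[1]]$per_sequence_length))
  expect_equal(calls2[[1]]$per_sequence_length[nm],
               calls[[1]]$per_sequence_length[nm])
})

test_that("tightening theta_out or min_len never creates new calls", {
  g <- csi_fixture(seed = 55, jitter = 2L)
  loose <- call_csis(g$alignment, g$groups, theta_out = 0.2, min_len = 5)
  tight <- call_csis(g$alignment, g$groups, theta_out = 0.05, min_len = 10)
  key <- function(calls) vapply(calls, function(cl) {
    paste(cl$clade, cl$col_start, cl$col_end)
  }, "")
  # every tight call lies within some loose call
  for (cl in tight) {
    inside <- any(vapply(loose, function(lo) {
      lo$clade == cl$clade && lo$col_start <= cl$col_start &&
        lo$col_end >= cl$col_end
    }, TRUE))
    expect_true(inside)
  }
})

test_that("logo frequencies are weighted, gap-aware and normalised", {
  aln <- mk_aln(c("AA--", "AA--", "AL--", "AL--", "--CC", "--CC"),
                paste0("s", 1:6))
  ga <- group_assignment(list(E = paste0("s", 1:4), T = paste0("s", 5:6)))
  calls <- call_csis(aln, ga, min_len = 2, theta_in = 0.5, theta_out = 0.1)
  expect_length(calls, 2) # E block (cols 1-2) and T block (cols 3-4)
  lg <- csi_logo(aln, calls[[1]], ga)
  expect_equal(unname(lg[1, "A"]), 1)
  expect_equal(unname(lg[2, "A"]), 0.5)
  expect_equal(unname(lg[2, "L"]), 0.5)
  expect_equal(unname(rowSums(lg)), rep(1, 2), tolerance = 1e-12)
})

test_that("tree annotation reports per-leaf insert lengths", {
  g <- csi_fixture(seed = 61, jitter = 3L)
  calls <- call_csis(g$alignment, g$groups)
  ann <- csi_tree_annotation(calls, g$tree, g$alignment)
  col <- grep("^csi1", names(ann), value = TRUE)
  members <- g$groups$groups$E
  expect_equal(sort(ann$leaf), sort(g$alignment$ids))
  expect_true(all(ann[[col]][ann$leaf %in% members] ==
                    calls[[1]]$per_sequence_length[
                      ann$leaf[ann$leaf %in% members]]))
  expect_true(all(ann[[col]][!ann$leaf %in% members] == 0))
  # lengths vary within the clade when jitter is planted
  expect_gt(length(unique(ann[[col]][ann$leaf %in% members])), 1)
})

test_that("CSI contract violations are refused", {
  aln <- mk_aln(c("ACDE", "ACDE"))
  expect_error(call_csis(aln, group_assignment(list(A = aln$ids))),
               "at least two groups")
  ga <- group_assignment(list(A = "s1", B = "s2"))
  expect_error(call_csis(aln, ga, theta_in = 0.3, theta_out = 0.5),
               "theta_out")
})
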