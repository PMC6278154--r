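test_that("pairwise MI matches hand-derived joint-table values", {
  # (A,A,R,R) vs (L,L,V,V): one-to-one 2x2 joint, MI = ln 2
  aln <- mk_aln(c("AL", "AL", "RV", "RV"))
  mi <- pairwise_mi(aln, pseudocount = 0)
  expect_equal(mi$mi_raw, log(2), tolerance = 1e-12)

  # product-form joint: MI = 0
  aln2 <- mk_aln(c("AL", "AV", "RL", "RV"))
  expect_equal(pairwise_mi(aln2, pseudocount = 0)$mi_raw, 0,
               tolerance = 1e-12)

  # conserved column: no variation, no information as the pseudocount
  # vanishes (the flat pseudocount itself carries off-diagonal mass, which
  # the shuffle null later absorbs)
  set.seed(1)
  rows <- paste0("A", sample(c("L", "V"), 100, replace = TRUE))
  aln3 <- mk_aln(rows, paste0("s", 1:100))
  expect_equal(pairwise_mi(aln3, pseudocount = 0)$mi_raw, 0,
               tolerance = 1e-12)
  expect_lte(pairwise_mi(aln3, pseudocount = 1e-3)$mi_raw, 0.01)
})

test_that("module MI equals the brute-force oracle on small alignments", {
  set.seed(99)
  for (rep in 1:15) {
    n <- sample(4:10, 1)
    p <- sample(3:10, 1)
    rows <- replicate(n, paste(sample(c(AA20_h, "-", "X"), p, replace = TRUE,
                                      prob = c(rep(2, 20), 3, 1)),
                               collapse = ""))
    aln <- mk_aln(rows)
    w <- setNames(runif(n, 0.2, 2), aln$ids)
    pc <- sample(c(0, 0.05, 0.2), 1)
    mi <- pairwise_mi(aln, w, columns = 1:p, pseudocount = pc,
                      min_occupancy = 0)
    pc_total <- pc * sum(w)
    for (r in seq_len(nrow(mi))) {
      ora <- mi_oracle(aln$mat[, mi$col_i[r]], aln$mat[, mi$col_j[r]],
                       w, pc_total)
      expect_equal(mi$mi_raw[r], ora, tolerance = 1e-12)
      expect_gte(mi$mi_raw[r], 0)
    }
  }
})

test_that("APC closed forms hold", {
  # all pairwise MI equal: correction removes everything
  cols <- c(1, 2, 3, 4)
  mi <- data.frame(col_i = c(1, 1, 1, 2, 2, 3), col_j = c(2, 3, 4, 3, 4, 4),
                   mi_raw = 0.7)
  apc <- apc_correct(mi)
  expect_equal(apc$mi_apc, rep(0, 6), tolerance = 1e-12)

  # all-zero MI: zero stays zero (warning: mean is 0)
  mi0 <- mi
  mi0$mi_raw <- 0
  expect_warning(apc0 <- apc_correct(mi0), "APC skipped")
  expect_equal(apc0$mi_apc, rep(0, 6))

  # mi(1,2) = mi(1,3) = c, mi(2,3) = 0: apc(2,3) = -3c/8
  mi3 <- data.frame(col_i = c(1, 1, 2), col_j = c(2, 3, 3),
                    mi_raw = c(0.4, 0.4, 0))
  apc3 <- apc_correct(mi3)
  expect_lt(apc3$mi_apc[3], 0)
  expect_equal(apc3$mi_apc[3], -3 * 0.4 / 8, tolerance = 1e-12)

  expect_error(apc_correct(data.frame(col_i = 1, col_j = 2, mi_raw = 1)),
               "at least 3")
})

test_that("a planted deterministic pair attains the top z-score", {
  truth <- synthetic_truth(52, c(A = 50, B = 50),
                           pair_columns = rbind(c(25, 26)), rho = 1,
                           conserved_frac = 0)
  g <- generate_msa(truth, 5)
  cov <- mi_zscores(g$alignment, n_shuffles = 60, seed = 9)
  top <- cov$pairs[which.max(cov$pairs$z), ]
  expect_equal(c(top$col_i, top$col_j), c(25, 26))
  # no self-pairs
  expect_true(all(cov$pairs$col_i < cov$pairs$col_j))
})

test_that("near-conserved pairs are flagged degenerate, not infinite", {
  rows <- c(rep("AAQ", 30), "AAL", "CAV")
  aln <- mk_aln(rows, paste0("s", 1:32))
  cov <- mi_zscores(aln, n_shuffles = 50, seed = 3, min_occupancy = 0,
                    pseudocount = 0)
  # columns 1 and 2 are (near-)constant: their pair has null sd 0
  pair12 <- cov$pairs[cov$pairs$col_i == 1 & cov$pairs$col_j == 2, ]
  expect_true(pair12$degenerate)
  expect_equal(pair12$z, 0)
  expect_true(all(is.finite(cov$pairs$z)))
})

test_that("observed MI and APC are invariant to sequence order", {
  set.seed(21)
  rows <- replicate(20, paste(sample(AA20_h[1:6], 8, replace = TRUE),
                              collapse = ""))
  aln <- mk_aln(rows)
  ord <- sample(20)
  aln_p <- mk_aln(rows[ord], aln$ids[ord])
  m1 <- apc_correct(pairwise_mi(aln, pseudocount = 0))
  m2 <- apc_correct(pairwise_mi(aln_p, pseudocount = 0))
  expect_equal(m1$mi_raw, m2$mi_raw, tolerance = 1e-12)
  expect_equal(m1$mi_apc, m2$mi_apc, tolerance = 1e-12)
})

test_that("shuffle-null contracts are enforced", {
  aln <- mk_aln(c("ACDE", "ACDF", "GHIK", "GHIL"))
  expect_error(mi_zscores(aln, n_shuffles = 60), "seed")
  expect_error(mi_zscores(aln, n_shuffles = 10, seed = 1), "n_shuffles")
  expect_error(pairwise_mi(mk_aln(c("A", "C"))), "fewer than 2")
})
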