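#' Scan for cluster-determining positions (CDPs)
#'
#' A CDP is an alignment column whose residue composition is significantly
#' associated with membership of one of two clades. The statistic per column
#' is the weighted mutual information `I(residue; clade)` in nats, computed
#' over sequences that are non-gap at the column with identity-cluster
#' weights (weights renormalise per column, keeping frequencies proper).
#'
#' Significance comes from a label-permutation null: clade labels are
#' permuted `n_perm` times and the statistic recomputed for every column
#' under each permutation. Labels are permuted at the identity-cluster
#' level — whole clusters swap labels together — so near-identical sequences
#' do not make the null anti-conservative. One permutation per replicate is
#' applied to all columns, preserving between-column dependence.
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`;
#' `z = (observed - null mean) / null sd`.
#'
#' @param aln an [alignment()].
#' @param groups a [group_assignment()] with exactly two groups (or a
#'   `focal_pair` naming the two to contrast).
#' @param weights a [cluster_weights()] result (or named numeric vector;
#'   `NULL` for unit weights, in which case permutation is per sequence).
#' @param n_perm number of label permutations, at least 99.
#' @param alpha significance level applied after adjustment.
#' @param adjust multiple-testing adjustment, `"bh"` or `"bonferroni"`.
#' @param seed integer seed; required (reproducibility contract).
#' @param column_map optional [build_column_map()] to annotate reference
#'   positions.
#' @return A data.frame of class `cdp_result` with one row per column:
#'   `column`, `ref_position`, `statistic`, `p_value`, `p_adjusted`, `z`,
#'   `is_cdp`. Attributes record `n_perm`, `alpha`, `adjust`, `seed` and the
#'   contrasted group labels.
#' @export
cdp_scan <- function(aln, groups, weights = NULL, n_perm = 999L,
                     alpha = 0.05, adjust = c("bh", "bonferroni"),
                     seed, column_map = NULL) {
  adjust <- match.arg(adjust)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for the permutation null")
  }
  if (n_perm < 99L) stop("n_perm must be at least 99")
  pair <- focal_groups(groups)
  ids_a <- intersect(aln$ids, groups$groups[[pair[1L]]])
  ids_b <- intersect(aln$ids, groups$groups[[pair[2L]]])
  if (length(ids_a) == 0L || length(ids_b) == 0L) {
    stop("both groups must have sequences present in the alignment")
  }
  ids <- c(ids_a, ids_b)
  sub <- subset_alignment(aln, ids)
  X <- encode_alignment(sub)
  w <- resolve_weights(weights, ids)
  g <- c(rep(1L, length(ids_a)), rep(2L, length(ids_b)))
  for (k in 1:2) {
    if (all(X[g == k, , drop = FALSE] == 0L)) {
      stop("group '", pair[k], "' has zero non-gap residues at every column")
    }
  }

  obs <- group_mi_kernel(X, w, g)

  # cluster-level label permutation: each identity cluster carries one label
  cl <- if (inherits(weights, "sequence_weights")) {
    unname(weights$cluster[ids])
  } else {
    seq_along(ids) # no cluster structure known: per-sequence permutation
  }
  cl <- match(cl, unique(cl))
  cl_label <- vapply(split(g, cl), function(v) {
    as.integer(names(which.max(table(v))))
  }, integer(1))

  set.seed(as.integer(seed))
  null_ge <- numeric(length(obs))
  null_sum <- numeric(length(obs))
  null_sumsq <- numeric(length(obs))
  for (b in seq_len(n_perm)) {
    gp <- cl_label[sample(length(cl_label))][cl]
    mi_b <- group_mi_kernel(X, w, gp)
    null_ge <- null_ge + (mi_b >= obs)
    null_sum <- null_sum + mi_b
    null_sumsq <- null_sumsq + mi_b^2
  }
  p <- (1 + null_ge) / (n_perm + 1)
  mu <- null_sum / n_perm
  sdv <- sqrt(pmax(0, null_sumsq / n_perm - mu^2) * n_perm / (n_perm - 1))
  z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  p_adj <- p.adjust(p, method = if (adjust == "bh") "BH" else "bonferroni")

  out <- data.frame(column = seq_len(ncol(X)),
                    ref_position = if (is.null(column_map)) NA_integer_ else
                      map_col_to_ref(column_map, seq_len(ncol(X))),
                    statistic = obs,
                    p_value = p,
                    p_adjusted = p_adj,
                    z = z,
                    is_cdp = p_adj <= alpha & obs > 0)
  attr(out, "n_perm") <- n_perm
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  attr(out, "seed") <- as.integer(seed)
  attr(out, "groups") <- pair
  class(out) <- c("cdp_result", "data.frame")
  out
}

focal_groups <- function(groups) {
  if (!inherits(groups, "group_assignment")) {
    stop("groups must be a group_assignment")
  }
  if (!is.null(groups$focal_pair)) return(groups$focal_pair)
  if (length(groups$groups) != 2L) {
    stop("a two-group contrast needs exactly two groups or a focal_pair")
  }
  names(groups$groups)
}

#' Extract the CDP columns from a scan
#' @param cdps a [cdp_scan()] result (or an integer vector, returned as-is).
#' @return Integer vector of CDP columns.
#' @export
cdp_columns <- function(cdps) {
  if (is.numeric(cdps)) return(as.integer(cdps))
  if (!inherits(cdps, "cdp_result")) stop("not a cdp_result")
  cdps$column[cdps$is_cdp]
}

#' Write the CDP report as TSV
#' @param cdps a [cdp_scan()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cdp_report <- function(cdps, path) {
  hdr <- sprintf("# cdp_scan: groups=%s vs %s, n_perm=%d, alpha=%g, adjust=%s, seed=%d",
                 attr(cdps, "groups")[1L], attr(cdps, "groups")[2L],
                 attr(cdps, "n_perm"), attr(cdps, "alpha"),
                 attr(cdps, "adjust"), attr(cdps, "seed"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(as.data.frame(cdps), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
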