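#' Call cluster-specific inserts (CSIs)
#'
#' A CSI is an alignment region occupied predominantly by one clade and
#' gapped in the others. Per clade, columns are marked where the weighted
#' in-clade occupancy reaches `theta_in` while every other clade stays at
#' or below `theta_out`; marked columns are merged into maximal runs
#' tolerating up to `max_gap_run` unmarked columns between them, and runs
#' of at least `min_len` columns are reported. Occupancy uses
#' identity-cluster weights so large shallow subclades do not dominate.
#'
#' A region shared by all clades but longer in one is called only over its
#' clade-exclusive portion — the part where the other clades fall below
#' `theta_out`.
#'
#' @param aln an [alignment()].
#' @param groups a [group_assignment()] with at least two groups.
#' @param weights optional [cluster_weights()] result or named vector.
#' @param theta_in minimum weighted in-clade occupancy.
#' @param theta_out maximum weighted occupancy in any other clade; must be
#'   below `theta_in`.
#' @param min_len minimum interval length in columns.
#' @param max_gap_run unmarked columns tolerated inside a run.
#' @return A list of class `csi_calls`; each element has `clade`,
#'   `col_start`, `col_end` (1-based inclusive), `occupancy_in`,
#'   `occupancy_out_max` (means over the marked columns of the interval)
#'   and `per_sequence_length` (named non-gap residue counts for the
#'   clade's members). Intervals per clade are non-overlapping and sorted.
#' @export
call_csis <- function(aln, groups, weights = NULL, theta_in = 0.5,
                      theta_out = 0.1, min_len = 5L, max_gap_run = 2L) {
  if (!inherits(groups, "group_assignment")) {
    stop("groups must be a group_assignment")
  }
  if (length(groups$groups) < 2L) {
    stop("CSI calling needs at least two groups to contrast")
  }
  if (!(theta_out < theta_in)) stop("theta_out must be below theta_in")
  occ <- clade_occupancy(aln, groups, weights)
  calls <- list()
  for (clade in rownames(occ)) {
    occ_in <- occ[clade, ]
    occ_out <- apply(occ[setdiff(rownames(occ), clade), , drop = FALSE],
                     2L, max)
    marked <- occ_in >= theta_in & occ_out <= theta_out
    for (run in merge_runs(which(marked), max_gap_run)) {
      if (run[2L] - run[1L] + 1L < min_len) next
      mk <- intersect(run[1L]:run[2L], which(marked))
      members <- intersect(aln$ids, groups$groups[[clade]])
      seg <- aln$mat[members, run[1L]:run[2L], drop = FALSE]
      calls[[length(calls) + 1L]] <- list(
        clade = clade,
        col_start = run[1L],
        col_end = run[2L],
        occupancy_in = mean(occ_in[mk]),
        occupancy_out_max = max(occ_out[mk]),
        per_sequence_length = setNames(
          as.integer(rowSums(seg != "-")), members))
    }
  }
  structure(calls, class = "csi_calls",
            theta_in = theta_in, theta_out = theta_out,
            min_len = min_len, max_gap_run = max_gap_run)
}

# weighted non-gap fraction per clade (rows) x column; 'X' counts as gap
clade_occupancy <- function(aln, groups, weights = NULL) {
  nongap <- aln$mat != "-" & aln$mat != "X"
  out <- matrix(0, nrow = length(groups$groups), ncol = aln$n_cols,
                dimnames = list(names(groups$groups), NULL))
  for (clade in names(groups$groups)) {
    members <- intersect(aln$ids, groups$groups[[clade]])
    if (length(members) == 0L) stop("group '", clade,
                                    "' has no sequences in the alignment")
    w <- resolve_weights(weights, members)
    out[clade, ] <- colSums(nongap[members, , drop = FALSE] * w) / sum(w)
  }
  out
}

# merge sorted marked positions into runs tolerating gaps <= max_gap_run;
# returns list of c(start, end) anchored on marked columns
merge_runs <- function(marked, max_gap_run) {
  if (length(marked) == 0L) return(list())
  breaks <- which(diff(marked) > max_gap_run + 1L)
  starts <- marked[c(1L, breaks + 1L)]
  ends <- marked[c(breaks, length(marked))]
  mapply(function(s, e) c(s, e), starts, ends, SIMPLIFY = FALSE)
}

#' @export
print.csi_calls <- function(x, ...) {
  cat("csi_calls:", length(x), "insert(s)\n")
  if (length(x) > 0L) print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.csi_calls <- function(x, ...) {
  do.call(rbind, lapply(x, function(cl) {
    data.frame(clade = cl$clade, col_start = cl$col_start,
               col_end = cl$col_end,
               length = cl$col_end - cl$col_start + 1L,
               occupancy_in = cl$occupancy_in,
               occupancy_out_max = cl$occupancy_out_max,
               median_seq_length = stats::median(cl$per_sequence_length))
  }))
}

#' Per-column residue frequency matrix of a CSI (logo input)
#'
#' For each column of the call's interval, the weighted residue frequencies
#' within the focal clade. Gaps (and `'X'`) are reported as a separate
#' `gap` fraction; each row sums to 1.
#'
#' @param aln an [alignment()].
#' @param call one element of a [call_csis()] result.
#' @param groups the [group_assignment()] the call was made against.
#' @param weights optional weights, as in [call_csis()].
#' @return A numeric matrix, rows = interval columns (named by column
#'   index), columns = 20 amino acids plus `gap`.
#' @export
csi_logo <- function(aln, call, groups, weights = NULL) {
  members <- intersect(aln$ids, groups$groups[[call$clade]])
  w <- resolve_weights(weights, members)
  cols <- call$col_start:call$col_end
  out <- matrix(0, nrow = length(cols), ncol = 21L,
                dimnames = list(cols, c(AA20, "gap")))
  for (k in seq_along(cols)) {
    res <- aln$mat[members, cols[k]]
    gap <- res == "-" | res == "X"
    out[k, "gap"] <- sum(w[gap]) / sum(w)
    for (a in AA20) out[k, a] <- sum(w[res == a]) / sum(w)
  }
  out
}

#' Per-leaf CSI insert lengths for tree annotation
#'
#' A table consumable by external tree viewers (e.g. as simple bars): per
#' tree leaf and per CSI, the number of residues that leaf carries in the
#' insert interval (0 when absent). Leaves missing from the alignment are
#' listed with empty (NA) lengths.
#'
#' @param calls a [call_csis()] result.
#' @param tree an `ape::phylo`, Newick string or file path.
#' @param aln the [alignment()] the calls were made on.
#' @return A data.frame: `leaf`, then one `csi<k>_<clade>` column per call.
#' @export
csi_tree_annotation <- function(calls, tree, aln) {
  phy <- as_phylo(tree)
  leaves <- phy$tip.label
  out <- data.frame(leaf = leaves)
  for (k in seq_along(calls)) {
    cl <- calls[[k]]
    cols <- cl$col_start:cl$col_end
    len <- rep(NA_integer_, length(leaves))
    present <- leaves %in% aln$ids
    len[present] <- as.integer(rowSums(
      aln$mat[leaves[present], cols, drop = FALSE] != "-"))
    out[[paste0("csi", k, "_", cl$clade)]] <- len
  }
  attr(out, "missing_leaves") <- setdiff(leaves, aln$ids)
  out
}

#' Write CSI calls as TSV
#' @param calls a [call_csis()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csi_report <- function(calls, path) {
  df <- as.data.frame(calls)
  if (is.null(df)) df <- data.frame()
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
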