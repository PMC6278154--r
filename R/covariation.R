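#' Pairwise mutual information between alignment columns
#'
#' For each unordered column pair, weighted joint residue counts are taken
#' over the sequences that are non-gap at both columns, a flat pseudocount
#' is added (total added mass = `pseudocount * n_clusters`, spread over the
#' 400 cells of the 20x20 joint table; a low-count correction in the
#' Buslje style), and mutual information is computed from the normalised
#' joint and marginal frequencies, in nats.
#'
#' Columns with non-gap fraction below `min_occupancy` are excluded; the
#' columns actually used are recorded in the result.
#'
#' @param aln an [alignment()].
#' @param weights a [cluster_weights()] result, named numeric vector, or
#'   `NULL` for unit weights.
#' @param columns optional integer vector restricting the scan; defaults to
#'   all columns passing the occupancy filter.
#' @param pseudocount flat pseudocount rate (mass per cluster).
#' @param min_occupancy minimum non-gap fraction for a column to be used.
#' @return A data.frame with `col_i`, `col_j` (`col_i < col_j`) and
#'   `mi_raw`; attribute `columns_used` lists the columns scanned.
#' @export
pairwise_mi <- function(aln, weights = NULL, columns = NULL,
                        pseudocount = 0.05, min_occupancy = 0.5) {
  X <- encode_alignment(aln)
  w <- resolve_weights(weights, aln$ids)
  n_clusters <- if (inherits(weights, "sequence_weights")) {
    weights$n_clusters
  } else {
    sum(w)
  }
  usable <- which(colMeans(X > 0L) >= min_occupancy)
  cols <- if (is.null(columns)) usable else intersect(as.integer(columns), usable)
  if (length(cols) < 2L) {
    stop("fewer than 2 usable columns (occupancy >= ", min_occupancy, ")")
  }
  mi <- mi_pairs_kernel(X, unname(w), cols, pseudocount * n_clusters)
  out <- pair_index_frame(cols)
  out$mi_raw <- mi
  attr(out, "columns_used") <- cols
  attr(out, "pseudocount") <- pseudocount
  out
}

# data.frame of (col_i, col_j) in the kernel's upper-triangle order
pair_index_frame <- function(cols) {
  m <- length(cols)
  i <- rep(seq_len(m - 1L), times = (m - 1L):1L)
  j <- unlist(lapply(seq_len(m - 1L), function(k) seq(k + 1L, m)),
              use.names = FALSE)
  data.frame(col_i = cols[i], col_j = cols[j])
}

#' Average-product correction of pairwise mutual information
#'
#' Removes the background component of raw MI that reflects per-column
#' conservation and phylogeny rather than genuine covariation:
#' `mi_apc(i,j) = mi_raw(i,j) - m(i) m(j) / m_bar`, where `m(i)` is the mean
#' raw MI of all pairs containing column `i` and `m_bar` the overall mean.
#' If `m_bar` is 0 the correction is skipped with a warning.
#'
#' @param mi a [pairwise_mi()] result (needs `col_i`, `col_j`, `mi_raw`
#'   over at least 3 columns).
#' @return The input with an added `mi_apc` column (may be negative).
#' @export
apc_correct <- function(mi) {
  cols <- sort(unique(c(mi$col_i, mi$col_j)))
  if (length(cols) < 3L) stop("APC needs pairs over at least 3 columns")
  idx_i <- match(mi$col_i, cols)
  idx_j <- match(mi$col_j, cols)
  k <- length(cols)
  col_sum <- numeric(k)
  for (r in seq_len(nrow(mi))) {
    col_sum[idx_i[r]] <- col_sum[idx_i[r]] + mi$mi_raw[r]
    col_sum[idx_j[r]] <- col_sum[idx_j[r]] + mi$mi_raw[r]
  }
  m_i <- col_sum / (k - 1L)
  m_bar <- mean(mi$mi_raw)
  if (m_bar == 0) {
    warning("overall mean MI is 0; APC skipped (mi_apc = mi_raw)")
    mi$mi_apc <- mi$mi_raw
  } else {
    mi$mi_apc <- mi$mi_raw - m_i[idx_i] * m_i[idx_j] / m_bar
  }
  mi
}

#' Corrected mutual information with shuffled-alignment z-scores
#'
#' Computes APC-corrected MI for all usable column pairs and calibrates each
#' pair against a shuffle null: in each replicate the residues of every
#' column are independently permuted among that column's non-gap positions
#' (preserving per-column composition and gap structure while destroying
#' covariation) and `mi_apc` is recomputed. Per pair,
#' `z = (observed - null mean) / null sd`. Pairs whose null sd is 0 are
#' flagged `degenerate` and given `z = 0` rather than an infinite score.
#'
#' @inheritParams pairwise_mi
#' @param n_shuffles number of shuffle replicates, at least 50.
#' @param seed integer seed; required.
#' @return An object of class `covariation`: list with `pairs` (data.frame
#'   `col_i`, `col_j`, `mi_raw`, `mi_apc`, `z`, `degenerate`),
#'   `columns_used`, `n_shuffles`, `pseudocount`, `seed`.
#' @export
mi_zscores <- function(aln, weights = NULL, columns = NULL,
                       n_shuffles = 100L, pseudocount = 0.05,
                       min_occupancy = 0.5, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for the shuffle null")
  }
  if (n_shuffles < 50L) stop("n_shuffles must be at least 50")
  obs <- apc_correct(pairwise_mi(aln, weights, columns, pseudocount,
                                 min_occupancy))
  cols <- attr(obs, "columns_used")
  X <- encode_alignment(aln)
  w <- unname(resolve_weights(weights, aln$ids))
  n_clusters <- if (inherits(weights, "sequence_weights")) {
    weights$n_clusters
  } else {
    sum(w)
  }
  pc_total <- pseudocount * n_clusters
  nongap <- lapply(cols, function(c) which(X[, c] > 0L))

  set.seed(as.integer(seed))
  np <- nrow(obs)
  s1 <- numeric(np)
  s2 <- numeric(np)
  Xs <- X
  for (b in seq_len(n_shuffles)) {
    for (k in seq_along(cols)) {
      idx <- nongap[[k]]
      Xs[idx, cols[k]] <- X[idx[sample.int(length(idx))], cols[k]]
    }
    mi_b <- mi_pairs_kernel(Xs, w, cols, pc_total)
    apc_b <- apc_vector(mi_b, length(cols))
    s1 <- s1 + apc_b
    s2 <- s2 + apc_b^2
  }
  mu <- s1 / n_shuffles
  sdv <- sqrt(pmax(0, s2 / n_shuffles - mu^2) * n_shuffles / (n_shuffles - 1))
  degenerate <- sdv <= .Machine$double.eps^0.5
  z <- ifelse(degenerate, 0, (obs$mi_apc - mu) / sdv)

  pairs <- data.frame(col_i = obs$col_i, col_j = obs$col_j,
                      mi_raw = obs$mi_raw, mi_apc = obs$mi_apc,
                      z = z, degenerate = degenerate)
  structure(list(pairs = pairs, columns_used = cols,
                 n_shuffles = n_shuffles, pseudocount = pseudocount,
                 seed = as.integer(seed)),
            class = "covariation")
}

# APC on a raw upper-triangle vector over m columns (kernel pair order)
apc_vector <- function(mi, m) {
  col_sum <- numeric(m)
  k <- 0L
  for (i in seq_len(m - 1L)) {
    jj <- seq(k + 1L, k + m - i)
    col_sum[i] <- col_sum[i] + sum(mi[jj])
    col_sum[(i + 1L):m] <- col_sum[(i + 1L):m] + mi[jj]
    k <- k + m - i
  }
  m_i <- col_sum / (m - 1L)
  m_bar <- mean(mi)
  if (m_bar == 0) return(mi)
  i <- rep(seq_len(m - 1L), times = (m - 1L):1L)
  j <- unlist(lapply(seq_len(m - 1L), function(x) seq(x + 1L, m)),
              use.names = FALSE)
  mi - m_i[i] * m_i[j] / m_bar
}

#' @export
print.covariation <- function(x, ...) {
  cat("covariation:", nrow(x$pairs), "pairs over", length(x$columns_used),
      "columns,", x$n_shuffles, "shuffles (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Write the covariation edge table as TSV
#' @param cov a [mi_zscores()] result.
#' @param path output path.
#' @param column_map optional [build_column_map()] for reference numbering.
#' @return `path`, invisibly.
#' @export
write_covariation_report <- function(cov, path, column_map = NULL) {
  tab <- cov$pairs
  tab$ref_i <- if (is.null(column_map)) NA_integer_ else
    map_col_to_ref(column_map, tab$col_i)
  tab$ref_j <- if (is.null(column_map)) NA_integer_ else
    map_col_to_ref(column_map, tab$col_j)
  tab <- tab[, c("col_i", "col_j", "ref_i", "ref_j",
                 "mi_raw", "mi_apc", "z", "degenerate")]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
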