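#' Describe a synthetic alignment with planted signal
#'
#' The generator emulates the statistical structure the clade analyses
#' assume: background columns of varying conservation, clade-diagnostic
#' (CDP-like) columns, covarying column pairs, and clade-exclusive insert
#' blocks — each on disjoint column sets, so every stage of the pipeline
#' can be validated by recovery of known truth.
#'
#' Background columns draw their residue distribution from a symmetric
#' Dirichlet: concentration `bg_alpha` for ordinary columns and the much
#' smaller `conserved_alpha` for a `conserved_frac` share of near-conserved
#' columns. A planted CDP column emits a clade-specific dominant residue
#' with probability `q`, else a background draw. A planted pair couples
#' column `j` to column `i` through a fixed residue bijection with
#' probability `rho`; the marginal of `j` is the bijected image of `i`'s
#' distribution, so coupling is invisible to single-column statistics
#' unless `pairs_are_cdp = TRUE`, in which case the pair columns are also
#' clade-diagnostic (coupled CDPs). A planted CSI is occupied only in its
#' clade, with optional per-sequence presence and length noise.
#'
#' @param n_cols total number of alignment columns.
#' @param clades named integer vector of clade sizes (at least 2 each).
#' @param cdp_columns columns carrying clade-diagnostic signal.
#' @param q diagnostic purity: probability of the clade's dominant residue.
#' @param pair_columns coupled columns: a two-column matrix (one coupled
#'   pair per row) or a list of integer vectors (a coupled group per
#'   element; all columns of a group follow bijections of one latent
#'   residue, so every within-group pair covaries — groups of three or
#'   more give each column two or more coupling partners).
#' @param rho coupling strength in `[0, 1]`.
#' @param pairs_are_cdp make the pair columns clade-diagnostic as well.
#' @param csis list of inserts, each `list(clade=, col_start=, col_end=,
#'   presence=, length_jitter=)` (`presence` defaults to 1,
#'   `length_jitter` to 0 — residues removed from the interval's right end).
#' @param bg_alpha Dirichlet concentration of ordinary background columns.
#' @param conserved_frac share of background columns drawn near-conserved.
#' @param conserved_alpha Dirichlet concentration of conserved columns.
#' @return An object of class `synthetic_truth` echoing the parameters,
#'   plus `cdp_truth` (all clade-diagnostic columns) and `pair_truth`.
#' @export
synthetic_truth <- function(n_cols, clades = c(cladeA = 100L, cladeB = 100L),
                            cdp_columns = integer(0), q = 0.9,
                            pair_columns = NULL, rho = 1,
                            pairs_are_cdp = FALSE,
                            csis = list(),
                            bg_alpha = 0.5, conserved_frac = 0.25,
                            conserved_alpha = 0.02) {
  if (is.null(names(clades)) || length(clades) < 2L) {
    stop("clades must be a named vector of at least two clade sizes")
  }
  if (any(clades < 2L)) stop("every clade needs at least 2 sequences")
  pair_groups <- NULL
  if (!is.null(pair_columns)) {
    pair_groups <- if (is.list(pair_columns)) {
      lapply(pair_columns, as.integer)
    } else {
      pm <- matrix(as.integer(pair_columns), ncol = 2L)
      lapply(seq_len(nrow(pm)), function(r) pm[r, ])
    }
    if (any(lengths(pair_groups) < 2L)) {
      stop("every coupled group needs at least 2 columns")
    }
  }
  csis <- lapply(csis, function(cs) {
    if (is.null(cs$presence)) cs$presence <- 1
    if (is.null(cs$length_jitter)) cs$length_jitter <- 0L
    if (!cs$clade %in% names(clades)) stop("unknown CSI clade: ", cs$clade)
    if (cs$col_start > cs$col_end) stop("empty CSI interval")
    cs
  })
  csi_cols <- unlist(lapply(csis, function(cs) cs$col_start:cs$col_end))
  planted <- c(cdp_columns, unlist(pair_groups), csi_cols)
  if (anyDuplicated(planted)) {
    stop("planted features overlap on column ",
         planted[duplicated(planted)][1L])
  }
  if (length(planted) > 0L && (max(planted) > n_cols || min(planted) < 1L)) {
    stop("planted columns outside 1..n_cols")
  }
  pair_truth <- NULL
  if (!is.null(pair_groups)) {
    pair_truth <- do.call(rbind, lapply(pair_groups, function(g) {
      t(utils::combn(sort(g), 2L))
    }))
  }
  structure(list(n_cols = as.integer(n_cols), clades = clades,
                 cdp_columns = as.integer(cdp_columns), q = q,
                 pair_groups = pair_groups, rho = rho,
                 pairs_are_cdp = pairs_are_cdp, csis = csis,
                 bg_alpha = bg_alpha, conserved_frac = conserved_frac,
                 conserved_alpha = conserved_alpha,
                 cdp_truth = sort(c(as.integer(cdp_columns),
                                    if (isTRUE(pairs_are_cdp))
                                      unlist(pair_groups))),
                 pair_truth = pair_truth),
            class = "synthetic_truth")
}

rdirichlet1 <- function(alpha_vec) {
  g <- rgamma(length(alpha_vec), shape = alpha_vec, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1L)] <- 1
  g / sum(g)
}

#' Generate a synthetic alignment, clade partition and tree
#'
#' Fully reproducible: the same `(truth, seed)` yields a byte-identical
#' alignment. The tree is a caterpillar within each clade, clades joined at
#' the root, consistent with the partition.
#'
#' @param truth a [synthetic_truth()].
#' @param seed integer seed.
#' @return A list: `alignment` ([alignment()]), `groups`
#'   ([group_assignment()]), `tree` (Newick string) and `truth` (the input
#'   with `seed` recorded).
#' @export
generate_msa <- function(truth, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  clades <- truth$clades
  ids <- unlist(lapply(names(clades), function(cl) {
    paste0(cl, "_", seq_len(clades[[cl]]))
  }))
  clade_of <- rep(names(clades), clades)
  n <- length(ids)
  mat <- matrix("-", nrow = n, ncol = truth$n_cols,
                dimnames = list(ids, NULL))

  role <- rep("bg", truth$n_cols)
  role[truth$cdp_columns] <- "cdp"
  role[unlist(truth$pair_groups)] <- "pair"
  csi_of <- integer(truth$n_cols)
  for (k in seq_along(truth$csis)) {
    cs <- truth$csis[[k]]
    role[cs$col_start:cs$col_end] <- "csi"
    csi_of[cs$col_start:cs$col_end] <- k
  }

  draw_bg_column <- function() {
    alpha <- if (runif(1) < truth$conserved_frac) truth$conserved_alpha
             else truth$bg_alpha
    p <- rdirichlet1(rep(alpha, 20L))
    AA20[sample.int(20L, n, replace = TRUE, prob = p)]
  }
  draw_cdp_column <- function() {
    dom <- sample.int(20L, length(clades))
    names(dom) <- names(clades)
    p_bg <- rdirichlet1(rep(truth$bg_alpha, 20L))
    codes <- ifelse(runif(n) < truth$q, dom[clade_of],
                    sample.int(20L, n, replace = TRUE, prob = p_bg))
    AA20[codes]
  }

  for (c in which(role == "bg")) mat[, c] <- draw_bg_column()
  for (c in which(role == "cdp")) mat[, c] <- draw_cdp_column()

  for (grp in truth$pair_groups) {
    if (isTRUE(truth$pairs_are_cdp)) {
      dom <- sample.int(20L, length(clades))
      names(dom) <- names(clades)
      p_bg <- rdirichlet1(rep(truth$bg_alpha, 20L))
      draw_latent <- function() ifelse(runif(n) < truth$q, dom[clade_of],
                                       sample.int(20L, n, replace = TRUE,
                                                  prob = p_bg))
    } else {
      p_i <- rdirichlet1(rep(truth$bg_alpha, 20L))
      draw_latent <- function() sample.int(20L, n, replace = TRUE,
                                           prob = p_i)
    }
    latent <- draw_latent()
    mat[, grp[1L]] <- AA20[latent]
    for (cj in grp[-1L]) {
      sigma <- sample.int(20L) # fixed residue bijection for this column
      indep <- draw_latent()   # independent draw from the same law
      coupled <- runif(n) < truth$rho
      mat[, cj] <- AA20[sigma[ifelse(coupled, latent, indep)]]
    }
  }

  for (k in seq_along(truth$csis)) {
    cs <- truth$csis[[k]]
    cols <- cs$col_start:cs$col_end
    len <- length(cols)
    members <- which(clade_of == cs$clade)
    freqs <- lapply(seq_len(len), function(i) rdirichlet1(rep(0.3, 20L)))
    for (m in members) {
      if (runif(1) >= cs$presence) next # insert absent in this sequence
      jit <- if (cs$length_jitter > 0L) {
        sample.int(cs$length_jitter + 1L, 1L) - 1L
      } else 0L
      keep <- seq_len(max(0L, len - jit))
      for (i in keep) {
        mat[m, cols[i]] <- AA20[sample.int(20L, 1L, prob = freqs[[i]])]
      }
    }
  }

  truth$seed <- as.integer(seed)
  list(alignment = alignment(apply(mat, 1L, paste, collapse = ""), ids),
       groups = group_assignment(split(ids, clade_of)[names(clades)]),
       tree = caterpillar_newick(split(ids, clade_of)[names(clades)]),
       truth = truth)
}

# caterpillar within each clade, clades joined caterpillar-style at the root
caterpillar_newick <- function(id_sets) {
  cat_sub <- function(ids, bl) {
    if (length(ids) == 1L) return(paste0(ids, ":", bl))
    paste0("(", ids[1L], ":", bl, ",",
           cat_sub(ids[-1L], bl), "):", bl)
  }
  clades <- vapply(id_sets, cat_sub, "", bl = 0.05)
  join <- function(parts) {
    if (length(parts) == 1L) return(parts)
    paste0("(", parts[1L], ":0.5,", join(parts[-1L]), ":0.5)")
  }
  paste0(join(unname(clades)), ";")
}

#' Compare a stage result with the planted truth
#'
#' @param result detected features: an integer vector of columns
#'   (`what = "cdp"`), a data.frame with `col_i`/`col_j`
#'   (`what = "pairs"`), or a [call_csis()] result (`what = "csi"`).
#' @param truth the `truth` element returned by [generate_msa()].
#' @param what which planted feature set to score against.
#' @return A list: `sensitivity`, `precision` (`NA` when nothing was
#'   detected), and for CSIs `boundary_error` (max over planted inserts of
#'   the larger start/end offset of the best-overlapping call; `Inf` for a
#'   missed insert).
#' @export
truth_compare <- function(result, truth,
                          what = c("cdp", "pairs", "csi")) {
  what <- match.arg(what)
  if (what == "cdp") {
    planted <- truth$cdp_truth
    found <- sort(unique(as.integer(result)))
    hit <- intersect(found, planted)
    return(list(sensitivity = if (length(planted)) length(hit) / length(planted)
                              else NA_real_,
                precision = if (length(found)) length(hit) / length(found)
                            else NA_real_))
  }
  if (what == "pairs") {
    if (is.null(truth$pair_truth)) stop("no planted pairs in this truth")
    canon <- function(i, j) paste(pmin(i, j), pmax(i, j))
    planted <- canon(truth$pair_truth[, 1L], truth$pair_truth[, 2L])
    found <- unique(canon(result$col_i, result$col_j))
    hit <- intersect(found, planted)
    return(list(sensitivity = length(hit) / length(planted),
                precision = if (length(found)) length(hit) / length(found)
                            else NA_real_))
  }
  # csi
  calls <- result
  n_hit <- 0L
  be <- numeric(0)
  used <- logical(length(calls))
  for (cs in truth$csis) {
    best <- NA_integer_
    best_ov <- 0L
    for (k in seq_along(calls)) {
      cl <- calls[[k]]
      if (cl$clade != cs$clade) next
      ov <- min(cl$col_end, cs$col_end) - max(cl$col_start, cs$col_start) + 1L
      if (ov > best_ov) { best_ov <- ov; best <- k }
    }
    if (!is.na(best)) {
      n_hit <- n_hit + 1L
      used[best] <- TRUE
      be <- c(be, max(abs(calls[[best]]$col_start - cs$col_start),
                      abs(calls[[best]]$col_end - cs$col_end)))
    } else {
      be <- c(be, Inf)
    }
  }
  list(sensitivity = if (length(truth$csis)) n_hit / length(truth$csis)
                     else NA_real_,
       precision = if (length(calls)) sum(used) / length(calls) else NA_real_,
       boundary_error = if (length(be)) max(be) else NA_real_)
}
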