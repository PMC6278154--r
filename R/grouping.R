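#' Construct a group assignment
#'
#' A group assignment is the clade partition all two-group statistics are
#' computed against: a named list of disjoint, non-empty id sets. Ids
#' outside every group are "unassigned" and excluded from group statistics.
#'
#' @param groups named list of character vectors of sequence ids.
#' @param focal_pair optional character(2) naming the two groups of a
#'   two-group analysis.
#' @return An object of class `group_assignment`.
#' @export
group_assignment <- function(groups, focal_pair = NULL) {
  if (length(groups) == 0L || is.null(names(groups)) ||
      any(!nzchar(names(groups)))) {
    stop("groups must be a non-empty named list")
  }
  groups <- lapply(groups, function(g) unique(as.character(g)))
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty")
  all_ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("groups overlap on id: ", all_ids[duplicated(all_ids)][1L])
  }
  if (!is.null(focal_pair)) {
    if (length(focal_pair) != 2L || !all(focal_pair %in% names(groups))) {
      stop("focal_pair must name two existing groups")
    }
  }
  structure(list(groups = groups, focal_pair = focal_pair),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("group_assignment:", length(x$groups), "groups (",
      paste(names(x$groups), lengths(x$groups), sep = ":", collapse = ", "),
      ")\n")
  invisible(x)
}

#' Read a group assignment from a two-column TSV
#'
#' @param path TSV with columns id, group (no header).
#' @return A [group_assignment()].
#' @export
groups_from_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) stop("cannot parse group table: ", conditionMessage(e)))
  if (ncol(tab) < 2L) stop("group table must have two columns (id, group)")
  tab <- tab[, 1:2]
  names(tab) <- c("id", "group")
  dup <- tab$id[duplicated(tab$id)]
  for (d in dup) {
    if (length(unique(tab$group[tab$id == d])) > 1L) {
      stop("id assigned to conflicting groups: ", d)
    }
  }
  tab <- tab[!duplicated(tab$id), ]
  group_assignment(split(tab$id, tab$group))
}

#' Derive a group assignment from a tree by exemplar MRCA clades
#'
#' Each group is the full leaf set of the most recent common ancestor of
#' its exemplar leaves, after rooting. With `root = "midpoint"` the tree is
#' midpoint rooted first (the convention for unrooted distance-scaled
#' phylograms); with `"as-given"` the input rooting is used.
#'
#' @param tree an `ape::phylo` tree or a path to / string of Newick.
#' @param exemplars named list: group label -> character vector of leaf ids
#'   (at least one leaf; a single exemplar yields that leaf alone).
#' @param root `"midpoint"` or `"as-given"`.
#' @return A [group_assignment()].
#' @export
groups_from_tree <- function(tree, exemplars, root = c("midpoint", "as-given")) {
  root <- match.arg(root)
  phy <- as_phylo(tree)
  if (root == "midpoint") phy <- phangorn::midpoint(phy)
  missing <- setdiff(unlist(exemplars), phy$tip.label)
  if (length(missing) > 0L) {
    stop("exemplar leaves not in tree: ", paste(missing, collapse = ", "))
  }
  groups <- lapply(exemplars, function(leaves) {
    leaves <- unique(as.character(leaves))
    if (length(leaves) == 1L) return(leaves)
    node <- ape::getMRCA(phy, leaves)
    clade_tips(phy, node)
  })
  names(groups) <- names(exemplars)
  if (length(groups) > 1L) {
    for (i in seq_len(length(groups) - 1L)) {
      for (j in seq(i + 1L, length(groups))) {
        if (length(intersect(groups[[i]], groups[[j]])) > 0L) {
          stop("exemplar clades are not monophyletic: groups '",
               names(groups)[i], "' and '", names(groups)[j],
               "' have overlapping MRCA leaf sets")
        }
      }
    }
  }
  group_assignment(groups)
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("tree must be a phylo object, a Newick string or a file path")
}

clade_tips <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  if (node <= n_tip) return(phy$tip.label[node])
  phy$tip.label[phangorn::Descendants(phy, node, type = "tips")[[1L]]]
}

#' Identity-cluster sequence weights
#'
#' Near-identical sequences would otherwise dominate every frequency-based
#' statistic; each sequence is therefore down-weighted by the size of its
#' identity cluster. Clustering is greedy single-pass in input order,
#' CD-HIT-style: a sequence joins the first cluster whose founding
#' representative shares pairwise identity at least `identity_threshold`,
#' else founds a new cluster. Identity is computed on the aligned rows as
#' matches over positions where both rows are non-gap (zero shared non-gap
#' positions gives identity 0). Within a cluster every weight is
#' `1 / cluster size`, so the weights sum to the number of clusters.
#'
#' @param aln an [alignment()].
#' @param identity_threshold pairwise identity threshold in `(0, 1]`.
#' @param restrict_to optional id set; weights are computed on that subset
#'   only.
#' @return An object of class `sequence_weights`: list with `weight` (named
#'   numeric), `cluster` (named integer cluster index) and `n_clusters`.
#' @export
cluster_weights <- function(aln, identity_threshold = 0.62,
                            restrict_to = NULL) {
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]")
  }
  ids <- aln$ids
  if (!is.null(restrict_to)) {
    ids <- ids[ids %in% restrict_to]
    if (length(ids) == 0L) stop("restrict_to shares no ids with the alignment")
  }
  mat <- aln$mat[ids, , drop = FALSE]
  gap <- mat == "-" | mat == "X"
  n <- length(ids)
  cluster <- integer(n)
  reps <- integer(0) # row indices of cluster representatives
  for (i in seq_len(n)) {
    assigned <- 0L
    for (k in seq_along(reps)) {
      r <- reps[k]
      both <- !gap[i, ] & !gap[r, ]
      nb <- sum(both)
      ident <- if (nb == 0L) 0 else sum(mat[i, both] == mat[r, both]) / nb
      if (ident >= identity_threshold) { assigned <- k; break }
    }
    if (assigned == 0L) {
      reps <- c(reps, i)
      assigned <- length(reps)
    }
    cluster[i] <- assigned
  }
  sizes <- tabulate(cluster)
  structure(list(weight = setNames(1 / sizes[cluster], ids),
                 cluster = setNames(cluster, ids),
                 n_clusters = length(reps)),
            class = "sequence_weights")
}

#' @export
print.sequence_weights <- function(x, ...) {
  cat("sequence_weights:", length(x$weight), "sequences in",
      x$n_clusters, "identity clusters\n")
  invisible(x)
}

#' Write the weights report as TSV
#' @param w a [cluster_weights()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weights_report <- function(w, path) {
  write.table(data.frame(id = names(w$weight), cluster = w$cluster,
                         weight = w$weight),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Resolve weights for a set of ids: a sequence_weights object, a named
# numeric vector, or NULL for unit weights.
resolve_weights <- function(weights, ids) {
  if (is.null(weights)) return(setNames(rep(1, length(ids)), ids))
  if (inherits(weights, "sequence_weights")) weights <- weights$weight
  if (is.null(names(weights))) stop("weights must be named by sequence id")
  missing <- setdiff(ids, names(weights))
  if (length(missing) > 0L) {
    stop("no weight for ids: ", paste(head(missing, 5L), collapse = ", "))
  }
  weights[ids]
}
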