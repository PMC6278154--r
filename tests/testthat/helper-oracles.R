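# Independent oracles and small fixture builders shared across tests.

AA20_h <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

mk_aln <- function(rows, ids = paste0("s", seq_along(rows))) {
  alignment(rows, ids)
}

# Brute-force weighted MI between two columns given as character vectors,
# written independently of the package kernel: explicit joint table,
# explicit double loop over the 20x20 cells.
mi_oracle <- function(col_a, col_b, w = rep(1, length(col_a)),
                      pc_total = 0) {
  joint <- matrix(0, 20, 20, dimnames = list(AA20_h, AA20_h))
  for (r in seq_along(col_a)) {
    a <- col_a[r]; b <- col_b[r]
    if (a %in% AA20_h && b %in% AA20_h) joint[a, b] <- joint[a, b] + w[r]
  }
  joint <- joint + pc_total / 400
  tot <- sum(joint)
  if (tot == 0) return(0)
  p <- joint / tot
  pa <- rowSums(p); pb <- colSums(p)
  mi <- 0
  for (a in 1:20) for (b in 1:20) {
    if (p[a, b] > 0) mi <- mi + p[a, b] * log(p[a, b] / (pa[a] * pb[b]))
  }
  unname(mi)
}

# Brute-force connected components by union-find over an edge list.
uf_components <- function(nodes, edges) {
  parent <- setNames(as.character(nodes), as.character(nodes))
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      ra <- find(as.character(edges[r, 1])); rb <- find(as.character(edges[r, 2]))
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(as.character(nodes), find, "")
  comps <- split(as.integer(nodes), roots)
  deg <- table(factor(as.character(c(edges[, 1], edges[, 2])),
                      levels = as.character(nodes)))
  comps <- comps[vapply(comps, function(cp) {
    any(deg[as.character(cp)] > 0)
  }, TRUE)] # only non-isolated nodes form components
  unname(lapply(comps, sort))
}

# Minimal covariation object for network tests: all listed pairs with a z.
fake_cov <- function(pairs, columns = sort(unique(c(pairs$col_i, pairs$col_j)))) {
  pairs$mi_raw <- if (is.null(pairs$mi_raw)) pairs$z else pairs$mi_raw
  pairs$mi_apc <- if (is.null(pairs$mi_apc)) pairs$z else pairs$mi_apc
  pairs$degenerate <- if (is.null(pairs$degenerate)) FALSE else pairs$degenerate
  structure(list(pairs = pairs, columns_used = columns,
                 n_shuffles = 100L, pseudocount = 0.05, seed = 1L),
            class = "covariation")
}

# Write a toy PDB file from a data.frame with chain, resno, resname,
# atom_name, element, x, y, z and optional alt, occ, het.
write_toy_pdb <- function(atoms, path) {
  lines <- character(nrow(atoms))
  for (r in seq_len(nrow(atoms))) {
    a <- atoms[r, ]
    alt <- if (is.null(atoms$alt)) " " else substr(paste0(a$alt, " "), 1, 1)
    occ <- if (is.null(atoms$occ)) 1 else a$occ
    rec <- if (!is.null(atoms$het) && isTRUE(a$het)) "HETATM" else "ATOM  "
    name <- if (nchar(a$atom_name) < 4) paste0(" ", a$atom_name) else a$atom_name
    lines[r] <- sprintf("%s%5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                        rec, r, name, alt, a$resname, a$chain, a$resno,
                        a$x, a$y, a$z, occ, 0, a$element)
  }
  writeLines(c(lines, "END"), path)
  path
}
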