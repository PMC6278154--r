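#' Read a PDB-format structure
#'
#' Parses the first model of a PDB file. Alternate locations are resolved
#' to a single conformer per atom (highest occupancy, ties to the first
#' altLoc code). HETATM records are retained with `het = TRUE` — metal ions
#' at interfaces matter for distance queries.
#'
#' @param path path to a PDB-format file.
#' @return An object of class `structure_model`: list with `atoms`, a
#'   data.frame (`chain`, `resno`, `insert`, `resid`, `atom_name`, `element`,
#'   `x`, `y`, `z`, `het`).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  if (is.null(at) || !any(at$type == "ATOM")) {
    stop("no ATOM records in ", path)
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # resolve altlocs: keep the highest-occupancy conformer per atom slot
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "|")), ]
  at <- at[order(at$eleno), ]
  elem <- at$elesy
  missing_elem <- is.na(elem) | elem == ""
  elem[missing_elem] <- substr(gsub("[0-9]", "", at$elety[missing_elem]), 1, 1)
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      insert = at$insert, resid = at$resid,
                      atom_name = at$elety, element = toupper(elem),
                      x = at$x, y = at$y, z = at$z,
                      het = at$type == "HETATM")
  if (any(!is.finite(atoms$x + atoms$y + atoms$z))) {
    stop("non-finite coordinates in ", path)
  }
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Select residues of a structure
#'
#' @param chain chain id (single value), or `NULL` for all chains.
#' @param resno integer vector of residue numbers, or `NULL` for all.
#' @return A `residue_selection` to pass to [min_distance()] /
#'   [proximity_report()].
#' @export
residue_selection <- function(chain = NULL, resno = NULL) {
  structure(list(chain = chain, resno = resno), class = "residue_selection")
}

resolve_selection <- function(s, sel, atoms = c("heavy", "all", "CA"),
                              label = "selection") {
  atoms <- match.arg(atoms)
  at <- s$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(sel$chain)) keep <- keep & at$chain %in% sel$chain
  if (!is.null(sel$resno)) keep <- keep & at$resno %in% sel$resno
  if (atoms == "heavy") keep <- keep & at$element != "H"
  if (atoms == "CA") keep <- keep & at$atom_name == "CA"
  out <- at[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop(label, " resolves to no atoms (chain=",
         if (is.null(sel$chain)) "*" else paste(sel$chain, collapse = ","),
         ", resno=",
         if (is.null(sel$resno)) "*" else paste(sel$resno, collapse = ","), ")")
  }
  out
}

#' Minimum inter-atomic distance between two residue selections
#'
#' @param s a [read_structure()] result.
#' @param sel_a,sel_b [residue_selection()]s.
#' @param atoms atom filter: `"heavy"` (non-hydrogen; the convention for
#'   crystal structures), `"all"`, or `"CA"`.
#' @return Minimum pairwise distance in Angstrom. Overlapping selections
#'   give 0 (the same atom appears on both sides).
#' @export
min_distance <- function(s, sel_a, sel_b, atoms = c("heavy", "all", "CA")) {
  atoms <- match.arg(atoms)
  a <- resolve_selection(s, sel_a, atoms, "sel_a")
  b <- resolve_selection(s, sel_b, atoms, "sel_b")
  min(cross_dist(a, b))
}

cross_dist <- function(a, b) {
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Distance of positions to a residue site
#'
#' For each query position, the minimum heavy-atom distance to any residue
#' of the site (e.g. the catalytic triad plus oxyanion), with a flag for
#' positions within `cutoff`. Positions that resolve to no atoms in the
#' stated chain are listed as unmapped (`NA` distance), never dropped.
#'
#' @param s a [read_structure()] result.
#' @param positions integer vector of query residue numbers.
#' @param site integer vector of site residue numbers.
#' @param chain chain id the numbering refers to.
#' @param cutoff proximity cutoff in Angstrom.
#' @param atoms atom filter, as in [min_distance()].
#' @return A data.frame: `position`, `min_distance`, `within_cutoff`,
#'   `unmapped`.
#' @export
proximity_report <- function(s, positions, site, chain, cutoff = 5.0,
                             atoms = c("heavy", "all", "CA")) {
  atoms <- match.arg(atoms)
  site_atoms <- resolve_selection(s, residue_selection(chain, site), atoms,
                                  "site")
  rows <- lapply(positions, function(p) {
    at <- tryCatch(
      resolve_selection(s, residue_selection(chain, p), atoms, "position"),
      error = function(e) NULL)
    if (is.null(at)) {
      return(data.frame(position = p, min_distance = NA_real_,
                        within_cutoff = NA, unmapped = TRUE))
    }
    d <- min(cross_dist(at, site_atoms))
    data.frame(position = p, min_distance = d,
               within_cutoff = d <= cutoff, unmapped = FALSE)
  })
  do.call(rbind, rows)
}
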