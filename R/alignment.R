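#' Construct an alignment object
#'
#' An `alignment` holds a rectangular protein multiple sequence alignment as
#' a character matrix: one row per sequence, one column per alignment
#' position. Rows are upper-cased on ingest; the alphabet is the 20 amino
#' acids plus `'X'` (unknown residue) and `'-'` (gap). `'X'` is retained in
#' the rows but is excluded, like a gap, from every frequency-based
#' statistic.
#'
#' @param seqs character vector of aligned rows, all of identical length.
#' @param ids character vector of unique, non-empty sequence identifiers.
#' @return An object of class `alignment`: a list with `mat` (character
#'   matrix, rownames = ids), `ids` and `n_cols`.
#' @examples
#' aln <- alignment(c("AC-D", "ACGD"), c("s1", "s2"))
#' n_cols(aln)
#' @export
alignment <- function(seqs, ids = names(seqs)) {
  if (is.null(ids)) stop("sequence ids are required")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  }
  if (any(!nzchar(ids))) stop("empty sequence id")
  if (length(seqs) == 0L) stop("alignment must contain at least one sequence")
  seqs <- toupper(as.character(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- ids[lens != lens[1L]][1L]
    stop("alignment rows have unequal lengths (offending id: ", bad, ")")
  }
  if (lens[1L] < 1L) stop("alignment must have at least one column")
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(ids, NULL))
  illegal <- !(mat %in% ALPHABET)
  dim(illegal) <- dim(mat)
  if (any(illegal)) {
    idx <- which(illegal, arr.ind = TRUE)[1L, ]
    stop("illegal character '", mat[idx[1L], idx[2L]], "' in sequence '",
         ids[idx[1L]], "' at column ", idx[2L])
  }
  structure(list(mat = mat, ids = ids, n_cols = ncol(mat)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment:", length(x$ids), "sequences x", x$n_cols, "columns\n")
  invisible(x)
}

#' Number of alignment columns
#' @param aln an `alignment`.
#' @return Integer column count.
#' @export
n_cols <- function(aln) aln$n_cols

#' Read an aligned FASTA file
#'
#' Sequences are validated against the alignment invariants: equal row
#' lengths, unique ids, alphabet of 20 amino acids plus `'X'` and `'-'`.
#' Input order is preserved (it matters for identity-cluster weighting).
#' Ids are the FASTA headers up to the first whitespace.
#'
#' @param path path to an aligned FASTA file.
#' @return An [alignment()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  alignment(as.character(ss), ids)
}

#' Write an alignment as FASTA
#'
#' @param aln an [alignment()].
#' @param path output file path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 60L) {
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Per-column gap fraction, entropy and occupancy
#'
#' `'X'` counts as a gap for these statistics (it carries no residue
#' identity) while staying in the alignment rows. Entropy is Shannon entropy
#' of the residue frequencies (gaps excluded), normalised by `ln 20` so a
#' maximally diverse column scores 1. An all-gap column has undefined
#' entropy; it is reported as 0 with `all_gap = TRUE`.
#'
#' @param aln an [alignment()].
#' @return A data.frame with `column`, `gap_fraction`, `entropy_norm`,
#'   `occupancy`, `all_gap`.
#' @export
column_stats <- function(aln) {
  mat <- aln$mat
  n <- nrow(mat)
  is_gap <- mat == "-" | mat == "X"
  gap_fraction <- colMeans(is_gap)
  entropy <- vapply(seq_len(ncol(mat)), function(c) {
    res <- mat[!is_gap[, c], c]
    if (length(res) == 0L) return(0)
    f <- table(res) / length(res)
    -sum(f * log(f)) / log(20)
  }, numeric(1))
  data.frame(column = seq_len(ncol(mat)),
             gap_fraction = gap_fraction,
             entropy_norm = entropy,
             occupancy = 1 - gap_fraction,
             all_gap = gap_fraction == 1)
}

#' Map alignment columns to reference residue numbering
#'
#' Positions are reported throughout in the numbering of a chosen reference
#' sequence (e.g. a structure's chain numbering). The map is defined exactly
#' on the columns where the reference row is non-gap, numbered consecutively
#' from `first_residue_number`.
#'
#' @param aln an [alignment()].
#' @param reference_id id of the reference sequence in `aln`.
#' @param first_residue_number residue number of the reference's first
#'   non-gap column.
#' @return An object of class `column_map`: list with `reference_id`,
#'   `col_to_ref` (named integer vector, names are 1-based columns) and
#'   `ref_to_col` (the inverse).
#' @examples
#' aln <- alignment(c("AC-D", "ACGD"), c("ref", "s2"))
#' cm <- build_column_map(aln, "ref", 1)
#' map_col_to_ref(cm, 4)  # 3
#' @export
build_column_map <- function(aln, reference_id, first_residue_number = 1L) {
  if (!reference_id %in% aln$ids) {
    stop("reference id not in alignment: ", reference_id)
  }
  row <- aln$mat[reference_id, ]
  cols <- which(row != "-")
  if (length(cols) == 0L) stop("reference row is all gaps: ", reference_id)
  refs <- seq.int(first_residue_number, length.out = length(cols))
  structure(list(reference_id = reference_id,
                 col_to_ref = setNames(as.integer(refs), cols),
                 ref_to_col = setNames(as.integer(cols), refs)),
            class = "column_map")
}

#' @export
print.column_map <- function(x, ...) {
  cat("column_map: reference", x$reference_id, "-",
      length(x$col_to_ref), "mapped columns\n")
  invisible(x)
}

#' Translate columns to reference positions (NA where the reference gaps)
#' @param cm a [build_column_map()] result.
#' @param columns integer vector of 1-based alignment columns.
#' @return Integer vector of reference residue numbers, `NA` for unmapped.
#' @export
map_col_to_ref <- function(cm, columns) {
  unname(cm$col_to_ref[as.character(columns)])
}

#' Translate reference positions to columns (NA where unknown)
#' @param cm a [build_column_map()] result.
#' @param positions integer vector of reference residue numbers.
#' @return Integer vector of 1-based alignment columns, `NA` for unmapped.
#' @export
map_ref_to_col <- function(cm, positions) {
  unname(cm$ref_to_col[as.character(positions)])
}

#' Trim an alignment by gap fraction and entropy
#'
#' Retains exactly the columns with `gap_fraction <= g` and
#' `entropy_norm <= h`. This is a BMGE-like trimmer: plain Shannon entropy
#' normalised by `ln 20` rather than BLOSUM-smoothed entropy, so trimmed
#' column counts are comparable but not bit-identical to BMGE's. All-gap
#' columns are always removed regardless of `h`.
#'
#' @param aln an [alignment()].
#' @param g maximum gap fraction, in `[0, 1]`.
#' @param h maximum normalised entropy, in `[0, 1]`.
#' @return A list with `alignment` (the trimmed [alignment()]),
#'   `kept_columns` (original 1-based indices) and `stats` (the
#'   [column_stats()] table plus a `kept` flag).
#' @export
trim_alignment <- function(aln, g = 0.3, h = 0.8) {
  if (!is.numeric(g) || length(g) != 1L || g < 0 || g > 1) {
    stop("g must be a single value in [0, 1]")
  }
  if (!is.numeric(h) || length(h) != 1L || h < 0 || h > 1) {
    stop("h must be a single value in [0, 1]")
  }
  st <- column_stats(aln)
  keep <- st$gap_fraction <= g & st$entropy_norm <= h & !st$all_gap
  if (!any(keep)) stop("trimming removed every column")
  st$kept <- keep
  kept <- which(keep)
  trimmed <- alignment(apply(aln$mat[, kept, drop = FALSE], 1L,
                             paste, collapse = ""), aln$ids)
  list(alignment = trimmed, kept_columns = kept, stats = st)
}

#' Write the trim report as TSV
#' @param trim a [trim_alignment()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trim_report <- function(trim, path) {
  write.table(trim$stats[, c("column", "gap_fraction", "entropy_norm", "kept")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Integer-code an alignment: 1..20 for amino acids in AA20 order, 0 for
# gap/'X'. The encoding all statistics run on.
encode_alignment <- function(aln) {
  codes <- setNames(c(seq_along(AA20), 0L, 0L), ALPHABET)
  matrix(codes[aln$mat], nrow = nrow(aln$mat),
         dimnames = list(aln$ids, NULL))
}

# Subset an alignment to a set of sequence ids, preserving order of `ids`.
subset_alignment <- function(aln, ids) {
  missing <- setdiff(ids, aln$ids)
  if (length(missing) > 0L) {
    stop("ids not in alignment: ", paste(head(missing, 5L), collapse = ", "))
  }
  alignment(apply(aln$mat[ids, , drop = FALSE], 1L, paste, collapse = ""), ids)
}
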