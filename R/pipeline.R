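#' Run the full two-clade specificity analysis
#'
#' Orchestrates the analysis end to end on one alignment and two clades:
#' gap/entropy trimming, identity-cluster weighting, the CDP scan
#' (clade A vs clade B), three covariation runs (A only, B only, and the
#' combined set), one SDP network per covariation run, the key-SDP
#' intersection of the two single-clade networks, the cross-network
#' connectivity table, and CSI calls. All tables report positions in the
#' ORIGINAL alignment's column coordinates (trimmed-frame indices are
#' remapped back), one coordinate frame throughout.
#'
#' The combined covariation run is computed and reported, but key-SDP
#' determination uses only the two single-clade networks: the z cut-off is
#' calibrated for ~400 sequence clusters and combined sets typically exceed
#' that, inflating z-scores. CSI calling always uses the untrimmed
#' alignment — trimming removes exactly the gap-dominated regions inserts
#' live in.
#'
#' @param aln an [alignment()] (untrimmed).
#' @param groups a [group_assignment()] containing `clade_a` and `clade_b`.
#' @param clade_a,clade_b the two group labels to contrast.
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @param reference_id optional id for reference numbering (positions in
#'   reports); `NULL` numbers positions by original column.
#' @param first_residue_number numbering of the reference's first residue.
#' @param g,h trimming thresholds, see [trim_alignment()].
#' @param identity_threshold see [cluster_weights()].
#' @param n_perm,alpha,adjust see [cdp_scan()].
#' @param pseudocount,n_shuffles,min_occupancy see [mi_zscores()].
#' @param z_threshold see [build_network()].
#' @param theta_in,theta_out,min_len,max_gap_run see [call_csis()].
#' @param out_dir optional directory; when given, every table is written
#'   there with the run configuration.
#' @return A list with `trim`, `weights`, `column_map`, `cdps`, `cov`
#'   (list `a`, `b`, `combined`), `networks` (same names), `key_sdps`,
#'   `connectivity`, `csis`, `config`.
#' @export
run_two_clade_analysis <- function(aln, groups, clade_a, clade_b, seed,
                                   reference_id = NULL,
                                   first_residue_number = 1L,
                                   g = 0.3, h = 0.8,
                                   identity_threshold = 0.62,
                                   n_perm = 999L, alpha = 0.05,
                                   adjust = "bh",
                                   pseudocount = 0.05, n_shuffles = 100L,
                                   min_occupancy = 0.5, z_threshold = 6.5,
                                   theta_in = 0.5, theta_out = 0.1,
                                   min_len = 5L, max_gap_run = 2L,
                                   out_dir = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required to run the stochastic stages")
  }
  if (!all(c(clade_a, clade_b) %in% names(groups$groups))) {
    stop("clade_a/clade_b must name groups in the assignment")
  }
  config <- list(clade_a = clade_a, clade_b = clade_b, seed = as.integer(seed),
                 reference_id = reference_id,
                 first_residue_number = first_residue_number,
                 g = g, h = h, identity_threshold = identity_threshold,
                 n_perm = n_perm, alpha = alpha, adjust = adjust,
                 pseudocount = pseudocount, n_shuffles = n_shuffles,
                 min_occupancy = min_occupancy, z_threshold = z_threshold,
                 theta_in = theta_in, theta_out = theta_out,
                 min_len = min_len, max_gap_run = max_gap_run)
  set.seed(as.integer(seed))
  stage_seed <- sample.int(.Machine$integer.max, 4L)

  ids_a <- intersect(aln$ids, groups$groups[[clade_a]])
  ids_b <- intersect(aln$ids, groups$groups[[clade_b]])
  pair_groups <- group_assignment(setNames(list(ids_a, ids_b),
                                           c(clade_a, clade_b)),
                                  focal_pair = c(clade_a, clade_b))

  trim <- trim_alignment(aln, g = g, h = h)
  kept <- trim$kept_columns
  cmap <- if (is.null(reference_id)) {
    identity_column_map(aln$n_cols)
  } else {
    build_column_map(aln, reference_id, first_residue_number)
  }

  weights <- cluster_weights(trim$alignment, identity_threshold,
                             restrict_to = c(ids_a, ids_b))
  w_a <- cluster_weights(trim$alignment, identity_threshold,
                         restrict_to = ids_a)
  w_b <- cluster_weights(trim$alignment, identity_threshold,
                         restrict_to = ids_b)

  cdps <- cdp_scan(trim$alignment, pair_groups, weights,
                   n_perm = n_perm, alpha = alpha, adjust = adjust,
                   seed = stage_seed[1L])
  cdps <- remap_cdp(cdps, kept, cmap)

  mi_run <- function(ids, w, s) {
    cov <- mi_zscores(subset_alignment(trim$alignment, ids), w,
                      pseudocount = pseudocount, n_shuffles = n_shuffles,
                      min_occupancy = min_occupancy, seed = s)
    remap_cov(cov, kept)
  }
  cov <- list(a = mi_run(ids_a, w_a, stage_seed[2L]),
              b = mi_run(ids_b, w_b, stage_seed[3L]),
              combined = mi_run(c(ids_a, ids_b), weights, stage_seed[4L]))

  cdp_cols <- cdp_columns(cdps)
  net_of <- function(cv, ncl) {
    usable <- intersect(cdp_cols, cv$columns_used)
    dropped <- setdiff(cdp_cols, usable)
    if (length(dropped) > 0L) {
      warning("CDP column(s) below the occupancy filter in one dataset, ",
              "excluded from its network: ", paste(dropped, collapse = ", "))
    }
    if (length(usable) == 0L) return(NULL)
    build_network(usable, cv, z_threshold = z_threshold, n_clusters = ncl)
  }
  networks <- list(a = net_of(cov$a, w_a$n_clusters),
                   b = net_of(cov$b, w_b$n_clusters),
                   combined = net_of(cov$combined, weights$n_clusters))

  keys <- if (!is.null(networks$a) && !is.null(networks$b)) {
    key_sdps(networks$a, networks$b, cmap, cmap)
  } else {
    integer(0)
  }
  conn <- {
    nets <- Filter(Negate(is.null), networks[c("a", "b")])
    if (length(nets) > 0L) {
      connectivity_table(nets, rep(list(cmap), length(nets)),
                         names = names(nets))
    } else {
      NULL
    }
  }

  csi_weights <- cluster_weights(aln, identity_threshold,
                                 restrict_to = c(ids_a, ids_b))
  csis <- call_csis(aln, pair_groups, csi_weights,
                    theta_in = theta_in, theta_out = theta_out,
                    min_len = min_len, max_gap_run = max_gap_run)

  res <- list(trim = trim, weights = weights, column_map = cmap,
              cdps = cdps, cov = cov, networks = networks,
              key_sdps = keys, connectivity = conn, csis = csis,
              config = config)
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

# identity numbering when no reference sequence is nominated
identity_column_map <- function(n_cols) {
  cols <- seq_len(n_cols)
  structure(list(reference_id = NA_character_,
                 col_to_ref = setNames(cols, cols),
                 ref_to_col = setNames(cols, cols)),
            class = "column_map")
}

# translate trimmed-frame column indices back to original coordinates
remap_cdp <- function(cdps, kept, cmap) {
  cdps$column <- kept[cdps$column]
  cdps$ref_position <- map_col_to_ref(cmap, cdps$column)
  cdps
}

remap_cov <- function(cov, kept) {
  cov$pairs$col_i <- kept[cov$pairs$col_i]
  cov$pairs$col_j <- kept[cov$pairs$col_j]
  cov$columns_used <- kept[cov$columns_used]
  cov
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  jsonlite::write_json(res$config, p("config.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  write_trim_report(res$trim, p("trim.tsv"))
  write_cdp_report(res$cdps, p("cdp.tsv"))
  for (nm in names(res$cov)) {
    write_covariation_report(res$cov[[nm]], p(paste0("mi_", nm, ".tsv")),
                             res$column_map)
  }
  for (nm in names(res$networks)) {
    if (is.null(res$networks[[nm]])) next
    write_network(res$networks[[nm]], p(paste0("network_", nm, ".tsv")),
                  p(paste0("network_", nm, ".graphml")))
    write_network_summary(res$networks[[nm]], p(paste0("network_", nm, ".json")))
  }
  if (!is.null(res$connectivity)) {
    write.table(res$connectivity, p("connectivity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(key_sdps = res$key_sdps,
                            unmapped = attr(res$key_sdps, "unmapped")),
                       p("key_sdps.json"), auto_unbox = TRUE, pretty = TRUE)
  write_csi_report(res$csis, p("csi.tsv"))
  jsonlite::write_json(list(
    n_sequences = length(res$weights$weight),
    n_clusters = res$weights$n_clusters,
    n_columns_kept = length(res$trim$kept_columns),
    n_cdps = length(cdp_columns(res$cdps)),
    n_key_sdps = length(res$key_sdps),
    n_csis = length(res$csis)
  ), p("summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
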