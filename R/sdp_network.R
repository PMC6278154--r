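#' Build the SDP network from CDPs and covariation z-scores
#'
#' Nodes are the CDP columns; an edge joins two CDPs whose covariation
#' z-score reaches `z_threshold` (a "direct connection" is an edge between
#' two CDPs — non-CDP columns never enter the graph). CDPs are then
#' classified by degree: at least two direct connections makes an SDP,
#' exactly one a putative SDP (pSDP), none leaves the CDP unsupported.
#' Connected components over the non-isolated nodes are the
#' specificity-determining networks (SDNs), numbered by size, largest
#' first.
#'
#' The default threshold 6.5 is the MISTIC-convention cut-off calibrated
#' for datasets of about 400 sequence clusters; a warning is issued when
#' the dataset's cluster count exceeds that, since z-scores grow with
#' cluster count and the cut-off should then be higher (no automatic
#' rescaling is attempted).
#'
#' @param cdps a [cdp_scan()] result, or an integer vector of CDP columns.
#' @param cov a [mi_zscores()] result covering all CDP columns.
#' @param z_threshold minimum z for an edge.
#' @param n_clusters optional dataset cluster count, used only for the
#'   threshold-validity warning.
#' @return An object of class `sdp_network`: list with `nodes` (data.frame
#'   `column`, `degree`, `class`, `sdn`), `edges` (data.frame `col_i`,
#'   `col_j`, `z`), `components` (list of column sets, size-descending) and
#'   `threshold`.
#' @export
build_network <- function(cdps, cov, z_threshold = 6.5, n_clusters = NULL) {
  nodes <- sort(unique(cdp_columns(cdps)))
  if (length(nodes) == 0L) stop("no CDP columns supplied")
  if (!inherits(cov, "covariation")) stop("cov must be a covariation result")
  missing <- setdiff(nodes, cov$columns_used)
  if (length(missing) > 0L) {
    stop("CDP column(s) not covered by the covariation result: ",
         paste(missing, collapse = ", "))
  }
  if (!is.null(n_clusters) && n_clusters > 400) {
    warning("dataset has ", n_clusters, " sequence clusters (> ~400): ",
            "z-scores grow with cluster count and the ", z_threshold,
            " cut-off is likely too permissive")
  }
  p <- cov$pairs
  keep <- p$col_i %in% nodes & p$col_j %in% nodes &
    !p$degenerate & p$z >= z_threshold
  edges <- p[keep, c("col_i", "col_j", "z")]
  rownames(edges) <- NULL

  deg <- setNames(integer(length(nodes)), nodes)
  if (nrow(edges) > 0L) {
    d <- table(factor(c(edges$col_i, edges$col_j), levels = nodes))
    deg <- setNames(as.integer(d), nodes)
  }
  cls <- ifelse(deg >= 2L, "SDP", ifelse(deg == 1L, "pSDP", "unsupported"))

  sdn <- setNames(rep(NA_integer_, length(nodes)), nodes)
  components <- list()
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$col_i),
                 to = as.character(edges$col_j)),
      directed = FALSE,
      vertices = as.character(nodes[deg > 0L]))
    comp <- igraph::components(g)
    member <- split(as.integer(names(comp$membership)), comp$membership)
    member <- member[order(-lengths(member), vapply(member, min, 0L))]
    for (k in seq_along(member)) {
      sdn[as.character(member[[k]])] <- k
      components[[k]] <- sort(member[[k]])
    }
  }

  structure(list(nodes = data.frame(column = nodes,
                                    degree = unname(deg),
                                    class = unname(cls),
                                    sdn = unname(sdn)),
                 edges = edges,
                 components = components,
                 threshold = z_threshold),
            class = "sdp_network")
}

#' @export
print.sdp_network <- function(x, ...) {
  tab <- table(factor(x$nodes$class, levels = c("SDP", "pSDP", "unsupported")))
  cat("sdp_network: ", nrow(x$nodes), " CDP nodes (", tab[["SDP"]], " SDP, ",
      tab[["pSDP"]], " pSDP, ", tab[["unsupported"]], " unsupported), ",
      nrow(x$edges), " edges at z >= ", x$threshold, ", ",
      length(x$components), " SDN(s)\n", sep = "")
  invisible(x)
}

#' Columns of a network with a given classification
#' @param net an [build_network()] result.
#' @param class one of `"SDP"`, `"pSDP"`, `"unsupported"`.
#' @return Integer vector of columns.
#' @export
network_columns <- function(net, class = "SDP") {
  net$nodes$column[net$nodes$class %in% class]
}

#' Key SDPs: positions classified SDP in two independent networks
#'
#' The two networks come from covariation analyses of independently
#' evolving clades; a position that earns the SDP class in both is the
#' strongest evidence of involvement in the shared functional
#' diversification ("key SDP"). Columns are translated to a common
#' reference numbering before intersection. pSDPs are excluded by default
#' (promotion of a pSDP needs evidence beyond the network); set
#' `include_psdp = TRUE` for exploration.
#'
#' SDP columns where the reference sequence is gapped cannot be numbered;
#' they are reported in the `unmapped` attribute, never silently dropped.
#'
#' @param net_a,net_b [build_network()] results.
#' @param map_a,map_b [build_column_map()] results translating each
#'   network's columns to the same reference numbering.
#' @param include_psdp also intersect pSDP positions.
#' @return Sorted integer vector of reference positions, with attribute
#'   `unmapped`: a list of unmapped SDP columns per network.
#' @export
key_sdps <- function(net_a, net_b, map_a, map_b, include_psdp = FALSE) {
  classes <- if (include_psdp) c("SDP", "pSDP") else "SDP"
  cols_a <- network_columns(net_a, classes)
  cols_b <- network_columns(net_b, classes)
  ref_a <- map_col_to_ref(map_a, cols_a)
  ref_b <- map_col_to_ref(map_b, cols_b)
  out <- sort(intersect(ref_a[!is.na(ref_a)], ref_b[!is.na(ref_b)]))
  attr(out, "unmapped") <- list(a = cols_a[is.na(ref_a)],
                                b = cols_b[is.na(ref_b)])
  out
}

#' Cross-network connectivity table
#'
#' One row per reference position that is a node in any of the networks;
#' per network, its classification, degree (number of direct connections to
#' other CDPs) and SDN membership id. Positions unmapped in a network's
#' reference show as absent there.
#'
#' @param nets list of [build_network()] results.
#' @param maps list of [build_column_map()] results, parallel to `nets`.
#' @param names optional network names (columns of the table).
#' @return A data.frame: `ref_position`, then `class_<name>`,
#'   `degree_<name>`, `sdn_<name>` per network.
#' @export
connectivity_table <- function(nets, maps, names = NULL) {
  if (length(nets) == 0L) stop("at least one network is required")
  if (length(nets) != length(maps)) stop("nets and maps must be parallel")
  if (is.null(names)) names <- paste0("net", seq_along(nets))
  per_net <- lapply(seq_along(nets), function(k) {
    nd <- nets[[k]]$nodes
    nd$ref_position <- map_col_to_ref(maps[[k]], nd$column)
    nd[!is.na(nd$ref_position), ]
  })
  positions <- sort(unique(unlist(lapply(per_net, `[[`, "ref_position"))))
  out <- data.frame(ref_position = positions)
  for (k in seq_along(nets)) {
    m <- match(positions, per_net[[k]]$ref_position)
    out[[paste0("class_", names[k])]] <- per_net[[k]]$class[m]
    out[[paste0("degree_", names[k])]] <- per_net[[k]]$degree[m]
    out[[paste0("sdn_", names[k])]] <- per_net[[k]]$sdn[m]
  }
  out
}

#' Sweep the edge z-threshold of a covariation result
#'
#' Reports, for each threshold, the edge count, SDP/pSDP counts and SDN
#' number and sizes — the raw material for judging where sub-networks merge
#' as the threshold is lowered. No merge decision is made.
#'
#' @param cdps CDP columns (as for [build_network()]).
#' @param cov a [mi_zscores()] result.
#' @param z_values numeric vector of thresholds.
#' @return A data.frame: `z`, `n_edges`, `n_sdp`, `n_psdp`, `n_sdn`,
#'   `sdn_sizes` (comma-separated, size-descending).
#' @export
threshold_sweep <- function(cdps, cov, z_values) {
  if (length(z_values) == 0L) stop("z_values must be non-empty")
  rows <- lapply(sort(z_values, decreasing = TRUE), function(z) {
    net <- build_network(cdps, cov, z_threshold = z)
    data.frame(z = z,
               n_edges = nrow(net$edges),
               n_sdp = sum(net$nodes$class == "SDP"),
               n_psdp = sum(net$nodes$class == "pSDP"),
               n_sdn = length(net$components),
               sdn_sizes = paste(lengths(net$components), collapse = ","))
  })
  do.call(rbind, rows)
}

#' Export a network as edge-list TSV and GraphML
#' @param net an [build_network()] result.
#' @param edge_path TSV path for the edge list (`NULL` to skip).
#' @param graphml_path GraphML path (`NULL` to skip).
#' @return Invisibly, the igraph object written.
#' @export
write_network <- function(net, edge_path = NULL, graphml_path = NULL) {
  g <- igraph::graph_from_data_frame(
    if (nrow(net$edges) > 0L) {
      data.frame(from = as.character(net$edges$col_i),
                 to = as.character(net$edges$col_j), z = net$edges$z)
    } else {
      data.frame(from = character(0), to = character(0), z = numeric(0))
    },
    directed = FALSE, vertices = data.frame(
      name = as.character(net$nodes$column),
      class = net$nodes$class, degree = net$nodes$degree))
  if (!is.null(edge_path)) {
    write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(g)
}

#' Summarise a network as JSON
#' @param net an [build_network()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_summary <- function(net, path) {
  jsonlite::write_json(list(
    threshold = net$threshold,
    n_nodes = nrow(net$nodes),
    n_edges = nrow(net$edges),
    classes = as.list(table(net$nodes$class)),
    sdn_sizes = lengths(net$components)
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
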