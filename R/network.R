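# Merging of the pairwise bipartite networks into one typed undirected
# graph, the minimum-membership node filter, topology metrics and
# connectivity-hub detection. Graph algorithms (components, distances,
# local clustering) are delegated to igraph.

#' Merge pairwise networks into one typed graph
#'
#' Takes the union of nodes and edges of all pairwise networks. Each
#' node's membership count (in how many of the contributing networks it
#' appears) is recorded for the downstream filter. Duplicate edges — the
#' same unordered node pair contributed by several networks, which cannot
#' happen among type-distinct pairwise networks but can with user-supplied
#' inputs — are collapsed keeping the maximum-magnitude weight, with the
#' provenance list retained. The graph is simple and undirected.
#'
#' @param networks Non-empty list of `pairwise_network` objects (see
#'   [build_pairwise_network()]); node IDs must be globally unique within
#'   a data type and no ID may carry two different types.
#' @return A `merged_network`: `nodes` (data frame `id`, `data_type`,
#'   `n_networks`) and `edges` (data frame `from`, `to`, `weight`, `sign`,
#'   `from_type`, `to_type`, `networks`).
#' @export
merge_networks <- function(networks) {
  if (!length(networks)) stop("empty network list")
  node_rows <- list()
  edge_rows <- list()
  for (net in networks) {
    e <- net$edges
    if (!nrow(e)) next
    node_rows[[length(node_rows) + 1L]] <- data.frame(
      id = c(unique(e$from), unique(e$to)),
      data_type = rep(c(net$data_type_x, net$data_type_y),
                      c(length(unique(e$from)), length(unique(e$to)))),
      network = net$label, stringsAsFactors = FALSE)
    e$networks <- net$label
    edge_rows[[length(edge_rows) + 1L]] <- e
  }
  if (!length(edge_rows)) stop("all input networks are empty")
  nr <- do.call(rbind, node_rows)
  type_of <- tapply(nr$data_type, nr$id, unique)
  multi <- names(type_of)[lengths(type_of) > 1L]
  if (length(multi))
    stop("conflicting data-type labels for node(s): ",
         paste(multi, collapse = ", "))
  membership <- tapply(nr$network, nr$id, function(x) length(unique(x)))
  ids <- sort(names(membership))
  nodes <- data.frame(id = ids,
                      data_type = unlist(type_of[ids], use.names = FALSE),
                      n_networks = as.integer(membership[ids]),
                      stringsAsFactors = FALSE)
  ee <- do.call(rbind, edge_rows)
  key <- paste(pmin(ee$from, ee$to), pmax(ee$from, ee$to), sep = "\r")
  if (anyDuplicated(key)) {
    ee <- do.call(rbind, lapply(split(ee, key), function(d) {
      best <- d[which.max(abs(d$weight)), , drop = FALSE]
      best$networks <- paste(sort(unique(d$networks)), collapse = ";")
      best
    }))
  }
  ee <- ee[order(ee$from, ee$to), , drop = FALSE]
  rownames(ee) <- NULL
  structure(list(nodes = nodes, edges = ee), class = "merged_network")
}

#' @export
print.merged_network <- function(x, ...) {
  cat(sprintf("<merged_network> %d nodes (%d types), %d edges\n",
              nrow(x$nodes), length(unique(x$nodes$data_type)),
              nrow(x$edges)))
  invisible(x)
}

#' Filter nodes by network membership
#'
#' Keeps only nodes present in at least `k` of the contributing pairwise
#' networks (default 2), then drops edges incident to a removed node. The
#' filter is a single pass: membership counts always refer to the original
#' networks, so it is idempotent. An equivalent formulation counts
#' distinct neighbour data types instead of networks (`variant =
#' "types"`); the two coincide when every pairwise network joins a
#' distinct type pair. Nodes left without any edge are dropped.
#'
#' @param merged A `merged_network`.
#' @param k Minimum membership count (default 2).
#' @param variant `"networks"` (membership in contributing networks, the
#'   default) or `"types"` (distinct neighbour data types).
#' @return The filtered `merged_network`.
#' @export
filter_min_membership <- function(merged, k = 2L, variant = c("networks", "types")) {
  variant <- match.arg(variant)
  count <- if (variant == "networks") {
    stats::setNames(merged$nodes$n_networks, merged$nodes$id)
  } else {
    e <- merged$edges
    nb_types <- tapply(c(e$to_type, e$from_type), c(e$from, e$to),
                       function(x) length(unique(x)))
    out <- stats::setNames(rep(0L, nrow(merged$nodes)), merged$nodes$id)
    out[names(nb_types)] <- as.integer(nb_types)
    out
  }
  keep <- names(count)[count >= k]
  e <- merged$edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  still <- unique(c(e$from, e$to))
  nodes <- merged$nodes[merged$nodes$id %in% still, , drop = FALSE]
  rownames(nodes) <- rownames(e) <- NULL
  structure(list(nodes = nodes, edges = e), class = "merged_network")
}

as_igraph <- function(merged) {
  igraph::graph_from_data_frame(
    merged$edges[, c("from", "to", "weight", "sign")],
    directed = FALSE,
    vertices = merged$nodes[, c("id", "data_type")])
}

#' Topology report of a merged network
#'
#' Computes the summary statistics of the merged-network table: node and
#' edge counts (total and per data type), degree range, average number of
#' neighbours, average local clustering coefficient (a node with fewer
#' than 2 neighbours contributes 0), characteristic path length — defined
#' as the *median* over nodes of each node's mean shortest-path distance
#' to the other nodes it can reach — density `2E / (N (N - 1))`, and the
#' number of connected components.
#'
#' @param merged A non-empty `merged_network` (or `pairwise_network`,
#'   coerced via its edge list).
#' @return A `topology_report` list, including the per-node table
#'   `node_metrics` (`id`, `data_type`, `degree`, `clustering`).
#' @export
network_topology <- function(merged) {
  if (inherits(merged, "pairwise_network")) merged <- merge_networks(list(merged))
  if (!nrow(merged$nodes)) stop("empty network")
  g <- as_igraph(merged)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  d <- igraph::distances(g, weights = NA) # hop counts, not signed weights
  diag(d) <- NA
  mean_dist <- apply(d, 1L, function(row) {
    r <- row[is.finite(row)]
    if (length(r)) mean(r) else NA_real_
  })
  cpl <- stats::median(mean_dist, na.rm = TRUE)
  density <- if (n > 1) 2 * m / (n * (n - 1)) else 0
  structure(
    list(n_nodes = n, n_edges = m,
         nodes_per_type = table(merged$nodes$data_type),
         degree_range = range(deg),
         avg_neighbors = mean(deg),
         clustering = mean(cc),
         char_path_length = cpl,
         density = density,
         n_components = igraph::count_components(g),
         node_metrics = data.frame(
           id = igraph::V(g)$name,
           data_type = igraph::V(g)$data_type,
           degree = as.integer(deg), clustering = cc,
           stringsAsFactors = FALSE, row.names = NULL)),
    class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Network statistics\n")
  cat(sprintf("  Total number of nodes   %d\n", x$n_nodes))
  cat(sprintf("  Total number of edges   %d\n", x$n_edges))
  for (ty in names(x$nodes_per_type))
    cat(sprintf("  %s nodes   %d\n", ty, x$nodes_per_type[[ty]]))
  cat(sprintf("  Degree range            %d-%d\n",
              x$degree_range[1L], x$degree_range[2L]))
  cat(sprintf("  Average neighbors       %.2f\n", x$avg_neighbors))
  cat(sprintf("  Clustering coefficient  %.2f\n", x$clustering))
  cat(sprintf("  Characteristic path length  %.2f\n", x$char_path_length))
  cat(sprintf("  Network density         %.2f\n", x$density))
  cat(sprintf("  Connected components    %d\n", x$n_components))
  invisible(x)
}

#' Connectivity hubs
#'
#' A node is a connectivity hub when its neighbours span every data type
#' present in the network other than the node's own — with five types, a
#' hub touches all four other layers.
#'
#' @param merged A `merged_network` with at least two data types.
#' @return Data frame `id`, `data_type`, `n_neighbor_types`, `is_hub`.
#' @export
find_hubs <- function(merged) {
  types <- unique(merged$nodes$data_type)
  if (length(types) < 2L) stop("hub detection needs >= 2 data types")
  e <- merged$edges
  nb_types <- tapply(c(e$to_type, e$from_type), c(e$from, e$to),
                     function(x) unique(x), simplify = FALSE)
  res <- merged$nodes[, c("id", "data_type"), drop = FALSE]
  res$n_neighbor_types <- vapply(res$id, function(v) {
    nt <- nb_types[[v]]
    if (is.null(nt)) 0L else length(nt)
  }, integer(1))
  res$is_hub <- mapply(function(v, own) {
    nt <- nb_types[[v]]
    !is.null(nt) && all(setdiff(types, own) %in% nt)
  }, res$id, res$data_type)
  rownames(res) <- NULL
  res
}

#' Write node attributes TSV
#'
#' Columns: `id`, `data_type`, `degree`, `clustering`, `is_hub`.
#'
#' @param merged A `merged_network`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_node_attributes <- function(merged, path) {
  topo <- network_topology(merged)
  hubs <- find_hubs(merged)
  df <- merge(topo$node_metrics, hubs[, c("id", "is_hub")], by = "id")
  df$clustering <- round(df$clustering, 10)
  utils::write.table(df[order(df$id), ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a SIF file for Cytoscape
#'
#' Simple interaction format: `source  <sign>  target`, one edge per line.
#'
#' @param network A `pairwise_network` or `merged_network`.
#' @param path Output SIF path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  e <- network$edges
  writeLines(paste(e$from, e$sign, e$to, sep = "\t"), path)
  invisible(path)
}
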