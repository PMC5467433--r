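# End-to-end driver: screen every block, integrate every pair, optionally
# build permutation nulls, merge, filter and report. One master seed is
# split deterministically into per-pair substreams so that adding a block
# does not perturb the randomness of unrelated pairs.

#' Run the full multi-omics integration pipeline
#'
#' Stages: (1) per-block differential screen and restriction to the
#' selected features; (2) pairwise sPLS integration of every pair of
#' screened blocks (`C(B, 2)` networks); (3) optional permutation null
#' model per pair; (4) merging, minimum-membership filtering, topology and
#' hub detection. Blocks whose screen selects nothing are dropped from the
#' integration with a warning.
#'
#' @param blocks Named list of [omics_block()]s with distinct `data_type`
#'   labels (>= 2).
#' @param fdr_thresholds Scalar or per-block (recycled/named) FDR
#'   cut-offs for the screen.
#' @param log_offsets Scalar or per-block pseudo-offsets for the log
#'   transform.
#' @param spls An [spls_config()].
#' @param fraction Per-sign retained fraction for the dynamic thresholds.
#' @param null_iterations Number of permutation iterations per pair; 0
#'   (default) skips the null model stage.
#' @param min_networks Minimum-membership filter threshold for the merged
#'   network (default 2). Capped at `B - 1` so that with two blocks the
#'   merged network equals the single pairwise network.
#' @param seed Master seed for the null models (and any other stochastic
#'   stage); per-pair seeds are derived from it.
#' @param out_dir Optional directory; when given, all per-stage TSVs, the
#'   JSON report and the run manifest are written there.
#' @return A `pipeline_result` list: `screens`, `networks` (named by
#'   `typeA~typeB`), `associations`, `nulls`, `null_comparisons`,
#'   `pair_summary` (per-network data frame with thresholds, node counts
#'   per side, edge and component counts), `merged`, `filtered`,
#'   `topology`, `hubs`, `manifest`.
#' @examples
#' sim <- generate_blocks(sim_config(list(
#'   sim_block_spec("cytokine", 25, 24, prop_responsive = 0.4),
#'   sim_block_spec("metabolomics_serum", 30, 24, prop_responsive = 0.4),
#'   sim_block_spec("microbiota", 20, 20, prop_responsive = 0.4)
#' ), n_groups = 4, seed = 11))
#' res <- run_pipeline(sim$blocks, fdr_thresholds = 0.1, seed = 1)
#' res$pair_summary
#' @export
run_pipeline <- function(blocks, fdr_thresholds = 0.05, log_offsets = 0,
                         spls = spls_config(), fraction = 0.05,
                         null_iterations = 0, min_networks = 2L,
                         seed = 1L, out_dir = NULL) {
  if (length(blocks) < 2L) stop("need at least two blocks")
  types <- vapply(blocks, `[[`, character(1), "data_type")
  if (anyDuplicated(types)) stop("block data_type labels must be distinct")
  names(blocks) <- types
  fdr_thresholds <- expand_per_block(fdr_thresholds, types, "fdr_thresholds")
  log_offsets <- expand_per_block(log_offsets, types, "log_offsets")

  screens <- list()
  screened <- list()
  for (ty in types) {
    sc <- screen_block(blocks[[ty]], fdr_threshold = fdr_thresholds[[ty]],
                       log_offset = log_offsets[[ty]])
    screens[[ty]] <- sc
    if (length(sc$selected)) {
      screened[[ty]] <- subset_features(sc$block, sc$selected)
    } else {
      warning("block '", ty, "' selected no features; excluded from integration")
    }
  }
  if (length(screened) < 2L)
    stop("fewer than two blocks survive the screen; nothing to integrate")

  pairs <- utils::combn(names(screened), 2L)
  n_pairs <- ncol(pairs)
  pair_seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L,
                                                 n_pairs))
  networks <- list()
  associations <- list()
  nulls <- list()
  null_cmp <- list()
  summary_rows <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    ta <- pairs[1L, k]; tb <- pairs[2L, k]
    label <- paste(ta, tb, sep = "~")
    res <- tryCatch(
      build_pairwise_network(screened[[ta]], screened[[tb]],
                             config = spls, fraction = fraction),
      error = function(e) stop("pairwise integration failed for ", label,
                               ": ", conditionMessage(e), call. = FALSE))
    networks[[label]] <- res$network
    associations[[label]] <- res$association
    if (null_iterations > 0) {
      nd <- null_threshold_distribution(screened[[ta]], screened[[tb]],
                                        config = spls, fraction = fraction,
                                        n_iterations = null_iterations,
                                        seed = pair_seeds[k])
      nulls[[label]] <- nd
      null_cmp[[label]] <- compare_to_null(res$association$th_l,
                                           res$association$th_h,
                                           res$network$edges$weight, nd)
    }
    summary_rows[[k]] <- data.frame(
      pair = label, th_l = res$association$th_l, th_h = res$association$th_h,
      nodes_x = res$network$n_nodes_x, nodes_y = res$network$n_nodes_y,
      edges = nrow(res$network$edges),
      components = res$network$n_components, stringsAsFactors = FALSE)
  }
  pair_summary <- do.call(rbind, summary_rows)

  merged <- merge_networks(networks)
  k_eff <- min(min_networks, length(screened) - 1L)
  filtered <- filter_min_membership(merged, k = k_eff)
  topo <- if (nrow(filtered$nodes)) network_topology(filtered) else NULL
  hubs <- if (nrow(filtered$nodes)) find_hubs(filtered) else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("plsnet")),
    data_types = types,
    n_features = vapply(blocks, function(b) nrow(b$values), integer(1)),
    n_samples = vapply(blocks, function(b) ncol(b$values), integer(1)),
    fdr_thresholds = fdr_thresholds, log_offsets = log_offsets,
    spls = unclass(spls), fraction = fraction,
    null_iterations = null_iterations, min_networks = k_eff,
    seed = seed,
    pair_seeds = as.list(stats::setNames(
      pair_seeds, apply(pairs, 2L, paste, collapse = "~"))))

  out <- structure(
    list(screens = screens, networks = networks, associations = associations,
         nulls = nulls, null_comparisons = null_cmp,
         pair_summary = pair_summary, merged = merged, filtered = filtered,
         topology = topo, hubs = hubs, manifest = manifest),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

expand_per_block <- function(x, types, what) {
  if (length(x) == 1L) x <- rep(x, length(types))
  if (is.null(names(x))) {
    if (length(x) != length(types))
      stop("`", what, "` must be scalar, per-block, or named")
    names(x) <- types
  }
  missing <- setdiff(types, names(x))
  if (length(missing))
    stop("`", what, "` missing entries for: ", paste(missing, collapse = ", "))
  as.list(x[types])
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d blocks -> %d pairwise networks\n",
              length(x$screens), length(x$networks)))
  if (!is.null(x$topology)) {
    cat(sprintf("  merged (filtered): %d nodes, %d edges, %d hub(s)\n",
                x$topology$n_nodes, x$topology$n_edges,
                if (!is.null(x$hubs)) sum(x$hubs$is_hub) else 0L))
  }
  invisible(x)
}

#' Serialise a topology report (and hubs) as JSON
#'
#' @param topology A `topology_report`.
#' @param hubs Optional hub data frame from [find_hubs()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(topology, path, hubs = NULL) {
  rep <- list(
    n_nodes = topology$n_nodes, n_edges = topology$n_edges,
    nodes_per_type = as.list(topology$nodes_per_type),
    degree_range = topology$degree_range,
    avg_neighbors = topology$avg_neighbors,
    clustering = topology$clustering,
    char_path_length = topology$char_path_length,
    density = topology$density, n_components = topology$n_components)
  if (!is.null(hubs)) {
    rep$n_hubs <- sum(hubs$is_hub)
    rep$hubs_per_type <- as.list(table(hubs$data_type[hubs$is_hub]))
    rep$hub_ids <- hubs$id[hubs$is_hub]
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (ty in names(res$screens))
    write_screen_report(res$screens[[ty]],
                        file.path(out_dir, paste0("screen_", ty, ".tsv")))
  for (label in names(res$networks))
    write_edge_list(res$networks[[label]],
                    file.path(out_dir,
                              paste0("network_", gsub("~", "_", label), ".tsv")))
  for (label in names(res$nulls))
    write_null_distribution(res$nulls[[label]],
                            file.path(out_dir,
                                      paste0("null_", gsub("~", "_", label), ".tsv")))
  utils::write.table(within(res$pair_summary, {
    th_l <- round(th_l, 10); th_h <- round(th_h, 10)
  }), file.path(out_dir, "pair_summary.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
  write_edge_list(res$filtered, file.path(out_dir, "merged_edges.tsv"))
  write_sif(res$filtered, file.path(out_dir, "merged.sif"))
  if (!is.null(res$topology)) {
    write_node_attributes(res$filtered,
                          file.path(out_dir, "merged_nodes.tsv"))
    write_report(res$topology, file.path(out_dir, "merged_report.json"),
                 hubs = res$hubs)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
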