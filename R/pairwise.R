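# One association network per pair of omics blocks: sPLS run in both
# predictor/response orientations, the two masked correlation matrices
# combined by M = Ma + t(Mb), dynamic dual thresholds keeping the top
# fraction of positive and of negative weights, and the binary adjacency /
# bipartite edge list derived from them.

#' Align two blocks on their shared samples
#'
#' @param block_x,block_y [omics_block()]s on the analysis (log2) scale.
#' @param min_shared Minimum number of shared sample IDs (default 3; with
#'   fewer, a Pearson correlation is meaningless).
#' @return List with `X` and `Y` (samples x features matrices restricted
#'   to the shared samples, identically ordered) and `samples`.
#' @export
align_samples <- function(block_x, block_y, min_shared = 3L) {
  shared <- intersect(sample_ids(block_x), sample_ids(block_y))
  if (length(shared) < min_shared)
    stop("blocks '", block_x$data_type, "' and '", block_y$data_type,
         "' share only ", length(shared), " sample(s); need >= ", min_shared)
  list(X = t(block_x$values[, shared, drop = FALSE]),
       Y = t(block_y$values[, shared, drop = FALSE]),
       samples = shared)
}

#' Combine the two orientation-specific association matrices
#'
#' `M = Ma + t(Mb)`: a pair detected in both orientations with correlation
#' r gets combined weight 2r; a pair detected in one orientation keeps r.
#'
#' @param ma `n_x x n_y` matrix (X as predictor).
#' @param mb `n_y x n_x` matrix (roles swapped).
#' @return The `n_x x n_y` combined matrix.
#' @export
combine_association <- function(ma, mb) {
  if (!identical(dim(ma), rev(dim(mb))))
    stop("shape mismatch: ma is ", paste(dim(ma), collapse = "x"),
         ", mb is ", paste(dim(mb), collapse = "x"))
  ma + t(mb)
}

#' Dynamic dual thresholds
#'
#' The upper threshold is the value of the `ceiling(fraction * n_pos)`-th
#' largest positive non-zero weight, the lower threshold the corresponding
#' most-negative order statistic, so that the top `fraction` of positive
#' and of negative weights are retained (entries tied with the threshold
#' are all kept, matching the inclusive comparisons of the adjacency
#' rule). Structural zeros are not part of the weight population.
#'
#' @param m Combined association matrix.
#' @param fraction Fraction per sign to retain, in (0, 0.5\] (default
#'   0.05, i.e. the top 5 percent).
#' @return List with `th_l` (< 0), `th_h` (> 0), and the retained
#'   `retained_pos` / `retained_neg` weight vectors. When one sign is
#'   absent the corresponding threshold is `+Inf` / `-Inf` (one-sided
#'   network) and a warning is raised.
#' @export
dynamic_thresholds <- function(m, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 0.5)
  pos <- m[m > 0]
  neg <- m[m < 0]
  if (!length(pos) && !length(neg))
    stop("no non-zero weights; cannot derive thresholds")
  if (length(pos)) {
    k <- ceiling(fraction * length(pos))
    th_h <- sort(pos, decreasing = TRUE)[k]
  } else {
    warning("no positive weights; positive tail is empty")
    th_h <- Inf
  }
  if (length(neg)) {
    k <- ceiling(fraction * length(neg))
    th_l <- sort(neg)[k]
  } else {
    warning("no negative weights; negative tail is empty")
    th_l <- -Inf
  }
  list(th_l = th_l, th_h = th_h,
       retained_pos = pos[pos >= th_h], retained_neg = neg[neg <= th_l])
}

#' Binary adjacency from the dual thresholds
#'
#' `A[i, j] = 1` iff `m[i, j] >= th_h` or `m[i, j] <= th_l`.
#'
#' @param m Combined association matrix.
#' @param th_l,th_h Thresholds with `th_l < 0 < th_h`.
#' @return Binary (0/1) matrix of the same shape as `m`.
#' @export
adjacency_matrix <- function(m, th_l, th_h) {
  stopifnot(th_l < 0, th_h > 0)
  (m >= th_h | m <= th_l) * 1L
}

#' Build the association network for one pair of blocks
#'
#' Runs [spls_fit()] in both orientations, masks the Pearson correlations
#' by the dependency pattern ([association_ma()]), combines the two
#' matrices, derives the dynamic dual thresholds and emits the bipartite
#' weighted edge list. Pass blocks already restricted to their screened
#' (significant) features and on the log2 scale — e.g. the `block` element
#' of a [screen_block()] result subset with [subset_features()].
#'
#' @param block_x,block_y Screened, log2-scale [omics_block()]s of two
#'   different data types.
#' @param config An [spls_config()]. `ncomp` is capped at
#'   `min(n_x, n_y, n_shared_samples - 1)` so that small screened blocks
#'   remain integrable with the default of 5 components.
#' @param fraction Per-sign retained fraction, see [dynamic_thresholds()].
#' @return List with
#'   \describe{
#'     \item{association}{an `association_matrix`: `ma`, `mb`, `m`,
#'       `th_l`, `th_h`, binary `a`, data-type labels and feature IDs.}
#'     \item{network}{a `pairwise_network`: bipartite edge data frame
#'       (`from`, `to`, `weight`, `sign`, `from_type`, `to_type`), node
#'       counts per side, connected-component count and thresholds.
#'       Features with no retained edge are not emitted.}
#'   }
#' @export
build_pairwise_network <- function(block_x, block_y, config = spls_config(),
                                   fraction = 0.05) {
  if (block_x$data_type == block_y$data_type)
    stop("pairwise integration requires two different data types")
  al <- align_samples(block_x, block_y)
  n <- length(al$samples)
  eff <- config
  eff$ncomp <- min(config$ncomp, ncol(al$X), ncol(al$Y), n - 1L)
  fit_a <- spls_fit(al$X, al$Y, eff)
  fit_b <- spls_fit(al$Y, al$X, eff)
  ma <- association_ma(al$X, al$Y, dependency_pairs(fit_a))
  mb <- association_ma(al$Y, al$X, dependency_pairs(fit_b))
  m <- combine_association(ma, mb)
  th <- dynamic_thresholds(m, fraction)
  a <- adjacency_matrix(m, th$th_l, th$th_h)
  assoc <- structure(
    list(ma = ma, mb = mb, m = m, th_l = th$th_l, th_h = th$th_h, a = a,
         data_type_x = block_x$data_type, data_type_y = block_y$data_type,
         feature_ids_x = rownames(m), feature_ids_y = colnames(m)),
    class = "association_matrix")
  list(association = assoc,
       network = pairwise_network(assoc))
}

#' Bipartite edge list of an association matrix
#'
#' @param assoc An `association_matrix` (see [build_pairwise_network()]).
#' @return A `pairwise_network` object.
#' @export
pairwise_network <- function(assoc) {
  idx <- which(assoc$a == 1L, arr.ind = TRUE)
  w <- assoc$m[idx]
  edges <- data.frame(
    from = assoc$feature_ids_x[idx[, 1L]],
    to = assoc$feature_ids_y[idx[, 2L]],
    weight = w,
    sign = ifelse(w > 0, "positive", "negative"),
    from_type = assoc$data_type_x, to_type = assoc$data_type_y,
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  n_comp <- if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       directed = FALSE)
    igraph::count_components(g)
  } else 0L
  structure(
    list(edges = edges,
         data_type_x = assoc$data_type_x, data_type_y = assoc$data_type_y,
         label = paste(assoc$data_type_x, assoc$data_type_y, sep = "~"),
         n_nodes_x = length(unique(edges$from)),
         n_nodes_y = length(unique(edges$to)),
         n_components = n_comp,
         th_l = assoc$th_l, th_h = assoc$th_h),
    class = "pairwise_network")
}

#' @export
print.pairwise_network <- function(x, ...) {
  cat(sprintf(
    "<pairwise_network> %s: %d + %d nodes, %d edges, %d component(s), th_l = %.3f, th_h = %.3f\n",
    x$label, x$n_nodes_x, x$n_nodes_y, nrow(x$edges), x$n_components,
    x$th_l, x$th_h))
  invisible(x)
}

#' Write an edge list TSV (Cytoscape-importable)
#'
#' Columns: `source`, `target`, `weight`, `sign`, `source_type`,
#' `target_type`.
#'
#' @param network A `pairwise_network` or `merged_network`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  e <- network$edges
  df <- data.frame(source = e$from, target = e$to,
                   weight = round(e$weight, 10), sign = e$sign,
                   source_type = e$from_type, target_type = e$to_type,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
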