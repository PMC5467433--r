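# Shared fixtures and independent oracles, all built in code.

# quick omics_block from a matrix (2 groups by default)
make_block <- function(values, data_type = "cytokine",
                       groups = NULL, reference = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("%s_f%02d", data_type, seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(groups)) {
    half <- ceiling(ncol(values) / 2)
    groups <- setNames(rep(c("ctrl", "trt"), c(half, ncol(values) - half)),
                       colnames(values))
  }
  if (is.null(reference)) reference <- groups[[1L]]
  omics_block(values, data_type, groups, reference)
}

# random Gaussian block on the log scale
random_log_block <- function(p, n, data_type = "cytokine", sd = 1,
                             n_groups = 2) {
  v <- matrix(rnorm(p * n, mean = 8, sd = sd), p, n)
  make_block(v, data_type,
             groups = setNames(sort(rep_len(paste0("g", seq_len(n_groups)), n)),
                               sprintf("s%02d", seq_len(n))),
             reference = "g1")
}

# brute-force Benjamini-Hochberg step-up: p * n / rank, cumulative min from
# the largest p downward, capped at 1
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# two-block generator with planted cross-block pairs, returned log2-scaled
planted_pair_blocks <- function(p = 12, q = 12, n_retained = 30,
                                n_planted = 10, r = 0.85, seed = 1,
                                n_groups = 6, mice_per_group = 6,
                                prop_responsive = 0) {
  stopifnot(n_planted <= min(p, q))
  pp <- if (n_planted > 0) {
    data.frame(block_a = "cytokine", feature_a = seq_len(n_planted),
               block_b = "microbiota", feature_b = seq_len(n_planted),
               r = rep(c(r, -r), length.out = n_planted))
  } else NULL
  cfg <- sim_config(list(
    sim_block_spec("cytokine", p, n_retained,
                   prop_responsive = prop_responsive),
    sim_block_spec("microbiota", q, n_retained,
                   prop_responsive = prop_responsive)),
    n_groups = n_groups, mice_per_group = mice_per_group,
    planted_pairs = pp, seed = seed)
  sim <- generate_blocks(cfg)
  list(blocks = lapply(sim$blocks, log_transform), truth = sim$truth)
}

# random typed graph as a merged_network, for hub/topology oracles
random_typed_network <- function(n_nodes = 20, n_types = 4, p_edge = 0.2) {
  types <- paste0("T", seq_len(n_types))
  node_type <- setNames(sample(types, n_nodes, replace = TRUE),
                        sprintf("n%02d", seq_len(n_nodes)))
  pairs <- t(combn(names(node_type), 2))
  # cross-type edges only, as in the pipeline's bipartite networks
  cross <- node_type[pairs[, 1]] != node_type[pairs[, 2]]
  keep <- cross & runif(nrow(pairs)) < p_edge
  e <- pairs[keep, , drop = FALSE]
  w <- runif(nrow(e), -1, 1)
  edges <- data.frame(from = e[, 1], to = e[, 2], weight = w,
                      sign = ifelse(w > 0, "positive", "negative"),
                      from_type = unname(node_type[e[, 1]]),
                      to_type = unname(node_type[e[, 2]]),
                      networks = "synthetic", stringsAsFactors = FALSE)
  ids <- sort(unique(c(edges$from, edges$to)))
  nodes <- data.frame(id = ids, data_type = unname(node_type[ids]),
                      n_networks = 1L, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "merged_network")
}

# build a merged_network directly from an edge list and a node-type map
make_merged <- function(from, to, types, weight = NULL) {
  if (is.null(weight)) weight <- rep(1, length(from))
  edges <- data.frame(from = from, to = to, weight = weight,
                      sign = ifelse(weight > 0, "positive", "negative"),
                      from_type = unname(types[from]),
                      to_type = unname(types[to]),
                      networks = "manual", stringsAsFactors = FALSE)
  ids <- sort(unique(c(from, to)))
  nodes <- data.frame(id = ids, data_type = unname(types[ids]),
                      n_networks = 1L, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "merged_network")
}

# brute-force hub oracle: enumerate every node's neighbour types directly
hubs_brute <- function(merged) {
  types <- unique(merged$nodes$data_type)
  sapply(merged$nodes$id, function(v) {
    e <- merged$edges
    nb <- c(e$to[e$from == v], e$from[e$to == v])
    nt <- unique(merged$nodes$data_type[match(nb, merged$nodes$id)])
    own <- merged$nodes$data_type[merged$nodes$id == v]
    all(setdiff(types, own) %in% nt)
  })
}

# minimal spls_fit stub for dependency-pattern tests
fake_spls_fit <- function(x_features, y_features, selected_x, selected_y) {
  structure(list(
    x_loadings = matrix(0, length(x_features), length(selected_x),
                        dimnames = list(x_features, NULL)),
    y_loadings = matrix(0, length(y_features), length(selected_y),
                        dimnames = list(y_features, NULL)),
    selected_x = selected_x, selected_y = selected_y),
    class = "spls_fit")
}

# five-block desk-scale design with planted cross-block pairs
five_block_sim <- function(seed = 101) {
  pp <- data.frame(
    block_a = c(rep("cytokine", 3), rep("microbiota", 3),
                rep("metabolomics_serum", 2)),
    feature_a = c(1:3, 1:3, 4:5),
    block_b = c(rep("metabolomics_serum", 3), rep("transcriptomics", 3),
                rep("metabolomics_urine", 2)),
    feature_b = c(1:3, 1:3, 1:2),
    r = c(0.85, -0.85, 0.85, 0.85, -0.85, 0.85, 0.85, -0.85))
  cfg <- sim_config(list(
    sim_block_spec("transcriptomics", 40, 33, prop_responsive = 0.5),
    sim_block_spec("microbiota", 25, 33, prop_responsive = 0.6),
    sim_block_spec("cytokine", 23, 36, prop_responsive = 0.6),
    sim_block_spec("metabolomics_serum", 30, 36, prop_responsive = 0.6),
    sim_block_spec("metabolomics_urine", 16, 28, prop_responsive = 1.0)),
    planted_pairs = pp, seed = seed)
  generate_blocks(cfg)
}

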