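# Synthetic multi-block generator.
#
# Generative model, on the log2 scale, for feature f of block b in sample s:
#   L[f, s] = baseline_f + delta_f * I(group(s) in affected_f) * effect_size
#             + lambda_f * U[p(f), s] + eps,   eps ~ N(0, noise_sd_b^2)
# where U holds one shared standard-normal latent factor per planted pair and
# lambda is chosen analytically so the pair attains its target Pearson
# correlation on the log scale. Output values are 2^L, so the pipeline's own
# log transform is exercised. Diet-responsive features and planted-pair
# features are disjoint, which keeps the closed-form correlation exact.

#' Specification of one synthetic omics block
#'
#' @param data_type Block label (must be unique across specs).
#' @param n_features Number of features to simulate.
#' @param n_samples_retained Number of samples kept after simulated
#'   quality-control dropout (at most the full design size).
#' @param noise_sd Standard deviation of the per-cell Gaussian noise on the
#'   log2 scale.
#' @param prop_responsive Fraction of features given a diet effect.
#' @return A `sim_block_spec` list.
#' @seealso [sim_config()], [generate_blocks()]
#' @export
sim_block_spec <- function(data_type, n_features, n_samples_retained,
                           noise_sd = 0.5, prop_responsive = 0.2) {
  stopifnot(n_features >= 1, n_samples_retained >= 1, noise_sd > 0,
            prop_responsive >= 0, prop_responsive <= 1)
  structure(list(data_type = data_type, n_features = as.integer(n_features),
                 n_samples_retained = as.integer(n_samples_retained),
                 noise_sd = noise_sd, prop_responsive = prop_responsive),
            class = "sim_block_spec")
}

#' Default five-block design
#'
#' Desk-scale stand-ins for the five internal-phenotype layers of the
#' motivating mouse feeding trial: 36 mice in 6 diet groups, with per-block
#' sample retention mirroring the real blocks (33/33/36/36/28) and feature
#' counts scaled down from the assay sizes (the transcriptome block keeps
#' its 16,410 probes only when you ask for them via `n_features`).
#'
#' @return List of five [sim_block_spec()] objects.
#' @export
default_block_specs <- function() {
  list(
    sim_block_spec("transcriptomics",    200, 33, noise_sd = 0.5, prop_responsive = 0.15),
    sim_block_spec("microbiota",          50, 33, noise_sd = 0.5, prop_responsive = 0.30),
    sim_block_spec("cytokine",            23, 36, noise_sd = 0.5, prop_responsive = 0.50),
    sim_block_spec("metabolomics_serum",  41, 36, noise_sd = 0.5, prop_responsive = 0.60),
    sim_block_spec("metabolomics_urine",  16, 28, noise_sd = 0.5, prop_responsive = 1.00)
  )
}

#' Configuration for the synthetic multi-omics generator
#'
#' @param block_specs List of [sim_block_spec()] objects (>= 2, distinct
#'   `data_type` labels).
#' @param n_groups Number of diet groups (default 6, as in the feeding
#'   trial: one reference protein source plus five alternatives).
#' @param mice_per_group Animals per group (default 6, i.e. 36 samples).
#' @param effect_size Diet shift for responsive features, in log2 units.
#'   The default 1.5 equals three noise standard deviations at the default
#'   `noise_sd = 0.5`, a clearly detectable but not degenerate effect.
#' @param planted_pairs `NULL`, or a data frame with columns `block_a`,
#'   `feature_a`, `block_b`, `feature_b`, `r`: cross-block feature pairs
#'   (blocks by label, features by index) given a shared latent factor so
#'   their log-scale Pearson correlation equals `r` in the generating
#'   model. Each feature may appear in at most one pair; `|r| < 1` (a
#'   perfect correlation is infeasible with positive noise and raises an
#'   error rather than being clipped).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A `sim_config` list with group labels attached (for the default
#'   six groups the diets are named after their protein source, with
#'   `"soy"` as reference).
#' @export
sim_config <- function(block_specs = default_block_specs(),
                       n_groups = 6, mice_per_group = 6,
                       effect_size = 1.5, planted_pairs = NULL, seed = 1) {
  stopifnot(n_groups >= 2, mice_per_group >= 1)
  if (length(block_specs) < 2L)
    stop("need at least two block specs")
  labels <- vapply(block_specs, `[[`, character(1), "data_type")
  if (anyDuplicated(labels))
    stop("block data_type labels must be distinct")
  n_total <- n_groups * mice_per_group
  for (bs in block_specs)
    if (bs$n_samples_retained > n_total)
      stop("block '", bs$data_type, "' retains more samples (",
           bs$n_samples_retained, ") than the design has (", n_total, ")")
  group_labels <- if (n_groups == 6)
    c("soy", "casein", "whey", "plasma", "gluten", "mealworm")
  else sprintf("diet%d", seq_len(n_groups))
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs)
    need <- c("block_a", "feature_a", "block_b", "feature_b", "r")
    if (!all(need %in% names(planted_pairs)))
      stop("planted_pairs needs columns ", paste(need, collapse = ", "))
    if (any(abs(planted_pairs$r) > 1))
      stop("planted target correlations must lie in [-1, 1]")
    if (any(planted_pairs$block_a == planted_pairs$block_b))
      stop("planted pairs must connect two different blocks")
    bad <- setdiff(c(planted_pairs$block_a, planted_pairs$block_b), labels)
    if (length(bad)) stop("planted pair references unknown block(s): ",
                          paste(unique(bad), collapse = ", "))
    key <- c(paste(planted_pairs$block_a, planted_pairs$feature_a),
             paste(planted_pairs$block_b, planted_pairs$feature_b))
    if (anyDuplicated(key))
      stop("each feature may appear in at most one planted pair")
  }
  structure(list(block_specs = block_specs, n_groups = n_groups,
                 mice_per_group = mice_per_group,
                 group_labels = group_labels, reference = group_labels[1L],
                 effect_size = effect_size, planted_pairs = planted_pairs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# loading magnitude giving log-scale correlation r between
# (lambda u + N(0, sd_a^2)) and (sign(r) lambda u + N(0, sd_b^2))
planted_loading <- function(r, sd_a, sd_b) {
  if (r == 0) return(0)
  if (abs(r) >= 1)
    stop("target correlation ", r,
         " is infeasible with positive noise (|r| must be < 1)")
  r2 <- r^2
  s2 <- sd_a^2 + sd_b^2
  t <- (r2 * s2 + sqrt(r2^2 * s2^2 + 4 * (1 - r2) * r2 * sd_a^2 * sd_b^2)) /
    (2 * (1 - r2))
  sqrt(t)
}

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic omics blocks with known ground truth
#'
#' Simulates the full design (`n_groups * mice_per_group` animals), applies
#' per-block sample dropout, plants diet effects and cross-block latent
#' correlations, and returns both the blocks and the ground truth needed by
#' recovery tests.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{blocks}{named list of [omics_block()]s, one per spec, with the
#'       requested dimensions; values are on the raw (exponentiated) scale.}
#'     \item{truth}{list with `true_edges` (data frame `block_a`,
#'       `feature_a`, `block_b`, `feature_b`, `r` using feature IDs) and
#'       `responsive` (named list of diet-responsive feature IDs per
#'       block).}
#'   }
#' @details Planted correlations hold on the log2 scale (the scale on which
#'   the pipeline computes all correlations). Responsive features are drawn
#'   from the features not involved in planted pairs; each gets a random
#'   sign and a random non-empty subset of non-reference groups in which the
#'   shift applies, so a feature can be significant in anywhere from one to
#'   all treatment-vs-reference contrasts.
#' @export
generate_blocks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    n_total <- config$n_groups * config$mice_per_group
    samples <- sprintf("M%03d", seq_len(n_total))
    groups <- stats::setNames(
      rep(config$group_labels, each = config$mice_per_group), samples)
    pp <- config$planted_pairs
    n_pairs <- if (is.null(pp)) 0L else nrow(pp)
    U <- if (n_pairs) matrix(stats::rnorm(n_pairs * n_total), n_pairs, n_total)
         else NULL
    labels <- vapply(config$block_specs, `[[`, character(1), "data_type")
    noise_of <- stats::setNames(
      vapply(config$block_specs, `[[`, numeric(1), "noise_sd"), labels)

    blocks <- list()
    responsive <- list()
    id_of <- function(type, idx) sprintf("%s_%03d", type, idx)

    for (bs in config$block_specs) {
      nf <- bs$n_features
      fid <- id_of(bs$data_type, seq_len(nf))
      baseline <- stats::runif(nf, 4, 12)
      L <- matrix(baseline, nf, n_total) # per-feature baseline in every column
      # planted latent contributions
      if (n_pairs) {
        for (k in seq_len(n_pairs)) {
          for (side in c("a", "b")) {
            if (pp[[paste0("block_", side)]][k] != bs$data_type) next
            f <- pp[[paste0("feature_", side)]][k]
            if (f > nf) stop("planted feature index ", f,
                             " exceeds block '", bs$data_type, "' size")
            lam <- planted_loading(pp$r[k], noise_of[pp$block_a[k]],
                                   noise_of[pp$block_b[k]])
            if (side == "b" && pp$r[k] < 0) lam <- -lam
            L[f, ] <- L[f, ] + lam * U[k, ]
          }
        }
      }
      # diet-responsive features (disjoint from planted features)
      planted_here <- integer(0)
      if (n_pairs) {
        planted_here <- c(pp$feature_a[pp$block_a == bs$data_type],
                          pp$feature_b[pp$block_b == bs$data_type])
      }
      candidates <- setdiff(seq_len(nf), planted_here)
      n_resp <- min(round(bs$prop_responsive * nf), length(candidates))
      resp <- sort(sample(candidates, n_resp))
      non_ref <- config$group_labels[-1L]
      for (f in resp) {
        sgn <- sample(c(-1, 1), 1L)
        affected <- sample(non_ref, sample.int(length(non_ref), 1L))
        hit <- groups %in% affected
        L[f, hit] <- L[f, hit] + sgn * config$effect_size
      }
      L <- L + matrix(stats::rnorm(nf * n_total, sd = bs$noise_sd), nf, n_total)
      keep <- sort(sample.int(n_total, bs$n_samples_retained))
      V <- 2^L[, keep, drop = FALSE]
      dimnames(V) <- list(fid, samples[keep])
      blocks[[bs$data_type]] <- omics_block(V, bs$data_type, groups[keep],
                                            config$reference)
      responsive[[bs$data_type]] <- id_of(bs$data_type, resp)
    }

    true_edges <- if (n_pairs) {
      data.frame(block_a = pp$block_a,
                 feature_a = id_of(pp$block_a, pp$feature_a),
                 block_b = pp$block_b,
                 feature_b = id_of(pp$block_b, pp$feature_b),
                 r = pp$r, stringsAsFactors = FALSE)
    } else {
      data.frame(block_a = character(0), feature_a = character(0),
                 block_b = character(0), feature_b = character(0),
                 r = numeric(0))
    }
    list(blocks = blocks,
         truth = list(true_edges = true_edges, responsive = responsive))
  })
}

#' Write a simulated dataset to a directory
#'
#' One feature-table TSV and one sample-group TSV per block (the dialect of
#' [write_omics_block()]), plus `ground_truth_edges.tsv` listing the planted
#' cross-block correlations.
#'
#' @param sim Result of [generate_blocks()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (blk in sim$blocks) {
    write_omics_block(blk,
                      file.path(dir, paste0(blk$data_type, ".tsv")),
                      file.path(dir, paste0(blk$data_type, "_groups.tsv")))
  }
  utils::write.table(sim$truth$true_edges,
                     file.path(dir, "ground_truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
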