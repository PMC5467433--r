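# Permutation null model for the dynamic thresholds: each feature's values
# are shuffled independently across samples (preserving every feature's
# value distribution while destroying all within- and cross-block
# correlation), the full pairwise integration is re-run, and the dynamic
# cut-offs (th_lk, th_hk) are recorded over the iterations. The real
# network's thresholds are then located in this null distribution.

#' Permute a block's values over samples
#'
#' Each feature row is shuffled independently, so the per-feature value
#' multiset (and hence its marginal distribution) is unchanged while all
#' correlation structure is destroyed. Group labels are untouched. Uses
#' the current RNG stream; seed the caller for reproducibility.
#'
#' @param block An [omics_block()] with at least 2 samples.
#' @return The permuted block.
#' @export
permute_block <- function(block) {
  n <- ncol(block$values)
  if (n < 2L) stop("permutation needs at least 2 samples")
  v <- block$values
  for (f in seq_len(nrow(v)))
    v[f, ] <- v[f, sample.int(n)]
  block$values <- v
  block
}

#' Null distribution of the dynamic thresholds
#'
#' For each of `n_iterations` iterations, both blocks are permuted over
#' samples with [permute_block()], [build_pairwise_network()] is re-run on
#' the permuted data, and the resulting thresholds (th_lk, th_hk) are
#' recorded. Iterations in which the sPLS fit degenerates are recorded as
#' missing and skipped; more than 10 percent failures aborts.
#'
#' @param block_x,block_y Screened, log2-scale [omics_block()]s (the same
#'   objects the real network was built from).
#' @param config An [spls_config()].
#' @param fraction Per-sign retained fraction (must match the real
#'   network's).
#' @param n_iterations Number of permutation iterations. The reference
#'   setting is 1,000; smaller values (e.g. 200) already locate the real
#'   thresholds well and keep desk-scale runs fast.
#' @param seed Optional integer; when given, the whole distribution is
#'   reproducible and the caller's RNG state is left untouched.
#' @return A `null_thresholds` object: vectors `th_l` and `th_h` of length
#'   `n_iterations` (NA for failed iterations), `n_iterations`, `seed`,
#'   `pair` label.
#' @export
null_threshold_distribution <- function(block_x, block_y,
                                        config = spls_config(),
                                        fraction = 0.05,
                                        n_iterations = 200, seed = NULL) {
  stopifnot(n_iterations >= 1)
  run <- function() {
    th_l <- th_h <- rep(NA_real_, n_iterations)
    for (k in seq_len(n_iterations)) {
      res <- tryCatch(
        suppressWarnings(build_pairwise_network(
          permute_block(block_x), permute_block(block_y),
          config = config, fraction = fraction)),
        error = function(e) NULL)
      if (!is.null(res)) {
        th_l[k] <- res$association$th_l
        th_h[k] <- res$association$th_h
      }
    }
    n_fail <- sum(is.na(th_h))
    if (n_fail > 0.1 * n_iterations)
      stop("permutation null failed in ", n_fail, " of ", n_iterations,
           " iterations")
    if (n_fail > 0)
      message(n_fail, " degenerate iteration(s) recorded as missing")
    structure(
      list(th_l = th_l, th_h = th_h, n_iterations = n_iterations,
           seed = seed,
           pair = paste(block_x$data_type, block_y$data_type, sep = "~")),
      class = "null_thresholds")
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' @export
print.null_thresholds <- function(x, ...) {
  ok <- !is.na(x$th_h)
  cat(sprintf(
    "<null_thresholds> %s: %d iterations (%d ok); th_h in [%.3f, %.3f], th_l in [%.3f, %.3f]\n",
    x$pair, x$n_iterations, sum(ok),
    min(x$th_h[ok]), max(x$th_h[ok]), min(x$th_l[ok]), max(x$th_l[ok])))
  invisible(x)
}

#' Locate the real thresholds in the permutation null
#'
#' Per tail, the empirical exceedance probability uses add-one smoothing:
#' `p = (1 + #{null thresholds at least as extreme as the real one}) /
#' (n_ok + 1)`, so the most extreme possible real threshold gets
#' `1/(N_it + 1)`, never 0. An overlap flag per tail reports whether any
#' retained real edge weight lies inside the span of the null thresholds
#' (overlap weakens the significance of that tail's edges).
#'
#' @param th_l,th_h Real thresholds of the unpermuted network.
#' @param weights Retained real edge weights (the `weight` column of the
#'   pairwise network's edges).
#' @param null A `null_thresholds` object.
#' @return List: `p_high`, `p_low` (empirical exceedance p per tail),
#'   `overlap_high`, `overlap_low`, `overlap` (either tail), `n_used`
#'   (non-missing iterations).
#' @export
compare_to_null <- function(th_l, th_h, weights, null) {
  stopifnot(inherits(null, "null_thresholds"))
  nh <- null$th_h[!is.na(null$th_h)]
  nl <- null$th_l[!is.na(null$th_l)]
  if (!length(nh) || !length(nl)) stop("null distribution is empty")
  p_high <- (1 + sum(nh >= th_h)) / (length(nh) + 1)
  p_low <- (1 + sum(nl <= th_l)) / (length(nl) + 1)
  pos_w <- weights[weights > 0]
  neg_w <- weights[weights < 0]
  overlap_high <- length(pos_w) > 0 && any(pos_w < max(nh))
  overlap_low <- length(neg_w) > 0 && any(neg_w > min(nl))
  list(p_high = p_high, p_low = p_low,
       overlap_high = overlap_high, overlap_low = overlap_low,
       overlap = overlap_high || overlap_low,
       n_used = min(length(nh), length(nl)))
}

#' Histogram of real weights against the null thresholds
#'
#' Side-by-side view of the retained real edge weights and the null
#' threshold distributions; clear separation of the real thresholds from
#' the null spans indicates significant edges.
#'
#' @param x A `null_thresholds` object.
#' @param real_weights Retained real edge weights.
#' @param real_th Optional `c(th_l, th_h)` of the real network, drawn as
#'   vertical lines.
#' @param ... Passed to [graphics::hist()].
#' @return Invisibly, `NULL`.
#' @export
plot.null_thresholds <- function(x, real_weights = NULL, real_th = NULL, ...) {
  vals <- c(x$th_l, x$th_h, real_weights, real_th)
  vals <- vals[is.finite(vals)]
  graphics::hist(c(x$th_l, x$th_h), breaks = 40,
                 xlim = range(vals), col = "grey70", border = NA,
                 main = paste("Null thresholds:", x$pair),
                 xlab = "combined association weight", ...)
  if (!is.null(real_weights))
    graphics::rug(real_weights, col = "steelblue", lwd = 1.5)
  if (!is.null(real_th))
    graphics::abline(v = real_th, col = "firebrick", lwd = 2)
  invisible(NULL)
}

#' Write a null-threshold distribution as TSV
#'
#' Columns: `iteration`, `th_l`, `th_h`.
#'
#' @param null A `null_thresholds` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_null_distribution <- function(null, path) {
  utils::write.table(
    data.frame(iteration = seq_len(null$n_iterations),
               th_l = round(null$th_l, 10), th_h = round(null$th_h, 10)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
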