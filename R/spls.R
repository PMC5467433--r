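# Sparse partial least squares in regression mode.
#
# Component h maximises cov(X u, Y v) under LASSO-style penalties on the
# loading vectors, solved by the alternating NIPALS scheme on the
# cross-product M = t(X) %*% Y:
#     u <- normalise(soft(M v,  lambda_u))
#     v <- normalise(soft(t(M) u, lambda_v))
# with the soft-threshold level chosen so that exactly keep_x / keep_y
# entries survive. Deflation is asymmetric (regression mode): both blocks
# are deflated by regression on the X scores.

#' sPLS configuration
#'
#' @param ncomp Number of latent components (default 5).
#' @param keep_x,keep_y Number of features with non-zero loadings retained
#'   per component on the predictor / response side. A scalar is recycled
#'   over components; `NULL` (default) keeps all features, i.e. no
#'   sparsity.
#' @param max_iter Maximum NIPALS iterations per component (default 500).
#' @param tol Convergence tolerance on the change of the loading vectors
#'   (default 1e-9).
#' @param scale Centre and unit-variance scale the columns before fitting
#'   (default `TRUE`; scaling makes blocks measured in different units
#'   comparable).
#' @return An `spls_config` list.
#' @export
spls_config <- function(ncomp = 5, keep_x = NULL, keep_y = NULL,
                        max_iter = 500, tol = 1e-9, scale = TRUE) {
  stopifnot(ncomp >= 1, max_iter >= 1, tol > 0)
  structure(list(ncomp = as.integer(ncomp), keep_x = keep_x, keep_y = keep_y,
                 max_iter = as.integer(max_iter), tol = tol,
                 scale = isTRUE(scale)),
            class = "spls_config")
}

#' Soft-thresholding operator
#'
#' `soft(x, lambda) = sign(x) * max(|x| - lambda, 0)`, the proximal
#' operator of the L1 penalty used to sparsify loading vectors.
#'
#' @param x Numeric vector.
#' @param lambda Non-negative threshold.
#' @return Shrunken vector.
#' @export
soft_threshold <- function(x, lambda) {
  stopifnot(lambda >= 0)
  sign(x) * pmax(abs(x) - lambda, 0)
}

# keep the `keep` largest-|.| entries (ties broken toward the lower index),
# soft-thresholding survivors by the largest dropped magnitude
sparsify <- function(a, keep) {
  p <- length(a)
  if (keep >= p) return(a)
  ord <- order(-abs(a), seq_len(p))
  lambda <- abs(a[ord[keep + 1L]])
  out <- soft_threshold(a, lambda)
  out[ord[-seq_len(keep)]] <- 0
  out
}

normalise <- function(x) {
  n <- sqrt(sum(x^2))
  if (n > 0) x / n else x
}

# flip so the largest-|.| entry is positive (loadings are sign-indeterminate)
fix_sign <- function(x) {
  i <- which.max(abs(x))
  if (length(i) && x[i] < 0) -x else x
}

scale_columns <- function(M, scale, what) {
  M <- sweep(M, 2L, colMeans(M))
  if (scale) {
    s <- sqrt(colSums(M^2) / (nrow(M) - 1L))
    if (any(s == 0))
      stop("constant column(s) in ", what, ": ",
           paste(utils::head(colnames(M)[s == 0], 5), collapse = ", "))
    M <- sweep(M, 2L, s, "/")
  }
  M
}

#' Fit sparse PLS in regression mode
#'
#' @param X,Y Numeric matrices, samples in rows (identical row order —
#'   align with [align_samples()] first) and features in columns, with
#'   dimnames.
#' @param config An [spls_config()]. `ncomp` must not exceed
#'   `min(ncol(X), ncol(Y), nrow(X) - 1)`.
#' @return An `spls_fit`: `x_loadings` (`ncol(X) x ncomp`), `y_loadings`,
#'   `x_scores`, `y_scores` (`nrow(X) x ncomp`), `selected_x`,
#'   `selected_y` (per-component character vectors of features with
#'   non-zero loadings), `keep_x`, `keep_y`, `converged` (per component),
#'   `config`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("x", 1:5)))
#' Y <- matrix(rnorm(48), 12, 4, dimnames = list(NULL, paste0("y", 1:4)))
#' fit <- spls_fit(X, Y, spls_config(ncomp = 2, keep_x = 2, keep_y = 2))
#' fit$selected_x
#' @export
spls_fit <- function(X, Y, config = spls_config()) {
  stopifnot(is.matrix(X), is.matrix(Y))
  if (nrow(X) != nrow(Y))
    stop("X and Y must share an identical ordered sample set (",
         nrow(X), " vs ", nrow(Y), " rows)")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop("X and Y sample IDs differ or are ordered differently")
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  H <- config$ncomp
  if (H > min(p, q, n - 1L))
    stop("ncomp = ", H, " exceeds min(n_x, n_y, n_samples - 1) = ",
         min(p, q, n - 1L))
  keep_x <- rep_len(if (is.null(config$keep_x)) p else config$keep_x, H)
  keep_y <- rep_len(if (is.null(config$keep_y)) q else config$keep_y, H)
  if (any(keep_x < 1 | keep_x > p) || any(keep_y < 1 | keep_y > q))
    stop("keep counts must lie in [1, n_features] for every component")

  Xc <- scale_columns(X, config$scale, "X")
  Yc <- scale_columns(Y, config$scale, "Y")

  U <- matrix(0, p, H, dimnames = list(colnames(X), NULL))
  V <- matrix(0, q, H, dimnames = list(colnames(Y), NULL))
  TT <- matrix(0, n, H, dimnames = list(rownames(X), NULL))
  W <- matrix(0, n, H, dimnames = list(rownames(X), NULL))
  converged <- logical(H)

  for (h in seq_len(H)) {
    M <- crossprod(Xc, Yc)
    if (all(M == 0))
      stop("degenerate component ", h, ": zero cross-product matrix")
    sv <- svd(M, nu = 1L, nv = 1L)
    u <- sv$u[, 1L]; v <- sv$v[, 1L]
    for (it in seq_len(config$max_iter)) {
      u_new <- normalise(sparsify(drop(M %*% v), keep_x[h]))
      v_new <- normalise(sparsify(drop(crossprod(M, u_new)), keep_y[h]))
      delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
      u <- u_new; v <- v_new
      if (delta < config$tol) { converged[h] <- TRUE; break }
    }
    u <- fix_sign(u); v <- fix_sign(v)
    xi <- drop(Xc %*% u)
    omega <- drop(Yc %*% v)
    U[, h] <- u; V[, h] <- v; TT[, h] <- xi; W[, h] <- omega
    # regression-mode deflation: both blocks regressed on the X scores
    ss <- sum(xi^2)
    if (ss > 0) {
      Xc <- Xc - xi %*% t(crossprod(Xc, xi) / ss)
      Yc <- Yc - xi %*% t(crossprod(Yc, xi) / ss)
    }
  }
  structure(
    list(x_loadings = U, y_loadings = V, x_scores = TT, y_scores = W,
         selected_x = lapply(seq_len(H), function(h) colnames(X)[U[, h] != 0]),
         selected_y = lapply(seq_len(H), function(h) colnames(Y)[V[, h] != 0]),
         keep_x = keep_x, keep_y = keep_y, converged = converged,
         config = config),
    class = "spls_fit")
}

#' @export
print.spls_fit <- function(x, ...) {
  cat(sprintf("<spls_fit> %d component(s); selected per component: x = %s, y = %s\n",
              ncol(x$x_loadings),
              paste(lengths(x$selected_x), collapse = "/"),
              paste(lengths(x$selected_y), collapse = "/")))
  invisible(x)
}

#' Dependent feature pairs of an sPLS fit
#'
#' A pair (i, j) is dependent when feature i carries a non-zero predictor
#' loading and feature j a non-zero response loading on at least one common
#' component; these are the pairs the association matrix assigns a
#' correlation to (all other entries are structurally zero).
#'
#' @param fit An `spls_fit`.
#' @return Logical matrix (`n_x x n_y`, dimnames from the fit) marking the
#'   dependent pairs.
#' @export
dependency_pairs <- function(fit) {
  xn <- rownames(fit$x_loadings)
  yn <- rownames(fit$y_loadings)
  dep <- matrix(FALSE, length(xn), length(yn), dimnames = list(xn, yn))
  for (h in seq_along(fit$selected_x))
    dep[fit$selected_x[[h]], fit$selected_y[[h]]] <- TRUE
  dep
}

#' Masked cross-block correlation matrix
#'
#' Entry (i, j) is the Pearson correlation of feature i of `X` with feature
#' j of `Y` across the shared samples when the pair is dependent, and
#' exactly 0 otherwise.
#'
#' @param X,Y Samples x features matrices on the analysis (log2) scale,
#'   identically ordered samples.
#' @param pairs Logical dependency matrix from [dependency_pairs()].
#' @return Numeric `ncol(X) x ncol(Y)` matrix with entries in \[-1, 1\].
#' @export
association_ma <- function(X, Y, pairs) {
  stopifnot(nrow(X) == nrow(Y),
            identical(dim(pairs), c(ncol(X), ncol(Y))))
  involved_x <- apply(pairs, 1L, any)
  involved_y <- apply(pairs, 2L, any)
  sd_x <- apply(X, 2L, stats::sd)
  sd_y <- apply(Y, 2L, stats::sd)
  bad <- c(colnames(X)[involved_x & sd_x == 0],
           colnames(Y)[involved_y & sd_y == 0])
  if (length(bad))
    stop("zero-variance feature(s) among dependent pairs: ",
         paste(bad, collapse = ", "))
  ma <- matrix(0, ncol(X), ncol(Y), dimnames = list(colnames(X), colnames(Y)))
  if (any(pairs)) {
    r <- stats::cor(X[, involved_x, drop = FALSE], Y[, involved_y, drop = FALSE])
    ma[involved_x, involved_y] <- r
    ma[!pairs] <- 0
  }
  ma
}

#' Export sPLS loadings as a tidy table
#'
#' @param fit An `spls_fit`.
#' @return Data frame with columns `component`, `side` (`"x"`/`"y"`),
#'   `feature`, `loading`, restricted to non-zero loadings.
#' @export
spls_loadings_table <- function(fit) {
  grab <- function(L, side) {
    idx <- which(L != 0, arr.ind = TRUE)
    data.frame(component = idx[, 2L], side = side,
               feature = rownames(L)[idx[, 1L]],
               loading = L[idx], stringsAsFactors = FALSE)
  }
  out <- rbind(grab(fit$x_loadings, "x"), grab(fit$y_loadings, "y"))
  out[order(out$component, out$side, out$feature), , drop = FALSE]
}
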