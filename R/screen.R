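# Per-block differential screen: cell-means linear model over the diet
# groups, treatment-vs-reference contrasts, empirical-Bayes variance
# moderation and BH FDR. The model fitting and moderation are delegated to
# limma (lmFit / contrasts.fit / eBayes), the standard tool for this class
# of moderated screens.

#' Fit the group-means linear model to a block
#'
#' Ordinary least squares per feature on the cell-means parameterisation
#' (one mean per group), with explicit treatment-minus-reference contrasts.
#'
#' @param block An [omics_block()], already on the log2 scale.
#' @return A `group_fit` list: `fit` (the limma contrast fit), `logFC`
#'   (features x contrasts matrix of contrast estimates), `s2` (residual
#'   variances), `df_residual` (`n_samples - n_groups`), `contrasts`
#'   (contrast names, `<group>-<reference>`).
#' @export
fit_group_model <- function(block) {
  g <- block$groups
  lev <- c(block$reference, setdiff(unique(g), block$reference))
  counts <- table(factor(g, levels = lev))
  if (any(counts == 0))
    stop("group(s) without samples: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  df_resid <- length(g) - length(lev)
  if (df_resid < 1)
    stop("no residual degrees of freedom (", length(g), " samples, ",
         length(lev), " groups)")
  gf <- factor(g, levels = lev)
  design <- stats::model.matrix(~ 0 + gf)
  colnames(design) <- lev
  fit <- limma::lmFit(block$values, design)
  cm <- matrix(0, length(lev), length(lev) - 1L,
               dimnames = list(lev, paste0(lev[-1L], "-", lev[1L])))
  cm[1L, ] <- -1
  cm[cbind(2:length(lev), seq_len(length(lev) - 1L))] <- 1
  cfit <- limma::contrasts.fit(fit, cm)
  list(fit = cfit, logFC = cfit$coefficients,
       s2 = fit$sigma^2, df_residual = df_resid,
       contrasts = colnames(cm))
}

#' Empirical-Bayes moderation of the per-feature statistics
#'
#' Squeezes residual variances toward a prior fitted across the feature
#' ensemble and returns moderated t-statistics and two-sided p-values on
#' `df_residual + df_prior` degrees of freedom.
#'
#' @param gfit A `group_fit` from [fit_group_model()].
#' @param proportion Assumed proportion of differentially regulated
#'   features (default 0.01). It parameterises the posterior log-odds of
#'   the original method only; p-values and FDR — the quantities this
#'   pipeline filters on — do not depend on it. Stored for reporting.
#' @return List with `t` and `p` (features x contrasts), `df_prior`,
#'   `s2_prior`, `s2_post`, `proportion`.
#' @export
moderate_statistics <- function(gfit, proportion = 0.01) {
  if (nrow(gfit$logFC) < 2L)
    stop("variance moderation needs at least two features")
  if (all(gfit$s2 < 1e-24)) # lmFit reports ~1e-31 residual "variance" on exact fits
    stop("all residual variances are zero; moderation is undefined")
  eb <- limma::eBayes(gfit$fit, proportion = proportion)
  list(t = eb$t, p = eb$p.value,
       df_prior = eb$df.prior, s2_prior = eb$s2.prior, s2_post = eb$s2.post,
       proportion = proportion)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (`stats::p.adjust(method = "BH")` with input
#' validation): monotone non-decreasing in p and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of BH-adjusted values (FDR).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential screen of one omics block
#'
#' Runs the full per-block screen: optional log2 transform, group-means
#' model, treatment-vs-reference contrasts, empirical-Bayes moderation, BH
#' FDR per contrast, and selection of features significant in at least one
#' contrast.
#'
#' @param block An [omics_block()] on the raw scale (or already logged, see
#'   `transform`).
#' @param fdr_threshold Per-block FDR cut-off in (0, 1\] (typical values
#'   range from 0.001 to 0.1 depending on block size; default 0.05).
#' @param log_offset Pseudo-offset for [log_transform()].
#' @param transform If `FALSE` the block is assumed to be on the log2
#'   scale already.
#' @param proportion Passed to [moderate_statistics()].
#' @return A `screen_result`: `logFC`, `t`, `p`, `fdr` (features x
#'   contrasts), `df_residual`, `df_prior`, `s2_prior`, `selected`
#'   (feature IDs with min FDR over contrasts <= threshold),
#'   `fdr_threshold`, `data_type`, `block` (the log2-scale block, for
#'   downstream integration).
#' @examples
#' sim <- generate_blocks(sim_config(list(
#'   sim_block_spec("cytokine", 30, 24, prop_responsive = 0.3),
#'   sim_block_spec("microbiota", 40, 24, prop_responsive = 0.3)
#' ), n_groups = 4, seed = 7))
#' res <- screen_block(sim$blocks$cytokine, fdr_threshold = 0.05)
#' res$selected
#' @export
screen_block <- function(block, fdr_threshold = 0.05, log_offset = 0,
                         transform = TRUE, proportion = 0.01) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1)
  lblock <- if (transform) log_transform(block, log_offset) else block
  gfit <- fit_group_model(lblock)
  mod <- moderate_statistics(gfit, proportion)
  fdr <- apply(mod$p, 2L, bh_adjust)
  dimnames(fdr) <- dimnames(mod$p)
  res <- structure(
    list(logFC = gfit$logFC, t = mod$t, p = mod$p, fdr = fdr,
         df_residual = gfit$df_residual, df_prior = mod$df_prior,
         s2_prior = mod$s2_prior, fdr_threshold = fdr_threshold,
         data_type = block$data_type, block = lblock),
    class = "screen_result")
  res$selected <- select_significant(res, fdr_threshold)
  if (!length(res$selected))
    warning("no feature of block '", block$data_type,
            "' passes FDR <= ", fdr_threshold)
  res
}

#' Features significant in at least one contrast
#'
#' @param result A `screen_result` from [screen_block()].
#' @param fdr_threshold FDR cut-off in (0, 1\].
#' @return Character vector of selected feature IDs.
#' @export
select_significant <- function(result, fdr_threshold = result$fdr_threshold) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1)
  min_fdr <- apply(result$fdr, 1L, min)
  rownames(result$fdr)[min_fdr <= fdr_threshold]
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "<screen_result> %s: %d features, %d contrasts, %d selected at FDR <= %g\n",
    x$data_type, nrow(x$fdr), ncol(x$fdr), length(x$selected),
    x$fdr_threshold))
  invisible(x)
}

#' Write a screen report TSV
#'
#' One row per feature with per-contrast logFC / moderated t / p / FDR and
#' the selection flag.
#'
#' @param result A `screen_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(result, path) {
  flat <- function(m, tag) {
    out <- as.data.frame(round(m, 10))
    names(out) <- paste0(tag, ".", colnames(m))
    out
  }
  df <- cbind(data.frame(feature_id = rownames(result$fdr)),
              flat(result$logFC, "logFC"), flat(result$t, "t"),
              flat(result$p, "p"), flat(result$fdr, "fdr"),
              selected = rownames(result$fdr) %in% result$selected)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
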