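#' Construct an omics data block
#'
#' An `omics_block` bundles one internal-phenotype dataset — a numeric
#' feature-by-sample matrix — with its sample-to-group map and a data-type
#' label. It is the unit every stage of the pipeline operates on: the
#' differential screen, the pairwise sparse-PLS integration and the
#' permutation null model all take and return `omics_block` objects.
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#'   Row names (feature IDs) and column names (sample IDs) are mandatory
#'   and must be unique. Units are data-type specific (expression
#'   intensity, relative abundance, pg/ml, uM, ...).
#' @param data_type Single string labelling the block, e.g.
#'   `"transcriptomics"`, `"microbiota"`, `"cytokine"`,
#'   `"metabolomics_serum"`, `"metabolomics_urine"`, or any user-defined
#'   label. Labels must be distinct across the blocks of one analysis.
#' @param groups Named character vector mapping every sample ID of
#'   `values` to its experimental group (e.g. diet).
#' @param reference Group label designating the reference group against
#'   which all contrasts are formed.
#'
#' @return An object of class `omics_block`: a list with elements
#'   `values`, `data_type`, `groups` (aligned to the column order of
#'   `values`) and `reference`.
#' @examples
#' m <- matrix(rlnorm(20), 4, 5,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
#' grp <- setNames(rep(c("ctrl", "trt"), c(3, 2)), colnames(m))
#' blk <- omics_block(m, "cytokine", grp, reference = "ctrl")
#' @export
omics_block <- function(values, data_type, groups, reference) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x samples)")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("`values` must have feature row names and sample column names")
  if (anyDuplicated(fid)) stop("duplicate feature IDs: ",
                               paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid)) stop("duplicate sample IDs: ",
                               paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!is.character(data_type) || length(data_type) != 1L)
    stop("`data_type` must be a single string")
  groups <- vapply(groups, as.character, character(1))
  missing_grp <- setdiff(sid, names(groups))
  if (length(missing_grp))
    stop("samples without a group label: ", paste(missing_grp, collapse = ", "))
  groups <- groups[sid]
  if (!reference %in% groups)
    stop("reference group '", reference, "' has no samples in this block")
  structure(
    list(values = values, data_type = data_type,
         groups = groups, reference = reference),
    class = "omics_block"
  )
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("<omics_block> %s: %d features x %d samples\n",
              x$data_type, nrow(x$values), ncol(x$values)))
  tab <- table(x$groups)
  cat("  groups: ",
      paste(sprintf("%s=%d%s", names(tab), tab,
                    ifelse(names(tab) == x$reference, "*", "")),
            collapse = ", "),
      "  (* reference)\n", sep = "")
  invisible(x)
}

#' @rdname omics_block
#' @param x An `omics_block`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname omics_block
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset a block to a set of features
#'
#' Used after the differential screen to restrict a block to its selected
#' (treatment-responsive) features before integration.
#'
#' @param block An [omics_block()].
#' @param features Character vector of feature IDs to keep (order is kept).
#' @return The restricted `omics_block`.
#' @export
subset_features <- function(block, features) {
  unknown <- setdiff(features, feature_ids(block))
  if (length(unknown))
    stop("unknown feature IDs: ", paste(utils::head(unknown, 5), collapse = ", "))
  if (!length(features))
    stop("cannot subset '", block$data_type, "' to an empty feature set")
  omics_block(block$values[features, , drop = FALSE],
              block$data_type, block$groups, block$reference)
}

#' Log2-transform a block
#'
#' All downstream statistics (linear models, correlations) operate on the
#' log2 scale; assays are measured on positive multiplicative scales.
#'
#' @param block An [omics_block()].
#' @param offset Non-negative pseudo-offset added before taking logs
#'   (use e.g. 1 for count-like data that may contain zeros; 0 for
#'   strictly positive assays).
#' @return The block with `values` replaced by `log2(values + offset)`.
#' @export
log_transform <- function(block, offset = 0) {
  if (offset < 0) stop("`offset` must be non-negative")
  v <- block$values + offset
  if (any(v <= 0)) {
    bad <- which(v <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-positive value after offset %g for feature '%s' in sample '%s'",
      offset, rownames(v)[bad[1L]], colnames(v)[bad[2L]]))
  }
  block$values <- log2(v)
  block
}

#' Read / write an omics block as TSV
#'
#' The tabular dialect is a plain TSV: one row per feature, first column
#' `feature_id`, remaining columns one per sample with sample IDs in the
#' header. The sample-to-group map is a two-column TSV (`sample_id`,
#' `group`). Floating point values are rounded to 10 decimals on write so
#' that write/read round-trips are exact.
#'
#' @param path Path of the feature-table TSV.
#' @param groups_path Path of the sample-group TSV.
#' @param data_type,reference See [omics_block()].
#' @return `read_omics_block()` returns an `omics_block`;
#'   `write_omics_block()` returns `path` invisibly.
#' @export
read_omics_block <- function(path, groups_path, data_type, reference) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L || names(tab)[1L] != "feature_id")
    stop("malformed feature table '", path, "': first column must be 'feature_id'")
  fid <- as.character(tab[[1L]])
  if (anyDuplicated(fid)) {
    dup <- fid[duplicated(fid)][1L]
    stop("duplicate feature ID '", dup, "' at line ",
         which(fid == dup)[2L] + 1L, " of ", path)
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1)))[1L]
    stop("non-numeric cells in column '", names(tab)[bad + 1L], "' of ", path)
  }
  rownames(m) <- fid
  gtab <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(gtab)))
    stop("malformed group table '", groups_path,
         "': needs columns sample_id, group")
  omics_block(m, data_type,
              stats::setNames(as.character(gtab$group), gtab$sample_id),
              reference)
}

#' @rdname read_omics_block
#' @param block An [omics_block()] to serialise.
#' @export
write_omics_block <- function(block, path, groups_path = NULL) {
  df <- data.frame(feature_id = feature_ids(block),
                   round(block$values, 10), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    utils::write.table(
      data.frame(sample_id = sample_ids(block), group = block$groups),
      groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
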