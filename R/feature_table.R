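#' Feature table: an LC-MS intensity matrix with its two metadata tables
#'
#' The central container of the package, mirroring the Workflow4Metabolomics
#' (W4M) triplet: a features-in-rows intensity matrix (`dataMatrix`), one row
#' of sample metadata per injected sample (`sampleMetadata`) and one row of
#' feature metadata per detected feature (`variableMetadata`).
#'
#' @param matrix numeric matrix of non-negative intensities, features in rows,
#'   samples in columns; `rownames` are feature ids, `colnames` sample ids.
#'   `NA` cells are allowed only when `missing_convention = "NA"`.
#' @param sample_meta data.frame with one row per sample. Must contain a
#'   `sample_id` column matching `colnames(matrix)` and a `role` column with
#'   values in `study`, `qc_pool`, `blank`, `solvent`. Design columns
#'   (`species_code`, `pool`, `diversity_level`, `season`, `replicate`,
#'   `plot_id`, `lab_id`, `batch_id`, `injection_index`) are optional for
#'   hand-built tables but produced by the design and simulation modules.
#' @param feature_meta data.frame with one row per feature: `feature_id`
#'   matching `rownames(matrix)`, `mz` (> 0, Da/e) and `rt` (>= 0, seconds).
#' @param missing_convention how empty cells are encoded: `"NA"` (literal NA
#'   markers), `"zero"` (zeros stand for not-detected) or `"imputed"` (no
#'   missing cells remain; noise has been imputed, see [impute_noise()]).
#' @param imputed_mask optional logical matrix (same dimensions) flagging the
#'   cells that were imputed; carried by [impute_noise()] so that downstream
#'   stages can recover pre-imputation detection status.
#'
#' @return an object of class `feature_table`.
#' @seealso [read_w4m()], [write_w4m()], [detection_matrix()]
#' @export
feature_table <- function(matrix, sample_meta, feature_meta,
                          missing_convention = c("NA", "zero", "imputed"),
                          imputed_mask = NULL) {
  missing_convention <- match.arg(missing_convention)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  storage.mode(matrix) <- "double"
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  feature_meta <- as.data.frame(feature_meta, stringsAsFactors = FALSE)
  ft <- structure(
    list(matrix = matrix,
         sample_meta = sample_meta,
         feature_meta = feature_meta,
         missing_convention = missing_convention,
         imputed_mask = imputed_mask),
    class = "feature_table")
  validate_feature_table(ft)
  ft
}

#' Validate a feature table against its invariants
#'
#' Checks identifier agreement between the matrix and both metadata tables,
#' non-negativity of intensities, the declared missing-value convention and
#' the role partition. Called by the constructor; exported so that tables
#' modified by hand can be re-checked.
#'
#' @param ft a `feature_table`.
#' @return `ft`, invisibly; errors describe the first violated invariant.
#' @export
validate_feature_table <- function(ft) {
  m <- ft$matrix
  sm <- ft$sample_meta
  fm <- ft$feature_meta
  if (is.null(colnames(m)) && ncol(m) > 0)
    stop("matrix must have sample ids as colnames")
  if (is.null(rownames(m)) && nrow(m) > 0)
    stop("matrix must have feature ids as rownames")
  if (!"sample_id" %in% names(sm)) stop("sample_meta must have a sample_id column")
  if (!"feature_id" %in% names(fm)) stop("feature_meta must have a feature_id column")
  if (anyDuplicated(sm$sample_id)) stop("duplicate sample identifiers in sample_meta")
  if (anyDuplicated(fm$feature_id)) stop("duplicate feature identifiers in feature_meta")
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers in matrix")
  if (anyDuplicated(rownames(m))) stop("duplicate feature identifiers in matrix")
  if (!identical(as.character(colnames(m)), as.character(sm$sample_id))) {
    extra <- setdiff(colnames(m), sm$sample_id)
    miss  <- setdiff(sm$sample_id, colnames(m))
    if (length(extra) || length(miss))
      stop("unmatched sample identifiers between dataMatrix and sampleMetadata: ",
           paste(c(extra, miss), collapse = ", "))
    stop("sample order differs between dataMatrix and sampleMetadata")
  }
  if (!identical(as.character(rownames(m)), as.character(fm$feature_id))) {
    extra <- setdiff(rownames(m), fm$feature_id)
    miss  <- setdiff(fm$feature_id, rownames(m))
    if (length(extra) || length(miss))
      stop("unmatched feature identifiers between dataMatrix and variableMetadata: ",
           paste(c(extra, miss), collapse = ", "))
    stop("feature order differs between dataMatrix and variableMetadata")
  }
  if ("role" %in% names(sm)) {
    bad <- setdiff(unique(sm$role), c("study", "qc_pool", "blank", "solvent"))
    if (length(bad)) stop("unknown sample role(s): ", paste(bad, collapse = ", "))
  }
  if (any(m < 0, na.rm = TRUE)) stop("negative intensity in dataMatrix")
  if (ft$missing_convention != "NA" && anyNA(m))
    stop("NA markers present but missing_convention is '", ft$missing_convention, "'")
  if (ft$missing_convention == "imputed" && is.null(ft$imputed_mask))
    stop("imputed table must carry its imputed_mask")
  if (!is.null(ft$imputed_mask)) {
    if (!identical(dim(ft$imputed_mask), dim(m)))
      stop("imputed_mask dimensions differ from matrix")
  }
  if ("mz" %in% names(fm) && any(!is.na(fm$mz) & fm$mz <= 0))
    stop("feature mz must be > 0")
  if ("rt" %in% names(fm) && any(!is.na(fm$rt) & fm$rt < 0))
    stop("feature rt must be >= 0")
  invisible(ft)
}

#' @export
dim.feature_table <- function(x) dim(x$matrix)

#' @export
print.feature_table <- function(x, ...) {
  roles <- if ("role" %in% names(x$sample_meta))
    table(factor(x$sample_meta$role,
                 levels = c("study", "qc_pool", "blank", "solvent")))
  else NULL
  cat(sprintf("feature_table: %d features x %d samples (missing: %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$missing_convention))
  if (!is.null(roles))
    cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  if (!is.null(x$imputed_mask))
    cat(sprintf("  imputed cells: %d (%.1f%%)\n", sum(x$imputed_mask),
                100 * mean(x$imputed_mask)))
  invisible(x)
}

#' @export
summary.feature_table <- function(object, ...) {
  m <- object$matrix
  empty <- if (object$missing_convention == "imputed" &&
               !is.null(object$imputed_mask)) mean(object$imputed_mask)
           else mean(is_missing_cell(object))
  out <- list(n_features = nrow(m), n_samples = ncol(m),
              missing_convention = object$missing_convention,
              empty_fraction = empty,
              intensity_range = range(m, na.rm = TRUE))
  class(out) <- "summary.feature_table"
  out
}

#' @export
print.summary.feature_table <- function(x, ...) {
  cat(sprintf("%d features x %d samples; empty fraction %.3f; intensities [%.3g, %.3g]\n",
              x$n_features, x$n_samples, x$empty_fraction,
              x$intensity_range[1], x$intensity_range[2]))
  invisible(x)
}

#' Subset a feature table
#'
#' @param x a `feature_table`.
#' @param features character vector of feature ids, or logical/integer index
#'   over rows; `NULL` keeps all.
#' @param samples character vector of sample ids, or logical/integer index
#'   over columns; `NULL` keeps all.
#' @return a `feature_table` restricted to the requested rows/columns; the
#'   imputed mask, if any, is subset alongside.
#' @export
ft_subset <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "feature_table"))
  fi <- if (is.null(features)) seq_len(nrow(x$matrix)) else features
  si <- if (is.null(samples)) seq_len(ncol(x$matrix)) else samples
  if (is.character(fi)) fi <- match(fi, rownames(x$matrix))
  if (is.character(si)) si <- match(si, colnames(x$matrix))
  if (anyNA(fi)) stop("unknown feature id in subset")
  if (anyNA(si)) stop("unknown sample id in subset")
  m <- x$matrix[fi, si, drop = FALSE]
  feature_table(m,
                x$sample_meta[si, , drop = FALSE],
                x$feature_meta[fi, , drop = FALSE],
                missing_convention = x$missing_convention,
                imputed_mask = if (!is.null(x$imputed_mask))
                  x$imputed_mask[fi, si, drop = FALSE])
}

#' Sample ids carrying a given role
#'
#' @param x a `feature_table`.
#' @param roles character vector of roles (`study`, `qc_pool`, `blank`,
#'   `solvent`).
#' @return character vector of sample ids.
#' @export
samples_by_role <- function(x, roles) {
  stopifnot(inherits(x, "feature_table"), "role" %in% names(x$sample_meta))
  x$sample_meta$sample_id[x$sample_meta$role %in% roles]
}

## TRUE where a cell is an empty marker; zeros and NAs both count as missing
## (the two conventions differ only in which marker they write)
is_missing_cell <- function(x) {
  if (x$missing_convention == "imputed")
    stop("missing cells are undefined for an imputed table")
  is.na(x$matrix) | (!is.na(x$matrix) & x$matrix == 0)
}

#' Detection matrix of a feature table
#'
#' TRUE where a feature was detected in a sample, judged on pre-imputation
#' information: for `zero`/`NA` tables a cell is detected when it is neither
#' `NA` nor zero; for an imputed table the carried imputed-cell mask is used
#' (imputed cells are not detections).
#'
#' @param x a `feature_table`.
#' @return logical matrix with the dimensions of `x$matrix`.
#' @export
detection_matrix <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (x$missing_convention == "imputed") {
    if (is.null(x$imputed_mask))
      stop("imputed table without an imputed-cell mask: detection is unrecoverable")
    return(!x$imputed_mask)
  }
  !is.na(x$matrix) & x$matrix != 0
}

#' Fraction of empty cells in a feature table
#'
#' The share of matrix cells that are missing markers (zeros or NAs under the
#' table's convention). Untargeted peak tables over many species are sparse
#' because each sample detects only its own species' metabolite fingerprint;
#' the study design this package models yields roughly 90% empty cells.
#'
#' @param x a `feature_table` with convention `zero` or `NA`.
#' @param roles optional character vector: restrict the count to samples with
#'   these roles (default: all samples).
#' @return a number in \[0, 1\]; `NaN` for an empty matrix.
#' @export
realized_zero_fraction <- function(x, roles = NULL) {
  stopifnot(inherits(x, "feature_table"))
  if (x$missing_convention == "imputed")
    stop("zero fraction is undefined for an imputed table")
  m <- is_missing_cell(x)
  if (!is.null(roles)) m <- m[, colnames(x$matrix) %in% samples_by_role(x, roles), drop = FALSE]
  if (length(m) == 0) return(NaN)
  mean(m)
}
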