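#' Column and value aliases used when reading W4M sampleMetadata
#'
#' Deposited W4M exports do not share one canonical sampleMetadata schema, so
#' the reader maps common column names (`sampleType`/`class` for the role,
#' `batch`/`analytical_batch` for the batch, `injectionOrder` for the
#' injection index) and common role labels (`sample` for study samples,
#' `pool` for the pooled QC) onto the package's canonical names. Pass a
#' modified copy of this list to [read_w4m()] for other schemas.
#'
#' @return a list with elements `columns` (canonical name -> candidate column
#'   names, first match wins) and `roles` (label -> canonical role).
#' @export
w4m_aliases <- function() {
  list(
    columns = list(
      role            = c("role", "sampleType", "sample_type", "class"),
      batch_id        = c("batch_id", "batch", "analytical_batch"),
      injection_index = c("injection_index", "injectionOrder", "injection_order")
    ),
    roles = c(sample = "study", study = "study",
              pool = "qc_pool", QC = "qc_pool", qc = "qc_pool",
              qc_pool = "qc_pool",
              blank = "blank", solvent = "solvent")
  )
}

read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA")
}

#' Read a W4M triplet into a feature table
#'
#' Reads the three tab-separated files of the W4M exchange format. The first
#' column of each file holds identifiers; the matrix is expected features in
#' rows (the W4M convention) and a transposed matrix is rejected, not guessed.
#' Identifier sets must match exactly between the matrix and both metadata
#' tables: mismatches raise an error rather than silently intersecting.
#'
#' @param dataMatrix_path,sampleMetadata_path,variableMetadata_path paths to
#'   the three TSV files.
#' @param missing_convention convention of empty cells in the matrix file
#'   (`"NA"` or `"zero"`).
#' @param aliases schema aliases, see [w4m_aliases()].
#' @return a [feature_table()].
#' @export
read_w4m <- function(dataMatrix_path, sampleMetadata_path, variableMetadata_path,
                     missing_convention = c("NA", "zero"),
                     aliases = w4m_aliases()) {
  missing_convention <- match.arg(missing_convention)
  dm <- read_tsv_table(dataMatrix_path)
  sm <- read_tsv_table(sampleMetadata_path)
  fm <- read_tsv_table(variableMetadata_path)

  fid <- as.character(dm[[1]])
  m <- as.matrix(dm[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- fid

  names(sm)[1] <- "sample_id"
  sm$sample_id <- as.character(sm$sample_id)
  names(fm)[1] <- "feature_id"
  fm$feature_id <- as.character(fm$feature_id)

  # map aliased columns onto canonical names without clobbering existing ones
  for (canon in names(aliases$columns)) {
    if (canon %in% names(sm)) next
    hit <- intersect(aliases$columns[[canon]], names(sm))
    if (length(hit)) names(sm)[match(hit[1], names(sm))] <- canon
  }
  if ("role" %in% names(sm)) {
    mapped <- aliases$roles[as.character(sm$role)]
    known <- !is.na(mapped)
    sm$role[known] <- unname(mapped[known])
  }

  # reject a transposed matrix: its columns would match feature ids instead
  if (ncol(m) > 0 && !any(colnames(m) %in% sm$sample_id) &&
      any(colnames(m) %in% fm$feature_id))
    stop("dataMatrix appears transposed (columns match feature ids, not sample ids)")

  if (anyDuplicated(sm$sample_id)) stop("duplicate sample identifiers in sampleMetadata")
  if (anyDuplicated(fm$feature_id)) stop("duplicate feature identifiers in variableMetadata")
  extra <- setdiff(colnames(m), sm$sample_id)
  miss  <- setdiff(sm$sample_id, colnames(m))
  if (length(extra) || length(miss))
    stop("unmatched sample identifiers: ", paste(c(extra, miss), collapse = ", "))
  fextra <- setdiff(rownames(m), fm$feature_id)
  fmiss  <- setdiff(fm$feature_id, rownames(m))
  if (length(fextra) || length(fmiss))
    stop("unmatched feature identifiers: ", paste(c(fextra, fmiss), collapse = ", "))

  sm <- sm[match(colnames(m), sm$sample_id), , drop = FALSE]
  fm <- fm[match(rownames(m), fm$feature_id), , drop = FALSE]
  rownames(sm) <- NULL
  rownames(fm) <- NULL
  feature_table(m, sm, fm, missing_convention = missing_convention)
}

format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Write a feature table as a W4M triplet
#'
#' Serializes the three tables as tab-separated UTF-8 files with "." decimal
#' separator; NA markers are written as the literal token `NA`. Column order
#' of the matrix and row order of the metadata are preserved, so
#' `read_w4m(write_w4m(x))` round-trips exactly (values to numeric-text
#' precision).
#'
#' @param x a `feature_table`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; files are named
#'   `<prefix>dataMatrix.tsv`, `<prefix>sampleMetadata.tsv`,
#'   `<prefix>variableMetadata.tsv`.
#' @return named character vector of the three paths, invisibly.
#' @export
write_w4m <- function(x, dir, prefix = "") {
  stopifnot(inherits(x, "feature_table"))
  validate_feature_table(x)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(dataMatrix     = file.path(dir, paste0(prefix, "dataMatrix.tsv")),
             sampleMetadata = file.path(dir, paste0(prefix, "sampleMetadata.tsv")),
             variableMetadata = file.path(dir, paste0(prefix, "variableMetadata.tsv")))

  m <- x$matrix
  header <- paste(c("feature_id", colnames(m)), collapse = "\t")
  body <- if (nrow(m) > 0) {
    txt <- apply(m, 1, function(r) paste(format_num(r), collapse = "\t"))
    paste(rownames(m), txt, sep = if (ncol(m) > 0) "\t" else "")
  } else character(0)
  writeLines(c(header, body), paths[["dataMatrix"]])

  write_meta <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  }
  write_meta(x$sample_meta, paths[["sampleMetadata"]])
  write_meta(x$feature_meta, paths[["variableMetadata"]])
  invisible(paths)
}

#' Parse a Lab-ID of the form NNN_YYYY_S
#'
#' Lab-IDs label study samples with a per-season running number (001--128), the
#' sampling year and the season letter, e.g. `013_2017_A`. Extraction and
#' injection order follow these ids, which is what randomizes the design
#' factors across analytical batches.
#'
#' @param lab_id character vector of Lab-IDs.
#' @return data.frame with columns `number` (integer), `year` (integer),
#'   `season` (character, one of A--D).
#' @export
parse_lab_id <- function(lab_id) {
  lab_id <- as.character(lab_id)
  ok <- grepl("^[0-9]{3}_[0-9]{4}_[A-Za-z]$", lab_id)
  if (any(!ok))
    stop("malformed Lab-ID (expected NNN_YYYY_S): ",
         paste(lab_id[!ok], collapse = ", "))
  number <- as.integer(substr(lab_id, 1, 3))
  year <- as.integer(substr(lab_id, 5, 8))
  season <- substr(lab_id, 10, 10)
  if (any(!season %in% c("A", "B", "C", "D")))
    stop("season outside A-D in Lab-ID: ",
         paste(lab_id[!season %in% c("A", "B", "C", "D")], collapse = ", "))
  if (any(number < 1 | number > 128))
    stop("Lab-ID number outside 001-128: ",
         paste(lab_id[number < 1 | number > 128], collapse = ", "))
  data.frame(number = number, year = year, season = season,
             stringsAsFactors = FALSE)
}
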