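#' Retention-time region-of-interest filter
#'
#' Keeps features whose retention time lies inside `[rt_min, rt_max]`
#' (inclusive on both ends) and drops the rest from the matrix and the
#' feature metadata. The defaults cut the injection front / very polar region
#' (below 80 s) and the column-wash / very nonpolar region (above 840 s).
#'
#' @param x a `feature_table` whose `feature_meta` carries `rt` (seconds).
#' @param rt_min,rt_max inclusive bounds in seconds.
#' @return the filtered `feature_table`.
#' @export
roi_filter <- function(x, rt_min = 80, rt_max = 840) {
  stopifnot(inherits(x, "feature_table"))
  if (!(rt_min >= 0 && rt_min < rt_max)) stop("need 0 <= rt_min < rt_max")
  rt <- x$feature_meta$rt
  if (is.null(rt) || anyNA(rt)) stop("feature_meta must carry a complete rt column")
  keep <- rt >= rt_min & rt <= rt_max
  ft_subset(x, features = which(keep))
}

#' Remove blank-derived (contaminant) features
#'
#' Blanks contain no biological material but pass through the whole
#' procedure, so any feature detected in a blank is treated as a systematic
#' contamination. Features detected in at least `min_blank_detections` blanks
#' are removed from the matrix and the feature metadata everywhere, and the
#' blank samples themselves are then dropped from the table. Detection is
#' judged on pre-imputation information (empty markers, or the imputed-cell
#' mask for an imputed table).
#'
#' @param x a `feature_table` containing at least one blank sample.
#' @param min_blank_detections detections in blanks required for removal.
#'   The default 1 removes features seen in any blank; a stricter fraction
#'   rule (e.g. 25% of blanks) can be requested instead.
#' @return list with `table` (filtered, blanks dropped) and `removed`
#'   (character vector of removed feature ids).
#' @export
blank_filter <- function(x, min_blank_detections = 1L) {
  stopifnot(inherits(x, "feature_table"))
  blanks <- samples_by_role(x, "blank")
  if (length(blanks) == 0) stop("no blank samples in table")
  det <- detection_matrix(x)[, blanks, drop = FALSE]
  removed <- rownames(x$matrix)[rowSums(det) >= min_blank_detections]
  keep_feat <- setdiff(rownames(x$matrix), removed)
  keep_samp <- setdiff(colnames(x$matrix), blanks)
  list(table = ft_subset(x, features = keep_feat, samples = keep_samp),
       removed = removed)
}

#' Build per-species feature fingerprints by the minimum-detection rule
#'
#' A feature belongs to a species' fingerprint when it is detected in at
#' least `max(min_count, ceiling(min_fraction * n))` of the species' `n`
#' study samples — the "detected in at least 25% (>= 8) of the samples" rule.
#' Detection is judged on pre-imputation information.
#'
#' @param x a `feature_table` with study samples carrying `species_code`.
#' @param min_fraction minimum detection fraction within the species.
#' @param min_count floor on the required number of detections.
#' @return named list (one element per species) of `species_fingerprint`
#'   objects: `species_code`, `features`, per-feature `detection_fraction`
#'   (over all features), `threshold` and `n_samples`.
#' @export
build_fingerprints <- function(x, min_fraction = 0.25, min_count = 8L) {
  stopifnot(inherits(x, "feature_table"))
  det <- detection_matrix(x)
  sm <- x$sample_meta
  study <- sm$sample_id[sm$role == "study"]
  codes <- sort(unique(sm$species_code[sm$role == "study"]))
  if (length(codes) == 0) stop("no study samples with species codes")
  out <- list()
  for (code in codes) {
    ids <- sm$sample_id[sm$role == "study" & !is.na(sm$species_code) &
                          sm$species_code == code]
    n <- length(ids)
    if (n == 0) stop("species with zero samples: ", code)
    hits <- rowSums(det[, ids, drop = FALSE])
    thr <- max(min_count, ceiling(min_fraction * n))
    members <- rownames(x$matrix)[hits >= thr]
    out[[code]] <- structure(
      list(species_code = code, features = members,
           detection_fraction = stats::setNames(hits / n, rownames(x$matrix)),
           threshold = thr, n_samples = n,
           min_fraction = min_fraction, min_count = min_count),
      class = "species_fingerprint")
  }
  out
}

#' @export
print.species_fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint of %s: %d features (detected in >= %d of %d samples)\n",
              x$species_code, length(x$features), x$threshold, x$n_samples))
  invisible(x)
}

#' Fingerprint sizes as a data frame
#'
#' @param fingerprints result of [build_fingerprints()].
#' @return data.frame with `species_code`, `n_samples`, `n_features`.
#' @export
fingerprint_summary <- function(fingerprints) {
  do.call(rbind, lapply(fingerprints, function(fp)
    data.frame(species_code = fp$species_code, n_samples = fp$n_samples,
               n_features = length(fp$features), stringsAsFactors = FALSE)))
}
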