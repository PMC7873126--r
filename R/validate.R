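#' Parameters of the per-species sample validity check
#'
#' A sample passes when (i) its Mahalanobis distance to its species centroid
#' is at most `distance_multiplier` times the average distance of the
#' remaining samples of that species (strictly greater fails), and (ii) it
#' shares strictly more than `min_shared_fraction` of its species fingerprint
#' (detection judged pre-imputation). With many more features than samples
#' the species covariance is singular, so the distance is computed under a
#' regularization: by default in a PCA score space of
#' `min(n_samples - 2, 10)` components; a pseudo-inverse and a diagonal
#' shrinkage covariance are available as alternatives.
#'
#' @param distance_multiplier multiple of the peer-average distance above
#'   which a sample fails.
#' @param min_shared_fraction fingerprint fraction that must be exceeded.
#' @param covariance_regularization one of `"pca_projection"`,
#'   `"pseudo_inverse"`, `"shrinkage"`.
#' @param n_components score-space dimension for `pca_projection`; `NULL`
#'   selects `min(n_samples - 2, 10)` per species.
#' @param shrinkage_gamma weight of the diagonal target for `"shrinkage"`.
#' @return list of class `validity_params`.
#' @export
validity_params <- function(distance_multiplier = 3.0,
                            min_shared_fraction = 0.25,
                            covariance_regularization = c(
                              "pca_projection", "pseudo_inverse", "shrinkage"),
                            n_components = NULL,
                            shrinkage_gamma = 0.1) {
  covariance_regularization <- match.arg(covariance_regularization)
  if (distance_multiplier <= 0) stop("distance_multiplier must be > 0")
  if (min_shared_fraction < 0 || min_shared_fraction > 1)
    stop("min_shared_fraction must lie in [0, 1]")
  structure(list(distance_multiplier = distance_multiplier,
                 min_shared_fraction = min_shared_fraction,
                 covariance_regularization = covariance_regularization,
                 n_components = n_components,
                 shrinkage_gamma = shrinkage_gamma),
            class = "validity_params")
}

## log profiles for distance computations; exact natural log keeps Mahalanobis
## decisions scale invariant, log1p is the fallback when zeros are present
log_profiles <- function(m) {
  if (all(m > 0)) log(m) else log1p(m)
}

#' Per-species Mahalanobis distances
#'
#' Computes, for every study sample of one species, its Mahalanobis distance
#' to the species centroid on the log intensity scale. The centroid and
#' covariance are estimated on all samples of the species (not leave-one-out)
#' for stability; under the default `pca_projection` regularization the
#' covariance is the (diagonal) score covariance in an `n_components`-
#' dimensional PCA space.
#'
#' @param x a `feature_table` (batch-corrected, imputed) with study samples.
#' @param species_code species to evaluate (>= 4 samples required).
#' @param params a [validity_params()].
#' @return named numeric vector of distances (one per sample of the species).
#' @export
mahalanobis_per_species <- function(x, species_code,
                                    params = validity_params()) {
  stopifnot(inherits(x, "feature_table"))
  sm <- x$sample_meta
  ids <- sm$sample_id[sm$role == "study" & !is.na(sm$species_code) &
                        sm$species_code == species_code]
  n <- length(ids)
  if (n < 4) stop("species ", species_code, " has fewer than 4 samples")
  M <- t(log_profiles(x$matrix[, ids, drop = FALSE]))   # samples x features
  if (anyNA(M)) stop("distances require a table without NA cells")
  Xc <- sweep(M, 2, colMeans(M))

  d2 <- switch(params$covariance_regularization,
    pca_projection = {
      q <- params$n_components
      if (is.null(q)) q <- min(n - 2L, 10L)
      q <- max(1L, min(q, n - 1L, ncol(Xc)))
      pr <- svd(Xc, nu = q, nv = 0)
      lambda <- (pr$d^2) / (n - 1)
      keep <- seq_len(q)[lambda[seq_len(q)] > 1e-12]
      if (length(keep) == 0) rep(0, n)
      else {
        scores <- pr$u[, keep, drop = FALSE] %*% diag(pr$d[keep], length(keep))
        rowSums(sweep(scores^2, 2, lambda[keep], "/"))
      }
    },
    pseudo_inverse = {
      s <- svd(Xc, nu = min(n, ncol(Xc)), nv = 0)
      lambda <- (s$d^2) / (n - 1)
      keep <- which(lambda > max(lambda) * 1e-10)
      if (length(keep) == 0) stop("singular covariance with zero tolerance")
      scores <- s$u[, keep, drop = FALSE] %*% diag(s$d[keep], length(keep))
      rowSums(sweep(scores^2, 2, lambda[keep], "/"))
    },
    shrinkage = {
      S <- crossprod(Xc) / (n - 1)
      g <- params$shrinkage_gamma
      target <- mean(diag(S))
      Ssh <- (1 - g) * S + g * diag(target, ncol(S))
      stats::mahalanobis(M, colMeans(M), Ssh)
    })
  d2[d2 < 0] <- 0
  stats::setNames(sqrt(d2), ids)
}

#' Fraction of a species fingerprint detected in a sample
#'
#' @param detected character vector of feature ids detected in the sample
#'   (see [detection_matrix()]).
#' @param fingerprint a `species_fingerprint`.
#' @return `|detected in fingerprint| / |fingerprint|`.
#' @export
shared_fraction <- function(detected, fingerprint) {
  stopifnot(inherits(fingerprint, "species_fingerprint"))
  if (length(fingerprint$features) == 0)
    stop("empty fingerprint for species ", fingerprint$species_code)
  length(intersect(detected, fingerprint$features)) /
    length(fingerprint$features)
}

#' Validate study samples against their species
#'
#' Applies the two-criterion validity check to every study sample: the
#' Mahalanobis criterion on the (batch-corrected, imputed) intensity profiles
#' and the shared-fingerprint criterion on pre-imputation detections. Each
#' sample is labelled `pass`, `fail_distance`, `fail_shared` or `fail_both`,
#' and a filtered table excluding the failures is returned.
#'
#' @param x a `feature_table` with study samples (no missing cells).
#' @param fingerprints result of [build_fingerprints()]; every species in `x`
#'   must be present.
#' @param params a [validity_params()].
#' @param detection_table table used for detection status (defaults to `x`,
#'   whose imputed mask encodes pre-imputation detections; pass the raw
#'   pre-correction table to use its markers instead).
#' @return object of class `validity_report`: `report` data.frame (sample_id,
#'   species_code, mahalanobis_distance, peer_average_distance,
#'   shared_fraction, decision) and `table`, the filtered `feature_table`.
#' @export
validate_samples <- function(x, fingerprints, params = validity_params(),
                             detection_table = x) {
  stopifnot(inherits(x, "feature_table"))
  sm <- x$sample_meta
  codes <- sort(unique(sm$species_code[sm$role == "study" &
                                         !is.na(sm$species_code)]))
  missing_fp <- setdiff(codes, names(fingerprints))
  if (length(missing_fp))
    stop("species absent from fingerprints: ", paste(missing_fp, collapse = ", "))
  det <- detection_matrix(detection_table)

  rows <- list()
  for (code in codes) {
    d <- mahalanobis_per_species(x, code, params)
    n <- length(d)
    peer <- vapply(seq_len(n), function(i) mean(d[-i]), numeric(1))
    fp <- fingerprints[[code]]
    sh <- vapply(names(d), function(sid)
      shared_fraction(rownames(det)[det[, sid]], fp), numeric(1))
    fail_d <- d > params$distance_multiplier * peer
    fail_s <- !(sh > params$min_shared_fraction)
    decision <- ifelse(fail_d & fail_s, "fail_both",
                ifelse(fail_d, "fail_distance",
                ifelse(fail_s, "fail_shared", "pass")))
    rows[[code]] <- data.frame(
      sample_id = names(d), species_code = code,
      mahalanobis_distance = unname(d), peer_average_distance = peer,
      shared_fraction = unname(sh), decision = decision,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  failed <- report$sample_id[report$decision != "pass"]
  keep <- setdiff(colnames(x$matrix), failed)
  structure(list(report = report,
                 table = ft_subset(x, samples = keep),
                 params = params),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  tab <- table(x$report$decision)
  cat(sprintf("validity report: %d samples, %d failed\n",
              nrow(x$report), sum(x$report$decision != "pass")))
  cat(" ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  bad <- x$report[x$report$decision != "pass", , drop = FALSE]
  if (nrow(bad)) {
    cat("  failing samples:\n")
    print(bad, row.names = FALSE)
  }
  invisible(x)
}
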