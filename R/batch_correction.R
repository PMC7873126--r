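#' Fit a pooled-QC batch-correction model
#'
#' Estimates unwanted between-batch variation from the repeated pooled-QC
#' injections: on the (natural-) log scale, QC profiles are centered by the
#' global QC mean and the top `k` right singular vectors of the centered QC
#' matrix become the unwanted-variation directions. Because the pooled QC is
#' a single replicate group, this replicate-centered SVD coincides with the
#' unwanted-factor estimate of RUV-style correction, and subtracting the
#' projection onto these directions (see [predict.batch_correction()])
#' removes the systematic part of the QC variation from every sample.
#'
#' @param x a `feature_table` without missing cells (imputed, or strictly
#'   positive throughout) containing at least 2 QC samples spanning at least
#'   2 batches.
#' @param k number of unwanted-variation components (0 gives an identity
#'   model); must satisfy `k <= min(#QC - 1, #features)`.
#' @param log_transform work on the natural-log scale (default); batch
#'   effects on LC-MS intensities are multiplicative, hence additive in logs.
#' @return an object of class `batch_correction` with orthonormal
#'   `directions` (features x k), the `qc_center` profile, the QC singular
#'   values, the ids the model was fitted on, and a `zero_variance` flag set
#'   when the QC profiles carry (numerically) no variation.
#' @export
fit_batch_correction <- function(x, k, log_transform = TRUE) {
  stopifnot(inherits(x, "feature_table"))
  m <- x$matrix
  if (anyNA(m)) stop("batch correction requires a table without missing cells; impute first")
  qc_ids <- samples_by_role(x, "qc_pool")
  if (length(qc_ids) < 2) stop("need at least 2 QC samples")
  qc_meta <- x$sample_meta[x$sample_meta$role == "qc_pool", , drop = FALSE]
  if (length(unique(qc_meta$batch_id)) < 2)
    stop("QC samples must span at least 2 batches")
  if (k < 0 || k > min(length(qc_ids) - 1L, nrow(m)))
    stop("k must lie in 0..min(#QC - 1, #features) = 0..",
         min(length(qc_ids) - 1L, nrow(m)))
  if (log_transform) {
    if (any(m <= 0)) stop("log transform requires strictly positive intensities; impute first")
    m <- log(m)
  }
  Y <- t(m[, qc_ids, drop = FALSE])            # QC samples x features
  center <- colMeans(Y)
  Yc <- sweep(Y, 2, center)
  sv <- svd(Yc, nu = 0, nv = k)
  zero_variance <- all(sv$d < 1e-10)
  directions <- if (k > 0) sv$v else matrix(0, ncol(Y), 0)
  structure(list(k = as.integer(k), directions = directions,
                 qc_center = center, log_transform = log_transform,
                 singular_values = sv$d[seq_len(min(k, length(sv$d)))],
                 all_singular_values = sv$d,
                 fitted_on = qc_ids, zero_variance = zero_variance,
                 feature_ids = rownames(x$matrix)),
            class = "batch_correction")
}

#' @export
print.batch_correction <- function(x, ...) {
  cat(sprintf("batch_correction model: k = %d component(s) over %d features, fitted on %d QC injections\n",
              x$k, length(x$qc_center), length(x$fitted_on)))
  if (x$zero_variance) cat("  note: QC profiles carry no variance\n")
  else if (x$k > 0)
    cat("  singular values:", paste(signif(x$singular_values, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Remove fitted unwanted variation from a feature table
#'
#' Centers every sample profile by the QC mean on the log scale, subtracts
#' its projection onto the fitted unwanted-variation directions, and maps the
#' result back to the intensity scale. QC and study samples are both
#' transformed, so post-correction diagnostics remain computable. The
#' operation is a projection: applying it twice equals applying it once.
#'
#' @param object a fitted [fit_batch_correction()] model.
#' @param x a `feature_table` over the same features.
#' @param ... unused.
#' @return the corrected `feature_table` (convention and mask carried over).
#' @export
predict.batch_correction <- function(object, x, ...) {
  stopifnot(inherits(x, "feature_table"))
  if (!identical(object$feature_ids, rownames(x$matrix)))
    stop("feature set of table differs from the fitted model")
  m <- x$matrix
  if (anyNA(m)) stop("cannot correct a table with missing cells")
  if (object$log_transform) {
    if (any(m <= 0)) stop("log transform requires strictly positive intensities")
    m <- log(m)
  }
  Y <- sweep(t(m), 2, object$qc_center)        # samples x features
  if (object$k > 0) {
    U <- object$directions
    Y <- Y - (Y %*% U) %*% t(U)
  }
  out <- t(sweep(Y, 2, object$qc_center, "+"))
  if (object$log_transform) out <- exp(out)
  dimnames(out) <- dimnames(x$matrix)
  feature_table(out, x$sample_meta, x$feature_meta,
                missing_convention = x$missing_convention,
                imputed_mask = x$imputed_mask)
}

#' @rdname predict.batch_correction
#' @param model a fitted `batch_correction` model.
#' @export
correct_batches <- function(x, model) predict(model, x)

#' Inter- and intra-batch distance diagnostic
#'
#' Quantifies batch structure in a group of samples: profiles are log(1+x)
#' transformed and summarized as the mean distance of each profile to its own
#' batch centroid (`intra`) and the mean pairwise distance among batch
#' centroids divided by `intra` (`inter`, dimensionless). Repeated pooled-QC
#' injections have small intra-batch spread, so their inter ratio is large
#' whenever batch effects are present, while heterogeneous study samples give
#' a small ratio — the diagnostic contrast that motivates QC-anchored
#' correction. The ratio is already unit free; per-feature unit-variance
#' scaling is available but off by default, because it caps the batch-effect
#' contribution of every feature at the same weight as pure imputation noise
#' and thereby floors the diagnostic.
#'
#' @param x a `feature_table` with `batch_id` sample metadata.
#' @param roles which samples to use (default the pooled QCs).
#' @param log apply `log1p` before computing distances.
#' @param standardize unit-scale each feature within the subset (centering
#'   alone would not change any distance).
#' @return object of class `batch_distance_report`: `inter_batch_distance`
#'   (ratio), `intra_batch_distance`, `inter_centroid_distance` (unnormalized
#'   mean pairwise centroid distance), `per_batch_centroids`, per-batch sizes
#'   and a `zero_variance` flag (identical profiles are reported as inter = 0
#'   with the flag set).
#' @export
batch_distances <- function(x, roles = "qc_pool", log = TRUE,
                            standardize = FALSE) {
  stopifnot(inherits(x, "feature_table"))
  ids <- samples_by_role(x, roles)
  meta <- x$sample_meta[match(ids, x$sample_meta$sample_id), , drop = FALSE]
  if (length(ids) < 2) stop("need at least 2 samples in the subset")
  batches <- unique(meta$batch_id)
  if (length(batches) < 2) stop("subset spans a single batch")
  counts <- table(meta$batch_id)
  if (any(counts == 0)) stop("a batch has no members in the subset")

  M <- t(x$matrix[, ids, drop = FALSE])        # samples x features
  if (anyNA(M)) stop("distances require a table without NA cells")
  if (log) M <- log1p(M)
  if (standardize) {
    mu <- colMeans(M)
    sd_ <- apply(M, 2, stats::sd)
    sd_[sd_ < 1e-12] <- 1
    M <- sweep(sweep(M, 2, mu), 2, sd_, "/")
  }
  d <- batch_dist_core(M, meta$batch_id)
  structure(list(roles = roles, inter_batch_distance = d$inter,
                 intra_batch_distance = d$intra,
                 inter_centroid_distance = d$inter_raw,
                 per_batch_centroids = d$centroids,
                 batch_sizes = counts, zero_variance = d$zero_variance),
            class = "batch_distance_report")
}

## distance arithmetic shared by batch_distances() and scree_select_k();
## M is samples x features on the scale distances are taken on
batch_dist_core <- function(M, batch_id) {
  batches <- unique(batch_id)
  cent <- do.call(rbind, lapply(batches, function(b)
    colMeans(M[batch_id == b, , drop = FALSE])))
  rownames(cent) <- batches
  devs <- M - cent[match(batch_id, batches), , drop = FALSE]
  intra <- mean(sqrt(rowSums(devs^2)))
  inter_raw <- mean(stats::dist(cent))
  eps <- 1e-12
  zero_variance <- intra < eps
  inter <- if (zero_variance) {
    if (inter_raw < eps) 0 else Inf
  } else inter_raw / intra
  list(inter = inter, intra = intra, inter_raw = inter_raw,
       centroids = cent, zero_variance = zero_variance)
}

#' @export
print.batch_distance_report <- function(x, ...) {
  cat(sprintf("batch distances (%s): inter/intra ratio = %.3f (intra = %.3f, centroid dist = %.3f)%s\n",
              paste(x$roles, collapse = ","), x$inter_batch_distance,
              x$intra_batch_distance, x$inter_centroid_distance,
              if (x$zero_variance) " [zero variance]" else ""))
  invisible(x)
}

#' Scree-based selection of the number of correction components
#'
#' Fits the QC model once at `k_max`, then for each `k` in `0..k_max` removes
#' the top-k directions and records the remaining QC inter-batch distance.
#' The chosen `k` is the smallest one after which the curve has flattened:
#' the first `k` whose decrease to `k + 1` falls below `tol` times the
#' uncorrected distance (the `k = 0` value). Measuring the decrease against
#' the uncorrected distance keeps the rule stable once the curve reaches the
#' technical-noise floor, where decreases relative to the current value never
#' vanish.
#'
#' @param x a `feature_table` (imputed) with QC samples across >= 2 batches.
#' @param k_max largest number of components to examine (< #QC).
#' @param tol flatness tolerance as a fraction of the uncorrected distance
#'   (default 1%).
#' @param log_transform passed to [fit_batch_correction()].
#' @return object of class `scree_selection`: `chosen_k`, the `curve`
#'   data.frame (`k`, `inter_batch_distance`) and `tol`. Has a `plot` method.
#' @export
scree_select_k <- function(x, k_max, tol = 0.01, log_transform = TRUE) {
  model <- fit_batch_correction(x, k = k_max, log_transform = log_transform)
  qc <- ft_subset(x, samples = samples_by_role(x, "qc_pool"))
  m <- qc$matrix
  if (log_transform) m <- log(m)
  Y <- sweep(t(m), 2, model$qc_center)
  batch_id <- qc$sample_meta$batch_id
  d <- raw <- numeric(k_max + 1L)
  for (k in 0:k_max) {
    Yk <- if (k == 0) Y else {
      U <- model$directions[, seq_len(k), drop = FALSE]
      Y - (Y %*% U) %*% t(U)
    }
    # distances taken directly in the projected log space: nested projections
    # then shrink every centroid distance monotonically in k
    dk <- batch_dist_core(Yk, batch_id)
    d[k + 1L] <- dk$inter
    raw[k + 1L] <- dk$inter_raw
  }
  eps <- 1e-12
  chosen <- k_max
  if (d[1] < eps) chosen <- 0L
  else for (k in 0:(k_max - 1L)) {
    if (d[k + 1L] < eps || (d[k + 1L] - d[k + 2L]) < tol * d[1]) {
      chosen <- k
      break
    }
  }
  structure(list(chosen_k = as.integer(chosen),
                 curve = data.frame(k = 0:k_max, inter_batch_distance = d,
                                    inter_centroid_distance = raw),
                 tol = tol), class = "scree_selection")
}

#' @export
print.scree_selection <- function(x, ...) {
  cat(sprintf("scree selection: chosen k = %d (tol %.1f%% of uncorrected distance)\n",
              x$chosen_k, 100 * x$tol))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @export
plot.scree_selection <- function(x, ...) {
  plot(x$curve$k, x$curve$inter_batch_distance, type = "b",
       xlab = "components removed (k)", ylab = "QC inter-batch distance",
       main = "Scree of QC inter-batch distance", ...)
  graphics::abline(v = x$chosen_k, lty = 2)
  invisible(x)
}
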