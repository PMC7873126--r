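#' Parameters of the missing-value noise imputation
#'
#' Missing cells are replaced by the absolute value of draws from a normal
#' distribution whose defaults (mean 70, sd 20) sit below the noise floor of
#' the upstream peak detection (threshold 100), so imputed noise is
#' distinguishable from measured signal. The threshold itself is carried as
#' documentation only: draws are not truncated at it (about 6.7% of draws
#' exceed 100 and are kept, since the stated distribution — not its
#' motivation — defines the imputation).
#'
#' @param noise_mean mean of the noise distribution (intensity units).
#' @param noise_sd standard deviation of the noise distribution.
#' @param detection_threshold documented upstream noise floor.
#' @param seed integer seed.
#' @return list of class `imputation_params`.
#' @export
imputation_params <- function(noise_mean = 70, noise_sd = 20,
                              detection_threshold = 100, seed = 1L) {
  if (noise_mean <= 0) stop("noise_mean must be > 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(list(noise_mean = noise_mean, noise_sd = noise_sd,
                 detection_threshold = detection_threshold,
                 seed = as.integer(seed)),
            class = "imputation_params")
}

#' Impute missing intensities with sub-threshold noise
#'
#' Replaces every empty cell (zeros and NAs are both treated as missing) by
#' `|x|` with `x ~ Normal(noise_mean, noise_sd)`; non-missing cells are
#' unchanged. The result has `missing_convention = "imputed"` and carries the
#' logical mask of imputed cells, so later stages can recover pre-imputation
#' detection status and the zero/NA output variants.
#'
#' @param x a `feature_table` with convention `zero` or `NA`.
#' @param params an [imputation_params()].
#' @return an imputed `feature_table` (deterministic given `params$seed`).
#' @export
impute_noise <- function(x, params = imputation_params()) {
  stopifnot(inherits(x, "feature_table"))
  if (x$missing_convention == "imputed")
    stop("table is already imputed")
  mask <- is_missing_cell(x)
  m <- x$matrix
  n_missing <- sum(mask)
  if (n_missing > 0) {
    local_rng(params$seed)
    m[mask] <- abs(stats::rnorm(n_missing, params$noise_mean, params$noise_sd))
  }
  feature_table(m, x$sample_meta, x$feature_meta,
                missing_convention = "imputed", imputed_mask = mask)
}

#' Restore missing markers at imputed positions
#'
#' Produces the zero- or NA-convention variant of an imputed (possibly
#' batch-corrected) table: cells flagged by the imputed mask are reset to the
#' requested marker, all other cells keep their current values.
#'
#' @param x an imputed `feature_table` carrying its mask.
#' @param convention `"zero"` or `"NA"`.
#' @return a `feature_table` in the requested convention, without a mask.
#' @export
restore_missing <- function(x, convention = c("zero", "NA")) {
  convention <- match.arg(convention)
  stopifnot(inherits(x, "feature_table"))
  if (x$missing_convention != "imputed" || is.null(x$imputed_mask))
    stop("restore_missing() needs an imputed table with its mask")
  m <- x$matrix
  m[x$imputed_mask] <- if (convention == "NA") NA_real_ else 0
  feature_table(m, x$sample_meta, x$feature_meta,
                missing_convention = convention)
}
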