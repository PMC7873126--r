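# an imputed-like dense table of one species from log-scale profiles
species_table <- function(M, code = "HOLLAN") {
  tiny_table(t(exp(M)), species = code, convention = "zero")
}

test_that("a sample displaced along a high-variance axis has the largest distance", {
  set.seed(1)
  n <- 20; p <- 8
  M <- matrix(rnorm(n * p, 8, 0.2), n, p)
  M[, 1] <- M[, 1] + rnorm(n, 0, 2)  # high-variance direction
  M[n, 1] <- M[n, 1] + 15            # displaced sample
  tab <- species_table(M)
  d <- mahalanobis_per_species(tab, "HOLLAN")
  expect_equal(which.max(d), n, ignore_attr = TRUE)
})

test_that("identical samples all sit at distance zero", {
  M <- matrix(rep(rnorm(6, 8, 1), each = 10), nrow = 10)
  tab <- species_table(M)
  d <- mahalanobis_per_species(tab, "HOLLAN")
  expect_equal(unname(d), rep(0, 10))
})

test_that("mean squared Mahalanobis distance matches the chi-square expectation", {
  set.seed(2)
  n <- 2000; p <- 30; q <- 10
  M <- matrix(rnorm(n * p, 6, 1), n, p)
  tab <- species_table(M)
  d <- mahalanobis_per_species(tab, "HOLLAN",
                               validity_params(n_components = q))
  expect_equal(mean(d^2), q, tolerance = 0.05)
})

test_that("regularization variants agree on a well-conditioned problem", {
  set.seed(3)
  n <- 60; p <- 5
  M <- matrix(rnorm(n * p, 6, 1), n, p)
  tab <- species_table(M)
  d_pca <- mahalanobis_per_species(tab, "HOLLAN",
                                   validity_params(n_components = p))
  d_pinv <- mahalanobis_per_species(
    tab, "HOLLAN", validity_params(covariance_regularization = "pseudo_inverse"))
  expect_equal(unname(d_pca), unname(d_pinv), tolerance = 1e-6)
  d_shr <- mahalanobis_per_species(
    tab, "HOLLAN", validity_params(covariance_regularization = "shrinkage",
                                   shrinkage_gamma = 1e-8))
  expect_equal(unname(d_pinv), unname(d_shr), tolerance = 1e-3)
})

test_that("species with fewer than 4 samples are refused", {
  tab <- species_table(matrix(rnorm(9, 6, 1), 3, 3))
  expect_error(mahalanobis_per_species(tab, "HOLLAN"), "fewer than 4")
})

test_that("shared fraction is plain set arithmetic over the fingerprint", {
  fp <- structure(list(species_code = "X", features = paste0("f", 1:40)),
                  class = "species_fingerprint")
  expect_equal(shared_fraction(paste0("f", 1:40), fp), 1.0)
  expect_equal(shared_fraction(character(0), fp), 0.0)
  expect_equal(shared_fraction(c(paste0("f", 1:12), paste0("g", 1:100)), fp), 0.30)
  empty <- structure(list(species_code = "X", features = character(0)),
                     class = "species_fingerprint")
  expect_error(shared_fraction("f1", empty), "empty fingerprint")
})

test_that("Mahalanobis decisions are invariant to a global intensity scale", {
  sim <- cached_sim(seed = 3, n_outlier_samples = 5L)
  imp <- impute_noise(sim$table, imputation_params(seed = 4))
  cor_ <- predict(fit_batch_correction(imp, k = 3), imp)
  keep <- setdiff(colnames(cor_$matrix), samples_by_role(cor_, "qc_pool"))
  bf <- blank_filter(ft_subset(cor_, samples = keep))$table
  d1 <- mahalanobis_per_species(bf, "HOLLAN")
  scaled <- feature_table(bf$matrix * 1000, bf$sample_meta, bf$feature_meta,
                          missing_convention = bf$missing_convention,
                          imputed_mask = bf$imputed_mask)
  d2 <- mahalanobis_per_species(scaled, "HOLLAN")
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("the boundary rule passes at the multiplier and fails above it", {
  set.seed(5)
  n <- 24; p <- 6
  M <- matrix(rnorm(n * p, 8, 0.5), n, p)
  tab <- species_table(M)
  d <- mahalanobis_per_species(tab, "HOLLAN",
                               validity_params(n_components = 4))
  peer <- vapply(seq_len(n), function(i) mean(d[-i]), numeric(1))
  fp <- structure(list(species_code = "HOLLAN",
                       features = rownames(tab$matrix)),
                  class = "species_fingerprint")
  # distance multiplier chosen so that every sample is exactly at or below
  # its own boundary: none may fail
  mult_at <- max(d / peer)
  vr <- validate_samples(tab, list(HOLLAN = fp),
                         validity_params(distance_multiplier = mult_at,
                                         n_components = 4))
  expect_true(all(vr$report$decision == "pass"))
  # nudging the multiplier below the extreme sample's ratio must fail it
  vr2 <- validate_samples(tab, list(HOLLAN = fp),
                          validity_params(distance_multiplier = mult_at * 0.999,
                                          n_components = 4))
  expect_equal(sum(vr2$report$decision == "fail_distance"), 1L)
})

test_that("the report partitions the species and filters the table", {
  sim <- cached_sim(seed = 3, n_outlier_samples = 5L)
  imp <- impute_noise(sim$table, imputation_params(seed = 4))
  cor_ <- predict(fit_batch_correction(imp, k = 3), imp)
  keep <- setdiff(colnames(cor_$matrix), samples_by_role(cor_, "qc_pool"))
  bf <- blank_filter(ft_subset(cor_, samples = keep))$table
  fps <- build_fingerprints(bf)
  vr <- validate_samples(bf, fps)
  n_study <- sum(bf$sample_meta$role == "study")
  expect_equal(nrow(vr$report), n_study)
  expect_equal(sum(vr$report$decision == "pass") +
                 sum(vr$report$decision != "pass"), n_study)
  expect_equal(ncol(vr$table$matrix),
               ncol(bf$matrix) - sum(vr$report$decision != "pass"))
  expect_false(any(vr$report$sample_id[vr$report$decision != "pass"] %in%
                     colnames(vr$table$matrix)))
})

test_that("injected outliers are flagged and clean samples survive", {
  sim <- cached_sim(seed = 3, n_outlier_samples = 5L)
  imp <- impute_noise(sim$table, imputation_params(seed = 4))
  cor_ <- predict(fit_batch_correction(imp, k = 3), imp)
  keep <- setdiff(colnames(cor_$matrix), samples_by_role(cor_, "qc_pool"))
  bf <- blank_filter(ft_subset(cor_, samples = keep))$table
  fps <- build_fingerprints(bf)
  vr <- validate_samples(bf, fps)
  truth_out <- names(sim$truth$sample_outlier)[sim$truth$sample_outlier]
  flagged <- vr$report$sample_id[vr$report$decision != "pass"]
  expect_true(all(truth_out %in% flagged))
  fp_rate <- sum(!flagged %in% truth_out) /
    sum(!vr$report$sample_id %in% truth_out)
  expect_lte(fp_rate, 0.02)
})

test_that("species missing from the fingerprints are reported", {
  sim <- cached_sim(seed = 1)
  imp <- impute_noise(sim$table, imputation_params(seed = 2))
  keep <- setdiff(colnames(imp$matrix), samples_by_role(imp, "qc_pool"))
  bf <- blank_filter(ft_subset(imp, samples = keep))$table
  fps <- build_fingerprints(bf)
  expect_error(validate_samples(bf, fps[-1]), "absent from fingerprints")
})
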