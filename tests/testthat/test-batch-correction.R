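make_qc_table <- function(M, batches) {
  # M: samples x features on the log scale; converted to intensities
  m <- t(exp(M))
  tiny_table(m, roles = "qc_pool", batch = batches, convention = "zero")
}

test_that("a k = 0 model has no directions and transforms to identity", {
  sim <- cached_sim(seed = 1)
  imp <- impute_noise(sim$table, imputation_params(seed = 2))
  mod <- fit_batch_correction(imp, k = 0)
  expect_equal(ncol(mod$directions), 0L)
  out <- predict(mod, imp)
  expect_equal(out$matrix, imp$matrix, tolerance = 1e-12)
})

test_that("a rank-1 QC perturbation is recovered as one collinear direction", {
  set.seed(10)
  p <- 60
  base <- rnorm(p, 8, 1)
  v <- rnorm(p); v <- v / sqrt(sum(v^2))
  alpha <- c(-2, -1, 1, 2, -1.5, 1.5)   # per-sample loading, rank-1 exactly
  M <- t(sapply(alpha, function(a) base + a * v))
  tab <- make_qc_table(M, batches = rep(c("b1", "b2", "b3"), each = 2))
  mod <- fit_batch_correction(tab, k = 1)
  cosine <- abs(sum(mod$directions[, 1] * v))
  expect_gt(cosine, 0.999)
})

test_that("identical QC profiles yield a zero-variance fit and zero distances", {
  M <- matrix(rep(rnorm(20, 8, 1), each = 6), nrow = 6)
  tab <- make_qc_table(M, batches = rep(c("b1", "b2"), each = 3))
  mod <- fit_batch_correction(tab, k = 2)
  expect_true(mod$zero_variance)
  rep_ <- batch_distances(tab, "qc_pool")
  expect_true(rep_$zero_variance)
  expect_equal(rep_$inter_batch_distance, 0)
})

test_that("fit rejects invalid k, too few QCs, and batches", {
  sim <- cached_sim(seed = 1)
  imp <- impute_noise(sim$table, imputation_params(seed = 2))
  n_qc <- length(samples_by_role(imp, "qc_pool"))
  expect_error(fit_batch_correction(imp, k = n_qc), "k must lie")
  expect_error(fit_batch_correction(sim$table, k = 2), "missing|impute")
  one_batch <- ft_subset(imp, samples = imp$sample_meta$sample_id[
    imp$sample_meta$batch_id == "pos01"])
  expect_error(fit_batch_correction(one_batch, k = 1), "2 batches")
})

test_that("the correction is a projection: applying it twice changes nothing", {
  sim <- cached_sim(seed = 1)
  imp <- impute_noise(sim$table, imputation_params(seed = 2))
  mod <- fit_batch_correction(imp, k = 3)
  once <- predict(mod, imp)
  twice <- predict(mod, once)
  expect_equal(log(twice$matrix), log(once$matrix), tolerance = 1e-9)
})

test_that("correcting with k >= the true rank removes most QC batch distance", {
  sim <- cached_sim(seed = 1)
  imp <- impute_noise(sim$table, imputation_params(seed = 2))
  pre <- batch_distances(imp, "qc_pool")$inter_batch_distance
  r <- sim$truth$config$batch_effect_rank
  for (k in c(r, r + 2)) {
    post <- batch_distances(predict(fit_batch_correction(imp, k = k), imp),
                            "qc_pool")$inter_batch_distance
    expect_lt(post, 0.10 * pre)
  }
})

test_that("transform requires matching feature sets", {
  sim <- cached_sim(seed = 1)
  imp <- impute_noise(sim$table, imputation_params(seed = 2))
  mod <- fit_batch_correction(imp, k = 1)
  shrunk <- ft_subset(imp, features = 1:100)
  expect_error(predict(mod, shrunk), "feature set")
})

test_that("two separated batches reproduce the closed-form distance ratio", {
  # isotropic N(0, I3) clouds, centroids delta apart along one axis;
  # E||x - centroid|| = sqrt(2) * gamma(2) / gamma(1.5) for chi with 3 df
  set.seed(20)
  n <- 4000; p <- 3; delta <- 50
  M <- matrix(rnorm(2 * n * p), 2 * n, p)
  M[seq_len(n), 1] <- M[seq_len(n), 1] + delta
  M <- M + 100  # keep intensities positive
  tab <- tiny_table(t(M), roles = "qc_pool",
                    batch = rep(c("b1", "b2"), each = n), convention = "zero")
  rep_ <- batch_distances(tab, "qc_pool", log = FALSE, standardize = FALSE)
  chi3_mean <- sqrt(2) * gamma(2) / gamma(1.5)
  expect_equal(rep_$inter_batch_distance, delta / chi3_mean, tolerance = 0.02)
})

test_that("the QC batch diagnostic dwarfs the study-sample diagnostic before correction", {
  sim <- cached_sim(seed = 1)
  imp <- impute_noise(sim$table, imputation_params(seed = 2))
  qc <- batch_distances(imp, "qc_pool")$inter_batch_distance
  st <- batch_distances(imp, "study")$inter_batch_distance
  expect_gt(qc, 5 * st)
})

test_that("the scree curve is non-increasing and flattens at the true rank", {
  sim <- cached_sim(seed = 1)
  imp <- impute_noise(sim$table, imputation_params(seed = 2))
  sc <- scree_select_k(imp, k_max = 7)
  # centroid distances under nested projections shrink monotonically (exact)
  expect_true(all(diff(sc$curve$inter_centroid_distance) <= 1e-9))
  # the normalized ratio is non-increasing up to noise (intra also shrinks,
  # so past the elbow the ratio may wiggle by a sliver of the k = 0 value)
  d <- sc$curve$inter_batch_distance
  expect_true(all(diff(d) <= 1e-3 * d[1]))
  expect_equal(sc$chosen_k, sim$truth$config$batch_effect_rank)
})

test_that("without batch effects the scree selects zero components", {
  cfg <- sim_config(seed = 6, batch_effect_sd = 0, qc_log_sd = 0)
  sim <- simulate_study(cfg = cfg)
  imp <- impute_noise(sim$table, imputation_params(seed = 7))
  # imputed cells still vary between QCs, but the uncorrected distance is
  # already at its floor: no component earns a decrease
  sc <- scree_select_k(imp, k_max = 4)
  expect_equal(sc$chosen_k, 0L)
})

test_that("between-species separation survives the correction", {
  sim <- cached_sim(seed = 1)
  imp <- impute_noise(sim$table, imputation_params(seed = 2))
  cor_ <- predict(fit_batch_correction(imp, k = 3), imp)
  sep <- function(tab) {
    ids <- samples_by_role(tab, "study")
    sm <- tab$sample_meta[match(ids, tab$sample_meta$sample_id), ]
    M <- t(log(tab$matrix[, ids]))
    cent <- do.call(rbind, lapply(split(seq_len(nrow(M)), sm$species_code),
                                  function(i) colMeans(M[i, , drop = FALSE])))
    mean(dist(cent))
  }
  s0 <- sep(imp); s1 <- sep(cor_)
  expect_lt(abs(s1 - s0) / s0, 0.15)
})
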