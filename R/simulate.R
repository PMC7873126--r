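#' Configuration of the synthetic feature-table generator
#'
#' Parameters of [simulate_study()]. The defaults emulate the statistical
#' structure of the modeled study: thirteen species with largely disjoint
#' metabolite fingerprints, a small shared core, procedural contaminants
#' visible in blanks, pooled-QC columns diluted by averaging over all study
#' extracts, feature-wise multiplicative batch effects of low rank, and a
#' detection threshold that censors weak signals. With the full 595-column
#' design they produce an overall empty-cell fraction close to
#' `target_zero_fraction` (0.90).
#'
#' @param n_features_per_species fingerprint size per species, including the
#'   shared core.
#' @param n_shared_features features common to all species' fingerprints
#'   (phylogenetically shared chemistry).
#' @param n_contaminant_features procedural contaminants: present in blanks
#'   and in biological samples, members of no fingerprint.
#' @param baseline_log_intensity mean and sd of the per-feature base
#'   intensity, on the log10 scale.
#' @param sample_log_sd within-feature, between-sample biological spread
#'   (log10 sd).
#' @param qc_log_sd technical spread of repeated QC injections (log10 sd).
#' @param batch_effect_sd per-feature sd of the multiplicative batch effect
#'   on the log10 scale (0 disables batch effects).
#' @param batch_effect_rank number of independent directions spanning the
#'   batch effects in feature space.
#' @param detection_dropout probability that a fingerprint feature is missed
#'   in a given sample.
#' @param detection_threshold intensities below this (after batch effects)
#'   are censored to missing; matches the noise floor of the upstream peak
#'   detection (100 counts).
#' @param target_zero_fraction the empty-cell fraction the defaults are
#'   calibrated to reproduce on the full design.
#' @param n_outlier_samples number of study samples turned into outliers by
#'   swapping part of their fingerprint for another species' features.
#' @param outlier_swap_fraction fraction of an outlier's detected fingerprint
#'   features replaced by foreign features.
#' @param seed integer seed; all randomness of the generator flows from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_features_per_species = 200L,
                       n_shared_features = 20L,
                       n_contaminant_features = 30L,
                       baseline_log_intensity = c(mean = 3.2, sd = 0.5),
                       sample_log_sd = 0.3,
                       qc_log_sd = 0.05,
                       batch_effect_sd = 1.2,
                       batch_effect_rank = 3L,
                       detection_dropout = 0.35,
                       detection_threshold = 100,
                       target_zero_fraction = 0.90,
                       n_outlier_samples = 0L,
                       outlier_swap_fraction = 0.8,
                       seed = 1L) {
  cfg <- list(n_features_per_species = as.integer(n_features_per_species),
              n_shared_features = as.integer(n_shared_features),
              n_contaminant_features = as.integer(n_contaminant_features),
              baseline_log_intensity = baseline_log_intensity,
              sample_log_sd = sample_log_sd, qc_log_sd = qc_log_sd,
              batch_effect_sd = batch_effect_sd,
              batch_effect_rank = as.integer(batch_effect_rank),
              detection_dropout = detection_dropout,
              detection_threshold = detection_threshold,
              target_zero_fraction = target_zero_fraction,
              n_outlier_samples = as.integer(n_outlier_samples),
              outlier_swap_fraction = outlier_swap_fraction,
              seed = as.integer(seed))
  probs <- c(cfg$detection_dropout, cfg$target_zero_fraction,
             cfg$outlier_swap_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(cfg$n_features_per_species, cfg$n_shared_features,
              cfg$n_contaminant_features, cfg$n_outlier_samples,
              cfg$batch_effect_rank)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (cfg$n_shared_features > cfg$n_features_per_species)
    stop("n_shared_features cannot exceed n_features_per_species")
  if (any(c(cfg$sample_log_sd, cfg$qc_log_sd, cfg$batch_effect_sd) < 0))
    stop("spread parameters must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a study-shaped feature table with known ground truth
#'
#' Generates the W4M-style feature table of a full study run: study samples
#' carry their species fingerprint drawn from a log-normal baseline (thinned
#' by detection dropout), pooled-QC columns equal the mean of all study
#' profiles before batch effects (so weak single-species features fall below
#' the detection threshold in the QC, as dilution does in a real pool),
#' blanks carry only the contaminant features, and every intensity in batch
#' *b* is multiplied by a feature-wise batch factor of low rank. Intensities
#' below the detection threshold are censored to missing (`NA` convention).
#'
#' @param design a [study_design()].
#' @param cfg a [sim_config()].
#' @param losses sample losses applied before injection-sequence assembly;
#'   default the study's single documented loss (511 analytical samples).
#' @return a list with elements `table` (a [feature_table()]) and `truth`
#'   (class `sim_truth`): per-feature species membership and contaminant
#'   flags, per-sample outlier flags, the true per-batch log10 effect matrix
#'   (features x batches) and its generating directions/scores, and the
#'   pre-batch QC base profile.
#' @export
simulate_study <- function(design = study_design(), cfg = sim_config(),
                           losses = known_losses()) {
  stopifnot(inherits(design, "study_design"), inherits(cfg, "sim_config"))
  records <- enumerate_study_samples(design)
  records <- apply_known_losses(records, losses)
  records <- assign_lab_ids(records, seed = cfg$seed + 1L)
  inj <- build_injection_sequence(records, design, seed = cfg$seed + 2L)
  samples <- inj[inj$role != "solvent", , drop = FALSE]
  rownames(samples) <- NULL

  species <- design_species(design)$species_code
  n_sp <- length(species)
  n_private <- cfg$n_features_per_species - cfg$n_shared_features

  ## feature bookkeeping: shared core, per-species private, contaminants
  n_feat <- cfg$n_shared_features + n_sp * n_private + cfg$n_contaminant_features
  feature_id <- sprintf("FT%04d", seq_len(n_feat))
  type <- c(rep("shared", cfg$n_shared_features),
            rep("fingerprint", n_sp * n_private),
            rep("contaminant", cfg$n_contaminant_features))
  owner <- c(rep(NA_character_, cfg$n_shared_features),
             rep(species, each = n_private),
             rep(NA_character_, cfg$n_contaminant_features))
  is_contaminant <- type == "contaminant"

  ## membership: feature x species
  member <- matrix(FALSE, n_feat, n_sp, dimnames = list(feature_id, species))
  member[type == "shared", ] <- TRUE
  for (s in species) member[!is.na(owner) & owner == s, s] <- TRUE

  local_rng(cfg$seed)
  base_log <- stats::rnorm(n_feat, cfg$baseline_log_intensity[["mean"]],
                           cfg$baseline_log_intensity[["sd"]])
  ## contaminants are systematic: keep their base level clearly above noise
  base_log[is_contaminant] <- pmax(base_log[is_contaminant], 2.7)

  study <- samples[samples$role == "study", , drop = FALSE]
  n_study <- nrow(study)
  sp_idx <- match(study$species_code, species)

  present <- member[, sp_idx, drop = FALSE] | is_contaminant
  dropout <- matrix(stats::runif(n_feat * n_study) < cfg$detection_dropout,
                    n_feat, n_study)
  present <- present & !dropout

  ## outlier injection: replace part of the fingerprint by a donor species'
  outlier_flag <- rep(FALSE, n_study)
  outlier_info <- NULL
  if (cfg$n_outlier_samples > 0) {
    pick <- sample.int(n_study, cfg$n_outlier_samples)
    outlier_flag[pick] <- TRUE
    rows <- list()
    for (i in pick) {
      own <- which(present[, i] & member[, sp_idx[i]] & !is_contaminant)
      k <- ceiling(cfg$outlier_swap_fraction * length(own))
      donors <- setdiff(seq_len(n_sp), sp_idx[i])
      donor <- donors[sample.int(length(donors), 1L)]
      off <- own[sample.int(length(own), k)]
      candidates <- which(member[, donor] & !member[, sp_idx[i]] & !present[, i])
      on <- candidates[sample.int(length(candidates), min(k, length(candidates)))]
      present[off, i] <- FALSE
      present[on, i] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = study$sample_id[i], species_code = study$species_code[i],
        donor_species = species[donor], n_swapped = k,
        n_fingerprint_present = length(own), stringsAsFactors = FALSE)
    }
    outlier_info <- do.call(rbind, rows)
  }

  intens <- 10^(base_log + matrix(stats::rnorm(n_feat * n_study, 0,
                                               cfg$sample_log_sd),
                                  n_feat, n_study))
  study_pre <- intens * present  # pre-batch-effect study profiles

  ## pooled QC: mean of all study profiles before batch effects (dilution)
  qc_base <- rowMeans(study_pre)
  qc <- samples[samples$role == "qc_pool", , drop = FALSE]
  n_qc <- nrow(qc)
  qc_pre <- qc_base * 10^matrix(stats::rnorm(n_feat * n_qc, 0, cfg$qc_log_sd),
                                n_feat, n_qc)

  blank <- samples[samples$role == "blank", , drop = FALSE]
  n_blank <- nrow(blank)
  blank_pre <- matrix(0, n_feat, n_blank)
  if (n_blank > 0 && cfg$n_contaminant_features > 0) {
    bl <- 10^(base_log[is_contaminant] +
                matrix(stats::rnorm(sum(is_contaminant) * n_blank, 0,
                                    cfg$sample_log_sd),
                       sum(is_contaminant), n_blank))
    blank_pre[is_contaminant, ] <- bl
  }

  ## low-rank multiplicative batch effects, constant within batch
  batches <- sprintf("pos%02d", seq_len(design$n_batches))
  r <- cfg$batch_effect_rank
  if (cfg$batch_effect_sd > 0 && r > 0) {
    V <- matrix(stats::rnorm(n_feat * r), n_feat, r)
    S <- matrix(stats::rnorm(design$n_batches * r, 0,
                             cfg$batch_effect_sd / sqrt(r)),
                design$n_batches, r)
  } else {
    V <- matrix(0, n_feat, max(r, 1L))
    S <- matrix(0, design$n_batches, max(r, 1L))
  }
  log_effects <- V %*% t(S)  # features x batches, log10 scale
  colnames(log_effects) <- batches
  rownames(log_effects) <- feature_id

  apply_batch <- function(mat, batch_ids) {
    if (ncol(mat) == 0) return(mat)
    mat * 10^log_effects[, match(batch_ids, batches), drop = FALSE]
  }
  study_m <- apply_batch(study_pre, study$batch_id)
  qc_m <- apply_batch(qc_pre, qc$batch_id)
  blank_m <- apply_batch(blank_pre, blank$batch_id)
  ## contaminants survive the threshold in every blank (systematic carryover)
  if (n_blank > 0 && cfg$n_contaminant_features > 0)
    blank_m[is_contaminant, ] <- pmax(blank_m[is_contaminant, ],
                                      cfg$detection_threshold * 1.05)

  ## detection threshold: censor weak signals (and true zeros) to missing.
  ## For the QC the detection mask is a property of the pooled material
  ## (fixed across injections, judged before the batch factor), so the QC
  ## batch effect stays exactly linear on the log scale; study samples are
  ## censored after the batch factor, as the instrument sees them.
  study_m[study_m < cfg$detection_threshold] <- NA_real_
  qc_m[qc_base < cfg$detection_threshold, ] <- NA_real_
  blank_m[blank_m < cfg$detection_threshold] <- NA_real_
  m <- cbind(study_m, qc_m, blank_m)
  meta <- rbind(study, qc, blank)
  colnames(m) <- meta$sample_id
  rownames(m) <- feature_id

  ## restore injection order
  ord <- order(match(meta$batch_id, batches), meta$injection_index)
  m <- m[, ord, drop = FALSE]
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL
  meta <- meta[, c("sample_id", "role", "lab_id", "species_code", "pool",
                   "diversity_level", "season", "replicate", "plot_id",
                   "batch_id", "injection_index", "block")]

  feature_meta <- data.frame(
    feature_id = feature_id,
    mz = round(stats::runif(n_feat, 100, 1000), 4),
    rt = round(stats::runif(n_feat, 0, 1080), 1),
    annotation = NA_character_, stringsAsFactors = FALSE)

  tab <- feature_table(m, meta, feature_meta, missing_convention = "NA")

  truth <- structure(list(
    feature = data.frame(feature_id = feature_id, type = type,
                         species = owner, contaminant = is_contaminant,
                         stringsAsFactors = FALSE),
    membership = member,
    sample_outlier = stats::setNames(outlier_flag, study$sample_id),
    outlier_info = outlier_info,
    log_effects = log_effects,
    effect_directions = V, effect_scores = S,
    qc_base = stats::setNames(qc_base, feature_id),
    config = cfg), class = "sim_truth")

  list(table = tab, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d features (%d contaminant), %d outlier samples, batch-effect rank %d\n",
              nrow(x$feature), sum(x$feature$contaminant),
              sum(x$sample_outlier), x$config$batch_effect_rank))
  invisible(x)
}

#' Serialize simulation ground truth as TSV sidecars
#'
#' Writes the per-feature truth (type, species, contaminant flag), per-sample
#' outlier flags and the per-batch log10 effect matrix as three TSV files.
#'
#' @param truth a `sim_truth`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return named vector of paths, invisibly.
#' @export
write_ground_truth <- function(truth, dir, prefix = "truth_") {
  stopifnot(inherits(truth, "sim_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(features = file.path(dir, paste0(prefix, "features.tsv")),
             samples = file.path(dir, paste0(prefix, "samples.tsv")),
             batch_effects = file.path(dir, paste0(prefix, "batch_effects.tsv")))
  utils::write.table(truth$feature, paths[["features"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(truth$sample_outlier),
               outlier = unname(truth$sample_outlier)),
    paths[["samples"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature_id = rownames(truth$log_effects) %||%
                 truth$feature$feature_id, truth$log_effects,
               check.names = FALSE),
    paths[["batch_effects"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
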