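#' The factorial field-sampling design
#'
#' Encodes a grassland sampling design: two pools of eight species (four
#' grasses, four herbs each, three species present in both pools), sampled at
#' four seasonal time points in plots of four diversity levels with two
#' replicates, and measured in twelve analytical batches of four 11-sample
#' blocks. The default arguments reproduce the design of the study this
#' package models: 4 seasons x 4 diversity levels x 2 pools x 8 species x 2
#' replicates = 512 study samples.
#'
#' @param seasons ordered season codes.
#' @param diversity_levels numbers of sown species per plot.
#' @param pools named list of pools; each pool is a named list with `grass`
#'   and `herb` character vectors of species codes (4 each).
#' @param replicates replicate codes within a plot.
#' @param n_batches number of analytical batches.
#' @param block_size study samples per block within a batch.
#' @param blocks_per_batch blocks per batch.
#' @param qc_per_batch pooled-QC injections per batch under the default
#'   layout (run-in QC + QC before the first block + one after each block).
#' @return an object of class `study_design`.
#' @export
study_design <- function(
    seasons = c("A", "B", "C", "D"),
    diversity_levels = c(1L, 2L, 4L, 8L),
    pools = list(
      P1 = list(grass = c("AVEPUB", "FESRUB", "PHLPRA", "POAPRA"),
                herb  = c("CENJAC", "KNAARV", "LEUVUL", "PLALAN")),
      P2 = list(grass = c("ANTODO", "DACGLO", "HOLLAN", "PHLPRA"),
                herb  = c("GERPRA", "LEUVUL", "PLALAN", "RANACR"))),
    replicates = c("a", "b"),
    n_batches = 12L,
    block_size = 11L,
    blocks_per_batch = 4L,
    qc_per_batch = 6L) {
  for (p in pools) {
    if (length(p$grass) != 4L || length(p$herb) != 4L)
      stop("each pool must contain exactly 4 grass and 4 herb species")
    if (anyDuplicated(c(p$grass, p$herb)))
      stop("duplicated species code within a pool")
  }
  d <- structure(
    list(seasons = seasons, diversity_levels = as.integer(diversity_levels),
         pools = pools, replicates = replicates,
         n_batches = as.integer(n_batches), block_size = as.integer(block_size),
         blocks_per_batch = as.integer(blocks_per_batch),
         qc_per_batch = as.integer(qc_per_batch)),
    class = "study_design")
  d
}

#' @export
print.study_design <- function(x, ...) {
  sp <- design_species(x)
  cat(sprintf(
    "study_design: %d seasons x %d DLs x %d pools x 8 species x %d replicates = %d study samples\n",
    length(x$seasons), length(x$diversity_levels), length(x$pools),
    length(x$replicates),
    length(x$seasons) * length(x$diversity_levels) * length(x$pools) * 8 *
      length(x$replicates)))
  cat(sprintf("  %d distinct species (%d grass, %d herb); %d batches of %d x %d-sample blocks\n",
              nrow(sp), sum(sp$functional_group == "grass"),
              sum(sp$functional_group == "herb"),
              x$n_batches, x$blocks_per_batch, x$block_size))
  invisible(x)
}

#' Distinct species of a design with functional group and pool membership
#'
#' @param design a `study_design`.
#' @return data.frame with columns `species_code`, `functional_group`,
#'   `pools` (comma-separated pool names).
#' @export
design_species <- function(design) {
  rows <- list()
  for (pn in names(design$pools)) {
    p <- design$pools[[pn]]
    rows[[pn]] <- data.frame(
      species_code = c(p$grass, p$herb),
      functional_group = rep(c("grass", "herb"), each = 4L),
      pool = pn, stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  agg <- aggregate(pool ~ species_code + functional_group, data = all,
                   FUN = function(v) paste(sort(unique(v)), collapse = ","))
  names(agg)[names(agg) == "pool"] <- "pools"
  agg[order(agg$species_code), , drop = FALSE]
}

#' Enumerate the study samples of a design
#'
#' One record per (season, pool, diversity level, species-in-pool, replicate),
#' in that deterministic order. Species present in both pools are enumerated
#' once per pool, so they accumulate twice the records of single-pool species.
#'
#' @param design a `study_design`.
#' @return data.frame of sample records with the design columns plus
#'   `role = "study"`, a synthetic `plot_id`, and empty `lab_id`/`batch_id`
#'   columns to be filled by [assign_lab_ids()] and
#'   [build_injection_sequence()].
#' @export
enumerate_study_samples <- function(design) {
  stopifnot(inherits(design, "study_design"))
  rows <- vector("list", 0L)
  i <- 0L
  for (season in design$seasons)
    for (pn in names(design$pools)) {
      sp <- c(design$pools[[pn]]$grass, design$pools[[pn]]$herb)
      for (dl in design$diversity_levels)
        for (code in sp)
          for (rep_ in design$replicates) {
            i <- i + 1L
            rows[[i]] <- data.frame(
              season = season, pool = pn, diversity_level = dl,
              species_code = code, replicate = rep_,
              stringsAsFactors = FALSE)
          }
    }
  rec <- do.call(rbind, rows)
  rec$role <- "study"
  rec$plot_id <- sprintf("%s_DL%d", rec$pool, rec$diversity_level)
  rec$sample_id <- sprintf("2017_%s_%s_%s_DL%d_%s", rec$season,
                           rec$species_code, rec$pool,
                           rec$diversity_level, rec$replicate)
  rec$lab_id <- NA_character_
  rec$batch_id <- NA_character_
  rec$injection_index <- NA_integer_
  rownames(rec) <- NULL
  rec
}

#' Remove known sample losses from an enumeration
#'
#' Each loss is a named list of record fields (e.g. `list(season = "B",
#' species_code = "FESRUB", pool = "P1", diversity_level = 1, replicate =
#' "b")`) and must match exactly one record; matching zero or several records
#' is an error. `known_losses()` returns the single documented loss of the
#' modeled study (a sample tube broken before analysis), which takes the
#' enumeration from 512 to 511 records.
#'
#' @param records data.frame from [enumerate_study_samples()].
#' @param losses list of loss keys.
#' @return `records` minus the matched rows.
#' @export
apply_known_losses <- function(records, losses = known_losses()) {
  if (length(losses) == 0) return(records)
  drop <- integer(0)
  for (loss in losses) {
    keep <- rep(TRUE, nrow(records))
    for (f in names(loss)) {
      if (!f %in% names(records)) stop("unknown loss field: ", f)
      keep <- keep & records[[f]] == loss[[f]]
    }
    idx <- which(keep)
    if (length(idx) != 1L)
      stop("loss key matches ", length(idx), " records (must match exactly 1): ",
           paste(sprintf("%s=%s", names(loss), unlist(loss)), collapse = ", "))
    if (idx %in% drop)
      stop("duplicate loss key: record already removed")
    drop <- c(drop, idx)
  }
  out <- records[-drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname apply_known_losses
#' @export
known_losses <- function() {
  list(list(season = "B", species_code = "FESRUB", pool = "P1",
            diversity_level = 1L, replicate = "b"))
}

#' Assign per-season Lab-IDs to study records
#'
#' Lab numbers run 001 up to the per-season sample count (128 in the full
#' design). With a seed the numbers are a random permutation within each
#' season — emulating ids drawn at sampling time, which is what randomizes
#' species, diversity level and replicate across extraction and injection
#' order; without a seed they follow enumeration order.
#'
#' @param records study records.
#' @param year sampling year used in the id.
#' @param seed optional integer seed for the within-season permutation.
#' @return `records` with `lab_id` filled.
#' @export
assign_lab_ids <- function(records, year = 2017L, seed = NULL) {
  if (!is.null(seed)) local_rng(seed)
  for (season in unique(records$season)) {
    idx <- which(records$season == season)
    n <- length(idx)
    nums <- if (is.null(seed)) seq_len(n) else sample.int(n)
    records$lab_id[idx] <- sprintf("%03d_%d_%s", nums, year, season)
  }
  records
}

## seed the RNG for the calling function's scope; the caller's previous
## global RNG state is restored when that function exits
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  set.seed(seed)
  expr <- if (is.null(old))
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  else bquote(assign(".Random.seed", .(old), envir = globalenv()))
  do.call(on.exit, list(expr, TRUE), envir = envir)
  invisible(NULL)
}

#' Build the blocked injection sequence
#'
#' Distributes study records across batches in Lab-ID order (samples with the
#' lowest block of per-season lab numbers fill the first batch across all
#' seasons, and so on), filling each batch to `block_size * blocks_per_batch`
#' study slots and leaving any shortfall in the final batch. Within a batch,
#' samples are randomly permuted across its blocks under the given seed. Each
#' batch starts with a run-in (3 solvent injections, 1 pooled QC), then a QC
#' and one blank before the first block; every block is followed by a QC, so
#' blocks are always flanked by QC injections.
#'
#' @param records study records with `lab_id` assigned.
#' @param design a `study_design`.
#' @param seed integer seed for the within-batch randomization.
#' @return an object of class `injection_sequence`: a data.frame with one row
#'   per injection (`sample_id`, `role`, `batch_id`, `injection_index`,
#'   `block`, plus the design columns for study samples), ordered by
#'   injection.
#' @export
build_injection_sequence <- function(records, design, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  if (anyNA(records$lab_id)) stop("records need lab ids; call assign_lab_ids() first")
  capacity <- design$n_batches * design$block_size * design$blocks_per_batch
  if (nrow(records) > capacity)
    stop("more records (", nrow(records), ") than injection capacity (", capacity, ")")

  lab <- parse_lab_id(records$lab_id)
  ord <- order((lab$number - 1L) %/% design$block_size, lab$season, lab$number)
  records <- records[ord, , drop = FALSE]

  per_batch <- design$block_size * design$blocks_per_batch
  batch_of <- (seq_len(nrow(records)) - 1L) %/% per_batch + 1L

  local_rng(seed)
  out <- vector("list", design$n_batches)
  for (b in seq_len(design$n_batches)) {
    bid <- sprintf("pos%02d", b)
    brec <- records[batch_of == b, , drop = FALSE]
    if (nrow(brec) == 0) next
    brec <- brec[sample.int(nrow(brec)), , drop = FALSE]  # randomize across blocks
    n_blocks <- ceiling(nrow(brec) / design$block_size)

    tech <- function(role, tag) data.frame(
      season = NA_character_, pool = NA_character_,
      diversity_level = NA_integer_, species_code = NA_character_,
      replicate = NA_character_, role = role, plot_id = NA_character_,
      sample_id = sprintf("%s_%s", bid, tag), lab_id = NA_character_,
      batch_id = bid, injection_index = NA_integer_,
      stringsAsFactors = FALSE)

    seqs <- list(tech("solvent", "solvent1"), tech("solvent", "solvent2"),
                 tech("solvent", "solvent3"), tech("qc_pool", "QC1"),
                 tech("qc_pool", "QC2"), tech("blank", "blank1"))
    qc_n <- 2L
    blocks <- integer(0)
    for (blk in seq_len(n_blocks)) {
      take <- seq.int((blk - 1L) * design$block_size + 1L,
                      min(blk * design$block_size, nrow(brec)))
      chunk <- brec[take, , drop = FALSE]
      chunk$batch_id <- bid
      seqs <- c(seqs, list(chunk))
      qc_n <- qc_n + 1L
      seqs <- c(seqs, list(tech("qc_pool", sprintf("QC%d", qc_n))))
    }
    bat <- do.call(rbind, seqs)
    bat$injection_index <- seq_len(nrow(bat))
    # block index per study sample, in order of appearance
    blkv <- rep(NA_integer_, nrow(bat))
    sidx <- which(bat$role == "study")
    blkv[sidx] <- (seq_along(sidx) - 1L) %/% design$block_size + 1L
    bat$block <- blkv
    out[[b]] <- bat
  }
  seq_df <- do.call(rbind, out)
  rownames(seq_df) <- NULL
  class(seq_df) <- c("injection_sequence", "data.frame")
  seq_df
}

#' @export
print.injection_sequence <- function(x, ...) {
  tab <- table(x$batch_id, x$role)
  cat(sprintf("injection_sequence: %d injections in %d batches\n",
              nrow(x), length(unique(x$batch_id))))
  print(tab)
  invisible(x)
}
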