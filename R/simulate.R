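#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of a two-group early-pregnancy
#' plasma metabolome study: 50 pregnant (8-16 weeks of gestation) and 21
#' non-pregnant women, ~637 metabolites of which 44% are differential with
#' 81% of those less abundant in pregnancy, log-normal total-ion-count
#' abundances with correlated sub-pathway blocks, multiplicative run-day
#' batch effects, storage-time exponential decay on a subset of compounds,
#' technical replicates of one pregnant sample at ~12% CV, gestational-age
#' slopes for a small subset of differential metabolites, and per-metabolite
#' left-censoring below the limit of detection.
#'
#' @param n_pregnant,n_nonpregnant study group sizes (defaults 50 and 21).
#' @param n_metabolites number of metabolites (default 637).
#' @param frac_differential fraction of metabolites with a planted group
#'   effect (default 0.44).
#' @param frac_down probability a differential metabolite is lower in
#'   pregnancy (default 0.81).
#' @param log2fc_range magnitude range of planted log2 fold changes
#'   (default `c(log2(1.5), 5)`).
#' @param n_pathways number of sub-pathways (default 30, grouped under 8
#'   super-pathways).
#' @param block_rho target within-pathway Spearman correlation (default 0.6).
#' @param n_run_days instrument batches for the study samples (default 4).
#' @param batch_sd_log2 SD of per-(metabolite, day) log2 batch shifts
#'   (default 0.3).
#' @param frac_decaying fraction of metabolites subject to storage decay
#'   (default 0.15).
#' @param decay_rate_range decay-rate range, per month on the natural-log
#'   scale (default `c(0.02, 0.08)`).
#' @param storage_max_months storage times drawn uniformly on
#'   `[0, storage_max_months]` (default 36).
#' @param lod_quantile per-metabolite censoring quantile (default 0.1).
#' @param n_reference reference samples for decay fitting (default 20).
#' @param n_replicates technical replicates of one pregnant sample
#'   (default 5; 0 disables).
#' @param replicate_cv multiplicative replicate noise as a CV (default 0.12).
#' @param ga_range_weeks gestational-age range in weeks (default `c(8, 16)`).
#' @param n_ga_trend differential metabolites given a gestational-age slope
#'   (default 14; capped at the number of differential metabolites).
#' @param ga_slope_range magnitude range of GA slopes, log2 units per week
#'   (default `c(0.05, 0.15)`; signs random).
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_pregnant = 50, n_nonpregnant = 21,
                         n_metabolites = 637, frac_differential = 0.44,
                         frac_down = 0.81,
                         log2fc_range = c(log2(1.5), 5),
                         n_pathways = 30, block_rho = 0.6,
                         n_run_days = 4, batch_sd_log2 = 0.3,
                         frac_decaying = 0.15,
                         decay_rate_range = c(0.02, 0.08),
                         storage_max_months = 36,
                         lod_quantile = 0.1, n_reference = 20,
                         n_replicates = 5, replicate_cv = 0.12,
                         ga_range_weeks = c(8, 16), n_ga_trend = 14,
                         ga_slope_range = c(0.05, 0.15), seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_pregnant >= 2, cfg$n_nonpregnant >= 2,
            cfg$n_metabolites >= 1,
            cfg$frac_differential >= 0, cfg$frac_differential <= 1,
            cfg$frac_down >= 0, cfg$frac_down <= 1,
            length(cfg$log2fc_range) == 2, diff(cfg$log2fc_range) >= 0,
            cfg$log2fc_range[1] >= 0,
            cfg$n_pathways >= 1, cfg$block_rho >= 0, cfg$block_rho < 1,
            cfg$n_run_days >= 1, cfg$batch_sd_log2 >= 0,
            cfg$frac_decaying >= 0, cfg$frac_decaying <= 1,
            length(cfg$decay_rate_range) == 2, diff(cfg$decay_rate_range) >= 0,
            cfg$decay_rate_range[1] >= 0, cfg$storage_max_months > 0,
            cfg$lod_quantile >= 0, cfg$lod_quantile < 1,
            cfg$n_reference >= 0, cfg$n_replicates >= 0,
            cfg$replicate_cv >= 0,
            length(cfg$ga_range_weeks) == 2, diff(cfg$ga_range_weeks) > 0,
            cfg$ga_range_weeks[1] > 0, cfg$ga_range_weeks[2] < 45,
            cfg$n_ga_trend >= 0,
            length(cfg$ga_slope_range) == 2, diff(cfg$ga_slope_range) >= 0)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic early-pregnancy metabolome cohort
#'
#' Draws a complete study -- abundance matrix with detection mask, sample
#' metadata, metabolite annotation, reference samples for decay fitting, and
#' the full ground truth of planted effects -- from the generative model
#' described in [synth_config()]. The model, in order: per-metabolite
#' log2-normal baselines; one latent factor per sub-pathway inducing
#' within-block rank correlation; a group effect on a `frac_differential`
#' subset (lower in pregnancy with probability `frac_down`); gestational-age
#' slopes on `n_ga_trend` differential metabolites; per-(metabolite, run
#' day) multiplicative batch shifts; exponential storage decay on a
#' `frac_decaying` subset (study and reference samples); technical
#' replicates of the first pregnant sample; and per-metabolite left-
#' censoring at the `lod_quantile` quantile of the pooled study values.
#' All randomness flows from one seeded generator, so a given seed
#' reproduces the cohort bit-exactly.
#'
#' @param config a [synth_config()].
#' @return A list: `abund` (stage `"raw"`, censored cells `NA`), `metadata`
#'   (tibble; groups `pregnant`, `non_pregnant`, `replicate`), `annotation`
#'   (tibble), `reference` (`abund` of reference samples), `reference_meta`,
#'   and `truth` (tibble `metabolite_id, sub_pathway, is_differential,
#'   log2_fc, ga_slope, decay_rate, lod_threshold` with the per-(metabolite,
#'   day) batch shifts as attribute `"batch_log2"`).
#' @export
simulate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  M <- cfg$n_metabolites
  met_ids <- sprintf("M%04d", seq_len(M))
  preg_ids <- sprintf("P%03d", seq_len(cfg$n_pregnant))
  nonp_ids <- sprintf("N%03d", seq_len(cfg$n_nonpregnant))
  study_ids <- c(preg_ids, nonp_ids)
  n_study <- length(study_ids)

  # (1) baselines
  mu <- stats::runif(M, 10, 20)
  sigma <- stats::runif(M, 0.3, 1.2)

  # (2) pathway blocks via one latent factor per sub-pathway; the loading is
  # chosen so the within-block Spearman correlation is ~ block_rho
  # (Spearman = (6/pi) asin(pearson/2) for bivariate normals).
  pw <- sample(seq_len(cfg$n_pathways), M, replace = TRUE)
  pearson_target <- 2 * sin(pi * cfg$block_rho / 6)
  lambda <- sqrt(pearson_target)
  fac <- matrix(stats::rnorm(cfg$n_pathways * n_study), cfg$n_pathways, n_study)
  eps <- matrix(stats::rnorm(M * n_study), M, n_study)
  y <- mu + sigma * (lambda * fac[pw, , drop = FALSE] +
                       sqrt(1 - lambda^2) * eps)
  dimnames(y) <- list(met_ids, study_ids)

  # (3) group effect on pregnant samples
  n_diff <- round(cfg$frac_differential * M)
  diff_idx <- sample.int(M, n_diff)
  log2_fc <- numeric(M)
  if (n_diff > 0) {
    sign <- ifelse(stats::runif(n_diff) < cfg$frac_down, -1, 1)
    mag <- stats::runif(n_diff, cfg$log2fc_range[1], cfg$log2fc_range[2])
    log2_fc[diff_idx] <- sign * mag
    y[diff_idx, preg_ids] <- y[diff_idx, preg_ids, drop = FALSE] +
      log2_fc[diff_idx]
  }

  # (4) gestational-age trends on a subset of the differential metabolites
  ga <- stats::runif(cfg$n_pregnant, cfg$ga_range_weeks[1], cfg$ga_range_weeks[2])
  n_ga <- min(cfg$n_ga_trend, n_diff)
  ga_slope <- numeric(M)
  if (n_ga > 0) {
    ga_idx <- sample(diff_idx, n_ga)
    slope <- stats::runif(n_ga, cfg$ga_slope_range[1], cfg$ga_slope_range[2]) *
      sample(c(-1, 1), n_ga, replace = TRUE)
    ga_slope[ga_idx] <- slope
    y[ga_idx, preg_ids] <- y[ga_idx, preg_ids, drop = FALSE] +
      outer(slope, ga - cfg$ga_range_weeks[1])
  }

  # (5) run-day batch shifts (study samples; the reference set is profiled
  # as its own batch and needs no shift -- an intercept would not move the
  # decay slope anyway)
  run_day <- paste0("day", sample.int(cfg$n_run_days, n_study, replace = TRUE))
  batch <- matrix(stats::rnorm(M * cfg$n_run_days, 0, cfg$batch_sd_log2),
                  M, cfg$n_run_days,
                  dimnames = list(met_ids, paste0("day", seq_len(cfg$n_run_days))))
  y <- y + batch[, run_day, drop = FALSE]

  vals <- 2^y

  # (6) storage decay, study and reference
  storage <- stats::runif(n_study, 0, cfg$storage_max_months)
  n_decay <- round(cfg$frac_decaying * M)
  decay_rate <- numeric(M)
  if (n_decay > 0) {
    decay_idx <- sample.int(M, n_decay)
    decay_rate[decay_idx] <- stats::runif(n_decay, cfg$decay_rate_range[1],
                                          cfg$decay_rate_range[2])
  }
  vals <- vals * exp(-outer(decay_rate, storage))

  # reference samples: same baselines/blocks, own storage times, no group
  # or GA effect
  if (cfg$n_reference > 0) {
    ref_ids <- sprintf("REF%03d", seq_len(cfg$n_reference))
    ref_storage <- stats::runif(cfg$n_reference, 0, cfg$storage_max_months)
    ref_fac <- matrix(stats::rnorm(cfg$n_pathways * cfg$n_reference),
                      cfg$n_pathways, cfg$n_reference)
    ref_eps <- matrix(stats::rnorm(M * cfg$n_reference), M, cfg$n_reference)
    ref_y <- mu + sigma * (lambda * ref_fac[pw, , drop = FALSE] +
                             sqrt(1 - lambda^2) * ref_eps)
    ref_vals <- 2^ref_y * exp(-outer(decay_rate, ref_storage))
    dimnames(ref_vals) <- list(met_ids, ref_ids)
  } else {
    ref_ids <- character()
    ref_storage <- numeric()
    ref_vals <- matrix(numeric(), M, 0, dimnames = list(met_ids, NULL))
  }

  # (7) technical replicates of the first pregnant sample
  if (cfg$n_replicates > 0) {
    rep_ids <- sprintf("REP%02d", seq_len(cfg$n_replicates))
    sdlog <- sqrt(log(1 + cfg$replicate_cv^2))
    rep_vals <- vals[, preg_ids[1]] *
      exp(matrix(stats::rnorm(M * cfg$n_replicates, -sdlog^2 / 2, sdlog),
                 M, cfg$n_replicates))
    dimnames(rep_vals) <- list(met_ids, rep_ids)
    vals <- cbind(vals, rep_vals)
    run_day <- c(run_day, rep(run_day[1], cfg$n_replicates))
    storage <- c(storage, rep(storage[1], cfg$n_replicates))
  } else {
    rep_ids <- character()
  }

  # (8) left-censoring at the per-metabolite lod_quantile of pooled study
  # values; the same absolute threshold censors replicates and reference
  lod <- apply(vals[, study_ids, drop = FALSE], 1, stats::quantile,
               probs = cfg$lod_quantile, names = FALSE)
  if (cfg$lod_quantile > 0) {
    vals[vals < lod] <- NA_real_
    ref_vals[ref_vals < lod] <- NA_real_
  }

  # (9) demographics mimicking the study's marginals
  eth_p <- ifelse(stats::runif(cfg$n_pregnant) < 0.90, "african_american", "white")
  eth_n <- ifelse(stats::runif(cfg$n_nonpregnant) < 0.52, "african_american", "white")
  age_p <- pmin(pmax(round(stats::rnorm(cfg$n_pregnant, 23, 3.7)), 18), 42)
  age_n <- pmin(pmax(round(stats::rnorm(cfg$n_nonpregnant, 29, 5.9)), 18), 45)
  smoke_p <- stats::runif(cfg$n_pregnant) < 0.20
  smoke_n <- stats::runif(cfg$n_nonpregnant) < 0.04

  metadata <- tibble::tibble(
    sample_id = c(study_ids, rep_ids),
    group = c(rep("pregnant", cfg$n_pregnant),
              rep("non_pregnant", cfg$n_nonpregnant),
              rep("replicate", cfg$n_replicates)),
    gestational_age = c(ga, rep(NA_real_, cfg$n_nonpregnant),
                        rep(NA_real_, cfg$n_replicates)),
    run_day = run_day,
    storage_time_months = storage,
    maternal_age = c(age_p, age_n, rep(age_p[1], cfg$n_replicates)),
    ethnicity = c(eth_p, eth_n, rep(eth_p[1], cfg$n_replicates)),
    smoker = c(smoke_p, smoke_n, rep(smoke_p[1], cfg$n_replicates)),
    replicate_group = c(rep(NA_character_, n_study),
                        rep(if (cfg$n_replicates > 0) "repgrp1" else NA_character_,
                            cfg$n_replicates))
  )

  super <- paste0("super_", ((seq_len(cfg$n_pathways) - 1) %% 8) + 1)
  annotation <- tibble::tibble(
    metabolite_id = met_ids,
    display_name = met_ids,
    platform = sample(c("pos_early", "pos_late", "neg", "polar"), M,
                      replace = TRUE),
    super_pathway = super[pw],
    sub_pathway = sprintf("pathway_%02d", pw)
  )

  truth <- tibble::tibble(
    metabolite_id = met_ids,
    sub_pathway = annotation$sub_pathway,
    is_differential = seq_len(M) %in% diff_idx,
    log2_fc = log2_fc,
    ga_slope = ga_slope,
    decay_rate = decay_rate,
    lod_threshold = lod
  )
  attr(truth, "batch_log2") <- batch

  ref_meta <- tibble::tibble(
    sample_id = ref_ids, group = rep("reference", length(ref_ids)),
    gestational_age = NA_real_, run_day = "ref_day",
    storage_time_months = ref_storage, maternal_age = NA_real_,
    ethnicity = NA_character_, smoker = NA, replicate_group = NA_character_
  )

  list(abund = abund(vals, stage = "raw"),
       metadata = metadata,
       annotation = annotation,
       reference = if (length(ref_ids)) abund(ref_vals, stage = "raw") else NULL,
       reference_meta = ref_meta,
       truth = truth)
}

#' Write a synthetic cohort to CSV fixture files
#'
#' Writes `abundance.csv`, `metadata.csv`, `annotation.csv`,
#' `reference.csv`, `reference_metadata.csv` and `truth.csv` in the
#' package's CSV dialects. Regeneration with the same config is
#' byte-identical.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  paths <- c(abundance = file.path(out_dir, "abundance.csv"),
             metadata = file.path(out_dir, "metadata.csv"),
             annotation = file.path(out_dir, "annotation.csv"),
             reference = file.path(out_dir, "reference.csv"),
             reference_metadata = file.path(out_dir, "reference_metadata.csv"),
             truth = file.path(out_dir, "truth.csv"))
  write_abundance_csv(sim$abund, paths["abundance"])
  meta_out <- dplyr::mutate(sim$metadata,
    gestational_age = format_gestational_age(.data$gestational_age))
  readr::write_csv(meta_out, paths["metadata"], na = "")
  readr::write_csv(sim$annotation, paths["annotation"], na = "")
  if (!is.null(sim$reference)) {
    write_abundance_csv(sim$reference, paths["reference"])
    readr::write_csv(sim$reference_meta, paths["reference_metadata"], na = "")
  }
  readr::write_csv(sim$truth, paths["truth"], na = "")
  invisible(paths)
}
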