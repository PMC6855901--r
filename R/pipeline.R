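#' Run the full metabolome analysis pipeline
#'
#' Orchestrates preprocessing (run-day median scaling, detection filtering,
#' limit-of-detection imputation, optional storage-decay correction,
#' quantile normalization), differential abundance on the unadjusted
#' ("abundance") and quantile-normalized ("adjusted abundance") branches,
#' the direction binomial test, pathway over-representation, the Spearman
#' correlation network and metabolite clustering among pregnant women,
#' gestational-age trends over the adjusted-analysis significant set, the
#' two sensitivity re-analyses, and the intra-assay QC report. The headline
#' dual criterion (FDR < 0.1 and fold change > 1.5) applies to the
#' unadjusted branch; the gestational-age candidate set comes from the
#' adjusted branch.
#'
#' Skip switches support data deposited at a later processing level:
#' `skip_scaling` and `skip_imputation` assert the corresponding step has
#' already been applied upstream, and decay correction is skipped with a
#' warning when no reference samples are supplied.
#'
#' @param abundance an `abund` at stage `"raw"` (or later, with skips).
#' @param metadata sample metadata (data frame; see [read_sample_metadata()]).
#' @param annotation metabolite annotation (see [read_annotation()]).
#' @param reference,reference_meta optional reference-sample matrix and
#'   metadata for storage-decay fitting.
#' @param cfg a [pipeline_config()].
#' @param analysis `"both"` (default), `"raw"`, or `"adjusted"`.
#' @param skip_scaling,skip_imputation,skip_decay stage toggles.
#' @param out_dir if given, all result tables, a human-readable
#'   `report.txt`, and a JSON run manifest are written there.
#' @return A list of class `"gravidmet_run"`; see [glance.gravidmet_run()]
#'   and [tidy.gravidmet_run()] for tabular summaries.
#' @export
run_pipeline <- function(abundance, metadata, annotation,
                         reference = NULL, reference_meta = NULL,
                         cfg = pipeline_config(),
                         analysis = c("both", "raw", "adjusted"),
                         skip_scaling = FALSE, skip_imputation = FALSE,
                         skip_decay = FALSE, out_dir = NULL) {
  analysis <- match.arg(analysis)
  t0 <- Sys.time()
  joined <- join_metadata(abundance, metadata)
  x <- joined$abund
  meta <- joined$metadata
  stages_run <- character()

  if (skip_scaling) {
    x <- set_stage(x, "scaled")
  } else {
    x <- scale_run_days(x, meta)
    stages_run <- c(stages_run, "scale_run_days")
  }
  x <- filter_detection(x, cfg$detection_min_samples)
  stages_run <- c(stages_run, "filter_detection")
  n_detected <- nrow(x$values)

  if (skip_imputation) {
    if (anyNA(x$values)) stop("skip_imputation with censored cells present",
                              call. = FALSE)
    x <- set_stage(x, "imputed")
  } else {
    x <- impute_lod(x, cfg$imputation_fraction)
    stages_run <- c(stages_run, "impute_lod")
  }

  decay_models <- NULL
  if (!skip_decay && !is.null(reference)) {
    decay_models <- fit_decay(reference, reference_meta, cfg$decay_alpha)
    x <- apply_decay(x, meta, decay_models)
    stages_run <- c(stages_run, "fit_decay", "apply_decay")
  } else {
    if (!skip_decay) warning("no reference samples; storage-decay correction skipped")
    x <- set_stage(x, "decay_corrected")
  }
  raw_branch <- x

  adjusted <- quantile_normalize(x)
  stages_run <- c(stages_run, "quantile_normalize")

  diff_raw <- if (analysis %in% c("both", "raw")) {
    run_differential(raw_branch, meta, cfg)
  }
  diff_adj <- if (analysis %in% c("both", "adjusted")) {
    run_differential(adjusted, meta, cfg)
  }
  headline <- if (!is.null(diff_raw)) diff_raw else diff_adj

  binom <- if (sum(headline$significant) > 0) direction_binomial(headline)
  enrich <- fisher_enrichment(headline, annotation, cfg$fdr_threshold)
  enriched <- pathway_table(enrich, cfg$fdr_threshold)

  preg_ids <- meta$sample_id[meta$group == "pregnant"]
  sp <- spearman_matrix(adjusted, preg_ids)
  k <- min(cfg$n_clusters, sum(!is.na(diag(sp$rho))))
  clusters <- cluster_metabolites(sp, k)
  pairs <- significant_pairs(sp, cfg$fdr_threshold)
  degree_summary <- if (nrow(enriched) > 0) {
    pathway_degree_summary(sp, annotation, enriched$pathway, cfg$edge_abs_rho)
  }

  trend_branch <- if (!is.null(diff_adj)) diff_adj else headline
  candidates <- trend_branch$metabolite_id[trend_branch$significant]
  trends <- if (length(candidates) > 0) {
    gestational_trends(adjusted, meta, candidates, cfg$fdr_threshold)
  }

  sens_age <- tryCatch(
    sensitivity_exclude(raw_branch, meta, "oldest_white_nonpregnant_5", cfg),
    error = function(e) NULL)
  sens_smoke <- tryCatch(
    sensitivity_exclude(raw_branch, meta, "smokers", cfg),
    error = function(e) NULL)

  qc <- compute_qc(raw_branch, meta)

  run <- structure(list(
    config = cfg,
    metadata = meta,
    annotation = annotation,
    raw_branch = raw_branch,
    adjusted = adjusted,
    n_detected = n_detected,
    decay_models = decay_models,
    diff_raw = diff_raw,
    diff_adjusted = diff_adj,
    binomial = binom,
    enrichment = enrich,
    enriched_pathways = enriched,
    spearman = sp,
    clusters = clusters,
    significant_pairs = pairs,
    degree_summary = degree_summary,
    trends = trends,
    sensitivity_age = sens_age,
    sensitivity_smokers = sens_smoke,
    qc = qc,
    stages_run = stages_run,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "gravidmet_run")

  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

#' @export
print.gravidmet_run <- function(x, ...) {
  g <- generics::glance(x)
  cat("<gravidmet_run>\n")
  cat(paste0("  ", report_lines(x), "\n"), sep = "")
  invisible(x)
}

report_lines <- function(run) {
  cfg <- run$config
  g <- generics::glance(run)
  lines <- c(
    sprintf("thresholds: detection >= %d samples; imputation %.2f x min; FDR < %g; fold change > %g; |rho| > %g; %d clusters",
            cfg$detection_min_samples, cfg$imputation_fraction,
            cfg$fdr_threshold, cfg$fc_threshold, cfg$edge_abs_rho,
            cfg$n_clusters),
    sprintf("metabolites passing detection filter: %d", g$n_detected),
    sprintf("significant (dual criterion, abundance branch): %d / %d (%.0f%%)",
            g$n_significant, g$n_tested, 100 * g$n_significant / g$n_tested))
  if (!is.na(g$n_significant_adjusted)) {
    lines <- c(lines, sprintf("significant (adjusted branch): %d",
                              g$n_significant_adjusted))
  }
  lines <- c(lines,
    sprintf("at FDR < 0.05 without fold-change cutoff: %d", g$n_fdr05_no_fc))
  if (!is.na(g$k_down)) {
    lines <- c(lines, sprintf("direction: %d / %d down in pregnancy (%.0f%%), binomial p = %.3g",
                              g$k_down, g$n_significant,
                              100 * g$k_down / g$n_significant, g$binomial_p))
  }
  lines <- c(lines,
    sprintf("enriched pathways (FDR < %g): %d", cfg$fdr_threshold,
            g$n_enriched_pathways),
    sprintf("gestational-age trends (FDR < %g): %d / %d", cfg$fdr_threshold,
            g$n_ga_trend, g$n_ga_candidates),
    sprintf("sensitivity fold-change concordance: oldest-white rule %.3f, smoker rule %.3f",
            g$concordance_age, g$concordance_smokers),
    sprintf("median intra-assay CV: %.1f%%", g$median_cv_percent),
    sprintf("power at Cohen's d = 0.75, alpha 0.05: %.3f",
            power_two_sample(sum(run$metadata$group == "pregnant"),
                             sum(run$metadata$group == "non_pregnant"),
                             0.75, 0.05)))
  lines
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  put <- function(obj, name) {
    if (is.null(obj)) return()
    p <- file.path(out_dir, name)
    readr::write_tsv(obj, p, na = "")
    written <<- c(written, p)
  }
  put(run$diff_raw, "differential_abundance.tsv")
  put(run$diff_adjusted, "differential_adjusted.tsv")
  put(run$enrichment, "pathway_enrichment.tsv")
  put(run$clusters, "metabolite_clusters.tsv")
  put(run$significant_pairs, "significant_correlations.tsv")
  put(run$degree_summary, "pathway_degree_summary.tsv")
  put(run$trends, "gestational_trends.tsv")
  put(run$decay_models, "decay_models.tsv")
  put(run$qc$cv, "intra_assay_cv.tsv")
  rpt <- file.path(out_dir, "report.txt")
  writeLines(report_lines(run), rpt)
  written <- c(written, rpt)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gravidmet")),
    config = unclass(run$config),
    stages_run = run$stages_run,
    outputs = basename(written),
    elapsed_s = run$elapsed_s,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mf <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  missing <- written[!file.exists(written)]
  if (length(missing)) stop("manifest incomplete; missing: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  invisible(c(written, mf))
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a pipeline run
#'
#' @param x a `gravidmet_run`.
#' @param ... unused.
#' @return A one-row tibble with the headline counts: metabolites tested,
#'   significant under the dual criterion (and in the adjusted branch),
#'   the FDR-0.05-only count, the down/up split with its binomial p,
#'   enriched pathways, gestational-age trend hits, sensitivity
#'   concordances, and the median replicate CV.
#' @method glance gravidmet_run
#' @export
glance.gravidmet_run <- function(x, ...) {
  headline <- if (!is.null(x$diff_raw)) x$diff_raw else x$diff_adjusted
  s <- attr(headline, "summary")
  tibble::tibble(
    n_detected = x$n_detected,
    n_tested = s$n_tested,
    n_significant = s$n_significant,
    n_down = s$n_down,
    n_up = s$n_up,
    n_significant_adjusted = if (!is.null(x$diff_adjusted))
      attr(x$diff_adjusted, "summary")$n_significant else NA_integer_,
    n_fdr05_no_fc = sum(headline$q_value < 0.05),
    k_down = if (!is.null(x$binomial)) x$binomial$k_down else NA_integer_,
    binomial_p = if (!is.null(x$binomial)) x$binomial$p_value else NA_real_,
    n_enriched_pathways = nrow(x$enriched_pathways),
    n_ga_candidates = if (!is.null(x$trends)) nrow(x$trends) else 0L,
    n_ga_trend = if (!is.null(x$trends))
      sum(x$trends$trending, na.rm = TRUE) else 0L,
    concordance_age = if (!is.null(x$sensitivity_age))
      x$sensitivity_age$fold_change_concordance else NA_real_,
    concordance_smokers = if (!is.null(x$sensitivity_smokers))
      x$sensitivity_smokers$fold_change_concordance else NA_real_,
    median_cv_percent = x$qc$median_cv_percent
  )
}

#' Per-metabolite results of a pipeline run
#'
#' Joins the unadjusted-branch differential results with annotation and,
#' when present, the adjusted-branch q-values, cluster labels and
#' gestational-age trends -- the analogue of a per-metabolite supplementary
#' results table.
#'
#' @param x a `gravidmet_run`.
#' @param ... unused.
#' @return A tibble with one row per tested metabolite.
#' @method tidy gravidmet_run
#' @export
tidy.gravidmet_run <- function(x, ...) {
  headline <- if (!is.null(x$diff_raw)) x$diff_raw else x$diff_adjusted
  out <- dplyr::left_join(headline,
    x$annotation[, c("metabolite_id", "display_name", "platform",
                     "sub_pathway")], by = "metabolite_id")
  if (!is.null(x$diff_raw) && !is.null(x$diff_adjusted)) {
    adj <- x$diff_adjusted[, c("metabolite_id", "q_value", "fold_change",
                               "significant")]
    names(adj)[-1] <- paste0(names(adj)[-1], "_adjusted")
    out <- dplyr::left_join(out, adj, by = "metabolite_id")
  }
  out <- dplyr::left_join(out, x$clusters, by = "metabolite_id")
  if (!is.null(x$trends)) {
    out <- dplyr::left_join(out,
      x$trends[, c("metabolite_id", "rho_ga", "q_value")] |>
        dplyr::rename(q_value_ga = "q_value"), by = "metabolite_id")
  }
  out
}
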