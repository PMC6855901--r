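#' Pipeline configuration
#'
#' Holds the analysis thresholds used throughout: the detection filter
#' (metabolites kept when detected in at least `detection_min_samples`
#' samples), the limit-of-detection imputation fraction (imputed value =
#' `imputation_fraction` x per-metabolite minimum detected), the unadjusted
#' screening alpha for storage-time decay, the dual significance criterion
#' (Benjamini-Hochberg FDR < `fdr_threshold` AND fold change magnitude
#' > `fc_threshold`), the correlation-network edge threshold on |Spearman
#' rho|, and the number of hierarchical clusters.
#'
#' @param detection_min_samples minimum samples a metabolite must be
#'   detected in (default 10, half the smaller group of the 50 + 21 design).
#' @param imputation_fraction fraction of the minimum detected value used
#'   for censored cells (default 0.99).
#' @param decay_alpha unadjusted Spearman p-value threshold for applying a
#'   storage-decay correction (default 0.05).
#' @param fdr_threshold Benjamini-Hochberg FDR cut-off (default 0.1).
#' @param fc_threshold fold-change magnitude cut-off (default 1.5, applied
#'   as `max(FC, 1/FC) > fc_threshold`).
#' @param edge_abs_rho absolute Spearman coefficient above which two
#'   metabolites are connected in the correlation network (default 0.5).
#' @param n_clusters number of clusters the metabolite dendrogram is cut
#'   into (default 25).
#' @param rng_seed seed for any stochastic step (default 1).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(detection_min_samples = 10,
                            imputation_fraction = 0.99,
                            decay_alpha = 0.05,
                            fdr_threshold = 0.1,
                            fc_threshold = 1.5,
                            edge_abs_rho = 0.5,
                            n_clusters = 25,
                            rng_seed = 1L) {
  cfg <- list(detection_min_samples = as.integer(detection_min_samples),
              imputation_fraction = imputation_fraction,
              decay_alpha = decay_alpha,
              fdr_threshold = fdr_threshold,
              fc_threshold = fc_threshold,
              edge_abs_rho = edge_abs_rho,
              n_clusters = as.integer(n_clusters),
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$detection_min_samples >= 1,
            cfg$imputation_fraction > 0, cfg$imputation_fraction <= 1,
            cfg$decay_alpha > 0, cfg$decay_alpha < 1,
            cfg$fdr_threshold > 0, cfg$fdr_threshold < 1,
            cfg$fc_threshold > 1,
            cfg$edge_abs_rho > 0, cfg$edge_abs_rho < 1,
            cfg$n_clusters >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(unclass(x))) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read a flat `key: value` configuration file
#'
#' Unknown keys error; values are coerced to the type of the corresponding
#' [pipeline_config()] default. Lines starting with `#` and blank lines are
#' ignored.
#'
#' @param path text file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  if (any(lengths(kv) < 2)) stop("config line without ':': ",
                                 lines[lengths(kv) < 2][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = ":"), ""))
  known <- names(formals(pipeline_config))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  args <- stats::setNames(lapply(vals, function(v) as.numeric(v)), keys)
  do.call(pipeline_config, args)
}
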