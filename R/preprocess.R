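#' Equalize per-metabolite medians across run days
#'
#' Instrument batches ("run days") introduce multiplicative shifts in total
#' ion counts. For each metabolite, values measured on a run day are
#' rescaled so that the median of its detected values is equal across all
#' days. The common target is the grand median of the metabolite's pooled
#' detected values, which preserves the overall scale; factors are computed
#' on detected values only and undetected cells stay censored. A run day
#' with no detected values for a metabolite gets factor 1 (logged). The
#' operation is idempotent.
#'
#' @param x an `abund` at stage `"raw"`.
#' @param meta metadata with a `run_day` for every sample of `x`.
#' @return An `abund` at stage `"scaled"`.
#' @export
scale_run_days <- function(x, meta) {
  require_stage(x, c("raw", "scaled"), "scale_run_days")
  meta <- align_meta(x, meta)
  if (any(is.na(meta$run_day))) {
    stop("scale_run_days: sample(s) without run_day: ",
         paste(meta$sample_id[is.na(meta$run_day)], collapse = ", "),
         call. = FALSE)
  }
  days <- unique(meta$run_day)
  vals <- x$values
  if (length(days) > 1) {
    grand <- apply(vals, 1, stats::median, na.rm = TRUE)
    for (d in days) {
      cols <- meta$sample_id[meta$run_day == d]
      day_med <- apply(vals[, cols, drop = FALSE], 1, stats::median,
                       na.rm = TRUE)
      factor <- grand / day_med
      factor[!is.finite(factor)] <- 1   # no detected value (or median 0) that day
      vals[, cols] <- vals[, cols, drop = FALSE] * factor
    }
  }
  x$values <- vals
  set_stage(x, "scaled")
}

#' Drop metabolites detected in too few samples
#'
#' @param x an `abund` object (any stage before imputation).
#' @param min_samples detection threshold; metabolites detected in at least
#'   this many samples are retained, in their original order.
#' @return The filtered `abund` (stage unchanged).
#' @export
filter_detection <- function(x, min_samples = 10) {
  stopifnot(is_abund(x), min_samples >= 1)
  keep <- rowSums(x$detected) >= min_samples
  x$values <- x$values[keep, , drop = FALSE]
  x$detected <- x$detected[keep, , drop = FALSE]
  x
}

#' Impute censored cells to a fraction of the minimum detected value
#'
#' Non-detections are interpreted as abundance below the limit of detection
#' and set to `fraction` (default 0.99) of the metabolite's minimum detected
#' value. Imputation runs after run-day scaling so the minimum is taken on
#' the common scale. The detection mask is preserved unchanged: an imputed
#' cell remains flagged as undetected.
#'
#' @param x an `abund` at stage `"scaled"`.
#' @param fraction multiplier of the per-metabolite minimum detected value.
#' @return An `abund` at stage `"imputed"` with every cell finite and > 0.
#' @export
impute_lod <- function(x, fraction = 0.99) {
  require_stage(x, "scaled", "impute_lod")
  stopifnot(fraction > 0, fraction <= 1)
  n_det <- rowSums(x$detected)
  if (any(n_det == 0)) {
    stop("impute_lod: metabolite(s) with no detected value (filter first): ",
         paste(rownames(x$values)[n_det == 0], collapse = ", "),
         call. = FALSE)
  }
  mins <- apply(x$values, 1, min, na.rm = TRUE)
  miss <- which(!x$detected, arr.ind = TRUE)
  if (nrow(miss) > 0) {
    x$values[miss] <- fraction * mins[miss[, 1]]
  }
  set_stage(x, "imputed")
}

#' Fit storage-time decay models on reference samples
#'
#' Long-term frozen storage degrades some compounds. For each metabolite,
#' the association between storage time (months) and abundance in a
#' reference sample set is screened with a two-sided Spearman correlation
#' test; metabolites with p < `alpha` (unadjusted, as a per-metabolite
#' screen) get a log-linear decay model, i.e. an ordinary least-squares fit
#' of natural-log abundance on storage time, consistent with exponential
#' decay. Only detected values enter the fit -- imputed constants would bias
#' the slope.
#'
#' @param reference an `abund` of reference samples (any stage; detected
#'   values are used as-is).
#' @param reference_meta metadata carrying `storage_time_months` for every
#'   reference sample.
#' @param alpha screening p-value threshold (default 0.05).
#' @return A tibble with one row per metabolite: `metabolite_id`,
#'   `spearman_rho`, `spearman_p`, `slope` (per month, natural-log scale)
#'   and `applied`.
#' @export
fit_decay <- function(reference, reference_meta, alpha = 0.05) {
  stopifnot(is_abund(reference))
  meta <- align_meta(reference, reference_meta)
  t <- meta$storage_time_months
  if (any(is.na(t))) stop("fit_decay: reference sample(s) without storage time",
                          call. = FALSE)
  if (length(unique(t)) < 3) {
    stop("fit_decay: need >= 3 distinct storage times", call. = FALSE)
  }
  rows <- purrr::map(rownames(reference$values), function(m) {
    det <- reference$detected[m, ]
    y <- reference$values[m, det]
    tt <- t[det]
    if (sum(det) < 3 || length(unique(y)) < 2 || length(unique(tt)) < 2) {
      return(tibble::tibble(metabolite_id = m, spearman_rho = NA_real_,
                            spearman_p = NA_real_, slope = NA_real_,
                            applied = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(tt, y, method = "spearman",
                                           exact = FALSE))
    fit <- stats::lm.fit(cbind(1, tt), log(y))
    slope <- unname(fit$coefficients[2])
    applied <- is.finite(slope) && ct$p.value < alpha
    tibble::tibble(metabolite_id = m, spearman_rho = unname(ct$estimate),
                   spearman_p = ct$p.value, slope = slope, applied = applied)
  })
  dplyr::bind_rows(rows)
}

#' Back-correct study samples for storage-time decay
#'
#' For each metabolite with an applied decay model, every study value is
#' multiplied by `exp(-slope * storage_time)`, i.e. projected back to
#' storage time zero. Metabolites without an applied model are untouched.
#'
#' @param x an `abund` at stage `"imputed"`.
#' @param meta study metadata with `storage_time_months`.
#' @param models tibble from [fit_decay()].
#' @return An `abund` at stage `"decay_corrected"`.
#' @export
apply_decay <- function(x, meta, models) {
  require_stage(x, "imputed", "apply_decay")
  meta <- align_meta(x, meta)
  models <- dplyr::filter(models, .data$applied,
                          .data$metabolite_id %in% rownames(x$values))
  if (nrow(models) > 0) {
    t <- meta$storage_time_months
    if (any(is.na(t))) {
      stop("apply_decay: sample(s) without storage time while decay models apply: ",
           paste(meta$sample_id[is.na(t)], collapse = ", "), call. = FALSE)
    }
    corr <- exp(outer(-models$slope, t))   # metabolites x samples
    x$values[models$metabolite_id, ] <-
      x$values[models$metabolite_id, , drop = FALSE] * corr
  }
  set_stage(x, "decay_corrected")
}

#' Quantile normalization across samples
#'
#' Transforms each sample so that all samples share an identical abundance
#' distribution, cancelling systematic sample-to-sample dilution (e.g.
#' pregnancy hemodilution). The reference distribution is the per-rank mean
#' of the samples' sorted value vectors; each value is replaced by the
#' reference value at its within-sample rank, and tied values receive the
#' mean of the reference values over their tied ranks (the convention of the
#' microarray-era procedure). Requires a fully imputed matrix.
#'
#' @param x an `abund` at stage `"imputed"` or `"decay_corrected"`.
#' @return An `abund` at stage `"adjusted"`. With no within-sample ties the
#'   sorted value vector of every sample equals the reference exactly.
#' @export
quantile_normalize <- function(x) {
  require_stage(x, c("imputed", "decay_corrected"), "quantile_normalize")
  if (anyNA(x$values)) {
    stop("quantile_normalize: matrix has missing cells; run impute_lod() first",
         call. = FALSE)
  }
  x$values <- quantile_normalize_matrix(x$values)
  set_stage(x, "adjusted")
}

# Core rank-mean algorithm on a plain matrix (metabolites x samples; each
# column is one sample's distribution).
quantile_normalize_matrix <- function(values) {
  n <- nrow(values)
  ref <- rowMeans(apply(values, 2, sort))
  cref <- cumsum(ref)
  out <- values
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    rmin <- rank(v, ties.method = "min")
    rmax <- rank(v, ties.method = "max")
    # mean of ref over the tied rank span [rmin, rmax]
    lo <- c(0, cref)[rmin]
    out[, j] <- (cref[rmax] - lo) / (rmax - rmin + 1)
  }
  out
}

#' Intra-assay reproducibility report from technical replicates
#'
#' For each replicate group (samples sharing `replicate_group`), a
#' per-metabolite coefficient of variation, CV(%) = 100 x sd/mean over the
#' replicate values, computed with the sample (n-1) standard deviation and
#' restricted to metabolites detected (not imputed) in at least
#' `ceiling(0.8 * r)` of the r replicates (4/5 for the canonical 5-replicate
#' design). Detected values only enter the CV.
#'
#' @param x an `abund` object containing the replicate samples.
#' @param meta metadata with `replicate_group` set for technical replicates.
#' @return A list of class `"qc_report"`: `cv` (tibble `metabolite_id,
#'   replicate_group, n_detected_replicates, cv_percent`), `median_cv_percent`,
#'   and `median_instrument_rsd` / `median_process_rsd` (NA unless spike-in /
#'   pooled-matrix samples are supplied, which this pipeline does not model).
#' @export
compute_qc <- function(x, meta) {
  stopifnot(is_abund(x))
  meta <- align_meta(x, meta)
  groups <- unique(meta$replicate_group[!is.na(meta$replicate_group)])
  groups <- groups[vapply(groups, function(g)
    sum(meta$replicate_group == g, na.rm = TRUE) >= 2, TRUE)]
  if (length(groups) == 0) {
    message("compute_qc: no replicate groups with >= 2 samples; empty report")
    cv <- tibble::tibble(metabolite_id = character(),
                         replicate_group = character(),
                         n_detected_replicates = integer(),
                         cv_percent = numeric())
  } else {
    cv <- purrr::map_dfr(groups, function(g) {
      cols <- meta$sample_id[!is.na(meta$replicate_group) &
                               meta$replicate_group == g]
      r <- length(cols)
      need <- ceiling(0.8 * r)
      det <- x$detected[, cols, drop = FALSE]
      vals <- x$values[, cols, drop = FALSE]
      n_det <- rowSums(det)
      keep <- which(n_det >= need)
      purrr::map_dfr(keep, function(i) {
        v <- vals[i, det[i, ]]
        tibble::tibble(metabolite_id = rownames(vals)[i], replicate_group = g,
                       n_detected_replicates = as.integer(n_det[i]),
                       cv_percent = 100 * stats::sd(v) / mean(v))
      })
    })
  }
  structure(list(cv = cv,
                 median_cv_percent = stats::median(cv$cv_percent),
                 median_instrument_rsd = NA_real_,
                 median_process_rsd = NA_real_),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d metabolite x replicate-group CVs, median CV %.1f%%\n",
              nrow(x$cv), x$median_cv_percent))
  invisible(x)
}

#' Log2-transform an abundance matrix
#'
#' @param x an `abund` with all values present and > 0.
#' @return A plain numeric matrix of log2 abundances.
#' @export
log2_transform <- function(x) {
  stopifnot(is_abund(x))
  if (anyNA(x$values) || any(x$values <= 0)) {
    stop("log2_transform: all values must be present and > 0", call. = FALSE)
  }
  log2(x$values)
}

# Reorder a metadata table to the matrix's columns (which are themselves in
# metadata order after join_metadata); errors on samples without metadata.
align_meta <- function(x, meta) {
  meta <- validate_metadata(normalize_metadata(meta))
  orphans <- setdiff(colnames(x$values), meta$sample_id)
  if (length(orphans)) {
    stop("samples missing from metadata: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  meta[match(colnames(x$values), meta$sample_id), , drop = FALSE]
}
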