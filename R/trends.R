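#' Gestational-age trends among pregnancy-associated metabolites
#'
#' Among pregnant samples only, tests each candidate metabolite's adjusted
#' abundance against gestational age with a two-sided Spearman correlation,
#' controls the FDR across candidates by Benjamini-Hochberg, and fits an
#' ordinary least-squares line of log2 abundance on gestational age for
#' plotting (presentation only; inference is rank-based). The canonical
#' candidate set is the metabolites significant in the adjusted-abundance
#' differential analysis.
#'
#' @param x an `abund` (adjusted stage in the canonical pipeline).
#' @param meta sample metadata; pregnant samples must carry
#'   `gestational_age` in decimal weeks.
#' @param candidate_set metabolite ids to test; all must be rows of `x`.
#' @param fdr FDR threshold for the `trending` flag (default 0.1).
#' @return A tibble `metabolite_id, rho_ga, p_value, q_value,
#'   regression_slope, trending`. Constant metabolites get `NA` rho and are
#'   excluded from FDR control and flagged `trending = NA`.
#' @export
gestational_trends <- function(x, meta, candidate_set, fdr = 0.1) {
  stopifnot(is_abund(x))
  meta <- align_meta(x, meta)
  missing <- setdiff(candidate_set, rownames(x$values))
  if (length(missing)) {
    stop("gestational_trends: candidate(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  preg <- meta$group == "pregnant" & !is.na(meta$gestational_age)
  if (sum(preg) < 3) stop("gestational_trends: need >= 3 pregnant samples with GA",
                          call. = FALSE)
  ga <- meta$gestational_age[preg]
  vals <- x$values[candidate_set, meta$sample_id[preg], drop = FALSE]
  rows <- purrr::map_dfr(candidate_set, function(m) {
    y <- vals[m, ]
    if (length(unique(y)) == 1) {
      message("gestational_trends: constant metabolite excluded: ", m)
      return(tibble::tibble(metabolite_id = m, rho_ga = NA_real_,
                            p_value = NA_real_, regression_slope = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(ga, y, method = "spearman",
                                           exact = FALSE))
    slope <- unname(stats::lm.fit(cbind(1, ga), log2(y))$coefficients[2])
    tibble::tibble(metabolite_id = m, rho_ga = unname(ct$estimate),
                   p_value = ct$p.value, regression_slope = slope)
  })
  ok <- !is.na(rows$p_value)
  rows$q_value <- NA_real_
  rows$q_value[ok] <- benjamini_hochberg(rows$p_value[ok])
  rows$trending <- rows$q_value < fdr
  rows[, c("metabolite_id", "rho_ga", "p_value", "q_value",
           "regression_slope", "trending")]
}

#' PCA scores of samples for visualization
#'
#' Principal component analysis of log2-transformed abundances: metabolites
#' are centered and scaled to unit variance (zero-variance metabolites are
#' dropped with a warning), and sample scores on the first two components
#' are returned with the percentage of variance each component explains.
#' Component signs follow a deterministic convention: the largest-magnitude
#' loading of each component is made positive.
#'
#' @param x an `abund` with all values present and > 0.
#' @param meta sample metadata (carried into the output for plotting).
#' @return A tibble `sample_id, group, PC1, PC2` with attribute
#'   `"var_explained"` (percentages for all components, summing to 100).
#' @export
pca_plot_data <- function(x, meta) {
  stopifnot(is_abund(x))
  meta <- align_meta(x, meta)
  lv <- log2_transform(x)
  vars <- apply(lv, 1, stats::var)
  if (any(vars == 0)) {
    warning("pca_plot_data: dropping zero-variance metabolite(s): ",
            paste(rownames(lv)[vars == 0], collapse = ", "))
    lv <- lv[vars > 0, , drop = FALSE]
  }
  if (ncol(lv) < 3) stop("pca_plot_data: need >= 3 samples", call. = FALSE)
  pc <- stats::prcomp(t(lv), center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  out <- tibble::tibble(sample_id = meta$sample_id, group = meta$group,
                        PC1 = unname(scores[, 1]),
                        PC2 = if (ncol(scores) >= 2) unname(scores[, 2]) else 0)
  attr(out, "var_explained") <- ve
  out
}

#' Sensitivity re-analysis under sample-exclusion rules
#'
#' Re-runs the differential analysis after excluding either the five oldest
#' white non-pregnant participants (`"oldest_white_nonpregnant_5"`; age ties
#' broken deterministically by metadata order) or all self-reported smokers
#' (`"smokers"`), and summarizes how stable the results are: the Spearman
#' correlation between the full and reduced fold-change vectors over all
#' metabolites, and the metabolites whose significance flag flips.
#'
#' @param x the `abund` the primary analysis ran on.
#' @param meta sample metadata.
#' @param rule `"oldest_white_nonpregnant_5"` or `"smokers"`, or `"none"`
#'   (empty exclusion; concordance is exactly 1).
#' @param cfg a [pipeline_config()].
#' @return A list of class `"sensitivity_report"`: `excluded_samples`,
#'   `fold_change_concordance`, `gained_significance`, `lost_significance`,
#'   `full`, `reduced` (the two result tibbles).
#' @export
sensitivity_exclude <- function(x, meta, rule = c("oldest_white_nonpregnant_5",
                                                  "smokers", "none"),
                                cfg = pipeline_config()) {
  rule <- match.arg(rule)
  meta <- align_meta(x, meta)
  excluded <- switch(rule,
    none = character(),
    smokers = meta$sample_id[!is.na(meta$smoker) & meta$smoker &
                               meta$group %in% c("pregnant", "non_pregnant")],
    oldest_white_nonpregnant_5 = {
      cand <- meta[meta$group == "non_pregnant" &
                     !is.na(meta$ethnicity) & meta$ethnicity == "white" &
                     !is.na(meta$maternal_age), , drop = FALSE]
      # stable sort: ties in age keep metadata order
      cand <- cand[order(-cand$maternal_age), , drop = FALSE]
      utils::head(cand$sample_id, 5)
    })
  keep_meta <- meta[!meta$sample_id %in% excluded, , drop = FALSE]
  if (!any(keep_meta$group == "pregnant") ||
      !any(keep_meta$group == "non_pregnant")) {
    stop("sensitivity_exclude: rule removes an entire group", call. = FALSE)
  }
  full <- run_differential(x, meta, cfg)
  reduced <- run_differential(
    abund_subset_samples(x, keep_meta$sample_id), keep_meta, cfg)
  concordance <- if (length(excluded) == 0) 1 else
    stats::cor(full$fold_change, reduced$fold_change, method = "spearman")
  structure(list(
    rule = rule,
    excluded_samples = excluded,
    fold_change_concordance = concordance,
    gained_significance = reduced$metabolite_id[reduced$significant &
                                                  !full$significant],
    lost_significance = full$metabolite_id[full$significant &
                                             !reduced$significant],
    full = full, reduced = reduced
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> rule '%s': %d excluded, fold-change concordance %.3f\n",
              x$rule, length(x$excluded_samples), x$fold_change_concordance))
  cat(sprintf("  significance flips: +%d / -%d\n",
              length(x$gained_significance), length(x$lost_significance)))
  invisible(x)
}
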