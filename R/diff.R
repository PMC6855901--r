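#' Mann-Whitney U test between two groups
#'
#' Two-sided Mann-Whitney-Wilcoxon U test. The exact null distribution is
#' enumerated only for small tie-free groups (both groups of size <= 8 with
#' no tied values); otherwise -- in particular for the study design of 50 vs
#' 21 samples with imputation ties -- the tie-corrected normal approximation
#' with a 0.5 continuity correction is used, so results are deterministic
#' and reproducible.
#'
#' @param a,b numeric vectors (non-empty).
#' @return A list with `u_statistic` (U of `a`, i.e. the number of pairs
#'   where `a` exceeds `b`, counting ties 1/2) and `p_value`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("mann_whitney: both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && min(length(a), length(b)) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  list(u_statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values: monotone step-up adjusted values clipped to <= 1.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("benjamini_hochberg: p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-metabolite fold changes between pregnant and non-pregnant samples
#'
#' Fold change = median abundance over pregnant samples divided by median
#' over non-pregnant samples, reported as-is: values below 1 indicate lower
#' abundance in pregnancy. Requires a fully imputed matrix (all values > 0),
#' so the denominator cannot vanish.
#'
#' @param x an imputed/adjusted `abund`.
#' @param meta metadata assigning each sample a `group`.
#' @return A tibble `metabolite_id, fold_change`.
#' @export
fold_changes <- function(x, meta) {
  stopifnot(is_abund(x))
  meta <- align_meta(x, meta)
  if (anyNA(x$values)) stop("fold_changes: impute first", call. = FALSE)
  preg <- meta$sample_id[meta$group == "pregnant"]
  nonp <- meta$sample_id[meta$group == "non_pregnant"]
  med_p <- apply(x$values[, preg, drop = FALSE], 1, stats::median)
  med_n <- apply(x$values[, nonp, drop = FALSE], 1, stats::median)
  if (any(med_n == 0)) stop("fold_changes: zero non-pregnant median", call. = FALSE)
  tibble::tibble(metabolite_id = rownames(x$values),
                 fold_change = unname(med_p / med_n))
}

#' Differential abundance under the dual FDR / fold-change criterion
#'
#' Runs a two-sided Mann-Whitney U test per metabolite between pregnant and
#' non-pregnant samples, adjusts p-values by Benjamini-Hochberg, computes
#' the pregnant/non-pregnant median fold change on the same matrix, and
#' flags metabolites significant when BOTH the FDR is below
#' `cfg$fdr_threshold` and the fold-change magnitude `max(FC, 1/FC)` exceeds
#' `cfg$fc_threshold`. The criterion is symmetric in direction: >30-fold
#' increases and <0.01 decreases are treated alike.
#'
#' @param x an `abund` at stage `"imputed"`, `"decay_corrected"` or
#'   `"adjusted"` (the caller chooses the "abundance" vs "adjusted
#'   abundance" branch).
#' @param meta sample metadata; only groups `pregnant` / `non_pregnant`
#'   enter the test (reference and replicate samples are ignored).
#' @param cfg a [pipeline_config()].
#' @return A tibble with one row per metabolite: `metabolite_id`,
#'   `u_statistic`, `p_value`, `q_value`, `fold_change`, `direction`
#'   (`up_in_pregnancy` / `down_in_pregnancy` / `unchanged`), `significant`.
#'   Summary counts are attached as attribute `"summary"`.
#' @export
run_differential <- function(x, meta, cfg = pipeline_config()) {
  require_stage(x, c("imputed", "decay_corrected", "adjusted"),
                "run_differential")
  meta <- align_meta(x, meta)
  keep <- meta$group %in% c("pregnant", "non_pregnant")
  meta <- meta[keep, , drop = FALSE]
  preg <- meta$sample_id[meta$group == "pregnant"]
  nonp <- meta$sample_id[meta$group == "non_pregnant"]
  if (length(preg) < 2 || length(nonp) < 2) {
    stop("run_differential: need >= 2 samples per group", call. = FALSE)
  }
  vp <- x$values[, preg, drop = FALSE]
  vn <- x$values[, nonp, drop = FALSE]
  tests <- purrr::map(seq_len(nrow(vp)),
                      function(i) mann_whitney(vp[i, ], vn[i, ]))
  res <- tibble::tibble(
    metabolite_id = rownames(x$values),
    u_statistic = purrr::map_dbl(tests, "u_statistic"),
    p_value = purrr::map_dbl(tests, "p_value")
  )
  res$q_value <- benjamini_hochberg(res$p_value)
  sub <- abund_subset_samples(x, c(preg, nonp))
  res <- dplyr::left_join(res, fold_changes(sub, meta), by = "metabolite_id")
  res <- dplyr::mutate(res,
    direction = dplyr::case_when(
      .data$fold_change < 1 ~ "down_in_pregnancy",
      .data$fold_change > 1 ~ "up_in_pregnancy",
      TRUE ~ "unchanged"),
    significant = .data$q_value < cfg$fdr_threshold &
      pmax(.data$fold_change, 1 / .data$fold_change) > cfg$fc_threshold
  )
  attr(res, "summary") <- diff_summary(res)
  res
}

diff_summary <- function(res) {
  sig <- res[res$significant, , drop = FALSE]
  list(n_tested = nrow(res),
       n_significant = nrow(sig),
       n_up = sum(sig$direction == "up_in_pregnancy"),
       n_down = sum(sig$direction == "down_in_pregnancy"))
}

abund_subset_samples <- function(x, sample_ids) {
  x$values <- x$values[, sample_ids, drop = FALSE]
  x$detected <- x$detected[, sample_ids, drop = FALSE]
  x
}

#' Binomial test on the direction split of significant metabolites
#'
#' Tests whether the proportion of significant metabolites that decreased in
#' pregnancy is compatible with a fair split, by a two-sided exact binomial
#' test at null proportion 0.5. Exact tail summation handles the extreme
#' p-values (~1e-27) such splits produce.
#'
#' @param results tibble from [run_differential()].
#' @return A list `k_down`, `n_significant`, `p_value`.
#' @export
direction_binomial <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  n <- nrow(sig)
  if (n < 1) stop("direction_binomial: no significant metabolites", call. = FALSE)
  k <- sum(sig$direction == "down_in_pregnancy")
  list(k_down = k, n_significant = n,
       p_value = stats::binom.test(k, n, p = 0.5,
                                   alternative = "two.sided")$p.value)
}

#' Normal-approximation power of a two-sample comparison
#'
#' Power of a two-sided two-sample test at standardized effect size
#' (Cohen's d) `d`: `Phi(d/se - z) + Phi(-d/se - z)` with
#' `se = sqrt(1/n1 + 1/n2)` and `z` the upper `alpha/2` normal quantile
#' (the minor-tail term is included, so `d = 0` gives exactly `alpha`).
#'
#' @param n1,n2 group sizes (>= 2).
#' @param d Cohen's d (>= 0): group mean difference over the common SD.
#' @param alpha two-sided significance level.
#' @return Power in \[0, 1\].
#' @examples
#' power_two_sample(50, 21, 0.75, 0.05)  # the 50 + 21 design: > 0.80
#' @export
power_two_sample <- function(n1, n2, d, alpha = 0.05) {
  if (n1 < 2 || n2 < 2 || d < 0 || alpha <= 0 || alpha >= 1) {
    stop("power_two_sample: invalid arguments", call. = FALSE)
  }
  se <- sqrt(1 / n1 + 1 / n2)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(d / se - z) + stats::pnorm(-d / se - z)
}
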