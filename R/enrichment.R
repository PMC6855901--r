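#' Pathway over-representation by Fisher's exact test
#'
#' For each sub-pathway with at least one detected (tested) metabolite, a
#' 2x2 table {in-pathway, out-of-pathway} x {significant, not significant}
#' is tested with a two-sided Fisher exact test; q-values are
#' Benjamini-Hochberg across pathways. The background universe is the set
#' of metabolites that entered differential testing (i.e. passed the
#' detection filter), not all annotated metabolites. Metabolites with
#' sub-pathway `"unannotated"` form their own stratum and are excluded from
#' pathway rows (but stay in the background totals).
#'
#' @param results tibble from [run_differential()].
#' @param annotation annotation tibble (see [read_annotation()]).
#' @param fdr FDR threshold carried into [pathway_table()] defaults.
#' @return A tibble, one row per sub-pathway: `pathway`, `n_significant`,
#'   `n_detected`, `background_significant`, `background_detected`,
#'   `p_value`, `q_value`, `example_metabolite` (the most significant
#'   metabolite of the pathway).
#' @export
fisher_enrichment <- function(results, annotation, fdr = 0.1) {
  if (nrow(results) == 0) {
    return(tibble::tibble(pathway = character(), n_significant = integer(),
                          n_detected = integer(),
                          background_significant = integer(),
                          background_detected = integer(),
                          p_value = numeric(), q_value = numeric(),
                          example_metabolite = character()))
  }
  ann <- annotation[, c("metabolite_id", "sub_pathway")]
  tab <- dplyr::left_join(results, ann, by = "metabolite_id")
  tab$sub_pathway[is.na(tab$sub_pathway)] <- "unannotated"
  n_bg <- nrow(tab)
  k_bg <- sum(tab$significant)
  pathways <- setdiff(unique(tab$sub_pathway), "unannotated")
  rows <- purrr::map_dfr(pathways, function(pw) {
    inpw <- tab$sub_pathway == pw
    n_in <- sum(inpw)
    k_in <- sum(tab$significant[inpw])
    m <- matrix(c(k_in, n_in - k_in, k_bg - k_in, n_bg - n_in - (k_bg - k_in)),
                nrow = 2, byrow = TRUE)
    p <- stats::fisher.test(m, alternative = "two.sided")$p.value
    sig_in <- tab[inpw & tab$significant, , drop = FALSE]
    example <- if (nrow(sig_in)) {
      sig_in$metabolite_id[which.min(sig_in$p_value)]
    } else {
      tab$metabolite_id[inpw][which.min(tab$p_value[inpw])]
    }
    tibble::tibble(pathway = pw, n_significant = k_in, n_detected = n_in,
                   background_significant = k_bg, background_detected = n_bg,
                   p_value = p, example_metabolite = example)
  })
  rows$q_value <- benjamini_hochberg(rows$p_value)
  rows[, c("pathway", "n_significant", "n_detected", "background_significant",
           "background_detected", "p_value", "q_value", "example_metabolite")]
}

#' Filter and sort the enrichment table
#'
#' @param enrichment tibble from [fisher_enrichment()].
#' @param threshold keep pathways with `q_value` below this (default 0.1).
#' @return Rows with q below the threshold, in ascending p order.
#' @export
pathway_table <- function(enrichment, threshold = 0.1) {
  dplyr::arrange(dplyr::filter(enrichment, .data$q_value < threshold),
                 .data$p_value)
}
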