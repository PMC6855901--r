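#' Pairwise Spearman correlations among metabolites
#'
#' Tie-corrected Spearman rho between all metabolite pairs over a sample
#' subset (canonically the pregnant women, on adjusted abundances), with
#' two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#' Metabolites with zero rank variance (constant over the subset) get `NA`
#' rho/p and are excluded from downstream edges.
#'
#' @param x an `abund` at stage `"adjusted"` (rank-based, so any monotone
#'   per-metabolite transform of the values gives identical results).
#' @param sample_subset sample ids to correlate over (default: all columns).
#' @param require_adjusted set `FALSE` to allow other stages (used by
#'   recovery simulations).
#' @return A list of class `"spearman_matrix"`: `rho` and `p` (symmetric
#'   matrices, unit/zero diagonal), `n` (samples used).
#' @export
spearman_matrix <- function(x, sample_subset = colnames(x$values),
                            require_adjusted = TRUE) {
  if (require_adjusted) require_stage(x, "adjusted", "spearman_matrix")
  if (length(sample_subset) == 0) stop("empty sample subset", call. = FALSE)
  vals <- t(x$values[, sample_subset, drop = FALSE])  # samples x metabolites
  n <- nrow(vals)
  if (n < 3) stop("spearman_matrix: need >= 3 samples", call. = FALSE)
  constant <- apply(vals, 2, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(stats::cor(vals, method = "spearman"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho)[!constant] <- 1
  if (any(constant)) {
    message("spearman_matrix: constant metabolite(s) excluded: ",
            paste(colnames(vals)[constant], collapse = ", "))
  }
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  structure(list(rho = rho, p = p, n = n), class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat(sprintf("<spearman_matrix> %d metabolites over %d samples\n",
              nrow(x$rho), x$n))
  invisible(x)
}

#' Threshold a correlation matrix into a network
#'
#' Edges connect metabolite pairs with `|rho|` above `threshold`; node
#' degree is the number of incident edges. Degree mean and interquartile
#' range summarize a pathway's connectivity.
#'
#' @param sp a `spearman_matrix` (or plain symmetric rho matrix).
#' @param node_subset metabolite ids to restrict to (default: all).
#' @param threshold absolute-rho edge threshold in (0, 1); default 0.5.
#' @return A list of class `"cor_network"`: `edges` (tibble `metabolite_a,
#'   metabolite_b, rho`), `degree` (named integer vector over all subset
#'   nodes), `mean_degree`, `degree_iqr` (25th/75th percentiles),
#'   `threshold`.
#' @export
build_network <- function(sp, node_subset = NULL, threshold = 0.5) {
  rho <- if (inherits(sp, "spearman_matrix")) sp$rho else sp
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(node_subset)) node_subset <- rownames(rho)
  node_subset <- intersect(node_subset, rownames(rho))
  if (length(node_subset) == 0) stop("build_network: empty node subset",
                                     call. = FALSE)
  r <- rho[node_subset, node_subset, drop = FALSE]
  idx <- which(upper.tri(r) & !is.na(r) & abs(r) > threshold, arr.ind = TRUE)
  edges <- tibble::tibble(metabolite_a = rownames(r)[idx[, 1]],
                          metabolite_b = colnames(r)[idx[, 2]],
                          rho = r[idx])
  degree <- stats::setNames(integer(length(node_subset)), node_subset)
  if (nrow(edges)) {
    counts <- table(c(edges$metabolite_a, edges$metabolite_b))
    degree[names(counts)] <- as.integer(counts)
  }
  structure(list(edges = edges, degree = degree,
                 mean_degree = mean(degree),
                 degree_iqr = unname(stats::quantile(degree, c(0.25, 0.75))),
                 threshold = threshold),
            class = "cor_network")
}

#' @export
print.cor_network <- function(x, ...) {
  cat(sprintf("<cor_network> %d nodes, %d edges (|rho| > %.2f), mean degree %.2f, IQR %g-%g\n",
              length(x$degree), nrow(x$edges), x$threshold, x$mean_degree,
              x$degree_iqr[1], x$degree_iqr[2]))
  invisible(x)
}

#' Hierarchical clustering of metabolites from Spearman correlations
#'
#' Agglomerative clustering with average linkage on the distance
#' `d = 1 - rho` (anti-correlated metabolites end up in different clusters;
#' set `absolute = TRUE` for `1 - |rho|`), with the dendrogram cut into
#' exactly `k` clusters. Metabolites with undefined correlations (constant
#' over the samples) are assigned their own singleton clusters beyond `k`.
#'
#' @param sp a `spearman_matrix` or plain rho matrix.
#' @param k number of clusters to cut into.
#' @param absolute use `1 - |rho|` as the distance instead of `1 - rho`.
#' @return A tibble `metabolite_id, cluster` (integer labels, 1..k first).
#' @export
cluster_metabolites <- function(sp, k = 25, absolute = FALSE) {
  rho <- if (inherits(sp, "spearman_matrix")) sp$rho else sp
  defined <- rownames(rho)[!is.na(diag(rho))]
  undefined <- setdiff(rownames(rho), defined)
  if (k < 1 || k > length(defined)) {
    stop("cluster_metabolites: k must be in 1..#metabolites with defined rho",
         call. = FALSE)
  }
  r <- rho[defined, defined, drop = FALSE]
  d <- if (absolute) 1 - abs(r) else 1 - r
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  labels <- stats::cutree(hc, k = k)
  out <- tibble::tibble(metabolite_id = names(labels),
                        cluster = as.integer(labels))
  if (length(undefined)) {
    message("cluster_metabolites: singleton cluster(s) for constant metabolite(s): ",
            paste(undefined, collapse = ", "))
    out <- dplyr::bind_rows(out,
      tibble::tibble(metabolite_id = undefined,
                     cluster = k + seq_along(undefined)))
  }
  out[match(rownames(rho), out$metabolite_id), ]
}

#' Significantly correlated metabolite pairs
#'
#' All unordered pairs whose two-sided Spearman p-value passes
#' Benjamini-Hochberg FDR control (across all pairs) at `fdr`, sorted by
#' `|rho|` descending.
#'
#' @param sp a `spearman_matrix`.
#' @param fdr FDR threshold (default 0.1).
#' @return A tibble `metabolite_a, metabolite_b, rho, p_value, q_value`.
#' @export
significant_pairs <- function(sp, fdr = 0.1) {
  stopifnot(inherits(sp, "spearman_matrix"))
  idx <- which(upper.tri(sp$rho) & !is.na(sp$rho), arr.ind = TRUE)
  pairs <- tibble::tibble(metabolite_a = rownames(sp$rho)[idx[, 1]],
                          metabolite_b = colnames(sp$rho)[idx[, 2]],
                          rho = sp$rho[idx], p_value = sp$p[idx])
  pairs$q_value <- benjamini_hochberg(pairs$p_value)
  pairs <- dplyr::filter(pairs, .data$q_value < fdr)
  dplyr::arrange(pairs, dplyr::desc(abs(.data$rho)))
}

#' Per-pathway degree summaries of the correlation network
#'
#' Builds one network per enriched sub-pathway and reports its node count,
#' mean degree and degree interquartile range.
#'
#' @param sp a `spearman_matrix`.
#' @param annotation annotation tibble.
#' @param pathways character vector of sub-pathways to summarize.
#' @param threshold absolute-rho edge threshold.
#' @return A tibble `pathway, n_nodes, n_edges, mean_degree,
#'   degree_iqr_low, degree_iqr_high`.
#' @export
pathway_degree_summary <- function(sp, annotation, pathways, threshold = 0.5) {
  purrr::map_dfr(pathways, function(pw) {
    nodes <- annotation$metabolite_id[annotation$sub_pathway == pw]
    nodes <- intersect(nodes, rownames(sp$rho))
    if (length(nodes) == 0) {
      return(tibble::tibble(pathway = pw, n_nodes = 0L, n_edges = 0L,
                            mean_degree = NA_real_,
                            degree_iqr_low = NA_real_,
                            degree_iqr_high = NA_real_))
    }
    nw <- build_network(sp, nodes, threshold)
    tibble::tibble(pathway = pw, n_nodes = length(nw$degree),
                   n_edges = nrow(nw$edges), mean_degree = nw$mean_degree,
                   degree_iqr_low = nw$degree_iqr[1],
                   degree_iqr_high = nw$degree_iqr[2])
  })
}
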