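adjusted_abund <- function(vals) tiny_abund(vals, stage = "adjusted")

test_that("Spearman matrix is symmetric, rank-invariant, and flags constants", {
  set.seed(31)
  x <- matrix(2^rnorm(5 * 20, 12, 1), 5, 20,
              dimnames = list(paste0("m", 1:5), paste0("s", 1:20)))
  x[5, ] <- 7  # constant metabolite
  sp <- suppressMessages(spearman_matrix(adjusted_abund(x)))
  expect_equal(sp$rho, t(sp$rho))
  expect_equal(unname(diag(sp$rho)[1:4]), rep(1, 4))
  expect_true(all(is.na(sp$rho[5, ])))
  # monotone transform of a metabolite leaves rho identical
  y <- x
  y[1, ] <- exp(x[1, ] / 1000)
  sp2 <- suppressMessages(spearman_matrix(adjusted_abund(y)))
  expect_equal(sp2$rho, sp$rho)
  # p-values match cor.test's t approximation pairwise
  ct <- suppressWarnings(cor.test(x[1, ], x[2, ], method = "spearman",
                                  exact = FALSE))
  expect_equal(sp$p[1, 2], ct$p.value, tolerance = 1e-10)
})

test_that("within-block correlation matches the planted latent-factor level", {
  rhos <- vapply(1:60, function(s) {
    sim <- simulate_cohort(synth_config(
      n_metabolites = 12, n_pathways = 2, n_pregnant = 25, n_nonpregnant = 25,
      frac_differential = 0, frac_decaying = 0, n_replicates = 0,
      n_reference = 0, lod_quantile = 0, batch_sd_log2 = 0, n_run_days = 1,
      seed = 4000 + s))
    sp <- spearman_matrix(sim$abund, require_adjusted = FALSE)
    same <- outer(sim$annotation$sub_pathway, sim$annotation$sub_pathway, "==")
    mean(sp$rho[same & upper.tri(same)])
  }, numeric(1))
  expect_equal(mean(rhos), 0.6, tolerance = 0.1)
})

test_that("network thresholding yields the forced topology and degree identity", {
  rho <- matrix(0.9, 3, 3, dimnames = list(paste0("m", 1:3), paste0("m", 1:3)))
  diag(rho) <- 1
  nw <- build_network(rho, threshold = 0.5)
  expect_equal(nrow(nw$edges), 3)
  expect_equal(unname(nw$degree), c(2, 2, 2))
  expect_equal(nw$mean_degree, 2)
  expect_equal(sum(nw$degree), 2 * nrow(nw$edges))
  # near-unity threshold: empty edge set on noisy data
  set.seed(32)
  x <- matrix(2^rnorm(6 * 30, 12, 1), 6, 30,
              dimnames = list(paste0("m", 1:6), paste0("s", 1:30)))
  sp <- spearman_matrix(adjusted_abund(x))
  expect_equal(nrow(build_network(sp, threshold = 0.999)$edges), 0)
  expect_error(build_network(sp, node_subset = character()), "empty")
})

test_that("edge sets are invariant under monotone per-metabolite transforms", {
  set.seed(33)
  x <- matrix(2^rnorm(8 * 25, 12, 1), 8, 25,
              dimnames = list(paste0("m", 1:8), paste0("s", 1:25)))
  sp1 <- spearman_matrix(adjusted_abund(x))
  y <- x^3
  y[2, ] <- log(x[2, ])
  sp2 <- spearman_matrix(adjusted_abund(y))
  e1 <- build_network(sp1, threshold = 0.3)$edges
  e2 <- build_network(sp2, threshold = 0.3)$edges
  expect_equal(e1, e2)
})

test_that("dendrogram cuts are exact, nested, and handle degenerate k", {
  set.seed(34)
  x <- matrix(2^rnorm(10 * 30, 12, 1), 10, 30,
              dimnames = list(paste0("m", 1:10), paste0("s", 1:30)))
  sp <- spearman_matrix(adjusted_abund(x))
  expect_equal(length(unique(cluster_metabolites(sp, 1)$cluster)), 1)
  expect_equal(length(unique(cluster_metabolites(sp, 10)$cluster)), 10)
  for (k in 2:8) {
    ck <- cluster_metabolites(sp, k)$cluster
    ck1 <- cluster_metabolites(sp, k + 1)$cluster
    expect_equal(length(unique(ck)), k)
    # nested: the k+1 cut refines the k cut by exactly one split
    tab <- table(ck, ck1)
    expect_equal(sum(tab > 0), k + 1)
    expect_true(all(colSums(tab > 0) == 1))
  }
})

test_that("two uncorrelated blocks are recovered by the k = 2 cut", {
  skip_if_not_installed("mclust")
  ari <- vapply(1:40, function(s) {
    set.seed(5000 + s)
    n <- 50
    f1 <- rnorm(n); f2 <- rnorm(n)
    lam <- sqrt(0.7)
    x <- 2^(12 + rbind(
      t(replicate(6, lam * f1 + sqrt(1 - lam^2) * rnorm(n))),
      t(replicate(6, lam * f2 + sqrt(1 - lam^2) * rnorm(n)))))
    rownames(x) <- paste0("m", 1:12)
    colnames(x) <- paste0("s", 1:n)
    cl <- cluster_metabolites(spearman_matrix(adjusted_abund(x)), 2)
    mclust::adjustedRandIndex(cl$cluster, rep(1:2, each = 6))
  }, numeric(1))
  expect_gte(mean(ari > 0.9), 0.95)
})

test_that("significant pairs rank a planted correlation first and control FDR", {
  firsts <- vapply(1:30, function(s) {
    set.seed(6000 + s)
    n <- 40
    base <- rnorm(n)
    x <- 2^(12 + rbind(base + rnorm(n, 0, 0.3), base + rnorm(n, 0, 0.3),
                       matrix(rnorm(6 * n), 6, n)))
    rownames(x) <- paste0("m", 1:8)
    colnames(x) <- paste0("s", 1:n)
    pr <- significant_pairs(spearman_matrix(adjusted_abund(x)), 0.1)
    nrow(pr) >= 1 && setequal(c(pr$metabolite_a[1], pr$metabolite_b[1]),
                              c("m1", "m2"))
  }, logical(1))
  expect_gte(mean(firsts), 0.99)

  # null data: tiny sample sizes give no significant pairs
  set.seed(35)
  xs <- matrix(2^rnorm(6 * 4, 12, 1), 6, 4,
               dimnames = list(paste0("m", 1:6), paste0("s", 1:4)))
  expect_equal(nrow(significant_pairs(spearman_matrix(adjusted_abund(xs)),
                                      0.1)), 0)
})

test_that("per-pathway degree summaries restrict the network correctly", {
  set.seed(36)
  n <- 30
  f <- rnorm(n)
  x <- 2^(12 + rbind(t(replicate(4, f + rnorm(n, 0, 0.2))),
                     matrix(rnorm(4 * n), 4, n)))
  rownames(x) <- paste0("m", 1:8)
  colnames(x) <- paste0("s", 1:n)
  ann <- tibble::tibble(metabolite_id = rownames(x),
                        sub_pathway = rep(c("tight", "loose"), each = 4))
  sp <- spearman_matrix(adjusted_abund(x))
  ds <- pathway_degree_summary(sp, ann, c("tight", "loose"), threshold = 0.5)
  expect_equal(ds$n_nodes, c(4, 4))
  expect_gt(ds$mean_degree[1], ds$mean_degree[2])
})
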