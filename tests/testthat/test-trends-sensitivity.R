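test_that("gestational trends are rank-based and handle degenerate inputs", {
  set.seed(41)
  n <- 30
  ga <- runif(n, 8, 16)
  vals <- rbind(up = 2^(12 + 0.3 * ga + rnorm(n, 0, 0.2)),
                flat = 2^rnorm(n, 12, 0.5),
                const = rep(100, n))
  colnames(vals) <- paste0("p", 1:n)
  a <- tiny_abund(vals, stage = "adjusted")
  meta <- tiny_meta(colnames(vals), rep("pregnant", n), gestational_age = ga)
  tr <- suppressMessages(
    gestational_trends(a, meta, c("up", "flat", "const"), fdr = 0.1))
  expect_gt(tr$rho_ga[tr$metabolite_id == "up"], 0.5)
  expect_true(tr$trending[tr$metabolite_id == "up"])
  expect_true(is.na(tr$rho_ga[tr$metabolite_id == "const"]))
  expect_gt(tr$regression_slope[tr$metabolite_id == "up"], 0.1)
  # invariant to monotone transforms of abundance
  b <- a
  b$values["up", ] <- a$values["up", ]^2
  tr2 <- suppressMessages(
    gestational_trends(b, meta, c("up", "flat", "const"), fdr = 0.1))
  expect_equal(tr2$rho_ga, tr$rho_ga)
  expect_error(gestational_trends(a, meta, "absent"), "absent")
})

test_that("a planted gestational-age slope is detected reliably", {
  hits <- vapply(1:30, function(s) {
    set.seed(7000 + s)
    n <- 50
    ga <- runif(n, 8, 16)
    vals <- rbind(trend = 2^(12 + 0.1 * ga + rnorm(n, 0, 0.3)),
                  matrix(2^rnorm(9 * n, 12, 0.3), 9, n))
    rownames(vals)[2:10] <- paste0("null", 1:9)
    colnames(vals) <- paste0("p", 1:n)
    a <- tiny_abund(vals, stage = "adjusted")
    meta <- tiny_meta(colnames(vals), rep("pregnant", n),
                      gestational_age = ga)
    tr <- gestational_trends(a, meta, rownames(vals), fdr = 0.1)
    isTRUE(tr$trending[tr$metabolite_id == "trend"])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("PCA scores separate a distinct sample and conserve variance", {
  vals <- 2^cbind(c(10, 11, 9), c(10, 11, 9), c(12, 13, 8))
  dimnames(vals) <- list(paste0("m", 1:3), paste0("s", 1:3))
  a <- tiny_abund(vals, stage = "adjusted")
  meta <- tiny_meta(colnames(vals), rep("non_pregnant", 3))
  sc <- pca_plot_data(a, meta)
  ve <- attr(sc, "var_explained")
  expect_equal(sum(ve), 100, tolerance = 1e-6)
  # samples 1 and 2 identical: PC1 separates sample 3, PC2 variance ~ 0
  expect_equal(sc$PC1[1], sc$PC1[2], tolerance = 1e-8)
  expect_gt(abs(sc$PC1[3] - sc$PC1[1]), 1)
  expect_lt(ve[2], 1e-9)
  # scores invariant (up to sign convention, here exactly) to sample order
  perm <- c(2, 3, 1)
  a2 <- gravidmet:::abund_subset_samples(a, colnames(vals)[perm])
  sc2 <- pca_plot_data(a2, meta[perm, ])
  expect_equal(sc2$PC1[match(sc$sample_id, sc2$sample_id)], sc$PC1)
  # zero-variance metabolites are dropped with a warning
  vals0 <- rbind(vals, m4 = c(8, 8, 8))
  expect_warning(pca_plot_data(tiny_abund(vals0, stage = "adjusted"), meta),
                 "zero-variance")
})

test_that("group structure shows as PC1 separation on synthetic cohorts", {
  seps <- vapply(1:10, function(s) {
    sim <- simulate_cohort(synth_config(n_metabolites = 80, seed = 8000 + s))
    prep <- impute_lod(scale_run_days(sim$abund, sim$metadata),
                       0.99)
    keep <- sim$metadata$group %in% c("pregnant", "non_pregnant")
    sub <- gravidmet:::abund_subset_samples(prep,
                                            sim$metadata$sample_id[keep])
    sc <- pca_plot_data(sub, sim$metadata[keep, ])
    g <- sc$group == "pregnant"
    # standardized separation of group means along PC1
    abs(mean(sc$PC1[g]) - mean(sc$PC1[!g])) /
      sqrt(var(sc$PC1[g]) / 2 + var(sc$PC1[!g]) / 2)
  }, numeric(1))
  expect_gt(median(seps), 1)
})

test_that("sensitivity exclusions report concordance and flips", {
  sim <- simulate_cohort(synth_config(n_metabolites = 60, seed = 99))
  prep <- impute_lod(scale_run_days(sim$abund, sim$metadata), 0.99)
  prep <- gravidmet:::set_stage(prep, "imputed")
  cfg <- pipeline_config()

  # empty exclusion set reproduces the primary analysis exactly
  none <- sensitivity_exclude(prep, sim$metadata, "none", cfg)
  expect_equal(none$fold_change_concordance, 1)
  expect_equal(length(none$gained_significance), 0)
  expect_equal(length(none$lost_significance), 0)
  expect_equal(none$full, none$reduced)

  smoke <- sensitivity_exclude(prep, sim$metadata, "smokers", cfg)
  smokers <- sim$metadata$sample_id[
    sim$metadata$smoker & sim$metadata$group %in% c("pregnant", "non_pregnant")]
  expect_setequal(smoke$excluded_samples, smokers)
  expect_gt(smoke$fold_change_concordance, 0.8)

  age <- sensitivity_exclude(prep, sim$metadata, "oldest_white_nonpregnant_5",
                             cfg)
  expect_lte(length(age$excluded_samples), 5)
  white_np <- sim$metadata[sim$metadata$group == "non_pregnant" &
                             sim$metadata$ethnicity == "white", ]
  expect_true(all(age$excluded_samples %in% white_np$sample_id))
  # excluded are the oldest among white non-pregnant women
  if (length(age$excluded_samples) < nrow(white_np)) {
    kept <- setdiff(white_np$sample_id, age$excluded_samples)
    expect_gte(min(white_np$maternal_age[white_np$sample_id %in%
                                           age$excluded_samples]),
               max(white_np$maternal_age[white_np$sample_id %in% kept]))
  }

  # removing an entire group errors
  all_np <- sim$metadata
  all_np$smoker[all_np$group == "non_pregnant"] <- TRUE
  expect_error(sensitivity_exclude(prep, all_np, "smokers", cfg),
               "entire group")
})
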