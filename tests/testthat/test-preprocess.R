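test_that("run-day scaling equalizes per-day medians at the grand median", {
  vals <- matrix(c(2, 4, 6, 1, 2, 3), 1, 6,
                 dimnames = list("m1", paste0("s", 1:6)))
  a <- tiny_abund(vals)
  meta <- tiny_meta(paste0("s", 1:6), rep("non_pregnant", 6),
                    run_day = rep(c("dayA", "dayB"), each = 3))
  s <- scale_run_days(a, meta)
  # grand median of pooled detected values is 2.5: day A x 0.625, day B x 1.25
  expect_equal(unname(s$values[1, ]),
               c(c(2, 4, 6) * 0.625, c(1, 2, 3) * 1.25))
  expect_equal(abund_stage(s), "scaled")

  # single run day: unchanged
  meta1 <- tiny_meta(paste0("s", 1:6), rep("non_pregnant", 6))
  expect_equal(scale_run_days(a, meta1)$values, a$values)

  # all-identical values: unchanged
  const <- tiny_abund(matrix(5, 1, 6, dimnames = list("m1", paste0("s", 1:6))))
  expect_equal(scale_run_days(const, meta)$values, const$values)
})

test_that("run-day scaling is idempotent and tolerates undetectable days", {
  set.seed(42)
  vals <- matrix(2^rnorm(50 * 12, 12, 1), 50, 12)
  vals[1, 1:4] <- NA  # metabolite 1 never detected on day A
  a <- tiny_abund(vals)
  meta <- tiny_meta(colnames(a$values), rep("non_pregnant", 12),
                    run_day = rep(c("dayA", "dayB", "dayC"), each = 4))
  s1 <- scale_run_days(a, meta)
  s2 <- scale_run_days(s1, meta)
  expect_equal(s2$values, s1$values, tolerance = 1e-12)
  expect_identical(is.na(s1$values), is.na(a$values))
  # per-metabolite day medians agree across days after scaling
  for (d in c("dayA", "dayB", "dayC")) {
    cols <- meta$sample_id[meta$run_day == d]
    med <- apply(s1$values[-1, cols], 1, median, na.rm = TRUE)
    ref <- apply(s1$values[-1, ], 1, median, na.rm = TRUE)
    expect_equal(med, ref, tolerance = 1e-12)
  }
})

test_that("detection filter keeps metabolites at the threshold boundary", {
  vals <- matrix(1, 3, 12, dimnames = list(c("nine", "ten", "all"),
                                           paste0("s", 1:12)))
  vals["nine", 1:3] <- NA
  vals["ten", 1:2] <- NA
  a <- tiny_abund(vals)
  f <- filter_detection(a, 10)
  expect_setequal(rownames(f$values), c("ten", "all"))
  expect_equal(rownames(filter_detection(a, 1)$values), rownames(vals))
})

test_that("LOD imputation fills censored cells from the scaled minimum", {
  vals <- rbind(m1 = c(100, 200, NA), m2 = c(300, NA, 150))
  colnames(vals) <- c("s1", "s2", "s3")
  a <- tiny_abund(vals, stage = "scaled")
  imp <- impute_lod(a, 0.99)
  expect_equal(imp$values["m1", "s3"], 0.99 * 100)
  expect_equal(imp$values["m2", "s2"], 0.99 * 150)
  expect_identical(imp$detected, a$detected)  # mask never flips
  expect_true(all(is.finite(imp$values) & imp$values > 0))
  # detected cells never change; fraction 1 hits the minimum exactly
  expect_equal(impute_lod(a, 1)$values["m1", "s3"], 100)
  # stage enforcement: imputation only after scaling
  expect_error(impute_lod(tiny_abund(vals), 0.99), "stage")
  # all-censored metabolite is an error
  bad <- vals; bad[1, ] <- NA
  expect_error(impute_lod(tiny_abund(bad, stage = "scaled"), 0.99),
               "no detected")
})

test_that("decay fit recovers a noiseless exponential and skips constants", {
  t <- 0:12
  vals <- rbind(1000 * exp(-0.1 * t), rep(50, 13))
  rownames(vals) <- c("decays", "flat")
  colnames(vals) <- sprintf("r%02d", seq_along(t))
  ref <- tiny_abund(vals)
  meta <- tiny_meta(colnames(vals), rep("reference", 13), storage = t)
  models <- fit_decay(ref, meta, alpha = 0.05)
  expect_equal(models$slope[models$metabolite_id == "decays"], -0.1,
               tolerance = 1e-9)
  expect_equal(models$spearman_rho[models$metabolite_id == "decays"], -1)
  expect_true(models$applied[models$metabolite_id == "decays"])
  expect_false(models$applied[models$metabolite_id == "flat"])
})

test_that("decay fit recovers planted rates from noisy reference samples", {
  errs <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    t <- runif(20, 0, 36)
    y <- 5000 * exp(-0.05 * t) * exp(rnorm(20, 0, 0.1))
    ref <- tiny_abund(matrix(y, 1, 20, dimnames = list("m1", sprintf("r%02d", 1:20))))
    meta <- tiny_meta(colnames(ref$values), rep("reference", 20), storage = t)
    fit_decay(ref, meta)$slope[1]
  }, numeric(1))
  expect_lt(median(abs(errs + 0.05)), 0.02)
  expect_lt(max(abs(errs + 0.05)), 0.05)
})

test_that("decay back-correction projects study values to storage time zero", {
  vals <- matrix(c(50, 80), 1, 2, dimnames = list("m1", c("s1", "s2")))
  a <- tiny_abund(vals, stage = "scaled")
  a <- impute_lod(a, 0.99)
  meta <- tiny_meta(c("s1", "s2"), rep("non_pregnant", 2), storage = c(12, 0))
  models <- tibble::tibble(metabolite_id = "m1", spearman_rho = -1,
                           spearman_p = 0.001, slope = -0.1, applied = TRUE)
  out <- apply_decay(a, meta, models)
  expect_equal(out$values["m1", "s1"], 50 * exp(1.2))
  expect_equal(out$values["m1", "s2"], 80)  # storage 0: untouched
  expect_equal(abund_stage(out), "decay_corrected")
  # applied = FALSE leaves everything unchanged
  models$applied <- FALSE
  expect_equal(apply_decay(a, meta, models)$values, a$values)
  # missing storage time while a model applies is an error
  models$applied <- TRUE
  meta_bad <- tiny_meta(c("s1", "s2"), rep("non_pregnant", 2))
  expect_error(apply_decay(a, meta_bad, models), "storage")
})

test_that("quantile normalization maps samples onto the rank-mean reference", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                 dimnames = list(c("m1", "m2", "m3"), c("s1", "s2")))
  a <- tiny_abund(vals, stage = "imputed")
  q <- quantile_normalize(a)
  expect_equal(unname(q$values[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q$values[, "s2"]), c(2.5, 3.5, 4.5))
  expect_equal(abund_stage(q), "adjusted")

  ident <- tiny_abund(matrix(c(3, 1, 2, 3, 1, 2), 3, 2), stage = "imputed")
  expect_equal(quantile_normalize(ident)$values, ident$values)

  miss <- tiny_abund(matrix(c(1, NA, 2, 3), 2, 2), stage = "imputed")
  expect_error(quantile_normalize(miss), "impute")
})

test_that("quantile normalization postcondition, tie rule, and invariances", {
  set.seed(7)
  for (rep in 1:20) {
    vals <- matrix(2^rnorm(40 * 6, 12, 2), 40, 6)
    a <- tiny_abund(vals, stage = "imputed")
    q <- quantile_normalize(a)$values
    sorted <- apply(q, 2, sort)
    expect_equal(unname(sorted), unname(sorted[, c(2:6, 1)]))
    expect_equal(max(abs(colSums(q) - mean(colSums(q)))), 0, tolerance = 1e-8)
    # within-sample rank order is preserved
    for (j in 1:6) expect_equal(unname(rank(q[, j])), rank(vals[, j]))
    # idempotent: a second pass maps every sample onto itself
    q2 <- quantile_normalize(tiny_abund(q, stage = "imputed"))$values
    expect_equal(unname(q2), unname(q), tolerance = 1e-12)
  }
  # against the independent microarray-era implementation on tie-free data
  skip_if_not_installed("limma")
  set.seed(8)
  vals <- matrix(rexp(200 * 5, 1 / 100), 200, 5)
  mine <- quantile_normalize(tiny_abund(vals, stage = "imputed"))$values
  theirs <- limma::normalizeQuantiles(vals, ties = TRUE)
  expect_equal(unname(mine), unname(theirs), tolerance = 1e-12)
  # the tie rule: tied cells get the mean of the reference over tied ranks
  tied <- matrix(c(1, 1, 2, 1, 2, 3), 3, 2)
  qt <- quantile_normalize(tiny_abund(tied, stage = "imputed"))$values
  ref <- rowMeans(apply(tied, 2, sort))
  expect_equal(unname(qt[, 1]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
})

test_that("intra-assay CV uses detected replicates and the 4-of-5 rule", {
  vals <- rbind(c(100, 100, 100, 100, 100),
                c(90, 100, 110, 100, 100),
                c(100, NA, NA, 90, 110))
  rownames(vals) <- c("flat", "varied", "sparse")
  colnames(vals) <- paste0("rep", 1:5)
  a <- tiny_abund(vals)
  meta <- tiny_meta(colnames(vals), rep("replicate", 5),
                    replicate_group = "g1")
  qc <- compute_qc(a, meta)
  cv <- qc$cv
  expect_equal(cv$cv_percent[cv$metabolite_id == "flat"], 0)
  expect_equal(cv$cv_percent[cv$metabolite_id == "varied"], 7.07,
               tolerance = 1e-3)
  expect_false("sparse" %in% cv$metabolite_id)  # detected in 3/5 only
  # no replicate groups: empty report
  expect_message(
    empty <- compute_qc(a, tiny_meta(colnames(vals), rep("pregnant", 5),
                                     gestational_age = 12)),
    "no replicate")
  expect_equal(nrow(empty$cv), 0)
})

test_that("log2 transform validates positivity", {
  a <- tiny_abund(matrix(c(8, 1, 2, 4), 2, 2), stage = "imputed")
  expect_equal(log2_transform(a), log2(a$values))
  bad <- tiny_abund(matrix(c(8, 0, 2, 4), 2, 2), stage = "imputed")
  expect_error(log2_transform(bad), "> 0")
})
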