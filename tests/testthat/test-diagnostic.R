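test_that("AUC follows the Mann-Whitney form", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)  # all tied
  expect_error(auc(1:4, rep(1, 4)), "both classes")
  withr::with_seed(2, {
    s <- rnorm(60); y <- rbinom(60, 1, 0.5)
    base <- auc(s, y)
    for (f in monotone_bank) expect_equal(auc(f(s), y), base)
    # independent implementation check
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(base, ref, tolerance = 1e-12)
  })
})

test_that("discovery split is stratified, deterministic and exact", {
  # the 474-sample discovery layout: 372 cases, 102 controls
  labels <- stats::setNames(c(rep(1L, 372), rep(0L, 102)),
                            sprintf("d%03d", 1:474))
  sp <- split_discovery(labels, 0.8, seed = 1)
  expect_equal(length(sp$train), 379)
  expect_equal(length(sp$test), 95)
  expect_setequal(c(sp$train, sp$test), names(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  # stratification keeps both classes on both sides
  expect_true(all(table(labels[sp$train]) >= 1))
  expect_true(all(table(labels[sp$test]) >= 1))
  expect_identical(split_discovery(labels, 0.8, seed = 1), sp)
  expect_false(identical(split_discovery(labels, 0.8, seed = 2)$train,
                         sp$train))
  expect_error(split_discovery(c(a = 1L, b = 1L, c = 0L)), "2 samples")
})

test_that("stability selection separates a planted pair from noise", {
  fs <- planted_feature_set(n_case = 100, n_ctrl = 100, n_null = 20,
                            rate_case = 0.95, rate_ctrl = 0.05, seed = 5)
  n_rep <- 40
  stab <- stability_select(fs$features, fs$labels, n_repeats = n_rep,
                           seed = 5)
  expect_s3_class(stab, "pairdx_stability")
  expect_length(stab$split_auc, n_rep)
  expect_true(all(stab$occurrence <= n_rep))
  # planted pair selected in >= 90% of repeats, each null in <= 20%
  expect_gte(stab$occurrence[[fs$planted_id]], ceiling(0.9 * n_rep))
  nulls <- stab$occurrence[setdiff(names(stab$occurrence), fs$planted_id)]
  expect_lte(max(nulls), floor(0.2 * n_rep))
  # determinism
  expect_identical(stability_select(fs$features, fs$labels,
                                    n_repeats = n_rep, seed = 5), stab)
  expect_error(stability_select(fs$features, fs$labels, n_repeats = 0),
               "n_repeats")
})

test_that("candidate selection applies a strict threshold with stable order", {
  stab <- structure(list(occurrence = c("a|b" = 73L, "c|d" = 50L,
                                        "e|f" = 12L),
                         split_auc = rep(0.9, 100), n_repeats = 100L,
                         seed = 1L, auc_gate = 0.8),
                    class = "pairdx_stability")
  cand <- select_candidates(stab, 50)
  expect_equal(nrow(cand), 1)  # strictly greater than 50
  expect_equal(cand$gene_a, "a")
  # ties broken lexicographically, order independent of input order
  stab$occurrence <- c("x|y" = 60L, "a|b" = 60L, "c|d" = 80L)
  cand2 <- select_candidates(stab, 50)
  expect_equal(pairdx:::pair_id(cand2$gene_a, cand2$gene_b),
               c("c|d", "a|b", "x|y"))
  stab$occurrence <- rev(stab$occurrence)
  expect_equal(select_candidates(stab, 50), cand2)
  # boundary: only strictly-greater occurrences survive
  expect_equal(nrow(select_candidates(stab, 79)), 1)
  expect_error(select_candidates(stab, 90), "threshold")
})

test_that("occurrence-threshold tuning returns the grid argmax", {
  fs <- planted_feature_set(n_case = 120, n_ctrl = 120, n_null = 15,
                            rate_case = 0.9, rate_ctrl = 0.1, seed = 9)
  sp <- split_discovery(fs$labels, 0.8, seed = 9)
  ftr <- pairdx:::subset_samples(fs$features, sp$train)
  fte <- pairdx:::subset_samples(fs$features, sp$test)
  stab <- stability_select(ftr, fs$labels, n_repeats = 30, seed = 9)
  thr <- tune_occurrence_threshold(stab, ftr, fs$labels, fte, fs$labels,
                                   grid = seq(5, 30, by = 5),
                                   cv_folds = 5, seed = 9)
  by_thr <- attr(thr, "auc_by_threshold")
  expect_true(as.integer(thr) %in% seq(5, 30, by = 5))
  # returned threshold attains the maximum, smallest on ties
  best <- max(by_thr, na.rm = TRUE)
  expect_equal(unname(by_thr[as.character(thr)]), best)
  expect_equal(as.integer(thr),
               min(as.integer(names(by_thr)[!is.na(by_thr) &
                                              by_thr == best])))
  expect_gte(best, 0.9)
  # single-value grid returns that value; tuning is deterministic
  expect_equal(as.integer(tune_occurrence_threshold(
    stab, ftr, fs$labels, fte, fs$labels, grid = 15, cv_folds = 5,
    seed = 9)), 15)
  expect_identical(tune_occurrence_threshold(
    stab, ftr, fs$labels, fte, fs$labels, grid = seq(5, 30, by = 5),
    cv_folds = 5, seed = 9), thr)
})

test_that("final model recovers planted structure and prunes under null", {
  withr::with_seed(13, {
    n <- 240
    ids <- sprintf("s%03d", 1:n)
    labels <- stats::setNames(rep(c(1L, 0L), each = n / 2), ids)
    rate <- ifelse(labels == 1L, 0.9, 0.1)
    planted <- sapply(1:3, function(i) ifelse(runif(n) < rate, 1L, -1L))
    nulls <- matrix(sample(c(1L, -1L), 7 * n, TRUE), ncol = 7)
    values <- t(cbind(planted, nulls))
    pairs <- data.frame(gene_a = sprintf("P%02da", 1:10),
                        gene_b = sprintf("P%02db", 1:10))
    rownames(values) <- pairdx:::pair_id(pairs$gene_a, pairs$gene_b)
    colnames(values) <- ids
    feats <- pairdx:::new_pair_features(pairs, values)
    m <- fit_final_model(feats, labels, pairs, cv_folds = 10, seed = 3)
    got <- pairdx:::pair_id(m$pairs$gene_a, m$pairs$gene_b)
    # all three planted pairs kept with positive coefficients
    expect_true(all(rownames(values)[1:3] %in% got))
    expect_true(all(m$coefficients[match(rownames(values)[1:3], got)] > 0))
    expect_true(all(m$coefficients != 0))
    # refit with the same seed is identical
    expect_identical(fit_final_model(feats, labels, pairs, cv_folds = 10,
                                     seed = 3), m)

    # labels independent of features: no useful model survives
    null_labels <- stats::setNames(sample(labels), ids)
    null_auc <- tryCatch({
      m0 <- fit_final_model(feats, null_labels, pairs, cv_folds = 10,
                            seed = 3)
      auc(predict(m0, feats), null_labels)
    }, error = function(e) 0.5)  # "no non-zero coefficient" also passes
    expect_lt(abs(null_auc - 0.5), 0.2)
  })
})

test_that("model prediction is the linear pair score", {
  fs <- planted_feature_set(seed = 30, n_null = 3)
  m <- pairdx:::new_diag_model(
    fs$features$pairs[1:2, ], coefficients = c(1.5, -0.5), intercept = 0.25)
  lp <- predict(m, fs$features)
  manual <- 1.5 * fs$features$values[1, ] - 0.5 * fs$features$values[2, ] +
    0.25
  expect_equal(lp, manual)
  expect_equal(predict(m, fs$features, type = "response"), plogis(manual))
})

test_that("tree-ensemble comparators also separate an easy study", {
  fs <- planted_feature_set(n_case = 80, n_ctrl = 80, n_null = 5,
                            rate_case = 0.95, rate_ctrl = 0.05, seed = 8)
  sp <- split_discovery(fs$labels, 0.8, seed = 8)
  ftr <- pairdx:::subset_samples(fs$features, sp$train)
  fte <- pairdx:::subset_samples(fs$features, sp$test)
  pairs <- fs$features$pairs
  comp <- fit_comparators(ftr, fs$labels, pairs, seed = 8)
  aucs <- comparator_aucs(comp, fte, fs$labels)
  expect_named(aucs, c("random_forest", "gradient_boosted_trees"))
  expect_true(all(aucs >= 0.9))
  lasso <- fit_final_model(ftr, fs$labels, pairs, cv_folds = 5, seed = 8)
  expect_gte(auc(predict(lasso, fte), fs$labels[fte$sample_ids]), 0.9)
  # seeded determinism
  expect_equal(comparator_aucs(fit_comparators(ftr, fs$labels, pairs,
                                               seed = 8), fte, fs$labels),
               aucs)
})
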