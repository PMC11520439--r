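test_that("univariate Cox recovers a single planted effect", {
  withr::with_seed(41, {
    n <- 500
    ids <- sprintf("s%03d", 1:n)
    r <- matrix(sample(c(1L, -1L), n, TRUE), 1,
                dimnames = list("GA|GB", ids))
    surv <- survival_from_features(r, betas = 1.0, seed = 41)
    fit <- univariate_cox(r[1, ], surv)
    expect_gt(fit$beta, 0.7)
    expect_lt(fit$beta, 1.3)
    expect_lt(fit$p_value, 1e-10)
    expect_equal(fit$hazard_ratio, exp(fit$beta))
    # flipping the feature sign negates the estimate
    flip <- univariate_cox(-r[1, ], surv)
    expect_equal(flip$beta, -fit$beta, tolerance = 1e-8)
  })
})

test_that("univariate Cox is calibrated under the null", {
  hits <- 0
  for (seed in 1:50) {
    withr::with_seed(seed, {
      n <- 500
      ids <- sprintf("s%03d", 1:n)
      r <- matrix(sample(c(1L, -1L), n, TRUE), 1,
                  dimnames = list("GA|GB", ids))
      surv <- survival_from_features(r, betas = 0, seed = seed + 500)
      fit <- univariate_cox(r[1, ], surv)
      if (abs(fit$beta) < 0.25 && fit$p_value > 0.05) hits <- hits + 1
    })
  }
  expect_gte(hits, 45)  # >= 90% of null runs stay quiet
})

test_that("univariate filter keeps prognostic pairs and orders by p", {
  s <- generate_study(preset_prognostic(51))
  nulls <- data.frame(gene_a = sprintf("G%04d", seq(21, 39, 2)),
                      gene_b = sprintf("G%04d", seq(22, 40, 2)))
  allp <- rbind(s$truth$planted[, c("gene_a", "gene_b")], nulls)
  feats <- pair_feature_matrix(s$cohorts$C1$expr, allp)
  filt <- filter_univariate(allp, feats, s$survival)
  got <- pairdx:::pair_id(filt$gene_a, filt$gene_b)
  planted <- pairdx:::pair_id(s$truth$planted$gene_a,
                              s$truth$planted$gene_b)
  expect_true(all(planted %in% got))
  expect_lte(sum(!got %in% planted), 2)  # at most a couple of null leaks
  expect_false(is.unsorted(filt$p_value))
  # alpha = 1 retains every non-degenerate pair (constant features are
  # skipped: two genes far apart in baseline mean never reverse)
  surv_ids <- intersect(colnames(feats$values), s$survival$sample_id)
  non_degen <- apply(feats$values[, surv_ids, drop = FALSE], 1,
                     function(v) length(unique(v)) > 1)
  all_in <- suppressMessages(
    filter_univariate(allp, feats, s$survival, alpha = 1))
  expect_setequal(pairdx:::pair_id(all_in$gene_a, all_in$gene_b),
                  rownames(feats$values)[non_degen])
  expect_identical(filter_univariate(allp, feats, s$survival), filt)
})

test_that("lasso-Cox keeps planted effects with correct signs", {
  withr::with_seed(61, {
    n <- 400
    ids <- sprintf("s%03d", 1:n)
    values <- matrix(sample(c(1L, -1L), 10 * n, TRUE), nrow = 10)
    pairs <- data.frame(gene_a = sprintf("Q%02da", 1:10),
                        gene_b = sprintf("Q%02db", 1:10))
    dimnames(values) <- list(pairdx:::pair_id(pairs$gene_a, pairs$gene_b),
                             ids)
    feats <- pairdx:::new_pair_features(pairs, values)
    surv <- survival_from_features(values, betas = c(1, -1), seed = 62)
    m <- lasso_cox(feats, surv, pairs, seed = 63)
    got <- pairdx:::pair_id(m$pairs$gene_a, m$pairs$gene_b)
    expect_true(all(rownames(values)[1:2] %in% got))
    expect_gt(m$coefficients[match(rownames(values)[1], got)], 0)
    expect_lt(m$coefficients[match(rownames(values)[2], got)], 0)
    expect_lte(sum(!got %in% rownames(values)[1:2]), 2)
    expect_lte(length(m$coefficients), nrow(pairs))
    expect_true(all(m$coefficients != 0))
    expect_identical(lasso_cox(feats, surv, pairs, seed = 63), m)
  })
})

test_that("risk scores are the exact linear predictor", {
  m <- pairdx:::new_prog_model(data.frame(gene_a = "GA", gene_b = "GB"),
                               coefficients = 0.5)
  values <- matrix(c(1L, -1L), 1, dimnames = list("GA|GB", c("x", "y")))
  feats <- pairdx:::new_pair_features(
    data.frame(gene_a = "GA", gene_b = "GB"), values)
  expect_equal(risk_score(m, feats), c(x = 0.5, y = -0.5))

  withr::with_seed(71, {
    k <- 6; n <- 20
    vals <- matrix(sample(c(1L, -1L), k * n, TRUE), k)
    pairs <- data.frame(gene_a = sprintf("R%02da", 1:k),
                        gene_b = sprintf("R%02db", 1:k))
    dimnames(vals) <- list(pairdx:::pair_id(pairs$gene_a, pairs$gene_b),
                           sprintf("s%02d", 1:n))
    beta <- rnorm(k)
    mm <- pairdx:::new_prog_model(pairs, beta)
    f <- pairdx:::new_pair_features(pairs, vals)
    # independent dot-product oracle
    oracle <- apply(vals, 2, function(col) sum(beta * col))
    expect_equal(risk_score(mm, f), oracle)
    neg <- pairdx:::new_prog_model(pairs, -beta)
    expect_equal(risk_score(neg, f), -oracle)
  })
})

test_that("median split uses a >= cutoff with documented tie policy", {
  sc <- stats::setNames(1:10 + 0.5, sprintf("s%02d", 1:10))
  ms <- median_split(sc)
  expect_equal(sum(ms$group == "high"), 5)
  expect_equal(sum(ms$group == "low"), 5)
  expect_true(all(ms$score[ms$group == "high"] >= attr(ms, "cutoff")))

  tied <- stats::setNames(rep(2, 4), letters[1:4])
  expect_true(all(median_split(tied)$group == "high"))

  odd <- stats::setNames(c(5, 1, 3, 2, 4), letters[1:5])
  expect_equal(sum(median_split(odd)$group == "high"), 3)  # (n+1)/2
  # an externally supplied (training) cutoff overrides the own median
  ext <- median_split(odd, cutoff = 4.5)
  expect_equal(sum(ext$group == "high"), 1)
  expect_equal(attr(ext, "cutoff"), 4.5)
  expect_error(median_split(c(a = 1)), "2 samples")
})

test_that("KM curves and log-rank behave on hand-checkable input", {
  # identical survival in both groups: zero statistic, p = 1
  surv <- data.frame(sample_id = sprintf("s%d", 1:12),
                     time = rep(c(1, 2, 3, 4, 5, 6), 2),
                     event = rep(c(1L, 1L, 0L, 1L, 0L, 0L), 2))
  strata <- data.frame(sample_id = surv$sample_id,
                       score = 0,
                       group = rep(c("high", "low"), each = 6))
  km <- km_logrank(strata, surv)
  expect_equal(km$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(km$logrank_p, 1)
  # product-limit hand computation for one group:
  # S(1) = 5/6, S(2) = 5/6 * 4/5 = 2/3, S(4) = 2/3 * 2/3 = 4/9
  hi <- km$curves[km$curves$group == "high", ]
  expect_equal(hi$time, c(1, 2, 4))
  expect_equal(hi$survival, c(5 / 6, 2 / 3, 4 / 9))
  # KM starts below 1 and never increases
  expect_true(all(diff(hi$survival) <= 0))
  expect_true(all(hi$survival <= 1))
  expect_error(km_logrank(strata[strata$group == "high", ], surv),
               "both risk groups")
})

test_that("a strong planted effect separates the risk groups", {
  withr::with_seed(81, {
    n <- 300
    pairs <- data.frame(gene_a = c("GA", "GC"), gene_b = c("GB", "GD"))
    values <- matrix(sample(c(1L, -1L), 2 * n, TRUE), 2,
                     dimnames = list(pairdx:::pair_id(pairs$gene_a,
                                                      pairs$gene_b),
                                     sprintf("s%03d", 1:n)))
    surv <- survival_from_features(values, betas = c(1.2, -0.8),
                                   seed = 82)
    m <- pairdx:::new_prog_model(pairs, c(1.2, -0.8))
    f <- pairdx:::new_pair_features(pairs, values)
    km <- km_logrank(median_split(risk_score(m, f)), surv)
    expect_lt(km$logrank_p, 0.05)
  })
})

test_that("time-dependent AUC matches its oracles", {
  withr::with_seed(91, {
    # perfect ranking, no censoring: AUC 1 at any valid horizon
    n <- 60
    times <- sort(rexp(n, 0.2))
    surv <- data.frame(sample_id = sprintf("s%02d", 1:n), time = times,
                       event = 1L)
    scores <- stats::setNames(-times, surv$sample_id)  # earlier = riskier
    for (h in stats::quantile(times, c(0.25, 0.5, 0.75)))
      expect_equal(time_dependent_auc(scores, surv, h), 1)

    # zero censoring: equals the plain AUC on the dichotomized outcome
    r <- matrix(sample(c(1L, -1L), 2 * 200, TRUE), 2,
                dimnames = list(c("A|B", "C|D"), sprintf("t%03d", 1:200)))
    sv <- survival_from_features(r, betas = c(0.8, -0.5),
                                 censor_max = Inf, seed = 92)
    sc <- stats::setNames(as.numeric(0.8 * r[1, ] - 0.5 * r[2, ]),
                          colnames(r))
    for (h in c(2, 5, 10)) {
      plain <- auc(sc, as.integer(sv$time <= h))
      expect_equal(time_dependent_auc(sc, sv, h), plain,
                   tolerance = 1e-10)
    }

    # scores independent of survival: near 0.5 at n = 400
    r2 <- matrix(sample(c(1L, -1L), 400, TRUE), 1,
                 dimnames = list("A|B", sprintf("u%03d", 1:400)))
    sv2 <- survival_from_features(r2, betas = 0, seed = 93)
    sc2 <- stats::setNames(rnorm(400), colnames(r2))
    expect_lt(abs(time_dependent_auc(sc2, sv2, 5) - 0.5), 0.1)

    # degenerate horizons are named errors
    expect_error(time_dependent_auc(scores, surv, min(times) / 2),
                 "horizon")
    expect_error(time_dependent_auc(scores, surv, max(times) + 1),
                 "horizon")
  })
})
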