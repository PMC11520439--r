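#' Area under the ROC curve (Mann-Whitney form)
#'
#' `(#concordant + 0.5 * #tied) / (n_pos * n_neg)` over all case/control
#' score pairs, computed via ranks; invariant under any strictly
#' increasing transform of the scores.
#'
#' @param scores Numeric score per sample (higher = more case-like).
#' @param labels 0/1 vector aligned with `scores`; both classes required.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC requires both classes to be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified discovery split
#'
#' Randomly partitions samples into train/test parts at the requested
#' fraction, stratified by label. The train size is `floor(fraction_train
#' * n)`, allocated across classes by largest remainder; allocations are
#' nudged so both parts retain at least one sample of each class.
#'
#' @param labels Named 0/1 vector (>= 2 samples per class).
#' @param fraction_train Train fraction in (0, 1); default 0.8 (an 8:2
#'   split).
#' @param seed Integer seed; the same seed always yields the same split.
#' @return `list(train = ids, test = ids)` — a partition of the samples.
#' @export
split_discovery <- function(labels, fraction_train = 0.8, seed = 1L) {
  labels <- validate_labels(labels)
  stopifnot(fraction_train > 0, fraction_train < 1)
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2))
    stop("each class needs at least 2 samples to split")
  n <- length(labels)
  target <- floor(fraction_train * n)
  classes <- sort(unique(labels))
  raw <- fraction_train * as.numeric(tab[as.character(classes)])
  k <- floor(raw)
  rem <- target - sum(k)
  if (rem > 0) {
    ord <- order(-(raw - k), classes)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  # keep >= 1 per class on both sides
  for (i in seq_along(classes)) {
    k[i] <- min(max(k[i], 1), tab[as.character(classes[i])] - 1)
  }
  train <- with_stream(seed, "split", {
    unlist(lapply(seq_along(classes), function(i) {
      ids <- names(labels)[labels == classes[i]]
      sample(ids, k[i])
    }), use.names = FALSE)
  })
  train <- names(labels)[names(labels) %in% train]  # preserve input order
  list(train = train, test = setdiff(names(labels), train))
}

#' Stability selection over repeated random splits
#'
#' Repeats, `n_repeats` times: draw a fresh stratified train/test split,
#' fit an L1-penalized logistic regression on the train part (penalty
#' chosen by internal cross-validation at the conservative
#' one-standard-error rule), score the held-out part, and — only when the
#' held-out AUC exceeds `auc_gate` — count each pair with a non-zero
#' coefficient as selected once. Pairs that are selected in a large
#' fraction of repeats are stable biomarker candidates insensitive to the
#' particular split.
#'
#' @param features `pair_features` over the discovery samples.
#' @param labels Named 0/1 vector.
#' @param n_repeats Number of random splits (default 100).
#' @param fraction_train Train fraction per split (default 0.8).
#' @param seed Master seed; each repeat uses its own substream.
#' @param auc_gate Held-out AUC a repeat's model must exceed for its
#'   selections to count (default 0.8).
#' @param nfolds Folds for the internal penalty cross-validation.
#' @return `pairdx_stability`: list with `occurrence` (named count per
#'   pair), `split_auc` (one held-out AUC per repeat), `n_repeats`,
#'   `seed`.
#' @export
stability_select <- function(features, labels, n_repeats = 100,
                             fraction_train = 0.8, seed = 1L,
                             auc_gate = 0.8, nfolds = 5) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  labels <- align_labels(features, labels)
  x <- t(features$values)
  storage.mode(x) <- "double"
  occurrence <- stats::setNames(integer(nrow(features$pairs)),
                                rownames(features$values))
  split_auc <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    sp <- split_discovery(labels, fraction_train,
                          seed = stream_seed(seed, paste0("repeat", r)))
    fit <- with_stream(seed, paste0("fit", r), {
      suppressWarnings(glmnet::cv.glmnet(
        x[sp$train, , drop = FALSE], labels[sp$train],
        family = "binomial", alpha = 1, nfolds = nfolds,
        type.measure = "auc"))
    })
    beta <- stats::coef(fit, s = "lambda.1se")
    sel <- rownames(beta)[-1][as.numeric(beta)[-1] != 0]
    scores <- as.numeric(x[sp$test, , drop = FALSE] %*%
                           as.numeric(beta)[-1]) + as.numeric(beta)[1]
    split_auc[r] <- auc(scores, labels[sp$test])
    if (split_auc[r] > auc_gate && length(sel) > 0)
      occurrence[sel] <- occurrence[sel] + 1L
  }
  structure(list(occurrence = occurrence, split_auc = split_auc,
                 n_repeats = n_repeats, seed = seed, auc_gate = auc_gate),
            class = "pairdx_stability")
}

#' Candidate pairs from a stability-selection result
#'
#' Pairs selected in strictly more than `occurrence_threshold` of the
#' repeats, in descending occurrence order (ties broken lexicographically
#' by pair id).
#'
#' @param stab A `pairdx_stability`.
#' @param occurrence_threshold Count threshold in `[1, n_repeats]`
#'   (default 50, i.e. more than half of 100 repeats).
#' @return `data.frame` with `gene_a`, `gene_b`, `occurrence`.
#' @export
select_candidates <- function(stab, occurrence_threshold = 50) {
  stopifnot(inherits(stab, "pairdx_stability"),
            occurrence_threshold >= 1,
            occurrence_threshold <= stab$n_repeats)
  keep <- stab$occurrence[stab$occurrence > occurrence_threshold]
  if (length(keep) == 0)
    stop("no pair exceeds occurrence threshold ", occurrence_threshold,
         "; relax the threshold or increase n_repeats")
  keep <- keep[order(-keep, names(keep))]
  genes <- do.call(rbind, strsplit(names(keep), "|", fixed = TRUE))
  data.frame(gene_a = genes[, 1], gene_b = genes[, 2],
             occurrence = as.integer(keep), stringsAsFactors = FALSE)
}

#' Tune the occurrence threshold on an evaluation set
#'
#' Walks a grid of occurrence thresholds; for each, builds the candidate
#' set, refits the final sparse logistic model on the training samples,
#' and scores a disjoint evaluation set. Returns the grid value with the
#' best evaluation AUC (ties go to the smaller threshold). Grid values
#' with an empty candidate set are skipped.
#'
#' @param stab A `pairdx_stability`.
#' @param features_train,labels_train Training data for the refits.
#' @param features_eval,labels_eval Disjoint evaluation data.
#' @param grid Candidate thresholds (default 10, 20, ..., 100).
#' @param cv_folds,seed Passed to [fit_final_model()].
#' @return The selected threshold (integer), with attribute
#'   `auc_by_threshold` (named numeric; `NA` where the candidate set was
#'   empty or the fit degenerate).
#' @export
tune_occurrence_threshold <- function(stab, features_train, labels_train,
                                      features_eval, labels_eval,
                                      grid = seq(10L, 100L, by = 10L),
                                      cv_folds = 10, seed = 1L) {
  stopifnot(length(grid) >= 1)
  grid <- sort(unique(as.integer(grid)))
  aucs <- stats::setNames(rep(NA_real_, length(grid)), grid)
  for (i in seq_along(grid)) {
    cand <- tryCatch(select_candidates(stab, grid[i]), error = function(e) NULL)
    if (is.null(cand)) next
    model <- tryCatch(
      fit_final_model(features_train, labels_train, cand,
                      cv_folds = cv_folds, seed = seed),
      error = function(e) NULL)
    if (is.null(model)) next
    scores <- predict(model, features_eval)
    aucs[i] <- auc(scores, labels_eval[features_eval$sample_ids])
  }
  if (all(is.na(aucs)))
    stop("no occurrence threshold yields a non-empty candidate model")
  best <- grid[which.max(aucs)]  # which.max: first max, grid ascending
  structure(best, auc_by_threshold = aucs)
}

new_diag_model <- function(pairs, coefficients, intercept, meta = list()) {
  structure(list(pairs = pairs[, c("gene_a", "gene_b"), drop = FALSE],
                 coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept), meta = meta),
            class = "pairdx_diag_model")
}

#' @export
print.pairdx_diag_model <- function(x, ...) {
  cat("pairdx diagnostic model:", nrow(x$pairs),
      "pairs, intercept", signif(x$intercept, 4), "\n")
  invisible(x)
}

#' Fit the final sparse logistic pair model
#'
#' L1-penalized logistic regression restricted to the candidate pairs,
#' with the penalty chosen to maximize 10-fold cross-validated AUC over
#' glmnet's logarithmic lambda grid; pairs whose coefficient is exactly
#' zero at the chosen penalty are pruned from the returned model. With a
#' single candidate pair an unpenalized logistic fit is used (a lasso
#' path needs >= 2 predictors).
#'
#' @param features_train `pair_features` over the training samples.
#' @param labels_train Named 0/1 vector.
#' @param pairs Candidate pairs (`data.frame` with `gene_a`, `gene_b`).
#' @param cv_folds Cross-validation folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param mixing Elastic-net mixing weight in (0, 1]; 1 (default) is the
#'   pure lasso.
#' @return A `pairdx_diag_model`.
#' @export
fit_final_model <- function(features_train, labels_train, pairs,
                            cv_folds = 10, seed = 1L, mixing = 1) {
  labels_train <- align_labels(features_train, labels_train)
  ids <- pair_id(pairs$gene_a, pairs$gene_b)
  feats <- subset_pairs(features_train, ids)
  x <- t(feats$values)
  storage.mode(x) <- "double"
  y <- labels_train[rownames(x)]
  if (min(table(y)) < cv_folds)
    stop("need at least cv_folds samples per class")
  if (ncol(x) == 1) {
    fit <- stats::glm(y ~ x, family = stats::binomial())
    beta <- stats::coef(fit)[2]
    if (!is.finite(beta) || beta == 0)
      stop("no non-zero coefficient in the final model")
    return(new_diag_model(pairs, beta, stats::coef(fit)[1],
                          meta = list(seed = seed, penalty = "none",
                                      cv_folds = cv_folds)))
  }
  cvfit <- with_stream(seed, "final_fit", {
    suppressWarnings(glmnet::cv.glmnet(x, y, family = "binomial",
                                       alpha = mixing, nfolds = cv_folds,
                                       type.measure = "auc"))
  })
  beta <- stats::coef(cvfit, s = "lambda.min")
  coefs <- as.numeric(beta)[-1]
  keep <- coefs != 0
  if (!any(keep))
    stop("no non-zero coefficient at the selected penalty")
  new_diag_model(pairs[keep, , drop = FALSE], coefs[keep],
                 as.numeric(beta)[1],
                 meta = list(seed = seed, penalty = cvfit$lambda.min,
                             mixing = mixing, cv_folds = cv_folds))
}

#' Predict with a diagnostic pair model
#'
#' @param object A `pairdx_diag_model`.
#' @param features `pair_features` containing every model pair.
#' @param type `"link"` (linear predictor, default) or `"response"`
#'   (probability).
#' @param ... Unused.
#' @return Named numeric vector of per-sample scores.
#' @export
predict.pairdx_diag_model <- function(object, features,
                                      type = c("link", "response"), ...) {
  type <- match.arg(type)
  ids <- pair_id(object$pairs$gene_a, object$pairs$gene_b)
  feats <- subset_pairs(features, ids)
  lp <- as.numeric(crossprod(feats$values, object$coefficients)) +
    object$intercept
  names(lp) <- colnames(feats$values)
  if (type == "response") stats::plogis(lp) else lp
}

#' Tree-ensemble comparator models
#'
#' Fixed-seed default-grid random forest and gradient-boosted-tree fits on
#' the `+1`/`-1` pair features, used only for AUC comparison reports
#' against the sparse logistic model.
#'
#' @param features_train,labels_train Training data.
#' @param pairs Pairs to use as predictors.
#' @param seed Seed.
#' @return List with elements `random_forest` and
#'   `gradient_boosted_trees`, each carrying the fitted model and the pair
#'   ids it expects; see [comparator_aucs()].
#' @export
fit_comparators <- function(features_train, labels_train, pairs, seed = 1L) {
  labels_train <- align_labels(features_train, labels_train)
  ids <- pair_id(pairs$gene_a, pairs$gene_b)
  feats <- subset_pairs(features_train, ids)
  x <- t(feats$values)
  storage.mode(x) <- "double"
  y <- labels_train[rownames(x)]
  rf <- with_stream(seed, "rf", {
    randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                               ntree = 500)
  })
  xgb <- with_stream(seed, "xgb", {
    xgboost::xgboost(x, factor(y, levels = c(0, 1)), nrounds = 100,
                     max_depth = 3, learning_rate = 0.3, nthreads = 1,
                     verbosity = 0)
  })
  structure(list(random_forest = list(model = rf, pair_ids = ids),
                 gradient_boosted_trees = list(model = xgb, pair_ids = ids)),
            class = "pairdx_comparators")
}

#' @rdname fit_comparators
#' @param comparators Result of `fit_comparators()`.
#' @param features,labels Evaluation data.
#' @return `comparator_aucs()`: named numeric vector, one AUC per method.
#' @export
comparator_aucs <- function(comparators, features, labels) {
  stopifnot(inherits(comparators, "pairdx_comparators"))
  labels <- align_labels(features, labels)
  ids <- comparators$random_forest$pair_ids
  x <- t(subset_pairs(features, ids)$values)
  storage.mode(x) <- "double"
  rf_scores <- stats::predict(comparators$random_forest$model, x,
                              type = "prob")[, "1"]
  xgb_scores <- stats::predict(comparators$gradient_boosted_trees$model, x,
                               type = "response")
  c(random_forest = auc(rf_scores, labels[rownames(x)]),
    gradient_boosted_trees = auc(xgb_scores, labels[rownames(x)]))
}
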