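new_prog_model <- function(pairs, coefficients, meta = list()) {
  structure(list(pairs = pairs[, c("gene_a", "gene_b"), drop = FALSE],
                 coefficients = as.numeric(coefficients), meta = meta),
            class = "pairdx_prog_model")
}

#' @export
print.pairdx_prog_model <- function(x, ...) {
  cat("pairdx prognostic (Cox) model:", nrow(x$pairs), "pairs\n")
  invisible(x)
}

# Align a survival table with feature columns; returns df restricted to
# samples present in both, preserving feature order.
align_survival <- function(features, survival) {
  survival <- validate_survival(survival)
  ids <- intersect(colnames(features$values), survival$sample_id)
  if (length(ids) == 0)
    stop("no overlap between feature samples and survival table")
  survival[match(ids, survival$sample_id), , drop = FALSE]
}

#' Univariate Cox regression on one pair feature
#'
#' Partial-likelihood proportional-hazards fit of a single `+1`/`-1`
#' covariate with Wald p-value.
#'
#' @param feature Named `+1`/`-1` vector per sample.
#' @param survival Survival table covering (at least) those samples.
#' @return `list(beta, hazard_ratio, p_value, n)`.
#' @export
univariate_cox <- function(feature, survival) {
  survival <- validate_survival(survival)
  ids <- intersect(names(feature), survival$sample_id)
  if (length(ids) < 3) stop("too few overlapping samples for a Cox fit")
  s <- survival[match(ids, survival$sample_id), ]
  x <- as.numeric(feature[ids])
  if (length(unique(x)) < 2) stop("constant feature")
  if (sum(s$event) < 2) stop("fewer than 2 events")
  fit <- survival::coxph(survival::Surv(s$time, s$event) ~ x)
  sm <- summary(fit)
  list(beta = unname(stats::coef(fit)),
       hazard_ratio = unname(exp(stats::coef(fit))),
       p_value = unname(sm$coefficients[1, "Pr(>|z|)"]),
       n = length(ids))
}

#' Univariate proportional-hazards filter over pairs
#'
#' Screens each pair with [univariate_cox()] and keeps those with
#' two-sided Wald `p < alpha` (unadjusted — this stage is a liberal
#' pre-filter ahead of the penalized multivariable fit), ordered by p
#' ascending. Constant features and pairs with fewer than 2 events are
#' skipped with a message.
#'
#' @param pairs Pair `data.frame`.
#' @param features `pair_features` covering the survival samples.
#' @param survival Survival table.
#' @param alpha Significance level (default 0.05).
#' @return `data.frame` with `gene_a`, `gene_b`, `beta`, `hazard_ratio`,
#'   `p_value`, sorted by `p_value`.
#' @export
filter_univariate <- function(pairs, features, survival, alpha = 0.05) {
  ids <- pair_id(pairs$gene_a, pairs$gene_b)
  feats <- subset_pairs(features, ids)
  rows <- lapply(seq_along(ids), function(i) {
    f <- feats$values[ids[i], ]
    res <- tryCatch(univariate_cox(f, survival), error = function(e) {
      message("skipping pair ", ids[i], ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) return(NULL)
    data.frame(gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
               beta = res$beta, hazard_ratio = res$hazard_ratio,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pair admitted a univariate Cox fit")
  out <- out[out$p_value < alpha, , drop = FALSE]
  if (nrow(out) == 0)
    stop("no pair passes the univariate filter at alpha = ", alpha)
  out <- out[order(out$p_value, pair_id(out$gene_a, out$gene_b)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' L1-penalized Cox regression on pair features
#'
#' Multivariable proportional-hazards fit with lasso penalty; the penalty
#' is chosen by cross-validated partial likelihood at the conservative
#' one-standard-error rule, and zero-coefficient pairs are pruned. The
#' resulting model defines the linear risk score
#' `s_k = sum_p beta_p * r_pk`.
#'
#' @param features `pair_features` covering the survival samples.
#' @param survival Survival table.
#' @param pairs Candidate pairs.
#' @param cv_folds Cross-validation folds (default 10); at least
#'   `cv_folds` events required.
#' @param seed Seed for fold assignment.
#' @param lambda_rule `"lambda.1se"` (default) or `"lambda.min"`.
#' @return A `pairdx_prog_model`.
#' @export
lasso_cox <- function(features, survival, pairs, cv_folds = 10, seed = 1L,
                      lambda_rule = c("lambda.1se", "lambda.min")) {
  lambda_rule <- match.arg(lambda_rule)
  survival <- align_survival(features, survival)
  if (sum(survival$event) < cv_folds)
    stop("need at least cv_folds events for cross-validation")
  ids <- pair_id(pairs$gene_a, pairs$gene_b)
  feats <- subset_pairs(features, ids)
  x <- t(feats$values[, survival$sample_id, drop = FALSE])
  storage.mode(x) <- "double"
  y <- survival::Surv(survival$time, survival$event)
  if (ncol(x) == 1)
    stop("lasso_cox needs >= 2 candidate pairs; use univariate_cox")
  cvfit <- with_stream(seed, "lasso_cox", {
    suppressWarnings(glmnet::cv.glmnet(x, y, family = "cox", alpha = 1,
                                       nfolds = cv_folds))
  })
  beta <- as.numeric(stats::coef(cvfit, s = lambda_rule))
  keep <- beta != 0
  if (!any(keep))
    stop("all Cox coefficients are zero at the selected penalty")
  new_prog_model(pairs[keep, , drop = FALSE], beta[keep],
                 meta = list(seed = seed, cv_folds = cv_folds,
                             lambda = cvfit[[lambda_rule]],
                             lambda_rule = lambda_rule))
}

#' Linear risk score of a prognostic pair model
#'
#' `s_k = sum_p beta_p * r_pk`, the Cox linear predictor (no baseline
#' hazard term: only the ranking matters for stratification and ROC).
#'
#' @param model A `pairdx_prog_model`.
#' @param features `pair_features` containing every model pair.
#' @return Named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(model, features) {
  stopifnot(inherits(model, "pairdx_prog_model"))
  ids <- pair_id(model$pairs$gene_a, model$pairs$gene_b)
  feats <- subset_pairs(features, ids)
  s <- as.numeric(crossprod(feats$values, model$coefficients))
  stats::setNames(s, colnames(feats$values))
}

#' Median split into risk groups
#'
#' Cutoff = median score; samples with `score >= cutoff` are high risk
#' (so with all scores tied every sample is high risk — a documented
#' edge; `+1`/`-1` features make score ties common). For external
#' validation the cutoff learned on a training cohort can be supplied
#' instead of the cohort's own median.
#'
#' @param scores Named numeric vector (>= 2 samples).
#' @param cutoff Score cutoff; defaults to `median(scores)`.
#' @return `data.frame` with `sample_id`, `score`, `group`
#'   (`"high"`/`"low"`); attribute `cutoff`.
#' @export
median_split <- function(scores, cutoff = stats::median(scores)) {
  if (length(scores) < 2) stop("median split needs at least 2 samples")
  if (is.null(names(scores))) stop("scores must be named by sample id")
  out <- data.frame(sample_id = names(scores), score = as.numeric(scores),
                    group = ifelse(scores >= cutoff, "high", "low"),
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  out
}

#' Kaplan-Meier curves and log-rank test for risk strata
#'
#' Product-limit survival estimates per risk group plus the two-group
#' log-rank test.
#'
#' @param strata Result of [median_split()] (columns `sample_id`,
#'   `group`).
#' @param survival Survival table covering the stratified samples.
#' @return List with `curves` (`data.frame`: `group`, `time`, `n_risk`,
#'   `n_event`, `survival`), `logrank_chisq`, `logrank_p`.
#' @export
km_logrank <- function(strata, survival) {
  survival <- validate_survival(survival)
  m <- merge(strata[, c("sample_id", "group")], survival,
             by = "sample_id")
  if (length(unique(m$group)) < 2)
    stop("log-rank comparison needs both risk groups represented")
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = m)
  sm <- summary(sf, censored = FALSE)
  grp <- sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, survival = sm$surv,
                       stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = m)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  list(curves = curves, logrank_chisq = unname(sd_$chisq),
       logrank_p = unname(p))
}

#' Time-dependent AUC (cumulative cases / dynamic controls, IPCW)
#'
#' Discrimination of a risk score at a fixed horizon `t`: cases are
#' subjects with an observed event at or before `t`, controls are
#' subjects still event-free beyond `t`; the AUC is the Mann-Whitney
#' statistic on the scores with cases weighted by inverse
#' probability-of-censoring weights `1 / G(T_i-)` (G = Kaplan-Meier of
#' the censoring distribution) and controls by `1 / G(t)`. Subjects
#' censored before the horizon contribute to neither set (they are
#' handled through the weights). With no censoring this reduces exactly
#' to the plain AUC on the dichotomized outcome.
#'
#' @param scores Named risk scores.
#' @param survival Survival table.
#' @param horizon Time horizon (same unit as the survival times).
#' @return AUC at the horizon.
#' @export
time_dependent_auc <- function(scores, survival, horizon) {
  survival <- validate_survival(survival)
  ids <- intersect(names(scores), survival$sample_id)
  if (length(ids) == 0) stop("no overlap between scores and survival")
  s <- survival[match(ids, survival$sample_id), ]
  sc <- as.numeric(scores[ids])
  case <- s$time <= horizon & s$event == 1L
  ctrl <- s$time > horizon
  if (!any(case))
    stop("no events observed by horizon ", horizon)
  if (!any(ctrl))
    stop("no subjects at risk beyond horizon ", horizon)
  # Kaplan-Meier of the censoring distribution
  cfit <- survival::survfit(survival::Surv(s$time, 1 - s$event) ~ 1)
  G_minus <- stats::stepfun(cfit$time, c(1, cfit$surv), right = TRUE)
  G_right <- stats::stepfun(cfit$time, c(1, cfit$surv), right = FALSE)
  w_case <- 1 / G_minus(s$time[case])
  w_ctrl <- rep(1 / G_right(horizon), sum(ctrl))
  if (any(!is.finite(w_case)) || any(!is.finite(w_ctrl)))
    stop("censoring weights degenerate at horizon ", horizon)
  sc_case <- sc[case]; sc_ctrl <- sc[ctrl]
  conc <- outer(sc_case, sc_ctrl, ">") + 0.5 * outer(sc_case, sc_ctrl, "==")
  num <- as.numeric(w_case %*% conc %*% w_ctrl)
  num / (sum(w_case) * sum(w_ctrl))
}
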