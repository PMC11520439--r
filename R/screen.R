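#' Cross-tabulate a pair feature against case/control labels
#'
#' Counts `+1` / `-1` feature states separately in cases and controls,
#' giving the 2x2 table that the exact screen tests. Table margins always
#' equal the group sizes.
#'
#' @param features A `pair_features` object.
#' @param labels Named 0/1 vector covering every feature sample.
#' @param pair Pair id (`"geneA|geneB"`) or a one-row pair `data.frame`.
#' @return Named integer vector
#'   `c(n_case_pos, n_case_neg, n_ctrl_pos, n_ctrl_neg)`.
#' @export
reversal_table <- function(features, labels, pair) {
  labels <- align_labels(features, labels)
  if (is.data.frame(pair)) pair <- pair_id(pair$gene_a[1], pair$gene_b[1])
  if (!pair %in% rownames(features$values))
    stop("unknown pair: ", pair)
  v <- features$values[pair, ]
  c(n_case_pos = sum(v == 1L & labels == 1L),
    n_case_neg = sum(v == -1L & labels == 1L),
    n_ctrl_pos = sum(v == 1L & labels == 0L),
    n_ctrl_neg = sum(v == -1L & labels == 0L))
}

align_labels <- function(features, labels) {
  labels <- validate_labels(labels)
  miss <- setdiff(colnames(features$values), names(labels))
  if (length(miss) > 0) stop("unlabeled sample: ", miss[1])
  labels[colnames(features$values)]
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact conditional test of association in a 2x2 table using the
#' minimum-likelihood two-sided convention: the p-value is the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed the observed table's (with the
#' customary `1 + 1e-7` relative tolerance on the comparison). This is the
#' convention implemented by standard statistical software, stated here so
#' independent oracles match.
#'
#' @param n_case_pos,n_case_neg,n_ctrl_pos,n_ctrl_neg Non-negative counts;
#'   all four arguments are vectorized.
#' @return p-values in `(0, 1]`.
#' @examples
#' fisher_exact_two_sided(10, 0, 0, 10)  # 2 / choose(20, 10)
#' fisher_exact_two_sided(3, 0, 0, 3)    # 0.1
#' @export
fisher_exact_two_sided <- function(n_case_pos, n_case_neg,
                                   n_ctrl_pos, n_ctrl_neg) {
  a <- as.numeric(n_case_pos); b <- as.numeric(n_case_neg)
  cc <- as.numeric(n_ctrl_pos); d <- as.numeric(n_ctrl_neg)
  if (any(c(a, b, cc, d) < 0) || any(c(a, b, cc, d) != floor(c(a, b, cc, d))))
    stop("counts must be non-negative integers")
  n <- max(length(a), length(b), length(cc), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  cc <- rep_len(cc, n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    n1 <- a[i] + b[i]; n2 <- cc[i] + d[i]; k <- a[i] + cc[i]
    if (n1 == 0 || n2 == 0 || k == 0 || k == n1 + n2) return(1)
    lo <- max(0, k - n2); hi <- min(k, n1)
    xs <- lo:hi
    probs <- stats::dhyper(xs, n1, n2, k)
    pobs <- stats::dhyper(a[i], n1, n2, k)
    min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Bonferroni adjustment
#'
#' Family-wise error control: `min(1, p * n_tests)`.
#'
#' @param p_raw Raw p-values in `(0, 1]`.
#' @param n_tests Number of hypotheses tested (>= 1).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_raw, n_tests) {
  stopifnot(n_tests >= 1, all(p_raw > 0), all(p_raw <= 1))
  pmin(1, p_raw * n_tests)
}

#' Screen gene pairs for reversed relative expression
#'
#' For every pair, cross-tabulates the `+1`/`-1` state against the
#' case/control label and applies the two-sided Fisher exact test with
#' Bonferroni correction over the pairs actually tested. A pair is a
#' differential gene pair (DGP) when its adjusted p-value falls below
#' `alpha_threshold` (default `1e-20`, a deliberately stringent
#' family-wise level that suppresses batch-driven false positives when
#' many thousands of pairs are screened across pooled cohorts).
#'
#' @param features A `pair_features` object.
#' @param labels Named 0/1 vector; every sample must be labeled and both
#'   classes present.
#' @param alpha_threshold Significance level applied to the
#'   Bonferroni-adjusted p-value.
#' @return `data.frame` sorted by raw p (ties broken by pair id) with
#'   columns `gene_a`, `gene_b`, the four table counts, `p_raw`, `p_adj`,
#'   `direction` (`case_enriched_pos`/`case_enriched_neg`) and
#'   `significant`.
#' @export
screen_pairs <- function(features, labels, alpha_threshold = 1e-20) {
  labels <- align_labels(features, labels)
  n_case <- sum(labels == 1L); n_ctrl <- sum(labels == 0L)
  if (n_case == 0 || n_ctrl == 0)
    stop("screening requires at least one case and one control")
  pos <- features$values == 1L
  a <- as.integer(pos %*% (labels == 1L))
  cpos <- as.integer(pos %*% (labels == 0L))
  b <- n_case - a
  d <- n_ctrl - cpos
  p_raw <- fisher_exact_two_sided(a, b, cpos, d)
  p_adj <- bonferroni(p_raw, length(p_raw))
  res <- data.frame(
    gene_a = features$pairs$gene_a,
    gene_b = features$pairs$gene_b,
    n_case_pos = a, n_case_neg = b,
    n_ctrl_pos = cpos, n_ctrl_neg = d,
    p_raw = p_raw, p_adj = p_adj,
    direction = ifelse(a / n_case >= cpos / n_ctrl,
                       "case_enriched_pos", "case_enriched_neg"),
    significant = p_adj < alpha_threshold,
    stringsAsFactors = FALSE)
  ord <- order(res$p_raw, pair_id(res$gene_a, res$gene_b))
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "alpha_threshold") <- alpha_threshold
  attr(res, "n_tests") <- nrow(res)
  res
}
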