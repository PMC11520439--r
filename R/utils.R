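#' @importFrom stats dhyper phyper rnorm runif rexp median pchisq approx
#'   setNames rank p.adjust quantile sd t.test
#' @importFrom utils read.delim write.table
NULL

#' Number of unordered gene pairs
#'
#' Count of distinct unordered pairs among `n_genes` genes, `n (n - 1) / 2`.
#' At transcriptome scale this motivates restricting candidate pairs to
#' within-pathway combinations: 10,762 genes alone yield over 57 million
#' pairs.
#'
#' @param n_genes Number of genes (non-negative integer).
#' @return The pair count as a double (counts exceed integer range quickly).
#' @examples
#' n_possible_pairs(4)      # 6
#' n_possible_pairs(10762)  # > 57 million
#' @export
n_possible_pairs <- function(n_genes) {
  stopifnot(length(n_genes) == 1, is.numeric(n_genes), n_genes >= 0,
            n_genes == floor(n_genes))
  n_genes * (n_genes - 1) / 2
}

# Deterministic per-stage substream seed derived from one user seed and a
# stream label. Keeps results for one stage stable when another stage's
# draw count changes. Result always in [1, 2^31 - 2].
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  cp <- utf8ToInt(stream)
  h <- sum(cp * seq_along(cp)) %% 104729
  as.integer(((abs(as.numeric(seed)) %% 48611) * 44111 + h * 7919) %% 2147483629) + 1L
}

# Evaluate expr under a temporary RNG seed, restoring RNG state afterwards.
with_stream <- function(seed, stream, expr) {
  withr::with_seed(stream_seed(seed, stream), expr)
}

# Canonical pair identifier. Orientation is fixed lexicographically
# (gene_a < gene_b) before any statistic is computed, so serialized models
# are portable; the Fisher screen is orientation-symmetric and model
# coefficients absorb the sign.
pair_id <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "|")

# Build a canonical, deduplicated pair table from two id vectors.
canonical_pairs <- function(gene_a, gene_b) {
  stopifnot(length(gene_a) == length(gene_b))
  if (any(gene_a == gene_b))
    stop("a gene pair must consist of two distinct genes: ",
         gene_a[which(gene_a == gene_b)[1]])
  swap <- gene_a > gene_b
  tmp <- gene_a[swap]; gene_a[swap] <- gene_b[swap]; gene_b[swap] <- tmp
  df <- data.frame(gene_a = gene_a, gene_b = gene_b,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(pair_id(df$gene_a, df$gene_b)), , drop = FALSE]
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

assert_finite_matrix <- function(m, what = "expression matrix") {
  if (!all(is.finite(m)))
    stop(what, " contains non-finite values")
  invisible(m)
}

# Validate a genes x samples numeric matrix with unique dimnames.
validate_expression <- function(values, cohort_id = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix (genes x samples)")
  g <- rownames(values); s <- colnames(values)
  if (is.null(g) || is.null(s))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(g))
    stop("duplicate gene id: ", g[duplicated(g)][1])
  if (anyDuplicated(s))
    stop("duplicate sample id: ", s[duplicated(s)][1])
  assert_finite_matrix(values)
  if (!is.null(cohort_id)) attr(values, "cohort_id") <- cohort_id
  values
}

# Validate a named 0/1 label vector.
validate_labels <- function(labels) {
  ids <- names(labels)
  if (is.null(ids) || anyDuplicated(ids))
    stop("labels must be a named vector with unique sample ids")
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0 (control) or 1 (case); found: ",
         paste(unique(labels[!labels %in% c(0L, 1L)]), collapse = ", "))
  stats::setNames(as.integer(labels), ids)
}

validate_survival <- function(surv) {
  stopifnot(is.data.frame(surv),
            all(c("sample_id", "time", "event") %in% names(surv)))
  if (anyDuplicated(surv$sample_id))
    stop("duplicate sample id in survival table: ",
         surv$sample_id[duplicated(surv$sample_id)][1])
  if (!all(is.finite(surv$time)) || any(surv$time <= 0))
    stop("survival times must be positive and finite")
  if (!all(surv$event %in% c(0L, 1L)))
    stop("survival event indicator must be 0 (censored) or 1 (event)")
  surv$event <- as.integer(surv$event)
  surv
}

fmt_num <- function(x) sprintf("%.17g", x)
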