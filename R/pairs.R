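#' Within-sample relative expression of a gene pair
#'
#' The core rank-based transform: for one sample, the pair feature is
#' `+1` if the first gene's expression strictly exceeds the second's and
#' `-1` otherwise (exact ties map to `-1`, the sign-indicator convention
#' `I(x <= 0) = -1`). Because only the within-sample ordering enters, the
#' feature is invariant to any strictly increasing per-sample transform —
#' the property that lets cohorts from different platforms be pooled
#' without batch correction.
#'
#' @param g_a,g_b Finite expression values (vectorized).
#' @return Integer vector of `+1` / `-1`.
#' @examples
#' relative_expression(5.2, 3.1)  # +1
#' relative_expression(2.0, 2.0)  # -1 (tie)
#' @export
relative_expression <- function(g_a, g_b) {
  if (!all(is.finite(g_a)) || !all(is.finite(g_b)))
    stop("relative_expression requires finite inputs")
  ifelse(g_a > g_b, 1L, -1L)
}

#' Candidate gene pairs restricted to pathways
#'
#' For each gene set, intersects the members with the measured genes and
#' emits all unordered pairs of the intersection; the union over sets is
#' deduplicated and returned in canonical lexicographic order
#' (`gene_a < gene_b`). Pathway restriction keeps the candidate space
#' biologically focused and computationally tractable (all-vs-all pairing
#' at transcriptome scale runs to tens of millions of combinations, see
#' [n_possible_pairs()]).
#'
#' @param sets Gene-set collection as returned by [read_gmt()].
#' @param matrix_genes Character vector of measured gene ids.
#' @return `data.frame` with columns `gene_a`, `gene_b`.
#' @export
candidate_pairs <- function(sets, matrix_genes) {
  stopifnot(is.list(sets), length(sets) > 0)
  per_set <- lapply(sets, function(members) {
    inter <- sort(intersect(members, matrix_genes))
    if (length(inter) < 2) return(NULL)
    idx <- utils::combn(length(inter), 2)
    data.frame(gene_a = inter[idx[1, ]], gene_b = inter[idx[2, ]],
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_set)
  if (is.null(all) || nrow(all) == 0)
    stop("no gene set shares >= 2 genes with the expression matrix; ",
         "check that gene identifiers match between the GMT and the matrix")
  canonical_pairs(all$gene_a, all$gene_b)
}

#' Pair feature matrix from an expression matrix
#'
#' Computes the `+1`/`-1` relative-expression feature for every requested
#' pair in every sample. Column order follows the expression matrix's
#' sample order.
#'
#' @param expr Genes x samples numeric matrix with dimnames.
#' @param pairs `data.frame` with columns `gene_a`, `gene_b`.
#' @return A `pair_features` object: list with `pairs` (canonical pair
#'   table), `sample_ids`, and `values` (pairs x samples integer matrix of
#'   `+1`/`-1`, rownames `gene_a|gene_b`).
#' @export
pair_feature_matrix <- function(expr, pairs) {
  expr <- validate_expression(expr)
  pairs <- canonical_pairs(pairs$gene_a, pairs$gene_b)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(expr))
  if (length(missing) > 0)
    stop("pair gene absent from expression matrix: ", missing[1])
  a <- expr[pairs$gene_a, , drop = FALSE]
  b <- expr[pairs$gene_b, , drop = FALSE]
  values <- matrix(ifelse(a > b, 1L, -1L), nrow = nrow(pairs),
                   dimnames = list(pair_id(pairs$gene_a, pairs$gene_b),
                                   colnames(expr)))
  new_pair_features(pairs, values)
}

new_pair_features <- function(pairs, values) {
  structure(list(pairs = pairs, sample_ids = colnames(values),
                 values = values),
            class = "pair_features")
}

#' @export
print.pair_features <- function(x, ...) {
  cat("pair_features:", nrow(x$pairs), "pairs x", length(x$sample_ids),
      "samples\n")
  invisible(x)
}

# Subset a pair_features object to a pair-id vector (keeping given order).
subset_pairs <- function(features, ids) {
  miss <- setdiff(ids, rownames(features$values))
  if (length(miss) > 0) stop("pair missing from features: ", miss[1])
  new_pair_features(features$pairs[match(ids, rownames(features$values)), ,
                                   drop = FALSE],
                    features$values[ids, , drop = FALSE])
}

#' Concatenate pair features across cohorts
#'
#' Computes pair features independently within each cohort (no
#' cross-cohort numeric mixing ever occurs — the point of the pair
#' transform) and column-concatenates the resulting `+1`/`-1` matrices.
#' Sample ids must be globally unique; with `prefix = "auto"` cohort ids
#' are prepended (separated by `.`) only when a collision would otherwise
#' occur.
#'
#' @param cohorts Named list (names = cohort ids) of
#'   `list(expr = matrix, labels = named 0/1 vector)`.
#' @param pairs Pair `data.frame`; every pair gene must be measured in
#'   every cohort.
#' @param prefix `"auto"`, `"always"`, or `"never"`.
#' @return List with `features` (a `pair_features` over all samples) and
#'   `labels` (named 0/1 vector aligned to the feature columns).
#' @export
concat_cohorts <- function(cohorts, pairs,
                           prefix = c("auto", "always", "never")) {
  prefix <- match.arg(prefix)
  stopifnot(is.list(cohorts), length(cohorts) > 0)
  if (is.null(names(cohorts)) || anyDuplicated(names(cohorts)))
    stop("cohorts must be a uniquely named list")
  pairs <- canonical_pairs(pairs$gene_a, pairs$gene_b)
  genes_needed <- unique(c(pairs$gene_a, pairs$gene_b))
  for (cid in names(cohorts)) {
    miss <- setdiff(genes_needed, rownames(cohorts[[cid]]$expr))
    if (length(miss) > 0)
      stop("gene ", miss[1], " missing in cohort ", cid)
  }
  raw_ids <- unlist(lapply(cohorts, function(co) colnames(co$expr)),
                    use.names = FALSE)
  do_prefix <- switch(prefix,
                      always = TRUE, never = FALSE,
                      auto = anyDuplicated(raw_ids) > 0)
  feats <- vector("list", length(cohorts))
  labs <- vector("list", length(cohorts))
  for (i in seq_along(cohorts)) {
    cid <- names(cohorts)[i]
    co <- cohorts[[i]]
    f <- pair_feature_matrix(co$expr, pairs)
    lab <- validate_labels(co$labels)
    miss_lab <- setdiff(colnames(f$values), names(lab))
    if (length(miss_lab) > 0)
      stop("sample ", miss_lab[1], " in cohort ", cid, " has no label")
    lab <- lab[colnames(f$values)]
    if (do_prefix) {
      colnames(f$values) <- paste(cid, colnames(f$values), sep = ".")
      names(lab) <- colnames(f$values)
      f$sample_ids <- colnames(f$values)
    }
    feats[[i]] <- f
    labs[[i]] <- lab
  }
  values <- do.call(cbind, lapply(feats, `[[`, "values"))
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    stop("sample id collision across cohorts: ", dup,
         " (use prefix = \"always\")")
  }
  labels <- do.call(c, labs)
  list(features = new_pair_features(pairs, values), labels = labels)
}
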