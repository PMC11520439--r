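#' Hypergeometric upper-tail probability
#'
#' `P(X >= overlap)` for `X ~ Hypergeometric(universe_size, set_size,
#' list_size)`: the chance that a random gene list of the same size drawn
#' from the universe hits the set at least as often as observed.
#'
#' @param overlap Observed overlap count.
#' @param list_size Size of the query gene list (within the universe).
#' @param set_size Size of the gene set (within the universe).
#' @param universe_size Size of the gene universe.
#' @return Upper-tail probability in `(0, 1]`.
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeom_upper_tail <- function(overlap, list_size, set_size,
                                 universe_size) {
  ok <- overlap >= 0 & list_size >= 0 & set_size >= 0 &
    universe_size >= pmax(list_size, set_size) &
    overlap <= pmin(list_size, set_size)
  if (!all(ok)) stop("inconsistent hypergeometric counts")
  stats::phyper(overlap - 1, set_size, universe_size - set_size,
                list_size, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' Hypergeometric over-representation of a gene list against a gene-set
#' collection, restricted to a stated gene universe (typically the genes
#' measured in the analysis). Sets and the query list are intersected
#' with the universe before testing; one result per set with at least one
#' universe member; adjustment is over the sets actually tested. The
#' collection is annotation-agnostic — GO, KEGG or Reactome enter only as
#' GMT files.
#'
#' @param genes Query gene ids.
#' @param sets Gene-set collection ([read_gmt()]).
#' @param universe Universe gene ids; the query is intersected with it.
#' @param adjust `"benjamini_hochberg"` (default) or `"bonferroni"`.
#' @return `data.frame` sorted by raw p: `set_name`, `overlap`,
#'   `list_size`, `set_size`, `universe_size`, `p_raw`, `p_adj`.
#' @export
enrich <- function(genes, sets, universe,
                   adjust = c("benjamini_hochberg", "bonferroni")) {
  adjust <- match.arg(adjust)
  universe <- unique(universe)
  genes <- intersect(unique(genes), universe)
  if (length(genes) == 0)
    stop("query gene list has no overlap with the universe")
  sets_u <- lapply(sets, intersect, universe)
  sets_u <- sets_u[lengths(sets_u) > 0]
  if (length(sets_u) == 0) stop("no gene set overlaps the universe")
  overlap <- vapply(sets_u, function(s) length(intersect(s, genes)),
                    integer(1))
  set_size <- lengths(sets_u)
  p_raw <- hypergeom_upper_tail(overlap, length(genes), set_size,
                                length(universe))
  p_adj <- stats::p.adjust(p_raw, method = switch(adjust,
                                                  benjamini_hochberg = "BH",
                                                  bonferroni = "bonferroni"))
  out <- data.frame(set_name = names(sets_u), overlap = overlap,
                    list_size = length(genes), set_size = set_size,
                    universe_size = length(universe),
                    p_raw = p_raw, p_adj = p_adj,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
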