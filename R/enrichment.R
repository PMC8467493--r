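#' Read gene sets from a GMT file
#'
#' Tab-delimited GMT dialect: term id, description, then member genes.
#' Parsing is delegated to `fgsea::gmtPathways()`.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list, term id -> character vector of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test per gene set: with a universe
#' of N genes, a term of K genes, a selection of n genes and overlap k, the
#' p-value is P(X >= k) for X ~ Hypergeometric(N, K, n). Selected genes
#' outside the universe are dropped with a warning; term genes are
#' intersected with the universe. No multiple-testing correction is applied
#' by default (mirroring raw-p-threshold practice); Benjamini-Hochberg
#' adjustment is available via `p_adjust`.
#'
#' @param selected Character vector of selected gene ids.
#' @param gene_sets Named list, term id -> gene ids (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector: the gene universe against which
#'   over-representation is judged. Required; there is no safe default.
#' @param alpha Significance threshold on the (possibly adjusted) p-value;
#'   default 0.001.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return A data.frame of significant terms in ascending p order with
#'   columns `term_id`, `overlap`, `term_size`, `selection_size`,
#'   `universe_size`, `p_value` (and `p_adjusted` when adjustment is on).
#' @export
ora <- function(selected, gene_sets, universe, alpha = 0.001,
                p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  selected <- unique(selected)
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    warning(length(outside), " selected gene(s) outside the universe dropped")
    selected <- intersect(selected, universe)
  }
  n <- length(selected)
  N <- length(universe)
  rows <- lapply(names(gene_sets), function(tid) {
    term <- intersect(unique(gene_sets[[tid]]), universe)
    K <- length(term)
    k <- length(intersect(term, selected))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, overlap = k, term_size = K,
               selection_size = n, universe_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame())
  if (p_adjust == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p_value, "BH")
    res <- res[res$p_adjusted < alpha, , drop = FALSE]
    res <- res[order(res$p_adjusted, res$p_value), , drop = FALSE]
  } else {
    res <- res[res$p_value < alpha, , drop = FALSE]
    res <- res[order(res$p_value), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}
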