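#' Three-state discretization of an expression matrix
#'
#' Per gene, values below mean - sd map to -1, above mean + sd to +1, and to
#' 0 otherwise (strict comparisons; a constant gene maps entirely to 0).
#' This is the classical three-level scheme used by mutual-information
#' feature-ranking programs for continuous inputs.
#'
#' @param ds A [labeled_dataset()] or a numeric matrix (cells x genes).
#' @return A list of class `discretized_matrix` with `states` (integer
#'   matrix in \{-1, 0, 1\}, same dimnames as the input) and `thresholds`
#'   (genes x 2 matrix of the low/high cut points).
#' @export
discretize_expression <- function(ds) {
  m <- if (inherits(ds, "labeled_dataset")) ds$x else ds
  stopifnot(is.matrix(m), is.numeric(m))
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  lo <- mu - sd
  hi <- mu + sd
  states <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  states[sweep(m, 2, lo, "<")] <- -1L
  states[sweep(m, 2, hi, ">")] <- 1L
  structure(list(states = states,
                 thresholds = cbind(low = lo, high = hi)),
            class = "discretized_matrix")
}

#' Mutual information of two discrete vectors
#'
#' Plug-in estimator over the empirical joint contingency table, in bits
#' (log base 2). `mutual_information(x, x)` equals the empirical entropy
#' of `x`.
#'
#' @param x,y Vectors of equal length (any discrete values).
#' @return Non-negative mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (!length(x)) stop("empty vectors")
  joint <- table(x, y)
  n <- sum(joint)
  p <- joint / n
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

#' Rank genes by greedy minimum-redundancy maximum-relevance
#'
#' Greedy forward selection under the mutual-information difference (MID)
#' criterion: the first pick maximizes MI(gene, label); each subsequent pick
#' maximizes MI(gene, label) minus the mean MI between the gene and the
#' already-selected set. Ties are broken by input gene order. The full input
#' is ranked (selection runs to exhaustion), yielding a total importance
#' order for incremental feature selection.
#'
#' @param dm A `discretized_matrix` from [discretize_expression()], or a
#'   [labeled_dataset()] (discretized internally).
#' @param labels Class tags, one per cell (not needed when `dm` is a
#'   `labeled_dataset`).
#' @return An object of class `ranked_genes`: list with `gene_ids` (rank
#'   order, best first) and `scores` (the MID score of each gene at the
#'   moment it was selected).
#' @export
rank_mrmr <- function(dm, labels = NULL) {
  if (inherits(dm, "labeled_dataset")) {
    labels <- dm$labels
    dm <- discretize_expression(dm)
  }
  stopifnot(inherits(dm, "discretized_matrix"))
  states <- dm$states
  if (is.null(labels)) stop("'labels' required")
  if (length(labels) != nrow(states)) stop("label length mismatch")
  g <- ncol(states)
  if (g < 1) stop("need at least one gene")
  genes <- colnames(states)

  relevance <- vapply(seq_len(g),
                      function(j) mutual_information(states[, j], labels),
                      numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(g)        # sum of MI(candidate, s) over selected s
  remaining <- seq_len(g)
  while (length(remaining)) {
    crit <- if (length(selected))
      relevance[remaining] - red_sum[remaining] / length(selected)
    else relevance[remaining]
    pick <- remaining[which.max(crit)]   # first max = input-order tie-break
    selected <- c(selected, pick)
    scores <- c(scores, max(crit))
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j)
          mutual_information(states[, j], states[, pick]), numeric(1))
  }
  structure(list(gene_ids = genes[selected], scores = scores),
            class = "ranked_genes")
}

#' @export
print.ranked_genes <- function(x, n = 10, ...) {
  cat(sprintf("ranked_genes: %d genes (MID greedy order)\n",
              length(x$gene_ids)))
  top <- utils::head(data.frame(rank = seq_along(x$gene_ids),
                                gene_id = x$gene_ids,
                                score = x$scores), n)
  print(top, row.names = FALSE)
  if (length(x$gene_ids) > n) cat("...\n")
  invisible(x)
}

#' Write / read a ranked gene list
#'
#' Two-column delimited file (rank, gene_id), plus the selection-time score.
#'
#' @param ranked A `ranked_genes` object.
#' @param path Output path.
#' @return Invisibly, the data.frame written.
#' @export
write_ranked_genes <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_genes"))
  df <- data.frame(rank = seq_along(ranked$gene_ids),
                   gene_id = ranked$gene_ids,
                   score = ranked$scores)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

read_ranked_genes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df <- df[order(df$rank), ]
  structure(list(gene_ids = df$gene_id, scores = df$score),
            class = "ranked_genes")
}
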