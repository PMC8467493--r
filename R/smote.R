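#' Balance class sizes by synthetic minority oversampling (SMOTE)
#'
#' For every class smaller than the largest one, synthetic cells are added
#' until all classes have the majority-class count. Each synthetic cell is a
#' convex interpolation c = a + r (b - a), r ~ Uniform(0, 1), between a
#' randomly chosen member `a` of the minority class and one of its `k`
#' nearest same-class neighbors `b` (Euclidean distance on the feature set
#' passed in; `k` is capped at class size - 1, and distance ties are broken
#' by cell order). Original cells are kept unchanged.
#'
#' @param ds A [labeled_dataset()]; every minority class needs >= 2 cells.
#' @param k Number of nearest neighbors considered (default 5).
#' @param seed Integer seed; identical inputs and seed give identical
#'   output.
#' @return A `labeled_dataset` that additionally carries a `provenance`
#'   factor ("original"/"synthetic", one entry per cell) and a `parents`
#'   data.frame (synthetic cell id, the two parent cell ids), and inherits
#'   class `balanced_dataset`.
#' @export
smote_balance <- function(ds, k = 5, seed = 1) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (k < 1) stop("'k' must be >= 1")
  sz <- table(ds$labels)
  target <- max(sz)
  small <- names(sz)[sz < target]
  if (any(sz[small] < 2))
    stop("cannot oversample a class with a single cell: ",
         paste(names(sz)[sz == 1], collapse = ", "))
  set.seed(seed)
  new_rows <- list()
  new_labels <- character(0)
  parent_rows <- list()
  for (cl in small) {
    idx <- which(ds$labels == cl)
    xc <- ds$x[idx, , drop = FALSE]
    n <- length(idx)
    kk <- min(k, n - 1)
    d <- as.matrix(stats::dist(xc))
    # neighbor lists: k nearest, ties by cell order (order() is stable)
    nb <- lapply(seq_len(n), function(i) {
      ord <- order(d[i, ])
      ord <- ord[ord != i]
      ord[seq_len(kk)]
    })
    need <- target - n
    a_idx <- sample.int(n, need, replace = TRUE)
    b_idx <- vapply(a_idx, function(i) nb[[i]][sample.int(kk, 1)],
                    integer(1))
    r <- stats::runif(need)
    synth <- xc[a_idx, , drop = FALSE] +
      r * (xc[b_idx, , drop = FALSE] - xc[a_idx, , drop = FALSE])
    rownames(synth) <- sprintf("smote_%s_%04d", make.names(cl),
                               seq_len(need))
    new_rows[[cl]] <- synth
    new_labels <- c(new_labels, rep(cl, need))
    parent_rows[[cl]] <- data.frame(cell_id = rownames(synth),
                                    parent_a = rownames(xc)[a_idx],
                                    parent_b = rownames(xc)[b_idx],
                                    stringsAsFactors = FALSE)
  }
  if (length(new_rows)) {
    m <- rbind(ds$x, do.call(rbind, new_rows))
    labels <- factor(c(as.character(ds$labels), new_labels),
                     levels = levels(ds$labels))
  } else {
    m <- ds$x
    labels <- ds$labels
  }
  out <- labeled_dataset(m, labels)
  out$provenance <- factor(rep(c("original", "synthetic"),
                               c(nrow(ds$x), nrow(m) - nrow(ds$x))),
                           levels = c("original", "synthetic"))
  out$parents <- if (length(parent_rows)) do.call(rbind, c(parent_rows,
                                                           make.row.names = FALSE))
                 else data.frame(cell_id = character(),
                                 parent_a = character(),
                                 parent_b = character())
  class(out) <- c("balanced_dataset", class(out))
  out
}
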