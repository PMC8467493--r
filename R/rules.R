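#' Train a fully grown classification tree for rule extraction
#'
#' Fits a CART tree (Gini splits, no complexity penalty, minimum node size
#' 1) on the dataset restricted to a gene subset — typically the optimum
#' set found by incremental feature selection. The tree is grown to purity
#' up to the implementation's depth cap of 30, since its purpose is an
#' exhaustive, interpretable partition of the training cells rather than
#' generalization.
#'
#' @param ds A [labeled_dataset()] (by default the original, unbalanced
#'   cells; pass a [smote_balance()]d dataset for balanced training).
#' @param genes Gene subset to train on (default: all genes).
#' @param seed Unused by the deterministic tree; kept for interface
#'   symmetry with the other trainers.
#' @return An object of class `rule_tree` wrapping the fitted `rpart` tree.
#' @export
train_rule_tree <- function(ds, genes = NULL, seed = 1) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (is.null(genes)) genes <- colnames(ds$x)
  if (!length(genes)) stop("empty gene subset")
  missing <- setdiff(genes, colnames(ds$x))
  if (length(missing)) stop("unknown gene(s): ",
                            paste(utils::head(missing, 5), collapse = ", "))
  x <- ds$x[, genes, drop = FALSE]
  if (nlevels(ds$labels) == 1) {
    # a single class needs no splits; represent the trivial one-leaf tree
    return(structure(list(fit = NULL, genes = genes,
                          levels = levels(ds$labels), n = nrow(x)),
                     class = "rule_tree"))
  }
  colnames(x) <- paste0("g", seq_along(genes))
  df <- as.data.frame(x)
  df$.class <- ds$labels
  fit <- rpart::rpart(.class ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        minsplit = 2, minbucket = 1, cp = 0, xval = 0,
                        maxcompete = 0, maxsurrogate = 0, maxdepth = 30))
  structure(list(fit = fit, genes = genes,
                 levels = levels(ds$labels), n = nrow(x)),
            class = "rule_tree")
}

#' @export
print.rule_tree <- function(x, ...) {
  n_leaves <- if (is.null(x$fit)) 1L else sum(x$fit$frame$var == "<leaf>")
  cat(sprintf("rule_tree: %d genes, %d training cells, %d leaves\n",
              length(x$genes), x$n, n_leaves))
  invisible(x)
}

#' Extract root-to-leaf decision rules from a fitted tree
#'
#' One rule per leaf: the ordered conjunction of threshold conditions along
#' the path from the root, the leaf's majority class, its support (training
#' cells reaching the leaf) and purity (majority fraction). A single-leaf
#' tree yields one rule with an empty condition list. Relations are
#' recorded as `<=` (left branch) and `>` (right branch) on the split
#' threshold.
#'
#' @param tree A `rule_tree` from [train_rule_tree()].
#' @return An object of class `rule_set`: a list of rules, each a list with
#'   `conditions` (data.frame gene/relation/threshold), `class`, `support`,
#'   `purity`.
#' @export
extract_rules <- function(tree) {
  stopifnot(inherits(tree, "rule_tree"))
  if (is.null(tree$fit)) {
    rule <- list(conditions = data.frame(gene = character(),
                                         relation = character(),
                                         threshold = numeric(),
                                         stringsAsFactors = FALSE),
                 class = tree$levels[1], support = tree$n, purity = 1)
    return(structure(list(rule), class = "rule_set",
                     classes = tree$levels, genes = tree$genes))
  }
  fit <- tree$fit
  frame <- fit$frame
  nodes <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  ylevels <- attr(fit, "ylevels")
  K <- length(ylevels)

  # with maxcompete = maxsurrogate = 0, splits rows follow internal nodes
  # in frame order
  internal_idx <- which(!is_leaf)
  split_info <- NULL
  if (length(internal_idx)) {
    sp <- fit$splits
    split_info <- data.frame(
      node = nodes[internal_idx],
      var = as.character(frame$var[internal_idx]),
      threshold = sp[seq_along(internal_idx), "index"],
      ncat = sp[seq_along(internal_idx), "ncat"],
      stringsAsFactors = FALSE)
    rownames(split_info) <- split_info$node
  }
  gene_of <- stats::setNames(tree$genes, paste0("g", seq_along(tree$genes)))

  rules <- lapply(which(is_leaf), function(j) {
    leaf <- nodes[j]
    conds <- list()
    nd <- leaf
    while (nd > 1) {
      parent <- nd %/% 2
      left <- nd %% 2 == 0
      si <- split_info[as.character(parent), ]
      # ncat -1: left branch takes values below the threshold
      below <- if (si$ncat == -1) left else !left
      conds[[length(conds) + 1L]] <-
        data.frame(gene = gene_of[[si$var]],
                   relation = if (below) "<=" else ">",
                   threshold = si$threshold,
                   stringsAsFactors = FALSE)
      nd <- parent
    }
    conditions <- if (length(conds))
      do.call(rbind, rev(conds))
    else
      data.frame(gene = character(), relation = character(),
                 threshold = numeric(), stringsAsFactors = FALSE)
    counts <- frame$yval2[j, 1 + seq_len(K)]
    list(conditions = conditions,
         class = ylevels[frame$yval[j]],
         support = frame$n[j],
         purity = max(counts) / sum(counts))
  })
  structure(rules, class = "rule_set",
            classes = tree$levels, genes = tree$genes)
}

#' @export
print.rule_set <- function(x, n = 10, ...) {
  cat(sprintf("rule_set: %d rules over %d classes\n",
              length(x), length(attr(x, "classes"))))
  for (i in seq_len(min(n, length(x)))) {
    r <- x[[i]]
    cat(sprintf("  [%d] IF %s THEN %s (support %d, purity %.2f)\n", i,
                rule_condition_string(r), r$class, r$support, r$purity))
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

rule_condition_string <- function(rule) {
  if (!nrow(rule$conditions)) return("TRUE")
  paste(sprintf("%s %s %.4g", rule$conditions$gene,
                rule$conditions$relation, rule$conditions$threshold),
        collapse = " AND ")
}

#' Evaluate which rule each cell satisfies
#'
#' Applies every rule's conjunction to an expression matrix. Because the
#' rules of one tree are complementary root-to-leaf paths, each cell
#' satisfies exactly one rule.
#'
#' @param rules A `rule_set`.
#' @param x Expression matrix (cells x genes) containing the rule genes.
#' @return Integer vector: index of the (unique) satisfied rule per cell,
#'   `NA` where no rule fires.
#' @export
match_rules <- function(rules, x) {
  stopifnot(inherits(rules, "rule_set"), is.matrix(x))
  sat <- vapply(rules, function(r) {
    ok <- rep(TRUE, nrow(x))
    for (i in seq_len(nrow(r$conditions))) {
      v <- x[, r$conditions$gene[i]]
      ok <- ok & if (r$conditions$relation[i] == "<=")
        v <= r$conditions$threshold[i] else v > r$conditions$threshold[i]
    }
    ok
  }, logical(nrow(x)))
  if (nrow(x) == 1) sat <- matrix(sat, nrow = 1)
  hits <- rowSums(sat)
  out <- rep(NA_integer_, nrow(x))
  out[hits == 1] <- apply(sat[hits == 1, , drop = FALSE], 1, which)
  attr(out, "n_satisfied") <- hits
  out
}

#' Per-class exclusive genes
#'
#' A gene is exclusive to a class when it appears in at least one rule
#' predicting that class and in no rule predicting any other class
#' (occurrence is by gene, regardless of the relation's direction). Classes
#' without exclusive genes are absent from the report. Note that in a
#' single tree grown to complete purity every split gene lies on paths to
#' leaves of at least two classes, so exclusive genes arise only from
#' depth-capped or otherwise impure trees, or from rule sets filtered or
#' pooled by other means.
#'
#' @param rules A `rule_set` (or any list of rules with `conditions` and
#'   `class` fields).
#' @return Named list, class tag -> character vector of exclusive genes;
#'   classes may be missing. Each gene appears under at most one class.
#' @export
exclusive_genes <- function(rules) {
  if (!length(rules)) stop("empty rule list")
  occ <- list()
  for (r in rules) {
    for (g in unique(r$conditions$gene))
      occ[[g]] <- union(occ[[g]], r$class)
  }
  excl <- names(occ)[lengths(occ) == 1]
  if (!length(excl)) return(stats::setNames(list(), character()))
  cls <- vapply(occ[excl], `[[`, character(1), 1)
  split(excl, cls)
}

#' Write a rule table
#'
#' Delimited file: rule_id, class, support, purity, and the condition
#' string ("GENEX <= 1.23 AND GENEY > 0.45").
#'
#' @param rules A `rule_set`.
#' @param path Output path.
#' @return Invisibly, the data.frame written.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "rule_set"))
  df <- data.frame(rule_id = seq_along(rules),
                   class = vapply(rules, `[[`, character(1), "class"),
                   support = vapply(rules, `[[`, numeric(1), "support"),
                   purity = vapply(rules, `[[`, numeric(1), "purity"),
                   conditions = vapply(rules, rule_condition_string,
                                       character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
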