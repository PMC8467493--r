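#' All-relevant gene selection by the shadow-attribute scheme
#'
#' Implements the iterated shadow-feature test: at each iteration every gene
#' still in play is copied into a "shadow" column whose values are permuted
#' (destroying any association with the class label), a random forest is
#' grown on originals plus shadows, and a gene scores a "hit" when its
#' impurity importance exceeds the maximum shadow importance. After each
#' iteration the accumulated hit count of every undecided gene is compared
#' with a fair-coin Binomial(n, 1/2) null by a two-sided binomial test with
#' Bonferroni correction over the currently undecided genes: significantly
#' more hits than expected confirms the gene as `important`, significantly
#' fewer rejects it and removes it from subsequent forests. Genes still
#' undecided when the iteration budget is exhausted are `tentative`.
#'
#' Only `important` genes are passed downstream by the pipeline; tentative
#' genes are dropped.
#'
#' @param ds A [labeled_dataset()] with at least two classes.
#' @param max_iter Iteration budget (default 100). This is the effective
#'   stopping rule: persistent noise genes can never all be confirmed, so
#'   the loop ends when no gene is undecided or the budget is spent.
#' @param alpha Significance level of the binomial decision test.
#' @param num_trees Trees per random forest (default 100).
#' @param seed Integer seed driving both the shadow permutations and the
#'   forests.
#' @return An object of class `boruta_result`: list with `status` (named
#'   factor: important/tentative/rejected), `hit_counts` (named integer),
#'   `n_iterations`, and `important` (the confirmed gene ids in input order).
#' @export
run_boruta <- function(ds, max_iter = 100, alpha = 0.05,
                       num_trees = 100, seed = 1) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (nlevels(ds$labels) < 2) stop("need at least 2 classes")
  if (nrow(ds$x) < 5) stop("need at least 5 cells")
  if (ncol(ds$x) < 1) stop("need at least 1 gene")

  genes <- colnames(ds$x)
  g <- length(genes)
  status <- stats::setNames(rep("undecided", g), genes)
  hits <- stats::setNames(integer(g), genes)
  set.seed(seed)
  iter <- 0L
  while (any(status == "undecided") && iter < max_iter) {
    iter <- iter + 1L
    active <- names(status)[status != "rejected"]
    xa <- ds$x[, active, drop = FALSE]
    shadows <- apply(xa, 2, sample)
    k <- length(active)
    # positional names keep ranger happy with arbitrary gene identifiers
    colnames(xa) <- paste0("g", seq_len(k))
    colnames(shadows) <- paste0("s", seq_len(k))
    df <- as.data.frame(cbind(xa, shadows))
    df$.class <- ds$labels
    fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                          num.trees = num_trees, importance = "impurity",
                          num.threads = 1,
                          seed = sample.int(.Machine$integer.max, 1))
    imp <- fit$variable.importance
    shadow_max <- max(imp[paste0("s", seq_len(k))])
    hit_now <- active[imp[paste0("g", seq_len(k))] > shadow_max]
    hits[hit_now] <- hits[hit_now] + 1L

    undecided <- names(status)[status == "undecided"]
    m <- length(undecided)
    p_hi <- stats::pbinom(hits[undecided] - 1L, iter, 0.5, lower.tail = FALSE)
    p_lo <- stats::pbinom(hits[undecided], iter, 0.5)
    status[undecided[p_hi * m < alpha / 2]] <- "important"
    status[undecided[p_lo * m < alpha / 2]] <- "rejected"
  }
  status[status == "undecided"] <- "tentative"
  structure(list(status = factor(status,
                                 levels = c("important", "tentative",
                                            "rejected")),
                 hit_counts = hits,
                 n_iterations = iter,
                 important = genes[status == "important"]),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(x$status)
  cat(sprintf(
    "boruta_result: %d iterations; %d important, %d tentative, %d rejected\n",
    x$n_iterations, tab[["important"]], tab[["tentative"]],
    tab[["rejected"]]))
  invisible(x)
}

#' Write a shadow-selection report
#'
#' Three-column delimited report (gene_id, status, hit_count), one row per
#' input gene.
#'
#' @param res A `boruta_result`.
#' @param path Output path.
#' @return Invisibly, the data.frame written.
#' @export
write_boruta_report <- function(res, path) {
  stopifnot(inherits(res, "boruta_result"))
  df <- data.frame(gene_id = names(res$status),
                   status = as.character(res$status),
                   hit_count = res$hit_counts[names(res$status)],
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

read_boruta_report <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(list(status = stats::setNames(
                   factor(df$status,
                          levels = c("important", "tentative", "rejected")),
                   df$gene_id),
                 hit_counts = stats::setNames(as.integer(df$hit_count),
                                              df$gene_id),
                 n_iterations = NA_integer_,
                 important = df$gene_id[df$status == "important"]),
            class = "boruta_result")
}
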