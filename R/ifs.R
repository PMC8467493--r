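#' Nested gene-prefix sizes for incremental feature selection
#'
#' Prefix sizes step, 2*step, ... of a ranked gene list; when the total is
#' not a multiple of `step`, one final prefix holding every gene is
#' appended, so the last subset always uses the full ranking.
#'
#' @param ranked A `ranked_genes` object (or an integer gene count).
#' @param step Increment (default 10 genes).
#' @return Integer vector of prefix sizes, strictly increasing.
#' @export
ifs_subset_sizes <- function(ranked, step = 10) {
  n <- if (inherits(ranked, "ranked_genes")) length(ranked$gene_ids)
       else as.integer(ranked)
  if (n < 1) stop("empty ranking")
  if (step < 1) stop("'step' must be >= 1")
  sizes <- seq_len(n %/% step) * step
  if (!length(sizes) || sizes[length(sizes)] != n) sizes <- c(sizes, n)
  as.integer(sizes)
}

#' Incremental feature selection over a ranked gene list
#'
#' Evaluates nested prefixes of the ranking (sizes from
#' [ifs_subset_sizes()]) by SMOTE-balanced stratified cross-validation of
#' the given classifier, producing the MCC-vs-number-of-genes curve from
#' which the optimum gene set is read off. Each subset is evaluated
#' independently with a seed derived from the subset size, so results do
#' not depend on evaluation order.
#'
#' @param ds A [labeled_dataset()].
#' @param ranked A `ranked_genes` object.
#' @param spec A [classifier_spec()].
#' @param step Prefix increment (default 10).
#' @param folds Cross-validation folds (default 10).
#' @param smote_policy Passed to [cross_validate()] (default `"within"`,
#'   the leakage-safe choice).
#' @param smote_k Neighbor count for SMOTE.
#' @param seed Integer seed.
#' @return An object of class `ifs_curve`: data.frame-like list with
#'   `n_features`, `mcc`, `overall_accuracy`, per-subset `records`, the
#'   classifier name, and the ranking used.
#' @export
run_ifs <- function(ds, ranked, spec = classifier_spec(), step = 10,
                    folds = 10, smote_policy = "within", smote_k = 5,
                    seed = 1) {
  stopifnot(inherits(ds, "labeled_dataset"), inherits(ranked, "ranked_genes"))
  sizes <- ifs_subset_sizes(ranked, step)
  records <- lapply(sizes, function(sz) {
    cross_validate(ds, genes = ranked$gene_ids[seq_len(sz)], spec = spec,
                   folds = folds, smote_policy = smote_policy,
                   smote_k = smote_k,
                   seed = derive_seed(seed, paste0("ifs", sz)))
  })
  structure(list(n_features = sizes,
                 mcc = vapply(records, `[[`, numeric(1), "mcc"),
                 overall_accuracy = vapply(records, `[[`, numeric(1),
                                           "overall_accuracy"),
                 records = records,
                 classifier = spec$name,
                 ranked = ranked),
            class = "ifs_curve")
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat(sprintf("ifs_curve (%s): %d subsets, %d..%d genes\n",
              x$classifier, length(x$n_features), min(x$n_features),
              max(x$n_features)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ifs_curve <- function(x, ...) {
  data.frame(n_features = x$n_features, mcc = x$mcc,
             overall_accuracy = x$overall_accuracy)
}

#' Plot an incremental-feature-selection curve
#'
#' MCC on the y-axis against number of genes on the x-axis, with the
#' optimum highlighted.
#'
#' @param x An `ifs_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ifs_curve <- function(x, ...) {
  graphics::plot(x$n_features, x$mcc, type = "b", pch = 16,
                 xlab = "number of genes", ylab = "MCC",
                 main = sprintf("IFS curve (%s)", x$classifier), ...)
  opt <- find_optimum(x)
  graphics::abline(v = opt$n_features, lty = 2, col = "grey50")
  graphics::points(opt$n_features, opt$mcc, col = "red", pch = 16, cex = 1.3)
  invisible(x)
}

#' Locate the optimum of an IFS curve
#'
#' The row with maximal MCC; ties go to the smaller gene count (the cheaper
#' classifier).
#'
#' @param curve An `ifs_curve`.
#' @return List with `n_features`, `mcc`, the full `record`, and `genes`
#'   (the optimum gene prefix).
#' @export
find_optimum <- function(curve) {
  stopifnot(inherits(curve, "ifs_curve"))
  i <- which.max(curve$mcc)  # first max = smallest n_features on ties
  list(n_features = curve$n_features[i],
       mcc = curve$mcc[i],
       record = curve$records[[i]],
       genes = curve$ranked$gene_ids[seq_len(curve$n_features[i])])
}

#' Write an IFS results table
#'
#' One row per subset size with MCC, overall accuracy and per-class
#' accuracies — the per-step evaluation table behind the IFS curve.
#'
#' @param curve An `ifs_curve`.
#' @param path Output path.
#' @return Invisibly, the data.frame written.
#' @export
write_ifs_table <- function(curve, path) {
  stopifnot(inherits(curve, "ifs_curve"))
  per_class <- do.call(rbind, lapply(curve$records, function(r)
    r$per_class_accuracy))
  colnames(per_class) <- paste0("acc_", colnames(per_class))
  df <- cbind(data.frame(classifier = curve$classifier,
                         n_features = curve$n_features,
                         mcc = curve$mcc,
                         overall_accuracy = curve$overall_accuracy),
              as.data.frame(per_class))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
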