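#' @keywords internal
derive_seed <- function(seed, salt) {
  # deterministic per-stage/fold seed, kept inside 32-bit integer range
  s <- sum(utf8ToInt(as.character(salt)) * seq_along(utf8ToInt(as.character(salt))))
  as.integer((as.numeric(seed) * 48271 + s) %% 2147483646 + 1)
}

as_indicator <- function(f, levels) {
  f <- factor(f, levels = levels)
  if (anyNA(f)) stop("value outside the class level set")
  m <- matrix(0L, length(f), length(levels),
              dimnames = list(NULL, levels))
  m[cbind(seq_along(f), as.integer(f))] <- 1L
  m
}

#' Multi-class Matthews correlation coefficient
#'
#' The R_K generalization of the Matthews correlation coefficient: with X
#' and Y the N x K one-hot indicator matrices of predicted and actual
#' classes, MCC = cov(X, Y) / sqrt(cov(X, X) cov(Y, Y)), where
#' cov(A, B) = sum_nk (A_nk - mean_k(A)) (B_nk - mean_k(B)) over entries,
#' with column (per-class) means. The value lies in \[-1, 1\]: 1 for perfect
#' prediction, about 0 for label-independent prediction, -1 for the exact
#' complement in a binary problem. If either variance term is zero (all
#' predictions or all truths in one class) the coefficient is defined as 0.
#'
#' @param predicted,actual Class assignments: factors/character vectors of
#'   equal length, or N x K binary indicator matrices with unit row sums.
#' @param levels Optional common class level set (vector input only).
#' @return The multi-class MCC, a number in \[-1, 1\].
#' @export
multiclass_mcc <- function(predicted, actual, levels = NULL) {
  if (is.matrix(predicted) || is.matrix(actual)) {
    X <- predicted; Y <- actual
    if (!is.matrix(X) || !is.matrix(Y) || !all(dim(X) == dim(Y)))
      stop("indicator matrices must have identical dimensions")
    if (any(rowSums(X) != 1) || any(rowSums(Y) != 1))
      stop("each indicator row must sum to exactly 1")
  } else {
    if (length(predicted) != length(actual)) stop("length mismatch")
    if (is.null(levels))
      levels <- union(levels(as.factor(actual)), levels(as.factor(predicted)))
    X <- as_indicator(predicted, levels)
    Y <- as_indicator(actual, levels)
  }
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  num <- sum(Xc * Yc)
  vx <- sum(Xc * Xc)
  vy <- sum(Yc * Yc)
  if (vx == 0 || vy == 0) return(0)
  num / sqrt(vx * vy)
}

#' Per-class and overall accuracy plus MCC
#'
#' Per-class accuracy is the recall of each actual class (correct within
#' class / class size); overall accuracy is total correct / N. Classes with
#' no actual member get `NA`.
#'
#' @param predicted,actual Class assignments of equal length.
#' @param levels Optional common class level set.
#' @return An object of class `eval_record`: list with `mcc`,
#'   `overall_accuracy`, `per_class_accuracy` (named), and `n`.
#' @export
evaluate_predictions <- function(predicted, actual, levels = NULL) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (is.null(levels))
    levels <- union(levels(as.factor(actual)), levels(as.factor(predicted)))
  predicted <- factor(predicted, levels = levels)
  actual <- factor(actual, levels = levels)
  correct <- predicted == actual
  per_class <- vapply(levels, function(cl) {
    in_cl <- actual == cl
    if (!any(in_cl)) return(NA_real_)
    mean(correct[in_cl])
  }, numeric(1))
  structure(list(mcc = multiclass_mcc(predicted, actual, levels = levels),
                 overall_accuracy = mean(correct),
                 per_class_accuracy = per_class,
                 n = length(actual)),
            class = "eval_record")
}

#' @export
print.eval_record <- function(x, ...) {
  cat(sprintf("eval_record (n = %d): MCC = %.4f, overall accuracy = %.4f\n",
              x$n, x$mcc, x$overall_accuracy))
  invisible(x)
}

#' Specify a classifier for cross-validation and incremental selection
#'
#' Two classifiers are supported, both split on the Gini impurity: `"cart"`
#' (a single classification tree grown without a complexity penalty, i.e.
#' to purity up to the implementation's depth cap of 30) and
#' `"random_forest"` (an ensemble of `num_trees` trees with sqrt-mtry
#' feature sampling).
#'
#' @param name `"cart"` or `"random_forest"`.
#' @param num_trees Trees in the forest (ignored for cart; default 100).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(name = c("cart", "random_forest"),
                            num_trees = 100) {
  name <- match.arg(name)
  structure(list(name = name, num_trees = num_trees),
            class = "classifier_spec")
}

fit_classifier <- function(spec, x, y, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  genes <- colnames(x)
  colnames(x) <- paste0("g", seq_len(ncol(x)))
  df <- as.data.frame(x)
  df$.class <- y
  if (spec$name == "cart") {
    fit <- rpart::rpart(.class ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          minsplit = 2, minbucket = 1, cp = 0, xval = 0,
                          maxcompete = 0, maxsurrogate = 0))
  } else {
    fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                          num.trees = spec$num_trees,
                          num.threads = 1, seed = seed)
  }
  structure(list(spec = spec, fit = fit, genes = genes,
                 levels = levels(y)),
            class = "fitted_classifier")
}

predict_classifier <- function(model, newx) {
  stopifnot(inherits(model, "fitted_classifier"))
  newx <- newx[, model$genes, drop = FALSE]
  colnames(newx) <- paste0("g", seq_len(ncol(newx)))
  df <- as.data.frame(newx)
  if (model$spec$name == "cart") {
    cls <- predict(model$fit, df, type = "class")
  } else {
    cls <- predict(model$fit, df, num.threads = 1)$predictions
  }
  factor(as.character(cls), levels = model$levels)
}

#' Stratified k-fold cross-validation with optional in-fold SMOTE
#'
#' Splits the cells into `folds` stratified parts (class proportions
#' preserved), then for each fold fits the classifier on the remaining
#' folds — optionally SMOTE-balancing the training part first — and
#' predicts the held-out part. All held-out predictions are pooled into a
#' single evaluation (one confusion over all folds).
#'
#' `smote_policy` controls where oversampling happens: `"within"` (default,
#' leakage-safe: training folds only), `"before"` (balance the whole
#' dataset before splitting; synthetic cells then leak between training and
#' test folds — provided for fidelity with workflows that balance first),
#' or `"none"`.
#'
#' @param ds A [labeled_dataset()].
#' @param genes Optional gene subset (character vector).
#' @param spec A [classifier_spec()].
#' @param folds Number of folds (default 10).
#' @param smote_policy `"within"`, `"before"` or `"none"`.
#' @param smote_k Neighbor count for SMOTE.
#' @param seed Integer seed (folds, SMOTE and forests all derive from it).
#' @return An `eval_record` of the pooled held-out predictions.
#' @export
cross_validate <- function(ds, genes = NULL, spec = classifier_spec(),
                           folds = 10,
                           smote_policy = c("within", "before", "none"),
                           smote_k = 5, seed = 1) {
  stopifnot(inherits(ds, "labeled_dataset"))
  smote_policy <- match.arg(smote_policy)
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(ds$x))
    if (length(missing)) stop("unknown gene(s): ",
                              paste(utils::head(missing, 5), collapse = ", "))
    ds <- labeled_dataset(ds$x[, genes, drop = FALSE], ds$labels)
  }
  if (smote_policy == "before")
    ds <- smote_balance(ds, k = smote_k, seed = derive_seed(seed, "smote0"))
  sz <- table(ds$labels)
  if (any(sz < folds))
    warning("class(es) smaller than the fold count; stratification degenerates")
  set.seed(derive_seed(seed, "folds"))
  fold_of <- integer(nrow(ds$x))
  for (cl in levels(ds$labels)) {
    idx <- which(ds$labels == cl)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  pred <- character(nrow(ds$x))
  for (f in seq_len(folds)) {
    test <- fold_of == f
    train_x <- ds$x[!test, , drop = FALSE]
    train_y <- droplevels(ds$labels[!test])
    if (smote_policy == "within" && nlevels(train_y) > 1) {
      bal <- smote_balance(labeled_dataset(train_x, train_y),
                           k = smote_k,
                           seed = derive_seed(seed, paste0("smote", f)))
      train_x <- bal$x
      train_y <- bal$labels
    }
    model <- fit_classifier(spec, train_x, train_y,
                            seed = derive_seed(seed, paste0("fit", f)))
    pred[test] <- as.character(
      predict_classifier(model, ds$x[test, , drop = FALSE]))
  }
  evaluate_predictions(pred, ds$labels, levels = levels(ds$labels))
}
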