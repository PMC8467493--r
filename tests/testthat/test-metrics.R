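test_that("multi-class MCC hits its analytic anchor points", {
  y <- rep(c("A", "B", "C", "D"), each = 5)
  expect_equal(multiclass_mcc(y, y), 1)
  # complement of a binary labeling
  yb <- rep(c("A", "B"), c(6, 4))
  flip <- ifelse(yb == "A", "B", "A")
  expect_equal(multiclass_mcc(flip, yb), -1)
  # degenerate single-class prediction has zero variance -> defined as 0
  expect_equal(multiclass_mcc(rep("A", 10), yb), 0)
  expect_equal(multiclass_mcc(rep("A", 4), rep("A", 4), levels = c("A", "B")), 0)
})

test_that("indicator-matrix input validates row sums and shape", {
  X <- diag(3); Y <- diag(3)
  expect_equal(multiclass_mcc(X, Y), 1)
  bad <- X; bad[1, ] <- c(1, 1, 0)
  expect_error(multiclass_mcc(bad, Y), "sum to exactly 1")
  expect_error(multiclass_mcc(X, Y[1:2, ]), "identical dimensions")
})

test_that("the two-class case reduces to the classical binary MCC", {
  set.seed(11)
  for (i in 1:50) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    actual <- rep(c("pos", "pos", "neg", "neg"), as.vector(tab))
    pred   <- rep(c("pos", "neg", "pos", "neg"), as.vector(tab))
    expect_equal(multiclass_mcc(pred, actual, levels = c("pos", "neg")),
                 binary_mcc(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2]),
                 tolerance = 1e-12)
  }
})

test_that("MCC is invariant under simultaneous class relabeling", {
  set.seed(12)
  y <- sample(LETTERS[1:4], 60, replace = TRUE)
  p <- sample(LETTERS[1:4], 60, replace = TRUE)
  base <- multiclass_mcc(p, y, levels = LETTERS[1:4])
  perm <- c(C = "A", A = "B", D = "C", B = "D")
  expect_equal(multiclass_mcc(unname(perm[p]), unname(perm[y]),
                              levels = LETTERS[1:4]),
               base, tolerance = 1e-12)
  expect_true(base >= -1 && base <= 1)
})

test_that("per-class and overall accuracies count correctly", {
  rec <- evaluate_predictions(c("A", "B", "B", "B"), c("A", "A", "B", "B"))
  expect_equal(rec$overall_accuracy, 0.75)
  expect_equal(rec$per_class_accuracy, c(A = 0.5, B = 1.0))
  perfect <- evaluate_predictions(c("A", "B"), c("A", "B"))
  expect_equal(perfect$mcc, 1)
  expect_true(all(perfect$per_class_accuracy == 1))
  # class absent from the actuals is reported as missing
  rec2 <- evaluate_predictions(c("A", "A"), c("A", "A"),
                               levels = c("A", "B"))
  expect_true(is.na(rec2$per_class_accuracy[["B"]]))
  expect_equal(rec2$overall_accuracy, 1)
  expect_equal(rec2$mcc, 0)  # degenerate zero-variance path
})

test_that("cross-validation is deterministic and near-perfect on separable data", {
  sim <- separable_dataset(sizes = c(40, 20, 20), noise = 10, seed = 7)
  for (clf in c("cart", "random_forest")) {
    a <- cross_validate(sim$dataset, spec = classifier_spec(clf),
                        folds = 5, seed = 3)
    expect_gte(a$mcc, 0.95)
    b <- cross_validate(sim$dataset, spec = classifier_spec(clf),
                        folds = 5, seed = 3)
    expect_identical(a, b)
  }
})

test_that("a too-small class triggers the stratification warning", {
  m <- matrix(runif(40), 20, 2,
              dimnames = list(paste0("c", 1:20), c("g1", "g2")))
  ds <- labeled_dataset(m, rep(c("A", "B"), c(17, 3)))
  expect_warning(cross_validate(ds, folds = 5, smote_policy = "none",
                                spec = classifier_spec("cart"), seed = 1),
                 "smaller than the fold count")
})

test_that("restricting to a gene subset drops the other genes", {
  sim <- separable_dataset(seed = 8)
  genes <- unlist(sim$truth$marker_map)
  rec <- cross_validate(sim$dataset, genes = genes, folds = 4,
                        spec = classifier_spec("cart"), seed = 2)
  expect_gte(rec$mcc, 0.9)
  expect_error(cross_validate(sim$dataset, genes = "nope", folds = 4),
               "unknown gene")
})
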