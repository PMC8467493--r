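test_that("a one-gene separation yields a single split near the boundary", {
  m <- matrix(c(rep(1, 10), rep(9, 10), runif(20)), 20, 2,
              dimnames = list(paste0("c", 1:20), c("sep", "junk")))
  ds <- labeled_dataset(m, rep(c("A", "B"), each = 10))
  tree <- train_rule_tree(ds)
  rules <- extract_rules(tree)
  expect_equal(length(rules), 2)
  for (r in rules) {
    expect_equal(nrow(r$conditions), 1)
    expect_equal(r$conditions$gene, "sep")
    expect_gt(r$conditions$threshold, 1)
    expect_lt(r$conditions$threshold, 9)
  }
  expect_setequal(vapply(rules, `[[`, character(1), "class"), c("A", "B"))
  expect_setequal(vapply(rules, function(r) r$conditions$relation,
                         character(1)), c("<=", ">"))
})

test_that("pure single-class data gives one rule with no conditions", {
  m <- tiny_matrix(n_cells = 6, values = runif(12))
  ds <- labeled_dataset(m, rep("A", 6))
  rules <- extract_rules(train_rule_tree(ds))
  expect_equal(length(rules), 1)
  expect_equal(nrow(rules[[1]]$conditions), 0)
  expect_equal(rules[[1]]$class, "A")
  expect_equal(rules[[1]]$support, 6)
})

test_that("rules partition the training cells and supports sum to N", {
  for (s in 1:4) {
    sim <- simulate_cells(synthetic_config(
      class_sizes = c(30, 15, 10), n_noise_genes = 10,
      private_markers_per_class = 2, noise_sd = 0.7, seed = 50 + s))
    ds <- sim$dataset
    tree <- train_rule_tree(ds)
    rules <- extract_rules(tree)
    expect_equal(length(rules), sum(tree$fit$frame$var == "<leaf>"))
    hit <- match_rules(rules, ds$x)
    expect_true(all(attr(hit, "n_satisfied") == 1))
    expect_equal(sum(vapply(rules, `[[`, numeric(1), "support")),
                 nrow(ds$x))
    # the matched rule predicts the leaf class of the training cell
    pred <- vapply(rules, `[[`, character(1), "class")[hit]
    expect_gte(mean(pred == as.character(ds$labels)), 0.99)
  }
})

test_that("retraining on the same data reproduces the same tree", {
  sim <- separable_dataset(seed = 11)
  r1 <- extract_rules(train_rule_tree(sim$dataset, seed = 1))
  r2 <- extract_rules(train_rule_tree(sim$dataset, seed = 2))
  expect_identical(lapply(r1, `[[`, "conditions"),
                   lapply(r2, `[[`, "conditions"))
})

test_that("exclusive genes are those confined to one class's rules", {
  mk <- function(gene, relation, threshold, class)
    list(conditions = data.frame(gene = gene, relation = relation,
                                 threshold = threshold),
         class = class, support = 1, purity = 1)
  rules <- list(mk("g1", "<=", 2, "A"), mk("g2", ">", 1, "B"))
  expect_equal(exclusive_genes(rules), list(A = "g1", B = "g2"))
  # a gene shared between classes is excluded everywhere
  rules <- list(mk("g1", "<=", 2, "A"), mk("g1", ">", 2, "B"),
                mk("g2", ">", 1, "B"))
  expect_equal(exclusive_genes(rules), list(B = "g2"))
  # both relations within one class still count as one occurrence
  rules <- list(mk(c("g1", "g1"), c("<=", ">"), c(1, 0.2), "A"))
  expect_equal(exclusive_genes(rules), list(A = "g1"))
  # symmetry under class relabeling
  rules <- list(mk("g1", "<=", 2, "X"), mk("g2", ">", 1, "Y"))
  expect_equal(exclusive_genes(rules), list(X = "g1", Y = "g2"))
})

test_that("fully grown pure trees have no exclusive genes by construction", {
  # every split gene lies on paths to leaves of >= 2 classes, so the
  # exclusive-gene report of a purity-grown tree is empty
  sim <- separable_dataset(seed = 12)
  rules <- extract_rules(train_rule_tree(sim$dataset))
  expect_equal(length(exclusive_genes(rules)), 0)
})

test_that("the rule table serializes the condition strings", {
  sim <- separable_dataset(sizes = c(20, 10, 10), seed = 13)
  rules <- extract_rules(train_rule_tree(sim$dataset))
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- write_rules(rules, path)
  expect_equal(nrow(df), length(rules))
  expect_true(all(grepl("(<=|>)", df$conditions)))
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$support, df$support)
})
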