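test_that("discretization follows the mean +/- sd three-state scheme", {
  m <- cbind(flat = rep(2, 10), spike = c(rep(0, 9), 10))
  rownames(m) <- paste0("c", 1:10)
  dm <- discretize_expression(m)
  expect_true(all(dm$states[, "flat"] == 0))
  # spike gene: mu = 1, sd = sqrt(10); only the extreme cell exceeds mu + sd
  expect_equal(unname(dm$states[, "spike"]), c(rep(0L, 9), 1L))
  # states are invariant to cell order
  perm <- sample(nrow(m))
  dm2 <- discretize_expression(m[perm, ])
  expect_identical(dm2$states, dm$states[perm, ])
})

test_that("mutual information matches a hand oracle and its identities", {
  expect_equal(mutual_information(rep(1, 8), rep(c(0, 1), 4)), 0)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  # joint counts [[2,1],[1,2]]
  x <- c(0, 0, 0, 1, 1, 1)
  y <- c(0, 0, 1, 0, 1, 1)
  expect_equal(mutual_information(x, y), oracle_mi(x, y), tolerance = 1e-12)
  expect_error(mutual_information(1:3, 1:4), "length")
})

test_that("MI is symmetric and bounded by the marginal entropies", {
  set.seed(42)
  for (i in 1:20) {
    x <- sample(-1:1, 30, replace = TRUE)
    y <- sample(0:2, 30, replace = TRUE)
    mi <- mutual_information(x, y)
    expect_equal(mi, mutual_information(y, x), tolerance = 1e-12)
    hx <- mutual_information(x, x)
    hy <- mutual_information(y, y)
    expect_lte(mi, min(hx, hy) + 1e-12)
    expect_gte(mi, -1e-12)
  }
})

test_that("redundant copies are pushed down the ranking", {
  # f2 duplicates f1; f3 is equally relevant but independent of f1, so the
  # redundancy penalty must demote the copy below f3
  y  <- c("a", "a", "b", "b", "c", "c", "d", "d")
  f1 <- c(1, 1, 1, 1, -1, -1, -1, -1)
  f2 <- f1
  f3 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  states <- cbind(f1 = f1, f2 = f2, f3 = f3)
  dm <- structure(list(states = states, thresholds = NULL),
                  class = "discretized_matrix")
  ranked <- rank_mrmr(dm, y)
  expect_equal(ranked$gene_ids, c("f1", "f3", "f2"))
})

test_that("a single gene yields a one-entry list scored by label MI", {
  y <- c("A", "A", "B", "B")
  states <- cbind(g = c(1, 1, -1, -1))
  dm <- structure(list(states = states, thresholds = NULL),
                  class = "discretized_matrix")
  ranked <- rank_mrmr(dm, y)
  expect_equal(length(ranked$gene_ids), 1)
  expect_equal(ranked$scores, mutual_information(states[, 1], y))
})

test_that("greedy ranking equals exhaustive recomputation on small data", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(12:24, 1)
    g <- sample(3:6, 1)
    states <- matrix(sample(-1:1, n * g, replace = TRUE), n, g,
                     dimnames = list(NULL, paste0("v", seq_len(g))))
    labels <- sample(c("A", "B", "C"), n, replace = TRUE)
    dm <- structure(list(states = states, thresholds = NULL),
                    class = "discretized_matrix")
    ranking <- rank_mrmr(dm, labels)$gene_ids
    expect_identical(ranking, oracle_mrmr(states, labels))
    expect_true(oracle_mrmr_check(states, labels, ranking))
  }
})

test_that("the ranking is a permutation of the input genes", {
  sim <- separable_dataset(seed = 6)
  ranked <- rank_mrmr(sim$dataset)
  expect_setequal(ranked$gene_ids, colnames(sim$dataset$x))
  expect_equal(anyDuplicated(ranked$gene_ids), 0L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_genes(ranked, path)
  back <- scMarkerRules:::read_ranked_genes(path)
  expect_identical(back$gene_ids, ranked$gene_ids)
})

test_that("planted markers outrank the median noise gene", {
  for (s in 1:3) {
    sim <- simulate_cells(synthetic_config(
      class_sizes = c(60, 30, 30), n_noise_genes = 40,
      private_markers_per_class = 3, effect_size = 2, seed = 40 + s))
    ranked <- rank_mrmr(sim$dataset)
    pos <- match(colnames(sim$dataset$x), ranked$gene_ids)
    names(pos) <- colnames(sim$dataset$x)
    markers <- unlist(sim$truth$marker_map)
    noise <- setdiff(colnames(sim$dataset$x), markers)
    expect_true(all(pos[markers] < stats::median(pos[noise])))
  }
})
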