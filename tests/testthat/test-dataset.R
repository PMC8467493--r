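test_that("constructor enforces the dataset invariants", {
  m <- tiny_matrix()
  expect_s3_class(labeled_dataset(m, c("A", "A", "B")), "labeled_dataset")

  bad <- m; bad[1, 1] <- -1
  expect_error(labeled_dataset(bad, c("A", "A", "B")), "negative")
  bad <- m; bad[2, 2] <- NA
  expect_error(labeled_dataset(bad, c("A", "A", "B")), "missing")
  dup <- m; rownames(dup) <- c("c1", "c1", "c3")
  expect_error(labeled_dataset(dup, c("A", "A", "B")), "duplicate cell")
  dup <- m; colnames(dup) <- c("g1", "g1")
  expect_error(labeled_dataset(dup, c("A", "A", "B")), "duplicate gene")
  expect_error(labeled_dataset(m, c("A", "B")), "one class tag per cell")
})

test_that("dense read-back reproduces a written dataset bit-identically", {
  set.seed(1)
  m <- matrix(runif(12, 0, 8), 4, 3,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  ds <- labeled_dataset(m, c("A", "A", "B", "B"))
  mp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, mp, lp)
  back <- read_dataset(mp, lp)
  expect_identical(back$x, ds$x)
  expect_identical(as.character(back$labels), as.character(ds$labels))
})

test_that("dense and matrix-market inputs give the same dataset", {
  m <- tiny_matrix(c(0, 2, 3, 4, 0, 6))
  ds <- labeled_dataset(m, c("A", "A", "B"))
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "m.tsv"); lp <- file.path(dir, "l.tsv")
  write_dataset(ds, mp, lp)
  # matrix-market triplet with one explicit zero entry
  mm <- file.path(dir, "m.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "3 2 5",
               "1 1 0", "2 1 2", "3 1 3", "1 2 4", "3 2 6"), mm)
  writeLines(rownames(m), file.path(dir, "cells.txt"))
  writeLines(colnames(m), file.path(dir, "genes.txt"))
  sparse <- read_dataset(mm, lp, cells_path = file.path(dir, "cells.txt"),
                         genes_path = file.path(dir, "genes.txt"))
  dense <- read_dataset(mp, lp)
  expect_equal(sparse$x, dense$x)
})

test_that("label-file problems are caught", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "m.tsv"); lp <- file.path(dir, "l.tsv")
  write_dataset(ds, mp, lp)
  # remove one cell's label
  lab <- readLines(lp)
  writeLines(lab[-3], lp)
  expect_error(read_dataset(mp, lp), "unlabeled")
  # a label for a cell that is not in the matrix
  writeLines(c(lab, "c99\tB"), lp)
  expect_error(read_dataset(mp, lp), "absent from matrix")
  expect_error(read_dataset(file.path(dir, "nope.tsv"), lp), "not found")
})

test_that("comma-delimited matrices are sniffed", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "m.csv"); lp <- file.path(dir, "l.csv")
  write_dataset(ds, mp, lp, sep = ",")
  back <- read_dataset(mp, lp)
  expect_equal(back$x, ds$x)
})

test_that("class-size filter keeps classes strictly above the threshold", {
  sizes <- c(A = 150, B = 100, C = 101)
  m <- matrix(1, sum(sizes), 1,
              dimnames = list(paste0("c", seq_len(sum(sizes))), "g1"))
  ds <- labeled_dataset(m, rep(names(sizes), sizes))
  kept <- filter_cell_types(ds, 100)
  expect_setequal(levels(kept$labels), c("A", "C"))
  expect_equal(unname(class_sizes(kept)), c(150, 101))
  # idempotent
  expect_identical(class_sizes(filter_cell_types(kept, 100)),
                   class_sizes(kept))
  expect_error(filter_cell_types(ds, 1000), "no class passes")
})

test_that("class sizes always sum to the number of cells", {
  expect_equal(class_sizes(tiny_dataset(c("A", "A", "B"))), c(A = 2, B = 1))
  for (seed in 1:3) {
    sim <- simulate_cells(synthetic_config(
      class_sizes = c(30, 10, 5), n_noise_genes = 4, seed = seed))
    expect_equal(sum(class_sizes(sim$dataset)), nrow(sim$dataset$x))
  }
})
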