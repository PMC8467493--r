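#' Configuration for the synthetic expression generator
#'
#' Describes a labeled single-cell-like dataset with planted structure:
#' a large pool of uninformative "noise" genes shared by all classes, a set
#' of marker genes whose mean is shifted upward in one class (optionally
#' reused across classes' rule sets), and "private" markers that are shifted
#' in exactly one class and flat everywhere else. Class sizes may be
#' deliberately imbalanced to emulate annotated single-cell atlases.
#'
#' Baseline expression is drawn from a Normal(mu0 = 1, `noise_sd`) truncated
#' at zero on the log2(TPM+1) scale, which keeps values in the realistic
#' 0 to ~10 range. Dropout, when enabled, zeroes each entry independently
#' after the mean shift, emulating the sparsity of single-cell matrices; it
#' defaults to 0 so that planted mean differences equal `effect_size`
#' exactly in expectation.
#'
#' @param n_classes Number of classes (>= 2).
#' @param class_sizes Integer vector of per-class cell counts, length
#'   `n_classes`; imbalance is allowed and typical.
#' @param n_noise_genes Number of uninformative genes.
#' @param shared_markers_per_class Markers up-shifted in one class but drawn
#'   from a common naming pool (may be reused across downstream rules).
#' @param private_markers_per_class Markers up-shifted in exactly one class.
#' @param effect_size Mean shift, in log2 units, of a marker in its class.
#' @param noise_sd Standard deviation of baseline expression.
#' @param dropout_rate Probability that any entry is zeroed (default 0).
#' @param seed Integer seed; identical configurations generate bit-identical
#'   datasets.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 3,
                             class_sizes = c(200, 50, 50),
                             n_noise_genes = 100,
                             shared_markers_per_class = 0,
                             private_markers_per_class = 5,
                             effect_size = 2,
                             noise_sd = 0.5,
                             dropout_rate = 0,
                             seed = 1) {
  if (n_classes < 2) stop("need at least 2 classes")
  if (length(class_sizes) != n_classes)
    stop("'class_sizes' must have one entry per class")
  if (any(class_sizes < 1)) stop("class sizes must be positive")
  if (n_noise_genes < 0 || shared_markers_per_class < 0 ||
      private_markers_per_class < 0)
    stop("gene counts must be non-negative")
  if (effect_size < 0) stop("'effect_size' must be non-negative")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("'dropout_rate' must be in [0, 1]")
  structure(list(n_classes = as.integer(n_classes),
                 class_sizes = as.integer(class_sizes),
                 n_noise_genes = as.integer(n_noise_genes),
                 shared_markers_per_class = as.integer(shared_markers_per_class),
                 private_markers_per_class = as.integer(private_markers_per_class),
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a labeled dataset with planted marker genes
#'
#' Draws a cells x genes matrix under the configuration's generative model
#' and returns it together with the ground truth of planted markers. Gene
#' names encode their role ("noise_0001", "mk_<class>_01", "pv_<class>_01")
#' so that recovery can be asserted without carrying the truth object
#' through the pipeline.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with elements `dataset` (a [labeled_dataset()]) and
#'   `truth` (list with `marker_map` and `private_map`, class tag -> gene
#'   ids; private markers are a subset of all markers of their class).
#' @examples
#' sim <- simulate_cells(synthetic_config(seed = 7))
#' sim$dataset
#' @export
simulate_cells <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  classes <- LETTERS[seq_len(cfg$n_classes)]
  if (cfg$n_classes > 26)
    classes <- sprintf("C%02d", seq_len(cfg$n_classes))
  labels <- factor(rep(classes, cfg$class_sizes), levels = classes)
  n <- length(labels)

  noise_ids <- if (cfg$n_noise_genes)
    sprintf("noise_%04d", seq_len(cfg$n_noise_genes)) else character()
  shared_ids <- private_ids <- character()
  marker_map <- private_map <- stats::setNames(vector("list", length(classes)),
                                               classes)
  for (cl in classes) {
    sh <- if (cfg$shared_markers_per_class)
      sprintf("mk_%s_%02d", cl, seq_len(cfg$shared_markers_per_class))
      else character()
    pv <- if (cfg$private_markers_per_class)
      sprintf("pv_%s_%02d", cl, seq_len(cfg$private_markers_per_class))
      else character()
    shared_ids <- c(shared_ids, sh)
    private_ids <- c(private_ids, pv)
    marker_map[[cl]] <- c(sh, pv)
    private_map[[cl]] <- pv
  }
  gene_ids <- c(noise_ids, shared_ids, private_ids)
  if (!length(gene_ids)) stop("configuration yields zero genes")

  set.seed(cfg$seed)
  mu0 <- 1
  m <- matrix(pmax(stats::rnorm(n * length(gene_ids), mu0, cfg$noise_sd), 0),
              nrow = n, ncol = length(gene_ids),
              dimnames = list(sprintf("cell_%05d", seq_len(n)), gene_ids))
  for (cl in classes) {
    rows <- which(labels == cl)
    cols <- marker_map[[cl]]
    if (length(cols))
      m[rows, cols] <- pmax(matrix(stats::rnorm(length(rows) * length(cols),
                                                mu0 + cfg$effect_size,
                                                cfg$noise_sd),
                                   length(rows), length(cols)), 0)
  }
  if (cfg$dropout_rate > 0) {
    drop <- matrix(stats::runif(length(m)) < cfg$dropout_rate,
                   nrow = nrow(m))
    m[drop] <- 0
  }
  list(dataset = labeled_dataset(m, labels),
       truth = list(marker_map = marker_map, private_map = private_map))
}

#' Write a simulated dataset plus its ground truth
#'
#' Convenience wrapper: writes the dense matrix and label files via
#' [write_dataset()] and the planted-marker truth as a JSON sidecar.
#'
#' @param sim Result of [simulate_cells()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, paste0(prefix, "_matrix.tsv")),
             labels = file.path(dir, paste0(prefix, "_labels.tsv")),
             truth  = file.path(dir, paste0(prefix, "_truth.json")))
  write_dataset(sim$dataset, paths[["matrix"]], paths[["labels"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], pretty = TRUE)
  invisible(paths)
}
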