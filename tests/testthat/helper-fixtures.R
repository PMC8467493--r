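# small in-code fixtures shared across test files

tiny_matrix <- function(values = 1:6, n_cells = 3, n_genes = 2) {
  matrix(as.numeric(values), n_cells, n_genes,
         dimnames = list(paste0("c", seq_len(n_cells)),
                         paste0("g", seq_len(n_genes))))
}

tiny_dataset <- function(labels = c("A", "A", "B"), ...) {
  labeled_dataset(tiny_matrix(...), labels)
}

# dataset with classes cleanly separated by dedicated genes
separable_dataset <- function(sizes = c(40, 20, 20), noise = 10, seed = 1,
                              effect = 3) {
  sim <- simulate_cells(synthetic_config(
    n_classes = length(sizes), class_sizes = sizes, n_noise_genes = noise,
    private_markers_per_class = 2, effect_size = effect, seed = seed))
  sim
}

# independent plug-in mutual-information oracle (explicit cell-by-cell sums)
oracle_mi <- function(x, y) {
  n <- length(x)
  total <- 0
  for (vx in unique(x)) {
    px <- sum(x == vx) / n
    for (vy in unique(y)) {
      py <- sum(y == vy) / n
      pxy <- sum(x == vx & y == vy) / n
      if (pxy > 0) total <- total + pxy * log2(pxy / (px * py))
    }
  }
  total
}

# exhaustive greedy MID oracle: recomputes the criterion from scratch at
# every step (no incremental bookkeeping)
oracle_mrmr <- function(states, labels) {
  g <- ncol(states)
  sel <- integer(0)
  rem <- seq_len(g)
  while (length(rem)) {
    crit <- vapply(rem, function(j) {
      rel <- oracle_mi(states[, j], labels)
      red <- if (length(sel))
        sum(vapply(sel, function(s) oracle_mi(states[, j], states[, s]),
                   numeric(1))) / length(sel)
      else 0
      rel - red
    }, numeric(1))
    pick <- rem[which.max(crit)]
    sel <- c(sel, pick)
    rem <- setdiff(rem, pick)
  }
  colnames(states)[sel]
}

# verifies a greedy ranking against step-wise from-scratch recomputation:
# at every step the chosen gene must attain the maximal MID criterion
# (within tol, so that exact mathematical ties decided by floating-point
# summation order are accepted either way)
oracle_mrmr_check <- function(states, labels, ranking, tol = 1e-12) {
  sel <- integer(0)
  rem <- seq_len(ncol(states))
  for (gene in ranking) {
    crit <- vapply(rem, function(j) {
      rel <- oracle_mi(states[, j], labels)
      red <- if (length(sel))
        sum(vapply(sel, function(s) oracle_mi(states[, j], states[, s]),
                   numeric(1))) / length(sel)
      else 0
      rel - red
    }, numeric(1))
    pick <- match(gene, colnames(states))
    if (!(pick %in% rem)) return(FALSE)
    if (crit[match(pick, rem)] < max(crit) - tol) return(FALSE)
    sel <- c(sel, pick)
    rem <- setdiff(rem, pick)
  }
  length(rem) == 0
}

# classical binary MCC from a 2x2 confusion table
binary_mcc <- function(tp, fp, fn, tn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}
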