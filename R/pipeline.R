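#' Fit the full marker-discovery pipeline
#'
#' Runs the complete chain on a labeled expression dataset: optional
#' cell-type size filter, shadow-attribute (Boruta) all-relevant selection,
#' mRMR ranking of the confirmed genes, incremental feature selection with
#' SMOTE-balanced stratified cross-validation for both CART and random
#' forest, rule extraction from a fully grown tree on the CART-optimum gene
#' set, per-class exclusive genes, and (optionally) over-representation
#' analysis of the random-forest-optimum genes. A final random-forest and
#' CART model are refit on all cells for use by [predict.marker_pipeline()].
#'
#' @param ds A [labeled_dataset()].
#' @param min_cells Class-size filter threshold; 0 (default) disables
#'   filtering, 100 reproduces the usual atlas pre-filter.
#' @param boruta_max_iter,boruta_alpha,num_trees Shadow-selection and
#'   forest parameters (see [run_boruta()]).
#' @param step,folds IFS prefix increment and cross-validation folds.
#' @param smote_policy,smote_k Oversampling placement and neighbor count
#'   (see [cross_validate()]).
#' @param gene_sets,universe Optional gene-set list and universe for
#'   [ora()] on the random-forest optimum genes.
#' @param seed Integer seed; every stage derives its own stream from it.
#' @return An object of class `marker_pipeline` with components `boruta`,
#'   `ranking`, `ifs` (named list of `ifs_curve`s), `optima`, `rule_tree`,
#'   `rules`, `exclusive`, `enrichment`, `models`, and the parameters used.
#' @examples
#' \donttest{
#' sim <- simulate_cells(synthetic_config(class_sizes = c(60, 30, 30),
#'                                        n_noise_genes = 20, seed = 1))
#' fit <- marker_pipeline(sim$dataset, boruta_max_iter = 20, folds = 3,
#'                        seed = 1)
#' summary(fit)
#' }
#' @export
marker_pipeline <- function(ds, min_cells = 0,
                            boruta_max_iter = 100, boruta_alpha = 0.05,
                            num_trees = 100, step = 10, folds = 10,
                            smote_policy = "within", smote_k = 5,
                            gene_sets = NULL, universe = NULL, seed = 1) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (min_cells > 0) ds <- filter_cell_types(ds, min_cells)

  bor <- run_boruta(ds, max_iter = boruta_max_iter, alpha = boruta_alpha,
                    num_trees = num_trees, seed = derive_seed(seed, "boruta"))
  if (!length(bor$important))
    stop("no gene confirmed important; nothing to rank")
  sub <- labeled_dataset(ds$x[, bor$important, drop = FALSE], ds$labels)
  ranking <- rank_mrmr(sub)

  specs <- list(cart = classifier_spec("cart"),
                random_forest = classifier_spec("random_forest",
                                                num_trees = num_trees))
  ifs <- lapply(specs, function(sp)
    run_ifs(ds, ranking, spec = sp, step = step, folds = folds,
            smote_policy = smote_policy, smote_k = smote_k,
            seed = derive_seed(seed, paste0("ifs_", sp$name))))
  optima <- lapply(ifs, find_optimum)

  tree <- train_rule_tree(ds, genes = optima$cart$genes,
                          seed = derive_seed(seed, "rules"))
  rules <- extract_rules(tree)
  excl <- exclusive_genes(rules)

  enr <- NULL
  if (!is.null(gene_sets)) {
    if (is.null(universe)) universe <- colnames(ds$x)
    enr <- ora(optima$random_forest$genes, gene_sets, universe)
  }

  models <- lapply(names(specs), function(nm)
    fit_classifier(specs[[nm]], ds$x[, optima[[nm]]$genes, drop = FALSE],
                   ds$labels, seed = derive_seed(seed, paste0("final_", nm))))
  names(models) <- names(specs)

  structure(list(n_cells = nrow(ds$x), n_genes = ncol(ds$x),
                 classes = levels(ds$labels),
                 boruta = bor, ranking = ranking, ifs = ifs,
                 optima = optima, rule_tree = tree, rules = rules,
                 exclusive = excl, enrichment = enr, models = models,
                 params = list(min_cells = min_cells,
                               boruta_max_iter = boruta_max_iter,
                               boruta_alpha = boruta_alpha,
                               num_trees = num_trees, step = step,
                               folds = folds, smote_policy = smote_policy,
                               smote_k = smote_k, seed = seed)),
            class = "marker_pipeline")
}

#' @export
print.marker_pipeline <- function(x, ...) {
  cat(sprintf("marker_pipeline: %d cells x %d genes, %d classes\n",
              x$n_cells, x$n_genes, length(x$classes)))
  cat(sprintf("  confirmed genes: %d of %d\n",
              length(x$boruta$important), x$n_genes))
  for (nm in names(x$optima))
    cat(sprintf("  %s optimum: %d genes, MCC %.3f\n", nm,
                x$optima[[nm]]$n_features, x$optima[[nm]]$mcc))
  cat(sprintf("  rules: %d; classes with exclusive genes: %d\n",
              length(x$rules), length(x$exclusive)))
  invisible(x)
}

#' @export
summary.marker_pipeline <- function(object, ...) {
  print(object)
  cat("\ntop-ranked genes:\n")
  print(utils::head(data.frame(rank = seq_along(object$ranking$gene_ids),
                               gene_id = object$ranking$gene_ids), 10),
        row.names = FALSE)
  if (length(object$exclusive)) {
    cat("\nexclusive genes:\n")
    for (cl in names(object$exclusive))
      cat(" ", cl, ":", paste(object$exclusive[[cl]], collapse = ", "), "\n")
  }
  invisible(object)
}

#' Plot the IFS curves of a fitted pipeline
#'
#' @param x A `marker_pipeline`.
#' @param ... Passed to the underlying plot.
#' @export
plot.marker_pipeline <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$ifs)))
  on.exit(graphics::par(old))
  for (curve in x$ifs) plot(curve, ...)
  invisible(x)
}

#' Predict cell types for new expression profiles
#'
#' Uses the classifier refit on all cells with its optimum gene set.
#'
#' @param object A `marker_pipeline`.
#' @param newdata Expression matrix (cells x genes) containing the optimum
#'   genes, on the same scale as the training data.
#' @param classifier `"random_forest"` (default, the stronger model) or
#'   `"cart"`.
#' @param ... Ignored.
#' @return Factor of predicted class tags.
#' @export
predict.marker_pipeline <- function(object, newdata,
                                    classifier = c("random_forest", "cart"),
                                    ...) {
  classifier <- match.arg(classifier)
  predict_classifier(object$models[[classifier]], newdata)
}

# ---- staged, file-based runner -------------------------------------------

default_config <- function() {
  list(min_cells = 100,
       boruta = list(max_iter = 100, alpha = 0.05, num_trees = 100),
       smote = list(k = 5, policy = "within"),
       ifs = list(step = 10, folds = 10),
       seed = 1)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_config(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  if (is.null(cfg$input) && is.null(cfg$synthetic))
    stop("config needs either an 'input' block or a 'synthetic' block")
  if (!is.null(cfg$input)) {
    for (p in unlist(cfg$input[c("matrix", "labels", "cells", "genes")]))
      if (!file.exists(p)) stop("config references missing file: ", p)
  }
  if (!is.null(cfg$enrichment)) {
    for (p in unlist(cfg$enrichment[c("gmt", "universe")]))
      if (!is.null(p) && !file.exists(p))
        stop("config references missing file: ", p)
  }
  invisible(cfg)
}

#' Run the pipeline from a configuration file, stage by stage
#'
#' Orchestrates simulate/load, filter, Boruta, mRMR, IFS (both
#' classifiers), rule extraction, exclusive genes and optional
#' over-representation analysis, writing every intermediate artifact as
#' plain text into `output_dir` together with `run.log` and a
#' `manifest.json` recording all resolved parameters, seeds, package
#' version and per-stage timings. With `resume = TRUE`, stages whose
#' artifact already exists are skipped and re-read, so a run can be
#' restarted per stage with identical final outputs.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Recognized keys: `input` (matrix, labels and optionally cells,
#'   genes paths) or
#'   `synthetic` (arguments of [synthetic_config()]), `min_cells`,
#'   `boruta` (max_iter, alpha, num_trees), `smote` (k, policy), `ifs`
#'   (step, folds), `enrichment` (gmt, universe paths), `seed`,
#'   `output_dir`. Unset keys fall back to documented defaults.
#' @param output_dir Overrides the config's output directory.
#' @param resume Skip stages whose artifacts already exist.
#' @return Invisibly, a list with the artifact paths and the key in-memory
#'   results.
#' @export
run_pipeline <- function(config, output_dir = NULL, resume = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- merge_config(default_config(), cfg)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (is.null(cfg$output_dir)) stop("no output directory configured")
  validate_config(cfg)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run.log")
  note <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  seed <- cfg$seed
  timings <- list()
  art <- list(boruta = file.path(out, "boruta_report.tsv"),
              ranked = file.path(out, "ranked_genes.tsv"),
              ifs_cart = file.path(out, "ifs_cart.tsv"),
              ifs_rf = file.path(out, "ifs_random_forest.tsv"),
              rules = file.path(out, "rules.tsv"),
              exclusive = file.path(out, "exclusive_genes.tsv"),
              manifest = file.path(out, "manifest.json"))
  stage <- function(name, path, compute, reload) {
    t0 <- Sys.time()
    if (resume && !is.null(path) && all(file.exists(path))) {
      note("stage ", name, ": resumed from ", paste(path, collapse = ", "))
      val <- reload()
    } else {
      val <- compute()
      note("stage ", name, ": done")
    }
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    val
  }

  # -- data -----------------------------------------------------------------
  if (!is.null(cfg$synthetic)) {
    paths <- c(matrix = file.path(out, "synthetic_matrix.tsv"),
               labels = file.path(out, "synthetic_labels.tsv"))
    ds <- stage("simulate", unname(paths), function() {
      sc_args <- cfg$synthetic
      sc_args$class_sizes <- unlist(sc_args$class_sizes)
      if (is.null(sc_args$seed)) sc_args$seed <- derive_seed(seed, "simulate")
      sim <- simulate_cells(do.call(synthetic_config, sc_args))
      write_simulation(sim, out, "synthetic")
      sim$dataset
    }, function() read_dataset(paths[["matrix"]], paths[["labels"]]))
  } else {
    ds <- stage("load", NULL, function()
      read_dataset(cfg$input$matrix, cfg$input$labels,
                   format = if (is.null(cfg$input$format)) "auto"
                            else cfg$input$format,
                   cells_path = cfg$input$cells,
                   genes_path = cfg$input$genes), NULL)
  }
  if (cfg$min_cells > 0) {
    ds <- filter_cell_types(ds, cfg$min_cells)
    note("filter: ", nrow(ds$x), " cells in ", nlevels(ds$labels),
         " classes pass >", cfg$min_cells)
  }

  # -- boruta ---------------------------------------------------------------
  bor <- stage("boruta", art$boruta, function() {
    b <- run_boruta(ds, max_iter = cfg$boruta$max_iter,
                    alpha = cfg$boruta$alpha,
                    num_trees = cfg$boruta$num_trees,
                    seed = derive_seed(seed, "boruta"))
    write_boruta_report(b, art$boruta)
    b
  }, function() read_boruta_report(art$boruta))
  if (!length(bor$important)) stop("stage boruta: no gene confirmed important")
  note("boruta: ", length(bor$important), " important genes")

  # -- mrmr -----------------------------------------------------------------
  ranking <- stage("mrmr", art$ranked, function() {
    sub <- labeled_dataset(ds$x[, bor$important, drop = FALSE], ds$labels)
    r <- rank_mrmr(sub)
    write_ranked_genes(r, art$ranked)
    r
  }, function() read_ranked_genes(art$ranked))

  # -- ifs ------------------------------------------------------------------
  ifs_stage <- function(nm, path) {
    stage(paste0("ifs_", nm), path, function() {
      sp <- classifier_spec(nm, num_trees = cfg$boruta$num_trees)
      curve <- run_ifs(ds, ranking, spec = sp, step = cfg$ifs$step,
                       folds = cfg$ifs$folds,
                       smote_policy = cfg$smote$policy,
                       smote_k = cfg$smote$k,
                       seed = derive_seed(seed, paste0("ifs_", nm)))
      write_ifs_table(curve, path)
      curve
    }, function() {
      df <- utils::read.table(path, header = TRUE, sep = "\t")
      structure(list(n_features = df$n_features, mcc = df$mcc,
                     overall_accuracy = df$overall_accuracy,
                     records = vector("list", nrow(df)),
                     classifier = nm, ranked = ranking),
                class = "ifs_curve")
    })
  }
  ifs <- list(cart = ifs_stage("cart", art$ifs_cart),
              random_forest = ifs_stage("random_forest", art$ifs_rf))
  optima <- lapply(ifs, find_optimum)
  for (nm in names(optima))
    note("ifs ", nm, ": optimum ", optima[[nm]]$n_features,
         " genes, MCC ", sprintf("%.4f", optima[[nm]]$mcc))

  # -- rules ----------------------------------------------------------------
  rules <- stage("rules", c(art$rules, art$exclusive), function() {
    tree <- train_rule_tree(ds, genes = optima$cart$genes,
                            seed = derive_seed(seed, "rules"))
    rs <- extract_rules(tree)
    write_rules(rs, art$rules)
    excl <- exclusive_genes(rs)
    df <- if (length(excl))
      data.frame(class = rep(names(excl), lengths(excl)),
                 gene_id = unlist(excl, use.names = FALSE))
    else data.frame(class = character(), gene_id = character())
    utils::write.table(df, art$exclusive, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    rs
  }, function() NULL)

  # -- enrichment -----------------------------------------------------------
  enr <- NULL
  if (!is.null(cfg$enrichment)) {
    enr <- stage("enrichment", file.path(out, "enrichment.tsv"), function() {
      sets <- read_gmt(cfg$enrichment$gmt)
      uni <- readLines(cfg$enrichment$universe)
      res <- ora(optima$random_forest$genes, sets, uni,
                 alpha = if (is.null(cfg$enrichment$alpha)) 0.001
                         else cfg$enrichment$alpha)
      utils::write.table(res, file.path(out, "enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      res
    }, function() utils::read.table(file.path(out, "enrichment.tsv"),
                                    header = TRUE, sep = "\t"))
  }

  manifest <- list(package = "scMarkerRules",
                   version = as.character(utils::packageVersion("scMarkerRules")),
                   r_version = R.version.string,
                   config = cfg,
                   stage_seeds = lapply(
                     stats::setNames(nm = c("simulate", "boruta", "mrmr",
                                            "ifs_cart", "ifs_random_forest",
                                            "rules")),
                     function(s) derive_seed(seed, s)),
                   timings_sec = timings)
  jsonlite::write_json(manifest, art$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  note("manifest written")
  invisible(list(artifacts = art, dataset = ds, boruta = bor,
                 ranking = ranking, ifs = ifs, optima = optima,
                 rules = rules, enrichment = enr, config = cfg))
}
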