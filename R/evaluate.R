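#' Stratified k-fold cross-validation of the full pipeline
#'
#' Splits samples into k stratified folds (per-class fold sizes differ by at
#' most one) and, for each fold, runs gene selection, training and
#' prediction, reporting a `MetricsReport` per fold plus the across-fold
#' mean and SD of the macro metrics and overall accuracy. Under the default
#' leak-free `"per_fold"` policy, gene selection and standardisation are fit
#' inside each training fold only; `"global"` selects once on the full
#' dataset before splitting (faster, but lets test information into the
#' feature choice — exposed because published workflows are often silent
#' about which they did).
#'
#' @param ds A labelled `ExpressionDataset`.
#' @param k Number of folds (default 10).
#' @param selection_policy `"per_fold"` (default) or `"global"`.
#' @param fc_threshold,q_threshold Selection thresholds, as in
#'   [select_subtype_specific_genes()].
#' @param config A `TrainConfig` for the per-fold networks.
#' @param seed Integer seed controlling fold assignment and (via derived
#'   per-fold seeds) training; the whole procedure is deterministic in it.
#' @return A `cv_result` list: `folds` (per-fold list with `metrics`,
#'   `n_genes`, `n_test`), `aggregate` (data frame of mean and sd per
#'   summary metric), `policy`, `k`.
#' @export
cross_validate <- function(ds, k = 10,
                           selection_policy = c("per_fold", "global"),
                           fc_threshold = 1, q_threshold = 0.05,
                           config = train_config(), seed = 1) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  selection_policy <- match.arg(selection_policy)
  if (is.null(ds$labels)) stop("cross-validation needs labels")
  if (k < 2) stop("k must be >= 2")
  seed <- as.integer(seed)
  set.seed(seed)
  fold <- stratified_folds(ds$labels, k)

  global_genes <- NULL
  if (selection_policy == "global") {
    global_genes <- select_subtype_specific_genes(
      ds, fc_threshold, q_threshold)$genes
  }

  folds <- vector("list", k)
  for (f in seq_len(k)) {
    train_ds <- subset_samples(ds, fold != f)
    test_ds <- subset_samples(ds, fold == f)
    genes <- if (is.null(global_genes)) {
      select_subtype_specific_genes(train_ds, fc_threshold,
                                    q_threshold)$genes
    } else global_genes
    if (!length(genes$gene_ids))
      stop("fold ", f, ": no genes selected; relax the thresholds")
    fold_config <- config
    fold_config$seed <- seed + f
    model <- train_network(align_to_genes(train_ds, genes), fold_config)
    pred <- predict_cms(model, test_ds)
    cc <- confusion_counts(test_ds$labels, pred$predicted)
    folds[[f]] <- list(metrics = classification_metrics(cc),
                       n_genes = length(genes$gene_ids),
                       n_test = ncol(test_ds$values))
  }

  summarise <- function(extract) {
    x <- vapply(folds, extract, numeric(1))
    c(mean = mean(x), sd = stats::sd(x))
  }
  agg <- rbind(
    macro_sensitivity = summarise(function(f) f$metrics$macro["sensitivity"]),
    macro_specificity = summarise(function(f) f$metrics$macro["specificity"]),
    macro_precision = summarise(function(f) f$metrics$macro["precision"]),
    macro_class_accuracy =
      summarise(function(f) f$metrics$macro["class_accuracy"]),
    overall_accuracy = summarise(function(f) f$metrics$overall_accuracy),
    n_genes = summarise(function(f) f$n_genes)
  )
  structure(
    list(folds = folds,
         aggregate = data.frame(metric = rownames(agg), mean = agg[, 1],
                                sd = agg[, 2], row.names = NULL),
         policy = selection_policy, k = k),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Stratified", x$k, "fold cross-validation (selection:", x$policy,
      ")\n")
  print(x$aggregate, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Stratified hold-out split
#'
#' Random stratified split into a training and a test set. Within each
#' class, `round(fraction * n_class)` samples go to the training set, so
#' e.g. 512 labelled samples at the customary 9:1 ratio give a test set of
#' 51-52 depending on per-class rounding.
#'
#' @param ds A labelled `ExpressionDataset`.
#' @param train_fraction Fraction assigned to training, strictly in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` datasets (disjoint, covering all
#'   samples).
#' @export
holdout_split <- function(ds, train_fraction = 0.9, seed = 1) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.null(ds$labels)) stop("hold-out split needs labels")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be strictly between 0 and 1")
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (cl in unique(ds$labels)) {
    idx <- which(ds$labels == cl)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  list(train = subset_samples(ds, train_idx),
       test = subset_samples(ds, setdiff(seq_along(ds$labels), train_idx)))
}

#' Scan the regularisation coefficient by cross-validation
#'
#' Re-runs [cross_validate()] for each coefficient in the grid (the same
#' value used for both L1 and L2), with identical folds across grid points
#' (the fold seed is shared), and tabulates the mean and SD of overall
#' cross-validated accuracy. Past its optimum the curve is expected to fall:
#' too large a penalty limits what the network can learn.
#'
#' @param ds A labelled `ExpressionDataset`.
#' @param coef_grid Numeric vector of penalty coefficients (default
#'   0.1..0.9).
#' @param k Folds per grid point.
#' @param config Base `TrainConfig`; its `l1_coef`/`l2_coef` are overridden
#'   per grid point.
#' @param seed Integer seed shared across grid points.
#' @param ... Passed on to [cross_validate()].
#' @return Data frame with `coef`, `mean_accuracy`, `sd_accuracy`.
#' @export
regularizer_scan <- function(ds, coef_grid = seq(0.1, 0.9, by = 0.1),
                             k = 10, config = train_config(), seed = 1,
                             ...) {
  if (!length(coef_grid) || any(coef_grid < 0))
    stop("coef_grid must be non-negative and non-empty")
  rows <- lapply(coef_grid, function(cf) {
    cfg <- config
    cfg$l1_coef <- cf
    cfg$l2_coef <- cf
    cv <- cross_validate(ds, k = k, config = cfg, seed = seed, ...)
    acc <- cv$aggregate[cv$aggregate$metric == "overall_accuracy", ]
    data.frame(coef = cf, mean_accuracy = acc$mean, sd_accuracy = acc$sd)
  })
  do.call(rbind, rows)
}

#' Top genes by absolute weight per first-layer neuron
#'
#' Ranks the genes feeding each requested layer-1 neuron by the absolute
#' value of their connection weight, descending, ties broken by gene id —
#' the first step of weight-based interpretability, producing lists suitable
#' for external enrichment tools.
#'
#' @param model A `cms_model` (or `NetworkParams` plus `gene_ids`).
#' @param neuron_indices Layer-1 neuron indices (default the first 10).
#' @param k Number of genes per neuron (default 100, capped at the input
#'   width).
#' @param gene_ids Optional gene ids if `model` is a bare `NetworkParams`.
#' @return Named list (one element per neuron, `"neuron_<i>"`) of character
#'   vectors of gene ids.
#' @export
top_weight_genes <- function(model, neuron_indices = 1:10, k = 100,
                             gene_ids = NULL) {
  if (inherits(model, "cms_model")) {
    W1 <- model$params$W1
    gene_ids <- model$gene_ids
  } else if (inherits(model, "NetworkParams")) {
    W1 <- model$W1
    if (is.null(gene_ids)) stop("gene_ids required with bare NetworkParams")
  } else stop("model must be a cms_model or NetworkParams")
  if (length(gene_ids) != ncol(W1))
    stop("gene_ids length does not match the input width")
  if (any(neuron_indices < 1 | neuron_indices > nrow(W1)))
    stop("neuron index out of range (layer width ", nrow(W1), ")")
  if (k > ncol(W1)) stop("k exceeds the number of input genes")
  out <- lapply(neuron_indices, function(i) {
    w <- abs(W1[i, ])
    ord <- order(-w, gene_ids, method = "radix")
    gene_ids[ord][seq_len(k)]
  })
  names(out) <- paste0("neuron_", neuron_indices)
  out
}
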