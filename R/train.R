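#' Training configuration
#'
#' Collects every tunable of the training loop. Defaults follow common deep
#' learning practice where the method is silent: mini-batches of 32, at most
#' 200 epochs with early stopping after 20 epochs without improvement of the
#' full-data training loss, Adam at step size 1e-3 with its usual moment
#' defaults, and a reduce-on-plateau schedule (factor 0.1 after
#' `lr_patience` flat epochs) floored at `min_alpha = 1e-5`, the method's
#' stated minimum learning rate. Dropout keep probability 0.5 and L1/L2
#' coefficients of 0.3 are the method's chosen operating point.
#'
#' @param hidden Widths of the two representation layers.
#' @param dropout_keep_p Dropout keep probability in (0, 1].
#' @param l1_coef,l2_coef L1 / L2 penalty coefficients on hidden weights.
#' @param alpha Initial Adam step size.
#' @param min_alpha Learning-rate floor for the plateau schedule.
#' @param lr_factor Multiplicative learning-rate decay on plateau.
#' @param lr_patience Flat epochs before the learning rate is reduced.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Flat epochs before early stopping.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout; training is bit-reproducible under a fixed seed.
#' @return A `TrainConfig` list.
#' @export
train_config <- function(hidden = c(768, 128), dropout_keep_p = 0.5,
                         l1_coef = 0.3, l2_coef = 0.3, alpha = 1e-3,
                         min_alpha = 1e-5, lr_factor = 0.1,
                         lr_patience = 10, batch_size = 32,
                         max_epochs = 200, patience = 20, seed = 1) {
  structure(
    list(hidden = as.integer(hidden), dropout_keep_p = dropout_keep_p,
         l1_coef = l1_coef, l2_coef = l2_coef, alpha = alpha,
         min_alpha = min_alpha, lr_factor = lr_factor,
         lr_patience = as.integer(lr_patience),
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), seed = as.integer(seed)),
    class = "TrainConfig"
  )
}

# Per-gene z-scoring statistics; zero-variance genes get scale 1 so they
# standardise to a constant instead of NaN.
fit_standardizer <- function(values) {
  center <- rowMeans(values)
  scale <- apply(values, 1L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(values, std) {
  (values - std$center) / std$scale
}

#' Train the subtype classifier
#'
#' Expects a labelled dataset whose rows are already restricted to the
#' selected gene set (see [select_subtype_specific_genes()] and
#' [align_to_genes()]). Per-gene z-scoring is fit here on the training data
#' and stored in the model so prediction reuses the same statistics.
#' Optimisation is mini-batch Adam on the regularised cross-entropy, with
#' dropout on the two hidden layers; the per-epoch loss breakdown and
#' training accuracy are recorded in `history`.
#'
#' @param ds A labelled `ExpressionDataset` (all four CMS classes present).
#' @param config A `TrainConfig`.
#' @return A `cms_model` list: `params`, `gene_ids`, `center`, `scale`,
#'   `classes`, `config` and `history` (data frame of epoch, data_loss,
#'   l1_penalty, l2_penalty, total, accuracy, alpha).
#' @export
train_network <- function(ds, config = train_config()) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            inherits(config, "TrainConfig"))
  if (is.null(ds$labels)) stop("training data must have labels")
  missing_classes <- setdiff(cms_levels(), unique(ds$labels))
  if (length(missing_classes))
    stop("class(es) absent from training data: ",
         paste(missing_classes, collapse = ", "))
  n <- ncol(ds$values)
  set.seed(config$seed)

  std <- fit_standardizer(ds$values)
  Xs <- apply_standardizer(ds$values, std)    # genes x samples
  X <- t(Xs)                                  # samples x genes
  Y <- one_hot(ds$labels)

  params <- network_params(
    d_in = nrow(ds$values), hidden = config$hidden,
    dropout_keep_p = config$dropout_keep_p,
    l1_coef = config$l1_coef, l2_coef = config$l2_coef
  )
  trainable <- c("W1", "theta1", "W2", "theta2", "W3", "theta3")
  state <- adam_init(params[trainable], alpha = config$alpha)

  history <- vector("list", config$max_epochs)
  best_loss <- Inf
  since_best <- 0L
  since_lr <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      fw <- forward(params, X[idx, , drop = FALSE], mode = "train")
      grads <- backward(fw$cache, Y[, idx, drop = FALSE], params)
      upd <- adam_step(params, grads, state)
      params <- upd$params
      state <- upd$state
    }
    ev <- forward(params, X, mode = "eval")
    lb <- network_loss(ev$probs, Y, params)
    acc <- mean(max.col(ev$probs, ties.method = "first") ==
                  max.col(t(Y), ties.method = "first"))
    history[[epoch]] <- data.frame(
      epoch = epoch, data_loss = lb$data_loss, l1_penalty = lb$l1_penalty,
      l2_penalty = lb$l2_penalty, total = lb$total, accuracy = acc,
      alpha = state$alpha
    )
    if (lb$total < best_loss - 1e-8) {
      best_loss <- lb$total
      since_best <- 0L
      since_lr <- 0L
    } else {
      since_best <- since_best + 1L
      since_lr <- since_lr + 1L
    }
    if (since_best >= config$patience) break
    if (since_lr >= config$lr_patience && state$alpha > config$min_alpha) {
      state$alpha <- max(state$alpha * config$lr_factor, config$min_alpha)
      since_lr <- 0L
    }
  }
  structure(
    list(params = params, gene_ids = ds$gene_ids, center = std$center,
         scale = std$scale, classes = cms_levels(), config = config,
         history = do.call(rbind, history[!vapply(history, is.null,
                                                  logical(1))])),
    class = "cms_model"
  )
}

#' @export
print.cms_model <- function(x, ...) {
  cat("cms_model:", length(x$gene_ids), "genes ->",
      paste(x$config$hidden, collapse = "/"), "->",
      length(x$classes), "classes;",
      nrow(x$history), "epochs trained\n")
  invisible(x)
}

#' Predict CMS labels for a dataset
#'
#' Aligns the dataset rows to the model's gene set, standardises, and runs a
#' deterministic eval-mode forward pass. With `standardize = "stored"`
#' (default) the per-gene statistics fit on the training data are reused —
#' appropriate when the new samples come from the same platform as the
#' training cohort. With `standardize = "cohort"` the incoming cohort is
#' z-scored per gene with its own statistics, which exactly removes any
#' affine (location/scale) platform shift and is the recommended mode when
#' annotating an independent dataset from a different platform.
#'
#' @param model A `cms_model` from [train_network()] or [load_model()].
#' @param ds An `ExpressionDataset` (labels not required).
#' @param missing_policy Passed to [align_to_genes()]; `"fill_mean"` uses the
#'   training means stored in the model.
#' @param standardize `"stored"` or `"cohort"` (see Details).
#' @return Data frame with `sample_id`, `predicted` and one probability
#'   column per CMS class; probability rows sum to 1.
#' @export
predict_cms <- function(model, ds,
                        missing_policy = c("error", "fill_zero",
                                           "fill_mean"),
                        standardize = c("stored", "cohort")) {
  stopifnot(inherits(model, "cms_model"), inherits(ds, "ExpressionDataset"))
  missing_policy <- match.arg(missing_policy)
  standardize <- match.arg(standardize)
  means <- stats::setNames(model$center, model$gene_ids)
  aligned <- align_to_genes(ds, model$gene_ids, missing_policy,
                            gene_means = means)
  std <- if (standardize == "stored") {
    list(center = model$center, scale = model$scale)
  } else {
    if (ncol(aligned$values) < 2L)
      stop("standardize = \"cohort\" needs at least 2 samples")
    fit_standardizer(aligned$values)
  }
  Xs <- apply_standardizer(aligned$values, std)
  ev <- forward(model$params, t(Xs), mode = "eval")
  probs <- ev$probs
  colnames(probs) <- model$classes
  data.frame(
    sample_id = aligned$sample_ids,
    predicted = model$classes[max.col(probs, ties.method = "first")],
    probs, stringsAsFactors = FALSE, check.names = FALSE
  )
}
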