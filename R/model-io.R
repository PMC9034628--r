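#' Save a trained model bundle
#'
#' Writes a versioned JSON bundle containing the network weights, the
#' selected gene ids in their network-input order, the per-gene
#' standardisation statistics and the training configuration. Numbers are
#' written with 17 significant digits so `load_model(save_model(m))`
#' reproduces predictions bit-identically.
#'
#' @param model A `cms_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cms_model"))
  p <- model$params
  bundle <- list(
    format = "cms_model_bundle",
    format_version = 1L,
    classes = model$classes,
    gene_ids = model$gene_ids,
    center = unname(model$center),
    scale = unname(model$scale),
    config = unclass(model$config),
    params = list(
      d_in = ncol(p$W1), hidden = c(nrow(p$W1), nrow(p$W2)),
      n_classes = nrow(p$W3),
      dropout_keep_p = p$dropout_keep_p,
      l1_coef = p$l1_coef, l2_coef = p$l2_coef,
      W1 = as.numeric(p$W1), theta1 = as.numeric(p$theta1),
      W2 = as.numeric(p$W2), theta2 = as.numeric(p$theta2),
      W3 = as.numeric(p$W3), theta3 = as.numeric(p$theta3)
    )
  )
  jsonlite::write_json(bundle, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a model bundle
#'
#' @param path Path written by [save_model()].
#' @return A `cms_model`.
#' @export
load_model <- function(path) {
  bundle <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                     error = function(e)
                       stop("corrupted model bundle: ",
                            conditionMessage(e)))
  if (!identical(bundle$format, "cms_model_bundle"))
    stop("not a model bundle: ", path)
  if (!identical(as.integer(bundle$format_version), 1L))
    stop("unsupported bundle version: ", bundle$format_version)
  bp <- bundle$params
  need <- c("d_in", "hidden", "n_classes", "W1", "theta1", "W2", "theta2",
            "W3", "theta3")
  if (!all(need %in% names(bp)))
    stop("corrupted model bundle: missing parameter fields")
  d_in <- as.integer(bp$d_in)
  h <- as.integer(bp$hidden)
  k <- as.integer(bp$n_classes)
  shape <- function(x, nr, nc, what) {
    x <- as.numeric(x)
    if (length(x) != nr * nc)
      stop("corrupted model bundle: ", what, " has wrong length")
    matrix(x, nr, nc)
  }
  params <- structure(
    list(W1 = shape(bp$W1, h[1], d_in, "W1"),
         theta1 = as.numeric(bp$theta1),
         W2 = shape(bp$W2, h[2], h[1], "W2"),
         theta2 = as.numeric(bp$theta2),
         W3 = shape(bp$W3, k, h[2], "W3"),
         theta3 = as.numeric(bp$theta3),
         dropout_keep_p = bp$dropout_keep_p,
         l1_coef = bp$l1_coef, l2_coef = bp$l2_coef),
    class = "NetworkParams"
  )
  cfg <- bundle$config
  config <- train_config(
    hidden = cfg$hidden, dropout_keep_p = cfg$dropout_keep_p,
    l1_coef = cfg$l1_coef, l2_coef = cfg$l2_coef, alpha = cfg$alpha,
    min_alpha = cfg$min_alpha, lr_factor = cfg$lr_factor,
    lr_patience = cfg$lr_patience, batch_size = cfg$batch_size,
    max_epochs = cfg$max_epochs, patience = cfg$patience, seed = cfg$seed
  )
  structure(
    list(params = params, gene_ids = as.character(bundle$gene_ids),
         center = as.numeric(bundle$center),
         scale = as.numeric(bundle$scale),
         classes = as.character(bundle$classes), config = config,
         history = NULL),
    class = "cms_model"
  )
}
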