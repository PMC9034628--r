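#' Configuration for the synthetic expression simulator
#'
#' Defines a four-class (CMS1..CMS4) log2-scale expression cohort with a
#' planted set of subtype-specific genes. Background genes are
#' `Normal(baseline_mean, noise_sd)` in every class; a gene planted for the
#' subtype pair (a, b) has its class-a mean shifted by `+/- effect_size`
#' relative to class b (the sign is drawn per gene and recorded in the truth
#' table). Each planted gene belongs to exactly one pair, so selector recall
#' and precision against the truth record are unambiguous.
#'
#' Defaults describe a desk-scale cohort in the range of real colorectal
#' microarray series: 60 samples per class, 2000 genes, 50 planted genes for
#' each of the six subtype pairs, a two-fold-squared (2 log2 units) effect and
#' within-class SD of 0.5 log2 units around a baseline intensity of 7.
#'
#' @param n_samples_per_class Integer vector of 4 per-class sample counts
#'   (classes may be unbalanced, as real CMS cohorts are).
#' @param n_genes Total number of genes.
#' @param n_specific_per_pair Planted genes per pair; scalar or vector of 6
#'   (order of [cms_pairs()]).
#' @param effect_size Mean log2 shift of a planted gene in its up-regulated
#'   class (log2 expression units, >= 0).
#' @param noise_sd Within-class Gaussian SD (log2 units, > 0).
#' @param baseline_mean Background mean log2 intensity.
#' @param platform_shift Optional `list(location =, scale =)` affine shift
#'   applied to the generated values, emulating a cross-platform difference.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_samples_per_class = c(60, 60, 60, 60),
                              n_genes = 2000,
                              n_specific_per_pair = 50,
                              effect_size = 2,
                              noise_sd = 0.5,
                              baseline_mean = 7,
                              platform_shift = NULL,
                              seed = 1) {
  n_samples_per_class <- as.integer(n_samples_per_class)
  if (length(n_samples_per_class) != 4L || any(n_samples_per_class < 1L))
    stop("n_samples_per_class must be 4 positive integers")
  if (length(n_specific_per_pair) == 1L)
    n_specific_per_pair <- rep(as.integer(n_specific_per_pair), 6L)
  n_specific_per_pair <- as.integer(n_specific_per_pair)
  if (length(n_specific_per_pair) != 6L || any(n_specific_per_pair < 0L))
    stop("n_specific_per_pair must be 6 non-negative integers")
  if (sum(n_specific_per_pair) > n_genes)
    stop("total planted genes (", sum(n_specific_per_pair),
         ") exceeds n_genes (", n_genes, ")")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (!is.null(platform_shift) &&
      (is.null(platform_shift$location) || is.null(platform_shift$scale)))
    stop("platform_shift must be list(location =, scale =)")
  structure(
    list(n_samples_per_class = n_samples_per_class,
         n_genes = as.integer(n_genes),
         n_specific_per_pair = n_specific_per_pair,
         effect_size = effect_size, noise_sd = noise_sd,
         baseline_mean = baseline_mean, platform_shift = platform_shift,
         seed = as.integer(seed)),
    class = "SimulationConfig"
  )
}

#' Simulate a labelled four-class expression dataset
#'
#' @param cfg A `SimulationConfig` from [simulation_config()].
#' @param truth Optional truth data frame from a previous call. When
#'   supplied, the same genes are planted with the same signs (fresh noise
#'   is still drawn from `cfg$seed`), producing an independent replicate of
#'   the same population — e.g. a test cohort for a model trained on the
#'   original draw.
#' @return A list with `dataset` (an `ExpressionDataset` with labels) and
#'   `truth`: a data frame with one row per planted gene (`gene`, `pair`,
#'   `sign`, `up_class`, `down_class`), where `sign = +1` means the gene is
#'   up in the pair's first class.
#' @export
simulate_dataset <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  n_per <- cfg$n_samples_per_class
  n <- sum(n_per)
  labels <- rep(cms_levels(), times = n_per)
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  sample_ids <- sprintf("S%04d", seq_len(n))
  values <- matrix(stats::rnorm(cfg$n_genes * n, mean = cfg$baseline_mean,
                                sd = cfg$noise_sd),
                   nrow = cfg$n_genes, ncol = n)

  if (is.null(truth)) {
    truth <- draw_truth(cfg, gene_ids)
  } else {
    if (!all(truth$gene %in% gene_ids))
      stop("supplied truth refers to genes outside this configuration")
  }
  pairs_first <- vapply(strsplit(truth$pair, "_vs_"), `[`, character(1), 1)
  for (i in seq_len(nrow(truth))) {
    g <- match(truth$gene[i], gene_ids)
    cols_a <- which(labels == pairs_first[i])
    # the pair's first class is shifted by sign * effect relative to the
    # second, which stays at baseline
    values[g, cols_a] <- values[g, cols_a] + truth$sign[i] * cfg$effect_size
  }

  if (nrow(truth)) rownames(truth) <- NULL

  if (!is.null(cfg$platform_shift)) {
    values <- values * cfg$platform_shift$scale + cfg$platform_shift$location
  }
  list(
    dataset = expression_dataset(values, gene_ids, sample_ids,
                                 labels = labels),
    truth = truth
  )
}

# draw the planted-gene assignment: which genes, which pair, which sign
draw_truth <- function(cfg, gene_ids) {
  total_planted <- sum(cfg$n_specific_per_pair)
  if (total_planted == 0L)
    return(data.frame(gene = character(0), pair = character(0),
                      sign = integer(0), up_class = character(0),
                      down_class = character(0), stringsAsFactors = FALSE))
  planted_idx <- sample(cfg$n_genes, total_planted)
  signs <- sample(c(-1L, 1L), total_planted, replace = TRUE)
  pairs <- cms_pairs()
  offset <- 0L
  rows <- vector("list", 6L)
  for (p in seq_along(pairs)) {
    np <- cfg$n_specific_per_pair[p]
    if (np == 0L) next
    idx <- planted_idx[offset + seq_len(np)]
    sg <- signs[offset + seq_len(np)]
    offset <- offset + np
    a <- pairs[[p]][1]; b <- pairs[[p]][2]
    rows[[p]] <- data.frame(
      gene = gene_ids[idx], pair = pair_label(pairs[[p]]), sign = sg,
      up_class = ifelse(sg > 0, a, b), down_class = ifelse(sg > 0, b, a),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Apply an affine cross-platform shift to a dataset
#'
#' Emulates a location/scale difference between measurement platforms on the
#' log2 scale: `x' = scale * x + location`. The defaults (half a log2 unit of
#' location offset, 20% scale inflation) represent a moderate shift between
#' microarray platforms or labs.
#'
#' @param ds An `ExpressionDataset`.
#' @param location Additive offset (log2 units).
#' @param scale Multiplicative factor.
#' @return The shifted `ExpressionDataset`.
#' @export
apply_platform_shift <- function(ds, location = 0.5, scale = 1.2) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  expression_dataset(ds$values * scale + location, ds$gene_ids,
                     ds$sample_ids, labels = ds$labels)
}
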