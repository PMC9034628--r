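#' Log2 fold-change between two expression groups
#'
#' On log2-scale data (the package convention) the log2 fold-change is the
#' difference of group means, i.e. the log2 ratio of geometric means on the
#' linear scale. With `log_scale = FALSE` the inputs are taken as linear
#' intensities and the classical ratio-of-arithmetic-means definition
#' `log2(mean(a) / mean(b))` is used.
#'
#' @param group_a,group_b Non-empty numeric vectors of expression values for
#'   the same gene in two subtype groups.
#' @param log_scale Logical; are the inputs already log2-transformed?
#' @return The log2 fold-change of a over b (a single number).
#' @export
log2_fold_change <- function(group_a, group_b, log_scale = TRUE) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  if (log_scale) mean(group_a) - mean(group_b)
  else log2(mean(group_a) / mean(group_b))
}

#' Welch two-sample t statistic
#'
#' `t = (mean(a) - mean(b)) / sqrt(s2_a/n_a + s2_b/n_b)` with sample
#' variances (denominator n - 1), Welch-Satterthwaite degrees of freedom and
#' a two-sided p value from the t distribution. Unpooled variances make the
#' statistic valid for the unbalanced group sizes typical of CMS cohorts.
#'
#' Degenerate inputs follow explicit conventions rather than silent drops:
#' both variances zero with equal means gives `t = 0, p = 1`; both zero with
#' different means gives `p = 0` with a warning.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @return A list with `t`, `df` and `p`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  r <- row_welch(matrix(group_a, nrow = 1L), matrix(group_b, nrow = 1L))
  list(t = r$t, df = r$df, p = r$p)
}

# Vectorised Welch t over gene rows; A and B are genes x samples matrices.
row_welch <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- row_vars(A); vb <- row_vars(B)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  degenerate <- se2 == 0
  if (any(degenerate)) {
    eq <- degenerate & (ma == mb)
    ne <- degenerate & (ma != mb)
    t[eq] <- 0; df[eq] <- na + nb - 2; t[ne] <- Inf * sign(ma - mb)[ne]
    df[ne] <- na + nb - 2
    if (any(ne))
      warning(sum(ne), " gene(s) with zero variance in both groups and ",
              "different means; p set to 0")
  }
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p values ascending, forms `p_(i) * m / i`, takes the running minimum
#' from the largest rank down, caps at 1 and maps back to the input order.
#' Ties are handled stably.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return Vector of Q values in the input order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must be finite and within [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Select subtype-specific genes across the six CMS pair comparisons
#'
#' For every ordered subtype pair with at least 2 samples per class, each
#' gene's log2 fold-change (difference of group means on log2 data), Welch t
#' statistic and BH-adjusted Q value are computed; a gene is selected for a
#' pair when `|log2FC| > fc_threshold` and `Q < q_threshold`. The gene set is
#' the deterministic union of the six per-pair selections (see [gene_set()]
#' for the ordering rule).
#'
#' @param ds A labelled `ExpressionDataset`.
#' @param fc_threshold Absolute log2 fold-change cut-off (default 1, i.e. a
#'   two-fold change).
#' @param q_threshold FDR cut-off on the BH Q value (default 0.05).
#' @param bh_scope `"per_pair"` (default) adjusts p values within each pair
#'   comparison across genes; `"pooled"` adjusts across all six comparisons
#'   jointly.
#' @return A list with `genes` (a `GeneSet`) and `table`: a data frame with
#'   one row per (gene, pair) giving `gene`, `pair`, `mean_a`, `mean_b`,
#'   `log2fc`, `t`, `df`, `p`, `q` and `selected`.
#' @export
select_subtype_specific_genes <- function(ds, fc_threshold = 1,
                                          q_threshold = 0.05,
                                          bh_scope = c("per_pair",
                                                       "pooled")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  bh_scope <- match.arg(bh_scope)
  if (is.null(ds$labels)) stop("dataset has no labels")
  counts <- table(factor(ds$labels, levels = cms_levels()))
  usable <- names(counts)[counts >= 2L]
  if (length(usable) < 2L)
    stop("need at least two classes with >= 2 samples each")

  pieces <- list()
  skipped <- character(0)
  for (pair in cms_pairs()) {
    lb <- pair_label(pair)
    if (!all(pair %in% usable)) {
      if (any(counts[pair] > 0L)) skipped <- c(skipped, lb)
      next
    }
    A <- ds$values[, ds$labels == pair[1], drop = FALSE]
    B <- ds$values[, ds$labels == pair[2], drop = FALSE]
    st <- row_welch(A, B)
    pieces[[lb]] <- data.frame(
      gene = ds$gene_ids, pair = lb, mean_a = st$mean_a, mean_b = st$mean_b,
      log2fc = st$mean_a - st$mean_b, t = st$t, df = st$df, p = st$p,
      q = NA_real_, stringsAsFactors = FALSE
    )
  }
  if (length(skipped))
    warning("skipping ", paste(skipped, collapse = ", "),
            ": a class has fewer than 2 samples")
  if (!length(pieces)) stop("no subtype pair has enough samples")

  if (bh_scope == "per_pair") {
    for (lb in names(pieces)) pieces[[lb]]$q <- bh_adjust(pieces[[lb]]$p)
    tab <- do.call(rbind, pieces)
  } else {
    tab <- do.call(rbind, pieces)
    tab$q <- bh_adjust(tab$p)
  }
  rownames(tab) <- NULL
  tab$selected <- abs(tab$log2fc) > fc_threshold & tab$q < q_threshold

  prov <- lapply(split(tab, tab$pair), function(d) d$gene[d$selected])
  genes <- gene_set(prov)
  list(genes = genes, table = tab)
}
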