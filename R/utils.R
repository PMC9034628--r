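#' Consensus molecular subtype labels
#'
#' The four consensus molecular subtypes (CMS) of colorectal cancer:
#' CMS1 (MSI-immune), CMS2 (canonical), CMS3 (metabolic), CMS4 (mesenchymal).
#'
#' @return Character vector of the four subtype labels.
#' @export
cms_levels <- function() c("CMS1", "CMS2", "CMS3", "CMS4")

#' The six ordered subtype pairs
#'
#' Pairwise comparisons are always processed in this fixed order so that
#' downstream gene ordering is reproducible.
#'
#' @return A list of six length-2 character vectors.
#' @export
cms_pairs <- function() {
  lv <- cms_levels()
  list(
    c(lv[1], lv[2]), c(lv[1], lv[3]), c(lv[1], lv[4]),
    c(lv[2], lv[3]), c(lv[2], lv[4]), c(lv[3], lv[4])
  )
}

pair_label <- function(pair) paste0(pair[1], "_vs_", pair[2])

# per-row sample variance (denominator n - 1)
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 columns to compute a sample variance")
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

relu <- function(z) pmax(z, 0)

# column-wise softmax with max-subtraction for numerical stability
softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

one_hot <- function(labels) {
  lv <- cms_levels()
  f <- factor(as.character(labels), levels = lv)
  if (anyNA(f)) {
    bad <- unique(as.character(labels)[is.na(f)])
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  y <- matrix(0, nrow = length(lv), ncol = length(labels),
              dimnames = list(lv, NULL))
  y[cbind(as.integer(f), seq_along(labels))] <- 1
  y
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin so per-class fold sizes differ by at most one.
stratified_folds <- function(labels, k) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class ", cl, " has only ", length(idx),
           " samples; use k <= ", length(idx))
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
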