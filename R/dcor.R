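#' Distance correlation between two samples of vectors
#'
#' Szekely-Rizzo distance correlation: Euclidean distance matrices of the
#' rows of `X` and `Y` are doubly centred; the distance covariance is the
#' mean elementwise product of the centred matrices, and the correlation is
#' the covariance normalised by the geometric mean of the two distance
#' variances. The result lies in the unit interval, is symmetric in its arguments, and
#' is 0 (population version) iff the two variables are independent. A
#' constant input has zero distance variance; the correlation is then
#' defined as 0 and flagged via the `"degenerate"` attribute.
#'
#' @param X,Y Numeric matrices (or vectors) with the same number of rows
#'   (observations in rows, >= 2).
#' @return The distance correlation (single number); attribute
#'   `"degenerate"` is `TRUE` when either side is constant.
#' @export
distance_correlation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) < 2L) stop("need at least 2 observations")
  center <- function(M) {
    D <- as.matrix(stats::dist(M))
    D - rowMeans(D) - rep(colMeans(D), each = nrow(D)) + mean(D)
  }
  A <- center(X)
  B <- center(Y)
  dcov2 <- mean(A * B)
  dvarx <- mean(A * A)
  dvary <- mean(B * B)
  if (dvarx <= 0 || dvary <= 0)
    return(structure(0, degenerate = TRUE))
  r <- sqrt(max(dcov2, 0) / sqrt(dvarx * dvary))
  structure(min(max(r, 0), 1), degenerate = FALSE)
}

#' Distance correlation between two expression datasets
#'
#' Cohorts of different sizes cannot be compared sample-by-sample, so each
#' dataset is reduced to its per-gene mean profile over the genes the two
#' datasets share, and the distance correlation is computed over those
#' gene-wise observations.
#'
#' @param ds1,ds2 `ExpressionDataset` objects sharing at least 2 genes.
#' @return Distance correlation of the shared-gene mean profiles.
#' @export
dataset_distance_correlation <- function(ds1, ds2) {
  stopifnot(inherits(ds1, "ExpressionDataset"),
            inherits(ds2, "ExpressionDataset"))
  shared <- intersect(ds1$gene_ids, ds2$gene_ids)
  if (length(shared) < 2L) stop("datasets share fewer than 2 genes")
  p1 <- rowMeans(ds1$values[match(shared, ds1$gene_ids), , drop = FALSE])
  p2 <- rowMeans(ds2$values[match(shared, ds2$gene_ids), , drop = FALSE])
  distance_correlation(matrix(p1, ncol = 1), matrix(p2, ncol = 1))
}
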