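#' Initialise network parameters
#'
#' The classifier is a minimalist feed-forward network: two fully-connected
#' "representation" layers with ReLU activations (widths 768 and 128 by
#' default) followed by a 4-unit softmax output layer, one unit per CMS
#' class. Each layer computes `alpha(W %*% input - theta)` where `theta` is a
#' per-unit threshold. Dropout is applied to the outputs of the two hidden
#' layers only (never to the input), and L1/L2 penalties act on `W1` and `W2`
#' only — the output layer carries no regularisation.
#'
#' Hidden weights use He-uniform initialisation (suits ReLU), the output
#' layer Glorot-uniform; thresholds start at zero. Initialisation draws from
#' the current RNG stream, so callers seed before calling.
#'
#' @param d_in Input dimension (number of selected genes).
#' @param hidden Integer vector of the two hidden widths.
#' @param n_classes Number of output classes (4 CMS subtypes).
#' @param dropout_keep_p Keep probability of the inverted-dropout masks,
#'   in (0, 1]; 0.5 by default.
#' @param l1_coef,l2_coef Non-negative L1 / L2 penalty coefficients applied
#'   to the hidden-layer weights; 0.3 each by default.
#' @return A `NetworkParams` list with `W1`, `theta1`, `W2`, `theta2`, `W3`,
#'   `theta3` and the hyperparameters.
#' @export
network_params <- function(d_in, hidden = c(768, 128), n_classes = 4,
                           dropout_keep_p = 0.5, l1_coef = 0.3,
                           l2_coef = 0.3) {
  stopifnot(d_in >= 1, length(hidden) == 2L, all(hidden >= 1),
            n_classes >= 2)
  if (dropout_keep_p <= 0 || dropout_keep_p > 1)
    stop("dropout_keep_p must be in (0, 1]")
  if (l1_coef < 0 || l2_coef < 0) stop("penalty coefficients must be >= 0")
  he <- function(n_out, n_in) {
    lim <- sqrt(6 / n_in)
    matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
  }
  glorot <- function(n_out, n_in) {
    lim <- sqrt(6 / (n_in + n_out))
    matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
  }
  structure(
    list(W1 = he(hidden[1], d_in), theta1 = numeric(hidden[1]),
         W2 = he(hidden[2], hidden[1]), theta2 = numeric(hidden[2]),
         W3 = glorot(n_classes, hidden[2]), theta3 = numeric(n_classes),
         dropout_keep_p = dropout_keep_p,
         l1_coef = l1_coef, l2_coef = l2_coef),
    class = "NetworkParams"
  )
}

#' Draw an inverted-dropout mask
#'
#' Entries are 0 with probability `1 - keep_p` and `1 / keep_p` otherwise, so
#' the masked activation is an unbiased estimate of the unmasked one and
#' evaluation-mode forward passes need no rescaling.
#'
#' @param n_rows,n_cols Mask dimensions (units x samples).
#' @param keep_p Keep probability in (0, 1].
#' @return A numeric matrix mask.
#' @export
dropout_mask <- function(n_rows, n_cols, keep_p) {
  if (keep_p <= 0 || keep_p > 1) stop("keep_p must be in (0, 1]")
  if (keep_p == 1) return(matrix(1, n_rows, n_cols))
  matrix((stats::runif(n_rows * n_cols) < keep_p) / keep_p, n_rows, n_cols)
}

#' Forward pass of the classifier
#'
#' Computes class probabilities for `X` (samples in rows, selected genes in
#' columns, already standardised). In `"train"` mode fresh dropout masks are
#' drawn from the current RNG stream for the two hidden-layer outputs (or
#' taken from `masks` if supplied, which the gradient check uses to freeze
#' them); `"eval"` mode is deterministic with no masking.
#'
#' @param params A `NetworkParams`.
#' @param X Numeric matrix, n_samples x d_in.
#' @param mode `"eval"` (default) or `"train"`.
#' @param masks Optional list of two pre-drawn masks (train mode only).
#' @return A list with `probs` (n_samples x n_classes, rows sum to 1) and
#'   `cache` of intermediate activations and masks for [backward()].
#' @export
forward <- function(params, X, mode = c("eval", "train"), masks = NULL) {
  stopifnot(inherits(params, "NetworkParams"))
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("input contains non-finite values")
  if (ncol(X) != ncol(params$W1))
    stop("input has ", ncol(X), " features but the network expects ",
         ncol(params$W1))
  A0 <- t(X)                                   # d_in x n
  n <- ncol(A0)
  Z1 <- params$W1 %*% A0 - params$theta1
  A1 <- relu(Z1)
  if (mode == "train") {
    M1 <- masks[[1]] %||%
      dropout_mask(nrow(A1), n, params$dropout_keep_p)
    M2 <- masks[[2]] %||%
      dropout_mask(nrow(params$W2), n, params$dropout_keep_p)
  } else {
    M1 <- NULL; M2 <- NULL
  }
  A1d <- if (is.null(M1)) A1 else A1 * M1
  Z2 <- params$W2 %*% A1d - params$theta2
  A2 <- relu(Z2)
  A2d <- if (is.null(M2)) A2 else A2 * M2
  Z3 <- params$W3 %*% A2d - params$theta3
  P <- softmax_cols(Z3)
  list(
    probs = t(P),
    cache = list(A0 = A0, Z1 = Z1, A1d = A1d, M1 = M1, Z2 = Z2,
                 A2d = A2d, M2 = M2, P = P, mode = mode)
  )
}

#' Regularised cross-entropy loss
#'
#' `data_loss` is the mean negative log-probability of the true class, with
#' probabilities clipped below at 1e-12 so a confidently wrong prediction is
#' finite. The penalties are `l1_coef * (||W1||_1 + ||W2||_1)` and
#' `(l2_coef / 2) * (||W1||_F^2 + ||W2||_F^2)`; the output layer is never
#' penalised.
#'
#' @param probs n x n_classes probability matrix from [forward()].
#' @param y One-hot label matrix (n_classes x n) or a character vector of CMS
#'   labels.
#' @param params A `NetworkParams`.
#' @return A `LossBreakdown` list: `data_loss`, `l1_penalty`, `l2_penalty`,
#'   `total`.
#' @export
network_loss <- function(probs, y, params) {
  stopifnot(inherits(params, "NetworkParams"))
  if (is.character(y)) y <- one_hot(y)
  P <- t(probs)                                # classes x n
  if (!all(dim(P) == dim(y))) stop("probs / labels shape mismatch")
  p_true <- pmax(colSums(P * y), 1e-12)
  data_loss <- -mean(log(p_true))
  l1 <- params$l1_coef * (sum(abs(params$W1)) + sum(abs(params$W2)))
  l2 <- params$l2_coef / 2 * (sum(params$W1^2) + sum(params$W2^2))
  structure(list(data_loss = data_loss, l1_penalty = l1, l2_penalty = l2,
                 total = data_loss + l1 + l2),
            class = "LossBreakdown")
}

#' Jacobian of the softmax output
#'
#' For a probability vector `y`, the derivative of output `t` with respect to
#' pre-activation `k` is `y_t (1 - y_t)` on the diagonal and `-y_t y_k` off
#' it; every row therefore sums to zero.
#'
#' @param probs_row Probability vector (sums to 1).
#' @return The square Jacobian matrix.
#' @export
softmax_jacobian <- function(probs_row) {
  y <- as.numeric(probs_row)
  if (abs(sum(y) - 1) > 1e-6) stop("probs_row must sum to 1")
  diag(y) - outer(y, y)
}

#' Analytic gradients of the regularised loss
#'
#' Backpropagates through the cached train-mode forward pass. The
#' output-layer gradient is `(probs - onehot) / n` times the cached
#' layer-2 activations — the true class's weight row is reinforced, the
#' others penalised. Hidden gradients pass through the ReLU derivative and
#' the same dropout masks used forward; L2 adds `l2_coef * W` and L1 adds
#' `l1_coef * sign(W)` (subgradient 0 at exactly zero) for `W1`, `W2` only.
#' Thresholds enter as `W %*% input - theta`, so their gradients carry a
#' minus sign.
#'
#' @param cache Cache from a train-mode [forward()] call with these params.
#' @param y One-hot matrix (n_classes x n) or character labels.
#' @param params The same `NetworkParams` used in the forward pass.
#' @return List of gradients `W1`, `theta1`, `W2`, `theta2`, `W3`, `theta3`.
#' @export
backward <- function(cache, y, params) {
  stopifnot(inherits(params, "NetworkParams"))
  if (!identical(cache$mode, "train"))
    stop("backward() needs a cache from a train-mode forward pass")
  if (is.character(y)) y <- one_hot(y)
  n <- ncol(cache$P)
  if (ncol(y) != n || nrow(y) != nrow(cache$P))
    stop("label matrix does not match cached batch")
  if (nrow(cache$A0) != ncol(params$W1))
    stop("cache and params disagree on input width")

  dZ3 <- (cache$P - y) / n
  gW3 <- dZ3 %*% t(cache$A2d)
  gtheta3 <- -rowSums(dZ3)

  dA2d <- t(params$W3) %*% dZ3
  dA2 <- if (is.null(cache$M2)) dA2d else dA2d * cache$M2
  dZ2 <- dA2 * (cache$Z2 > 0)
  gW2 <- dZ2 %*% t(cache$A1d) +
    params$l2_coef * params$W2 + params$l1_coef * sign(params$W2)
  gtheta2 <- -rowSums(dZ2)

  dA1d <- t(params$W2) %*% dZ2
  dA1 <- if (is.null(cache$M1)) dA1d else dA1d * cache$M1
  dZ1 <- dA1 * (cache$Z1 > 0)
  gW1 <- dZ1 %*% t(cache$A0) +
    params$l2_coef * params$W1 + params$l1_coef * sign(params$W1)
  gtheta1 <- -rowSums(dZ1)

  list(W1 = gW1, theta1 = gtheta1, W2 = gW2, theta2 = gtheta2,
       W3 = gW3, theta3 = gtheta3)
}
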