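# Independent oracles the implementation is checked against. None of these
# call into the package's own code paths.

# Central finite differences of a scalar function of one numeric array.
numerical_gradient <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# relative error between two gradient arrays, gradcheck-style
grad_rel_error <- function(ga, gn) {
  sqrt(sum((ga - gn)^2)) / (sqrt(sum(ga^2)) + sqrt(sum(gn^2)) + 1e-12)
}

# Plain scalar-loop Adam, written directly from the update rule, used as the
# reference trajectory.
reference_adam_trajectory <- function(x0, grad_fn, n_steps, alpha = 1e-3,
                                      beta1 = 0.9, beta2 = 0.999,
                                      eps = 1e-8) {
  x <- x0
  m <- rep(0, length(x0))
  v <- rep(0, length(x0))
  out <- matrix(NA_real_, n_steps, length(x0))
  for (t in seq_len(n_steps)) {
    g <- grad_fn(x)
    for (j in seq_along(x)) {
      m[j] <- beta1 * m[j] + (1 - beta1) * g[j]
      v[j] <- beta2 * v[j] + (1 - beta2) * g[j]^2
      mhat <- m[j] / (1 - beta1^t)
      vhat <- v[j] / (1 - beta2^t)
      x[j] <- x[j] - alpha * mhat / (sqrt(vhat) + eps)
    }
    out[t, ] <- x
  }
  out
}

# O(n^2) double-loop distance correlation, straight from the definition.
brute_dcor <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  dmat <- function(M) {
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      D[i, j] <- sqrt(sum((M[i, ] - M[j, ])^2))
    D
  }
  dc <- function(D) {
    A <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      A[i, j] <- D[i, j] - mean(D[i, ]) - mean(D[, j]) + mean(D)
    A
  }
  A <- dc(dmat(X)); B <- dc(dmat(Y))
  dcov2 <- mean(A * B)
  dvx <- mean(A * A); dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}

# Metrics computed by definition from a 4x4 confusion matrix (true rows,
# predicted columns), independent of the package's counting code.
brute_metrics_from_matrix <- function(cm) {
  n <- sum(cm)
  per <- lapply(seq_len(4), function(c) {
    tp <- cm[c, c]
    fn <- sum(cm[c, ]) - tp
    fp <- sum(cm[, c]) - tp
    tn <- n - tp - fn - fp
    c(sens = if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_,
      spec = if (tn + fp > 0) tn / (tn + fp) * 100 else NA_real_,
      prec = if (tp + fp > 0) tp / (tp + fp) * 100 else NA_real_,
      cacc = (tp + tn) / n * 100)
  })
  m <- do.call(rbind, per)
  list(per_class = m,
       macro = colMeans(m, na.rm = TRUE),
       overall = sum(diag(cm)) / n * 100)
}

# all non-negative integer vectors of length k summing to total
compositions_of <- function(total, k) {
  if (k == 1L) return(matrix(total, 1, 1))
  do.call(rbind, lapply(0:total, function(i) {
    rest <- compositions_of(total - i, k - 1L)
    cbind(i, rest, deparse.level = 0)
  }))
}

# classes x n one-hot encoding, written directly
one_hot_ref <- function(labels) {
  lv <- cms_levels()
  vapply(labels, function(l) as.numeric(lv == l), numeric(4),
         USE.NAMES = FALSE)
}

# label vectors realising a given confusion matrix
labels_from_matrix <- function(cm) {
  lv <- cms_levels()
  tr <- character(0); pr <- character(0)
  for (i in seq_len(4)) for (j in seq_len(4)) {
    if (cm[i, j] > 0) {
      tr <- c(tr, rep(lv[i], cm[i, j]))
      pr <- c(pr, rep(lv[j], cm[i, j]))
    }
  }
  list(true = tr, pred = pr)
}
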