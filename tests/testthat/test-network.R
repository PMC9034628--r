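test_that("forward produces normalized, deterministic eval probabilities", {
  net <- toy_net()
  fw <- forward(net$params, net$X)
  expect_equal(rowSums(fw$probs), rep(1, nrow(net$X)), tolerance = 1e-9)
  expect_identical(fw$probs, forward(net$params, net$X)$probs)

  # all-zero parameters give the uniform distribution
  p0 <- net$params
  for (nm in c("W1", "W2", "W3")) p0[[nm]][] <- 0
  for (nm in c("theta1", "theta2", "theta3")) p0[[nm]][] <- 0
  expect_equal(forward(p0, net$X)$probs,
               matrix(0.25, nrow(net$X), 4), tolerance = 1e-12)

  # normalization holds on random inputs
  set.seed(1)
  Xr <- matrix(rnorm(100 * 10, sd = 3), 100, 10)
  expect_equal(rowSums(forward(net$params, Xr)$probs), rep(1, 100),
               tolerance = 1e-9)

  expect_error(forward(net$params, matrix(0, 2, 3)), "expects")
  expect_error(forward(net$params, matrix(NA_real_, 2, 10)), "non-finite")
})

test_that("keep_p = 1 makes train and eval modes identical", {
  net <- toy_net(keep_p = 1)
  set.seed(5)
  tr <- forward(net$params, net$X, mode = "train")
  ev <- forward(net$params, net$X, mode = "eval")
  expect_equal(tr$probs, ev$probs, tolerance = 1e-14)
})

test_that("dropout masks drop at the right rate and are unbiased", {
  expect_equal(dropout_mask(3, 4, 1), matrix(1, 3, 4))
  expect_error(dropout_mask(2, 2, 0), "keep_p")

  set.seed(13)
  n_draw <- 10000
  m <- dropout_mask(n_draw, 1, 0.5)
  zero_frac <- mean(m == 0)
  expect_lt(abs(zero_frac - 0.5), 3 * sqrt(0.25 / n_draw))

  # inverted scaling: E[mask * a] = a, checked at 3 sigma
  a <- 1.7
  keep <- 0.7
  masked <- dropout_mask(n_draw, 1, keep) * a
  se <- a * sqrt((1 - keep) / keep) / sqrt(n_draw)
  expect_lt(abs(mean(masked) - a), 3 * se)
})

test_that("loss breakdown matches hand-computed values", {
  net <- toy_net()
  # uniform predictions: data loss = ln 4
  probs <- matrix(0.25, 6, 4)
  lb <- network_loss(probs, net$labels, net$params)
  expect_equal(lb$data_loss, log(4), tolerance = 1e-12)
  expect_equal(lb$total, lb$data_loss + lb$l1_penalty + lb$l2_penalty)

  # penalties on a tiny hand-checked parameter set
  p <- network_params(2, hidden = c(2, 2), dropout_keep_p = 1,
                      l1_coef = 0.3, l2_coef = 0.4)
  p$W1 <- matrix(c(1, -2, 0, 3), 2, 2)
  p$W2 <- matrix(c(0.5, 0, -1, 2), 2, 2)
  lb2 <- network_loss(matrix(0.25, 1, 4), "CMS1", p)
  expect_equal(lb2$l1_penalty, 0.3 * (6 + 3.5))
  expect_equal(lb2$l2_penalty, 0.4 / 2 * (14 + 5.25))

  # perfect one-hot predictions with zero penalties: loss 0 up to the clip
  p$l1_coef <- 0; p$l2_coef <- 0
  hot <- diag(4)[rep(1, 3), ]
  lb3 <- network_loss(hot, rep("CMS1", 3), p)
  expect_equal(lb3$total, 0, tolerance = 1e-10)
  # zero probability at the true class is clip-guarded, never infinite
  cold <- diag(4)[rep(2, 3), ]
  expect_lt(network_loss(cold, rep("CMS1", 3), p)$total, -log(1e-13))
})

test_that("softmax Jacobian matches closed forms and sums to zero by row", {
  J <- softmax_jacobian(rep(0.25, 4))
  expect_equal(diag(J), rep(0.1875, 4), tolerance = 1e-12)
  expect_equal(J[1, 2], -0.0625, tolerance = 1e-12)
  expect_equal(softmax_jacobian(c(1, 0, 0, 0)), matrix(0, 4, 4))

  set.seed(3)
  for (i in 1:20) {
    y <- rexp(4); y <- y / sum(y)
    J <- softmax_jacobian(y)
    expect_equal(rowSums(J), rep(0, 4), tolerance = 1e-12)
    expect_equal(J, t(J), tolerance = 1e-12)
    # against a central-difference Jacobian of softmax
    z <- log(y)
    for (k in 1:4) {
      h <- 1e-7
      zp <- z; zp[k] <- z[k] + h
      zm <- z; zm[k] <- z[k] - h
      sm <- function(v) exp(v) / sum(exp(v))
      expect_equal(J[, k], (sm(zp) - sm(zm)) / (2 * h), tolerance = 1e-6)
    }
  }
})

test_that("analytic gradients match central finite differences", {
  net <- toy_net()
  fw <- forward(net$params, net$X, mode = "train", masks = net$masks)
  grads <- backward(fw$cache, net$labels, net$params)
  for (nm in c("W1", "theta1", "W2", "theta2", "W3", "theta3")) {
    gn <- numerical_gradient(toy_loss_fn(net, nm), net$params[[nm]])
    expect_lt(grad_rel_error(grads[[nm]], gn), 1e-5)
  }
})

test_that("output-layer gradient has the reinforce/penalise structure", {
  net <- toy_net(keep_p = 1)
  p <- net$params
  p$l1_coef <- 0; p$l2_coef <- 0
  fw <- forward(p, net$X, mode = "train")
  g <- backward(fw$cache, net$labels, p)
  # gradient equals (probs - onehot)/n times layer-2 activations
  expect_equal(unname(g$W3),
               unname(((t(fw$probs) - one_hot_ref(net$labels)) /
                         nrow(net$X)) %*% t(fw$cache$A2d)),
               tolerance = 1e-12)
  # a small step along -gradient decreases the loss
  loss_at <- function(par) {
    e <- forward(par, net$X, mode = "train")
    network_loss(e$probs, net$labels, par)$total
  }
  p2 <- p
  p2$W3 <- p$W3 - 1e-3 * g$W3
  expect_lt(loss_at(p2), loss_at(p))
})

test_that("backward rejects eval caches and mismatched labels", {
  net <- toy_net()
  ev <- forward(net$params, net$X, mode = "eval")
  expect_error(backward(ev$cache, net$labels, net$params), "train-mode")
  tr <- forward(net$params, net$X, mode = "train", masks = net$masks)
  expect_error(backward(tr$cache, net$labels[-1], net$params), "match")
})

test_that("adam_step follows the reference trajectory on a quadratic", {
  # f(x) = 0.5 * sum(c x^2), grad = c * x
  cvec <- c(0.5, 1, 2, 5)
  x0 <- c(3, -2, 1, 4)
  ref <- reference_adam_trajectory(x0, function(x) cvec * x, 100,
                                   alpha = 0.05)
  params <- list(x = x0)
  state <- adam_init(params, alpha = 0.05)
  for (t in 1:100) {
    upd <- adam_step(params, list(x = cvec * params$x), state)
    params <- upd$params
    state <- upd$state
    expect_equal(params$x, ref[t, ], tolerance = 1e-10)
  }
  expect_identical(state$t, 100L)
})

test_that("adam_step limit behaviours hold", {
  params <- list(w = matrix(c(1, -1, 2, 0.5), 2, 2))
  state <- adam_init(params, alpha = 0.01)
  g <- matrix(c(10, -3, 0.2, -40), 2, 2)
  upd <- adam_step(params, list(w = g), state)
  # first step with any constant gradient moves by ~ -alpha * sign(g)
  expect_equal(upd$params$w - params$w, -0.01 * sign(g), tolerance = 1e-6)
  # zero gradients leave parameters unchanged
  upd2 <- adam_step(params, list(w = g * 0), state)
  expect_equal(upd2$params$w, params$w)
  expect_error(adam_step(params, list(w = 1:3), state), "shape")
  expect_error(adam_step(params, list(), state), "missing")
})
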