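# Small fixtures built in code.

tiny_dataset <- function() {
  vals <- matrix(c(1, 2, 3, 4,
                   5, 6, 7, 8,
                   2, 4, 6, 8), nrow = 3, byrow = TRUE)
  expression_dataset(vals, c("TP53", "KRAS", "APC"),
                     c("s1", "s2", "s3", "s4"),
                     labels = c("CMS1", "CMS2", "CMS3", "CMS4"))
}

# toy network away from ReLU kinks and exact-zero weights so the finite
# difference check is well conditioned
toy_net <- function(seed = 42, d_in = 10, hidden = c(5, 3), n = 6,
                    keep_p = 0.8, l1 = 0.05, l2 = 0.1) {
  set.seed(seed)
  params <- network_params(d_in, hidden = hidden, dropout_keep_p = keep_p,
                           l1_coef = l1, l2_coef = l2)
  nudge <- function(w) sign(w) * pmax(abs(w), 0.05)
  params$W1 <- nudge(params$W1)
  params$W2 <- nudge(params$W2)
  params$W3 <- nudge(params$W3)
  params$theta1 <- runif(hidden[1], -0.2, 0.2)
  params$theta2 <- runif(hidden[2], -0.2, 0.2)
  params$theta3 <- runif(4, -0.2, 0.2)
  X <- matrix(rnorm(n * d_in), n, d_in)
  labels <- rep(cms_levels(), length.out = n)
  masks <- list(
    dropout_mask(hidden[1], n, keep_p),
    dropout_mask(hidden[2], n, keep_p)
  )
  list(params = params, X = X, labels = labels, masks = masks)
}

# loss as a pure function of one parameter tensor, masks frozen
toy_loss_fn <- function(net, tensor_name) {
  function(value) {
    p <- net$params
    p[[tensor_name]] <- value
    fw <- forward(p, net$X, mode = "train", masks = net$masks)
    network_loss(fw$probs, net$labels, p)$total
  }
}
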