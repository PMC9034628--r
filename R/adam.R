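#' Initialise Adam optimiser state
#'
#' First and second moment accumulators start at zero, shaped like every
#' trainable tensor; the step counter starts at 0 and increases by one per
#' [adam_step()].
#'
#' @param params Named list of numeric arrays (the trainable tensors).
#' @param alpha Step size (default 1e-3, the usual Adam setting).
#' @param beta1,beta2 Exponential decay rates of the moment estimates.
#' @param epsilon Small constant guarding the division.
#' @return An `AdamState` list.
#' @export
adam_init <- function(params, alpha = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      epsilon = 1e-8) {
  tensors <- params[vapply(params, is.numeric, logical(1))]
  zeros <- lapply(tensors, function(x) { x[] <- 0; x })
  structure(
    list(m = zeros, v = zeros, t = 0L, alpha = alpha, beta1 = beta1,
         beta2 = beta2, epsilon = epsilon),
    class = "AdamState"
  )
}

#' One Adam update
#'
#' Standard Adam with bias correction:
#' `m <- b1 m + (1 - b1) g`; `v <- b2 v + (1 - b2) g^2`;
#' `theta <- theta - alpha * mhat / (sqrt(vhat) + eps)` with
#' `mhat = m / (1 - b1^t)` and `vhat = v / (1 - b2^t)`.
#'
#' @param params Named list of numeric arrays to update.
#' @param grads Named list of gradients with matching names and shapes.
#' @param state An `AdamState` from [adam_init()].
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state) {
  stopifnot(inherits(state, "AdamState"))
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    if (is.null(g)) stop("gradient missing for tensor ", nm)
    if (length(g) != length(state$m[[nm]]))
      stop("gradient shape mismatch for tensor ", nm)
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - state$alpha * mhat /
      (sqrt(vhat) + state$epsilon)
  }
  list(params = params, state = state)
}
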