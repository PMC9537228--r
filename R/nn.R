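# Low-level network kernels.
#
# Batch tensors are stored channels-last as (T, J, B, C) arrays so that
# (a) a temporal slice X[k:(k+T2-1), , , ] is a cheap strided copy and
# (b) reshaping a slice to an N x Cin matrix needs no transposition.
# A temporal kernel-3 convolution then reduces to three tap-wise
# matrix products against (Cin x Cout) weight slices, which hands all
# heavy lifting to BLAS.

# X: (T, J, B, Cin); W: (3, Cin, Cout); b: length Cout.
# pad "valid": T2 = T - 2; pad "same": zero-pad one frame each side.
conv_t3_fwd <- function(X, W, b, pad = "valid") {
  if (dim(X)[1] < 3L && pad == "valid")
    stopf("temporal extent %d too small for a kernel of 3", dim(X)[1])
  .Call(C_conv3_fwd, X, W, as.numeric(b),
        if (pad == "same") 1L else 0L)
}

conv_t3_bwd <- function(X, W, dY, pad = "valid", need_dx = TRUE) {
  .Call(C_conv3_bwd, X, W, dY, if (pad == "same") 1L else 0L,
        if (need_dx) 1L else 0L)
}

relu_fwd <- function(X) .Call(C_relu_fwd, X)
relu_bwd <- function(X, dY) .Call(C_relu_bwd, X, dY)

# Adaptive 1x1 max pooling over the (T, J) spatial extent.
# X: (T2, J, B, C) -> P: (B, C) matrix; idx kept for the backward pass.
pool_max_fwd <- function(X) {
  out <- .Call(C_pool_max_fwd, X)
  list(P = out$P, idx = out$idx, dims = dim(X))
}

pool_max_bwd <- function(dP, pool) {
  .Call(C_pool_max_bwd, dP, pool$idx, as.integer(pool$dims))
}

gather_batch <- function(X, take) .Call(C_gather_batch, X, as.integer(take))

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Mean cross-entropy over a batch; y_idx are 1-based class indices.
batch_ce <- function(p, y_idx) {
  pt <- p[cbind(seq_along(y_idx), y_idx)]
  -mean(log(pmax(pt, 1e-12)))
}

#' Cross-entropy loss of one prediction
#'
#' `L = -sum(y * log(p))` in nats, the multiclass log loss of a
#' probability vector `p` against a one-hot truth `y`.  Probabilities
#' are clamped below at `1e-12` for numeric safety.
#'
#' @param p Probability vector (non-negative, sums to 1).
#' @param y One-hot vector of the same length.
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(p, y) {
  if (length(p) != length(y)) stopf("p and y lengths differ")
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6)
    stopf("p is not a probability vector")
  if (!all(y %in% c(0, 1)) || sum(y) != 1)
    stopf("y must be one-hot")
  -sum(y * log(pmax(p, 1e-12)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
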