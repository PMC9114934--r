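# Small dense networks with tanh hidden layers, explicit backprop and Adam.
# Sized for policy/value trunks (a few hundred units); all math is plain
# matrix algebra so training runs anywhere R does.

mlp_new <- function(sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(sizes) - 1
  W <- vector("list", n)
  b <- vector("list", n)
  for (i in seq_len(n)) {
    # Xavier-scaled init; final layer small so initial outputs are near zero
    sc <- sqrt(2 / (sizes[i] + sizes[i + 1]))
    if (i == n) sc <- sc * 0.01
    W[[i]] <- matrix(rnorm(sizes[i] * sizes[i + 1], 0, sc),
                     sizes[i], sizes[i + 1])
    b[[i]] <- rep(0, sizes[i + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

# X: n x d batch.  Returns output and the per-layer activations for backprop.
mlp_forward <- function(net, X) {
  n_layers <- length(net$W)
  acts <- vector("list", n_layers + 1)
  acts[[1]] <- X
  for (i in seq_len(n_layers)) {
    Z <- sweep(acts[[i]] %*% net$W[[i]], 2, net$b[[i]], "+")
    acts[[i + 1]] <- if (i < n_layers) tanh(Z) else Z
  }
  list(out = acts[[n_layers + 1]], acts = acts)
}

# dOut: gradient of the scalar loss w.r.t. the network output (n x out).
mlp_backward <- function(net, acts, dOut) {
  n_layers <- length(net$W)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  delta <- dOut
  for (i in rev(seq_len(n_layers))) {
    gW[[i]] <- crossprod(acts[[i]], delta)
    gb[[i]] <- colSums(delta)
    if (i > 1) {
      delta <- (delta %*% t(net$W[[i]])) * (1 - acts[[i]]^2)
    }
  }
  list(W = gW, b = gb)
}

adam_new <- function(net) {
  zeros <- function(p) if (is.matrix(p)) p * 0 else rep(0, length(p))
  list(mW = lapply(net$W, zeros), vW = lapply(net$W, zeros),
       mb = lapply(net$b, zeros), vb = lapply(net$b, zeros), t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$W)) {
    state$mW[[i]] <- beta1 * state$mW[[i]] + (1 - beta1) * grads$W[[i]]
    state$vW[[i]] <- beta2 * state$vW[[i]] + (1 - beta2) * grads$W[[i]]^2
    net$W[[i]] <- net$W[[i]] -
      lr * (state$mW[[i]] / bc1) / (sqrt(state$vW[[i]] / bc2) + eps)
    state$mb[[i]] <- beta1 * state$mb[[i]] + (1 - beta1) * grads$b[[i]]
    state$vb[[i]] <- beta2 * state$vb[[i]] + (1 - beta2) * grads$b[[i]]^2
    net$b[[i]] <- net$b[[i]] -
      lr * (state$mb[[i]] / bc1) / (sqrt(state$vb[[i]] / bc2) + eps)
  }
  list(net = net, state = state)
}

# scalar-parameter Adam (for the state-independent log-std vector)
adam_vec_new <- function(p) list(m = p * 0, v = p * 0, t = 0L)
adam_vec_step <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  p <- p - lr * (state$m / (1 - beta1^state$t)) /
    (sqrt(state$v / (1 - beta2^state$t)) + eps)
  list(p = p, state = state)
}
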