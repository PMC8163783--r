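# Minimal dense neural-network engine: MLP forward/backward and Adam, built
# on BLAS matrix products. Parameters live in nested named lists of W/b
# matrices; gradients and optimizer state mirror the same tree.

mlp_init <- function(sizes, zero_last = FALSE) {
  # He-style initialization; draws from the current RNG stream
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    W <- matrix(rnorm(fan_in * sizes[l + 1L], 0, sqrt(2 / fan_in)),
                fan_in, sizes[l + 1L])
    if (zero_last && l == length(layers)) W[] <- 0
    layers[[l]] <- list(W = W, b = numeric(sizes[l + 1L]))
  }
  layers
}

# X: rows x in; ReLU on hidden layers, linear output
mlp_forward <- function(layers, X) {
  nl <- length(layers)
  acts <- vector("list", nl + 1L)
  acts[[1L]] <- X
  for (l in seq_len(nl)) {
    Z <- acts[[l]] %*% layers[[l]]$W
    Z <- sweep_add(Z, layers[[l]]$b)
    if (l < nl) Z <- Z * (Z > 0)
    acts[[l + 1L]] <- Z
  }
  list(out = acts[[nl + 1L]], acts = acts)
}

sweep_add <- function(Z, b) {
  Z + matrix(b, nrow(Z), length(b), byrow = TRUE)
}

# dOut: gradient at the output; returns grads and gradient at the input
mlp_backward <- function(layers, cache, dOut) {
  nl <- length(layers)
  grads <- vector("list", nl)
  d <- dOut
  for (l in rev(seq_len(nl))) {
    if (l < nl) d <- d * (cache$acts[[l + 1L]] > 0)
    grads[[l]] <- list(W = crossprod(cache$acts[[l]], d), b = colSums(d))
    d <- tcrossprod(d, layers[[l]]$W)
  }
  list(grads = grads, dX = d)
}

tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- tree_map(f, a[[i]], if (!is.null(b)) b[[i]])
    }
    out
  } else {
    if (is.null(b)) f(a) else f(a, b)
  }
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                  state$m, state$v)
  params <- tree_map(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}

# decade step decay spanning lr..lr_min over the epoch budget
lr_at_epoch <- function(epoch, epochs, lr = 1e-3, lr_min = 1e-6) {
  n_drops <- max(0L, round(log10(lr / lr_min)))
  stage <- floor(n_drops * (epoch - 1L) / epochs)
  max(lr * 10^(-stage), lr_min)
}
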