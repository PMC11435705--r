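# Low-level neural-network primitives.
#
# All layers operate on matrices whose columns are time steps concatenated
# window-by-window: an input of B windows of length L with C channels is the
# C x (L*B) matrix [win1 | win2 | ...]. The dense numeric work (temporal
# convolution, batch norm, Softsign, pooling) lives in C++ kernels (src/);
# backward passes recompute cheap intermediates from cached layer inputs
# and are exact gradients, verified against finite differences in the test
# suite.

# ---- temporal convolution (stride 1, same padding, odd kernel) ----

conv_fwd <- function(X, L, p, k) {
  list(Y = conv_fwd_cpp(X, L, p$W, p$b, k),
       cache = list(X = X, L = L, k = k))
}

conv_bwd <- function(dY, p, cache, want_dx = TRUE) {
  out <- conv_bwd_cpp(dY, p$W, cache$X, cache$L, cache$k, want_dx)
  list(grads = list(W = out$dW, b = as.numeric(out$db)), dX = out$dX)
}

# ---- batch normalization (per row / feature channel) ----

bn_fwd <- function(X, p, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    out <- bn_fwd_train_cpp(X, p$gamma, p$beta, eps)
    p$run_mean <- (1 - momentum) * p$run_mean + momentum * as.numeric(out$mu)
    p$run_var <- (1 - momentum) * p$run_var + momentum * as.numeric(out$var)
    list(Y = out$Y,
         cache = list(X = X, mu = out$mu, invstd = out$invstd), p = p)
  } else {
    list(Y = bn_fwd_eval_cpp(X, p$gamma, p$beta, p$run_mean, p$run_var, eps),
         cache = NULL, p = p)
  }
}

bn_bwd <- function(dY, p, cache) {
  out <- bn_bwd_cpp(dY, p$gamma, cache$X, cache$mu, cache$invstd)
  list(grads = list(gamma = as.numeric(out$dgamma),
                    beta = as.numeric(out$dbeta)),
       dX = out$dX)
}

# ---- Softsign activation: x / (1 + |x|) ----

softsign_fwd <- function(X) list(Y = softsign_fwd_cpp(X), cache = X)

softsign_bwd <- function(dY, cache) softsign_bwd_cpp(dY, cache)

# ---- temporal max pooling (width p, stride p, remainder dropped) ----

pool_fwd <- function(X, L, p = 2L) {
  out <- pool_fwd_cpp(X, L, p)
  list(Y = out$Y,
       cache = list(arg = out$arg, L = L, p = p, nc = ncol(X),
                    Lout = L %/% p))
}

pool_bwd <- function(dY, cache, cin) {
  pool_bwd_cpp(dY, cache$arg, cache$L, cache$p, cache$nc)
}

# ---- dense layer ----

dense_fwd <- function(X, p) list(Y = p$W %*% X + p$b, cache = X)

dense_bwd <- function(dY, p, cache, want_dx = TRUE) {
  list(grads = list(W = tcrossprod(dY, cache), b = rowSums(dY)),
       dX = if (want_dx) crossprod(p$W, dY))
}

# ---- inverted dropout ----

dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0)
    return(list(Y = X, cache = NULL))
  mask <- matrix((stats::runif(length(X)) >= rate) / (1 - rate),
                 nrow(X), ncol(X))
  list(Y = X * mask, cache = mask)
}

dropout_bwd <- function(dY, cache) if (is.null(cache)) dY else dY * cache

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- parameter initialization ----

glorot <- function(nout, nin, fan_in, fan_out = nout) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nout * nin, -s, s), nout, nin)
}

init_conv <- function(cout, cin, k) {
  list(W = glorot(cout, cin * k, fan_in = cin * k), b = numeric(cout))
}

init_bn <- function(nf) {
  list(gamma = rep(1, nf), beta = numeric(nf),
       run_mean = numeric(nf), run_var = rep(1, nf))
}

init_dense <- function(nout, nin) {
  list(W = glorot(nout, nin, fan_in = nin), b = numeric(nout))
}

# ---- Adam optimizer over a nested parameter tree ----
# Gradient trees mirror parameter trees but contain only trainable leaves
# (W, b, gamma, beta); batch-norm running stats are never touched.

adam_state_new <- function() new.env(parent = emptyenv())

adam_update <- function(params, grads, state, path, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    key <- paste0(path, "/", nm)
    g <- grads[[nm]]
    if (is.list(g)) {
      params[[nm]] <- adam_update(params[[nm]], g, state, key, lr, t,
                                  beta1, beta2, eps)
    } else {
      st <- state[[key]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      state[[key]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  params
}

# Element-wise sum of two gradient trees (same shape; either may be NULL).
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(b)) a[[nm]] <- grad_add(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

grad_scale <- function(g, s) {
  if (is.list(g)) return(lapply(g, grad_scale, s = s))
  g * s
}
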