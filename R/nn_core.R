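# Shared neural-network plumbing for the GAN and the LSTM regressor:
# parameter initialization, Adam, batch normalization, activations and thin
# wrappers around the compiled conv/transposed-conv kernels.
#
# Batched sequences are arrays dim c(batch, time, channels). Transposed
# convolutions reuse the conv kernels as adjoints: convT forward is the
# conv input-gradient, convT input-gradient is the conv forward, and both
# weight gradients share cpp_conv1d_bw_weight with the roles of input and
# upstream gradient swapped.

glorot <- function(nrow, ncol, fan_in = nrow, fan_out = ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

## ---- activations ----

selu_scale <- 1.0507009873554805
selu_alpha <- 1.6732632423543772

selu  <- function(x) selu_scale * (pmax(x, 0) + selu_alpha * expm1(pmin(x, 0)))
dselu <- function(x) selu_scale * ((x > 0) + (x <= 0) * selu_alpha * exp(pmin(x, 0)))
# leaky ReLU in axpy form: a*x + (1-a)*(x + |x|)/2
lrelu  <- function(x, a = 0.2) 0.5 * (1 + a) * x + 0.5 * (1 - a) * abs(x)
dlrelu <- function(x, a = 0.2) 0.5 * (1 + a) + 0.5 * (1 - a) * sign(x)
sigmoid <- function(x) 1 / (1 + exp(-x))
# log(1 + e^x), overflow-safe
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

## ---- conv wrappers ----

channel_bias_grad <- function(dy) {
  d <- dim(dy)
  colSums(matrix(dy, d[1] * d[2], d[3]))
}

conv1d_fw <- function(x, W, b, stride = 2L, padl = 2L, l_out) {
  cpp_conv1d_fw(x, W, b, stride, padl, l_out)
}

# Transposed (upsampling) convolution: input (B, L, Ci) -> (B, L*stride, Co).
# W has conv-adjoint shape (k*Co x Ci).
convt_fw <- function(x, W, b, stride = 2L, padl = 2L, l_out, c_out) {
  cpp_conv1d_bw_input(x, W, b, stride, padl, l_out, c_out)
}

convt_bw_input  <- function(dy, W, stride = 2L, padl = 2L, l_in) {
  cpp_conv1d_fw(dy, W, numeric(ncol(W)), stride, padl, l_in)
}

convt_bw_weight <- function(x, dy, k = 5L, stride = 2L, padl = 2L) {
  # dW[tau*Co + co, ci] = sum_{b,t} dy[b, t*s - pl + tau, co] * x[b, t, ci]
  cpp_conv1d_bw_weight(dy, x, k, stride, padl)
}

## ---- batch normalization (per channel over batch x time) ----

bn_init <- function(n_channels) {
  list(run_mean = rep(0, n_channels), run_var = rep(1, n_channels))
}

# gamma/beta are model parameters owned by the caller; `bn` only carries
# the running statistics used in inference mode.
bn_forward <- function(x, bn, gamma, beta, training, momentum = 0.99,
                       eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    bn$run_mean <- momentum * bn$run_mean + (1 - momentum) * mu
    bn$run_var  <- momentum * bn$run_var  + (1 - momentum) * v
  } else {
    mu <- bn$run_mean; v <- bn$run_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = nrow(xm))) * rep(ivar, each = nrow(xm))
  y <- xhat * rep(gamma, each = nrow(xm)) + rep(beta, each = nrow(xm))
  list(y = array(y, d), bn = bn,
       cache = list(xhat = xhat, ivar = ivar, dims = d, training = training))
}

bn_backward <- function(dy, gamma, cache) {
  d <- cache$dims
  n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = n)
  if (!cache$training) {
    # inference-mode stats are constants: straight-through scaling
    dxm <- dxhat * rep(cache$ivar, each = n)
    return(list(dx = array(dxm, d), dgamma = dgamma, dbeta = dbeta))
  }
  # dx = ivar/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dxm <- (dxhat - rep(s1 / n, each = n) -
            cache$xhat * rep(s2 / n, each = n)) * rep(cache$ivar, each = n)
  list(dx = array(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

## ---- Adam ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## ---- pair <-> matrix helpers ----

pairs_to_matrices <- function(pairs) {
  if (length(pairs) == 0L) stop_data("empty pair list")
  V <- t(vapply(pairs, function(p) p$velocity, numeric(N_POINTS)))
  F_ <- t(vapply(pairs, function(p) p$force, numeric(N_POINTS)))
  list(velocity = V, force = F_)
}
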