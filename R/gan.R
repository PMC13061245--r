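# Paired-curve generative adversarial network.
#
# The generator maps a 50-dimensional latent draw to a 202-value output
# holding one velocity curve and one force curve (101 points each), both in
# tanh range after per-channel max-abs scaling:
#   dense 50 -> 3328, reshaped to 26 time steps x 128 channels,
#   transposed conv (kernel 5, stride 2) to 52 x 64, batch-norm, SELU,
#   transposed conv (kernel 5, stride 2) to 104 x 2, batch-norm, tanh,
#   dense 208 -> 202, tanh.
# The discriminator reads the pair as a 101 x 2 sequence:
#   conv (5, stride 2) to 51 x 64, LeakyReLU, 40% dropout,
#   conv (5, stride 2) to 26 x 128, LeakyReLU, 40% dropout,
#   dense 3328 -> 1, sigmoid.
# Both are trained with the non-saturating binary cross-entropy, one
# discriminator step per generator step, Adam at the configured rate.

#' GAN configuration
#'
#' Architecture constants are fixed (latent 50, dense 26x128, transposed
#' convs with 64 then 2 filters, discriminator convs with 64 then 128
#' filters, kernel 5, stride 2, 40% dropout, final dense 202); this object
#' carries the training controls.
#'
#' @param epochs passes over the training pairs (default 3000).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam step for both networks (default 1e-3).
#' @param beta1 Adam first-moment decay; 0.5 is the usual choice for
#'   adversarial training.
#' @param real_label target for real samples in the discriminator loss;
#'   0.9 applies one-sided label smoothing.
#' @param seed integer controlling weight init, latent draws, batching and
#'   dropout; the same seed reproduces the same training run bitwise.
#' @return an object of class `gan_config`.
#' @export
gan_config <- function(epochs = 3000, batch_size = 32, learning_rate = 1e-3,
                       beta1 = 0.5, real_label = 0.9, seed = 1L) {
  if (epochs < 1 || batch_size < 1)
    stop_config("epochs and batch_size must be positive")
  if (learning_rate <= 0)
    stop_config("learning_rate must be positive (got %g)", learning_rate)
  structure(list(latent_dim = 50L, dropout = 0.4, kernel = 5L, stride = 2L,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1,
                 real_label = real_label, seed = as.integer(seed)),
            class = "gan_config")
}

gan_init_params <- function(cfg) {
  k <- cfg$kernel
  list(
    G = list(W0 = glorot(cfg$latent_dim, 26L * 128L),
             b0 = rep(0, 26L * 128L),
             W1 = glorot(k * 64L, 128L), b1 = rep(0, 64L),
             g1 = rep(1, 64L), e1 = rep(0, 64L),
             W2 = glorot(k * 2L, 64L), b2 = rep(0, 2L),
             g2 = rep(1, 2L), e2 = rep(0, 2L),
             W3 = glorot(208L, 202L), b3 = rep(0, 202L)),
    D = list(Wc1 = glorot(k * 2L, 64L), bc1 = rep(0, 64L),
             Wc2 = glorot(k * 64L, 128L), bc2 = rep(0, 128L),
             Wd = glorot(26L * 128L, 1L), bd = 0))
}

# Generator forward. bn1/bn2 are batch-norm state lists; returns output,
# updated bn state and (if cache) everything backprop needs.
gen_forward <- function(z, P, bn1, bn2, training, cache = FALSE) {
  B <- nrow(z)
  a0 <- z %*% P$W0 + rep(P$b0, each = B)
  x1 <- array(a0, c(B, 26L, 128L))
  u1 <- convt_fw(x1, P$W1, P$b1, l_out = 52L, c_out = 64L)
  f1 <- bn_forward(u1, bn1, P$g1, P$e1, training)
  s1 <- selu(f1$y)
  u2 <- convt_fw(s1, P$W2, P$b2, l_out = 104L, c_out = 2L)
  f2 <- bn_forward(u2, bn2, P$g2, P$e2, training)
  t2 <- tanh(f2$y)
  flat <- matrix(t2, B, 208L)
  out <- tanh(flat %*% P$W3 + rep(P$b3, each = B))
  res <- list(out = out, bn1 = f1$bn, bn2 = f2$bn)
  if (cache)
    res$cache <- list(z = z, x1 = x1, c1 = f1$cache, n1 = f1$y, s1 = s1,
                      c2 = f2$cache, t2 = t2, flat = flat, out = out)
  res
}

gen_backward <- function(dout, P, cache) {
  B <- nrow(dout)
  dpre3 <- dout * (1 - cache$out^2)
  dW3 <- crossprod(cache$flat, dpre3)
  db3 <- colSums(dpre3)
  dt2 <- array(dpre3 %*% t(P$W3), c(B, 104L, 2L))
  dn2 <- dt2 * (1 - cache$t2^2)
  bb2 <- bn_backward(dn2, P$g2, cache$c2)
  db2 <- channel_bias_grad(bb2$dx)
  ds1 <- convt_bw_input(bb2$dx, P$W2, l_in = 52L)
  dW2 <- convt_bw_weight(cache$s1, bb2$dx)
  dn1 <- ds1 * dselu(cache$n1)
  bb1 <- bn_backward(dn1, P$g1, cache$c1)
  db1 <- channel_bias_grad(bb1$dx)
  dx1 <- convt_bw_input(bb1$dx, P$W1, l_in = 26L)
  dW1 <- convt_bw_weight(cache$x1, bb1$dx)
  da0 <- matrix(dx1, B, 26L * 128L)
  list(W0 = crossprod(cache$z, da0), b0 = colSums(da0),
       W1 = dW1, b1 = db1, g1 = bb1$dgamma, e1 = bb1$dbeta,
       W2 = dW2, b2 = db2, g2 = bb2$dgamma, e2 = bb2$dbeta,
       W3 = dW3, b3 = db3)
}

# Discriminator forward on x (B, 101, 2). Dropout masks are drawn by the
# caller (R RNG) so runs are reproducible; NULL masks mean inference.
disc_forward <- function(x, P, masks = NULL, cache = FALSE) {
  B <- dim(x)[1]
  c1 <- conv1d_fw(x, P$Wc1, P$bc1, l_out = 51L)
  l1 <- lrelu(c1)
  d1 <- if (is.null(masks)) l1 else l1 * masks$m1
  c2 <- conv1d_fw(d1, P$Wc2, P$bc2, l_out = 26L)
  l2 <- lrelu(c2)
  d2 <- if (is.null(masks)) l2 else l2 * masks$m2
  flat <- matrix(d2, B, 26L * 128L)
  logit <- drop(flat %*% P$Wd) + P$bd
  res <- list(logit = logit)
  if (cache) res$cache <- list(x = x, c1 = c1, d1 = d1, c2 = c2, flat = flat,
                               masks = masks)
  res
}

# Backward from d(loss)/d(logit); returns gradients and dL/dx.
disc_backward <- function(dlogit, P, cache) {
  B <- length(dlogit)
  dWd <- crossprod(cache$flat, matrix(dlogit, ncol = 1))
  dbd <- sum(dlogit)
  dflat <- matrix(dlogit, ncol = 1) %*% t(P$Wd)
  dd2 <- array(dflat, c(B, 26L, 128L))
  dl2 <- if (is.null(cache$masks)) dd2 else dd2 * cache$masks$m2
  dc2 <- dl2 * dlrelu(cache$c2)
  dWc2 <- cpp_conv1d_bw_weight(cache$d1, dc2, 5L, 2L, 2L)
  dbc2 <- channel_bias_grad(dc2)
  dd1 <- cpp_conv1d_bw_input(dc2, P$Wc2, numeric(64L), 2L, 2L, 51L, 64L)
  dl1 <- if (is.null(cache$masks)) dd1 else dd1 * cache$masks$m1
  dc1 <- dl1 * dlrelu(cache$c1)
  dWc1 <- cpp_conv1d_bw_weight(cache$x, dc1, 5L, 2L, 2L)
  dbc1 <- channel_bias_grad(dc1)
  dx <- cpp_conv1d_bw_input(dc1, P$Wc1, numeric(2L), 2L, 2L, 101L, 2L)
  list(grads = list(Wc1 = dWc1, bc1 = dbc1, Wc2 = dWc2, bc2 = dbc2,
                    Wd = dWd, bd = dbd),
       dx = dx)
}

dropout_masks <- function(B, p) {
  list(m1 = array((stats::runif(B * 51 * 64) > p) / (1 - p), c(B, 51L, 64L)),
       m2 = array((stats::runif(B * 26 * 128) > p) / (1 - p), c(B, 26L, 128L)))
}

bce_logit_loss <- function(logit, y) mean(softplus(logit) - y * logit)

# 202-vector packing: velocity then force, each scaled by its max-abs.
pairs_to_gan_matrix <- function(pairs, scaling) {
  m <- pairs_to_matrices(pairs)
  cbind(m$velocity / scaling$v_maxabs, m$force / scaling$f_maxabs)
}

gan_rows_to_input <- function(rows) {
  # (B,202) -> (B,101,2) discriminator input
  array(c(rows[, 1:101, drop = FALSE], rows[, 102:202, drop = FALSE]),
        c(nrow(rows), 101L, 2L))
}

#' Train the paired-curve GAN
#'
#' Fits the generator/discriminator pair on a set of measured (or synthetic)
#' velocity-force pairs. Curves are scaled per channel by the maximum
#' absolute value over the training set so the tanh output range covers the
#' data; the constants are stored with the model and inverted on generation.
#'
#' @param pairs list of [vf_pair()] objects (at least 8).
#' @param cfg a [gan_config()].
#' @return an object of class `scrum_gan` with the trained parameters,
#'   scaling constants, configuration and per-epoch loss history.
#' @seealso [generate_pairs()], [gan_fidelity()]
#' @export
train_gan <- function(pairs, cfg = gan_config()) {
  if (!inherits(cfg, "gan_config")) stop_config("cfg must be a gan_config")
  if (length(pairs) < 8L)
    stop_data("need at least 8 training pairs, got %d", length(pairs))
  m <- pairs_to_matrices(pairs)
  scaling <- list(v_maxabs = max(abs(m$velocity)), f_maxabs = max(abs(m$force)))
  if (scaling$v_maxabs == 0 || scaling$f_maxabs == 0)
    stop_data("degenerate scale: a channel is identically zero")
  X <- cbind(m$velocity / scaling$v_maxabs, m$force / scaling$f_maxabs)
  n <- nrow(X)

  with_seed(cfg$seed, {
    P <- gan_init_params(cfg)
    bn1 <- bn_init(64L); bn2 <- bn_init(2L)
    opt_g <- adam_init(P$G); opt_d <- adam_init(P$D)
    bsz <- min(cfg$batch_size, n)
    steps <- max(1L, floor(n / bsz))
    hist_d <- hist_g <- numeric(cfg$epochs)

    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      dl <- gl <- 0
      for (st in seq_len(steps)) {
        idx <- ord[((st - 1L) * bsz + 1L):(st * bsz)]
        real <- gan_rows_to_input(X[idx, , drop = FALSE])
        B <- length(idx)

        ## discriminator step: real batch + fresh fake batch
        z <- matrix(stats::rnorm(B * cfg$latent_dim), B)
        gf <- gen_forward(z, P$G, bn1, bn2, training = TRUE)
        bn1 <- gf$bn1; bn2 <- gf$bn2
        fake <- gan_rows_to_input(gf$out)
        mk_r <- dropout_masks(B, cfg$dropout)
        mk_f <- dropout_masks(B, cfg$dropout)
        fr <- disc_forward(real, P$D, mk_r, cache = TRUE)
        ff <- disc_forward(fake, P$D, mk_f, cache = TRUE)
        loss_d <- (bce_logit_loss(fr$logit, cfg$real_label) +
                     bce_logit_loss(ff$logit, 0)) / 2
        br <- disc_backward((sigmoid(fr$logit) - cfg$real_label) / (2 * B),
                            P$D, fr$cache)
        bf <- disc_backward(sigmoid(ff$logit) / (2 * B), P$D, ff$cache)
        gd <- Map(`+`, br$grads, bf$grads)
        upd <- adam_step(P$D, gd, opt_d, cfg$learning_rate, cfg$beta1)
        P$D <- upd$params; opt_d <- upd$state

        ## generator step: non-saturating loss, fresh latent draw
        z <- matrix(stats::rnorm(B * cfg$latent_dim), B)
        gf <- gen_forward(z, P$G, bn1, bn2, training = TRUE, cache = TRUE)
        bn1 <- gf$bn1; bn2 <- gf$bn2
        fake <- gan_rows_to_input(gf$out)
        mk <- dropout_masks(B, cfg$dropout)
        fo <- disc_forward(fake, P$D, mk, cache = TRUE)
        loss_g <- bce_logit_loss(fo$logit, 1)
        bo <- disc_backward((sigmoid(fo$logit) - 1) / B, P$D, fo$cache)
        dout <- matrix(c(bo$dx), nrow = B, ncol = 202L)  # unflatten (B,101,2)
        gg <- gen_backward(dout, P$G, gf$cache)
        upd <- adam_step(P$G, gg, opt_g, cfg$learning_rate, cfg$beta1)
        P$G <- upd$params; opt_g <- upd$state

        dl <- dl + loss_d; gl <- gl + loss_g
      }
      hist_d[ep] <- dl / steps; hist_g[ep] <- gl / steps
      if (!is.finite(hist_d[ep]) || !is.finite(hist_g[ep]))
        stop_divergence("GAN training diverged at epoch %d (d=%g, g=%g)",
                        ep, hist_d[ep], hist_g[ep])
    }

    structure(list(params = P, bn1 = bn1, bn2 = bn2, scaling = scaling,
                   config = cfg, n_train = n,
                   history = data.frame(epoch = seq_len(cfg$epochs),
                                        d_loss = hist_d, g_loss = hist_g)),
              class = "scrum_gan")
  })
}

#' Generate velocity-force pairs from a trained GAN
#'
#' Draws latent vectors, runs the generator in inference mode (batch-norm
#' running statistics) and inverts the max-abs scaling back to physical
#' units. Tiny negative velocity values permitted by the tanh output are
#' clipped to zero, since the velocity channel is a speed magnitude.
#'
#' @param model a trained [train_gan()] object.
#' @param n number of pairs to generate.
#' @param seed integer; the same seed yields identical pairs.
#' @return list of `n` [vf_pair()] objects with `source = "gan"`.
#' @export
generate_pairs <- function(model, n, seed = 1L) {
  if (!inherits(model, "scrum_gan")) stop_data("model must be a scrum_gan")
  if (!is.numeric(n) || n < 1)
    stop_config("n must be a positive count (got %s)", format(n))
  n <- as.integer(n)
  out <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * model$config$latent_dim), n)
    gen_forward(z, model$params$G, model$bn1, model$bn2, training = FALSE)$out
  })
  v <- pmax(out[, 1:101, drop = FALSE] * model$scaling$v_maxabs, 0)
  f <- out[, 102:202, drop = FALSE] * model$scaling$f_maxabs
  lapply(seq_len(n), function(i)
    vf_pair(v[i, ], f[i, ],
            meta = list(trial_id = sprintf("gan-%04d", i)), source = "gan"))
}

#' @export
simulate.scrum_gan <- function(object, nsim = 1, seed = NULL, ...) {
  generate_pairs(object, n = nsim, seed = seed %||% 1L)
}

#' Fidelity of generated curves against measured ones
#'
#' For each generated curve, finds the measured curve with the highest
#' Pearson correlation (per channel) and records that correlation and the
#' RMSE to the matched curve; reports channel-wise means. This
#' best-match rule rewards generators whose curves lie inside the measured
#' family; it does not require a one-to-one pairing.
#'
#' @param generated,measured lists of [vf_pair()] objects, both non-empty.
#' @return object of class `gan_fidelity`: `velocity_corr`, `force_corr`
#'   (mean matched Pearson r), `velocity_rmse` (m/s), `force_rmse` (N),
#'   and the matching rule used.
#' @export
gan_fidelity <- function(generated, measured) {
  if (length(generated) == 0L || length(measured) == 0L)
    stop_config("both generated and measured sets must be non-empty")
  g <- pairs_to_matrices(generated)
  m <- pairs_to_matrices(measured)
  chan <- function(Gm, Mm) {
    cc <- suppressWarnings(stats::cor(t(Gm), t(Mm)))
    cc[!is.finite(cc)] <- -1  # constant curves carry no shape to match
    best <- max.col(cc, ties.method = "first")
    corr <- cc[cbind(seq_len(nrow(cc)), best)]
    rmse <- sqrt(rowMeans((Gm - Mm[best, , drop = FALSE])^2))
    list(corr = mean(corr), rmse = mean(rmse))
  }
  v <- chan(g$velocity, m$velocity)
  f <- chan(g$force, m$force)
  structure(list(velocity_corr = v$corr, force_corr = f$corr,
                 velocity_rmse = v$rmse, force_rmse = f$rmse,
                 matching = "best-correlated measured curve per generated curve"),
            class = "gan_fidelity")
}

#' @export
print.gan_fidelity <- function(x, ...) {
  cat("Generated-curve fidelity (best-match rule)\n")
  cat(sprintf("  velocity: mean r = %.3f, mean RMSE = %.3f m/s\n",
              x$velocity_corr, x$velocity_rmse))
  cat(sprintf("  force:    mean r = %.3f, mean RMSE = %.1f N\n",
              x$force_corr, x$force_rmse))
  invisible(x)
}

#' @export
print.scrum_gan <- function(x, ...) {
  cat(sprintf("<scrum_gan> trained on %d pairs, %d epochs (batch %d, lr %g)\n",
              x$n_train, x$config$epochs, x$config$batch_size,
              x$config$learning_rate))
  cat(sprintf("  final losses: D %.3f, G %.3f; scale: v %.2f m/s, f %.0f N\n",
              utils::tail(x$history$d_loss, 1), utils::tail(x$history$g_loss, 1),
              x$scaling$v_maxabs, x$scaling$f_maxabs))
  invisible(x)
}

#' @export
summary.scrum_gan <- function(object, ...) {
  print(object)
  cat("  loss history quartiles:\n")
  print(rbind(D = stats::quantile(object$history$d_loss),
              G = stats::quantile(object$history$g_loss)))
  invisible(object)
}

#' @export
plot.scrum_gan <- function(x, ...) {
  graphics::matplot(x$history$epoch, cbind(x$history$d_loss, x$history$g_loss),
                    type = "l", lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("discriminator", "generator"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}
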