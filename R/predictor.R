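# LSTM sequence regressor: engagement-velocity curve -> contact-force curve.
#
# The model feeds the 101-point velocity curve, scaled by the training-set
# max-abs, through stacked LSTM layers (default 128 then 64 cells) and a
# per-time-step dense layer with one ReLU unit, trained with Adam on the
# mean squared error of the scaled force curve, with early stopping on
# validation loss and best-weight restoration.

#' LSTM regressor configuration
#'
#' @param layer_cells LSTM cell counts per layer, 1-3 layers
#'   (default `c(128, 64)`, the published architecture).
#' @param learning_rate Adam step (default 0.002).
#' @param epochs maximum training epochs (default 1000).
#' @param batch_size minibatch size (default 32).
#' @param patience early-stopping patience: training halts once validation
#'   loss has not improved for this many consecutive epochs, restoring the
#'   best weights (default 50; 0 stops at the first non-improving epoch).
#' @param seed integer controlling weight init and batch shuffling.
#' @return an object of class `rnn_config`.
#' @export
rnn_config <- function(layer_cells = c(128, 64), learning_rate = 0.002,
                       epochs = 1000, batch_size = 32, patience = 50,
                       seed = 1L) {
  if (length(layer_cells) < 1L || length(layer_cells) > 3L)
    stop_config("layer_cells must list 1 to 3 layers (got %d)", length(layer_cells))
  if (any(layer_cells < 1)) stop_config("cell counts must be positive")
  if (learning_rate <= 0) stop_config("learning_rate must be positive")
  if (patience < 0) stop_config("patience must be >= 0")
  structure(list(layer_cells = as.integer(layer_cells),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "rnn_config")
}

#' Max-abs normalization of a pair dataset
#'
#' Scales velocities and forces by the maximum absolute value of each
#' channel over the entire dataset, so every scaled sample lies in
#' `[-1, 1]` and at least one sample per channel attains magnitude 1.
#' The returned constants must be reused verbatim at prediction time;
#' [train_predictor()] and [predict_force()] do this automatically.
#'
#' @param pairs non-empty list of [vf_pair()]s.
#' @return list with `velocity` and `force` (scaled n x 101 matrices) and
#'   `norms` (`v_maxabs` in m/s, `f_maxabs` in N).
#' @export
normalize_pairs <- function(pairs) {
  m <- pairs_to_matrices(pairs)
  if (!all(is.finite(m$velocity)) || !all(is.finite(m$force)))
    stop_data("non-finite values in pair dataset")
  norms <- list(v_maxabs = max(abs(m$velocity)), f_maxabs = max(abs(m$force)))
  if (norms$v_maxabs == 0 || norms$f_maxabs == 0)
    stop_data("degenerate scale: a channel is identically zero")
  list(velocity = m$velocity / norms$v_maxabs,
       force = m$force / norms$f_maxabs, norms = norms)
}

#' Shuffled train/validation split
#'
#' @param pairs list of at least 5 [vf_pair()]s.
#' @param fraction_train fraction assigned to training (default 0.8);
#'   `round(fraction_train * N)` pairs go to training.
#' @param seed integer seed for the shuffle.
#' @return list with `train` and `validation`, disjoint and exhaustive.
#' @export
split_dataset <- function(pairs, fraction_train = 0.8, seed = 1L) {
  n <- length(pairs)
  if (n < 5L) stop_data("need at least 5 pairs to split, got %d", n)
  if (fraction_train <= 0 || fraction_train >= 1)
    stop_config("fraction_train must be in (0, 1)")
  n_train <- as.integer(round(fraction_train * n))
  n_train <- max(1L, min(n - 1L, n_train))
  ord <- with_seed(seed, sample.int(n))
  list(train = pairs[ord[seq_len(n_train)]],
       validation = pairs[ord[(n_train + 1L):n]])
}

## ---- forward / backward over stacked layers ----

rnn_init_params <- function(cfg, d_in = 1L) {
  cells <- cfg$layer_cells
  layers <- vector("list", length(cells))
  din <- d_in
  for (l in seq_along(cells)) {
    H <- cells[l]
    b <- rep(0, 4L * H)
    b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
    layers[[l]] <- list(W = glorot(din, 4L * H), U = glorot(H, 4L * H), b = b)
    din <- H
  }
  # head bias starts at the scale of the (positive, max-abs-scaled) force
  # targets so the ReLU unit is alive at initialization
  list(layers = layers,
       head = list(Wd = glorot(din, 1L), bd = 0.5))
}

rnn_forward <- function(V, P, cache = FALSE) {
  B <- nrow(V); T_ <- ncol(V)
  x <- array(V, c(B, T_, 1L))
  caches <- vector("list", length(P$layers))
  for (l in seq_along(P$layers)) {
    ly <- P$layers[[l]]
    fw <- cpp_lstm_fw(x, ly$W, ly$U, ly$b)
    if (cache) caches[[l]] <- list(x = x, fw = fw)
    x <- array(fw$h, c(B, T_, ncol(fw$h)))
  }
  hlast <- matrix(x, B * T_, dim(x)[3])
  pre <- drop(hlast %*% P$head$Wd) + P$head$bd
  yhat <- matrix(pmax(pre, 0), B, T_)
  if (cache) list(yhat = yhat, pre = pre, hlast = hlast, caches = caches)
  else yhat
}

rnn_backward <- function(fwd, P, dy) {
  B <- nrow(dy); T_ <- ncol(dy)
  dpre <- as.numeric(dy) * (fwd$pre > 0)
  grads <- list(layers = vector("list", length(P$layers)),
                head = list(Wd = crossprod(fwd$hlast, matrix(dpre, ncol = 1)),
                            bd = sum(dpre)))
  dh <- matrix(dpre, ncol = 1) %*% t(P$head$Wd)
  for (l in rev(seq_along(P$layers))) {
    cc <- fwd$caches[[l]]
    bw <- cpp_lstm_bw(cc$x, P$layers[[l]]$W, P$layers[[l]]$U,
                      cc$fw$h, cc$fw$c, cc$fw$i, cc$fw$f, cc$fw$g, cc$fw$o, dh)
    grads$layers[[l]] <- list(W = bw$dW, U = bw$dU, b = as.numeric(bw$db))
    dh <- bw$dx
  }
  grads
}

flatten_params <- function(P) {
  out <- list()
  for (l in seq_along(P$layers))
    for (nm in names(P$layers[[l]]))
      out[[sprintf("L%d.%s", l, nm)]] <- P$layers[[l]][[nm]]
  out$head.Wd <- P$head$Wd; out$head.bd <- P$head$bd
  out
}

unflatten_params <- function(flat, P) {
  for (l in seq_along(P$layers))
    for (nm in names(P$layers[[l]]))
      P$layers[[l]][[nm]] <- flat[[sprintf("L%d.%s", l, nm)]]
  P$head$Wd <- flat$head.Wd; P$head$bd <- flat$head.bd
  P
}

#' Train the velocity-to-force LSTM regressor
#'
#' Normalizes both channels by the training-set max-abs constants, fits the
#' stacked-LSTM model on the scaled force curves with Adam and mean squared
#' error, monitors validation loss every epoch, and stops early once it has
#' not improved for `cfg$patience` epochs, restoring the best weights.
#'
#' @param train,val non-empty lists of [vf_pair()]s in physical units;
#'   normalization is internal so constants can never be applied twice.
#' @param cfg an [rnn_config()].
#' @return an object of class `force_rnn`: weights, config, normalization
#'   constants, per-epoch history and the epoch training stopped at.
#' @seealso [predict_force()], [grid_search()]
#' @export
train_predictor <- function(train, val, cfg = rnn_config()) {
  if (!inherits(cfg, "rnn_config")) stop_config("cfg must be an rnn_config")
  if (length(train) == 0L || length(val) == 0L)
    stop_data("train and val must both be non-empty")
  tr <- normalize_pairs(train)
  vm <- pairs_to_matrices(val)
  Vv <- vm$velocity / tr$norms$v_maxabs
  Fv <- vm$force / tr$norms$f_maxabs

  with_seed(cfg$seed, {
    P <- rnn_init_params(cfg)
    opt <- adam_init(flatten_params(P))
    n <- nrow(tr$velocity)
    bsz <- min(cfg$batch_size, n)
    steps <- max(1L, floor(n / bsz))
    hist_tr <- hist_va <- numeric(0)
    best_val <- Inf; best_P <- P; best_epoch <- 0L; wait <- 0L
    stopped <- cfg$epochs

    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tl <- 0
      for (st in seq_len(steps)) {
        idx <- ord[((st - 1L) * bsz + 1L):(st * bsz)]
        Vb <- tr$velocity[idx, , drop = FALSE]
        Fb <- tr$force[idx, , drop = FALSE]
        fwd <- rnn_forward(Vb, P, cache = TRUE)
        err <- fwd$yhat - Fb
        loss <- mean(err^2)
        if (!is.finite(loss))
          stop_divergence("LSTM training diverged at epoch %d", ep)
        g <- rnn_backward(fwd, P, 2 * err / length(err))
        upd <- adam_step(flatten_params(P), flatten_params(g), opt,
                         cfg$learning_rate)
        P <- unflatten_params(upd$params, P)
        opt <- upd$state
        tl <- tl + loss
      }
      val_loss <- mean((rnn_forward(Vv, P) - Fv)^2)
      hist_tr <- c(hist_tr, tl / steps); hist_va <- c(hist_va, val_loss)
      if (val_loss < best_val) {
        best_val <- val_loss; best_P <- P; best_epoch <- ep; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > cfg$patience) { stopped <- ep; break }
      }
    }

    structure(list(params = best_P, config = cfg, norms = tr$norms,
                   history = data.frame(epoch = seq_along(hist_tr),
                                        train_loss = hist_tr,
                                        val_loss = hist_va),
                   stopped_epoch = stopped, best_epoch = best_epoch,
                   best_val_loss = best_val),
              class = "force_rnn")
  })
}

#' Predict a contact-force curve from a velocity curve
#'
#' Scales the input with the stored `v_maxabs`, runs the network, and
#' denormalizes with the stored `f_maxabs`. The ReLU output head guarantees
#' non-negative forces.
#'
#' @param model a trained [train_predictor()] object.
#' @param velocity numeric vector of length 101, or an n x 101 matrix of
#'   velocity curves (m/s).
#' @return force curve(s) in newtons: a vector for vector input, a matrix
#'   for matrix input.
#' @export
predict_force <- function(model, velocity) {
  if (!inherits(model, "force_rnn")) stop_data("model must be a force_rnn")
  vec_in <- is.null(dim(velocity))
  V <- if (vec_in) matrix(velocity, nrow = 1L) else as.matrix(velocity)
  if (ncol(V) != N_POINTS)
    stop_shape("velocity curves must have %d samples (got %d)", N_POINTS, ncol(V))
  if (!all(is.finite(V))) stop_data("velocity input contains non-finite values")
  Y <- rnn_forward(V / model$norms$v_maxabs, model$params) * model$norms$f_maxabs
  if (vec_in) drop(Y) else Y
}

#' @param object a `force_rnn` model.
#' @param newdata a [vf_pair()], a list of them, a velocity vector, or a
#'   matrix of velocity curves.
#' @param ... unused.
#' @rdname predict_force
#' @export
predict.force_rnn <- function(object, newdata, ...) {
  if (inherits(newdata, "vf_pair")) return(predict_force(object, newdata$velocity))
  if (is.list(newdata))
    return(predict_force(object, pairs_to_matrices(newdata)$velocity))
  predict_force(object, newdata)
}

#' Hyperparameter grid search with cross-validation
#'
#' Enumerates the full Cartesian product of layer counts, cell widths and
#' learning rates (one shared cell width per candidate, so the default
#' space has 3 x 3 x 3 = 27 combinations) and scores each by k-fold
#' cross-validated validation loss.
#'
#' @param pairs list of [vf_pair()]s.
#' @param layers_options,cells_options,lr_options the search space
#'   (defaults: 1-3 layers, 32/64/128 cells, 0.001/0.002/0.01).
#' @param cv_folds folds (default 5).
#' @param epochs,batch_size,patience training controls for the candidate
#'   fits (smaller than final-fit budgets by design).
#' @param seed integer seed; folds are fixed across combinations.
#' @return list with `best` (an [rnn_config()]) and `table` (one row per
#'   combination with mean and SD of the fold validation losses).
#' @export
grid_search <- function(pairs, layers_options = 1:3,
                        cells_options = c(32, 64, 128),
                        lr_options = c(0.001, 0.002, 0.01),
                        cv_folds = 5, epochs = 30, batch_size = 32,
                        patience = 10, seed = 1L) {
  n <- length(pairs)
  if (cv_folds < 2 || cv_folds > n)
    stop_config("cv_folds must be between 2 and the number of pairs (%d)", n)
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  grid <- expand.grid(layers = layers_options, cells = cells_options,
                      lr = lr_options, KEEP.OUT.ATTRS = FALSE)
  scores <- matrix(NA_real_, nrow(grid), cv_folds)
  for (i in seq_len(nrow(grid))) {
    cfg <- rnn_config(layer_cells = rep(grid$cells[i], grid$layers[i]),
                      learning_rate = grid$lr[i], epochs = epochs,
                      batch_size = batch_size, patience = patience,
                      seed = seed)
    for (f in seq_len(cv_folds)) {
      fit <- train_predictor(pairs[folds != f], pairs[folds == f], cfg)
      scores[i, f] <- fit$best_val_loss
    }
  }
  tab <- cbind(grid, mean_val_loss = rowMeans(scores),
               sd_val_loss = apply(scores, 1L, stats::sd))
  best <- which.min(tab$mean_val_loss)
  list(best = rnn_config(layer_cells = rep(grid$cells[best], grid$layers[best]),
                         learning_rate = grid$lr[best], seed = seed),
       table = tab)
}

#' @export
print.force_rnn <- function(x, ...) {
  cat(sprintf("<force_rnn> LSTM [%s] + dense-1 ReLU, lr %g\n",
              paste(x$config$layer_cells, collapse = ", "),
              x$config$learning_rate))
  cat(sprintf("  stopped at epoch %d (best epoch %d, val MSE %.3g scaled)\n",
              x$stopped_epoch, x$best_epoch, x$best_val_loss))
  cat(sprintf("  normalization: v_maxabs %.2f m/s, f_maxabs %.0f N\n",
              x$norms$v_maxabs, x$norms$f_maxabs))
  invisible(x)
}

#' @export
summary.force_rnn <- function(object, ...) {
  print(object)
  cat("  last epochs:\n")
  print(utils::tail(object$history, 3))
  invisible(object)
}

#' @export
plot.force_rnn <- function(x, ...) {
  graphics::matplot(x$history$epoch,
                    cbind(x$history$train_loss, x$history$val_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "MSE (scaled force)", log = "y", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
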