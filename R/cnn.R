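# Bird/non-bird convolutional classifier.
#
# Architecture: conv(LC1, 3x3) + ReLU + maxpool(2x2)
#             -> conv(LC2, 3x3) + ReLU + maxpool(2x2)
#             -> dense(LFC1) + ReLU -> dense(2) + softmax,
# on 100 x 100 x 3 crops scaled to [0, 1]; two-class cross-entropy loss,
# Adam optimizer. Convolutions are evaluated as GEMMs over im2col patch
# matrices (BLAS), with the layout kernels compiled in src/.

#' CNN configuration
#'
#' Defaults follow the production training recipe (Adam epsilon 1e-7,
#' learning rate 1e-5, 50 epochs, 10 % validation split, 3x3 kernels,
#' 2x2 max pooling). Scaled-down experiments on synthetic crops typically
#' raise the learning rate to 1e-3 and cut epochs; see the package vignette.
#'
#' @param lc1,lc2 filters in the two convolutional layers.
#' @param lfc1 neurons in the hidden dense layer.
#' @param lfc2 output classes (2: bird / non-bird).
#' @param kernel convolution kernel side, px.
#' @param input_size crop side, px.
#' @param channels crop channels.
#' @param learning_rate,adam_epsilon Adam hyper-parameters.
#' @param epochs training epochs.
#' @param validation_split held-out fraction for per-epoch validation.
#' @param batch_size minibatch size.
#' @return List of class `cnn_config`.
#' @export
cnn_config <- function(lc1 = 32, lc2 = 32, lfc1 = 128, lfc2 = 2,
                       kernel = 3, input_size = 100, channels = 3,
                       learning_rate = 1e-5, adam_epsilon = 1e-7,
                       epochs = 50, validation_split = 0.1,
                       batch_size = 32) {
  sizes <- c(lc1, lc2, lfc1, lfc2, kernel, input_size, channels, batch_size)
  if (any(sizes < 1)) stop("cnn_config: layer/size parameters must be >= 1")
  if (validation_split <= 0 || validation_split >= 1)
    stop("cnn_config: validation_split must be in (0, 1)")
  dims <- .cnn_dims(input_size, kernel)
  if (dims$pool2 < 1)
    stop("cnn_config: input_size too small for two conv/pool stages")
  structure(list(lc1 = lc1, lc2 = lc2, lfc1 = lfc1, lfc2 = lfc2,
                 kernel = kernel, input_size = input_size, channels = channels,
                 learning_rate = learning_rate, adam_epsilon = adam_epsilon,
                 epochs = epochs, validation_split = validation_split,
                 batch_size = batch_size),
            class = "cnn_config")
}

.cnn_dims <- function(input_size, kernel) {
  conv1 <- input_size - kernel + 1
  pool1 <- conv1 %/% 2
  conv2 <- pool1 - kernel + 1
  pool2 <- conv2 %/% 2
  list(conv1 = conv1, pool1 = pool1, conv2 = conv2, pool2 = pool2)
}

# He-normal initial weights; RNG state is the caller's responsibility
.init_weights <- function(cfg) {
  k <- cfg$kernel
  dims <- .cnn_dims(cfg$input_size, k)
  flat <- dims$pool2^2 * cfg$lc2
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  list(W1 = he(k^2 * cfg$channels, cfg$lc1), b1 = numeric(cfg$lc1),
       W2 = he(k^2 * cfg$lc1, cfg$lc2),     b2 = numeric(cfg$lc2),
       W3 = he(flat, cfg$lfc1),             b3 = numeric(cfg$lfc1),
       W4 = he(cfg$lfc1, cfg$lfc2),         b4 = numeric(cfg$lfc2))
}

#' Build an untrained bird classifier
#'
#' @param config a [cnn_config()].
#' @param seed integer seed for the weight initialization (reproducible).
#' @return Object of class `bird_cnn` (untrained).
#' @export
build_bird_cnn <- function(config = cnn_config(), seed = 1) {
  stopifnot(inherits(config, "cnn_config"))
  old <- globalenv()$.Random.seed
  set.seed(seed)
  w <- .init_weights(config)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(config = config, weights = w, history = NULL, trained = FALSE),
            class = "bird_cnn")
}

# coerce crops (list of H x W [x C] arrays, or H x W x C x N array) to a
# (pixels x N) matrix scaled to [0, 1]; one column is one (H, W, C) image
.crop_matrix <- function(crops, cfg) {
  s <- cfg$input_size; ch <- cfg$channels
  step <- s * s * ch
  if (is.array(crops) && length(dim(crops)) == 4) {
    if (!all(dim(crops)[1:3] == c(s, s, ch)))
      stop(sprintf("crops must be %d x %d x %d", s, s, ch))
    x <- crops / 255
    dim(x) <- c(step, dim(crops)[4])
    return(x)
  }
  if (!is.list(crops)) stop("crops must be a list of arrays or a 4-D array")
  out <- matrix(0, step, length(crops))
  for (i in seq_along(crops)) {
    cr <- crops[[i]]
    d <- dim(cr)
    if (length(d) == 2 && ch == 1) dim(cr) <- c(d, 1L)
    if (length(d) == 2 && ch == 3) cr <- array(rep(cr, 3), c(d, 3L))
    if (!all(dim(cr) == c(s, s, ch)))
      stop(sprintf("crop %d: expected %d x %d x %d, got %s",
                   i, s, s, ch, paste(dim(cr), collapse = " x ")))
    out[, i] <- as.numeric(cr) / 255
  }
  out
}

# forward pass; keep = TRUE caches intermediates for the backward pass
.cnn_forward <- function(w, cfg, xvec, B, keep = FALSE) {
  k <- cfg$kernel; s <- cfg$input_size
  d <- .cnn_dims(s, k)
  X1 <- im2col_cpp(xvec, s, s, cfg$channels, B, k)
  A1 <- X1 %*% w$W1
  relu_bias_inplace_cpp(A1, w$b1)
  p1 <- maxpool_cpp(A1, d$conv1, d$conv1, B)
  x2 <- mat_to_arr_cpp(p1$out, d$pool1, d$pool1, B)
  X2 <- im2col_cpp(x2, d$pool1, d$pool1, cfg$lc1, B, k)
  A2 <- X2 %*% w$W2
  relu_bias_inplace_cpp(A2, w$b2)
  p2 <- maxpool_cpp(A2, d$conv2, d$conv2, B)
  # flatten: row b = (position within channel, channel), position fastest
  nout2 <- d$pool2^2
  arr <- array(p2$out, c(nout2, B, cfg$lc2))
  arr <- aperm(arr, c(1, 3, 2))
  dim(arr) <- c(nout2 * cfg$lc2, B)
  Xf <- t(arr)
  Z3 <- sweep(Xf %*% w$W3, 2, w$b3, "+")
  A3 <- pmax(Z3, 0)
  Z4 <- sweep(A3 %*% w$W4, 2, w$b4, "+")
  # row-wise softmax (stabilized)
  m <- apply(Z4, 1, max)
  e <- exp(Z4 - m)
  probs <- e / rowSums(e)
  res <- list(probs = probs)
  if (keep) {
    res$cache <- list(X1 = X1, P1 = p1$out, arg1 = p1$argmax,
                      X2 = X2, P2 = p2$out, arg2 = p2$argmax,
                      Xf = Xf, A3 = A3, dims = d, B = B)
  }
  res
}

# backward pass; y in {1, 2}; returns gradients for all parameters
.cnn_backward <- function(w, cfg, fw, y) {
  cc <- fw$cache; d <- cc$dims; B <- cc$B
  onehot <- matrix(0, B, cfg$lfc2)
  onehot[cbind(seq_len(B), y)] <- 1
  dZ4 <- (fw$probs - onehot) / B
  g <- list()
  g$W4 <- crossprod(cc$A3, dZ4); g$b4 <- colSums(dZ4)
  dA3 <- tcrossprod(dZ4, w$W4)
  dZ3 <- dA3 * (cc$A3 > 0)
  g$W3 <- crossprod(cc$Xf, dZ3); g$b3 <- colSums(dZ3)
  dXf <- tcrossprod(dZ3, w$W3)
  # unflatten
  nout2 <- d$pool2^2
  a <- t(dXf); dim(a) <- c(nout2, cfg$lc2, B)
  a <- aperm(a, c(1, 3, 2)); dim(a) <- c(nout2 * B, cfg$lc2)
  # pool backward fused with the ReLU mask at the pooled maxima
  dA2 <- maxpool_bwd_cpp(a, cc$arg2, cc$P2, d$conv2^2 * B)
  g$W2 <- crossprod(cc$X2, dA2); g$b2 <- colSums(dA2)
  dX2 <- tcrossprod(dA2, w$W2)
  dx2 <- col2im_cpp(dX2, d$pool1, d$pool1, cfg$lc1, B, cfg$kernel)
  dP1 <- arr_to_mat_cpp(dx2, d$pool1, d$pool1, cfg$lc1, B)
  dA1 <- maxpool_bwd_cpp(dP1, cc$arg1, cc$P1, d$conv1^2 * B)
  g$W1 <- crossprod(cc$X1, dA1); g$b1 <- colSums(dA1)
  g
}

#' Train a bird classifier
#'
#' Minibatch Adam on two-class cross-entropy, with a seeded shuffle and a
#' validation split held out before training. Deterministic for a fixed
#' seed. `epochs = 0` returns the model unchanged (with an empty history).
#'
#' @param model a [build_bird_cnn()] object.
#' @param crops list of crops or `H x W x C x N` array, intensities 0--255.
#' @param labels factor/character/integer labels; the positive ("bird")
#'   class is `levels[2]` after coercion via [factor()], or pass a logical
#'   vector (`TRUE` = bird).
#' @param epochs training epochs (default from the model config).
#' @param seed RNG seed for shuffling.
#' @param verbose print per-epoch progress.
#' @return The trained `bird_cnn`, with `$history` (per-epoch data.frame of
#'   training loss/accuracy and validation accuracy).
#' @export
train_bird_cnn <- function(model, crops, labels, epochs = NULL, seed = 1,
                           verbose = FALSE) {
  stopifnot(inherits(model, "bird_cnn"))
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  y <- .coerce_labels(labels)
  n <- length(y$y)
  if (length(unique(y$y)) < 2)
    stop("train_bird_cnn: training data must contain both classes")
  if (epochs == 0) {
    model$history <- data.frame(epoch = integer(), loss = numeric(),
                                accuracy = numeric(), val_accuracy = numeric())
    return(model)
  }
  X <- .crop_matrix(crops, cfg)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perm <- sample.int(n)
  n_val <- max(1L, floor(cfg$validation_split * n))
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  w <- model$weights
  opt <- .adam_init(w)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    ep_loss <- 0; ep_hit <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      nb <- length(idx)
      fw <- .cnn_forward(w, cfg, X[, idx], nb, keep = TRUE)
      yb <- y$y[idx]
      p_true <- fw$probs[cbind(seq_len(nb), yb)]
      ep_loss <- ep_loss - sum(log(pmax(p_true, 1e-12)))
      ep_hit <- ep_hit + sum(max.col(fw$probs) == yb)
      g <- .cnn_backward(w, cfg, fw, yb)
      upd <- .adam_step(w, g, opt, cfg$learning_rate, cfg$adam_epsilon)
      w <- upd$w; opt <- upd$opt
    }
    val_acc <- {
      pv <- .predict_probs_mat(w, cfg, X, val_idx)
      mean(max.col(pv) == y$y[val_idx])
    }
    hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / length(ord),
                             accuracy = ep_hit / length(ord),
                             val_accuracy = val_acc)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, acc %.3f, val_acc %.3f",
                      ep, ep_loss / length(ord), ep_hit / length(ord), val_acc))
  }
  model$weights <- w
  model$history <- do.call(rbind, hist)
  model$classes <- y$classes
  model$trained <- TRUE
  model
}

#' Fit a bird classifier in one call
#'
#' Convenience wrapper: [build_bird_cnn()] + [train_bird_cnn()].
#'
#' @inheritParams train_bird_cnn
#' @param config a [cnn_config()].
#' @param seed RNG seed covering initialization and shuffling.
#' @return A trained `bird_cnn`.
#' @export
bird_cnn <- function(crops, labels, config = cnn_config(), seed = 1,
                     verbose = FALSE) {
  model <- build_bird_cnn(config, seed = seed)
  train_bird_cnn(model, crops, labels, seed = seed, verbose = verbose)
}

.coerce_labels <- function(labels) {
  if (is.logical(labels)) {
    classes <- c("non-bird", "bird")
    y <- as.integer(labels) + 1L
  } else {
    f <- factor(labels)
    if (nlevels(f) > 2) stop("labels must be binary")
    classes <- levels(f)
    y <- as.integer(f)
  }
  list(y = y, classes = classes)
}

.predict_probs_mat <- function(w, cfg, X, idx = seq_len(ncol(X)), chunk = 64) {
  n <- length(idx)
  out <- matrix(NA_real_, n, cfg$lfc2)
  for (start in seq(1, n, by = chunk)) {
    sel <- idx[start:min(start + chunk - 1, n)]
    out[start:(start + length(sel) - 1), ] <-
      .cnn_forward(w, cfg, X[, sel, drop = FALSE], length(sel))$probs
  }
  out
}

.predict_probs <- function(w, cfg, crops, idx, chunk = 64) {
  X <- .crop_matrix(crops, cfg)
  .predict_probs_mat(w, cfg, X[, idx, drop = FALSE], chunk = chunk)
}

#' Predict bird probabilities for crops
#'
#' @param object a `bird_cnn`.
#' @param crops list of crops or 4-D array (intensities 0--255).
#' @param type `"prob"` for the probability of the positive (bird) class,
#'   `"class"` for thresholded labels (0.5), `"matrix"` for the full
#'   two-column probability matrix.
#' @param ... unused.
#' @return Numeric vector, character vector, or matrix, per `type`.
#' @export
predict.bird_cnn <- function(object, crops, type = c("prob", "class", "matrix"),
                             ...) {
  type <- match.arg(type)
  n <- if (is.array(crops) && length(dim(crops)) == 4) dim(crops)[4] else length(crops)
  probs <- .predict_probs(object$weights, object$config, crops, seq_len(n))
  classes <- if (!is.null(object$classes)) object$classes else c("non-bird", "bird")
  switch(type,
         prob = probs[, 2],
         class = classes[ifelse(probs[, 2] >= 0.5, 2L, 1L)],
         matrix = structure(probs, dimnames = list(NULL, classes)))
}

#' @export
print.bird_cnn <- function(x, ...) {
  cfg <- x$config
  npar <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf("<bird_cnn %dx%dx%d -> conv%d -> conv%d -> fc%d -> %d classes; %s; %d parameters>\n",
              cfg$input_size, cfg$input_size, cfg$channels,
              cfg$lc1, cfg$lc2, cfg$lfc1, cfg$lfc2,
              if (isTRUE(x$trained)) "trained" else "untrained", npar))
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf("  final epoch: loss %.4f, val_acc %.3f\n",
                utils::tail(x$history$loss, 1), utils::tail(x$history$val_accuracy, 1)))
  invisible(x)
}

#' @export
plot.bird_cnn <- function(x, ...) {
  if (is.null(x$history) || !nrow(x$history)) stop("no training history to plot")
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "loss",
                 main = "bird_cnn training history", ...)
  invisible(x)
}

#' Save / load classifier weights
#'
#' Single-file serialization of the model (config + weights + history).
#'
#' @param model a `bird_cnn`.
#' @param path file path.
#' @return `load_bird_cnn` returns the model; `save_bird_cnn` the path,
#'   invisibly.
#' @export
save_bird_cnn <- function(model, path) {
  stopifnot(inherits(model, "bird_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_bird_cnn
#' @export
load_bird_cnn <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "bird_cnn"))
  model
}

# ---- Adam ----

.adam_init <- function(w) {
  list(m = lapply(w, function(p) p * 0), v = lapply(w, function(p) p * 0), t = 0)
}

.adam_step <- function(w, g, opt, lr, eps, beta1 = 0.9, beta2 = 0.999) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in names(w)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g[[nm]]^2
    w[[nm]] <- w[[nm]] - lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(w = w, opt = opt)
}

# ---- evaluation metrics ----

#' Confusion counts
#'
#' @param tp,fp,fn,tn non-negative detection counts.
#' @return List of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp, fp, fn, tn)
  if (any(v < 0) || any(!is.finite(v))) stop("confusion_counts: counts must be >= 0")
  if (sum(v) == 0) stop("confusion_counts: at least one count must be positive")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "confusion_counts")
}

#' Identification metrics from confusion counts
#'
#' Precision, recall (sensitivity), F1, specificity and accuracy. A metric
#' whose denominator is zero is reported as `NA` (undefined).
#'
#' @param counts a [confusion_counts()], or tp (with fp, fn, tn following).
#' @param fp,fn,tn counts when `counts` is given as a scalar tp.
#' @return Named list of class `metrics_report`.
#' @export
#' @examples
#' compute_metrics(confusion_counts(90, 10, 0, 0))
compute_metrics <- function(counts, fp = NULL, fn = NULL, tn = NULL) {
  if (!inherits(counts, "confusion_counts"))
    counts <- confusion_counts(counts, fp, fn, tn)
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- sdiv(counts$tp, counts$tp + counts$fp)
  recall <- sdiv(counts$tp, counts$tp + counts$fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(
    precision = precision,
    recall = recall,
    f1 = f1,
    specificity = sdiv(counts$tn, counts$tn + counts$fp),
    accuracy = sdiv(counts$tp + counts$tn,
                    counts$tp + counts$tn + counts$fn + counts$fp)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("precision %.3f | recall %.3f | F1 %.3f | specificity %.3f | accuracy %.3f\n",
              x$precision, x$recall, x$f1, x$specificity, x$accuracy))
  invisible(x)
}

#' Evaluate a classifier on labelled crops
#'
#' @param model a trained `bird_cnn`.
#' @param crops evaluation crops.
#' @param labels true labels (same convention as [train_bird_cnn()]).
#' @return A `metrics_report` with the confusion counts attached as
#'   `attr(., "counts")`.
#' @export
evaluate_bird_cnn <- function(model, crops, labels) {
  y <- .coerce_labels(labels)
  p <- predict(model, crops, type = "prob")
  pred_bird <- p >= 0.5
  true_bird <- y$y == 2L
  counts <- confusion_counts(tp = sum(pred_bird & true_bird),
                             fp = sum(pred_bird & !true_bird),
                             fn = sum(!pred_bird & true_bird),
                             tn = sum(!pred_bird & !true_bird))
  out <- compute_metrics(counts)
  attr(out, "counts") <- counts
  out
}
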