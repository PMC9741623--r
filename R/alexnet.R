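#' Configuration of the pooling-free 1-D AlexNet variant
#'
#' Five 1-D convolution blocks in the classic AlexNet layout with 1-D
#' kernels (11, 5, 3, 3, 3). All pooling layers are removed; batch
#' normalization follows the first three convolutions; every convolution
#' is followed by ReLU. The first convolution uses stride 4
#' (compensating the removed pooling); later strides default to
#' (2, 2, 1, 2). Default channel widths (32, 64, 96, 96, 64) and the
#' classifier (128, 64, n_class) are scaled for minutes-long single-CPU
#' runs; the classic widths (96, 256, 384, 384, 256) are available
#' through this configuration. Adam, learning rate 0.001, 80 epochs.
#'
#' @param channels Output channels of the five conv blocks.
#' @param kernels Kernel lengths.
#' @param strides Strides.
#' @param bn Logical flags: batch normalization after each conv block
#'   (defaults to the first three only).
#' @param classifier Fully connected widths before the `n_class` output.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param n_class Number of output classes.
#' @return An object of class `alexnet1d_config`.
#' @export
alexnet1d_config <- function(channels = c(32, 64, 96, 96, 64),
                             kernels = c(11, 5, 3, 3, 3),
                             strides = c(4, 2, 2, 1, 2),
                             bn = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                             classifier = c(128, 64),
                             lr = 1e-3, batch_size = 32, epochs = 80,
                             n_class = 4) {
  n <- length(channels)
  if (length(kernels) != n || length(strides) != n || length(bn) != n) {
    stop("channels, kernels, strides and bn must have equal length",
         call. = FALSE)
  }
  if (any(c(channels, kernels, strides, classifier) <= 0)) {
    stop("layer sizes must be positive", call. = FALSE)
  }
  if (lr <= 0) stop("`lr` must be > 0", call. = FALSE)
  structure(list(channels = as.integer(channels),
                 kernels = as.integer(kernels),
                 strides = as.integer(strides), bn = as.logical(bn),
                 classifier = as.integer(classifier), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 n_class = as.integer(n_class)),
            class = "alexnet1d_config")
}

#' Build the 1-D AlexNet variant
#'
#' @param config An [alexnet1d_config()].
#' @return An untrained model of class `alexnet1d_model`.
#' @export
build_alexnet1d <- function(config = alexnet1d_config()) {
  stopifnot(inherits(config, "alexnet1d_config"))
  structure(list(config = config, params = NULL, bn_stats = NULL,
                 classes = NULL, log = NULL, seed = NULL),
            class = "alexnet1d_model")
}

#' Layer table of the AlexNet variant
#'
#' One row per operator in forward order, for structural inspection
#' (e.g. verifying the absence of pooling and the placement of batch
#' normalization).
#'
#' @param config An [alexnet1d_config()].
#' @return Data frame with columns `layer`, `type`, `detail`.
#' @export
alexnet1d_layers <- function(config = alexnet1d_config()) {
  rows <- list()
  for (l in seq_along(config$channels)) {
    rows[[length(rows) + 1L]] <-
      c("conv1d", sprintf("ch=%d k=%d stride=%d", config$channels[l],
                          config$kernels[l], config$strides[l]))
    if (config$bn[l]) rows[[length(rows) + 1L]] <- c("batch_norm", "")
    rows[[length(rows) + 1L]] <- c("relu", "")
  }
  rows[[length(rows) + 1L]] <- c("flatten", "")
  for (w in config$classifier) {
    rows[[length(rows) + 1L]] <- c("dense", sprintf("units=%d", w))
    rows[[length(rows) + 1L]] <- c("relu", "")
  }
  rows[[length(rows) + 1L]] <- c("dense",
                                 sprintf("units=%d", config$n_class))
  data.frame(layer = seq_along(rows),
             type = vapply(rows, `[`, "", 1),
             detail = vapply(rows, `[`, "", 2))
}

conv_out_len <- function(len, k, stride) (len - k) %/% stride + 1L

alexnet_feature_len <- function(config, input_dim) {
  len <- input_dim
  for (l in seq_along(config$channels)) {
    len <- conv_out_len(len, config$kernels[l], config$strides[l])
    if (len < 1) stop("input too short for the conv stack", call. = FALSE)
  }
  len * config$channels[length(config$channels)]
}

alexnet_init_params <- function(config, input_dim) {
  params <- list()
  in_ch <- 1L
  for (l in seq_along(config$channels)) {
    fan_in <- in_ch * config$kernels[l]
    params[[paste0("Wc", l)]] <-
      t(glorot_init(fan_in, config$channels[l]))  # out_ch x (in_ch*k)
    params[[paste0("bc", l)]] <- numeric(config$channels[l])
    if (config$bn[l]) {
      params[[paste0("gamma", l)]] <- rep(1, config$channels[l])
      params[[paste0("beta", l)]] <- numeric(config$channels[l])
    }
    in_ch <- config$channels[l]
  }
  widths <- c(alexnet_feature_len(config, input_dim), config$classifier,
              config$n_class)
  for (l in seq_len(length(widths) - 1L)) {
    params[[paste0("Wf", l)]] <- glorot_init(widths[l], widths[l + 1])
    params[[paste0("bf", l)]] <- numeric(widths[l + 1])
  }
  params
}

# Forward through the conv stack + classifier.
# x: batch matrix (B x input_dim). Returns logits and caches for backward.
alexnet_forward <- function(params, config, x, train = TRUE,
                            bn_stats = NULL) {
  B <- nrow(x)
  cube <- array(t(x), dim = c(ncol(x), 1L, B))
  caches <- list()
  in_cube <- cube
  for (l in seq_along(config$channels)) {
    W <- params[[paste0("Wc", l)]]
    b <- params[[paste0("bc", l)]]
    z <- .conv1d_forward_cpp(in_cube, W, b, config$kernels[l],
                             config$strides[l])
    cache <- list(x = in_cube)
    if (config$bn[l]) {
      if (train) {
        bn <- .bn1d_forward_cpp(z, params[[paste0("gamma", l)]],
                                params[[paste0("beta", l)]], 1e-5)
        cache$z <- z
        cache$bn <- list(mu = as.numeric(bn$mu),
                         va = as.numeric(bn$va),
                         istd = as.numeric(bn$istd))
        z <- bn$y
      } else {
        st <- bn_stats[[paste0("bn", l)]]
        z <- .bn1d_eval_cpp(z, params[[paste0("gamma", l)]],
                            params[[paste0("beta", l)]], st$mu, st$va,
                            1e-5)
      }
    }
    a <- .relu_cpp(z)
    cache$a <- a
    caches[[l]] <- cache
    in_cube <- a
  }
  feat <- matrix(in_cube, nrow = prod(dim(in_cube)[1:2]), ncol = B)
  feat <- t(feat)
  fc_acts <- list(feat)
  n_fc <- length(config$classifier) + 1L
  h <- feat
  for (l in seq_len(n_fc)) {
    z <- sweep(h %*% params[[paste0("Wf", l)]], 2,
               params[[paste0("bf", l)]], "+")
    h <- if (l < n_fc) pmax(z, 0) else z
    fc_acts[[l + 1L]] <- h
  }
  list(logits = h, caches = caches, fc_acts = fc_acts,
       feat_dim = dim(in_cube)[1:2])
}

alexnet_backward <- function(params, config, fwd, labels) {
  prob <- softmax_rows(fwd$logits)
  B <- nrow(prob)
  delta <- (prob - one_hot(labels, ncol(prob))) / B
  grads <- list()
  n_fc <- length(config$classifier) + 1L
  for (l in rev(seq_len(n_fc))) {
    a_prev <- fwd$fc_acts[[l]]
    grads[[paste0("Wf", l)]] <- crossprod(a_prev, delta)
    grads[[paste0("bf", l)]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params[[paste0("Wf", l)]])) * (a_prev > 0)
    }
  }
  dfeat <- delta %*% t(params[["Wf1"]])
  d_cube <- array(t(dfeat), dim = c(fwd$feat_dim, B))
  for (l in rev(seq_along(config$channels))) {
    cache <- fwd$caches[[l]]
    d_cube <- .relu_bwd_cpp(d_cube, cache$a)
    if (config$bn[l]) {
      bnb <- .bn1d_backward_cpp(d_cube, cache$z, cache$bn$mu,
                                cache$bn$istd,
                                params[[paste0("gamma", l)]])
      grads[[paste0("gamma", l)]] <- as.numeric(bnb$dgamma)
      grads[[paste0("beta", l)]] <- as.numeric(bnb$dbeta)
      d_cube <- bnb$dx
    }
    cb <- .conv1d_backward_cpp(cache$x, params[[paste0("Wc", l)]], d_cube,
                               config$kernels[l], config$strides[l])
    grads[[paste0("Wc", l)]] <- cb$dw
    grads[[paste0("bc", l)]] <- as.numeric(cb$db)
    d_cube <- cb$dx
  }
  grads
}

#' @rdname train_model
#' @export
train_model.alexnet1d_model <- function(model, x, y, x_val = NULL,
                                        y_val = NULL, seed = 1L,
                                        verbose = FALSE, ...) {
  cfg <- model$config
  check_training_inputs(x, y)
  classes <- levels(y)
  with_seed(seed, {
    params <- alexnet_init_params(cfg, ncol(x))
    opt <- adam_init(params)
    log <- new_training_log(cfg$epochs)
    bn_stats <- list()
    for (l in which(cfg$bn)) {
      bn_stats[[paste0("bn", l)]] <- list(mu = numeric(cfg$channels[l]),
                                          va = rep(1, cfg$channels[l]))
    }
    momentum <- 0.1
    best <- list(val = -Inf, params = NULL, bn_stats = NULL)
    for (ep in seq_len(cfg$epochs)) {
      losses <- c()
      for (idx in minibatches(nrow(x), cfg$batch_size)) {
        fwd <- alexnet_forward(params, cfg, x[idx, , drop = FALSE],
                               train = TRUE)
        for (l in which(cfg$bn)) {
          key <- paste0("bn", l)
          bn <- fwd$caches[[l]]$bn
          bn_stats[[key]]$mu <- (1 - momentum) * bn_stats[[key]]$mu +
            momentum * bn$mu
          bn_stats[[key]]$va <- (1 - momentum) * bn_stats[[key]]$va +
            momentum * bn$va
        }
        grads <- alexnet_backward(params, cfg, fwd, y[idx])
        step <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- step$params; opt <- step$state
        losses <- c(losses, cross_entropy(softmax_rows(fwd$logits), y[idx]))
      }
      log$loss[ep] <- mean(losses)
      if (!is.null(x_val)) {
        pv <- alexnet_predict_prob(params, cfg, bn_stats, x_val)
        log$val_accuracy[ep] <- mean(argmax_labels(pv, classes) == y_val)
        # keep the best-validation epoch (latest on ties)
        if (log$val_accuracy[ep] >= best$val) {
          best <- list(val = log$val_accuracy[ep], params = params,
                       bn_stats = bn_stats)
        }
      }
      if (verbose) {
        message(sprintf("epoch %d loss %.4f val %.3f", ep, log$loss[ep],
                        log$val_accuracy[ep]))
      }
    }
    if (!is.null(best$params)) {
      params <- best$params
      bn_stats <- best$bn_stats
    }
    model$params <- params
    model$bn_stats <- bn_stats
    model$classes <- classes
    model$log <- log
    model$seed <- seed
    model
  })
}

alexnet_predict_prob <- function(params, config, bn_stats, x,
                                 chunk = 64L) {
  x <- as.matrix(x)
  out <- matrix(NA_real_, nrow(x), config$n_class)
  for (start in seq(1L, nrow(x), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(x))
    fwd <- alexnet_forward(params, config, x[idx, , drop = FALSE],
                           train = FALSE, bn_stats = bn_stats)
    out[idx, ] <- softmax_rows(fwd$logits)
  }
  out
}

#' @export
predict.alexnet1d_model <- function(object, x, type = c("class", "prob"),
                                    ...) {
  type <- match.arg(type)
  if (is.null(object$params)) stop("model is not trained", call. = FALSE)
  prob <- alexnet_predict_prob(object$params, object$config,
                               object$bn_stats, x)
  if (type == "prob") prob else argmax_labels(prob, object$classes)
}
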