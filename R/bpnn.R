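#' Configuration of the back-propagation neural network
#'
#' Three hidden layers of 512, 128 and 16 tanh units feeding a 4-way
#' softmax, trained with Adam at learning rate 0.001, batch size 16, 80
#' epochs, with an L2 weight penalty.
#'
#' @param hidden Hidden layer widths.
#' @param l2 L2 penalty weight on the connection weights.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param n_class Number of output classes.
#' @return An object of class `bpnn_config`.
#' @export
bpnn_config <- function(hidden = c(512, 128, 16), l2 = 1e-4, lr = 1e-3,
                        batch_size = 16, epochs = 80, n_class = 4) {
  if (any(hidden <= 0) || any(hidden != round(hidden))) {
    stop("hidden widths must be positive integers", call. = FALSE)
  }
  if (lr <= 0) stop("`lr` must be > 0", call. = FALSE)
  if (l2 < 0) stop("`l2` must be >= 0", call. = FALSE)
  structure(list(hidden = as.integer(hidden), l2 = l2, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 n_class = as.integer(n_class)),
            class = "bpnn_config")
}

#' Build a BPNN classifier
#'
#' @param config A [bpnn_config()].
#' @return An untrained model of class `bpnn_model`; fit it with
#'   [train_model()].
#' @export
build_bpnn <- function(config = bpnn_config()) {
  stopifnot(inherits(config, "bpnn_config"))
  structure(list(config = config, params = NULL, classes = NULL,
                 log = NULL, seed = NULL),
            class = "bpnn_model")
}

bpnn_init_params <- function(config, input_dim) {
  widths <- c(input_dim, config$hidden, config$n_class)
  params <- list()
  for (l in seq_len(length(widths) - 1L)) {
    params[[paste0("W", l)]] <- glorot_init(widths[l], widths[l + 1])
    params[[paste0("b", l)]] <- numeric(widths[l + 1])
  }
  params
}

bpnn_forward <- function(params, x) {
  n_layer <- length(params) / 2L
  acts <- vector("list", n_layer + 1L)
  acts[[1L]] <- x
  for (l in seq_len(n_layer)) {
    z <- acts[[l]] %*% params[[paste0("W", l)]]
    z <- sweep(z, 2, params[[paste0("b", l)]], "+")
    acts[[l + 1L]] <- if (l < n_layer) tanh(z) else z
  }
  list(logits = acts[[n_layer + 1L]], acts = acts)
}

bpnn_backward <- function(params, fwd, labels, l2) {
  n_layer <- length(params) / 2L
  prob <- softmax_rows(fwd$logits)
  n <- nrow(prob)
  delta <- (prob - one_hot(labels, ncol(prob))) / n
  grads <- list()
  for (l in rev(seq_len(n_layer))) {
    W <- params[[paste0("W", l)]]
    a_prev <- fwd$acts[[l]]
    grads[[paste0("W", l)]] <- crossprod(a_prev, delta) + 2 * l2 * W
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(W)) * (1 - fwd$acts[[l]]^2)
    }
  }
  grads
}

bpnn_loss <- function(params, x, labels, l2) {
  fwd <- bpnn_forward(params, x)
  ce <- cross_entropy(softmax_rows(fwd$logits), labels)
  w_sq <- sum(vapply(grep("^W", names(params), value = TRUE),
                     function(nm) sum(params[[nm]]^2), numeric(1)))
  ce + l2 * w_sq
}

#' @rdname train_model
#' @export
train_model.bpnn_model <- function(model, x, y, x_val = NULL, y_val = NULL,
                                   seed = 1L, verbose = FALSE, ...) {
  cfg <- model$config
  check_training_inputs(x, y)
  classes <- levels(y)
  with_seed(seed, {
    params <- bpnn_init_params(cfg, ncol(x))
    opt <- adam_init(params)
    log <- new_training_log(cfg$epochs)
    best <- list(val = -Inf, params = NULL)
    for (ep in seq_len(cfg$epochs)) {
      losses <- c()
      for (idx in minibatches(nrow(x), cfg$batch_size)) {
        fwd <- bpnn_forward(params, x[idx, , drop = FALSE])
        grads <- bpnn_backward(params, fwd, y[idx], cfg$l2)
        step <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- step$params; opt <- step$state
        losses <- c(losses, cross_entropy(softmax_rows(fwd$logits), y[idx]))
      }
      log$loss[ep] <- mean(losses)
      if (!is.null(x_val)) {
        pv <- softmax_rows(bpnn_forward(params, x_val)$logits)
        log$val_accuracy[ep] <-
          mean(argmax_labels(pv, classes) == y_val)
        # keep the best-validation epoch (latest on ties)
        if (log$val_accuracy[ep] >= best$val) {
          best <- list(val = log$val_accuracy[ep], params = params)
        }
      }
      if (verbose) {
        message(sprintf("epoch %d loss %.4f val %.3f", ep, log$loss[ep],
                        log$val_accuracy[ep]))
      }
    }
    if (!is.null(best$params)) params <- best$params
    model$params <- params
    model$classes <- classes
    model$log <- log
    model$seed <- seed
    model
  })
}

#' @export
predict.bpnn_model <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(object$params)) stop("model is not trained", call. = FALSE)
  prob <- softmax_rows(bpnn_forward(object$params, as.matrix(x))$logits)
  if (type == "prob") prob else argmax_labels(prob, object$classes)
}
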