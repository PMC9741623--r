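# Minimal neural-network primitives shared by the three classifiers:
# Glorot initialization, softmax cross-entropy, and an Adam optimizer
# over a flat named list of parameter arrays.

glorot_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

one_hot <- function(labels, n_class) {
  y <- matrix(0, length(labels), n_class)
  y[cbind(seq_along(labels), as.integer(labels))] <- 1
  y
}

# Mean cross-entropy of softmax probabilities against integer labels.
cross_entropy <- function(prob, labels) {
  eps <- 1e-12
  -mean(log(pmax(prob[cbind(seq_along(labels), as.integer(labels))], eps)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    up <- .adam_update_cpp(as.numeric(params[[nm]]),
                           as.numeric(state$m[[nm]]),
                           as.numeric(state$v[[nm]]),
                           as.numeric(grads[[nm]]),
                           state$t, lr, beta1, beta2, eps)
    p <- as.numeric(up$p)
    attributes(p) <- attributes(params[[nm]])
    params[[nm]] <- p
    state$m[[nm]] <- as.numeric(up$m)
    state$v[[nm]] <- as.numeric(up$v)
  }
  list(params = params, state = state)
}

# Shuffled minibatch index list for one epoch.
minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# Accuracy of argmax predictions (ties toward the lowest class index).
argmax_labels <- function(prob, classes) {
  factor(classes[max.col(prob, ties.method = "first")], levels = classes)
}

new_training_log <- function(epochs) {
  data.frame(epoch = seq_len(epochs), loss = NA_real_,
             val_accuracy = NA_real_)
}

#' Write a training log to CSV
#'
#' @param log Data frame with columns `epoch`, `loss`, `val_accuracy`
#'   (the `$log` element of a trained model).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
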