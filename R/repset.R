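#' Configuration of the improved RepSet classifier
#'
#' A permutation-invariant network: the spectrum is cut into
#' fixed-length windows ([spectrum_to_set()]), each window set is matched
#' against `m` trainable hidden sets of cardinality `c` by exact
#' maximum-weight bipartite matching under the ReLU inner-product score,
#' and the `m` matching values feed two fully connected layers (32 units,
#' then the class outputs). Hidden sets are initialized from a standard
#' normal draw and trained with Adam; defaults follow the study design
#' (learning rate 0.001, batch size 20, 30 epochs), with `m = 1000`,
#' `c = 20` as the reference configuration.
#'
#' @param m Number of hidden sets.
#' @param c Cardinality of each hidden set.
#' @param window Window length `d` used to cut spectra into sets.
#' @param fc Width of the intermediate fully connected layer.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param n_class Number of output classes.
#' @return An object of class `repset_config`.
#' @export
repset_config <- function(m = 1000, c = 20, window = 64, fc = 32,
                          lr = 1e-3, batch_size = 20, epochs = 30,
                          n_class = 4) {
  if (m < 1 || c < 1 || window < 1 || fc < 1) {
    stop("m, c, window and fc must be positive integers", call. = FALSE)
  }
  if (lr <= 0) stop("`lr` must be > 0", call. = FALSE)
  structure(list(m = as.integer(m), c = as.integer(c),
                 window = as.integer(window), fc = as.integer(fc),
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 n_class = as.integer(n_class)),
            class = "repset_config")
}

#' Build the improved RepSet classifier
#'
#' @param config A [repset_config()].
#' @return An untrained model of class `repset_model`.
#' @export
build_repset <- function(config = repset_config()) {
  stopifnot(inherits(config, "repset_config"))
  structure(list(config = config, params = NULL, bn_stats = NULL,
                 classes = NULL, log = NULL, seed = NULL),
            class = "repset_model")
}

repset_init_params <- function(config) {
  d <- config$window
  H <- matrix(rnorm(config$m * config$c * d), config$m * config$c, d)
  attr(H, "m") <- config$m
  attr(H, "c") <- config$c
  list(H = H,
       gamma = rep(1, config$m), beta = numeric(config$m),
       W1 = glorot_init(config$m, config$fc), b1 = numeric(config$fc),
       W2 = glorot_init(config$fc, config$n_class),
       b2 = numeric(config$n_class))
}

# Batch normalization of the matching features (one statistic per hidden
# set). The raw matching values carry a large common-mode component --
# every feature grows with the overall absorbance of the sample -- which
# conditions the head badly; standardizing them per feature makes the 30
# configured epochs sufficient. Training uses minibatch statistics;
# prediction uses running averages.
repset_bn_forward <- function(params, feats, eps = 1e-5) {
  mu <- colMeans(feats)
  va <- colMeans(sweep(feats, 2, mu)^2)
  istd <- 1 / sqrt(va + eps)
  fhat <- sweep(sweep(feats, 2, mu), 2, istd, "*")
  out <- sweep(sweep(fhat, 2, params$gamma, "*"), 2, params$beta, "+")
  list(out = out, fhat = fhat, mu = mu, va = va, istd = istd)
}

repset_bn_eval <- function(params, feats, stats, eps = 1e-5) {
  fhat <- sweep(sweep(feats, 2, stats$mu), 2,
                1 / sqrt(stats$va + eps), "*")
  sweep(sweep(fhat, 2, params$gamma, "*"), 2, params$beta, "+")
}

repset_bn_backward <- function(dout, bn, gamma) {
  B <- nrow(dout)
  dgamma <- colSums(dout * bn$fhat)
  dbeta <- colSums(dout)
  dfhat <- sweep(dout, 2, gamma, "*")
  dfeat <- sweep(
    dfhat - sweep(bn$fhat, 2, colMeans(dfhat * bn$fhat), "*") -
      matrix(colMeans(dfhat), B, ncol(dout), byrow = TRUE),
    2, bn$istd, "*")
  list(dfeat = dfeat, dgamma = dgamma, dbeta = dbeta)
}

# Stack the window sets of a spectra matrix into one tall matrix
# (n_samples * nw rows); sample b occupies rows (b-1)*nw + 1 .. b*nw.
repset_stack_sets <- function(x, window) {
  sets <- lapply(seq_len(nrow(x)),
                 function(i) spectrum_to_set(x[i, ], window))
  list(X = do.call(rbind, sets), nw = nrow(sets[[1]]))
}

# Matching features for a stacked batch. Returns feats (B x m) plus,
# when requested, the assignment arrays (B x m x nmatch) and the score
# matrix needed by the backward pass.
repset_batch_pass <- function(params, Xb, nw, keep_assignment = FALSE) {
  m <- attr(params$H, "m"); cc <- attr(params$H, "c")
  S <- pmax(Xb %*% t(params$H), 0)
  res <- .match_minibatch_cpp(S, nw, m, cc)
  list(feats = res$values,
       rows = if (keep_assignment) res$rows,
       cols = if (keep_assignment) res$cols,
       S = if (keep_assignment) S)
}

repset_head_forward <- function(params, feats) {
  z1 <- sweep(feats %*% params$W1, 2, params$b1, "+")
  h <- pmax(z1, 0)
  logits <- sweep(h %*% params$W2, 2, params$b2, "+")
  list(h = h, logits = logits)
}

#' Forward pass of the RepSet model for one input set
#'
#' Matching features, feature standardization, two fully connected
#' layers, softmax. The output is invariant under any permutation of the
#' input set's vectors.
#'
#' @param X Input set: numeric matrix, one window vector per row.
#' @param params Model parameter list (`H`, `gamma`, `beta`, `W1`, `b1`,
#'   `W2`, `b2`), e.g. the `params` element of a trained `repset_model`.
#' @param bn_stats Feature normalization statistics (list `mu`, `va`);
#'   the `bn_stats` element of a trained model. Defaults to the identity
#'   transform (zero mean, unit variance).
#' @return Class probability vector (sums to 1).
#' @export
repset_forward <- function(X, params, bn_stats = NULL) {
  f <- repset_features(as.matrix(X), params$H)
  if (is.null(bn_stats)) {
    bn_stats <- list(mu = numeric(length(f)),
                     va = rep(1 - 1e-5, length(f)))
  }
  fbn <- repset_bn_eval(params, matrix(f, 1), bn_stats)
  head <- repset_head_forward(params, fbn)
  as.numeric(softmax_rows(head$logits))
}

# Flattened (sample, hidden-set, slot) index triples of a stacked
# assignment array, with the zero padding and inactive (zero-score)
# entries removed. Returns global input row, hidden row, and the
# (sample, set) index of each retained match.
repset_match_triples <- function(pass, nw, m, cc) {
  B <- nrow(pass$feats)
  nmatch <- dim(pass$rows)[3]
  rows_v <- as.vector(pass$rows)
  cols_v <- as.vector(pass$cols)
  b_v <- rep.int(seq_len(B), m * nmatch)
  k_v <- rep.int(rep(seq_len(m), each = B), nmatch)
  ok <- rows_v > 0L
  rows_v <- rows_v[ok]; cols_v <- cols_v[ok]
  b_v <- b_v[ok]; k_v <- k_v[ok]
  xrow <- (b_v - 1L) * nw + rows_v
  hrow <- (k_v - 1L) * cc + cols_v
  act <- pass$S[cbind(xrow, hrow)] > 0
  list(xrow = xrow[act], hrow = hrow[act], b = b_v[act], k = k_v[act])
}

# Cross-entropy of the minibatch with the matching assignment and ReLU
# activity pattern frozen to `pass` -- the objective whose exact
# gradient repset_backward computes (normalization statistics stay
# live). Used for gradient verification.
repset_frozen_loss <- function(params, Xb, nw, labels, pass) {
  m <- attr(params$H, "m"); cc <- attr(params$H, "c")
  B <- nrow(pass$feats)
  tri <- repset_match_triples(pass, nw, m, cc)
  raw <- Xb %*% t(params$H)
  feats <- matrix(0, B, m)
  if (length(tri$xrow)) {
    vals <- raw[cbind(tri$xrow, tri$hrow)]
    acc <- rowsum(vals, tri$b + (tri$k - 1L) * B)
    feats[as.integer(rownames(acc))] <- acc
  }
  bn <- repset_bn_forward(params, feats)
  head <- repset_head_forward(params, bn$out)
  cross_entropy(softmax_rows(head$logits), labels)
}

repset_backward <- function(params, Xb, nw, labels, pass, bn, head) {
  m <- attr(params$H, "m"); cc <- attr(params$H, "c")
  prob <- softmax_rows(head$logits)
  n <- nrow(prob)
  delta <- (prob - one_hot(labels, ncol(prob))) / n
  grads <- list(H = NULL, gamma = NULL, beta = NULL, W1 = NULL,
                b1 = NULL, W2 = crossprod(head$h, delta),
                b2 = colSums(delta))
  dh <- (delta %*% t(params$W2)) * (head$h > 0)
  grads$W1 <- crossprod(bn$out, dh)
  grads$b1 <- colSums(dh)
  dbn <- dh %*% t(params$W1)  # n x m
  bnb <- repset_bn_backward(dbn, bn, params$gamma)
  grads$gamma <- bnb$dgamma
  grads$beta <- bnb$dbeta
  dfeat <- bnb$dfeat
  dH <- params$H * 0
  tri <- repset_match_triples(pass, nw, m, cc)
  if (length(tri$xrow)) {
    g <- dfeat[cbind(tri$b, tri$k)]
    contrib <- rowsum(Xb[tri$xrow, , drop = FALSE] * g, tri$hrow)
    tgt <- as.integer(rownames(contrib))
    dH[tgt, ] <- dH[tgt, , drop = FALSE] + contrib
  }
  attr(dH, "m") <- m; attr(dH, "c") <- cc
  grads$H <- dH
  grads
}

repset_predict_prob <- function(params, stack, bn_stats, chunk = 32L) {
  n <- nrow(stack$X) / stack$nw
  feats <- matrix(0, n, attr(params$H, "m"))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    rows <- rep((idx - 1L) * stack$nw, each = stack$nw) +
      rep(seq_len(stack$nw), length(idx))
    feats[idx, ] <- repset_batch_pass(params,
                                     stack$X[rows, , drop = FALSE],
                                     stack$nw)$feats
  }
  fbn <- repset_bn_eval(params, feats, bn_stats)
  softmax_rows(repset_head_forward(params, fbn)$logits)
}

#' @rdname train_model
#' @export
train_model.repset_model <- function(model, x, y, x_val = NULL,
                                     y_val = NULL, seed = 1L,
                                     verbose = FALSE, ...) {
  cfg <- model$config
  check_training_inputs(x, y)
  classes <- levels(y)
  stack <- repset_stack_sets(x, cfg$window)
  nw <- stack$nw
  val_stack <- if (!is.null(x_val)) {
    repset_stack_sets(as.matrix(x_val), cfg$window)
  }
  with_seed(seed, {
    params <- repset_init_params(cfg)
    opt <- adam_init(params)
    log <- new_training_log(cfg$epochs)
    bn_stats <- list(mu = numeric(cfg$m), va = rep(1, cfg$m))
    momentum <- 0.1
    best <- list(val = -Inf, params = NULL, bn_stats = NULL)
    for (ep in seq_len(cfg$epochs)) {
      losses <- c()
      for (idx in minibatches(nrow(x), cfg$batch_size)) {
        rows <- rep((idx - 1L) * nw, each = nw) +
          rep(seq_len(nw), length(idx))
        Xb <- stack$X[rows, , drop = FALSE]
        pass <- repset_batch_pass(params, Xb, nw, keep_assignment = TRUE)
        bn <- repset_bn_forward(params, pass$feats)
        bn_stats$mu <- (1 - momentum) * bn_stats$mu + momentum * bn$mu
        bn_stats$va <- (1 - momentum) * bn_stats$va + momentum * bn$va
        head <- repset_head_forward(params, bn$out)
        grads <- repset_backward(params, Xb, nw, y[idx], pass, bn, head)
        step <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- step$params
        attr(params$H, "m") <- cfg$m; attr(params$H, "c") <- cfg$c
        opt <- step$state
        losses <- c(losses, cross_entropy(softmax_rows(head$logits),
                                          y[idx]))
      }
      log$loss[ep] <- mean(losses)
      if (!is.null(x_val)) {
        pv <- repset_predict_prob(params, val_stack, bn_stats)
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

#' @export
predict.repset_model <- function(object, x, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  if (is.null(object$params)) stop("model is not trained", call. = FALSE)
  stack <- repset_stack_sets(as.matrix(x), object$config$window)
  prob <- repset_predict_prob(object$params, stack, object$bn_stats)
  if (type == "prob") prob else argmax_labels(prob, object$classes)
}

#' Hidden-set hyperparameter sweep
#'
#' Trains one RepSet model per `(m, c)` combination with a shared split
#' and a deterministic per-cell seed derived from `seed`, and returns the
#' grid of test accuracies together with the best cell.
#'
#' @param m_values Numbers of hidden sets to try (non-empty).
#' @param c_values Hidden-set cardinalities to try (non-empty).
#' @param dataset A processed [nir_spectra] object.
#' @param split A `split_indices` object.
#' @param seed Integer base seed.
#' @param config Template [repset_config()] supplying the remaining
#'   hyperparameters.
#' @param verbose Print per-cell progress.
#' @return List with `accuracy` (matrix, rows = `m_values`, cols =
#'   `c_values`), `best` (named vector `m`, `c`, `accuracy`).
#' @export
sweep_hidden_sets <- function(m_values, c_values, dataset, split,
                              seed = 1L, config = repset_config(),
                              verbose = FALSE) {
  if (!length(m_values) || !length(c_values)) {
    stop("`m_values` and `c_values` must be non-empty", call. = FALSE)
  }
  x <- dataset$absorbance
  y <- dataset$label
  acc <- matrix(NA_real_, length(m_values), length(c_values),
                dimnames = list(m = m_values, c = c_values))
  for (i in seq_along(m_values)) {
    for (j in seq_along(c_values)) {
      cfg <- config
      cfg$m <- as.integer(m_values[i])
      cfg$c <- as.integer(c_values[j])
      fitted <- train_model(
        build_repset(cfg),
        x[split$train, , drop = FALSE], y[split$train],
        x[split$validation, , drop = FALSE], y[split$validation],
        seed = stage_seed(seed, sprintf("sweep_%d_%d", cfg$m, cfg$c)))
      pred <- predict(fitted, x[split$test, , drop = FALSE])
      acc[i, j] <- mean(pred == y[split$test])
      if (verbose) {
        message(sprintf("m=%d c=%d accuracy %.3f", cfg$m, cfg$c,
                        acc[i, j]))
      }
    }
  }
  best_idx <- which(acc == max(acc), arr.ind = TRUE)[1, ]
  list(accuracy = acc,
       best = c(m = m_values[best_idx[1]], c = c_values[best_idx[2]],
                accuracy = max(acc)))
}
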