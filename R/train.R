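#' Train a classifier on spectra
#'
#' Fits a built model (from [build_bpnn()], [build_alexnet1d()] or
#' [build_repset()]) by minimizing softmax cross-entropy (plus the L2
#' penalty for the BPNN) with Adam at the configured learning rate for
#' the configured number of epochs. All randomness (weight
#' initialization, hidden-set draws, minibatch shuffling) is governed by
#' `seed`, so a fixed seed reproduces the training log bitwise.
#'
#' For the RepSet model the backward pass holds the forward matching
#' assignment fixed and propagates gradients only through the matched
#' ReLU scores (subgradient zero at negative pre-activations).
#'
#' @param model A built (untrained) model object.
#' @param x Numeric matrix of training spectra, one per row.
#' @param y Factor of training labels.
#' @param x_val,y_val Optional validation spectra/labels used for the
#'   per-epoch validation accuracy in the training log.
#' @param seed Integer seed.
#' @param verbose Print per-epoch progress.
#' @param ... Unused.
#' @return The fitted model, with elements `params`, `classes`, `log`
#'   (data frame `epoch`, `loss`, `val_accuracy`) and `seed`.
#' @export
train_model <- function(model, x, y, x_val = NULL, y_val = NULL,
                        seed = 1L, verbose = FALSE, ...) {
  UseMethod("train_model")
}

check_training_inputs <- function(x, y) {
  if (!is.matrix(x) || nrow(x) == 0L) {
    stop("training set must be a non-empty matrix", call. = FALSE)
  }
  if (!is.factor(y)) stop("`y` must be a factor", call. = FALSE)
  if (length(y) != nrow(x)) stop("label/row count mismatch", call. = FALSE)
  if (anyNA(y)) stop("label outside the class vocabulary", call. = FALSE)
  invisible(TRUE)
}

#' Count trainable parameters of a model
#'
#' For a trained model, counts the fitted arrays; for an untrained one,
#' derives the count from the architecture and `input_dim`.
#'
#' @param model A model object.
#' @param input_dim Input dimension (needed before training).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, input_dim = NULL) {
  params <- model$params
  if (is.null(params)) {
    if (is.null(input_dim)) {
      stop("`input_dim` is required for an untrained model", call. = FALSE)
    }
    params <- switch(
      class(model)[1],
      bpnn_model = with_seed(0, bpnn_init_params(model$config, input_dim)),
      alexnet1d_model = with_seed(0, alexnet_init_params(model$config,
                                                         input_dim)),
      repset_model = with_seed(0, repset_init_params(model$config)),
      stop("unknown model class", call. = FALSE)
    )
  }
  sum(vapply(params, length, integer(1)))
}

#' Train one or more models on a preprocessed dataset and report metrics
#'
#' Convenience wrapper used by the command-line interface: trains each
#' requested model on the train partition (validation accuracy tracked on
#' the validation partition) and evaluates on the test partition.
#'
#' @param dataset A processed [nir_spectra] object.
#' @param split A `split_indices` object from [split_dataset()].
#' @param models Character vector from `c("bpnn", "alexnet1d", "repset")`.
#' @param seed Integer run seed; per-model seeds are derived from it.
#' @param configs Optional named list of model configs overriding the
#'   defaults.
#' @param verbose Print progress.
#' @return Named list per model: `model` (fitted), `predictions`,
#'   `confusion` and `metrics` on the test partition.
#' @export
run_models <- function(dataset, split, models = c("bpnn", "alexnet1d",
                                                  "repset"),
                       seed = 1L, configs = list(), verbose = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  x <- dataset$absorbance
  y <- dataset$label
  out <- list()
  for (nm in models) {
    model <- switch(nm,
      bpnn = build_bpnn(configs[["bpnn"]] %||% bpnn_config()),
      alexnet1d = build_alexnet1d(configs[["alexnet1d"]] %||%
                                    alexnet1d_config()),
      repset = build_repset(configs[["repset"]] %||% repset_config())
    )
    fitted <- train_model(model,
                          x[split$train, , drop = FALSE], y[split$train],
                          x[split$validation, , drop = FALSE],
                          y[split$validation],
                          seed = stage_seed(seed, nm), verbose = verbose)
    pred <- predict(fitted, x[split$test, , drop = FALSE])
    cm <- confusion_matrix(y[split$test], pred, levels(y))
    out[[nm]] <- list(model = fitted, predictions = pred,
                      confusion = cm, metrics = report(cm))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
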