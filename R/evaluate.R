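#' Multiclass confusion matrix
#'
#' Counts of actual (rows) versus predicted (columns) labels over a fixed
#' class vocabulary. The one-vs-rest quantities follow the usual
#' decomposition: `TP_i` is diagonal entry `i`, `FP_i` the rest of column
#' `i`, `FN_i` the rest of row `i`, `TN_i` everything else.
#'
#' @param true_labels,predicted_labels Equal-length label vectors, all
#'   values in `vocabulary`.
#' @param vocabulary Class vocabulary; defaults to the four Maojian
#'   origins.
#' @return An object of class `confusion_matrix`: an integer K x K
#'   matrix with `vocabulary` as dimnames.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             vocabulary = maojian_classes()) {
  if (!length(true_labels)) stop("empty label vectors", call. = FALSE)
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  tl <- as.character(true_labels)
  pl <- as.character(predicted_labels)
  unknown <- setdiff(unique(c(tl, pl)), vocabulary)
  if (length(unknown)) {
    stop("label(s) outside the vocabulary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- table(actual = factor(tl, vocabulary),
                  predicted = factor(pl, vocabulary))
  structure(unclass(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>\n")
  print(unclass(x))
  invisible(x)
}

check_cm <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    stop("expected a `confusion_matrix`", call. = FALSE)
  }
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  invisible(cm)
}

#' Per-class precision
#'
#' `TP_i / (TP_i + FP_i)` for every class, i.e. the diagonal over the
#' column sum. A class that was never predicted (zero denominator) gets
#' precision 0 with a warning, never `NaN`, so batch sweeps do not abort.
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector of per-class precisions in `[0, 1]`.
#' @export
precision_per_class <- function(cm) {
  check_cm(cm)
  tp <- diag(cm)
  predicted <- colSums(cm)
  p <- ifelse(predicted > 0, tp / predicted, 0)
  if (any(predicted == 0)) {
    warning("class(es) never predicted; precision set to 0: ",
            paste(colnames(cm)[predicted == 0], collapse = ", "))
  }
  names(p) <- colnames(cm)
  p
}

#' Macro-average precision
#'
#' Unweighted arithmetic mean of the per-class precisions over the K
#' classes (the study design fixes K = 4; any K is accepted).
#'
#' @param precisions Non-empty numeric vector of per-class precisions.
#' @return Single proportion in `[0, 1]`.
#' @export
#' @examples
#' macro_avg(c(1, 1, 0.99, 1))  # 0.9975
macro_avg <- function(precisions) {
  if (!length(precisions)) stop("empty precision vector", call. = FALSE)
  mean(precisions)
}

#' Overall classification accuracy
#'
#' Multiclass overall accuracy, the trace of the confusion matrix over
#' the total count. For K = 2 this equals the binary
#' `(TP + TN) / (TP + FP + FN + TN)` form evaluated on the pooled
#' one-vs-rest decomposition; trace/total is its K-class generalization.
#'
#' @param cm A [confusion_matrix()].
#' @return Single proportion in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' Assemble the metrics report
#'
#' Per-class precision, macro average and overall accuracy in one
#' object, printed as percentages to two decimals.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `metrics_report`: list with
#'   `precision_by_class`, `macro_avg`, `accuracy` (full-precision
#'   proportions).
#' @export
report <- function(cm) {
  check_cm(cm)
  p <- precision_per_class(cm)
  structure(list(precision_by_class = p, macro_avg = macro_avg(p),
                 accuracy = accuracy(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (cl in names(x$precision_by_class)) {
    cat(sprintf("  precision %-10s %6.2f%%\n", cl,
                100 * x$precision_by_class[[cl]]))
  }
  cat(sprintf("  macro avg  %16.2f%%\n", 100 * x$macro_avg))
  cat(sprintf("  accuracy   %16.2f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Write / read a metrics report table
#'
#' Serializes one row per model in the layout of a results table:
#' per-class precision columns, macro average and accuracy (proportions,
#' full precision). `read_report_csv` restores the named list of
#' `metrics_report` objects.
#'
#' @param reports Named list of `metrics_report` objects (one per model).
#' @param path CSV path.
#' @return `path` invisibly / named list of `metrics_report`.
#' @export
write_report_csv <- function(reports, path) {
  stopifnot(length(reports) > 0)
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, t(r$precision_by_class),
               macro_avg = r$macro_avg, accuracy = r$accuracy,
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cls <- setdiff(names(df), c("model", "macro_avg", "accuracy"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    p <- as.numeric(df[i, cls])
    names(p) <- cls
    structure(list(precision_by_class = p, macro_avg = df$macro_avg[i],
                   accuracy = df$accuracy[i]), class = "metrics_report")
  })
  names(out) <- df$model
  out
}
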