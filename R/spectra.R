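#' Construct a labeled NIR spectra collection
#'
#' The central container of the pipeline: a matrix of absorbance traces on
#' one shared wavenumber grid, with per-row sample identity, origin label
#' and (optionally, before replicate averaging) a replicate index.
#'
#' @param absorbance Numeric matrix, one row per scan/spectrum, one column
#'   per grid point.
#' @param wavenumber Numeric vector of strictly increasing wavenumbers
#'   (cm^-1), one per column of `absorbance`.
#' @param sample_id Character vector of sample identifiers, one per row.
#' @param label Character or factor vector of origin labels, one per row;
#'   must be a subset of `classes`.
#' @param replicate Optional integer vector of replicate scan indices
#'   (`NULL` once replicates have been averaged).
#' @param classes Class vocabulary; defaults to the four Maojian origins.
#'
#' @return An object of class `nir_spectra`: a list with elements
#'   `absorbance`, `wavenumber`, `sample_id`, `label` (factor on the full
#'   vocabulary) and `replicate`.
#' @export
nir_spectra <- function(absorbance, wavenumber, sample_id, label,
                        replicate = NULL, classes = maojian_classes()) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  n <- nrow(absorbance)
  if (length(wavenumber) != ncol(absorbance)) {
    stop("`wavenumber` length must equal the number of absorbance columns",
         call. = FALSE)
  }
  validate_grid(wavenumber)
  if (length(sample_id) != n || length(label) != n) {
    stop("`sample_id` and `label` must have one entry per spectrum",
         call. = FALSE)
  }
  if (!all(is.finite(absorbance))) {
    stop("absorbance values must all be finite", call. = FALSE)
  }
  label <- as.character(label)
  unknown <- setdiff(unique(label), classes)
  if (length(unknown)) {
    stop("unknown class label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(replicate)) {
    replicate <- as.integer(replicate)
    if (length(replicate) != n || any(replicate < 1L)) {
      stop("`replicate` must be positive integers, one per scan",
           call. = FALSE)
    }
  }
  structure(
    list(
      absorbance = absorbance,
      wavenumber = as.numeric(wavenumber),
      sample_id = as.character(sample_id),
      label = factor(label, levels = classes),
      replicate = replicate
    ),
    class = "nir_spectra"
  )
}

#' @export
print.nir_spectra <- function(x, ...) {
  n <- nrow(x$absorbance)
  cat(sprintf(
    "<nir_spectra> %d %s, %d points (%.0f-%.0f cm^-1)\n",
    n, if (is.null(x$replicate)) "spectra" else "scans",
    length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)
  ))
  print(table(origin = x$label))
  invisible(x)
}

#' @export
dim.nir_spectra <- function(x) dim(x$absorbance)

#' Subset a spectra collection by row
#'
#' @param x An [nir_spectra] object.
#' @param i Row index vector (integer or logical).
#' @param ... Unused.
#' @return An [nir_spectra] with the selected scans.
#' @export
`[.nir_spectra` <- function(x, i, ...) {
  nir_spectra(
    x$absorbance[i, , drop = FALSE], x$wavenumber,
    x$sample_id[i], as.character(x$label[i]),
    replicate = if (is.null(x$replicate)) NULL else x$replicate[i],
    classes = levels(x$label)
  )
}

#' Plot class-mean spectra
#'
#' Draws the per-class mean absorbance trace, one line per origin.
#'
#' @param x An [nir_spectra] object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.nir_spectra <- function(x, ...) {
  means <- vapply(
    levels(x$label),
    function(cl) colMeans(x$absorbance[x$label == cl, , drop = FALSE]),
    numeric(length(x$wavenumber))
  )
  graphics::matplot(x$wavenumber, means, type = "l", lty = 1,
                    xlab = expression(Wavenumber ~ (cm^-1)),
                    ylab = "Absorbance", ...)
  graphics::legend("topright", legend = levels(x$label), lty = 1,
                   col = seq_len(nlevels(x$label)), bty = "n")
  invisible(x)
}
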