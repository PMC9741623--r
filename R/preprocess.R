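#' Average replicate scans into one spectrum per sample
#'
#' Each sample's replicate scans are collapsed to their pointwise
#' arithmetic mean, the trace used for all subsequent analysis.
#'
#' @param scans An [nir_spectra] object with replicate structure.
#' @return An [nir_spectra] object with one spectrum per `sample_id`
#'   (replicate slot dropped), in order of first appearance.
#' @export
average_replicates <- function(scans) {
  stopifnot(inherits(scans, "nir_spectra"))
  if (nrow(scans$absorbance) == 0L) stop("no scans to average", call. = FALSE)
  ids <- factor(scans$sample_id, levels = unique(scans$sample_id))
  lab_by_id <- tapply(as.character(scans$label), ids,
                      function(l) {
                        u <- unique(l)
                        if (length(u) != 1L) {
                          stop("sample with inconsistent class labels",
                               call. = FALSE)
                        }
                        u
                      })
  sums <- rowsum(scans$absorbance, ids)
  counts <- as.vector(table(ids))
  nir_spectra(sums / counts, scans$wavenumber,
              levels(ids), lab_by_id[levels(ids)],
              classes = levels(scans$label))
}

#' Rubber-band baseline correction
#'
#' Subtracts the lower convex hull envelope of the `(wavenumber,
#' absorbance)` points, linearly interpolated between hull vertices --
#' the standard rubber-band baseline. The corrected spectrum is
#' nonnegative everywhere, exactly zero at the hull vertices, invariant
#' to adding any affine ramp, and idempotent.
#'
#' `n_anchor` caps the number of interpolation anchors for compatibility
#' with acquisition-software conventions (the study design uses 64): when
#' the hull has more vertices than `n_anchor`, an evenly spaced vertex
#' subset (always keeping both endpoints) is used. For smooth spectra the
#' hull typically has far fewer vertices, and the parameter has no
#' effect.
#'
#' @param absorbance Numeric absorbance vector (finite, length >= 3).
#' @param wavenumber Matching wavenumber grid.
#' @param n_anchor Maximum number of baseline anchor points (>= 2).
#' @param details If `TRUE`, also return the baseline and hull vertex
#'   indices.
#' @return The corrected absorbance vector, or (with `details = TRUE`) a
#'   list with `corrected`, `baseline` and `vertices`.
#' @export
#' @examples
#' rubber_band_baseline(c(1, 3, 0.5, 2, 1), 0:4)  # 0 2.25 0 1.25 0
rubber_band_baseline <- function(absorbance, wavenumber = seq_along(absorbance),
                                 n_anchor = 64, details = FALSE) {
  y <- as.numeric(absorbance)
  x <- as.numeric(wavenumber)
  if (length(y) < 3L) stop("need at least 3 points", call. = FALSE)
  if (length(x) != length(y)) stop("grid/absorbance length mismatch",
                                   call. = FALSE)
  if (!all(is.finite(y)) || !all(is.finite(x))) {
    stop("non-finite values in spectrum", call. = FALSE)
  }
  if (n_anchor < 2) stop("`n_anchor` must be >= 2", call. = FALSE)
  validate_grid(x)
  verts <- lower_hull_indices(x, y)
  if (length(verts) > n_anchor) {
    # thinning keeps convexity (chords of a convex chain lie below it),
    # so nonnegativity of the residual is preserved
    verts <- verts[unique(round(seq(1, length(verts),
                                    length.out = n_anchor)))]
  }
  baseline <- stats::approx(x[verts], y[verts], xout = x)$y
  corrected <- pmax(y - baseline, 0)
  if (details) {
    list(corrected = corrected, baseline = baseline, vertices = verts)
  } else {
    corrected
  }
}

# Lower convex hull of points ordered by x (Andrew's monotone chain);
# returns vertex indices, always including both endpoints.
lower_hull_indices <- function(x, y) {
  n <- length(x)
  stack <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    while (top >= 2L) {
      a <- stack[top - 1L]; b <- stack[top]
      # drop b if it lies on or above segment a--i
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0) {
        top <- top - 1L
      } else break
    }
    top <- top + 1L
    stack[top] <- i
  }
  stack[seq_len(top)]
}

#' Min-max normalize a spectrum to the unit interval
#'
#' Per-spectrum linear rescaling `(x - min) / (max - min)` onto `[0, 1]`.
#' A constant spectrum (zero range) maps to all zeros with a warning
#' rather than erroring, so corrupted edge cases do not abort batch runs.
#'
#' @param absorbance Finite numeric vector.
#' @return Numeric vector spanning `[0, 1]` (or all zeros).
#' @export
min_max_normalize <- function(absorbance) {
  y <- as.numeric(absorbance)
  if (!all(is.finite(y))) stop("non-finite values in spectrum", call. = FALSE)
  rng <- range(y)
  if (rng[1] == rng[2]) {
    warning("constant spectrum; normalizing to all zeros")
    return(rep(0, length(y)))
  }
  (y - rng[1]) / (rng[2] - rng[1])
}

#' Stratified train / validation / test split
#'
#' Per class, `round_half_up(class_size * test_fraction)` samples go to
#' the test partition; then exactly `val_per_class` samples per class are
#' carved out of the remaining training portion as the validation set.
#' The remainder stays in train. Deterministic given `seed`.
#'
#' @param ds An [nir_spectra] object (one spectrum per sample).
#' @param test_fraction Test proportion in (0, 1); default 0.3 (the 7:3
#'   design).
#' @param val_per_class Validation samples drawn per class; default 10.
#' @param seed Integer seed.
#' @return An object of class `split_indices`: list of disjoint integer
#'   index vectors `train`, `validation`, `test` covering all samples.
#' @export
split_dataset <- function(ds, test_fraction = 0.3, val_per_class = 10,
                          seed = 1L) {
  stopifnot(inherits(ds, "nir_spectra"))
  if (!is.finite(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (val_per_class < 0) stop("`val_per_class` must be >= 0", call. = FALSE)
  lab <- ds$label
  with_seed(seed, {
    parts <- list(train = integer(0), validation = integer(0),
                  test = integer(0))
    for (cl in levels(lab)) {
      idx <- which(lab == cl)
      n <- length(idx)
      if (n == 0L) next
      n_test <- floor(n * test_fraction + 0.5)  # round half up
      if (n < n_test + val_per_class + 1) {
        stop("class `", cl, "` too small for the requested split",
             call. = FALSE)
      }
      test_i <- sample(idx, n_test)
      rest <- setdiff(idx, test_i)
      val_i <- if (val_per_class > 0) sample(rest, val_per_class) else
        integer(0)
      parts$test <- c(parts$test, test_i)
      parts$validation <- c(parts$validation, val_i)
      parts$train <- c(parts$train, setdiff(rest, val_i))
    }
    structure(lapply(parts, sort), class = "split_indices")
  })
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> train %d / validation %d / test %d\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Run the full measurement-to-model-input chain
#'
#' Composes the stages in acquisition order: replicate averaging,
#' rubber-band baseline correction, the stratified 7:3 split with its
#' per-class validation carve-out, then per-spectrum min-max
#' normalization. Normalization is per-spectrum, so its placement after
#' the split cannot leak test-set information into training.
#'
#' @param scans An [nir_spectra] object of raw replicate scans.
#' @param test_fraction,val_per_class,seed Passed to [split_dataset()].
#' @param n_anchor Passed to [rubber_band_baseline()].
#' @return A list with `dataset` (processed [nir_spectra]), `split`
#'   ([split_dataset()] result) and `manifest` (stages and parameters).
#' @export
preprocess <- function(scans, test_fraction = 0.3, val_per_class = 10,
                       seed = 1L, n_anchor = 64) {
  ds <- average_replicates(scans)
  corrected <- t(apply(ds$absorbance, 1, rubber_band_baseline,
                       wavenumber = ds$wavenumber, n_anchor = n_anchor))
  ds$absorbance <- corrected
  split <- split_dataset(ds, test_fraction, val_per_class, seed)
  ds$absorbance <- t(apply(ds$absorbance, 1, min_max_normalize))
  manifest <- list(
    stages = c("average_replicates", "rubber_band_baseline",
               "split_dataset", "min_max_normalize"),
    parameters = list(test_fraction = test_fraction,
                      val_per_class = val_per_class,
                      n_anchor = n_anchor, seed = seed),
    n_samples = nrow(ds$absorbance),
    n_points = length(ds$wavenumber)
  )
  list(dataset = ds, split = split, manifest = manifest)
}
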