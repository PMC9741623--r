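#' Configuration of the synthetic spectrum generator
#'
#' Collects every knob of the generator: the wavenumber grid, the
#' per-class peak profiles, baseline-drift scales, the measurement noise
#' level, biological within-class variability, the sampling design
#' (samples per class, replicate scans per sample) and the seed.
#'
#' The defaults reproduce the study design the pipeline targets: 100
#' samples per class, 3 replicate scans each, on a 1814-point grid over
#' 4000--11,000 cm^-1. Drift and noise defaults are small relative to the
#' peak amplitudes (about 0.5--1 absorbance units): measurement noise sd
#' 0.01, baseline offset/slope/curvature sds 0.05/0.05/0.02. Within-class
#' variability is modeled as per-sample multiplicative amplitude jitter
#' (sd 0.05 per peak) plus a common concentration scale jitter (sd 0.03);
#' replicates of one sample share amplitudes and differ only in drift and
#' noise, emulating repeated measurement of one physical sample.
#'
#' @param grid Wavenumber grid from [make_grid()].
#' @param peaks List of [peak_spec] profiles.
#' @param baseline List with elements `offset_sd`, `slope_sd`,
#'   `curvature_sd`: sds of the per-scan affine + quadratic drift
#'   coefficients (absorbance units over the full grid span).
#' @param noise_sd Sd of i.i.d. Gaussian measurement noise (absorbance
#'   units, >= 0).
#' @param amplitude_jitter_sd Per-sample, per-peak relative amplitude
#'   jitter sd.
#' @param scale_jitter_sd Per-sample common relative scale jitter sd.
#' @param n_per_class Samples per class (>= 1).
#' @param n_replicates Replicate scans per sample (>= 1).
#' @param seed Integer seed governing all generator randomness.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(grid = make_grid(),
                             peaks = default_class_profiles(),
                             baseline = list(offset_sd = 0.05,
                                             slope_sd = 0.05,
                                             curvature_sd = 0.02),
                             noise_sd = 0.01,
                             amplitude_jitter_sd = 0.05,
                             scale_jitter_sd = 0.03,
                             n_per_class = 100,
                             n_replicates = 3,
                             seed = 1L) {
  validate_grid(grid)
  if (!length(peaks) || !all(vapply(peaks, inherits, TRUE, "peak_spec"))) {
    stop("`peaks` must be a non-empty list of peak_spec objects",
         call. = FALSE)
  }
  centers <- vapply(peaks, `[[`, numeric(1), "center")
  if (any(centers < min(grid) | centers > max(grid))) {
    stop("every peak center must lie within the grid span", call. = FALSE)
  }
  for (nm in c("offset_sd", "slope_sd", "curvature_sd")) {
    if (is.null(baseline[[nm]]) || baseline[[nm]] < 0) {
      stop("`baseline$", nm, "` must be a nonnegative number", call. = FALSE)
    }
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  if (n_per_class < 1 || n_per_class != round(n_per_class)) {
    stop("`n_per_class` must be an integer >= 1", call. = FALSE)
  }
  if (n_replicates < 1 || n_replicates != round(n_replicates)) {
    stop("`n_replicates` must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(grid = as.numeric(grid), peaks = peaks, baseline = baseline,
         noise_sd = noise_sd, amplitude_jitter_sd = amplitude_jitter_sd,
         scale_jitter_sd = scale_jitter_sd,
         n_per_class = as.integer(n_per_class),
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Synthesize one scan of one sample
#'
#' The absorbance model is a sum of Gaussian bands plus a smooth per-scan
#' baseline drift (affine + quadratic with random coefficients) plus
#' i.i.d. Gaussian measurement noise. Randomness is drawn from the
#' caller's RNG stream; seed it (e.g. via [set.seed()]) for
#' reproducibility.
#'
#' @param peaks List of [peak_spec] profiles.
#' @param class Origin class label, used to look up peak amplitudes.
#' @param grid Wavenumber grid.
#' @param config A [generator_config()] providing drift and noise scales.
#' @param amplitudes Optional numeric vector overriding the per-peak
#'   amplitudes (already jittered for the sample); defaults to the
#'   profile amplitudes for `class`.
#'
#' @return Numeric absorbance vector of `length(grid)`.
#' @export
synthesize_scan <- function(peaks, class, grid, config,
                            amplitudes = NULL) {
  validate_grid(grid)
  centers <- vapply(peaks, `[[`, numeric(1), "center")
  if (any(centers < min(grid) | centers > max(grid))) {
    stop("every peak center must lie within the grid span", call. = FALSE)
  }
  if (config$noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(amplitudes)) {
    amplitudes <- vapply(peaks, function(p) {
      a <- p$amplitude_by_class[[class]]
      if (is.null(a)) stop("class `", class, "` missing from peak profile",
                           call. = FALSE)
      a
    }, numeric(1))
  }
  y <- numeric(length(grid))
  for (k in seq_along(peaks)) {
    if (amplitudes[k] > 0) {
      y <- y + amplitudes[k] *
        exp(-0.5 * ((grid - peaks[[k]]$center) / peaks[[k]]$width)^2)
    }
  }
  t01 <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
  bl <- config$baseline
  drift <- rnorm(1, 0, bl$offset_sd) +
    rnorm(1, 0, bl$slope_sd) * t01 +
    rnorm(1, 0, bl$curvature_sd) * (2 * t01 - 1)^2
  noise <- if (config$noise_sd > 0) {
    rnorm(length(grid), 0, config$noise_sd)
  } else 0
  y + drift + noise
}

#' Generate a full labeled synthetic dataset
#'
#' Draws `n_per_class` samples for each of the four origins and
#' `n_replicates` scans per sample. Replicates of one sample share the
#' same (jittered) peak amplitudes and differ only in their drift and
#' noise draws. The result is bitwise reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#'
#' @return An [nir_spectra] object with a `replicate` column:
#'   `4 * n_per_class * n_replicates` scans.
#' @export
#' @examples
#' cfg <- generator_config(n_per_class = 2, n_replicates = 2, seed = 7)
#' scans <- generate_dataset(cfg)
#' dim(scans)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  classes <- maojian_classes()
  n_scan <- length(classes) * config$n_per_class * config$n_replicates
  with_seed(config$seed, {
    absorb <- matrix(0, n_scan, length(config$grid))
    ids <- character(n_scan)
    labs <- character(n_scan)
    reps <- integer(n_scan)
    row <- 0L
    for (cl in classes) {
      base_amp <- vapply(config$peaks, function(p) p$amplitude_by_class[[cl]],
                         numeric(1))
      for (s in seq_len(config$n_per_class)) {
        scale <- 1 + rnorm(1, 0, config$scale_jitter_sd)
        jitter <- 1 + rnorm(length(base_amp), 0, config$amplitude_jitter_sd)
        amps <- pmax(base_amp * scale * jitter, 0)
        sid <- sprintf("%s_%03d", cl, s)
        for (r in seq_len(config$n_replicates)) {
          row <- row + 1L
          absorb[row, ] <- synthesize_scan(config$peaks, cl, config$grid,
                                           config, amplitudes = amps)
          ids[row] <- sid
          labs[row] <- cl
          reps[row] <- r
        }
      }
    }
    nir_spectra(absorb, config$grid, ids, labs, replicate = reps)
  })
}
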