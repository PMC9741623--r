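#' Build an equally spaced wavenumber grid
#'
#' The acquisition grid of the study design spans 4000--11,000 cm^-1 in
#' 1814 points; both limits are included.
#'
#' @param min_wn,max_wn Grid limits in cm^-1, `min_wn < max_wn`.
#' @param n_points Number of grid points (at least 2).
#'
#' @return Numeric vector of `n_points` strictly increasing wavenumbers
#'   from `min_wn` to `max_wn` inclusive.
#' @export
#' @examples
#' g <- make_grid()
#' length(g)  # 1814
make_grid <- function(min_wn = 4000, max_wn = 11000, n_points = 1814) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 2 ||
      n_points != round(n_points)) {
    stop("`n_points` must be an integer >= 2", call. = FALSE)
  }
  if (!is.finite(min_wn) || !is.finite(max_wn) || min_wn >= max_wn) {
    stop("need finite `min_wn` < `max_wn`", call. = FALSE)
  }
  seq(min_wn, max_wn, length.out = n_points)
}

validate_grid <- function(wavenumber) {
  if (length(wavenumber) < 2L || !all(is.finite(wavenumber))) {
    stop("wavenumber grid must hold at least 2 finite values", call. = FALSE)
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("wavenumber grid must be strictly increasing", call. = FALSE)
  }
  invisible(wavenumber)
}
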