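#' Write a spectra collection to wide CSV
#'
#' One row per scan, header `sample_id,class,replicate,<wn_1>,...,<wn_N>`
#' with the wavenumbers as column labels ('.' decimal separator, UTF-8).
#' Averaged datasets (no replicate structure) are written with
#' `replicate = 1`.
#'
#' @param x An [nir_spectra] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path) {
  stopifnot(inherits(x, "nir_spectra"))
  rep_col <- if (is.null(x$replicate)) rep(1L, nrow(x$absorbance)) else
    x$replicate
  dt <- data.table::data.table(
    sample_id = x$sample_id,
    class = as.character(x$label),
    replicate = rep_col
  )
  spec <- data.table::as.data.table(x$absorbance)
  data.table::setnames(spec, format_wn(x$wavenumber))
  data.table::fwrite(cbind(dt, spec), path)
  invisible(path)
}

format_wn <- function(wn) formatC(wn, digits = 10, format = "g")

#' Read a spectra collection from wide CSV
#'
#' Inverse of [write_dataset()]; `write` then `read` restores the dataset
#' to within 1e-9 relative tolerance. Grids stored in descending
#' wavenumber order are reversed on read (with a message). Malformed
#' files -- empty input, missing header columns, rows of the wrong
#' length, unknown class labels -- raise errors naming the offender.
#'
#' @param path CSV file written by [write_dataset()].
#' @param classes Class vocabulary for label validation.
#' @return An [nir_spectra] object.
#' @export
read_dataset <- function(path, classes = maojian_classes()) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop("empty or missing dataset file: ", path, call. = FALSE)
  }
  dt <- data.table::fread(path, header = TRUE, fill = TRUE,
                          colClasses = list(character = "sample_id"))
  need <- c("sample_id", "class", "replicate")
  if (nrow(dt) == 0L) stop("dataset file has no data rows", call. = FALSE)
  if (!all(need %in% names(dt))) {
    stop("malformed header: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  wn_cols <- setdiff(names(dt), need)
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (anyNA(wn)) {
    stop("malformed header: non-numeric wavenumber column(s): ",
         paste(utils::head(wn_cols[is.na(wn)], 3), collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(dt[, wn_cols, with = FALSE])
  bad <- which(rowSums(!is.finite(mat)) > 0)
  if (length(bad)) {
    stop("row ", bad[1], " has wrong length or non-numeric values",
         call. = FALSE)
  }
  if (all(diff(wn) < 0)) {
    message("descending wavenumber grid detected; reversing to ascending")
    wn <- rev(wn)
    mat <- mat[, rev(seq_along(wn_cols)), drop = FALSE]
  }
  unknown <- setdiff(unique(dt$class), classes)
  if (length(unknown)) {
    stop("unknown class label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  nir_spectra(mat, wn, dt$sample_id, dt$class,
              replicate = dt$replicate, classes = classes)
}

#' Export one spectrum as JCAMP-DX
#'
#' Writes a single absorbance trace in JCAMP-DX 4.24 `(XY..XY)` form
#' (x in cm^-1, y in absorbance units) for interoperability with
#' spectroscopy software. Import is not supported.
#'
#' @param absorbance Numeric absorbance vector.
#' @param wavenumber Matching wavenumber grid.
#' @param path Output file path.
#' @param title Spectrum title recorded in the header.
#' @return `path`, invisibly.
#' @export
write_jdx <- function(absorbance, wavenumber, path, title = "spectrum") {
  validate_grid(wavenumber)
  stopifnot(length(absorbance) == length(wavenumber),
            all(is.finite(absorbance)))
  lines <- c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    paste0("##FIRSTX=", format(wavenumber[1], digits = 12)),
    paste0("##LASTX=", format(wavenumber[length(wavenumber)], digits = 12)),
    paste0("##NPOINTS=", length(wavenumber)),
    "##XYDATA=(XY..XY)",
    paste(format(wavenumber, digits = 10, trim = TRUE),
          format(absorbance, digits = 10, trim = TRUE), sep = ", "),
    "##END="
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
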