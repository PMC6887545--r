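#' Build a spectrum tibble
#'
#' Spectra are plain tibbles with a `wavelength` column (nm) and a `value`
#' column, tagged with a `kind` attribute: one of `"transmittance"`,
#' `"sensitivity"`, `"power"`, or `"reflectance"`. All package functions
#' accept and return this shape, so spectra compose with dplyr verbs.
#'
#' @param wavelength Numeric vector of wavelengths in nm.
#' @param value Numeric vector the same length as `wavelength`.
#' @param kind One of `"transmittance"`, `"sensitivity"`, `"power"`,
#'   `"reflectance"`.
#'
#' @return A tibble with columns `wavelength` and `value`, sorted by
#'   wavelength, of class `spectrum_tbl`.
#' @examples
#' spectrum_tbl(380:780, rep(0.5, 401), kind = "transmittance")
#' @export
spectrum_tbl <- function(wavelength, value,
                         kind = c("transmittance", "sensitivity", "power", "reflectance")) {
  kind <- match.arg(kind)
  if (length(wavelength) != length(value)) {
    abort("`wavelength` and `value` must have the same length.",
      class = "specfilt_error_data"
    )
  }
  if (anyNA(wavelength) || any(!is.finite(wavelength))) {
    abort("Wavelengths must be finite.", class = "specfilt_error_data")
  }
  ord <- order(wavelength)
  x <- tibble::tibble(wavelength = as.numeric(wavelength[ord]), value = as.numeric(value[ord]))
  if (any(duplicated(x$wavelength))) {
    abort("Duplicate wavelengths; collapse them first (read_spectrum() averages duplicates).",
      class = "specfilt_error_data"
    )
  }
  new_spectrum_tbl(x, kind)
}

new_spectrum_tbl <- function(x, kind) {
  class(x) <- c("spectrum_tbl", class(tibble::tibble()))
  attr(x, "kind") <- kind
  x
}

#' @rdname spectrum_tbl
#' @param x A spectrum tibble.
#' @export
spectrum_kind <- function(x) {
  attr(x, "kind") %||% "transmittance"
}

#' Read a spectrum from a delimited file
#'
#' Reads a two-or-more-column delimited table (comma or tab separated,
#' header optional) holding one wavelength column and one value column,
#' the layout in which digitized transmittance curves are circulated.
#' Rows are sorted by wavelength and duplicate wavelengths (digitization
#' double-clicks) are collapsed by their mean. No cleaning is applied:
#' values may be negative, exceed 1, or sit on an irregular grid --
#' pass the result through [clean_spectrum()].
#'
#' @param path Path to a delimited text file.
#' @param wavelength_col,value_col Optional column names (or 1-based
#'   indices) selecting the wavelength and value columns. When `NULL`,
#'   a column named like "wavelength"/"lambda"/"wl"/"nm" is used if
#'   present, else column 1; the value column defaults to the first
#'   remaining numeric column.
#' @param kind Spectrum kind tag, see [spectrum_tbl()].
#'
#' @return A raw (uncleaned) spectrum tibble.
#' @export
read_spectrum <- function(path, wavelength_col = NULL, value_col = NULL,
                          kind = "transmittance") {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "specfilt_error_io")
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  has_header <- !grepl("^\\s*[-+0-9.eE]+[,\t]", first)
  dat <- utils::read.table(path,
    sep = delim, header = has_header,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (!has_header) names(dat) <- paste0("V", seq_along(dat))
  pick <- function(sel, candidates, what) {
    if (is.numeric(sel)) {
      if (sel < 1 || sel > ncol(dat)) {
        abort(sprintf("%s column index %d out of range.", what, sel),
          class = "specfilt_error_format"
        )
      }
      return(as.integer(sel))
    }
    hit <- match(tolower(sel), tolower(names(dat)))
    if (is.na(hit)) {
      abort(
        sprintf(
          "%s column '%s' not found; available: %s", what, sel,
          paste(names(dat), collapse = ", ")
        ),
        class = "specfilt_error_format"
      )
    }
    hit
  }
  if (is.null(wavelength_col)) {
    auto <- match(TRUE, tolower(names(dat)) %in% c("wavelength", "wavelength_nm", "lambda", "wl", "nm"))
    iw <- if (is.na(auto)) 1L else auto
  } else {
    iw <- pick(wavelength_col, names(dat), "Wavelength")
  }
  if (is.null(value_col)) {
    numeric_cols <- which(vapply(dat, is.numeric, logical(1)))
    rest <- setdiff(numeric_cols, iw)
    if (length(rest) == 0) {
      abort(
        sprintf(
          "No numeric value column found; columns: %s",
          paste(names(dat), collapse = ", ")
        ),
        class = "specfilt_error_format"
      )
    }
    iv <- rest[[1]]
  } else {
    iv <- pick(value_col, names(dat), "Value")
  }
  wl <- suppressWarnings(as.numeric(dat[[iw]]))
  v <- suppressWarnings(as.numeric(dat[[iv]]))
  keep <- is.finite(wl) & is.finite(v)
  wl <- wl[keep]
  v <- v[keep]
  if (length(wl) < 2) {
    abort("Fewer than 2 usable rows in spectrum file.", class = "specfilt_error_data")
  }
  collapsed <- tibble::tibble(wavelength = wl, value = v) |>
    dplyr::summarise(value = mean(.data$value), .by = "wavelength") |>
    dplyr::arrange(.data$wavelength)
  new_spectrum_tbl(collapsed, kind)
}

#' Write a spectrum to a CSV file
#'
#' Two-column CSV (`wavelength,value`) with a header;
#' `read_spectrum(write_spectrum(x))` is an identity on the grid.
#'
#' @param x A spectrum tibble.
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("wavelength", "value") %in% names(x)))
  readr::write_csv(tibble::as_tibble(x)[c("wavelength", "value")], path)
  invisible(x)
}

#' Clean and resample a digitized spectrum
#'
#' Post-processing for graph-digitized spectral curves. Within the span
#' of the raw data, values are interpolated onto the working grid with a
#' piecewise cubic Hermite interpolating polynomial (PCHIP), which is
#' shape-preserving (no overshoot between data points). Grid wavelengths
#' outside the raw span are set to exactly 0, so light there does not
#' enter any downstream integral. Negative values (digitization
#' inaccuracy) are set to exactly 0. For transmittance and reflectance
#' spectra, values above 1 are physically impossible and are clipped to
#' 1 with a warning.
#'
#' Cleaning is idempotent: cleaning an already-clean spectrum returns it
#' unchanged.
#'
#' @param x A raw spectrum tibble (at least 2 samples), e.g. from
#'   [read_spectrum()].
#' @param grid A [grid_spec()]; defaults to 380--780 nm at 1 nm.
#' @param kind Spectrum kind; defaults to the input's tag. Clipping at 1
#'   applies only to `"transmittance"` and `"reflectance"`.
#'
#' @return A spectrum tibble on the full grid, values in `[0, 1]` for
#'   transmittance/reflectance. Attributes `n_negative_clipped` and
#'   `n_above_one_clipped` record how many grid points were touched.
#' @examples
#' raw <- spectrum_tbl(seq(450, 700, 10), pmin(1, seq(0, 1, length.out = 26)))
#' cleaned <- clean_spectrum(raw)
#' range(cleaned$value)
#' @export
clean_spectrum <- function(x, grid = grid_spec(), kind = NULL) {
  stopifnot(is.data.frame(x), all(c("wavelength", "value") %in% names(x)))
  kind <- kind %||% spectrum_kind(x)
  wl_raw <- x$wavelength
  v_raw <- x$value
  ord <- order(wl_raw)
  wl_raw <- wl_raw[ord]
  v_raw <- v_raw[ord]
  if (length(wl_raw) < 2) {
    abort("Need at least 2 samples to interpolate.", class = "specfilt_error_data")
  }
  if (any(duplicated(wl_raw))) {
    agg <- tapply(v_raw, wl_raw, mean)
    wl_raw <- as.numeric(names(agg))
    v_raw <- as.numeric(agg)
  }
  wl <- grid_wavelengths(grid)
  if (max(wl_raw) < min(wl) || min(wl_raw) > max(wl)) {
    abort("Raw spectrum lies entirely outside the working grid.",
      class = "specfilt_error_data"
    )
  }
  inside <- wl >= min(wl_raw) & wl <= max(wl_raw)
  v <- numeric(length(wl)) # zero-fill outside the digitized span
  if (any(inside)) {
    v[inside] <- pracma::pchip(wl_raw, v_raw, wl[inside])
  }
  n_neg <- sum(v < 0)
  v[v < 0] <- 0
  n_hi <- 0L
  if (kind %in% c("transmittance", "reflectance")) {
    n_hi <- sum(v > 1)
    if (n_hi > 0) {
      warn(sprintf(
        "%d interpolated value(s) exceeded 1 and were clipped (digitized %s).",
        n_hi, kind
      ), class = "specfilt_warning_clip")
      v[v > 1] <- 1
    }
  }
  out <- new_spectrum_tbl(tibble::tibble(wavelength = wl, value = v), kind)
  attr(out, "n_negative_clipped") <- n_neg
  attr(out, "n_above_one_clipped") <- n_hi
  out
}

#' Plot a spectrum
#'
#' @param x A spectrum tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$wavelength, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Wavelength (nm)",
      y = spectrum_kind(x)
    ) +
    ggplot2::theme_minimal()
}
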