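#' Define a wavelength grid
#'
#' A regular wavelength grid on which spectra are resampled and all
#' integrations are carried out. The default, 380--780 nm in 1 nm steps,
#' is the visible-range grid over which the transmittance integrals are
#' evaluated.
#'
#' @param start_nm,end_nm Grid limits in nanometres, `start_nm < end_nm`.
#' @param step_nm Grid spacing in nanometres, greater than 0. The span
#'   must be an integer multiple of the step (to within 1e-9).
#'
#' @return An object of class `grid_spec`: a list with elements
#'   `start_nm`, `end_nm`, `step_nm`.
#' @examples
#' g <- grid_spec()
#' length(grid_wavelengths(g))  # 401
#' @export
grid_spec <- function(start_nm = 380, end_nm = 780, step_nm = 1) {
  if (!is.numeric(start_nm) || !is.numeric(end_nm) || !is.numeric(step_nm)) {
    abort("grid_spec limits and step must be numeric.", class = "specfilt_error_grid")
  }
  if (start_nm >= end_nm) {
    abort("`start_nm` must be strictly less than `end_nm`.", class = "specfilt_error_grid")
  }
  if (step_nm <= 0) {
    abort("`step_nm` must be positive.", class = "specfilt_error_grid")
  }
  n_steps <- (end_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    abort("Grid span (end_nm - start_nm) must be divisible by step_nm.",
      class = "specfilt_error_grid"
    )
  }
  structure(
    list(start_nm = start_nm, end_nm = end_nm, step_nm = step_nm),
    class = "grid_spec"
  )
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
grid_wavelengths <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  seq(grid$start_nm, grid$end_nm, by = grid$step_nm)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<wavelength grid> %g-%g nm, step %g nm (%d points)\n",
    x$start_nm, x$end_nm, x$step_nm, length(grid_wavelengths(x))
  ))
  invisible(x)
}

# Shared check that a spectrum tibble sits exactly on `grid`.
assert_on_grid <- function(x, grid, arg = "spectrum") {
  wl <- grid_wavelengths(grid)
  if (nrow(x) != length(wl) || max(abs(x$wavelength - wl)) > 1e-9) {
    abort(
      sprintf("`%s` is not defined on the working grid; clean_spectrum() it first.", arg),
      class = "specfilt_error_grid_mismatch"
    )
  }
  invisible(TRUE)
}

# Check two or more spectra share one wavelength column.
assert_same_grid <- function(...) {
  sp <- list(...)
  w0 <- sp[[1]]$wavelength
  for (s in sp[-1]) {
    if (length(s$wavelength) != length(w0) || max(abs(s$wavelength - w0)) > 1e-9) {
      abort("Spectra are on different wavelength grids.",
        class = "specfilt_error_grid_mismatch"
      )
    }
  }
  invisible(TRUE)
}
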