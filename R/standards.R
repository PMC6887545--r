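#' Visual-pigment absorbance template (Govardovskii nomogram)
#'
#' Alpha-band A1 visual-pigment template parameterized by the wavelength
#' of peak absorbance:
#' \deqn{S(\lambda) = 1 / (e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D)}
#' with \eqn{x = \lambda_{max}/\lambda}, constants A = 69.7, B = 28,
#' C = -14.9, D = 0.674, b = 0.922, c = 1.104 and
#' \eqn{a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}}.
#' The optional beta (cis) band adds a Gaussian
#' \eqn{A_\beta e^{-((\lambda-\lambda_{m\beta})/b_\beta)^2}} with
#' \eqn{A_\beta = 0.26}, \eqn{\lambda_{m\beta} = 189 + 0.315\lambda_{max}},
#' \eqn{b_\beta = -40.5 + 0.195\lambda_{max}}; it is off by default since
#' the melanopic weighting used here is built from the alpha band alone.
#' The result is normalized to peak 1 on the grid.
#'
#' @param lambda_max_nm Peak wavelength in nm, within the template's
#'   validity range 400--620 nm (330--620 with beta band caveats; we
#'   enforce 400--620).
#' @param grid A [grid_spec()].
#' @param beta_band Include the beta band? Default `FALSE`.
#'
#' @return A sensitivity spectrum tibble, peak value 1.
#' @examples
#' s <- govardovskii_template(480)
#' s$value[s$wavelength == 480]
#' @export
govardovskii_template <- function(lambda_max_nm, grid = grid_spec(), beta_band = FALSE) {
  if (!is.numeric(lambda_max_nm) || lambda_max_nm < 400 || lambda_max_nm > 620) {
    abort("`lambda_max_nm` must lie in the template validity range [400, 620] nm.",
      class = "specfilt_error_domain"
    )
  }
  wl <- grid_wavelengths(grid)
  x <- lambda_max_nm / wl
  a <- 0.8795 + 0.0459 * exp(-(lambda_max_nm - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
    exp(-14.9 * (1.104 - x)) + 0.674)
  v <- alpha
  if (beta_band) {
    lmb <- 189 + 0.315 * lambda_max_nm
    bb <- -40.5 + 0.195 * lambda_max_nm
    v <- v + 0.26 * exp(-((wl - lmb) / bb)^2)
  }
  v <- v / max(v)
  new_spectrum_tbl(tibble::tibble(wavelength = wl, value = v), "sensitivity")
}

#' Ocular lens density and transmittance of the standard observer
#'
#' Two-component lens density model (components TL1, TL2 tabulated at
#' 10 nm, 400--650 nm) with a linear age term applied to TL1:
#' \eqn{D(\lambda) = TL1(\lambda)\,[1 + 0.02 (A - 32)] + TL2(\lambda)}
#' for ages 20--60. Below 400 nm each component is extrapolated linearly
#' from its two shortest-wavelength rows; above 650 nm the density is 0.
#' Lens transmittance is \eqn{10^{-D(\lambda)}}.
#'
#' @param grid A [grid_spec()].
#' @param age_years Observer age, 20--60. Default 32 (standard observer).
#' @return A tibble with columns `wavelength`, `density`, `transmittance`.
#' @export
lens_transmittance <- function(grid = grid_spec(), age_years = 32) {
  if (age_years < 20 || age_years > 60) {
    abort("Lens model is valid for ages 20-60 years.", class = "specfilt_error_domain")
  }
  tab <- read_bundled_table("lens_density_pokorny_10nm.csv")
  wl <- grid_wavelengths(grid)
  comp <- function(col) {
    y <- numeric(length(wl))
    inside <- wl >= 400 & wl <= 650
    y[inside] <- pracma::pchip(tab$wavelength, tab[[col]], wl[inside])
    below <- wl < 400
    slope <- (tab[[col]][1] - tab[[col]][2]) / (tab$wavelength[2] - tab$wavelength[1])
    y[below] <- tab[[col]][1] + slope * (400 - wl[below])
    y # above 650: 0
  }
  density <- comp("tl1") * (1 + 0.02 * (age_years - 32)) + comp("tl2")
  tibble::tibble(
    wavelength = wl, density = density,
    transmittance = 10^(-density)
  )
}

#' Melanopic spectral sensitivity
#'
#' The spectral sensitivity of melanopsin-driven (ipRGC) responses at
#' the cornea: a Govardovskii pigment template with peak at 480 nm,
#' weighted by the transmittance of the standard-observer (32-year) lens
#' and renormalized to peak 1. Pre-receptoral lens absorption at short
#' wavelengths shifts the corneal peak a few nm long of 480.
#'
#' @param grid A [grid_spec()].
#' @param lens_model `"std32"` (standard 32-year observer lens, the
#'   default), or `"none"` (no pre-receptoral filtering; returns the bare
#'   pigment template, useful for sensitivity analyses).
#' @param lambda_max_nm Pigment template peak; default 480 nm.
#'
#' @return A sensitivity spectrum tibble with attributes
#'   `peak_wavelength_nm` and `lens_model`.
#' @examples
#' s <- melanopic_sensitivity()
#' attr(s, "peak_wavelength_nm")
#' @export
melanopic_sensitivity <- function(grid = grid_spec(), lens_model = c("std32", "none"),
                                  lambda_max_nm = 480) {
  lens_model <- match.arg(lens_model)
  templ <- govardovskii_template(lambda_max_nm, grid)
  v <- templ$value
  if (lens_model == "std32") {
    v <- v * lens_transmittance(grid)$transmittance
  }
  v <- v / max(v)
  out <- new_spectrum_tbl(tibble::tibble(wavelength = templ$wavelength, value = v), "sensitivity")
  attr(out, "peak_wavelength_nm") <- templ$wavelength[which.max(v)]
  attr(out, "lens_model") <- lens_model
  out
}

read_bundled_table <- function(file) {
  path <- system.file("extdata", file, package = "specfilt")
  if (path == "" || !file.exists(path)) {
    abort(sprintf("Bundled reference table missing: %s", file),
      class = "specfilt_error_config"
    )
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# Resample a bundled (clean, tabulated) reference function onto the grid.
# Interpolation only -- grid points outside the tabulated range are 0.
resample_reference <- function(wavelength, value, grid, kind) {
  clean_spectrum(
    spectrum_tbl(wavelength, value, kind = kind),
    grid = grid, kind = kind
  )
}

#' Synthetic surface-reflectance sample set
#'
#' A seeded, reproducible stand-in for a representative set of surface
#' reflectances: smooth logistic-of-Gaussian-bumps curves in `[0, 1]`
#' whose chromaticities under D65 spread over the object-colour gamut.
#' It is used for the colour-gamut metric when the reference reflectance
#' collection (99 colour evaluation samples of real objects) is not
#' bundled; results with the stand-in track, but do not numerically
#' equal, those with the reference set.
#'
#' @param n Number of reflectance curves (default 99, matching the size
#'   of the reference colour-evaluation-sample set).
#' @param grid A [grid_spec()].
#' @param seed RNG seed (internal stream; the global RNG state is left
#'   untouched).
#'
#' @return A tibble with columns `sample_id`, `wavelength`, `value`
#'   (long format, `n` curves on the grid).
#' @export
synthetic_reflectances <- function(n = 99, grid = grid_spec(), seed = 2026L) {
  wl <- grid_wavelengths(grid)
  rng <- local_rng(seed)
  out <- purrr::map(seq_len(n), function(i) {
    n_bump <- 4L
    centers <- rng$runif(n_bump, 380, 780)
    widths <- rng$runif(n_bump, 30, 150)
    amps <- rng$rnorm(n_bump, 0, 1.3)
    base <- rng$rnorm(1, -0.4, 1.0)
    z <- base
    for (j in seq_len(n_bump)) {
      z <- z + amps[j] * exp(-((wl - centers[j]) / widths[j])^2)
    }
    tibble::tibble(
      sample_id = sprintf("R%03d", i),
      wavelength = wl,
      value = stats::plogis(z)
    )
  }) |> purrr::list_rbind()
  attr(out, "source_id") <- "synthetic"
  out
}

# Deterministic RNG stream independent of the caller's global seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) {
          if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", old, envir = globalenv())
        }
      })
      f(...)
    }
  }
  list(
    runif = with_state(stats::runif),
    rnorm = with_state(stats::rnorm),
    sample = with_state(base::sample),
    rlnorm = with_state(stats::rlnorm)
  )
}

#' Load the bundle of fixed reference functions
#'
#' Assembles, on one working grid, everything the four filter metrics
#' need: the CIE 1964 10-degree colour-matching functions (whose
#' \eqn{\bar y_{10}} serves as the large-field luminosity function
#' \eqn{V_{10}}), the D65 daylight spectral power distribution, the
#' melanopic spectral sensitivity, and a surface-reflectance sample set
#' for the gamut computation. Bundled tables (tabulated at 5 nm) are
#' resampled to the grid by shape-preserving interpolation.
#'
#' @param grid A [grid_spec()].
#' @param melanopic `"bundled"` (the frozen constructed tabulation
#'   shipped with the package) or `"constructed"` (rebuild from the
#'   pigment template and lens model at load time). The two agree; the
#'   option exists so the construction can be audited.
#' @param reflectances `"synthetic"` (the seeded stand-in set, default)
#'   -- see [synthetic_reflectances()].
#' @param n_reflectances Number of reflectance samples (default 99).
#'
#' @return An object of class `standards_bundle`: a list with elements
#'   `grid`, `observer` (tibble wavelength/xbar10/ybar10/zbar10),
#'   `d65`, `melanopic`, `reflectances`, and provenance fields
#'   `lens_model` and `reflectance_source`.
#' @examples
#' b <- load_standards()
#' dplyr::n_distinct(b$reflectances$sample_id)
#' @export
load_standards <- function(grid = grid_spec(),
                           melanopic = c("bundled", "constructed"),
                           reflectances = "synthetic",
                           n_reflectances = 99) {
  melanopic <- match.arg(melanopic)
  reflectances <- match.arg(reflectances, "synthetic")
  cmf <- read_bundled_table("cie1964_10deg_cmf_5nm.csv")
  obs <- tibble::tibble(
    wavelength = grid_wavelengths(grid),
    xbar10 = resample_reference(cmf$wavelength, cmf$xbar10, grid, "sensitivity")$value,
    ybar10 = resample_reference(cmf$wavelength, cmf$ybar10, grid, "sensitivity")$value,
    zbar10 = resample_reference(cmf$wavelength, cmf$zbar10, grid, "sensitivity")$value
  )
  d65_tab <- read_bundled_table("d65_spd_5nm.csv")
  d65 <- resample_reference(d65_tab$wavelength, d65_tab$power, grid, "power")
  mel <- if (melanopic == "bundled") {
    tab <- read_bundled_table("melanopic_std32_constructed_1nm.csv")
    s <- resample_reference(tab$wavelength, tab$value, grid, "sensitivity")
    s$value <- s$value / max(s$value)
    attr(s, "peak_wavelength_nm") <- s$wavelength[which.max(s$value)]
    attr(s, "lens_model") <- "std32"
    s
  } else {
    melanopic_sensitivity(grid)
  }
  refl <- synthetic_reflectances(n = n_reflectances, grid = grid)
  structure(
    list(
      grid = grid,
      observer = obs,
      d65 = d65,
      melanopic = mel,
      reflectances = refl,
      lens_model = attr(mel, "lens_model") %||% "std32",
      reflectance_source = attr(refl, "source_id")
    ),
    class = "standards_bundle"
  )
}

#' @export
print.standards_bundle <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<standards bundle>\n  grid: %g-%g nm step %g\n",
      "  observer: CIE 1964 10-degree CMFs (V10 = ybar10)\n",
      "  illuminant: D65\n  melanopic peak: %g nm (lens: %s)\n",
      "  reflectances: %d (%s)\n"
    ),
    x$grid$start_nm, x$grid$end_nm, x$grid$step_nm,
    attr(x$melanopic, "peak_wavelength_nm"), x$lens_model,
    dplyr::n_distinct(x$reflectances$sample_id), x$reflectance_source
  ))
  invisible(x)
}
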