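#' Analytic sigmoid cut-off filter
#'
#' Long-pass ("blue-blocking") filters are well described by a logistic
#' transmittance profile
#' \deqn{T(\lambda) = \frac{L}{1 + e^{-k(\lambda - \lambda_0)}}}
#' where \eqn{\lambda_0} is the cut-off wavelength (transmittance is
#' exactly L/2 there), L the upper asymptote ("plateau"), and k the
#' slope (per nm; large k approaches a step edge).
#'
#' @param lambda0_nm Cut-off wavelength in nm; must lie within the grid
#'   span.
#' @param upper_asymptote L in (0, 1].
#' @param slope k > 0, in 1/nm.
#' @param grid A [grid_spec()].
#' @return A transmittance spectrum tibble, monotone nondecreasing,
#'   strictly inside (0, L).
#' @examples
#' f <- sigmoid_filter(550, 0.9, 0.5)
#' f$value[f$wavelength == 550] # 0.45
#' @export
sigmoid_filter <- function(lambda0_nm, upper_asymptote = 0.9, slope = 0.5,
                           grid = grid_spec()) {
  if (upper_asymptote <= 0 || upper_asymptote > 1) {
    abort("`upper_asymptote` must be in (0, 1].", class = "specfilt_error_domain")
  }
  if (slope <= 0) {
    abort("`slope` must be positive.", class = "specfilt_error_domain")
  }
  if (lambda0_nm < grid$start_nm || lambda0_nm > grid$end_nm) {
    abort("`lambda0_nm` must lie within the working grid span.",
      class = "specfilt_error_domain"
    )
  }
  wl <- grid_wavelengths(grid)
  v <- upper_asymptote / (1 + exp(-slope * (wl - lambda0_nm)))
  new_spectrum_tbl(tibble::tibble(wavelength = wl, value = v), "transmittance")
}

#' Neutral-density (spectrally flat) filter
#'
#' @param transmittance Constant transmittance in (0, 1]. Alternatively
#'   give `density` d, with transmittance \eqn{10^{-d}} (ND1.0 = 0.1).
#' @param density Optical density; overrides `transmittance` if given.
#' @param grid A [grid_spec()].
#' @return A constant transmittance spectrum tibble.
#' @examples
#' nd_filter(density = 1)$value[1] # 0.1
#' @export
nd_filter <- function(transmittance = NULL, density = NULL, grid = grid_spec()) {
  if (!is.null(density)) {
    if (density < 0) abort("`density` must be >= 0.", class = "specfilt_error_domain")
    transmittance <- 10^(-density)
  }
  if (is.null(transmittance) || transmittance <= 0 || transmittance > 1) {
    abort("`transmittance` must be in (0, 1].", class = "specfilt_error_domain")
  }
  wl <- grid_wavelengths(grid)
  new_spectrum_tbl(
    tibble::tibble(wavelength = wl, value = rep(transmittance, length(wl))),
    "transmittance"
  )
}

#' Notch (band-block) filter
#'
#' Transmittance 1 outside a blocked band and `1 - depth` inside it,
#' with smooth raised-cosine transition edges. Notch filters targeting
#' the melanopsin-sensitive region (460--500 nm) attenuate melanopsin
#' activation while sparing most of the luminance.
#'
#' @param center_nm Band centre in nm.
#' @param width_nm Full width of the flat blocked region, > 0.
#' @param depth Attenuation depth in `[0, 1]` (1 = fully opaque in-band).
#' @param edge_width_nm Width of each raised-cosine transition edge
#'   (default 10 nm).
#' @param grid A [grid_spec()].
#' @return A transmittance spectrum tibble.
#' @export
notch_filter <- function(center_nm, width_nm, depth, edge_width_nm = 10,
                         grid = grid_spec()) {
  if (width_nm <= 0) abort("`width_nm` must be positive.", class = "specfilt_error_domain")
  if (depth < 0 || depth > 1) abort("`depth` must be in [0, 1].", class = "specfilt_error_domain")
  if (edge_width_nm < 0) abort("`edge_width_nm` must be >= 0.", class = "specfilt_error_domain")
  wl <- grid_wavelengths(grid)
  half <- width_nm / 2
  d <- abs(wl - center_nm)
  # attenuation profile: 1 in-band, raised-cosine rolloff, 0 out-of-band
  att <- numeric(length(wl))
  att[d <= half] <- 1
  if (edge_width_nm > 0) {
    edge <- d > half & d < half + edge_width_nm
    att[edge] <- 0.5 * (1 + cos(pi * (d[edge] - half) / edge_width_nm))
  }
  v <- 1 - depth * att
  new_spectrum_tbl(tibble::tibble(wavelength = wl, value = v), "transmittance")
}

#' Sweep one sigmoid parameter and collect metrics
#'
#' Holds a base sigmoid filter fixed and varies one of its parameters,
#' computing the four retinally referenced metrics at each value --
#' the parametric-simulation experiment. Varying `lambda0_nm` moves
#' both transmittances down with melanopsin falling faster; varying
#' `upper_asymptote` slides the filter along the neutral-density locus
#' at fixed chromaticity; varying `slope` mostly trades melanopsin
#' attenuation and colour properties at near-constant luminance.
#'
#' @param parameter One of `"lambda0_nm"`, `"upper_asymptote"`, `"slope"`.
#' @param values Numeric vector of parameter values.
#' @param bundle A `standards_bundle`; built with defaults when missing.
#' @param lambda0_nm,upper_asymptote,slope Base parameters, held fixed
#'   except for the swept one. Defaults (550 nm, 0.9, 0.5/nm) are the
#'   canonical mid-range cut-off.
#' @return A tibble of class `filter_sweep`: one row per value with the
#'   swept `parameter`, `value`, and the metric columns of
#'   [filter_metrics()].
#' @examples
#' \donttest{
#' b <- load_standards()
#' sweep_filter_metrics("upper_asymptote", seq(0.1, 0.9, 0.2), bundle = b)
#' }
#' @export
sweep_filter_metrics <- function(parameter, values, bundle = load_standards(),
                                 lambda0_nm = 550, upper_asymptote = 0.9,
                                 slope = 0.5) {
  parameter <- match.arg(parameter, c("lambda0_nm", "upper_asymptote", "slope"))
  if (length(values) < 1) {
    abort("`values` must be non-empty.", class = "specfilt_error_domain")
  }
  base <- list(
    lambda0_nm = lambda0_nm, upper_asymptote = upper_asymptote,
    slope = slope
  )
  rows <- purrr::map(values, function(v) {
    p <- base
    p[[parameter]] <- v
    f <- sigmoid_filter(p$lambda0_nm, p$upper_asymptote, p$slope, grid = bundle$grid)
    dplyr::bind_cols(
      tibble::tibble(parameter = parameter, value = v),
      filter_metrics(f, bundle)
    )
  }) |> purrr::list_rbind()
  class(rows) <- c("filter_sweep", class(rows))
  attr(rows, "base") <- base
  rows
}

#' Default parameter ranges for the three sweeps
#'
#' Cut-off wavelength 450--600 nm (step 10), plateau 0.1--0.9 (step
#' 0.1), slope 0.05--1 per nm (log-spaced, 10 values). The figures in
#' the source analysis show these ranges graphically; the values here
#' are the package defaults and are configurable in every sweep call.
#'
#' @return A named list of numeric vectors.
#' @export
default_sweep_values <- function() {
  list(
    lambda0_nm = seq(450, 600, by = 10),
    upper_asymptote = seq(0.1, 0.9, by = 0.1),
    slope = exp(seq(log(0.05), log(1), length.out = 10))
  )
}

#' @method tidy filter_sweep
#' @export
tidy.filter_sweep <- function(x, ...) {
  tibble::as_tibble(x)[, c(
    "parameter", "value", "luminous_transmittance",
    "melanopsin_transmittance", "colour_shift", "gamut_ratio"
  )]
}

#' @method glance filter_sweep
#' @export
glance.filter_sweep <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter[1],
    n = nrow(x),
    luminous_range = diff(range(x$luminous_transmittance)),
    melanopic_range = diff(range(x$melanopsin_transmittance)),
    max_colour_shift = max(x$colour_shift, na.rm = TRUE),
    min_gamut_ratio = min(x$gamut_ratio)
  )
}

#' @method autoplot filter_sweep
#' @export
autoplot.filter_sweep <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(
      c(
        "luminous_transmittance", "melanopsin_transmittance",
        "colour_shift", "gamut_ratio"
      ),
      names_to = "metric", values_to = "metric_value"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$metric_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = object$parameter[1], y = NULL) +
    ggplot2::theme_minimal()
}
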