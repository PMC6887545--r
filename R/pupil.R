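# Unified light-adapted pupil model constants (corneal-flux-density
# form). All in one block so the transcription is auditable:
#   F = L * a * M(e)        corneal flux density (cd/m2 * deg2)
#     L  luminance, a field area in deg2, M(e) = 1 binocular, 0.1 monocular
#   D_SD(F) = 7.75 - 5.75 * q / (q + 2),  q = (F / 846)^0.41
#   D_U = D_SD + (age - 28.58) * (0.02132 - 0.009562 * D_SD)
.pupil_const <- list(
  d_max = 7.75, d_span = 5.75, f_ref = 846, f_exp = 0.41,
  age_ref = 28.58, age_a = 0.02132, age_b = 0.009562,
  m_monocular = 0.1, m_binocular = 1,
  diam_lo = 2, diam_hi = 9,
  age_lo = 20, age_hi = 80
)

#' Light-adapted pupil diameter
#'
#' Unified pupil-size model in its corneal-flux-density form: luminance,
#' field area and the monocular/binocular effect combine into one flux
#' density F = L a M(e) driving a saturating diameter function, with a
#' linear age correction around the reference age 28.58 years. Defaults
#' follow the real-world viewing approximation used throughout the
#' package: a 150-degree field, 32-year-old observer, binocular viewing.
#'
#' Diameters are clamped to the plausible 2--9 mm range; if clamping
#' occurred the result carries attribute `clamped = TRUE`.
#'
#' @param luminance_cd_m2 Positive luminance(s), cd/m2 (vectorized).
#' @param field_diameter_deg Circular field diameter in degrees (> 0);
#'   field area is \eqn{\pi (d/2)^2} deg2.
#' @param age_years Observer age, 20--80 (model validity).
#' @param eyes `"binocular"` or `"monocular"`.
#' @return Pupil diameter(s) in mm.
#' @examples
#' pupil_diameter(c(0.1, 10, 1000))
#' @export
pupil_diameter <- function(luminance_cd_m2, field_diameter_deg = 150,
                           age_years = 32,
                           eyes = c("binocular", "monocular")) {
  eyes <- match.arg(eyes)
  k <- .pupil_const
  if (any(!is.finite(luminance_cd_m2)) || any(luminance_cd_m2 <= 0)) {
    abort("`luminance_cd_m2` must be positive and finite.",
      class = "specfilt_error_domain"
    )
  }
  if (field_diameter_deg <= 0) {
    abort("`field_diameter_deg` must be positive.", class = "specfilt_error_domain")
  }
  if (age_years < k$age_lo || age_years > k$age_hi) {
    abort(sprintf(
      "`age_years` = %g outside model validity [%g, %g].",
      age_years, k$age_lo, k$age_hi
    ), class = "specfilt_error_domain")
  }
  area_deg2 <- pi * (field_diameter_deg / 2)^2
  m <- if (eyes == "binocular") k$m_binocular else k$m_monocular
  f <- luminance_cd_m2 * area_deg2 * m
  q <- (f / k$f_ref)^k$f_exp
  d_sd <- k$d_max - k$d_span * q / (q + 2)
  d <- d_sd + (age_years - k$age_ref) * (k$age_a - k$age_b * d_sd)
  clamped <- d < k$diam_lo | d > k$diam_hi
  d <- pmin(pmax(d, k$diam_lo), k$diam_hi)
  if (any(clamped)) attr(d, "clamped") <- TRUE
  d
}

#' Pupil area from diameter
#'
#' \eqn{\pi (d/2)^2} in mm2; the maximal retinal-illuminance modulation
#' available from the pupil alone is the area ratio between a fully
#' dilated 8 mm and a fully constricted 2 mm pupil, a factor of 16.
#'
#' @param diameter_mm Pupil diameter(s) in mm.
#' @return Area(s) in mm2.
#' @examples
#' pupil_area(8) / pupil_area(2) # 16
#' @export
pupil_area <- function(diameter_mm) {
  pi * (diameter_mm / 2)^2
}

#' Retinal illuminance across a luminance range, with and without filters
#'
#' For each stimulus luminance, the effective luminance behind a
#' spectrally uniform filter is luminance x transmittance; the pupil
#' adapts to the effective luminance; retinal illuminance (trolands) is
#' effective luminance x pupil area. Because the pupil can compensate by
#' at most a factor of ~16 in area while an ND3.0 filter removes a
#' factor of 1000, the curves for different ND filters are near-parallel
#' on log-log axes: what dominates retinal illuminance is the luminance
#' seen through the filter.
#'
#' @param luminances_cd_m2 Positive luminances; default 50 log-spaced
#'   values over 1e-3..1e4 cd/m2.
#' @param filter_transmittance Spectrally uniform transmittance(s) in
#'   (0, 1]; one curve per value (e.g. `c(1, 0.1, 0.01, 0.001)` for the
#'   natural pupil and ND1.0/2.0/3.0).
#' @inheritParams pupil_diameter
#' @return A tibble of class `retinal_illuminance_curve` with columns
#'   `filter_transmittance`, `luminance`, `effective_luminance`,
#'   `pupil_diameter_mm`, `retinal_illuminance_td`.
#' @examples
#' retinal_illuminance_curve(filter_transmittance = c(1, 0.1))
#' @export
retinal_illuminance_curve <- function(luminances_cd_m2 = NULL,
                                      filter_transmittance = 1,
                                      field_diameter_deg = 150,
                                      age_years = 32,
                                      eyes = "binocular") {
  if (is.null(luminances_cd_m2)) {
    luminances_cd_m2 <- 10^seq(-3, 4, length.out = 50)
  }
  if (any(filter_transmittance <= 0) || any(filter_transmittance > 1)) {
    abort("`filter_transmittance` must be in (0, 1].", class = "specfilt_error_domain")
  }
  out <- purrr::map(filter_transmittance, function(tr) {
    eff <- luminances_cd_m2 * tr
    d <- pupil_diameter(eff,
      field_diameter_deg = field_diameter_deg,
      age_years = age_years, eyes = eyes
    )
    tibble::tibble(
      filter_transmittance = tr,
      luminance = luminances_cd_m2,
      effective_luminance = eff,
      pupil_diameter_mm = as.numeric(d),
      retinal_illuminance_td = eff * pupil_area(as.numeric(d))
    )
  }) |> purrr::list_rbind()
  class(out) <- c("retinal_illuminance_curve", class(out))
  out
}

#' @method autoplot retinal_illuminance_curve
#' @export
autoplot.retinal_illuminance_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$luminance, y = .data$retinal_illuminance_td,
    colour = factor(.data$filter_transmittance)
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Luminance (cd/m²)", y = "Retinal illuminance (Td)",
      colour = "Filter transmittance"
    ) +
    ggplot2::theme_minimal()
}
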