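#' Spectrally weighted transmittance
#'
#' The fraction of photoreceptor-weighted light passing a filter under a
#' reference illuminant, by rectangle-rule numeric integration over the
#' working grid:
#' \deqn{T_w = \frac{\sum_\lambda F(\lambda) E(\lambda) S(\lambda) \Delta\lambda}
#'                  {\sum_\lambda E(\lambda) S(\lambda) \Delta\lambda}}
#' With \eqn{S = \bar y_{10} = V_{10}} this is the luminous
#' transmittance; with the melanopic sensitivity it is the melanopsin
#' transmittance.
#'
#' @param filter,illuminant,sensitivity Spectrum tibbles on one shared
#'   grid (`wavelength`, `value`).
#' @return A single number in `[0, 1]` for filters in `[0, 1]`.
#' @examples
#' b <- load_standards()
#' f <- nd_filter(0.5)
#' weighted_transmittance(f, b$d65, v10(b))
#' @export
weighted_transmittance <- function(filter, illuminant, sensitivity) {
  assert_same_grid(filter, illuminant, sensitivity)
  den <- sum(illuminant$value * sensitivity$value)
  if (den <= 0) {
    abort("Illuminant x sensitivity integrates to zero; degenerate weighting.",
      class = "specfilt_error_degenerate"
    )
  }
  sum(filter$value * illuminant$value * sensitivity$value) / den
}

#' V10 luminosity function of a standards bundle
#'
#' Convenience accessor: the large-field luminosity function is the
#' \eqn{\bar y_{10}} colour-matching function.
#'
#' @param bundle A `standards_bundle`.
#' @return A sensitivity spectrum tibble.
#' @export
v10 <- function(bundle) {
  new_spectrum_tbl(
    tibble::tibble(
      wavelength = bundle$observer$wavelength,
      value = bundle$observer$ybar10
    ),
    "sensitivity"
  )
}

#' Tristimulus values under the 10-degree observer
#'
#' Rectangle-rule sums of a spectral power distribution against the
#' CIE 1964 colour-matching functions, with the grid step as
#' \eqn{\Delta\lambda}.
#'
#' @param spd A power spectrum tibble.
#' @param observer The `observer` tibble of a `standards_bundle`
#'   (columns `wavelength`, `xbar10`, `ybar10`, `zbar10`).
#' @param step_nm Grid step in nm used as the integration weight.
#' @return Named numeric vector `c(X, Y, Z)`.
#' @export
tristimulus10 <- function(spd, observer, step_nm = NULL) {
  if (length(spd$wavelength) != length(observer$wavelength) ||
    max(abs(spd$wavelength - observer$wavelength)) > 1e-9) {
    abort("SPD and observer are on different wavelength grids.",
      class = "specfilt_error_grid_mismatch"
    )
  }
  step_nm <- step_nm %||% {
    d <- diff(spd$wavelength)
    d[1]
  }
  c(
    X = sum(spd$value * observer$xbar10) * step_nm,
    Y = sum(spd$value * observer$ybar10) * step_nm,
    Z = sum(spd$value * observer$zbar10) * step_nm
  )
}

#' CIE 1976 u'v' chromaticity from tristimulus values
#'
#' \eqn{u' = 4X/(X + 15Y + 3Z)}, \eqn{v' = 9Y/(X + 15Y + 3Z)}.
#' Computed from 10-degree tristimulus values these are the
#' \eqn{u'_{10} v'_{10}} coordinates.
#'
#' @param X,Y,Z Tristimulus values (or `X` a length-3 vector).
#' @return A one-row tibble with columns `u_prime`, `v_prime`.
#' @examples
#' uv_prime(1, 1, 1) # equal-energy point: (4/19, 9/19)
#' @export
uv_prime <- function(X, Y = NULL, Z = NULL) {
  if (is.null(Y) && length(X) == 3) {
    Z <- X[[3]]
    Y <- X[[2]]
    X <- X[[1]]
  }
  den <- X + 15 * Y + 3 * Z
  if (!is.finite(den) || den <= 0) {
    abort("Degenerate stimulus: X + 15Y + 3Z must be positive.",
      class = "specfilt_error_degenerate"
    )
  }
  tibble::tibble(u_prime = 4 * X / den, v_prime = 9 * Y / den)
}

# Wavelength-by-sample matrix view of the bundle's (long) reflectance set.
# Relies on the long table being sample-major with one full grid per sample.
reflectance_matrix <- function(bundle) {
  refl <- bundle$reflectances
  ids <- unique(refl$sample_id)
  wl <- grid_wavelengths(bundle$grid)
  stopifnot(nrow(refl) == length(wl) * length(ids))
  m <- matrix(refl$value, nrow = length(wl), ncol = length(ids))
  colnames(m) <- ids
  m
}

# u'v' of an SPD; returns NULL for an (effectively) all-zero stimulus.
spd_chromaticity <- function(spd, observer, black_tol = 0) {
  xyz <- tristimulus10(spd, observer)
  den <- xyz[["X"]] + 15 * xyz[["Y"]] + 3 * xyz[["Z"]]
  if (!is.finite(den) || den <= black_tol) {
    return(NULL)
  }
  uv_prime(xyz)
}

#' Area of the convex hull of chromaticity points
#'
#' Shoelace-formula area over the convex-hull vertices. Fewer than 3
#' distinct points, or a collinear set, have zero area.
#'
#' @param points A data frame with columns `u_prime`, `v_prime` (any
#'   2-D point set).
#' @return A nonnegative number.
#' @examples
#' sq <- tibble::tibble(u_prime = c(0, 1, 1, 0), v_prime = c(0, 0, 1, 1))
#' gamut_hull_area(sq) # 1
#' @export
gamut_hull_area <- function(points) {
  stopifnot(all(c("u_prime", "v_prime") %in% names(points)))
  pts <- unique(points[, c("u_prime", "v_prime")])
  if (nrow(pts) < 3) {
    return(0)
  }
  idx <- grDevices::chull(pts$u_prime, pts$v_prime)
  hx <- pts$u_prime[idx]
  hy <- pts$v_prime[idx]
  n <- length(idx)
  if (n < 3) {
    return(0)
  }
  j <- c(2:n, 1)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}

#' The four retinally referenced filter metrics
#'
#' Computes, for one cleaned transmittance spectrum under the bundle's
#' D65 illuminant:
#' * `luminous_transmittance` -- V10-weighted transmittance;
#' * `melanopsin_transmittance` -- melanopic-weighted transmittance;
#' * `colour_shift` -- Euclidean distance in u'10 v'10 between the D65
#'   white point seen with and without the filter;
#' * `gamut_ratio` -- area of the convex hull of the reflectance-sample
#'   chromaticities under filtered D65, divided by the hull area under
#'   unfiltered D65 (1 = no gamut change; a "gamut reduction" figure
#'   is `1 - gamut_ratio`).
#'
#' Reflectance samples rendered (numerically) black by the filter are
#' excluded from the hull; their count is returned. If fewer than 3
#' distinct chromaticities survive, `gamut_ratio` is 0 and
#' `degenerate_gamut` is `TRUE`. A `gamut_ratio` above 1 is possible in
#' principle for exotic filters and is reported unclamped.
#'
#' @param filter A cleaned transmittance spectrum tibble on the bundle
#'   grid (see [clean_spectrum()]).
#' @param bundle A `standards_bundle` from [load_standards()].
#' @return A one-row tibble: the four metrics plus
#'   `u_prime_filtered`, `v_prime_filtered`, `n_black_excluded`,
#'   `degenerate_gamut`.
#' @examples
#' b <- load_standards()
#' filter_metrics(sigmoid_filter(550, 0.9, 0.5), b)
#' @export
filter_metrics <- function(filter, bundle) {
  stopifnot(inherits(bundle, "standards_bundle"))
  assert_on_grid(filter, bundle$grid, "filter")
  lum <- weighted_transmittance(filter, bundle$d65, v10(bundle))
  mel <- weighted_transmittance(filter, bundle$d65, bundle$melanopic)
  wp0 <- spd_chromaticity(bundle$d65, bundle$observer)
  filtered_d65 <- bundle$d65
  filtered_d65$value <- filtered_d65$value * filter$value
  wp1 <- spd_chromaticity(filtered_d65, bundle$observer)
  if (is.null(wp1)) {
    # opaque filter: no white point; colour quantities undefined -> 0 gamut
    return(tibble::tibble(
      luminous_transmittance = lum, melanopsin_transmittance = mel,
      colour_shift = NA_real_, gamut_ratio = 0,
      u_prime_filtered = NA_real_, v_prime_filtered = NA_real_,
      n_black_excluded = dplyr::n_distinct(bundle$reflectances$sample_id),
      degenerate_gamut = TRUE
    ))
  }
  shift <- sqrt((wp1$u_prime - wp0$u_prime)^2 + (wp1$v_prime - wp0$v_prime)^2)

  refl_mat <- reflectance_matrix(bundle)
  cmf_mat <- cbind(
    bundle$observer$xbar10, bundle$observer$ybar10,
    bundle$observer$zbar10
  )
  hull_points <- function(illum) {
    xyz <- t(refl_mat * illum$value) %*% cmf_mat # rows: samples; cols: X, Y, Z
    den <- xyz[, 1] + 15 * xyz[, 2] + 3 * xyz[, 3]
    keep <- is.finite(den) & den > 0
    tibble::tibble(
      u_prime = 4 * xyz[keep, 1] / den[keep],
      v_prime = 9 * xyz[keep, 2] / den[keep]
    )
  }
  pts0 <- hull_points(bundle$d65)
  pts1 <- hull_points(filtered_d65)
  n_samples <- ncol(refl_mat)
  n_black <- n_samples - nrow(pts1)
  area0 <- gamut_hull_area(pts0)
  area1 <- if (nrow(pts1) > 0) gamut_hull_area(pts1) else 0
  degenerate <- area1 <= 0
  tibble::tibble(
    luminous_transmittance = lum,
    melanopsin_transmittance = mel,
    colour_shift = shift,
    gamut_ratio = if (area0 > 0) area1 / area0 else 0,
    u_prime_filtered = wp1$u_prime,
    v_prime_filtered = wp1$v_prime,
    n_black_excluded = n_black,
    degenerate_gamut = degenerate
  )
}
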