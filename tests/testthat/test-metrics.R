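test_that("weighted transmittance passes constants through and validates inputs", {
  b <- test_bundle()
  expect_equal(
    weighted_transmittance(nd_filter(0.5), b$d65, v10(b)), 0.5,
    tolerance = 1e-14
  )
  expect_equal(
    weighted_transmittance(nd_filter(1), b$d65, b$melanopic), 1.0,
    tolerance = 1e-14
  )
  coarse <- nd_filter(0.5, grid = grid_spec(380, 780, 5))
  expect_error(
    weighted_transmittance(coarse, b$d65, v10(b)),
    class = "specfilt_error_grid_mismatch"
  )
  zero_sens <- spectrum_tbl(380:780, rep(0, 401), kind = "sensitivity")
  expect_error(
    weighted_transmittance(nd_filter(0.5), b$d65, zero_sens),
    class = "specfilt_error_degenerate"
  )
})

test_that("weighted transmittance matches a 0.1 nm fine-grid oracle", {
  b <- test_bundle()
  for (p in list(c(550, 0.9, 0.5), c(480, 0.7, 0.1), c(600, 0.95, 1.5))) {
    f <- sigmoid_filter(p[1], p[2], p[3])
    got_lum <- weighted_transmittance(f, b$d65, v10(b))
    ora_lum <- oracle_sigmoid_transmittance(p[1], p[2], p[3], b$d65, v10(b))
    expect_lt(abs(got_lum - ora_lum), 1e-3)
    got_mel <- weighted_transmittance(f, b$d65, b$melanopic)
    ora_mel <- oracle_sigmoid_transmittance(p[1], p[2], p[3], b$d65, b$melanopic)
    expect_lt(abs(got_mel - ora_mel), 1e-3)
  }
})

test_that("uv_prime closed forms and projective invariance", {
  eq <- uv_prime(1, 1, 1)
  expect_equal(eq$u_prime, 4 / 19, tolerance = 1e-14)
  expect_equal(eq$v_prime, 9 / 19, tolerance = 1e-14)
  # X-only stimulus: denominator is X alone, so u' = 4X/X = 4, v' = 0
  red <- uv_prime(1, 0, 0)
  expect_equal(red$u_prime, 4)
  expect_equal(red$v_prime, 0)
  # Y-only stimulus: u' = 0, v' = 9/15
  green <- uv_prime(0, 1, 0)
  expect_equal(green$u_prime, 0)
  expect_equal(green$v_prime, 9 / 15, tolerance = 1e-14)
  a <- uv_prime(0.3, 0.5, 0.2)
  a_scaled <- uv_prime(0.3 * 17, 0.5 * 17, 0.2 * 17)
  expect_equal(a, a_scaled, tolerance = 1e-14)
  expect_error(uv_prime(0, 0, 0), class = "specfilt_error_degenerate")
})

test_that("tristimulus values are zero for darkness and linear in the stimulus", {
  b <- test_bundle()
  dark <- spectrum_tbl(380:780, rep(0, 401), kind = "power")
  expect_equal(unname(tristimulus10(dark, b$observer)), c(0, 0, 0))
  one <- tristimulus10(b$d65, b$observer)
  double_spd <- b$d65
  double_spd$value <- 2 * double_spd$value
  expect_equal(tristimulus10(double_spd, b$observer), 2 * one, tolerance = 1e-12)
})

test_that("hull area agrees with known polygons and the brute-force oracle", {
  square <- tibble::tibble(u_prime = c(0, 1, 1, 0), v_prime = c(0, 0, 1, 1))
  expect_equal(gamut_hull_area(square), 1.0, tolerance = 1e-14)
  expect_equal(
    gamut_hull_area(tibble::tibble(u_prime = rep(0.4, 5), v_prime = rep(0.2, 5))),
    0
  )
  collinear <- tibble::tibble(u_prime = 1:5, v_prime = 2 * (1:5))
  expect_equal(gamut_hull_area(collinear), 0)

  set.seed(11)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    u <- runif(n)
    v <- runif(n)
    expect_equal(
      gamut_hull_area(tibble::tibble(u_prime = u, v_prime = v)),
      oracle_hull_area(u, v),
      tolerance = 1e-12
    )
  }
  u <- runif(50)
  v <- runif(50)
  expect_equal(
    gamut_hull_area(tibble::tibble(u_prime = u, v_prime = v)),
    oracle_hull_area(u, v),
    tolerance = 1e-12
  )
})

test_that("a spectrally flat filter leaves colour untouched: metrics (c, c, 0, 1)", {
  b <- test_bundle()
  for (c_val in c(0.1, 0.5, 0.9)) {
    m <- filter_metrics(nd_filter(c_val), b)
    expect_equal(m$luminous_transmittance, c_val, tolerance = 1e-12)
    expect_equal(m$melanopsin_transmittance, c_val, tolerance = 1e-12)
    expect_equal(m$colour_shift, 0, tolerance = 1e-12)
    expect_equal(m$gamut_ratio, 1, tolerance = 1e-12)
    expect_equal(m$n_black_excluded, 0L)
    expect_false(m$degenerate_gamut)
  }
})

test_that("cut-off filters attenuate melanopsin more than luminance", {
  b <- test_bundle()
  for (l0 in c(450, 500, 550, 600)) {
    m <- filter_metrics(sigmoid_filter(l0, 0.9, 0.5), b)
    expect_lte(m$melanopsin_transmittance, m$luminous_transmittance + 1e-9)
  }
})

test_that("a narrow band-pass collapses the gamut and shifts the white point", {
  b <- test_bundle()
  wl <- 380:780
  band <- spectrum_tbl(wl, as.numeric(wl >= 585 & wl <= 595))
  m <- filter_metrics(band, b)
  expect_lt(m$gamut_ratio, 0.01)
  expect_gt(m$colour_shift, 0.05) # white point driven toward the spectral locus
})

test_that("transmittances compose multiplicatively only against a flat filter", {
  b <- test_bundle()
  f_cut <- sigmoid_filter(520, 0.9, 0.3)
  f_flat <- nd_filter(0.4)
  prod_flat <- f_cut
  prod_flat$value <- f_cut$value * f_flat$value
  m_cut <- filter_metrics(f_cut, b)
  m_prod <- filter_metrics(prod_flat, b)
  expect_equal(
    m_prod$luminous_transmittance,
    0.4 * m_cut$luminous_transmittance,
    tolerance = 1e-12
  )
  expect_equal(
    m_prod$melanopsin_transmittance,
    0.4 * m_cut$melanopsin_transmittance,
    tolerance = 1e-12
  )
  # two non-flat filters do not compose multiplicatively
  f2 <- sigmoid_filter(560, 0.8, 0.2)
  both <- f_cut
  both$value <- f_cut$value * f2$value
  m2 <- filter_metrics(f2, b)
  m_both <- filter_metrics(both, b)
  expect_gt(
    abs(
      m_both$luminous_transmittance -
        m_cut$luminous_transmittance * m2$luminous_transmittance
    ),
    1e-4
  )
})

test_that("an opaque filter yields a degenerate gamut, not an error", {
  b <- test_bundle()
  dark <- spectrum_tbl(380:780, rep(0, 401))
  m <- filter_metrics(dark, b)
  expect_equal(m$luminous_transmittance, 0)
  expect_equal(m$gamut_ratio, 0)
  expect_true(m$degenerate_gamut)
})
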