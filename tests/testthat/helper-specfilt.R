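# Shared fixtures and independent oracles for the test suite.
# The oracles are deliberately naive re-implementations that share no
# code with the package internals.

# One default-standards bundle per test run (loading reads the bundled
# tables and builds 99 reflectances; reuse keeps the suite fast).
test_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_standards()
    cache
  }
})

# Brute-force convex hull area: drop every point that lies inside (or
# on) a triangle of three other points, order the survivors by angle
# about their centroid, apply the shoelace formula.
oracle_hull_area <- function(u, v) {
  n <- length(u)
  pts <- unique(data.frame(u = u, v = v))
  u <- pts$u
  v <- pts$v
  n <- length(u)
  if (n < 3) {
    return(0)
  }
  tri_area2 <- function(ax, ay, bx, by, cx, cy) {
    (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
  }
  in_triangle <- function(px, py, ax, ay, bx, by, cx, cy) {
    d1 <- tri_area2(px, py, ax, ay, bx, by)
    d2 <- tri_area2(px, py, bx, by, cx, cy)
    d3 <- tri_area2(px, py, cx, cy, ax, ay)
    has_neg <- (d1 < 0) || (d2 < 0) || (d3 < 0)
    has_pos <- (d1 > 0) || (d2 > 0) || (d3 > 0)
    !(has_neg && has_pos)
  }
  interior <- rep(FALSE, n)
  combos <- utils::combn(n, 3)
  for (p in seq_len(n)) {
    for (j in seq_len(ncol(combos))) {
      tri <- combos[, j]
      if (p %in% tri) next
      if (abs(tri_area2(
        u[tri[1]], v[tri[1]], u[tri[2]], v[tri[2]],
        u[tri[3]], v[tri[3]]
      )) < 1e-300) {
        next
      }
      if (in_triangle(
        u[p], v[p], u[tri[1]], v[tri[1]],
        u[tri[2]], v[tri[2]], u[tri[3]], v[tri[3]]
      )) {
        interior[p] <- TRUE
        break
      }
    }
  }
  hu <- u[!interior]
  hv <- v[!interior]
  if (length(hu) < 3) {
    return(0)
  }
  ang <- atan2(hv - mean(hv), hu - mean(hu))
  ord <- order(ang)
  hu <- hu[ord]
  hv <- hv[ord]
  m <- length(hu)
  nxt <- c(2:m, 1)
  abs(sum(hu * hv[nxt] - hu[nxt] * hv)) / 2
}

# Textbook Pearson correlation from the raw sum formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Fine-grid (0.1 nm) weighted-transmittance oracle: linear resampling
# of illuminant and sensitivity, analytic sigmoid evaluation, plain
# rectangle sum. Independent of the package's integration path.
oracle_sigmoid_transmittance <- function(lambda0, L, k, illuminant, sensitivity) {
  wl_fine <- seq(380, 780, by = 0.1)
  e <- approx(illuminant$wavelength, illuminant$value, wl_fine)$y
  s <- approx(sensitivity$wavelength, sensitivity$value, wl_fine)$y
  f <- L / (1 + exp(-k * (wl_fine - lambda0)))
  sum(f * e * s) / sum(e * s)
}

# A tiny in-memory filter database of spectrally flat filters.
flat_filter_db <- function(transmittances, grid = grid_spec()) {
  tibble::tibble(
    id = sprintf("ND%02d", seq_along(transmittances)),
    category = rep("task_other", length(transmittances)),
    spectrum = lapply(transmittances, function(tr) nd_filter(tr, grid = grid)),
    source_note = "fixture"
  )
}
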