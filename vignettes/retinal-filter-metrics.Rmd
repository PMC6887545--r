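---
title: "Quantifying short-wavelength light filters at the retina"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying short-wavelength light filters at the retina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specfilt)
```

## The problem

"Blue-blocking" and "blue-attenuating" spectacle and contact-lens
filters are marketed and prescribed for a wide range of ocular,
neurological and psychiatric indications, yet the only quantity usually
published for them is the spectral transmittance curve \(F(\lambda)\).
A transmittance curve cannot be read "by eye" into physiological
consequences: the same curve simultaneously attenuates luminance
(via the L+M-cone luminosity mechanism), melanopsin activation in
intrinsically photosensitive retinal ganglion cells (ipRGCs, the cells
that drive circadian entrainment, melatonin suppression and steady-state
pupil size), and the colour appearance of the world. `specfilt`
operationalises a retinally referenced description of a filter as four
numbers, all computed under D65 daylight:

* **Luminous transmittance**
  \[
  T_{\mathrm{lum}} \;=\;
  \frac{\sum_{380}^{780} F(\lambda)\,E_{D65}(\lambda)\,V_{10}(\lambda)\,\Delta\lambda}
       {\sum_{380}^{780} E_{D65}(\lambda)\,V_{10}(\lambda)\,\Delta\lambda}
  \]
  with \(V_{10} = \bar y_{10}\), the CIE 1964 10° luminosity function.
* **Melanopsin transmittance** — the same ratio with the melanopic
  spectral sensitivity \(S_{\mathrm{mel}}(\lambda)\) in place of
  \(V_{10}\).
* **Colour shift** — the Euclidean distance in the CIE 1976
  \(u'_{10}v'_{10}\) chromaticity diagram between the D65 white point
  seen with and without the filter.
* **Gamut ratio** — the area of the convex hull of the chromaticities
  of a fixed set of surface reflectances under filtered D65, divided by
  the hull area under unfiltered D65 (reported as a ratio; a "gamut
  reduction" is \(1 - \) ratio).

Because every quantity is a ratio of integrals, all four metrics are
invariant to rescaling the illuminant or any sensitivity by a positive
constant; a property test asserts this.

## Reference functions and their provenance

`load_standards()` assembles the fixed ingredients on one wavelength
grid (default 380–780 nm at 1 nm, the integration range of the
formulas above):

* **CIE 1964 10° colour-matching functions** and **D65**, bundled as
  5 nm tables and resampled by shape-preserving interpolation. The 10°
  observer is used throughout — including for \(V_{10}\) — so that the
  photometric and colorimetric quantities share one observer. The D65
  chromaticity computed from the bundled tables reproduces the
  published CIE-1964-observer value (0.31382, 0.33100) to four decimal
  places; a test asserts this.
* **Melanopic sensitivity**: constructed as a Govardovskii A1 pigment
  template with \(\lambda_{max} = 480\) nm, multiplied by the
  transmittance of the 32-year standard-observer lens and renormalized
  to peak 1. The lens model is the two-component ageing-lens density
  (components tabulated at 10 nm over 400–650 nm, linear age term;
  extrapolated linearly below 400 nm, zero density above 650 nm). The
  resulting corneal sensitivity peaks at 487 nm — a few nm long of the
  pigment peak, as lens absorption at short wavelengths predicts. A
  frozen copy of this construction ships as the bundled tabulation
  (file name marked `constructed`); `melanopic = "constructed"`
  rebuilds it at load time, and a regression test keeps the two in
  agreement. The pigment template's beta band is available as an
  option but off by default: the melanopic weighting standardised for
  field use is alpha-band based, and at the lens-filtered short
  wavelengths the beta band contributes little.
* **Reflectance sample set**: the gamut metric needs a collection of
  representative object reflectances. The reference collection for
  this purpose (the 99 colour evaluation samples used in colour
  rendition work) is not redistributable, so the bundle uses a
  **synthetic stand-in**: 99 seeded, smooth logistic-of-Gaussian-bumps
  reflectances whose chromaticities spread over the object-colour
  gamut (`synthetic_reflectances()`, internal seed 2026, independent
  of user seeds; `reflectance_source` records `"synthetic"` in every
  provenance block). Gamut ratios computed with the stand-in track the
  reference set qualitatively but are not numerically interchangeable
  with it — correlations involving the gamut metric shift accordingly
  (see "What the tests do and do not show").

## Cleaning digitized spectra

Published transmittance curves are usually digitized from graphs, which
leaves three characteristic defects: irregular wavelength sampling,
missing data at the spectral extremes, and small negative (or >1)
excursions from tracing error. `clean_spectrum()` applies, in order:

1. **PCHIP interpolation** onto the working grid within the span of
   the raw data. PCHIP is shape-preserving: it passes exactly through
   the data points and cannot overshoot between them, which matters
   for curves that sit flat at 0 or at a plateau.
2. **Zero-fill** strictly outside the raw span, so wavelengths that
   were never digitized contribute no light to any integral.
3. **Negative clipping** to exactly 0.
4. **Clipping above 1** (transmittance and reflectance kinds only),
   with a warning and per-spectrum counts. The source procedure
   specifies only the negative case; clipping at 1 is this package's
   symmetric choice, recorded in the output attributes rather than
   silent.

Interpolation happens before zero-fill (so edge zeros are exact, not
interpolated), and cleaning is idempotent. Duplicate wavelengths in
raw files — digitization double-clicks — are averaged at read time.

## The analytic filter models

Cut-off ("long-pass") filters are modelled by the logistic
\[
T(\lambda) = \frac{L}{1 + e^{-k(\lambda - \lambda_0)}},
\]
with cut-off wavelength \(\lambda_0\) (where \(T = L/2\)), plateau
\(L \in (0,1]\) and slope \(k > 0\) per nm. `sweep_filter_metrics()`
varies one parameter while holding the others at the base values
(550 nm, 0.9, 0.5/nm); default sweep ranges are
\(\lambda_0 \in [450, 600]\) nm (step 10), \(L \in [0.1, 0.9]\)
(step 0.1), and \(k \in [0.05, 1]\)/nm (log-spaced) — the source
figures show their ranges only graphically, so these defaults are the
package's own, configurable in every call. The structural results the
sweeps reproduce: raising \(\lambda_0\) lowers both transmittances
with melanopsin falling strictly faster (its sensitivity peaks ~70 nm
short of \(V_{10}\)'s); varying \(L\) alone scales both transmittances
proportionally — a line of slope 1 in log–log attenuation space,
"parallel to the neutral-density locus" — at exactly constant
chromaticity; neutral-density filters (`nd_filter()`, \(T = 10^{-d}\))
are the reference case \((c, c, 0, 1)\). Notch filters use a flat
blocked band with raised-cosine edges (default 10 nm each side); the
edge shape is a package choice, since no analytic notch model is given
in the source analysis.

## Pupil size and retinal illuminance

Spectral filtering acts at the cornea, but the stimulus to the retina
also depends on pupil area. The light-adapted pupil is modelled in the
unified corneal-flux-density form: flux density
\(F = L \cdot a \cdot M(e)\) (luminance × field area in deg² ×
monocular attenuation, \(M = 1\) binocular, \(0.1\) monocular) drives
\[
D_{SD}(F) = 7.75 - 5.75\,\frac{(F/846)^{0.41}}{(F/846)^{0.41} + 2},
\qquad
D = D_{SD} + (A - 28.58)(0.02132 - 0.009562\,D_{SD}),
\]
with age \(A\) in years. All constants live in one auditable block in
`R/pupil.R`. Defaults are a 150° field, 32-year observer, binocular
viewing. Predicted diameters are clamped to 2–9 mm with a flag rather
than silently; in practice the unclamped model stays inside that range
over 10⁻³–10⁴ cd/m². Spectral (melanopsin-driven) pupil effects are
deliberately not modelled: the model is applied to spectrally uniform
filters, where retinal illuminance is effective luminance × pupil
area. The structural point `retinal_illuminance_curve()` makes: the
pupil can compensate by at most a factor of 16 in area (2 mm vs 8 mm),
so ND filter curves on log–log axes are near-parallel — the filter,
not the pupil, dominates retinal illuminance.

## The synthetic filter database

`synthetic_filter_database()` emulates a digitized database of 121
filters in three ad-hoc categories — medical (n = 76), safety
(n = 11) and task-specific (n = 34: 10 sport, 4 driving, 12 VDU, 8
other) — apportioned by largest remainder for other sizes. Shape
mixtures reflect the described diversity: medical filters are mostly
strong cut-offs at 480–600 nm (30% with a small nonzero floor),
safety filters cut at 440–520 nm, task filters mix mild cut-offs,
notches over the melanopsin band and shallow broad tints. Plateaus,
slopes and depths are drawn from wide ranges (e.g. \(L\) 0.5–0.98,
\(k\) log-normal about 0.3/nm). Digitization is emulated by ~5 nm
sampling with ±1.5 nm jitter, span truncation at either extreme (40%
probability each), and additive noise (sd 0.01) — which reliably
produces negative dips that exercise the cleaning pipeline. All
distributional choices were fixed when the generator was written,
from the qualitative description of the real database; they are not
fitted to any reported statistic.

## What the tests do and do not show

The suite validates the machinery against independent oracles: a
0.1 nm brute-force integration oracle for the weighted transmittances,
a triangle-elimination brute-force convex hull, the textbook Pearson
sum formula, closed-form chromaticity points, and frozen values from a
separate transcription of the pupil formula and pigment template. The
structural claims — identity-line bound for all monotone cut-offs,
slope-1 plateau locus at constant chromaticity, faster melanopsin
attenuation with increasing cut-off, near-parallel ND retinal
illuminance curves, gamut collapse under narrow band-passes — all
reproduce.

Numeric reproduction of the published database correlation matrix is a
different matter. On the synthetic 121-filter database the
luminous–melanopic Pearson correlation lands at ≈0.86, matching the
published value for the real digitized database; the correlations
involving colour shift and gamut come out stronger (≈−0.84 vs −0.74)
and weaker (≈−0.60 vs −0.78) respectively. Both discrepancies are
expected: the synthetic shape mixture and, especially, the synthetic
reflectance stand-in change exactly the colour-geometric quantities,
and the generator is intentionally not tuned to reproduce reported
statistics. With the real digitized spectra (and the reference
reflectance set) supplied via `read_filter_database()`, the same code
path computes the published analysis directly.

## Numerical choices and edge cases

* Integration is a plain rectangle (Riemann) sum with
  \(\Delta\lambda\) = grid step, matching the printed formulas; at
  1 nm the difference from a trapezoid rule is below the fine-grid
  oracle tolerance (10⁻³).
* Problem sizes are modest by construction: 401-point grids, 99
  reflectances, 121-filter batches; the full database analysis runs in
  about two seconds, and the whole test suite in well under a minute.
* Filters that render a reflectance numerically black are excluded
  from the hull with a count (`n_black_excluded`); fewer than 3
  surviving distinct chromaticities give `gamut_ratio = 0` and a
  `degenerate_gamut` flag instead of an error, and a fully opaque
  filter yields transmittances 0 with an undefined (`NA`) colour
  shift.
* `gamut_ratio > 1` is possible for exotic filters and is reported
  unclamped.
* Correlation matrices mark zero-variance metrics as undefined (`NA`)
  rather than 0; Pearson is the default (the source analysis does not
  name its estimator), Spearman is computed alongside in the `analyze`
  report.
* All generator randomness runs on isolated RNG streams, so library
  calls never perturb a caller's `set.seed()` state, and equal seeds
  give byte-identical `analyze` reports.

## Known limitations

UV transmission and ocular-damage assessment, polarisation and
scattering, chromatic and long-term adaptation, melanopsin
contributions to pupil size, and colour-rendering indices beyond the
hull-area ratio are out of scope. The melanopic construction uses a
published ageing-lens model at age 32 rather than the (unpublished)
composite lens function behind the standardised tabulation; the
difference is small relative to the metric tolerances used here but is
a known source of last-digit disagreement. The synthetic reflectance
set is a documented stand-in, not the reference sample set.
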