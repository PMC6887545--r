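test_that("the synthetic database is deterministic in its seed", {
  a <- synthetic_filter_database(n = 15, seed = 3)
  b <- synthetic_filter_database(n = 15, seed = 3)
  expect_identical(a$spectrum, b$spectrum)
  c <- synthetic_filter_database(n = 15, seed = 4)
  expect_false(identical(a$spectrum, c$spectrum))
})

test_that("category apportionment follows largest-remainder rounding", {
  db <- synthetic_filter_database(n = 121, seed = 1)
  counts <- table(db$category)
  expect_equal(unname(counts[c(
    "medical", "safety", "task_sport",
    "task_driving", "task_vdu", "task_other"
  )]), c(76, 11, 10, 4, 12, 8), ignore_attr = TRUE)
  small <- synthetic_filter_database(n = 10, seed = 1)
  expect_equal(sum(table(small$category)), 10)
  expect_error(
    synthetic_filter_database(category_mix = c(bogus = 1)),
    class = "specfilt_error_domain"
  )
})

test_that("generated raw spectra need cleaning, and cleaning fixes them", {
  db <- synthetic_filter_database(n = 30, seed = 2)
  raw_has_negative <- vapply(
    db$spectrum, function(s) any(s$value < 0), logical(1)
  )
  expect_true(any(raw_has_negative)) # digitization noise produces dips
  cleaned <- clean_database(db)
  for (s in cleaned$spectrum) {
    expect_true(all(s$value >= 0 & s$value <= 1))
    expect_equal(nrow(s), 401)
  }
  expect_gt(sum(cleaned$n_negative_clipped), 0)
})

test_that("database metrics: flat filters are exact, cut-offs sit under the identity line", {
  b <- test_bundle()
  flat <- flat_filter_db(c(0.9, 0.5, 0.1))
  m <- database_metrics(flat, b)
  expect_equal(m$luminous_transmittance, c(0.9, 0.5, 0.1), tolerance = 1e-12)
  expect_equal(m$melanopsin_transmittance, c(0.9, 0.5, 0.1), tolerance = 1e-12)
  expect_equal(m$colour_shift, rep(0, 3), tolerance = 1e-12)
  expect_equal(m$gamut_ratio, rep(1, 3), tolerance = 1e-10)

  cuts <- tibble::tibble(
    id = sprintf("C%02d", 1:6),
    category = "medical",
    spectrum = lapply(seq(440, 590, by = 30), function(l0) sigmoid_filter(l0)),
    source_note = "fixture"
  )
  mc <- database_metrics(cuts, b)
  expect_true(all(mc$melanopsin_transmittance <= mc$luminous_transmittance + 1e-9))
})

test_that("the full 121-filter synthetic pipeline yields finite metrics", {
  b <- test_bundle()
  db <- synthetic_filter_database(n = 121, seed = 1) |> clean_database()
  m <- database_metrics(db, b)
  expect_equal(nrow(m), 121)
  expect_true(all(is.na(m$metric_error)))
  expect_true(all(is.finite(m$luminous_transmittance)))
  expect_true(all(is.finite(m$melanopsin_transmittance)))
  expect_true(all(is.finite(m$colour_shift)))
  expect_true(all(is.finite(m$gamut_ratio)))
})

test_that("a corrupt record is reported per-row, not fatal", {
  b <- test_bundle()
  db <- flat_filter_db(c(0.5, 0.8))
  db$spectrum[[2]] <- nd_filter(0.8, grid = grid_spec(380, 780, 5)) # wrong grid
  m <- database_metrics(db, b)
  expect_true(is.na(m$metric_error[1]))
  expect_false(is.na(m$metric_error[2]))
  expect_true(is.na(m$luminous_transmittance[2]))
})

test_that("correlation matrix agrees with the textbook formula to 1e-12", {
  b <- test_bundle()
  db <- synthetic_filter_database(n = 40, seed = 5) |> clean_database()
  m <- database_metrics(db, b)
  cm <- metric_correlations(m)
  expect_equal(dim(cm$r), c(4, 4))
  expect_equal(diag(cm$r), rep(1, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(cm$r))
  vars <- c(
    "luminous_transmittance", "melanopsin_transmittance",
    "colour_shift", "gamut_ratio"
  )
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(
        cm$r[i, j],
        oracle_pearson(m[[vars[i]]], m[[vars[j]]]),
        tolerance = 1e-12
      )
    }
  }
})

test_that("perfect and null correlations behave as expected", {
  # metrics that are exact affine copies of one variable -> |r| = 1
  base <- seq(0.1, 0.9, length.out = 10)
  fake <- tibble::tibble(
    luminous_transmittance = base,
    melanopsin_transmittance = 2 * base - 0.05,
    colour_shift = 1 - base,
    gamut_ratio = 0.3 * base + 0.1
  )
  cm <- metric_correlations(fake)
  off <- cm$r[upper.tri(cm$r)]
  expect_equal(abs(off), rep(1, 6), tolerance = 1e-12)

  # independently shuffled columns -> near-zero correlations at n = 100
  set.seed(99)
  noise <- tibble::tibble(
    luminous_transmittance = sample(runif(100)),
    melanopsin_transmittance = sample(runif(100)),
    colour_shift = sample(runif(100)),
    gamut_ratio = sample(runif(100))
  )
  cn <- metric_correlations(noise)
  expect_true(all(abs(cn$r[upper.tri(cn$r)]) < 0.3))
})

test_that("zero-variance metrics are flagged as undefined, not zero", {
  flat <- tibble::tibble(
    luminous_transmittance = c(0.2, 0.5, 0.8),
    melanopsin_transmittance = c(0.1, 0.4, 0.7),
    colour_shift = rep(0.3, 3),
    gamut_ratio = c(0.9, 0.8, 0.7)
  )
  cm <- metric_correlations(flat)
  expect_equal(cm$zero_variance, "colour_shift")
  expect_true(all(is.na(cm$r["colour_shift", c(
    "luminous_transmittance",
    "melanopsin_transmittance", "gamut_ratio"
  )])))
  expect_equal(cm$r["colour_shift", "colour_shift"], 1)
  expect_error(
    metric_correlations(flat[1:2, ]),
    class = "specfilt_error_data"
  )
})

test_that("noise-free sigmoid databases recover a strong luminous-melanopic correlation", {
  b <- test_bundle()
  set.seed(8)
  db <- tibble::tibble(
    id = sprintf("S%03d", 1:40),
    category = "medical",
    spectrum = lapply(1:40, function(i) {
      sigmoid_filter(runif(1, 440, 600), runif(1, 0.3, 1), exp(runif(1, log(0.05), log(1))))
    }),
    source_note = "fixture"
  )
  m <- database_metrics(db, b)
  cm <- metric_correlations(m)
  expect_gt(cm$r["luminous_transmittance", "melanopsin_transmittance"], 0.8)
})

test_that("category summaries partition the database and reflect construction", {
  b <- test_bundle()
  db <- synthetic_filter_database(n = 60, seed = 6) |> clean_database()
  m <- database_metrics(db, b)
  sm <- summarize_by_category(m)
  counts <- unique(sm[, c("category", "n")])
  expect_equal(sum(counts$n), 60)
  # medical filters are built at the longest cut-offs -> lowest melanopsin medians
  mel <- sm[sm$metric == "melanopsin_transmittance", ]
  expect_equal(
    as.character(mel$category[which.min(mel$median)]),
    "medical"
  )

  single <- summarize_by_category(database_metrics(flat_filter_db(c(0.3, 0.6)), b))
  expect_equal(unique(as.character(single$category)), "task_other")
  expect_equal(nrow(single), 4)
})

test_that("filter databases round-trip through a directory of CSVs", {
  dir <- withr::local_tempdir()
  db <- synthetic_filter_database(n = 6, seed = 9)
  write_filter_database(db, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  back <- read_filter_database(dir)
  expect_equal(back$id, db$id)
  expect_equal(back$category, db$category)
  for (i in seq_len(nrow(db))) {
    expect_equal(back$spectrum[[i]]$value, db$spectrum[[i]]$value, tolerance = 1e-12)
  }
  expect_error(read_filter_database(file.path(dir, "nope")), class = "specfilt_error_io")
})
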