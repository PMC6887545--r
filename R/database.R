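#' Filter category vocabulary
#'
#' The fixed category labels for filter records: medical, safety, and
#' four task-specific subcategories (sport, driving, visual display
#' unit use, other).
#'
#' @return Character vector of the six category labels.
#' @export
filter_categories <- function() {
  c("medical", "safety", "task_sport", "task_driving", "task_vdu", "task_other")
}

# Largest-remainder apportionment of n among proportions.
largest_remainder <- function(n, proportions) {
  p <- proportions / sum(proportions)
  quota <- n * p
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic filter database
#'
#' A reproducible stand-in for a database of digitized short-wavelength
#' filter transmittances. Spectra are drawn from a mixture of shapes
#' reflecting the diversity seen in commercial filters:
#' * sigmoid cut-offs with widely varying cut-off wavelength, plateau
#'   and slope (the dominant shape; medical filters tend toward longer
#'   cut-offs, safety and task filters toward shorter ones);
#' * cut-offs sitting on a small nonzero floor (leaky coatings);
#' * notch filters blocking a bounded short-wavelength band;
#' * shallow broad tints.
#'
#' The generator then emulates graph digitization: irregular wavelength
#' sampling (about 5 nm with jitter), occasional truncation of the
#' recorded span at either spectral extreme, and additive noise
#' (sd 0.01) that produces small negative dips near zero-transmittance
#' regions -- so the spectra genuinely require [clean_spectrum()].
#'
#' @param n Number of filters (default 121).
#' @param category_mix Named proportions (or counts) over
#'   [filter_categories()]; apportioned by largest remainder. The
#'   default mix is 76 medical, 11 safety, and 34 task filters
#'   (10 sport / 4 driving / 12 VDU / 8 other) per 121.
#' @param seed Integer seed; the same seed reproduces the database
#'   exactly. The global RNG state is left untouched.
#'
#' @return A tibble with columns `id`, `category`, `shape`,
#'   `spectrum` (list of raw spectrum tibbles), `source_note`.
#' @examples
#' db <- synthetic_filter_database(n = 10, seed = 1)
#' dplyr::count(db, category)
#' @export
synthetic_filter_database <- function(n = 121,
                                      category_mix = c(
                                        medical = 76, safety = 11,
                                        task_sport = 10, task_driving = 4,
                                        task_vdu = 12, task_other = 8
                                      ),
                                      seed = 1L) {
  if (n < 1) abort("`n` must be >= 1.", class = "specfilt_error_domain")
  cats <- filter_categories()
  if (is.null(names(category_mix)) || !all(names(category_mix) %in% cats)) {
    abort(
      sprintf(
        "`category_mix` must be named with categories among: %s",
        paste(cats, collapse = ", ")
      ),
      class = "specfilt_error_domain"
    )
  }
  if (any(category_mix < 0) || sum(category_mix) <= 0) {
    abort("`category_mix` proportions must be nonnegative and not all zero.",
      class = "specfilt_error_domain"
    )
  }
  counts <- largest_remainder(n, as.numeric(category_mix))
  category <- rep(names(category_mix), counts)
  rng <- local_rng(seed)
  rows <- purrr::map(seq_len(n), function(i) {
    cat_i <- category[i]
    spec <- synth_filter_spectrum(cat_i, rng)
    tibble::tibble(
      id = sprintf("F%03d", i),
      category = cat_i,
      shape = spec$shape,
      spectrum = list(spec$spectrum),
      source_note = "synthetic"
    )
  }) |> purrr::list_rbind()
  attr(rows, "seed") <- seed
  rows
}

# One raw (digitization-emulating) filter spectrum for a category.
synth_filter_spectrum <- function(category, rng) {
  u <- rng$runif(1)
  if (category == "medical") {
    shape <- if (u < 0.7) "cutoff" else "cutoff_floor"
    lambda0 <- rng$runif(1, 480, 600)
    L <- rng$runif(1, 0.5, 0.95)
  } else if (category == "safety") {
    shape <- if (u < 0.8) "cutoff" else "cutoff_floor"
    lambda0 <- rng$runif(1, 440, 520)
    L <- rng$runif(1, 0.6, 0.95)
  } else {
    shape <- if (u < 0.5) "cutoff" else if (u < 0.75) "notch" else "tint"
    lambda0 <- rng$runif(1, 420, 500)
    L <- rng$runif(1, 0.7, 0.98)
  }
  k <- rng$rlnorm(1, log(0.3), 0.5)
  tfun <- switch(shape,
    cutoff = function(wl) L / (1 + exp(-k * (wl - lambda0))),
    cutoff_floor = {
      p <- rng$runif(1, 0.02, 0.15)
      function(wl) p + (L - p) / (1 + exp(-k * (wl - lambda0)))
    },
    notch = {
      center <- rng$runif(1, 440, 490)
      width <- rng$runif(1, 20, 80)
      depth <- rng$runif(1, 0.4, 1)
      function(wl) {
        half <- width / 2
        d <- abs(wl - center)
        att <- ifelse(d <= half, 1,
          ifelse(d < half + 10, 0.5 * (1 + cos(pi * (d - half) / 10)), 0)
        )
        L * (1 - depth * att)
      }
    },
    tint = {
      center <- rng$runif(1, 450, 520)
      sigma <- rng$runif(1, 40, 90)
      depth <- rng$runif(1, 0.2, 0.6)
      function(wl) L * (1 - depth * exp(-((wl - center) / sigma)^2))
    }
  )
  # digitization emulation: truncated span, jittered ~5 nm sampling, noise
  start <- if (rng$runif(1) < 0.4) rng$runif(1, 380, 440) else 380
  end <- if (rng$runif(1) < 0.4) rng$runif(1, 700, 780) else 780
  wl <- seq(start, end, by = 5)
  wl <- wl + c(0, rng$runif(length(wl) - 2, -1.5, 1.5), 0)
  v <- tfun(wl) + rng$rnorm(length(wl), 0, 0.01)
  list(
    shape = shape,
    spectrum = new_spectrum_tbl(tibble::tibble(wavelength = wl, value = v), "transmittance")
  )
}

#' Clean every spectrum in a filter database
#'
#' Applies [clean_spectrum()] to each record. Clipping warnings are
#' collected into per-record counts (`n_negative_clipped`,
#' `n_above_one_clipped`) instead of being raised one by one.
#'
#' @param db A filter database tibble (e.g. from
#'   [synthetic_filter_database()] or [read_filter_database()]).
#' @param grid A [grid_spec()].
#' @return `db` with the `spectrum` column replaced by cleaned spectra
#'   and the two clip-count columns added.
#' @export
clean_database <- function(db, grid = grid_spec()) {
  stopifnot(is.data.frame(db), "spectrum" %in% names(db))
  cleaned <- purrr::map(db$spectrum, function(s) {
    suppressWarnings(clean_spectrum(s, grid = grid), classes = "specfilt_warning_clip")
  })
  db$spectrum <- cleaned
  db$n_negative_clipped <- purrr::map_int(cleaned, ~ as.integer(attr(.x, "n_negative_clipped")))
  db$n_above_one_clipped <- purrr::map_int(cleaned, ~ as.integer(attr(.x, "n_above_one_clipped")))
  db
}

#' Compute metrics for every filter in a database
#'
#' Per-record failures are captured (column `metric_error`), not
#' propagated, so one corrupt spectrum does not abort a batch.
#'
#' @param db A filter database with cleaned spectra on the bundle grid.
#' @param bundle A `standards_bundle`.
#' @return A tibble of class `filter_metrics_tbl`: `db` without the
#'   `spectrum` list-column, joined with one metrics row per record.
#' @examples
#' \donttest{
#' b <- load_standards()
#' db <- synthetic_filter_database(n = 5, seed = 1) |> clean_database()
#' database_metrics(db, b)
#' }
#' @export
database_metrics <- function(db, bundle) {
  stopifnot(is.data.frame(db), "spectrum" %in% names(db))
  if (nrow(db) == 0) abort("Empty filter database.", class = "specfilt_error_data")
  res <- purrr::map(db$spectrum, function(s) {
    tryCatch(
      dplyr::mutate(filter_metrics(s, bundle), metric_error = NA_character_),
      error = function(e) {
        tibble::tibble(
          luminous_transmittance = NA_real_, melanopsin_transmittance = NA_real_,
          colour_shift = NA_real_, gamut_ratio = NA_real_,
          u_prime_filtered = NA_real_, v_prime_filtered = NA_real_,
          n_black_excluded = NA_integer_, degenerate_gamut = NA,
          metric_error = conditionMessage(e)
        )
      }
    )
  }) |> purrr::list_rbind()
  out <- dplyr::bind_cols(
    db[setdiff(names(db), "spectrum")],
    res
  )
  class(out) <- c("filter_metrics_tbl", class(tibble::tibble()))
  out
}

#' Correlation matrix of the four filter metrics
#'
#' Pairwise correlations among luminous transmittance, melanopsin
#' transmittance, colour shift and gamut ratio across a set of filters.
#' Metrics enter on their natural scales (fractions, u'v' distance);
#' correlations are scale-invariant. A metric with zero variance yields
#' `NA` in its row/column (flagged, not silently zeroed). Records with
#' any missing metric are dropped; `n` records the rows used.
#'
#' @param metrics A `filter_metrics_tbl` (or any data frame with the
#'   four metric columns).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `filter_cor`: list with `r` (4x4 matrix),
#'   `n`, `method`, `zero_variance` (character vector of degenerate
#'   variables, if any).
#' @examples
#' \donttest{
#' b <- load_standards()
#' db <- synthetic_filter_database(n = 20, seed = 1) |> clean_database()
#' metric_correlations(database_metrics(db, b))
#' }
#' @export
metric_correlations <- function(metrics, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  vars <- c(
    "luminous_transmittance", "melanopsin_transmittance",
    "colour_shift", "gamut_ratio"
  )
  stopifnot(all(vars %in% names(metrics)))
  m <- as.data.frame(metrics)[, vars]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) {
    abort("Need at least 3 records with complete metrics.",
      class = "specfilt_error_data"
    )
  }
  sds <- vapply(m, stats::sd, numeric(1))
  zv <- names(sds)[sds == 0]
  r <- suppressWarnings(stats::cor(m, method = method))
  r[zv, ] <- NA_real_
  r[, zv] <- NA_real_
  diag(r) <- 1
  structure(
    list(r = r, n = nrow(m), method = method, zero_variance = zv),
    class = "filter_cor"
  )
}

#' @export
print.filter_cor <- function(x, ...) {
  cat(sprintf(
    "<metric correlation matrix> method: %s, n = %d\n", x$method, x$n
  ))
  print(round(x$r, 3))
  if (length(x$zero_variance)) {
    cat("zero-variance (undefined):", paste(x$zero_variance, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy filter_cor
#' @export
tidy.filter_cor <- function(x, ...) {
  vars <- rownames(x$r)
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = vars[pairs[, 1]],
    var2 = vars[pairs[, 2]],
    estimate = x$r[pairs],
    method = x$method,
    n = x$n
  )
}

#' @method glance filter_cor
#' @export
glance.filter_cor <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  tibble::tibble(
    n = x$n, method = x$method,
    max_abs_r = max(abs(off), na.rm = TRUE),
    n_undefined = sum(is.na(off))
  )
}

#' Per-category metric summaries
#'
#' Median and interquartile range of each metric by filter category.
#' Categories with no records appear with `n = 0`.
#'
#' @param metrics A `filter_metrics_tbl`.
#' @return A tibble with columns `category`, `n`, `metric`, `median`,
#'   `q25`, `q75` (long over the four metrics).
#' @export
summarize_by_category <- function(metrics) {
  vars <- c(
    "luminous_transmittance", "melanopsin_transmittance",
    "colour_shift", "gamut_ratio"
  )
  stopifnot(all(c("category", vars) %in% names(metrics)))
  present <- unique(as.character(metrics$category))
  levels <- union(intersect(filter_categories(), present), present)
  long <- tibble::as_tibble(metrics) |>
    dplyr::mutate(category = factor(.data$category, levels = levels)) |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "metric", values_to = "value")
  counts <- tibble::as_tibble(metrics) |>
    dplyr::mutate(category = factor(.data$category, levels = levels)) |>
    dplyr::count(.data$category, .drop = FALSE, name = "n")
  long |>
    dplyr::summarise(
      median = stats::median(.data$value, na.rm = TRUE),
      q25 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q75 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      .by = c("category", "metric")
    ) |>
    dplyr::right_join(
      tidyr::expand_grid(category = factor(levels, levels = levels), metric = vars),
      by = c("category", "metric")
    ) |>
    dplyr::left_join(counts, by = "category") |>
    dplyr::select("category", "n", "metric", "median", "q25", "q75") |>
    dplyr::arrange(.data$category, .data$metric)
}

#' @method autoplot filter_metrics_tbl
#' @export
autoplot.filter_metrics_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$luminous_transmittance,
    y = .data$melanopsin_transmittance,
    colour = .data$category
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Luminous transmittance",
      y = "Melanopsin transmittance",
      colour = "Category"
    ) +
    ggplot2::theme_minimal()
}

#' Read a filter database from a directory of CSVs
#'
#' Layout: one CSV per filter plus a metadata CSV with columns `id`,
#' `category`, `filename` (paths relative to the directory).
#'
#' @param dir Directory containing the spectra.
#' @param meta Path to the metadata CSV (default `metadata.csv` inside
#'   `dir`).
#' @return A raw filter database tibble (uncleaned spectra).
#' @export
read_filter_database <- function(dir, meta = file.path(dir, "metadata.csv")) {
  if (!dir.exists(dir)) {
    abort(sprintf("Directory not found: %s", dir), class = "specfilt_error_io")
  }
  if (!file.exists(meta)) {
    abort(sprintf("Metadata file not found: %s", meta), class = "specfilt_error_io")
  }
  md <- readr::read_csv(meta, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "category", "filename")
  if (!all(need %in% names(md))) {
    abort(
      sprintf(
        "Metadata must have columns %s; found: %s",
        paste(need, collapse = ", "), paste(names(md), collapse = ", ")
      ),
      class = "specfilt_error_format"
    )
  }
  if (any(duplicated(md$id))) {
    abort("Duplicate filter ids in metadata.", class = "specfilt_error_data")
  }
  bad <- setdiff(unique(md$category), filter_categories())
  if (length(bad)) {
    abort(
      sprintf(
        "Unknown categories: %s (allowed: %s)",
        paste(bad, collapse = ", "), paste(filter_categories(), collapse = ", ")
      ),
      class = "specfilt_error_format"
    )
  }
  md |>
    dplyr::mutate(
      spectrum = purrr::map(.data$filename, ~ read_spectrum(file.path(dir, .x))),
      source_note = .data$filename
    ) |>
    dplyr::select("id", "category", "spectrum", "source_note")
}

#' Write a filter database's spectra and metadata to a directory
#'
#' Inverse of [read_filter_database()]: one CSV per filter plus
#' `metadata.csv`.
#'
#' @param db A filter database tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_filter_database <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  filenames <- paste0(db$id, ".csv")
  purrr::walk2(db$spectrum, filenames, ~ write_spectrum(.x, file.path(dir, .y)))
  readr::write_csv(
    tibble::tibble(id = db$id, category = db$category, filename = filenames),
    file.path(dir, "metadata.csv")
  )
  invisible(dir)
}
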