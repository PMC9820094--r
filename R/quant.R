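# Semi-quantitative BiFC analysis: background correction of emission
# spectra, the 530-534 nm peak-fluorescence metric, inter/intra ratio time
# courses, growth-phase averages, and phenomenological polynomial fits.

#' Subtract a control spectrum from a sample spectrum
#'
#' Pointwise subtraction of the non-fluorescent-control spectrum; negative
#' values are retained, not clipped.
#'
#' @param sample,control `spectrum` objects on identical wavelength grids.
#' @return The corrected `spectrum` (with `corrected = TRUE`).
#' @export
background_correct <- function(sample, control) {
  stopifnot(inherits(sample, "spectrum"), inherits(control, "spectrum"))
  if (length(sample$wavelengths) != length(control$wavelengths) ||
      any(sample$wavelengths != control$wavelengths)) {
    stop_param("sample and control wavelength grids differ")
  }
  out <- sample
  out$intensities <- sample$intensities - control$intensities
  out$corrected <- TRUE
  out
}

#' Peak fluorescence of a spectrum
#'
#' The mean intensity over the wavelength band (default 530-534 nm
#' inclusive, i.e. grid points 530, 532, 534 on the standard grid) — the
#' scalar per-spectrum readout of the semi-quantitative analysis.
#'
#' @param spectrum A `spectrum` (normally background-corrected).
#' @param band Length-2 numeric, inclusive band limits in nm.
#' @return Object of class `peak_fluorescence`: `value`, `band`,
#'   `corrected`.
#' @export
#' @examples
#' sp <- simulate_spectrum("reporter", spectrum_params(noise_sd = 0))
#' peak_fluorescence(sp)$value
peak_fluorescence <- function(spectrum, band = c(530, 534)) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (length(band) != 2L || band[1] > band[2]) {
    stop_param("`band` must be c(lower, upper)")
  }
  sel <- spectrum$wavelengths >= band[1] & spectrum$wavelengths <= band[2]
  if (!any(sel)) stop_param("band [%g, %g] nm contains no grid points",
                            band[1], band[2])
  structure(list(value = mean(spectrum$intensities[sel]), band = band,
                 corrected = isTRUE(spectrum$corrected)),
            class = "peak_fluorescence")
}

#' Peak-fluorescence series of a time course for one strain
#'
#' Convenience: background-corrects every spectrum of `strain` against the
#' time-matched control spectrum (if a control strain is present) and
#' returns the peak values over time.
#'
#' @param tc A `bifc_timecourse`.
#' @param strain Strain id.
#' @param control Control strain id, or `NULL` to skip correction.
#' @param band Peak band, nm.
#' @return `data.frame(time_h, value)`.
#' @export
peak_series <- function(tc, strain, control = "control", band = c(530, 534)) {
  stopifnot(inherits(tc, "bifc_timecourse"))
  pick <- function(s, t) {
    i <- which(vapply(tc$spectra, function(sp)
      identical(sp$strain, s) && isTRUE(sp$time_h == t), logical(1)))
    if (length(i) != 1L) stop_param("no unique spectrum for %s at t=%g h", s, t)
    tc$spectra[[i]]
  }
  times <- sort(unique(tc$data$time_h))
  vals <- vapply(times, function(t) {
    sp <- pick(strain, t)
    if (!is.null(control)) sp <- background_correct(sp, pick(control, t))
    peak_fluorescence(sp, band)$value
  }, numeric(1))
  data.frame(time_h = times, value = vals)
}

#' Inter/intra peak-fluorescence ratio time course
#'
#' Joins the two series on time (nearest neighbour within `time_tol` hours)
#' and divides.  Times where the intramolecular peak is not positive are
#' flagged undefined rather than dropped.
#'
#' @param inter,intra `data.frame(time_h, value)` peak series
#'   (intermolecular reporter and intramolecular reporter).
#' @param time_tol Join tolerance, hours.
#' @return Object of class `ratio_series`: `data.frame(time_h, inter,
#'   intra, ratio, defined)`.
#' @export
ratio_timecourse <- function(inter, intra, time_tol = 0.5) {
  stopifnot(is.data.frame(inter), is.data.frame(intra),
            all(c("time_h", "value") %in% names(inter)),
            all(c("time_h", "value") %in% names(intra)))
  idx <- vapply(inter$time_h, function(t) {
    d <- abs(intra$time_h - t)
    i <- which.min(d)
    if (d[i] <= time_tol) i else NA_integer_
  }, integer(1))
  if (all(is.na(idx))) stop_param("time grids of the two series are disjoint")
  keep <- !is.na(idx)
  df <- data.frame(time_h = inter$time_h[keep],
                   inter = inter$value[keep],
                   intra = intra$value[idx[keep]])
  df$defined <- df$intra > 0
  df$ratio <- ifelse(df$defined, df$inter / df$intra, NA_real_)
  structure(df[, c("time_h", "inter", "intra", "ratio", "defined")],
            class = c("ratio_series", "data.frame"))
}

#' Growth-phase averages of a ratio series
#'
#' Mean and SD of the defined ratios inside each time window.  When several
#' replicate series are supplied, the per-replicate window means are
#' averaged and the SD is across replicates (n - 1 denominator).
#'
#' @param series A `ratio_series`, or a list of replicate `ratio_series`.
#' @param windows Named list of `c(start_h, end_h)` windows; defaults to the
#'   exponential (5-25 h) and stationary (50-150 h) growth phases.
#' @return `data.frame(phase, mean, sd, n)`; windows containing no samples
#'   yield `NA` means and `n = 0` rather than an error.
#' @export
phase_averages <- function(series,
                           windows = list(exponential = c(5, 25),
                                          stationary = c(50, 150))) {
  reps <- if (inherits(series, "ratio_series")) list(series) else series
  stopifnot(length(reps) >= 1L,
            all(vapply(reps, inherits, logical(1), "ratio_series")))
  out <- lapply(names(windows), function(ph) {
    w <- windows[[ph]]
    means <- vapply(reps, function(s) {
      r <- s$ratio[s$defined & s$time_h >= w[1] & s$time_h <= w[2]]
      if (length(r) == 0L) NA_real_ else mean(r)
    }, numeric(1))
    if (length(reps) == 1L) {
      s <- reps[[1]]
      r <- s$ratio[s$defined & s$time_h >= w[1] & s$time_h <= w[2]]
      data.frame(phase = ph, mean = means[1],
                 sd = if (length(r) > 1L) stats::sd(r) else NA_real_,
                 n = length(r), stringsAsFactors = FALSE)
    } else {
      ok <- !is.na(means)
      data.frame(phase = ph, mean = mean(means[ok]),
                 sd = if (sum(ok) > 1L) stats::sd(means[ok]) else NA_real_,
                 n = sum(ok), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Phenomenological polynomial fit of a time series
#'
#' Least-squares polynomial (default degree 4) of value against time, as
#' used for smooth display of fluorescence time courses.  Fitted values are
#' only reported inside the data range (no extrapolation).
#'
#' @param time,value Numeric vectors.
#' @param degree Polynomial degree.
#' @return Object of class `phen_fit`: `coefficients` (ascending powers),
#'   `fitted`, `residuals`, `time_range`, and `predict(t)` restricted to
#'   the data range.
#' @export
#' @examples
#' t <- 0:10; y <- 2 + 0.5 * t - 0.04 * t^2
#' fit <- fit_phenomenological(t, y, degree = 2)
fit_phenomenological <- function(time, value, degree = 4L) {
  stopifnot(length(time) == length(value))
  if (length(time) < degree + 1L) {
    stop_param("need at least degree + 1 = %d points, got %d",
               degree + 1L, length(time))
  }
  fit <- stats::lm(value ~ poly(time, degree, raw = TRUE))
  rng <- range(time)
  co <- unname(stats::coef(fit))
  pred <- function(t) {
    if (any(t < rng[1] | t > rng[2])) {
      stop_param("prediction outside the fitted time range [%g, %g]",
                 rng[1], rng[2])
    }
    drop(outer(t, 0:degree, `^`) %*% co)
  }
  structure(list(coefficients = co, fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::residuals(fit)),
                 time_range = rng, degree = degree, predict = pred),
            class = "phen_fit")
}

#' @export
print.phen_fit <- function(x, ...) {
  cat(sprintf("<phen_fit> degree %d over [%g, %g] h, RMS residual %.4g\n",
              x$degree, x$time_range[1], x$time_range[2],
              sqrt(mean(x$residuals^2))))
  invisible(x)
}
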