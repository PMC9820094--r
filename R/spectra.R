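# Synthetic BiFC emission spectra and growth-phase time courses.  Spectra
# follow the microplate protocol this package models: emission recorded from
# 510 to 540 nm in 2 nm steps (16 grid points).  Time courses emulate
# cultures grown at different KCl concentrations, where the reporter
# fluorescence couples to the monomer/dimer composition of the transporter:
# the intramolecular reporter (VN/x/VC) reads out mostly monomers, the
# intermolecular pair (x/VN + x/VC) reads out dimers, and dimerisation rises
# during the stationary phase when K+ is not growth-limiting.

#' The standard emission wavelength grid
#'
#' @return Numeric vector, 510 to 540 nm in 2 nm steps (16 points).
#' @export
emission_grid <- function() seq(510, 540, by = 2)

#' Emission-spectrum simulation parameters
#'
#' @param wavelengths Wavelength grid, nm (default [emission_grid()]).
#' @param peak_center Emission peak position, nm (Venus-like, 528-534 nm).
#' @param peak_width Gaussian peak SD, nm.
#' @param amplitude Peak amplitude, a.u. (>= 0).
#' @param background_profile Per-wavelength baseline (recycled scalar
#'   allowed), a.u.
#' @param noise_sd Additive noise SD, a.u.
#' @param seed Default seed; `NULL` leaves the RNG untouched.
#' @return Object of class `spectrum_params`.
#' @export
spectrum_params <- function(wavelengths = emission_grid(),
                            peak_center = 530,
                            peak_width = 8,
                            amplitude = 100,
                            background_profile = 40,
                            noise_sd = 2,
                            seed = NULL) {
  if (length(wavelengths) < 2L || is.unsorted(wavelengths, strictly = TRUE)) {
    stop_param("`wavelengths` must be strictly increasing")
  }
  if (!(is.numeric(amplitude) && length(amplitude) == 1L && amplitude >= 0)) {
    stop_param("`amplitude` must be a single non-negative number")
  }
  check_positive_scalar(peak_width, "peak_width")
  check_nonneg_scalar(noise_sd, "noise_sd")
  bg <- rep_len(as.numeric(background_profile), length(wavelengths))
  structure(list(wavelengths = as.numeric(wavelengths),
                 peak_center = peak_center, peak_width = peak_width,
                 amplitude = amplitude, background_profile = bg,
                 noise_sd = noise_sd, seed = seed),
            class = "spectrum_params")
}

new_spectrum <- function(wavelengths, intensities, strain = NA_character_,
                         time_h = NA_real_, kcl_mM = NA_real_,
                         corrected = FALSE) {
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 strain = strain, time_h = time_h, kcl_mM = kcl_mM,
                 corrected = corrected), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s t=%sh: %d points, %.0f-%.0f nm%s\n",
              x$strain, format(x$time_h), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              if (x$corrected) " (background-corrected)" else ""))
  invisible(x)
}

#' Simulate an emission spectrum
#'
#' A reporter spectrum is the background profile plus a Gaussian-shaped
#' emission peak plus noise; a control spectrum (cells without fluorescent
#' protein) is background plus noise only.
#'
#' @param kind `"reporter"` or `"control"`.
#' @param params A [spectrum_params()].
#' @param seed Seed (default `params$seed`).
#' @return A `spectrum` object.
#' @export
#' @examples
#' sp <- simulate_spectrum("reporter", spectrum_params(seed = 1))
simulate_spectrum <- function(kind = c("reporter", "control"),
                              params = spectrum_params(),
                              seed = params$seed) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "spectrum_params"))
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  wl <- params$wavelengths
  base <- params$background_profile
  if (kind == "reporter") {
    base <- base + params$amplitude *
      exp(-(wl - params$peak_center)^2 / (2 * params$peak_width^2))
  }
  noise <- if (params$noise_sd > 0) stats::rnorm(length(wl), 0, params$noise_sd) else 0
  new_spectrum(wl, base + noise)
}

#' Growth and dimerisation scenario for a BiFC time course
#'
#' Encodes the culture conditions: logistic optical-density growth from an
#' inoculum of OD 0.1 (~1.1e6 cells/mL), a fluorophore-expression amplitude
#' that rises with the culture, a dimer fraction that rises logistically
#' into the stationary phase when KCl >= 1 mM but stays low and flat at
#' 0.1 mM, and (for 0.1 mM) a fluorescence decay after the late-exponential
#' peak.
#'
#' @param kcl_mM KCl concentration of the medium; one of 0.1, 1, 10, 100.
#' @param sample_times Measurement times, hours.
#' @param od0,od_max,od_rate Logistic OD parameters (inoculum, plateau,
#'   growth rate per hour).
#' @param expr_max,expr_mid,expr_scale Expression-amplitude logistic
#'   parameters (peak a.u., midpoint h, time scale h).
#' @param dimer_lo,dimer_hi,dimer_mid,dimer_scale Dimer-fraction curve:
#'   baseline, stationary plateau (used when `kcl_mM >= 1`), logistic
#'   midpoint and scale, hours.
#' @param decay_after_peak Logical; default `TRUE` only for 0.1 mM.
#' @param decay_peak_h,decay_tau_h Peak time and exponential decay time of
#'   the post-peak fluorescence decline, hours.
#' @return Object of class `growth_scenario`.
#' @export
growth_scenario <- function(kcl_mM = 1,
                            sample_times = c(4, 8, 12, 16, 20, 24, 30, 36,
                                             48, 60, 72, 96, 120, 144, 168),
                            od0 = 0.1, od_max = 2.5, od_rate = 0.35,
                            expr_max = 100, expr_mid = 15, expr_scale = 5,
                            dimer_lo = 0.12, dimer_hi = 0.75,
                            dimer_mid = 40, dimer_scale = 8,
                            decay_after_peak = (kcl_mM < 1),
                            decay_peak_h = 24, decay_tau_h = 60) {
  if (!kcl_mM %in% c(0.1, 1, 10, 100)) {
    stop_param("`kcl_mM` must be one of 0.1, 1, 10, 100")
  }
  stopifnot(all(sample_times >= 0), od0 > 0, od_max > od0)
  structure(list(kcl_mM = kcl_mM, sample_times = as.numeric(sample_times),
                 od0 = od0, od_max = od_max, od_rate = od_rate,
                 expr_max = expr_max, expr_mid = expr_mid,
                 expr_scale = expr_scale,
                 dimer_lo = dimer_lo, dimer_hi = dimer_hi,
                 dimer_mid = dimer_mid, dimer_scale = dimer_scale,
                 decay_after_peak = isTRUE(decay_after_peak),
                 decay_peak_h = decay_peak_h, decay_tau_h = decay_tau_h),
            class = "growth_scenario")
}

#' Optical density of a scenario at time t
#' @param scenario A `growth_scenario`.
#' @param t Time, hours.
#' @return OD600 values.
#' @export
scenario_od <- function(scenario, t) {
  with(scenario, od0 * od_max / (od0 + (od_max - od0) * exp(-od_rate * t)))
}

#' Expression amplitude of a scenario at time t
#' @inheritParams scenario_od
#' @return Amplitude, a.u.
#' @export
scenario_expression <- function(scenario, t) {
  e <- with(scenario, expr_max / (1 + exp(-(t - expr_mid) / expr_scale)))
  if (scenario$decay_after_peak) {
    e <- e * exp(-pmax(0, t - scenario$decay_peak_h) / scenario$decay_tau_h)
  }
  e
}

#' Dimer fraction of a scenario at time t
#' @inheritParams scenario_od
#' @return Fraction between 0 and 1.
#' @export
scenario_dimer_fraction <- function(scenario, t) {
  if (scenario$kcl_mM < 1) {
    rep(scenario$dimer_lo, length(t))
  } else {
    with(scenario, dimer_lo + (dimer_hi - dimer_lo) /
           (1 + exp(-(t - dimer_mid) / dimer_scale)))
  }
}

.bifc_strains <- c("YFP-full", "intra", "inter", "nc_inter", "control")

# Strain-specific coupling of peak amplitude to the monomer/dimer
# composition: intra reads monomers (plus a small dimer leak), inter reads
# dimers, nc_inter (N+C termini on separate monomers) is weakly
# dimer-coupled, YFP-full reads total expression, control reads nothing.
strain_coupling <- function(strain, dimer_fraction, eps_intra = 0.1) {
  switch(strain,
    "YFP-full" = rep(1, length(dimer_fraction)),
    intra = (1 - dimer_fraction) + eps_intra * dimer_fraction,
    inter = dimer_fraction,
    nc_inter = 0.02 + 0.08 * dimer_fraction,
    control = rep(0, length(dimer_fraction)),
    stop_param("unknown strain '%s'", strain)
  )
}

#' Simulate a growth-phase BiFC time course
#'
#' For every sample time and strain, generates one emission spectrum whose
#' peak amplitude is the expression amplitude times the strain-specific
#' coupling to the dimer fraction.  Ground truth (dimer fraction,
#' expression, couplings) is attached for recovery tests.
#'
#' @param scenario A [growth_scenario()].
#' @param strains Subset of `"YFP-full"`, `"intra"`, `"inter"`,
#'   `"nc_inter"`, `"control"`.
#' @param params A [spectrum_params()] supplying grid, peak shape,
#'   background and noise (its `amplitude` is ignored).
#' @param eps_intra Fractional dimer leak into the intramolecular reporter.
#' @param seed Seed for the whole time course.
#' @return Object of class `bifc_timecourse`: `spectra` (list of
#'   `spectrum`), `data` (long `data.frame`), `truth`
#'   (`data.frame(time_h, od, expression, dimer_fraction)`), `scenario`.
#' @export
#' @examples
#' tc <- simulate_bifc_timecourse(growth_scenario(1), c("intra", "inter"),
#'                                seed = 1)
simulate_bifc_timecourse <- function(scenario = growth_scenario(),
                                     strains = .bifc_strains,
                                     params = spectrum_params(),
                                     eps_intra = 0.1,
                                     seed = params$seed) {
  stopifnot(inherits(scenario, "growth_scenario"))
  bad <- setdiff(strains, .bifc_strains)
  if (length(bad) > 0L) {
    stop_param("unknown strain(s): %s", paste(bad, collapse = ", "))
  }
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  times <- scenario$sample_times
  expr <- scenario_expression(scenario, times)
  dimf <- scenario_dimer_fraction(scenario, times)
  spectra <- list()
  rows <- list()
  for (i in seq_along(times)) {
    for (s in strains) {
      amp <- expr[i] * strain_coupling(s, dimf[i], eps_intra)
      p <- params
      p$amplitude <- amp
      p$seed <- NULL
      sp <- simulate_spectrum(if (s == "control") "control" else "reporter", p,
                              seed = NULL)
      sp$strain <- s
      sp$time_h <- times[i]
      sp$kcl_mM <- scenario$kcl_mM
      spectra[[length(spectra) + 1L]] <- sp
      rows[[length(rows) + 1L]] <- data.frame(
        time_h = times[i], strain = s, kcl_mM = scenario$kcl_mM,
        wavelength_nm = sp$wavelengths, intensity = sp$intensities,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(
    spectra = spectra,
    data = do.call(rbind, rows),
    truth = data.frame(time_h = times, od = scenario_od(scenario, times),
                       expression = expr, dimer_fraction = dimf),
    scenario = scenario
  ), class = "bifc_timecourse")
}

#' @export
print.bifc_timecourse <- function(x, ...) {
  cat(sprintf("<bifc_timecourse> %.1f mM KCl, %d times x %d strains\n",
              x$scenario$kcl_mM, length(unique(x$data$time_h)),
              length(unique(x$data$strain))))
  invisible(x)
}

#' Write a time course as long-format CSV
#'
#' Columns `strain`, `time_h`, `kcl_mM`, `wavelength_nm`, `intensity`.
#'
#' @param tc A `bifc_timecourse`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "bifc_timecourse"))
  utils::write.table(
    tc$data[, c("strain", "time_h", "kcl_mM", "wavelength_nm", "intensity")],
    path, sep = ",", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
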