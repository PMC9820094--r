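test_that("parameter validation rejects degenerate trace settings", {
  expect_error(trace_params(n_frames = 0), "n_frames")
  expect_error(trace_params(amp_mean = -5), "amp_mean")
  expect_error(trace_params(mean_on_frames = 2000), "mean_on_frames")
  expect_error(trace_params(blink_off_rate = 1), "blink rates")
  expect_error(simulate_trace(-1, trace_params()), "n_emitters")
})

test_that("a spot with no emitters is pure background", {
  tr <- simulate_trace(0, trace_params(seed = 11))
  expect_length(tr$intensities, 1000L)
  expect_identical(tr$truth$n_emitters, 0L)
  expect_length(tr$truth$amplitude, 0L)
  expect_equal(mean(tr$intensities), 200, tolerance = 0.02)
})

test_that("simulated on-times and amplitudes recover the generative moments", {
  set.seed(301)
  p <- trace_params()
  on <- draws <- replicate(5000, {
    tr <- simulate_trace(1, p, seed = NULL)
    c(tr$truth$on_frames, tr$truth$amplitude)
  })
  on <- draws[1, ]; amp <- draws[2, ]
  # geometric on-time truncated at 1000 frames: E = 223 * (1 - (1-1/223)^1000)
  exp_on <- 223 * (1 - (1 - 1 / 223)^1000)
  expect_lt(abs(mean(on) - exp_on), 4 * sd(on) / sqrt(length(on)))
  expect_lt(abs(mean(amp) - 234.7), 4 * sd(amp) / sqrt(length(amp)))
  expect_lt(abs(sd(amp) - 47), 4)
})

test_that("the truncated-normal on-time mode matches the printed SD", {
  set.seed(302)
  p <- trace_params(on_time_model = "truncated_normal")
  on <- replicate(4000, simulate_trace(1, p, seed = NULL)$truth$on_frames)
  expect_lt(abs(mean(on) - 223), 4 * sd(on) / sqrt(length(on)))
  expect_lt(abs(sd(on) - 52), 5)
})

test_that("the expected initial level is additive in emitter count", {
  set.seed(303)
  p <- trace_params(blink = FALSE)
  first2 <- replicate(3000, simulate_trace(2, p, seed = NULL)$intensities[1])
  expect_equal(mean(first2), 200 + 2 * 234.7, tolerance = 0.02)
})

test_that("population composition follows the mixture", {
  pop <- simulate_population(mixture_spec(c(1, 0, 0), 100),
                             trace_params(n_frames = 20L, mean_on_frames = 10,
                                          seed = 5))
  expect_true(all(pop$truth$n_emitters == 1L))
  pop0 <- simulate_population(mixture_spec(c(0.5, 0.5, 0), 0), trace_params(seed = 1))
  expect_length(pop0$traces, 0L)
  # law of large numbers at 10^4 spots (short traces keep this cheap)
  pop <- simulate_population(mixture_spec(c(0.65, 0.35, 0), 10000L),
                             trace_params(n_frames = 10L, mean_on_frames = 5,
                                          seed = 6))
  se <- sqrt(0.65 * 0.35 / 10000)
  expect_lt(abs(mean(pop$truth$n_emitters == 1L) - 0.65), 3 * se)
  expect_error(mixture_spec(c(0.6, 0.3, 0.2)), "sum to 1")
})

test_that("simulation is bit-identical under a fixed seed and leaves the RNG stream alone", {
  p <- trace_params(seed = 99)
  t1 <- simulate_trace(2, p)
  set.seed(1234)
  before <- runif(1)
  t2 <- simulate_trace(2, p)
  expect_identical(t1, t2)
  set.seed(1234)
  expect_identical(runif(1), before)
  pop1 <- simulate_population(mixture_spec(c(0.5, 0.5, 0), 20), trace_params(seed = 7))
  pop2 <- simulate_population(mixture_spec(c(0.5, 0.5, 0), 20), trace_params(seed = 7))
  expect_identical(pop1$traces, pop2$traces)
})

test_that("the EMCCD noise model produces the requested mean with excess noise", {
  p <- trace_params(noise_model = "poisson_emccd", seed = 12)
  tr <- simulate_trace(0, p)
  expect_equal(mean(tr$intensities), 200, tolerance = 0.1)
  # gamma-amplified Poisson has variance ~ 2 * gain * mean (excess noise 2)
  expect_gt(var(tr$intensities), 1.3 * 30 * 200)
})

test_that("emission spectra follow the 16-point grid and peak construction", {
  expect_identical(emission_grid(), seq(510, 540, by = 2))
  expect_length(emission_grid(), 16L)
  sp <- simulate_spectrum("reporter", spectrum_params(seed = 1))
  expect_identical(sp$wavelengths, emission_grid())
  # zero-amplitude reporter is identical to the control under the same seed
  p0 <- spectrum_params(amplitude = 0)
  expect_identical(simulate_spectrum("reporter", p0, seed = 3)$intensities,
                   simulate_spectrum("control", p0, seed = 3)$intensities)
  # noiseless, background-free spectrum peaks at the configured centre
  p <- spectrum_params(noise_sd = 0, background_profile = 0,
                       amplitude = 7, peak_center = 532)
  sp <- simulate_spectrum("reporter", p)
  expect_equal(max(sp$intensities), 7)
  expect_identical(sp$wavelengths[which.max(sp$intensities)], 532)
  expect_error(spectrum_params(amplitude = -1), "amplitude")
})

test_that("growth scenarios produce the published qualitative patterns", {
  tc1 <- simulate_bifc_timecourse(growth_scenario(1), c("intra", "inter"), seed = 21)
  rs1 <- ratio_timecourse(peak_series(tc1, "inter", control = NULL),
                          peak_series(tc1, "intra", control = NULL))
  expect_lt(rs1$ratio[rs1$time_h == 12], 1)
  expect_gt(mean(rs1$ratio[rs1$time_h >= 50 & rs1$time_h <= 150]), 1)
  tc0 <- simulate_bifc_timecourse(growth_scenario(0.1), c("intra", "inter"), seed = 22)
  rs0 <- ratio_timecourse(peak_series(tc0, "inter", control = NULL),
                          peak_series(tc0, "intra", control = NULL))
  expect_true(all(rs0$ratio[rs0$defined] < 1))
  # OD never decreases; dimer fraction stays within [0, 1]
  sc <- growth_scenario(1)
  t <- seq(0, 170, by = 1)
  expect_true(all(diff(scenario_od(sc, t)) >= 0))
  expect_true(all(scenario_dimer_fraction(sc, t) >= 0 &
                    scenario_dimer_fraction(sc, t) <= 1))
})

test_that("the control strain yields peakless spectra", {
  tc <- simulate_bifc_timecourse(growth_scenario(1), c("control"),
                                 spectrum_params(noise_sd = 0), seed = 30)
  for (sp in tc$spectra) {
    expect_equal(sp$intensities, rep(40, 16))
  }
  expect_error(simulate_bifc_timecourse(growth_scenario(1), "nope"), "unknown strain")
})

test_that("time courses export as long-format CSV", {
  tc <- simulate_bifc_timecourse(growth_scenario(1), c("intra", "control"), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_timecourse(tc, path)
  df <- read.csv(path)
  expect_identical(names(df),
                   c("strain", "time_h", "kcl_mM", "wavelength_nm", "intensity"))
  expect_identical(nrow(df), 2L * length(tc$scenario$sample_times) * 16L)
})
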