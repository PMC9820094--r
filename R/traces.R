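# Synthetic stepwise-photobleaching traces.  Each diffraction-limited spot
# holds 1-3 GFP emitters; every emitter contributes a constant single-
# molecule amplitude until it irreversibly bleaches, with optional reversible
# blinking (telegraph dark states) before the bleach.  The generative
# statistics default to the acquisition statistics of the single-molecule
# experiments this package models: 1000 frames of 10 ms illumination,
# single-molecule amplitude 234.7 +/- 47 cnts/pix, mean pre-bleach on-time
# 223 frames.

#' Photobleaching trace simulation parameters
#'
#' @param n_frames Number of frames per trace.
#' @param frame_time Illumination time per frame, seconds.
#' @param amp_mean,amp_sd Mean and SD of the single-molecule amplitude
#'   (cnts/pix); amplitudes are drawn from a normal truncated at zero.
#' @param mean_on_frames Mean number of frames before an emitter bleaches.
#' @param on_time_model `"geometric"` (memoryless photobleaching; SD equals
#'   roughly the mean) or `"truncated_normal"` (matches an observed on-time
#'   SD via `on_sd`).
#' @param on_sd On-time SD for the truncated-normal model, frames.
#' @param blink Logical: enable two-state telegraph blinking.
#' @param blink_off_rate,blink_on_rate Per-frame switching probabilities
#'   (on to dark, dark to on).  Defaults give rare blinks with mean dark
#'   time of 5 frames, visibly shorter than bleaches.
#' @param background_mean,background_sd Camera background level and noise SD
#'   (cnts/pix).
#' @param noise_model `"gaussian"` or `"poisson_emccd"` (Poisson photon
#'   statistics with gamma-distributed electron-multiplying gain, excess
#'   noise factor 2).
#' @param emccd_gain EMCCD gain factor for the `poisson_emccd` model.
#' @param seed Default seed used by the simulators when they are not given
#'   one explicitly; `NULL` leaves the RNG stream untouched.
#' @return Object of class `trace_params`.
#' @export
trace_params <- function(n_frames = 1000L,
                         frame_time = 0.010,
                         amp_mean = 234.7,
                         amp_sd = 47,
                         mean_on_frames = 223,
                         on_time_model = c("geometric", "truncated_normal"),
                         on_sd = 52,
                         blink = TRUE,
                         blink_off_rate = 0.005,
                         blink_on_rate = 0.2,
                         background_mean = 200,
                         background_sd = 30,
                         noise_model = c("gaussian", "poisson_emccd"),
                         emccd_gain = 30,
                         seed = NULL) {
  on_time_model <- match.arg(on_time_model)
  noise_model <- match.arg(noise_model)
  check_positive_scalar(n_frames, "n_frames")
  check_positive_scalar(frame_time, "frame_time")
  check_positive_scalar(amp_mean, "amp_mean")
  check_nonneg_scalar(amp_sd, "amp_sd")
  check_positive_scalar(mean_on_frames, "mean_on_frames")
  if (mean_on_frames > n_frames) {
    stop_param("`mean_on_frames` must be in (0, n_frames]")
  }
  for (r in c(blink_off_rate, blink_on_rate)) {
    if (!(is.numeric(r) && length(r) == 1L && r >= 0 && r < 1)) {
      stop_param("blink rates must lie in [0, 1)")
    }
  }
  check_nonneg_scalar(background_mean, "background_mean")
  check_nonneg_scalar(background_sd, "background_sd")
  check_positive_scalar(emccd_gain, "emccd_gain")
  structure(list(
    n_frames = as.integer(n_frames), frame_time = frame_time,
    amp_mean = amp_mean, amp_sd = amp_sd,
    mean_on_frames = mean_on_frames, on_time_model = on_time_model,
    on_sd = on_sd, blink = isTRUE(blink),
    blink_off_rate = blink_off_rate, blink_on_rate = blink_on_rate,
    background_mean = background_mean, background_sd = background_sd,
    noise_model = noise_model, emccd_gain = emccd_gain, seed = seed
  ), class = "trace_params")
}

draw_amplitudes <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  a <- stats::rnorm(n, mean, sd)
  while (any(bad <- a <= 0)) a[bad] <- stats::rnorm(sum(bad), mean, sd)
  a
}

draw_on_frames <- function(n, params) {
  if (n == 0L) return(integer(0))
  k <- switch(params$on_time_model,
    geometric = stats::rgeom(n, prob = 1 / params$mean_on_frames) + 1L,
    truncated_normal = {
      x <- round(stats::rnorm(n, params$mean_on_frames, params$on_sd))
      while (any(bad <- x < 1)) {
        x[bad] <- round(stats::rnorm(sum(bad), params$mean_on_frames, params$on_sd))
      }
      as.integer(x)
    }
  )
  pmin(as.integer(k), params$n_frames)
}

# Per-frame on/off state of one emitter before its bleach frame.
telegraph_state <- function(on_frames, params) {
  state <- rep(TRUE, on_frames)
  if (!params$blink || params$blink_off_rate <= 0) return(state)
  u <- stats::runif(on_frames)
  s <- TRUE
  for (i in seq_len(on_frames)) {
    if (s) {
      if (u[i] < params$blink_off_rate) s <- FALSE
    } else {
      if (u[i] < params$blink_on_rate) s <- TRUE
    }
    state[i] <- s
  }
  state
}

#' Simulate one photobleaching trace
#'
#' Each emitter draws an amplitude (truncated normal), an on-time (frames
#' until bleach), and an optional telegraph blinking state sequence; the
#' trace is background plus the summed amplitude of emitters that are alive
#' and in the fluorescent state, plus camera noise.
#'
#' @param n_emitters Number of emitters in the spot (>= 0).
#' @param params A [trace_params()] object.
#' @param seed Seed for this trace (default: `params$seed`).  Identical
#'   parameters and seed give an identical trace.
#' @param spot_id Optional spot label.
#' @return Object of class `sp_trace`: `intensities`, `frame_time`,
#'   `spot_id`, and ground truth `truth` (`n_emitters`, per-emitter
#'   `amplitude`, `on_frames`, `n_blinks`).
#' @export
#' @examples
#' tr <- simulate_trace(2, trace_params(seed = 1))
#' plot(tr$intensities, type = "l")
simulate_trace <- function(n_emitters, params = trace_params(),
                           seed = params$seed, spot_id = "spot") {
  stopifnot(inherits(params, "trace_params"))
  if (!(is.numeric(n_emitters) && length(n_emitters) == 1L && n_emitters >= 0)) {
    stop_param("`n_emitters` must be a single non-negative count")
  }
  n_emitters <- as.integer(n_emitters)
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)

  n <- params$n_frames
  signal <- numeric(n)
  amp <- draw_amplitudes(n_emitters, params$amp_mean, params$amp_sd)
  on_frames <- draw_on_frames(n_emitters, params)
  n_blinks <- integer(n_emitters)
  for (e in seq_len(n_emitters)) {
    state <- telegraph_state(on_frames[e], params)
    signal[seq_len(on_frames[e])] <- signal[seq_len(on_frames[e])] + amp[e] * state
    n_blinks[e] <- sum(diff(state) == -1L)
  }
  intensities <- switch(params$noise_model,
    gaussian = params$background_mean + signal +
      stats::rnorm(n, 0, params$background_sd),
    poisson_emccd = {
      lambda <- (params$background_mean + signal) / params$emccd_gain
      photons <- stats::rpois(n, lambda)
      out <- numeric(n)
      pos <- photons > 0
      out[pos] <- stats::rgamma(sum(pos), shape = photons[pos],
                                scale = params$emccd_gain)
      out
    }
  )
  structure(list(
    intensities = intensities,
    frame_time = params$frame_time,
    spot_id = spot_id,
    truth = list(n_emitters = n_emitters, amplitude = amp,
                 on_frames = on_frames, n_blinks = n_blinks)
  ), class = "sp_trace")
}

#' @export
print.sp_trace <- function(x, ...) {
  cat(sprintf("<sp_trace> %s: %d frames, %d emitter(s)\n",
              x$spot_id, length(x$intensities), x$truth$n_emitters))
  invisible(x)
}

#' Specify an emitter-count mixture
#'
#' @param fractions Numeric vector of population fractions over 1, 2, 3
#'   emitters per spot; must be non-negative and sum to 1 (tolerance 1e-9).
#' @param n_spots Number of spots to simulate.
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(fractions = c(0.65, 0.35, 0), n_spots = 1000L) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop_param("`fractions` must be non-negative and sum to 1")
  }
  if (!(is.numeric(n_spots) && length(n_spots) == 1L && n_spots >= 0)) {
    stop_param("`n_spots` must be a single non-negative count")
  }
  structure(list(fractions = as.numeric(fractions),
                 n_spots = as.integer(n_spots)),
            class = "mixture_spec")
}

#' Simulate a population of spots
#'
#' Assigns each spot an emitter count drawn from the mixture and simulates
#' its trace.  With a fixed seed, the whole population is reproducible.
#'
#' @param mix A [mixture_spec()].
#' @param params A [trace_params()].
#' @param seed Seed for the whole population (default `params$seed`).
#' @return Object of class `trace_population`: `traces` (list of
#'   `sp_trace`), `truth` (`data.frame(spot_id, n_emitters)`), `mix`,
#'   `params`.
#' @export
#' @examples
#' pop <- simulate_population(mixture_spec(c(1, 0, 0), 10), trace_params(seed = 1))
#' table(pop$truth$n_emitters)
simulate_population <- function(mix, params = trace_params(), seed = params$seed) {
  stopifnot(inherits(mix, "mixture_spec"), inherits(params, "trace_params"))
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  sizes <- seq_along(mix$fractions)
  n_emitters <- if (mix$n_spots > 0L) {
    sample(sizes, mix$n_spots, replace = TRUE, prob = mix$fractions)
  } else integer(0)
  traces <- vector("list", mix$n_spots)
  for (i in seq_len(mix$n_spots)) {
    traces[[i]] <- simulate_trace(n_emitters[i], params, seed = NULL,
                                  spot_id = sprintf("spot_%05d", i))
  }
  structure(list(
    traces = traces,
    truth = data.frame(spot_id = vapply(traces, `[[`, character(1), "spot_id"),
                       n_emitters = as.integer(n_emitters),
                       stringsAsFactors = FALSE),
    mix = mix, params = params, seed = seed
  ), class = "trace_population")
}

#' @export
print.trace_population <- function(x, ...) {
  cat(sprintf("<trace_population> %d spots x %d frames\n",
              length(x$traces), x$params$n_frames))
  invisible(x)
}

#' Write traces as long-format TSV
#'
#' Columns `spot_id`, `frame` (0-based), `intensity`.
#'
#' @param traces A `trace_population` or list of `sp_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "trace_population")) traces <- traces$traces
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(spot_id = tr$spot_id,
               frame = seq_along(tr$intensities) - 1L,
               intensity = tr$intensities, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read traces from long-format TSV
#'
#' @param path TSV with columns `spot_id`, `frame`, `intensity`.
#' @param frame_time Frame illumination time (seconds) to attach.
#' @return List of `sp_trace` (without ground truth).
#' @export
read_traces <- function(path, frame_time = 0.010) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("spot_id", "frame", "intensity")
  if (!all(need %in% names(df))) {
    stop_param("trace file must have columns: %s", paste(need, collapse = ", "))
  }
  lapply(split(df, df$spot_id), function(d) {
    d <- d[order(d$frame), ]
    structure(list(intensities = d$intensity, frame_time = frame_time,
                   spot_id = d$spot_id[1], truth = NULL), class = "sp_trace")
  })
}
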