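# Emitter counting from a step fit, and population aggregation.  Every
# downward level change is a candidate bleach step; an upward change that
# matches a recent downward change in amplitude is a blink (the emitter
# returned from a reversible dark state), and the matched pair is not
# counted as a bleach.  The emitter count is the number of unpaired
# downward steps.

#' Emitter-counting configuration
#'
#' @param blink_tol Relative amplitude tolerance for pairing an upward step
#'   with a preceding downward step as a blink.
#' @param max_dark_gap Maximum dark interval (frames) between the paired
#'   down and up steps.
#' @param max_emitters Counts above this are flagged as aggregates.
#' @param level_tol Mismatch tolerance (in unit amplitudes) between the
#'   initial level and `n_emitters x unit amplitude` before a spot is
#'   flagged.
#' @return Object of class `count_config`.
#' @export
count_config <- function(blink_tol = 0.35, max_dark_gap = 50L,
                         max_emitters = 4L, level_tol = 1.5) {
  check_positive_scalar(blink_tol, "blink_tol")
  check_positive_scalar(max_dark_gap, "max_dark_gap")
  check_positive_scalar(max_emitters, "max_emitters")
  check_positive_scalar(level_tol, "level_tol")
  structure(list(blink_tol = blink_tol, max_dark_gap = as.integer(max_dark_gap),
                 max_emitters = as.integer(max_emitters), level_tol = level_tol),
            class = "count_config")
}

#' Count emitters from a step fit
#'
#' Classifies each downward level change as a bleach step, pairs upward
#' changes with preceding downward changes of comparable amplitude (within
#' `blink_tol`, dark gap at most `max_dark_gap` frames) as blinks, and
#' counts the unpaired downward steps as emitters.  The unit amplitude is
#' the median unpaired downward step size.
#'
#' @param fit A `step_fit` from [detect_steps()].
#' @param config A [count_config()].
#' @return Object of class `emitter_count`: `n_emitters`, `n_bleach_steps`,
#'   `n_blink_events`, `unit_amplitude_estimate`, `step_amplitudes`
#'   (unpaired downward magnitudes), `qc_flags` (character vector, possibly
#'   empty).
#' @export
count_emitters <- function(fit, config = count_config()) {
  stopifnot(inherits(fit, "step_fit"), inherits(config, "count_config"))
  if (length(fit$levels) == 0L) stop_param("empty step fit")

  k <- length(fit$change_points)
  qc <- character(0)
  if (k == 0L) {
    return(structure(list(n_emitters = 0L, n_bleach_steps = 0L,
                          n_blink_events = 0L,
                          unit_amplitude_estimate = NA_real_,
                          step_amplitudes = numeric(0), qc_flags = qc),
                     class = "emitter_count"))
  }
  delta <- diff(fit$levels)
  pos <- fit$change_points
  is_down <- delta < 0
  paired_down <- rep(FALSE, k)
  paired_up <- rep(FALSE, k)
  for (j in which(!is_down)) {
    # candidate preceding unpaired down steps, closest first
    cand <- which(is_down & !paired_down & seq_len(k) < j)
    for (i in rev(cand)) {
      if (pos[j] - pos[i] > config$max_dark_gap) break
      if (abs(abs(delta[j]) - abs(delta[i])) <=
            config$blink_tol * abs(delta[i])) {
        paired_down[i] <- TRUE
        paired_up[j] <- TRUE
        break
      }
    }
  }
  bleach_idx <- which(is_down & !paired_down)
  amps <- abs(delta[bleach_idx])
  n_emit <- length(bleach_idx)
  n_blink <- sum(paired_up)
  if (any(!is_down & !paired_up)) qc <- c(qc, "unpaired_rise")
  unit <- if (n_emit > 0) stats::median(amps) else stats::median(abs(delta[is_down]))
  if (n_emit > config$max_emitters) qc <- c(qc, "aggregate")
  if (n_emit > 0 && is.finite(unit)) {
    baseline <- fit$levels[length(fit$levels)]
    expected0 <- baseline + n_emit * unit
    if (abs(fit$levels[1] - expected0) > config$level_tol * unit) {
      qc <- c(qc, "level_mismatch")
    }
  }
  structure(list(n_emitters = as.integer(n_emit),
                 n_bleach_steps = as.integer(n_emit),
                 n_blink_events = as.integer(n_blink),
                 unit_amplitude_estimate = unit,
                 step_amplitudes = amps, qc_flags = qc),
            class = "emitter_count")
}

#' @export
print.emitter_count <- function(x, ...) {
  cat(sprintf("<emitter_count> %d emitter(s), %d blink(s), unit amplitude %s\n",
              x$n_emitters, x$n_blink_events,
              format(round(x$unit_amplitude_estimate, 1))))
  if (length(x$qc_flags)) cat("  QC:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Population-summary configuration
#'
#' @param n_boot Bootstrap resamples for the fraction confidence intervals.
#' @param conf_level Confidence level.
#' @param exclude_flagged Drop QC-flagged spots before aggregation.
#' @param seed Seed for the bootstrap.
#' @return Object of class `summary_config`.
#' @export
summary_config <- function(n_boot = 2000L, conf_level = 0.95,
                           exclude_flagged = FALSE, seed = NULL) {
  check_positive_scalar(n_boot, "n_boot")
  stopifnot(conf_level > 0, conf_level < 1)
  structure(list(n_boot = as.integer(n_boot), conf_level = conf_level,
                 exclude_flagged = isTRUE(exclude_flagged), seed = seed),
            class = "summary_config")
}

#' Aggregate per-spot emitter counts into population fractions
#'
#' Builds the histogram of emitter counts, the fractions over spots with at
#' least one detected emitter, and percentile bootstrap confidence
#' intervals for each fraction (resampling spots).
#'
#' @param counts List of `emitter_count` objects, or an integer vector of
#'   per-spot counts.
#' @param config A [summary_config()].
#' @return Object of class `population_summary`: `histogram` (named counts
#'   over 0..max), `fractions` (`data.frame(n_emitters, fraction, lower,
#'   upper)` over counts >= 1), `n_spots`, `n_used`, `n_excluded`.
#' @export
#' @examples
#' summarize_population(c(1L, 1L, 1L, 2L))
summarize_population <- function(counts, config = summary_config()) {
  stopifnot(inherits(config, "summary_config"))
  if (is.list(counts)) {
    if (length(counts) == 0L) stop_param("empty count list")
    flagged <- vapply(counts, function(cc) length(cc$qc_flags) > 0, logical(1))
    n <- vapply(counts, function(cc) cc$n_emitters, integer(1))
  } else {
    if (length(counts) == 0L) stop_param("empty count list")
    flagged <- rep(FALSE, length(counts))
    n <- as.integer(counts)
  }
  n_all <- length(n)
  if (config$exclude_flagged) n <- n[!flagged]
  hist_all <- table(factor(n, levels = 0:max(n, 1L)))
  used <- n[n >= 1L]
  if (length(used) == 0L) stop_param("no spots with detected emitters")

  cats <- sort(unique(used))
  obs <- as.numeric(table(factor(used, levels = cats)))
  frac <- obs / length(used)

  restore <- set_local_seed(config$seed)
  on.exit(restore(), add = TRUE)
  boot <- stats::rmultinom(config$n_boot, size = length(used), prob = frac)
  boot_frac <- boot / length(used)
  alpha <- (1 - config$conf_level) / 2
  ci <- t(apply(boot_frac, 1L, stats::quantile, probs = c(alpha, 1 - alpha)))

  structure(list(
    histogram = hist_all,
    fractions = data.frame(n_emitters = cats, fraction = frac,
                           lower = ci[, 1], upper = ci[, 2],
                           row.names = NULL),
    n_spots = n_all, n_used = length(used),
    n_excluded = n_all - length(n)
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %d spots (%d used)\n", x$n_spots, x$n_used))
  print(transform(x$fractions,
                  fraction = round(fraction, 3),
                  lower = round(lower, 3), upper = round(upper, 3)))
  invisible(x)
}

#' Run the full counting pipeline over a trace population
#'
#' [detect_steps()] and [count_emitters()] on every trace, then
#' [summarize_population()].
#'
#' @param population A `trace_population` or list of `sp_trace`.
#' @param step_cfg A [step_config()].
#' @param count_cfg A [count_config()].
#' @param summary_cfg A [summary_config()].
#' @return List with `counts` (per-spot `emitter_count`) and `summary`
#'   (`population_summary`).
#' @export
count_population <- function(population,
                             step_cfg = step_config(),
                             count_cfg = count_config(),
                             summary_cfg = summary_config()) {
  traces <- if (inherits(population, "trace_population")) population$traces
            else population
  counts <- lapply(traces, function(tr) {
    count_emitters(detect_steps(tr, step_cfg), count_cfg)
  })
  list(counts = counts, summary = summarize_population(counts, summary_cfg))
}
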