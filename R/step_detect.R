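# Bleaching-step detection: exact penalized piecewise-constant segmentation
# of a spot trace.  The penalty is BIC-style, proportional to the noise
# variance and log(n); the variance is estimated robustly from first
# differences (median absolute deviation / sqrt(2)), which is insensitive
# to the steps themselves.

#' Step-detection configuration
#'
#' @param penalty Explicit penalty per change point; `NULL` (default) uses
#'   `penalty_mult * sigma^2 * log(n)` with `sigma` estimated by
#'   `mad(diff(x)) / sqrt(2)`.
#' @param penalty_mult Penalty multiplier for the automatic penalty.
#' @param min_seg_len Minimum segment length, frames.
#' @return Object of class `step_config`.
#' @export
step_config <- function(penalty = NULL, penalty_mult = 2, min_seg_len = 1L) {
  if (!is.null(penalty)) check_positive_scalar(penalty, "penalty")
  check_positive_scalar(penalty_mult, "penalty_mult")
  check_positive_scalar(min_seg_len, "min_seg_len")
  structure(list(penalty = penalty, penalty_mult = penalty_mult,
                 min_seg_len = as.integer(min_seg_len)),
            class = "step_config")
}

trace_intensities <- function(trace) {
  if (inherits(trace, "sp_trace")) trace$intensities else as.numeric(trace)
}

#' Detect intensity steps in a photobleaching trace
#'
#' Finds the segmentation minimizing the sum of within-segment squared
#' deviations plus `penalty` per change point, exactly (pruned dynamic
#' programming).  Deterministic for a given trace and configuration.
#'
#' @param trace An `sp_trace` or numeric vector of intensities.
#' @param config A [step_config()].
#' @return Object of class `step_fit`: `change_points` (0-based, strictly
#'   increasing; a change point at `k` separates frames `k-1` and `k`),
#'   `levels` (per-segment means), `cost` (penalized score), `penalty`,
#'   `n`.
#' @export
#' @examples
#' x <- c(rep(500, 10), rep(250, 10), rep(0, 30))
#' detect_steps(x)$change_points  # 10, 20
detect_steps <- function(trace, config = step_config()) {
  x <- trace_intensities(trace)
  if (length(x) < 2L) stop_param("trace must have at least 2 frames")
  if (any(!is.finite(x))) stop_param("trace contains non-finite values")
  stopifnot(inherits(config, "step_config"))

  penalty <- config$penalty
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(x)) / sqrt(2)
    if (sigma <= 0) {
      # noiseless trace: any strictly positive penalty recovers the exact
      # piecewise-constant segmentation with the fewest change points
      sigma2 <- 1e-8 * max(1, mean(abs(x)))^2
    } else {
      sigma2 <- sigma^2
    }
    penalty <- config$penalty_mult * sigma2 * log(length(x))
  }
  cps <- pelt_mean_cpp(x, penalty, config$min_seg_len)
  bounds <- c(0L, cps, length(x))
  levels <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(x[(bounds[i] + 1L):bounds[i + 1L]])
  }, numeric(1))
  rss <- sum(vapply(seq_len(length(bounds) - 1L), function(i) {
    seg <- x[(bounds[i] + 1L):bounds[i + 1L]]
    sum((seg - mean(seg))^2)
  }, numeric(1)))
  structure(list(change_points = as.integer(cps), levels = levels,
                 cost = rss + penalty * length(cps), penalty = penalty,
                 n = length(x)),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit> %d change point(s) over %d frames\n",
              length(x$change_points), x$n))
  if (length(x$change_points)) {
    cat("  at:", paste(x$change_points, collapse = ", "), "\n")
  }
  cat("  levels:", paste(round(x$levels, 1), collapse = ", "), "\n")
  invisible(x)
}
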