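# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @useDynLib oligostate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rgeom rbinom rmultinom median mad sd quantile lm coef predict residuals rgamma rpois
#' @importFrom utils head tail write.table read.table
NULL

# Seed a computation locally: returns a restore function so that callers do
# not disturb the caller's RNG stream. seed = NULL leaves the RNG alone.
set_local_seed <- function(seed) {
  if (is.null(seed)) {
    return(function() invisible(NULL))
  }
  if (!(is.numeric(seed) && length(seed) == 1L && is.finite(seed))) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  function() {
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
    invisible(NULL)
  }
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive_scalar <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0)) {
    stop_param("`%s` must be a single positive finite number (got %s)",
               name, paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0)) {
    stop_param("`%s` must be a single non-negative finite number", name)
  }
  invisible(x)
}

# 2-D rotation matrix
rot2 <- function(angle) {
  matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
}

# Apply a rigid pose (rotation then translation) to an n x 2 coordinate matrix.
apply_pose <- function(xy, pose) {
  xy <- matrix(xy, ncol = 2L)
  sweep(xy %*% t(rot2(pose$angle)), 2L, pose$shift, "+")
}
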