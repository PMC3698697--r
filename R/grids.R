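#' Acquisition-time grid for a CPMG echo train
#'
#' Builds the vector of echo acquisition times `t_i = i * echo_spacing`,
#' `i = 1..m`. Times are in milliseconds throughout the package.
#'
#' @param echo_spacing Echo spacing (delta t) in ms; must be positive.
#'   The default 0.1 ms (100 microseconds) together with `m = 16384` echoes
#'   gives a 1638.4 ms acquisition window, long enough to observe decays with
#'   T2 of several hundred ms.
#' @param m Number of echoes (positive integer).
#' @return An object of class `time_grid`: a list with elements `times`
#'   (length-`m` numeric, strictly increasing), `echo_spacing`, and `m`.
#' @examples
#' tg <- build_time_grid(0.1, 16384)
#' tail(tg$times, 1)  # 1638.4
#' @export
build_time_grid <- function(echo_spacing = 0.1, m = 16384) {
  if (!is.numeric(echo_spacing) || length(echo_spacing) != 1 || echo_spacing <= 0)
    stop_invalid("'echo_spacing' must be a positive scalar (ms)")
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != as.integer(m))
    stop_invalid("'m' must be a positive integer")
  m <- as.integer(m)
  structure(list(times = seq_len(m) * echo_spacing,
                 echo_spacing = echo_spacing, m = m),
            class = "time_grid")
}

## Wrap explicit acquisition times (e.g. pruned or read from file).
time_grid_from_times <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 1 || any(!is.finite(times)) || any(times <= 0) ||
      any(diff(times) <= 0))
    stop_invalid("acquisition times must be positive, finite and strictly increasing")
  structure(list(times = times,
                 echo_spacing = if (length(times) > 1) times[2] - times[1] else times[1],
                 m = length(times)),
            class = "time_grid")
}

#' Logarithmic relaxation-time (T2) grid
#'
#' Builds `n` log-spaced relaxation-time constants between `t2_min` and
#' `t2_max` (both included exactly), i.e. with a constant ratio between
#' neighbouring grid points.
#'
#' The default range 0.1--10000 ms with 256 points brackets the T2 values seen
#' in typical LR-NMR samples (roughly 1--600 ms) with a wide margin on both
#' sides, so peaks near the range of interest are never squeezed against a
#' grid boundary.
#'
#' @param t2_min,t2_max Grid endpoints in ms, `0 < t2_min < t2_max`.
#' @param n Number of grid points (>= 2).
#' @return An object of class `t2_grid`: a list with elements `constants`
#'   (strictly increasing numeric of length `n`) and `n`.
#' @examples
#' build_t2_grid(1, 100, 3)$constants  # 1 10 100
#' @export
build_t2_grid <- function(t2_min = 0.1, t2_max = 1e4, n = 256) {
  if (!is.numeric(t2_min) || !is.numeric(t2_max) || t2_min <= 0 || t2_max <= t2_min)
    stop_invalid("need 0 < t2_min < t2_max")
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != as.integer(n))
    stop_invalid("'n' must be an integer >= 2")
  n <- as.integer(n)
  constants <- exp(seq(log(t2_min), log(t2_max), length.out = n))
  constants[1] <- t2_min
  constants[n] <- t2_max
  structure(list(constants = constants, n = n), class = "t2_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d echoes, spacing %g ms, window %g ms\n",
              x$m, x$echo_spacing, x$times[x$m]))
  invisible(x)
}

#' @export
print.t2_grid <- function(x, ...) {
  cat(sprintf("<t2_grid> %d log-spaced T2 constants in [%g, %g] ms\n",
              x$n, x$constants[1], x$constants[x$n]))
  invisible(x)
}
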