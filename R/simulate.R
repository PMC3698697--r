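#' Parametric description of a ground-truth spectrum
#'
#' A synthetic T2 spectrum is a sum of Gaussian peaks placed on the log T2
#' grid: `centers` give the peak positions in ms, `amplitudes` the relative
#' peak heights, and `width_std` the common Gaussian standard deviation
#' measured in grid-index units (so a width of 2 spans a couple of bins of
#' the 256-point log grid regardless of where the peak sits).
#'
#' @param centers Peak T2 positions in ms.
#' @param amplitudes Relative peak heights (> 0); recycled to the number of
#'   centers. Default: equal amplitudes.
#' @param width_std Gaussian standard deviation in grid-index units (> 0).
#' @param snr Target signal-to-noise ratio (`Inf` for noise-free).
#' @param seed Integer seed controlling the noise realization.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(centers, amplitudes = 1, width_std = 2,
                           snr = Inf, seed = 1L) {
  centers <- as.numeric(centers)
  amplitudes <- rep_len(as.numeric(amplitudes), length(centers))
  if (length(centers) < 1 || any(centers <= 0))
    stop_invalid("'centers' must be positive T2 values (ms)")
  if (any(amplitudes <= 0)) stop_invalid("'amplitudes' must be > 0")
  if (!is.numeric(width_std) || width_std <= 0)
    stop_invalid("'width_std' must be > 0")
  if (!is.numeric(snr) || is.na(snr) || snr <= 0)
    stop_invalid("'snr' must be > 0 (Inf for noise-free)")
  structure(list(centers = centers, amplitudes = amplitudes,
                 width_std = width_std, snr = snr, seed = as.integer(seed)),
            class = "synthetic_spec")
}

## Reference three-peak narrow signals: intrinsic T2 values in ms.
## Signals 1..5 share the middle peak; the outer peaks close in progressively,
## signal5 being the hardest (adjacent-peak ratios both ~2.47).
.narrow_signal_centers <- list(
  signal1 = c(1.44, 21.54, 323.45),
  signal2 = c(2.25, 21.54, 205.93),
  signal3 = c(3.54, 21.54, 131.11),
  signal4 = c(5.56, 21.54, 83.48),
  signal5 = c(8.73, 21.54, 53.15))

#' Reference narrow three-peak signals
#'
#' Named constructors for the five standard narrow-peak test signals used for
#' calibration and accuracy studies. Each has three Gaussian peaks; the outer
#' peaks move closer to the fixed middle peak (21.54 ms) from `signal1` to
#' `signal5`, whose adjacent-peak T2 ratios are both about 2.47 — close to
#' the resolution limit at moderate SNR.
#'
#' @param width_std,snr,seed Passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
signal1 <- function(width_std = 2, snr = Inf, seed = 1L)
  synthetic_spec(.narrow_signal_centers$signal1, 1, width_std, snr, seed)

#' @rdname signal1
#' @export
signal2 <- function(width_std = 2, snr = Inf, seed = 1L)
  synthetic_spec(.narrow_signal_centers$signal2, 1, width_std, snr, seed)

#' @rdname signal1
#' @export
signal3 <- function(width_std = 2, snr = Inf, seed = 1L)
  synthetic_spec(.narrow_signal_centers$signal3, 1, width_std, snr, seed)

#' @rdname signal1
#' @export
signal4 <- function(width_std = 2, snr = Inf, seed = 1L)
  synthetic_spec(.narrow_signal_centers$signal4, 1, width_std, snr, seed)

#' @rdname signal1
#' @export
signal5 <- function(width_std = 2, snr = Inf, seed = 1L)
  synthetic_spec(.narrow_signal_centers$signal5, 1, width_std, snr, seed)

#' Realize a ground-truth spectrum on a T2 grid
#'
#' Evaluates the Gaussian peaks of a [synthetic_spec()] in grid-index space:
#' `f_j = sum_k a_k * exp(-(j - j_k)^2 / (2 * width_std^2))`, where `j_k` is
#' the grid index nearest to the k-th peak center. Because the grid is
#' logarithmic, an index-space Gaussian is a log-normal-shaped bump in T2.
#'
#' @param spec A `synthetic_spec`.
#' @param grid A [build_t2_grid()].
#' @return Numeric spectrum of length `grid$n`.
#' @export
make_spectrum <- function(spec, grid) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(grid, "t2_grid"))
  rng <- range(grid$constants)
  if (any(spec$centers < rng[1] | spec$centers > rng[2]))
    stop_invalid("peak centers must lie inside the T2 grid range")
  j <- seq_len(grid$n)
  f <- numeric(grid$n)
  for (k in seq_along(spec$centers)) {
    jk <- which.min(abs(log(grid$constants) - log(spec$centers[k])))
    f <- f + spec$amplitudes[k] * exp(-(j - jk)^2 / (2 * spec$width_std^2))
  }
  f
}

#' Forward CPMG simulation
#'
#' Computes the clean multiexponential decay
#' `s_i = sum_j f_j * exp(-t_i / T_j)` — the unnormalized physical forward
#' model, so the first-echo amplitude approaches `sum(f)` as `t -> 0`.
#'
#' @param f Spectrum values on `t2g`.
#' @param tg A [build_time_grid()].
#' @param t2g A [build_t2_grid()].
#' @return Object of class `echo_train`: list with `times` (`time_grid`),
#'   `amplitudes`, `noise_component` (zero here), `realized_snr` (`Inf`).
#' @export
forward_simulate <- function(f, tg, t2g) {
  stopifnot(inherits(tg, "time_grid"), inherits(t2g, "t2_grid"))
  f <- as.numeric(f)
  if (length(f) != t2g$n) stop_invalid("length(f) must equal the T2 grid size")
  s <- drop(exp(-outer(tg$times, t2g$constants, "/")) %*% f)
  structure(list(times = tg, amplitudes = s,
                 noise_component = numeric(tg$m), realized_snr = Inf),
            class = "echo_train")
}

#' @export
print.echo_train <- function(x, ...) {
  cat(sprintf("<echo_train> %d echoes, first amplitude %.4g, realized SNR %.4g\n",
              x$times$m, x$amplitudes[1], x$realized_snr))
  invisible(x)
}

#' Add white noise at a target SNR
#'
#' Adds independent zero-mean Gaussian noise with standard deviation
#' `max(clean amplitudes) / target_snr` — the standard additive
#' white-noise model for LR-NMR echo trains. The realized SNR is re-estimated
#' from the noisy train via [estimate_snr()]. The caller's RNG state is left
#' untouched; the same seed gives a bit-identical train.
#'
#' @param clean An `echo_train` (its `noise_component` must be zero).
#' @param target_snr Target SNR > 0, or `Inf` to return the input unchanged.
#' @param seed Integer seed.
#' @return A noisy `echo_train`.
#' @export
add_noise <- function(clean, target_snr, seed = 1L) {
  stopifnot(inherits(clean, "echo_train"))
  if (!is.numeric(target_snr) || is.na(target_snr) || target_snr <= 0)
    stop_invalid("'target_snr' must be > 0 (Inf for no noise)")
  if (!is.finite(target_snr)) return(clean)
  sdev <- max(clean$amplitudes) / target_snr
  noise <- with_local_seed(seed, rnorm(clean$times$m, sd = sdev))
  out <- clean
  out$amplitudes <- clean$amplitudes + noise
  out$noise_component <- noise
  out$realized_snr <- suppressWarnings(estimate_snr(out))
  out
}

#' Simulate a noisy echo train from a synthetic spectrum
#'
#' Convenience pipeline: [make_spectrum()] then [forward_simulate()] then
#' [add_noise()] at the spec's SNR and seed.
#'
#' @param spec A [synthetic_spec()].
#' @param tg,t2g Grids (defaults: 16384 echoes at 0.1 ms, 256-point log T2
#'   grid on 0.1--10000 ms).
#' @return List with `train` (noisy `echo_train`), `truth` (spectrum on
#'   `t2g`) and the grids.
#' @export
simulate_train <- function(spec, tg = build_time_grid(), t2g = build_t2_grid()) {
  truth <- make_spectrum(spec, t2g)
  clean <- forward_simulate(truth, tg, t2g)
  train <- add_noise(clean, spec$snr, spec$seed)
  list(train = train, truth = truth, tg = tg, t2g = t2g)
}

#' Two-peak resolution series
#'
#' The 12-member series used to probe the resolution limit: one peak is fixed
#' at 81.54 ms while the second sits at 27.53, 30.03, 32.75, 35.73, 38.97,
#' 42.51, 46.36, 50.57, 55.16, 60.16, 65.62 or 71.58 ms, ordered from the
#' farthest pair (T2 ratio about 2.96) to the closest (about 1.14). Both
#' peaks have equal amplitude.
#'
#' @param width_std Gaussian width in grid-index units.
#' @param snr Target SNR for every member.
#' @param seed Seed stored in every member (vary it externally for repeats).
#' @return List of 12 [synthetic_spec()] objects, attribute `ratios` giving
#'   the fixed/moving T2 ratio of each member.
#' @export
two_peak_series <- function(width_std = 2, snr = Inf, seed = 1L) {
  fixed <- 81.54
  moving <- c(27.53, 30.03, 32.75, 35.73, 38.97, 42.51,
              46.36, 50.57, 55.16, 60.16, 65.62, 71.58)
  specs <- lapply(moving, function(pos)
    synthetic_spec(c(pos, fixed), 1, width_std, snr, seed))
  attr(specs, "ratios") <- fixed / moving
  specs
}

#' Broad-peak reference signal
#'
#' A synthetic stand-in for the broad unimodal distribution typical of an L2
#' (Tikhonov) solution of an oil sample: a single wide log-normal-shaped bump
#' (Gaussian of standard deviation ~20 grid indices on the log T2 grid)
#' centered near 150 ms. The shape is a parametric construct with the stated
#' qualitative character, not an empirical distribution.
#'
#' @param snr Target SNR.
#' @param seed Noise seed.
#' @param center Peak center in ms.
#' @param width_std Width in grid-index units.
#' @return A [synthetic_spec()].
#' @export
broad_peak_spec <- function(snr = 1000, seed = 1L, center = 150, width_std = 20) {
  synthetic_spec(center, 1, width_std, snr, seed)
}
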