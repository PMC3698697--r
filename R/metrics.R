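#' Estimate the signal-to-noise ratio of an echo train
#'
#' Signal is the maximum of an 8-point moving average of the amplitudes.
#' Noise is taken from the last 1024 echoes, where the decay has died out:
#' the tail is linearly detrended (best-fit straight line in echo index
#' removed, correcting any residual slope/offset) and the noise is the
#' root-mean-square of what remains. The estimate is their ratio.
#'
#' For trains shorter than 1032 echoes (8 for the signal window plus the
#' 1024-echo tail) the tail shrinks to `min(1024, floor(m / 4))` with a
#' warning. If the detrended tail is exactly zero the train is noise-free and
#' the infinite-SNR sentinel `Inf` is returned.
#'
#' @param train An `echo_train` or a plain numeric amplitude vector.
#' @return Estimated SNR (scalar), or `Inf` for a zero-noise tail.
#' @export
estimate_snr <- function(train) {
  x <- if (inherits(train, "echo_train")) train$amplitudes else as.numeric(train)
  m <- length(x)
  if (m < 8) stop_invalid("need at least 8 echoes to estimate the signal")
  win <- 8L
  mov <- (cumsum(x)[win:m] - c(0, cumsum(x)[1:(m - win)])) / win
  signal <- max(mov)

  tail_len <- 1024L
  if (m < 1032L) {
    tail_len <- max(2L, min(1024L, floor(m / 4)))
    warning("train shorter than 1032 echoes: noise tail shrunk to ",
            tail_len, " points", call. = FALSE)
  }
  tail_idx <- (m - tail_len + 1L):m
  yt <- x[tail_idx]
  it <- seq_along(yt)
  fit <- lm.fit(cbind(1, it), yt)
  resid <- fit$residuals
  noise <- sqrt(mean(resid^2))
  if (noise == 0) return(Inf)
  signal / noise
}

#' Repeatability via the coefficient of variation
#'
#' For `k >= 2` repeated spectra on a common T2 grid, the per-bin coefficient
#' of variation is `cv_i = 100 * sd_i / mean_i` (sample standard deviation
#' over the repeats). To measure the stability of the signal rather than of
#' baseline noise, the mean cv is taken only over bins whose mean value
#' exceeds `threshold_frac` times the maximum of the mean spectrum. Mean cv
#' values of up to about 15% are conventionally considered acceptable
#' stability.
#'
#' @param reps Numeric k x n matrix (rows = repeated measurements' spectra).
#' @param threshold_frac Fraction of the mean-spectrum maximum (in (0, 1),
#'   typically 0.25 or 0.10).
#' @return Mean cv in percent over the selected bins.
#' @export
compute_cv <- function(reps, threshold_frac = 0.25) {
  reps <- as.matrix(reps)
  if (nrow(reps) < 2) stop_invalid("need at least 2 repeated measurements")
  if (!is.numeric(threshold_frac) || threshold_frac <= 0 || threshold_frac >= 1)
    stop_invalid("'threshold_frac' must be in (0, 1)")
  mu <- colMeans(reps)
  sdv <- apply(reps, 2, sd)
  keep <- mu > threshold_frac * max(mu)
  if (!any(keep)) stop_invalid("no bin exceeds the threshold")
  mean(100 * sdv[keep] / mu[keep])
}

#' Detect peaks in a spectrum
#'
#' Strict local maxima of the spectrum above `min_height_frac * max(f)`.
#' Flat-topped maxima (plateaus) report their middle bin; the first and last
#' bins are never peaks. The default height floor of 1% of the maximum
#' ignores low-level numerical dust left by the interior-point solver.
#'
#' @param spec An `ilt_spectrum` or numeric vector.
#' @param min_height_frac Height floor as a fraction of the maximum.
#' @return Data frame with columns `bin`, `t2` (NA when the grid is unknown)
#'   and `height`; zero rows for an all-zero spectrum.
#' @export
find_peaks <- function(spec, min_height_frac = 0.01) {
  f <- if (inherits(spec, "ilt_spectrum")) spec$f else as.numeric(spec)
  t2 <- if (inherits(spec, "ilt_spectrum")) spec$t2 else NULL
  n <- length(f)
  empty <- data.frame(bin = integer(0), t2 = numeric(0), height = numeric(0))
  if (n < 3 || max(f) <= 0) return(empty)
  floor_h <- min_height_frac * max(f)

  bins <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (f[i] > f[i - 1L]) {
      j <- i
      while (j < n && f[j + 1L] == f[j]) j <- j + 1L   # walk the plateau
      if (j < n && f[j + 1L] < f[j]) {                 # strict fall: a maximum
        mid <- as.integer(floor((i + j) / 2))
        if (f[mid] >= floor_h) bins <- c(bins, mid)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(bin = bins,
             t2 = if (is.null(t2)) rep(NA_real_, length(bins)) else t2[bins],
             height = f[bins])
}

#' Two-peak resolution-limit sweep
#'
#' Determines the smallest T2 ratio at which two peaks of a given width can
#' still be separated at a given SNR and regularization. For each member of
#' the [two_peak_series()] (fixed peak 81.54 ms, moving peak closing in) and
#' each seed, a noisy echo train is simulated, logarithmically pruned,
#' inverted with weights from [compute_lambdas()], and its peak maxima
#' counted via [find_peaks()]. A separation is "resolved" when the majority
#' of seeds yield at least two detected maxima. The limit is the T2 ratio of
#' the smallest separation such that it and every larger separation are
#' resolved, rounded to two decimals.
#'
#' @param width_std Peak width in grid-index units (2--5 in the standard
#'   designs).
#' @param snr Target SNR (`Inf` simulates noise-free trains and uses
#'   near-zero weights).
#' @param alpha1,alpha2 Calibration constants for the weights.
#' @param seeds Integer vector of noise seeds (default 1:5; majority vote).
#' @param tg,t2g,prune Simulation time grid, inversion T2 grid, and pruned
#'   train length.
#' @param min_height_frac Peak-detection floor.
#' @param options Solver options.
#' @return Object of class `resolution_result`: list with `width_std`,
#'   `snr`, `alpha2`, `limit_ratio` (NA when nothing is resolved) and
#'   `per_separation`, a data frame with one row per candidate (moving-peak
#'   T2, ratio, seeds resolving it, resolved flag).
#' @export
resolution_limit <- function(width_std, snr, alpha1 = 10, alpha2 = 5,
                             seeds = 1:5,
                             tg = build_time_grid(), t2g = build_t2_grid(),
                             prune = 256L, min_height_frac = 0.01,
                             options = solver_options()) {
  if (!is.numeric(width_std) || width_std <= 0) stop_invalid("'width_std' must be > 0")
  if (!is.numeric(snr) || snr <= 0) stop_invalid("'snr' must be > 0")
  series <- two_peak_series(width_std, snr)
  ratios <- attr(series, "ratios")

  ## all members share the time grid: prune indices and kernel are reusable
  idx <- log_prune_indices(tg$m, prune)
  tg_p <- time_grid_from_times(tg$times[idx])
  kern <- build_kernel(tg_p, t2g)

  n_two <- integer(length(series))
  for (k in seq_along(series)) {
    spec <- series[[k]]
    truth <- make_spectrum(spec, t2g)
    clean <- forward_simulate(truth, tg, t2g)
    for (sd_i in seeds) {
      noisy <- if (is.finite(snr)) {
        spec_k <- spec; spec_k$seed <- as.integer(sd_i)
        add_noise(clean, snr, spec_k$seed)
      } else clean
      s <- noisy$amplitudes[idx]
      lam <- if (is.finite(snr))
        suppressWarnings(compute_lambdas(s, snr, alpha1, alpha2))
      else list(lambda1 = 1e-8, lambda2 = 1e-8)
      fit <- suppressWarnings(solve_inversion(
        inversion_model(kern, s, lam$lambda1, lam$lambda2), options))
      npk <- nrow(find_peaks(fit, min_height_frac))
      if (npk >= 2) n_two[k] <- n_two[k] + 1L
      if (!is.finite(snr)) {          # noise-free: seeds are identical
        n_two[k] <- n_two[k] * length(seeds)
        break
      }
    }
  }
  resolved <- n_two > length(seeds) / 2
  ## longest resolved run starting from the farthest separation
  run <- which(!resolved)
  last_ok <- if (length(run) == 0) length(series) else run[1] - 1L
  limit <- if (last_ok >= 1) round(ratios[last_ok], 2) else NA_real_

  structure(list(width_std = width_std, snr = snr,
                 alpha1 = alpha1, alpha2 = alpha2,
                 limit_ratio = limit,
                 per_separation = data.frame(
                   moving_t2 = vapply(series, function(s) s$centers[1], 0),
                   ratio = round(ratios, 2),
                   seeds_resolved = n_two,
                   resolved = resolved)),
            class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat(sprintf("<resolution_result> width %g, SNR %g, alpha2 %g: limit ratio %s\n",
              x$width_std, x$snr, x$alpha2,
              if (is.na(x$limit_ratio)) "unresolved" else format(x$limit_ratio)))
  print(x$per_separation)
  invisible(x)
}
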