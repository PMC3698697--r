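#' Logarithmic pruning of an echo train
#'
#' Long CPMG trains are subsampled to a fixed length before inversion: the
#' target indices are geometrically spaced over `[1, m]` (always including
#' the first and last echo), rounded to integers, de-duplicated, and then
#' backfilled with the smallest unused indices until exactly `n_out` remain.
#' Early echoes — where the geometric targets collide after rounding — thus
#' end up sampled densely (near-linearly), late echoes sparsely, matching the
#' information content of an exponential decay.
#'
#' @param train An `echo_train`.
#' @param n_out Number of echoes to keep (<= m; default 256).
#' @return The pruned `echo_train`.
#' @export
log_prune <- function(train, n_out = 256L) {
  stopifnot(inherits(train, "echo_train"))
  idx <- log_prune_indices(train$times$m, n_out)
  out <- train
  out$times <- time_grid_from_times(train$times$times[idx])
  out$amplitudes <- train$amplitudes[idx]
  out$noise_component <- train$noise_component[idx]
  out
}

#' @rdname log_prune
#' @param m Train length from which to draw indices.
#' @return `log_prune_indices`: strictly increasing integer indices of length
#'   `n_out`, including 1 and `m`.
#' @export
log_prune_indices <- function(m, n_out = 256L) {
  if (!is.numeric(m) || m < 1) stop_invalid("'m' must be >= 1")
  if (!is.numeric(n_out) || n_out < 1 || n_out > m)
    stop_invalid("'n_out' must be in [1, m]")
  m <- as.integer(m); n_out <- as.integer(n_out)
  if (n_out == m) return(seq_len(m))
  if (n_out == 1L) return(m)
  targets <- round(m^(seq(0, 1, length.out = n_out)))
  idx <- unique(pmin(pmax(as.integer(targets), 1L), m))
  if (length(idx) < n_out) {
    unused <- setdiff(seq_len(m), idx)
    idx <- sort(c(idx, unused[seq_len(n_out - length(idx))]))
  }
  idx
}

#' Read and write echo trains and spectra as delimited text
#'
#' Echo-train files are two numeric columns (time in ms, amplitude), with an
#' optional header row; comma and tab delimiters are auto-detected. Spectrum
#' files carry (T2 ms, f) columns. Values are written with 15 significant
#' digits so a write/read round trip preserves them to at least 12.
#'
#' @param path File path.
#' @param dialect `"auto"` (default), `"csv"` or `"tsv"`.
#' @return `read_echo_train`: an `echo_train`.
#' @export
read_echo_train <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  first <- readLines(path, n = 1L)
  sep <- switch(dialect, csv = ",", tsv = "\t",
                auto = if (grepl("\t", first)) "\t" else ",")
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(fields))))
  df <- read.table(path, sep = sep, header = header,
                   colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2) stop_invalid("expected two columns (time ms, amplitude)")
  tms <- suppressWarnings(as.numeric(df[[1]]))
  amp <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(is.na(tms) | is.na(amp))
  if (length(bad) > 0)
    stop_invalid("non-numeric value at data line ", bad[1], " of ", path)
  nonmono <- which(diff(tms) <= 0)
  if (length(nonmono) > 0)
    stop_invalid("acquisition times not strictly increasing at data line ",
                 nonmono[1] + 1L, " of ", path)
  structure(list(times = time_grid_from_times(tms), amplitudes = amp,
                 noise_component = numeric(length(amp)), realized_snr = NA_real_),
            class = "echo_train")
}

#' @rdname read_echo_train
#' @param train An `echo_train` to write.
#' @export
write_echo_train <- function(train, path) {
  stopifnot(inherits(train, "echo_train"))
  df <- data.frame(time_ms = format(train$times$times, digits = 15, trim = TRUE),
                   amplitude = format(train$amplitudes, digits = 15, trim = TRUE))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_echo_train
#' @param spec An `ilt_spectrum` (or list with `t2` and `f`) to write.
#' @export
write_spectrum <- function(spec, path) {
  t2 <- spec$t2
  if (is.null(t2)) t2 <- rep(NA_real_, length(spec$f))
  df <- data.frame(t2_ms = format(t2, digits = 15, trim = TRUE),
                   amplitude = format(spec$f, digits = 15, trim = TRUE))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_echo_train
#' @export
read_spectrum <- function(path, dialect = c("auto", "csv", "tsv")) {
  tr <- read_echo_train(path, dialect)
  list(t2 = tr$times$times, f = tr$amplitudes)
}

#' Invert an echo train end to end
#'
#' The standard pipeline: logarithmically prune the train, build the
#' normalized Laplace kernel on the pruned times, derive the regularization
#' weights from the SNR via the universal calibration (or use explicit
#' weights), and solve the non-negative sparse inversion.
#'
#' @param train An `echo_train`.
#' @param t2g Inversion T2 grid.
#' @param snr SNR driving the weights; `NULL` estimates it from the (full)
#'   train via [estimate_snr()].
#' @param alpha1,alpha2 Calibration constants; `alpha1 = 0` gives the
#'   L2-only mode (no sparsity term).
#' @param lambda1,lambda2 Explicit weights overriding the calibration.
#' @param prune Pruned length (set to the train length to disable).
#' @param kernel Optional precomputed kernel on the pruned time grid (reused
#'   across repeated inversions with identical grids).
#' @param options Solver options.
#' @return An `ilt_spectrum` (see [solve_inversion()]).
#' @export
invert_echo_train <- function(train, t2g = build_t2_grid(), snr = NULL,
                              alpha1 = 10, alpha2 = 5,
                              lambda1 = NULL, lambda2 = NULL,
                              prune = 256L, kernel = NULL,
                              options = solver_options()) {
  stopifnot(inherits(train, "echo_train"))
  if (is.null(snr) && (is.null(lambda1) || is.null(lambda2)))
    snr <- estimate_snr(train)
  pruned <- if (prune < train$times$m) log_prune(train, prune) else train
  if (is.null(kernel)) kernel <- build_kernel(pruned$times, t2g)
  if (is.null(lambda1) || is.null(lambda2)) {
    if (alpha1 == 0) {
      lam2 <- if (is.finite(snr)) alpha2 / snr else 0
      lambda1 <- 0
      lambda2 <- lam2
      if (is.finite(snr) && snr < 150)
        warning("SNR below 150 is outside the validated calibration range",
                call. = FALSE)
    } else {
      lam <- compute_lambdas(pruned$amplitudes, snr, alpha1, alpha2)
      lambda1 <- lam$lambda1
      lambda2 <- lam$lambda2
    }
  }
  solve_inversion(inversion_model(kernel, pruned$amplitudes, lambda1, lambda2),
                  options)
}
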