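#' Discretized Laplace kernel
#'
#' Builds the m x n exponential-decay operator with entries
#' `K[i, j] = exp(-t_i / T_j)` mapping a discrete T2 distribution to the clean
#' CPMG decay sampled at the acquisition times. With `normalize = TRUE`
#' (default) the matrix is divided by its maximum entry so that
#' `max(K) == 1`; the scale factor is retained so amplitudes can be restored.
#'
#' @param tg A [build_time_grid()] object (rows).
#' @param t2g A [build_t2_grid()] object (columns).
#' @param normalize Divide by the maximum entry (the largest entry is the one
#'   at the earliest time and the slowest T2).
#' @return An object of class `laplace_kernel`: list with `matrix` (m x n),
#'   `row_times` (`time_grid`), `col_constants` (`t2_grid`) and `scale`
#'   (the divisor applied; 1 when `normalize = FALSE`).
#' @examples
#' K <- build_kernel(build_time_grid(1, 10), build_t2_grid(1, 100, 8))
#' max(K$matrix)  # 1
#' @export
build_kernel <- function(tg, t2g, normalize = TRUE) {
  stopifnot(inherits(tg, "time_grid"), inherits(t2g, "t2_grid"))
  M <- exp(-outer(tg$times, t2g$constants, "/"))
  scale <- 1
  if (isTRUE(normalize)) {
    scale <- max(M)
    M <- M / scale
  }
  structure(list(matrix = M, row_times = tg, col_constants = t2g, scale = scale),
            class = "laplace_kernel")
}

#' @export
print.laplace_kernel <- function(x, ...) {
  cat(sprintf("<laplace_kernel> %d x %d, scale %.6g\n",
              nrow(x$matrix), ncol(x$matrix), x$scale))
  invisible(x)
}

#' Truncated singular value decomposition of the kernel
#'
#' Computes the full SVD `K = U diag(sigma) V'` and the best rank-`r`
#' approximation (the partial sum of the first `r` singular triplets). By the
#' Eckart--Young theorem the spectral-norm error of the truncation equals
#' `sigma[r + 1]` (zero when `r = n`). Truncation stabilizes the inversion
#' because the solution error is amplified by the reciprocals of the retained
#' singular values.
#'
#' @param K A `laplace_kernel` (or plain matrix).
#' @param r Number of singular components to retain, `1 <= r <= min(m, n)`.
#' @return List with `factors` (class `svd_factors`: `u`, `d`, `v`, `rank`)
#'   and `kernel`, the rank-`r` kernel (same class/metadata as the input when
#'   the input was a `laplace_kernel`).
#' @export
svd_compress <- function(K, r) {
  M <- if (inherits(K, "laplace_kernel")) K$matrix else as.matrix(K)
  nmin <- min(dim(M))
  if (!is.numeric(r) || length(r) != 1 || r < 1 || r > nmin || r != as.integer(r))
    stop_invalid("'r' must be an integer in [1, min(m, n)]")
  r <- as.integer(r)
  sv <- svd(M)
  factors <- structure(list(u = sv$u, d = sv$d, v = sv$v, rank = r),
                       class = "svd_factors")
  Mr <- sv$u[, seq_len(r), drop = FALSE] %*%
    (sv$d[seq_len(r)] * t(sv$v[, seq_len(r), drop = FALSE]))
  out <- K
  if (inherits(K, "laplace_kernel")) out$matrix <- Mr else out <- Mr
  list(factors = factors, kernel = out)
}

#' Tikhonov filter factors
#'
#' The weights `w(sigma) = sigma^2 / (sigma^2 + lambda)` by which L2 (ridge)
#' regularization damps each singular component of the solution: large
#' singular values pass almost unchanged (`w` near 1), small ones are smoothly
#' suppressed, the half-power point sitting at `sigma^2 = lambda`. SVD
#' truncation is the sharp-cutoff counterpart of this smooth damping.
#'
#' @param singular_values Non-negative numeric vector.
#' @param lam Regularization weight `lambda >= 0` (on the squared-norm scale;
#'   see [solve_inversion()] for how it relates to `lambda2`).
#' @return Numeric vector of weights in `[0, 1]`, non-decreasing in `sigma`.
#'   The degenerate case `sigma = 0, lambda = 0` is defined as 0.
#' @export
tikhonov_weights <- function(singular_values, lam) {
  if (any(singular_values < 0)) stop_invalid("singular values must be >= 0")
  if (!is.numeric(lam) || length(lam) != 1 || lam < 0)
    stop_invalid("'lam' must be a scalar >= 0")
  s2 <- singular_values^2
  w <- s2 / (s2 + lam)
  w[s2 == 0] <- 0
  w
}

#' Tikhonov (L2-only) solution via the SVD
#'
#' Closed-form unconstrained ridge solution
#' `f = V diag(sigma / (sigma^2 + lambda)) U' s`, i.e. the least-squares SVD
#' solution with each coefficient damped by the filter factor
#' `w(sigma) = sigma^2 / (sigma^2 + lambda)`. Used as the reference for the
#' solver's L2-only mode.
#'
#' @param K `laplace_kernel` or matrix.
#' @param s Measurement vector (length m).
#' @param lam Ridge weight on the squared-norm scale.
#' @return Numeric solution vector of length n.
#' @export
tikhonov_solve <- function(K, s, lam) {
  M <- if (inherits(K, "laplace_kernel")) K$matrix else as.matrix(K)
  sv <- svd(M)
  coefs <- sv$d / (sv$d^2 + lam) * crossprod(sv$u, s)
  drop(sv$v %*% coefs)
}
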