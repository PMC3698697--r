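## Independent oracles and shared fixtures for the solver tests.

## Exact solution of  min 0.5||Kf - s||^2 + l1*sum(f) + 0.5*l2*||f||^2, f >= 0
## by exhaustive enumeration of active sets (feasible for n <= ~12): for each
## support S solve the equality-constrained stationarity system and keep the
## KKT-feasible candidate with the smallest objective.
enum_nnqp_oracle <- function(K, s, l1, l2) {
  n <- ncol(K)
  G <- crossprod(K) + diag(l2, n)
  h <- drop(crossprod(K, s)) - l1
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    f <- numeric(n)
    if (length(S) > 0) {
      fs <- tryCatch(solve(G[S, S, drop = FALSE], h[S]), error = function(e) NULL)
      if (is.null(fs) || any(fs < 0)) next
      f[S] <- fs
    }
    if (all(drop(G %*% f) - h > -1e-9)) {
      obj <- 0.5 * sum((drop(K %*% f) - s)^2) + l1 * sum(f) + 0.5 * l2 * sum(f^2)
      if (obj < best_obj) {
        best_obj <- obj
        best <- f
      }
    }
  }
  list(f = best, objective = best_obj)
}

## Deterministic Gaussian noise the length of x, without touching the
## caller's RNG stream.
with_seed_noise <- function(x, seed, sd) {
  sparseilt:::with_local_seed(seed, rnorm(length(x), sd = sd))
}

## Small shared inversion fixture: pruned decay kernel with a two-spike truth.
small_fixture <- function(m = 200, n = 32, bins = c(12, 22), dt = 0.5,
                          t2_min = 1, t2_max = 1000) {
  tg <- build_time_grid(dt, m)
  t2g <- build_t2_grid(t2_min, t2_max, n)
  K <- build_kernel(tg, t2g)
  f0 <- numeric(n)
  f0[bins] <- 1
  list(K = K, t2g = t2g, tg = tg, f0 = f0, s = drop(K$matrix %*% f0))
}

## Shared pruned-acquisition setup matching the standard analysis pipeline
## (16384 echoes at 0.1 ms, pruned to 256, 256-point T2 grid). Built once per
## test run.
standard_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tg <- build_time_grid()
      t2g <- build_t2_grid()
      idx <- log_prune_indices(tg$m, 256)
      cache <<- list(tg = tg, t2g = t2g, idx = idx,
                     kern = build_kernel(sparseilt:::time_grid_from_times(tg$times[idx]),
                                         t2g))
    }
    cache
  }
})
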