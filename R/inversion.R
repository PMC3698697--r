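#' Regularized inversion problem
#'
#' Describes the non-negative L1+L2-regularized inverse Laplace problem
#' \deqn{\min_c\; \tfrac12\|K B c - s\|_2^2 + \lambda_1\|c\|_1 +
#'       \tfrac12\lambda_2\|c\|_2^2 \quad \mathrm{s.t.}\; f = Bc,\; f \ge 0,}
#' where `K` is the discretized Laplace kernel, `s` the measured echo
#' amplitudes and `B` a sparsifying dictionary. With the identity dictionary
#' (`B = NULL`, the default) the sparsity penalty acts on the spectrum `f`
#' itself, which suits sharp well-localized peaks; a non-identity `B` (e.g.
#' Gaussian atoms of several widths) makes `c` the sparse object instead.
#'
#' Note the L2 weight convention: `lambda2` multiplies the squared norm
#' directly (entering the interior-point template as
#' `D1 = sqrt(lambda2) * I`), so the L2-only mode (`lambda1 = 0`, bounds
#' released) coincides with the Tikhonov filtered-SVD solution at filter
#' weight `lambda = lambda2` — the same `lambda` as in
#' [tikhonov_weights()]. The universal calibration of [compute_lambdas()]
#' is defined with respect to this convention.
#'
#' @param kernel A [build_kernel()] object (or plain m x n matrix).
#' @param s Measurement vector of length m (signal units).
#' @param lambda1 L1 weight, >= 0.
#' @param lambda2 L2 weight, >= 0 (direct ridge weight; see above).
#' @param B Dictionary: `NULL` for identity, else an n x p matrix.
#' @param nonneg_c Constrain the coefficients `c` themselves to be
#'   non-negative. For the identity dictionary this is the physical
#'   non-negativity of the spectrum and defaults to `TRUE`. Setting it to
#'   `FALSE` with `lambda1 = 0` gives the unconstrained ridge (Tikhonov)
#'   problem; with `lambda1 > 0` the coefficients are sign-split internally.
#' @return Object of class `inversion_model`.
#' @export
inversion_model <- function(kernel, s, lambda1, lambda2, B = NULL,
                            nonneg_c = TRUE) {
  M <- if (inherits(kernel, "laplace_kernel")) kernel$matrix else as.matrix(kernel)
  s <- as.numeric(s)
  if (length(s) != nrow(M))
    stop_invalid("length(s) must equal nrow(K)")
  if (!is.numeric(lambda1) || lambda1 < 0 || !is.numeric(lambda2) || lambda2 < 0)
    stop_invalid("lambda1 and lambda2 must be >= 0")
  if (!is.null(B)) {
    B <- as.matrix(B)
    if (nrow(B) != ncol(M))
      stop_invalid("B must have nrow equal to ncol(K)")
  }
  structure(list(kernel = kernel, K = M, B = B, s = s,
                 lambda1 = lambda1, lambda2 = lambda2,
                 nonneg_c = isTRUE(nonneg_c),
                 m = nrow(M), n = ncol(M),
                 p = if (is.null(B)) ncol(M) else ncol(B)),
            class = "inversion_model")
}

#' Encode an inversion model in the interior-point template
#'
#' Translates an [inversion_model()] into an [ip_problem()]. Absolute-value
#' terms are handled by sign splitting `c = c1 - c2` with `c1, c2 >= 0`, under
#' which `|c| = c1 + c2` at the optimum, so the L1 penalty becomes the linear
#' cost `lambda1 * sum(c1 + c2)`.
#'
#' * Identity dictionary, non-negative `c`: variables are `c` itself
#'   (no doubling), `A = K`, `d2 = 1` on every data row, linear cost
#'   `lambda1`, `d1 = sqrt(lambda2)` (or `delta1` when `lambda2 = 0`).
#' * Identity dictionary, free `c`, `lambda1 = 0`: unconstrained ridge;
#'   free bounds, no splitting.
#' * Otherwise: variables `(c1, c2, f)` (dropping `c2` when `nonneg_c`),
#'   data rows `K f + r = s` with `d2 = 1`, and near-exact coupling rows
#'   `B c1 - B c2 - f + delta2 * r2 = 0` enforcing `f = B c`; `f >= 0` is a
#'   plain bound, `d1` is `sqrt(lambda2)` on the `c` blocks and `delta1` on
#'   `f`.
#'
#' @param model An [inversion_model()].
#' @param options See [solver_options()]; supplies `delta1`, `delta2`.
#' @return List with the `ip_problem` and index maps used to extract
#'   `c` and `f` from the stacked variable vector.
#' @export
split_dictionary_problem <- function(model, options = solver_options()) {
  stopifnot(inherits(model, "inversion_model"))
  opts <- modifyList(solver_options(), options)
  K <- model$K; s <- model$s
  n <- model$n; m <- model$m
  l1 <- model$lambda1; l2 <- model$lambda2
  d1c <- if (l2 > 0) sqrt(l2) else opts$delta1

  if (is.null(model$B)) {
    if (model$nonneg_c) {
      prob <- ip_problem(A = K, b = s, bl = 0, bu = Inf,
                         d1 = d1c, d2 = 1,
                         phi = if (l1 > 0) rep(l1, n) else NULL)
      return(list(problem = prob, layout = "identity_nonneg",
                  idx_c = seq_len(n), idx_f = seq_len(n)))
    }
    if (l1 == 0) {
      prob <- ip_problem(A = K, b = s, bl = -Inf, bu = Inf,
                         d1 = d1c, d2 = 1, phi = NULL)
      return(list(problem = prob, layout = "identity_free",
                  idx_c = seq_len(n), idx_f = seq_len(n)))
    }
    ## identity dictionary, signed c with an L1 term: split c = c1 - c2
    A <- cbind(K, -K)
    prob <- ip_problem(A = A, b = s, bl = 0, bu = Inf,
                       d1 = d1c, d2 = 1, phi = rep(l1, 2 * n))
    return(list(problem = prob, layout = "identity_split",
                idx_c1 = seq_len(n), idx_c2 = n + seq_len(n)))
  }

  B <- model$B
  p <- ncol(B)
  if (model$nonneg_c) {
    ## variables (c, f): rows [0 K][c; f] + r1 = s ; [B -I][c; f] + d2 r2 = 0
    A <- rbind(cbind(matrix(0, m, p), K), cbind(B, -diag(n)))
    prob <- ip_problem(A = A, b = c(s, numeric(n)), bl = 0, bu = Inf,
                       d1 = c(rep(d1c, p), rep(opts$delta1, n)),
                       d2 = c(rep(1, m), rep(opts$delta2, n)),
                       phi = c(rep(l1, p), numeric(n)))
    list(problem = prob, layout = "dict_nonneg",
         idx_c1 = seq_len(p), idx_c2 = integer(0), idx_f = p + seq_len(n))
  } else {
    ## variables (c1, c2, f)
    A <- rbind(cbind(matrix(0, m, 2 * p), K), cbind(B, -B, -diag(n)))
    prob <- ip_problem(A = A, b = c(s, numeric(n)), bl = 0, bu = Inf,
                       d1 = c(rep(d1c, 2 * p), rep(opts$delta1, n)),
                       d2 = c(rep(1, m), rep(opts$delta2, n)),
                       phi = c(rep(l1, 2 * p), numeric(n)))
    list(problem = prob, layout = "dict_split",
         idx_c1 = seq_len(p), idx_c2 = p + seq_len(p), idx_f = 2 * p + seq_len(n))
  }
}

#' Solve the regularized inversion
#'
#' Runs the primal-dual interior-point method on the encoded problem and
#' returns the relaxation-time spectrum with solver diagnostics. On iteration
#' cap or a linear-algebra failure the partial solution is returned with
#' `converged = FALSE` and a warning.
#'
#' @param model An [inversion_model()].
#' @param options See [solver_options()].
#' @return Object of class `ilt_spectrum`: list with `f` (spectrum values on
#'   the T2 grid, non-negative up to bound tolerance), `c` (dictionary
#'   coefficients; equals `f` for the identity dictionary), `t2` (grid
#'   constants, when known), `residual` (`s - K f`), `objective` and
#'   `diagnostics` (iterations, infeasibilities, complementarity gap,
#'   gap history, convergence flag).
#' @examples
#' tg <- build_time_grid(0.5, 200)
#' t2g <- build_t2_grid(1, 1000, 32)
#' K <- build_kernel(tg, t2g)
#' s <- K$matrix %*% replace(numeric(32), 17, 1)
#' sp <- solve_inversion(inversion_model(K, s, 1e-6, 1e-6))
#' which.max(sp$f)  # 17
#' @export
solve_inversion <- function(model, options = solver_options()) {
  stopifnot(inherits(model, "inversion_model"))
  enc <- split_dictionary_problem(model, options)
  sol <- interior_point_solve(enc$problem, options)

  cvec <- switch(enc$layout,
                 identity_nonneg = ,
                 identity_free = sol$x[enc$idx_c],
                 identity_split = sol$x[enc$idx_c1] - sol$x[enc$idx_c2],
                 dict_nonneg = sol$x[enc$idx_c1],
                 dict_split = sol$x[enc$idx_c1] - sol$x[enc$idx_c2])
  f <- switch(enc$layout,
              identity_nonneg = ,
              identity_free = cvec,
              identity_split = cvec,
              dict_nonneg = ,
              dict_split = sol$x[enc$idx_f])
  if (!sol$converged)
    warning("interior-point solver did not converge (",
            if (!is.null(sol$failure)) sol$failure else "iteration limit",
            "); returning the last iterate", call. = FALSE)

  t2 <- if (inherits(model$kernel, "laplace_kernel"))
    model$kernel$col_constants$constants else NULL
  structure(list(f = f, c = cvec, t2 = t2,
                 residual = model$s - drop(model$K %*% f),
                 objective = sol$objective,
                 diagnostics = list(iterations = sol$iterations,
                                    converged = sol$converged,
                                    primal_inf = sol$primal_inf,
                                    dual_inf = sol$dual_inf,
                                    compl_gap = sol$compl_gap,
                                    gap_history = sol$gap_history)),
            class = "ilt_spectrum")
}

#' @export
print.ilt_spectrum <- function(x, ...) {
  cat(sprintf("<ilt_spectrum> %d bins, %d solver iterations (%s), objective %.6g\n",
              length(x$f), x$diagnostics$iterations,
              if (x$diagnostics$converged) "converged" else "NOT converged",
              x$objective))
  invisible(x)
}

#' First-order optimality residual
#'
#' For the identity-dictionary non-negative problem the KKT conditions at an
#' optimum `f*` are, with
#' `g = K'(K f - s) + lambda1 + lambda2 * f`:
#' `g >= 0`, `f >= 0` and `g * f = 0` componentwise. This returns the largest
#' violation, `max_j max(-g_j, |g_j f_j| / (1 + |f_j|))` floored at zero;
#' it is exactly zero at the optimum and grows monotonically as the solution
#' is perturbed away from it.
#'
#' @param spec An `ilt_spectrum` (or plain numeric `f`).
#' @param model The [inversion_model()] it solves (identity dictionary,
#'   non-negative coefficients).
#' @return Scalar >= 0.
#' @export
kkt_residual <- function(spec, model) {
  stopifnot(inherits(model, "inversion_model"))
  if (!is.null(model$B) || !model$nonneg_c)
    stop_invalid("kkt_residual is defined for the identity-dictionary non-negative problem")
  f <- if (inherits(spec, "ilt_spectrum")) spec$f else as.numeric(spec)
  if (length(f) != model$n) stop_invalid("solution length does not match the model")
  g <- drop(crossprod(model$K, drop(model$K %*% f) - model$s)) +
    model$lambda1 + model$lambda2 * f
  max(0, max(-g), max(abs(g * f) / (1 + abs(f))))
}

#' Objective value of the inversion problem
#'
#' `0.5 * ||K B c - s||^2 + lambda1 * ||c||_1 + 0.5 * lambda2 * ||c||^2`,
#' evaluated for any coefficient vector. Useful for comparing solutions from
#' different solvers on the identical objective.
#'
#' @param cvec Coefficient vector (length p; equals `f` for identity `B`).
#' @param model An [inversion_model()].
#' @return Scalar objective value.
#' @export
inversion_objective <- function(cvec, model) {
  stopifnot(inherits(model, "inversion_model"))
  cvec <- as.numeric(cvec)
  f <- if (is.null(model$B)) cvec else drop(model$B %*% cvec)
  0.5 * sum((drop(model$K %*% f) - model$s)^2) +
    model$lambda1 * sum(abs(cvec)) + 0.5 * model$lambda2 * sum(cvec^2)
}
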