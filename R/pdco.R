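#' Interior-point problem template
#'
#' Describes a linearly constrained separable convex program in the structural
#' form
#' \deqn{\min_{x, r}\; \phi(x) + \tfrac12\|D_1 x\|^2 + \tfrac12\|r\|^2
#'       \quad \mathrm{s.t.}\quad A x + D_2 r = b,\; l \le x \le u,}
#' where \eqn{D_1, D_2} are positive diagonal matrices, `r` is a free residual
#' variable and \eqn{\phi} is convex and separable (diagonal Hessian). Setting
#' `d2 = 1` on a constraint row makes that row a least-squares data-fit row;
#' a small `d2` (e.g. 1e-4) makes it a near-exact linear constraint.
#'
#' @param A Constraint matrix (m x n), dense numeric.
#' @param b Right-hand side (length m).
#' @param bl,bu Lower/upper bounds on `x` (length n; `-Inf`/`Inf` allowed).
#' @param d1 Diagonal of `D1`: positive scalar or length-n vector. Enters the
#'   objective as `0.5 * sum((d1 * x)^2)`.
#' @param d2 Diagonal of `D2`: positive scalar or length-m vector.
#' @param phi Separable convex term: `NULL` (zero), a length-n numeric vector
#'   `c` (linear term `sum(c * x)`), or a list with functions
#'   `value(x)`, `grad(x)`, `hess(x)` (the latter returning the diagonal).
#' @return An object of class `ip_problem`.
#' @export
ip_problem <- function(A, b, bl, bu, d1, d2, phi = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  b <- as.numeric(b)
  stopifnot(length(b) == m)
  bl <- rep_len(as.numeric(bl), n)
  bu <- rep_len(as.numeric(bu), n)
  if (any(bl > bu)) stop_invalid("need bl <= bu elementwise")
  d1 <- rep_len(as.numeric(d1), n)
  d2 <- rep_len(as.numeric(d2), m)
  if (any(d1 <= 0) || any(d2 <= 0)) stop_invalid("d1 and d2 must be strictly positive")
  if (!is.null(phi) && !is.numeric(phi) &&
      !(is.list(phi) && all(c("grad", "hess") %in% names(phi))))
    stop_invalid("'phi' must be NULL, a numeric linear-cost vector, or a grad/hess list")
  if (is.numeric(phi)) phi <- rep_len(as.numeric(phi), n)
  structure(list(A = A, b = b, bl = bl, bu = bu, d1 = d1, d2 = d2, phi = phi,
                 m = m, n = n),
            class = "ip_problem")
}

#' Solver options
#'
#' @param tol Relative tolerance applied to primal infeasibility, dual
#'   infeasibility and complementarity.
#' @param maxit Iteration cap. Typical well-scaled problems converge in
#'   roughly 25--50 iterations.
#' @param delta1,delta2 Small positive safeguards used when assembling
#'   inversion problems ([split_dictionary_problem()]): `delta1` is the primal
#'   regularization applied to blocks that carry no explicit L2 weight,
#'   `delta2` the residual scaling of near-exact constraint rows.
#' @param sigma Centering parameter: each iteration targets
#'   `mu = sigma * gap / #bounds`.
#' @param step_frac Fraction-to-boundary factor keeping iterates strictly
#'   interior.
#' @param verbose Print per-iteration diagnostics.
#' @return A list of options for [interior_point_solve()].
#' @export
solver_options <- function(tol = 1e-6, maxit = 100L, delta1 = 1e-4, delta2 = 1e-4,
                           sigma = 0.1, step_frac = 0.99, verbose = FALSE) {
  list(tol = tol, maxit = as.integer(maxit), delta1 = delta1, delta2 = delta2,
       sigma = sigma, step_frac = step_frac, verbose = verbose)
}

#' Primal-dual interior-point solve
#'
#' Path-following primal-dual interior method for [ip_problem()] instances.
#' The residual variable `r` is eliminated through its optimality condition
#' `r = D2 y`, leaving the KKT system in `(x, y, z1, z2)` where `y` are the
#' duals of `A x + D2 r = b` and `z1, z2 >= 0` the bound multipliers. Each
#' iteration solves the positive-definite normal-equations system
#' `(A H^{-1} A' + D2^2) dy = rhs` (with
#' `H = hess(phi) + D1^2 + X1^{-1}Z1 + X2^{-1}Z2`), then back-substitutes
#' `dx = H^{-1}(A' dy + w)`. Because `D2^2` is added, the system stays
#' well-conditioned even for a severely ill-conditioned `A`. Steps are damped
#' by a fraction-to-boundary rule so all iterates stay strictly interior.
#' The method is deterministic: a fixed starting point, no randomization.
#'
#' @param problem An [ip_problem()].
#' @param options See [solver_options()].
#' @return List with `x`, `y`, `z1`, `z2`, `r` (the residual variable
#'   `D2 y`), `objective`, `iterations`, `converged`, `primal_inf`,
#'   `dual_inf`, `compl_gap` and `gap_history` (complementarity gap per
#'   iteration).
#' @export
interior_point_solve <- function(problem, options = solver_options()) {
  stopifnot(inherits(problem, "ip_problem"))
  opts <- modifyList(solver_options(), options)
  A <- problem$A; b <- problem$b
  bl <- problem$bl; bu <- problem$bu
  d1 <- problem$d1; d2 <- problem$d2
  m <- problem$m; n <- problem$n
  low <- is.finite(bl); upp <- is.finite(bu)
  nb <- sum(low) + sum(upp)

  phi <- problem$phi
  phi_grad <- function(x) {
    if (is.null(phi)) numeric(n)
    else if (is.numeric(phi)) phi
    else as.numeric(phi$grad(x))
  }
  phi_hess <- function(x) {
    if (is.null(phi) || is.numeric(phi)) numeric(n)
    else as.numeric(phi$hess(x))
  }
  phi_value <- function(x) {
    if (is.null(phi)) 0
    else if (is.numeric(phi)) sum(phi * x)
    else as.numeric(phi$value(x))
  }
  objective <- function(x, y) {
    r <- d2 * y
    phi_value(x) + 0.5 * sum((d1 * x)^2) + 0.5 * sum(r^2)
  }

  ## deterministic strictly interior start
  x <- numeric(n)
  x[low & upp] <- 0.5 * (bl[low & upp] + bu[low & upp])
  x[low & !upp] <- bl[low & !upp] + 1
  x[!low & upp] <- bu[!low & upp] - 1
  y <- numeric(m)
  z1 <- ifelse(low, 1, 0)
  z2 <- ifelse(upp, 1, 0)

  converged <- FALSE
  gap_history <- numeric(0)
  pinf <- dinf <- cinf <- NA_real_
  iter <- 0L
  bscale <- 1 + max(abs(b), 0)

  for (iter in seq_len(opts$maxit)) {
    g0 <- phi_grad(x)
    h0 <- phi_hess(x)
    x1 <- ifelse(low, x - bl, 1)   # placeholder 1 where inactive
    x2 <- ifelse(upp, bu - x, 1)

    r1 <- b - drop(A %*% x) - d2^2 * y
    grad_full <- g0 + d1^2 * x
    r2 <- grad_full - drop(crossprod(A, y)) - z1 + z2

    gap <- sum((x1 * z1)[low]) + sum((x2 * z2)[upp])
    gap_history <- c(gap_history, gap)

    obj <- objective(x, y)
    pinf <- max(abs(r1)) / bscale
    dinf <- max(abs(r2)) / (1 + max(abs(grad_full), 0))
    cinf <- if (nb > 0) gap / nb / (1 + abs(obj)) else 0
    if (opts$verbose)
      message(sprintf("it %3d  pinf %.2e  dinf %.2e  cinf %.2e", iter, pinf, dinf, cinf))
    if (pinf <= opts$tol && dinf <= opts$tol && cinf <= opts$tol) {
      converged <- TRUE
      break
    }

    mu <- if (nb > 0) opts$sigma * gap / nb else 0
    cL <- ifelse(low, mu - x1 * z1, 0)
    cU <- ifelse(upp, mu - x2 * z2, 0)

    H <- h0 + d1^2 + ifelse(low, z1 / x1, 0) + ifelse(upp, z2 / x2, 0)
    if (any(H <= 0) || any(!is.finite(H)))
      return(list(x = x, y = y, z1 = z1, z2 = z2, r = d2 * y,
                  objective = obj, iterations = iter, converged = FALSE,
                  primal_inf = pinf, dual_inf = dinf, compl_gap = cinf,
                  gap_history = gap_history,
                  failure = "singular scaling matrix"))

    w <- -r2 + ifelse(low, cL / x1, 0) - ifelse(upp, cU / x2, 0)
    ## normal equations in dy: (A H^-1 A' + D2^2) dy = r1 - A H^-1 w
    AH <- A * rep(1 / H, each = m)          # A %*% diag(1/H)
    M <- tcrossprod(AH, A)
    diag(M) <- diag(M) + d2^2
    rhs <- r1 - drop(AH %*% w)
    dy <- tryCatch(drop(solve(M, rhs)), error = function(e) NULL)
    if (is.null(dy))
      return(list(x = x, y = y, z1 = z1, z2 = z2, r = d2 * y,
                  objective = obj, iterations = iter, converged = FALSE,
                  primal_inf = pinf, dual_inf = dinf, compl_gap = cinf,
                  gap_history = gap_history,
                  failure = "normal-equations solve failed"))
    dx <- (drop(crossprod(A, dy)) + w) / H
    dz1 <- ifelse(low, (cL - z1 * dx) / x1, 0)
    dz2 <- ifelse(upp, (cU + z2 * dx) / x2, 0)

    ## fraction-to-boundary steps (primal on slacks, dual on multipliers)
    step_max <- function(v, dv) {
      neg <- dv < 0
      if (!any(neg)) Inf else min(-v[neg] / dv[neg])
    }
    ap <- min(1, opts$step_frac * min(step_max(x1[low], dx[low]),
                                      step_max(x2[upp], -dx[upp])))
    ad <- min(1, opts$step_frac * min(step_max(z1[low], dz1[low]),
                                      step_max(z2[upp], dz2[upp])))
    if (nb == 0) { ap <- 1; ad <- 1 }

    x <- x + ap * dx
    y <- y + ad * dy
    z1 <- z1 + ad * dz1
    z2 <- z2 + ad * dz2
    ## keep strictly interior against rounding
    eps <- .Machine$double.xmin
    z1[low] <- pmax(z1[low], eps)
    z2[upp] <- pmax(z2[upp], eps)
  }

  list(x = x, y = y, z1 = z1, z2 = z2, r = d2 * y,
       objective = objective(x, y), iterations = iter, converged = converged,
       primal_inf = pinf, dual_inf = dinf, compl_gap = cinf,
       gap_history = gap_history)
}
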