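#' Backward differentiation formula coefficients
#'
#' Coefficients a_0..a_k such that h^-1 sum_l a_l x_{n-l} reproduces the
#' derivative at t_n exactly for polynomials of degree <= k. They are
#' obtained from the interpolation conditions sum_l a_l (-l)^m = delta_{m,1}
#' for m = 0..k (a Vandermonde system); k = 1 gives the implicit Euler pair
#' (1, -1).
#'
#' @param k Order, integer in 1..5.
#' @return Numeric vector `c(a_0, ..., a_k)`.
#' @examples
#' bdf_coefficients(1)  # c(1, -1)
#' bdf_coefficients(2)  # c(3/2, -2, 1/2)
#' @export
bdf_coefficients <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > 5 || k != round(k))
    stop("k must be an integer between 1 and 5")
  l <- 0:k
  V <- outer(0:k, l, function(m, l) (-l)^m)
  rhs <- as.numeric(seq_len(k + 1) == 2)  # delta_{m,1}
  as.numeric(solve(V, rhs))
}

#' Fixed-step BDF integration of an implicit DAE system
#'
#' Advances the residual system F(t, x, xdot) = 0 with a fixed step: at each
#' step the BDF stencil replaces the derivative and the resulting nonlinear
#' algebraic system is solved by a chord Newton iteration with a
#' finite-difference Jacobian. For orders k > 1 the scheme self-starts: the
#' first step uses the trapezoidal rule (local error O(h^3), so it does not
#' degrade the global order up to k = 3) and subsequent steps ramp the BDF
#' order from 2 up to k. For k > 3 the startup limits the observed global
#' order to 3 even though the asymptotic stencil is order k.
#'
#' @param residual Function `residual(t, x, xdot)` returning the residual
#'   vector; must vanish at the consistent initial state.
#' @param x0 Initial state.
#' @param t_end Final time (> 0).
#' @param h Step size (> 0).
#' @param k BDF order (1..5).
#' @param newton_tol Convergence tolerance on the residual norm.
#' @param newton_max_iter Maximum Newton iterations per step.
#' @param jac_pert Relative finite-difference perturbation for the Jacobian.
#' @return A list with `times` (length n+1) and `x` (matrix, one row per
#'   time).
#' @export
bdf_integrate <- function(residual, x0, t_end, h, k = 2, newton_tol = 1e-10,
                          newton_max_iter = 25, jac_pert = 1e-8) {
  stopifnot(t_end > 0, h > 0)
  # keep the grid uniform: shrink h marginally so an integer number of
  # steps lands exactly on t_end
  n_steps <- ceiling(t_end / h - 1e-9)
  h <- t_end / n_steps
  d <- length(x0)
  X <- matrix(NA_real_, n_steps + 1, d)
  X[1, ] <- x0
  times <- seq(0, t_end, length.out = n_steps + 1)

  # consistent initial derivative, needed by the trapezoidal starting step:
  # solve residual(t0, x0, v) = 0 for v by Newton with an FD Jacobian
  solve_xdot0 <- function() {
    v <- rep(0, d)
    for (it in seq_len(newton_max_iter)) {
      r <- residual(times[1], x0, v)
      if (length(r) != d) stop("residual dimension does not match the state")
      if (sqrt(sum(r^2)) <= newton_tol) return(v)
      Jv <- matrix(0, d, d)
      for (j in seq_len(d)) {
        dv <- jac_pert * max(abs(v[j]), 1)
        vp <- v; vp[j] <- vp[j] + dv
        Jv[, j] <- (residual(times[1], x0, vp) - r) / dv
      }
      v <- v - as.numeric(solve(Jv, r))
    }
    stop("could not solve for a consistent initial derivative")
  }
  xdot0 <- if (k >= 2) solve_xdot0()

  for (n in seq_len(n_steps)) {
    ord <- min(k, n)
    a <- bdf_coefficients(ord)
    hist <- X[n:(n - ord + 1), , drop = FALSE]   # x_{n-1}, ..., x_{n-ord}
    tn <- times[n + 1]
    # G(x) = residual(tn, x, (a0 x + sum_{l>=1} a_l x_{n-l}) / h);
    # the first step of a k >= 2 run instead uses the trapezoidal rule,
    # whose O(h^3) local error keeps the self-start from capping the
    # global order below 3
    tail_sum <- colSums(a[-1] * hist)
    G <- if (n == 1 && k >= 2) {
      function(x) residual(tn, x, 2 * (x - x0) / h - xdot0)
    } else {
      function(x) residual(tn, x, (a[1] * x + tail_sum) / h)
    }
    x <- X[n, ]
    g <- G(x)
    if (length(g) != d) stop("residual dimension does not match the state")
    # finite-difference Jacobian, reused across the chord iteration
    J <- matrix(0, d, d)
    for (j in seq_len(d)) {
      dx <- jac_pert * max(abs(x[j]), 1)
      xp <- x; xp[j] <- xp[j] + dx
      J[, j] <- (G(xp) - g) / dx
    }
    lu <- tryCatch(solve(J), error = function(e)
      stop("singular BDF Newton Jacobian at t = ", tn))
    it <- 0
    while (sqrt(sum(g^2)) > newton_tol) {
      it <- it + 1
      if (it > newton_max_iter)
        stop(sprintf("BDF Newton failed to converge at t = %g (residual %.3g after %d iterations)",
                     tn, sqrt(sum(g^2)), newton_max_iter))
      x <- x - as.numeric(lu %*% g)
      g <- G(x)
      if (any(!is.finite(g)))
        stop("BDF Newton produced a non-finite residual at t = ", tn)
    }
    X[n + 1, ] <- x
  }
  list(times = times, x = X)
}
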