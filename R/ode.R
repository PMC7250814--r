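# Adaptive linearly-implicit (Rosenbrock) integrator for the stiff
# fast/slow systems in this package. Four-stage Kaps-Rentrop method with
# Shampine's parameter set: order 4 with an embedded order-3 error
# estimate, L-stable, so the step size is accuracy-limited rather than
# stability-limited. The systems integrated here are autonomous, so the
# time-derivative correction terms vanish.

KR_GAM <- 0.5
KR_A21 <- 2
KR_A31 <- 48 / 25
KR_A32 <- 6 / 25
KR_C21 <- -8
KR_C31 <- 372 / 25
KR_C32 <- 12 / 5
KR_C41 <- -112 / 125
KR_C42 <- -54 / 125
KR_C43 <- -2 / 5
KR_B <- c(19 / 9, 1 / 2, 25 / 108, 125 / 108)
KR_E <- c(17 / 54, 7 / 36, 0, 125 / 108)

#' Integrate an autonomous ODE system with a stiff-capable Rosenbrock scheme
#'
#' @param rhs function(t, y) returning dy/dt.
#' @param jac function(t, y) returning the Jacobian matrix, or `NULL` for a
#'   forward-difference approximation.
#' @param y0 initial state.
#' @param times strictly increasing output times (first entry is t0).
#' @param rtol,atol relative / absolute local error tolerances.
#' @param h0 initial step; `NULL` picks a conservative default.
#' @param hmin minimal step before the integrator aborts.
#' @param max_steps safety cap on attempted steps.
#' @param nonneg if `TRUE`, clip small negative undershoots (below
#'   `-1e-13 * max(1, |y|)` a warning is raised first).
#' @return list with `times`, `states` (length(times) x length(y0) matrix),
#'   `steps` (accepted step count).
#' @keywords internal
#' @export
ode_rosenbrock <- function(rhs, jac, y0, times, rtol = 1e-8, atol = 1e-10,
                           h0 = NULL, hmin = 1e-14, max_steps = 5e6,
                           nonneg = FALSE) {
  y <- as.numeric(y0)
  nv <- length(y)
  if (is.null(jac)) jac <- function(t, y) num_jacobian(rhs, t, y)
  out <- matrix(NA_real_, length(times), nv)
  out[1L, ] <- y
  t <- times[1L]
  h <- if (is.null(h0)) (times[length(times)] - t) * 1e-3 else h0
  steps <- 0L
  accepted <- 0L
  I <- diag(nv)
  for (iout in seq_along(times)[-1L]) {
    tend <- times[iout]
    while (t < tend - 1e-14 * max(1, abs(tend))) {
      h <- min(h, tend - t)
      f0 <- rhs(t, y)
      J <- jac(t, y)
      repeat {
        steps <- steps + 1L
        if (steps > max_steps) {
          stop(sprintf("ode_rosenbrock: step limit exceeded at t = %g", t),
               call. = FALSE)
        }
        W <- I / (KR_GAM * h) - J
        Wlu <- tryCatch(lu_factor(W), error = function(e) NULL)
        if (is.null(Wlu)) {
          h <- h / 4
          if (h < hmin) stop("ode_rosenbrock: singular stage matrix",
                             call. = FALSE)
          next
        }
        g1 <- lu_solve(Wlu, f0)
        g2 <- lu_solve(Wlu, rhs(t, y + KR_A21 * g1) + KR_C21 * g1 / h)
        y3 <- y + KR_A31 * g1 + KR_A32 * g2
        f3 <- rhs(t, y3)
        g3 <- lu_solve(Wlu, f3 + (KR_C31 * g1 + KR_C32 * g2) / h)
        g4 <- lu_solve(Wlu, f3 + (KR_C41 * g1 + KR_C42 * g2 +
                                    KR_C43 * g3) / h)
        ynew <- y + KR_B[1L] * g1 + KR_B[2L] * g2 + KR_B[3L] * g3 +
          KR_B[4L] * g4
        errv <- KR_E[1L] * g1 + KR_E[2L] * g2 + KR_E[3L] * g3 +
          KR_E[4L] * g4
        err <- max(abs(errv) / (atol + rtol * pmax(abs(y), abs(ynew))))
        if (!is.finite(err)) err <- 2
        if (err <= 1) {
          t <- t + h
          accepted <- accepted + 1L
          if (nonneg && any(ynew < 0)) {
            floor_tol <- -1e-13 * max(1, max(abs(ynew)))
            if (any(ynew < floor_tol)) {
              warning(sprintf("negative undershoot %.3g clipped at t = %g",
                              min(ynew), t), call. = FALSE)
            }
            ynew <- pmax(ynew, 0)
          }
          y <- ynew
          h <- h * min(5, max(0.2, 0.9 * max(err, 1e-12)^(-0.25)))
          break
        }
        h <- h * max(0.1, 0.9 * err^(-1 / 3))
        if (h < hmin) {
          stop(sprintf("ode_rosenbrock: step size underflow at t = %g", t),
               call. = FALSE)
        }
      }
    }
    out[iout, ] <- y
  }
  list(times = times, states = out, steps = accepted)
}

# one LU factorisation reused over the four stages
lu_factor <- function(W) {
  qr(W, LAPACK = TRUE)
}
lu_solve <- function(fac, b) {
  solve.qr(fac, b)
}

# forward-difference Jacobian, adequate for the small smooth systems here
num_jacobian <- function(rhs, t, y, eps = 1e-7) {
  f0 <- rhs(t, y)
  nv <- length(y)
  J <- matrix(0, nv, nv)
  for (j in seq_len(nv)) {
    dj <- eps * max(1, abs(y[j]))
    yj <- y
    yj[j] <- yj[j] + dj
    J[, j] <- (rhs(t, yj) - f0) / dj
  }
  J
}
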