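# Two-timescale simulation: the full state-resolved system with fast
# transitions at rate 1/epsilon and demography at O(1), and the reduced
# Gause-type system on the totals (X, Y) driven by the derived responses.
# Comparing the two quantifies the quality of the timescale-separation
# reduction.

#' Right-hand side of the full two-timescale system
#'
#' Fast state transitions contribute `fast_vector_field / epsilon`; the
#' slow demographic terms are: prey state k gains `prey_offspring[k] *
#' sum_i lam[i] x[i]` births, loses `mu[k] x[k]` natural deaths and
#' `x[k] * sum_j beta[k,j] y[j]` captures; predator state k gains
#' `pred_offspring[k] * sum_ij gamma[i,j] beta[i,j] x[i] y[j]` births and
#' loses `delta[k] y[k]`. Capture-driven prey removal is O(1) against the
#' O(1/epsilon) transitions, so the totals are conserved on the fast scale.
#'
#' @param model a [transition_model()].
#' @param rates a [demography_rates()].
#' @param epsilon timescale-separation parameter (> 0).
#' @param state a [population_state()] or list with `x`, `y`.
#' @return List with derivative vectors `dx`, `dy`.
#' @export
full_system_rhs <- function(model, rates, epsilon, state) {
  stopifnot(epsilon > 0)
  fast <- fast_vector_field(model, state)
  x <- state$x
  y <- state$y
  births_prey <- sum(rates$lam * x)
  capt <- rates$beta * outer(x, y)            # m x n capture fluxes
  births_pred <- sum(rates$gamma * capt)
  dx <- fast$dx / epsilon + rates$prey_offspring * births_prey -
    rates$mu * x - rowSums(capt)
  dy <- fast$dy / epsilon + rates$pred_offspring * births_pred -
    rates$delta * y
  list(dx = dx, dy = dy)
}

full_system_jacobian <- function(model, rates, epsilon, x, y) {
  m <- model$m
  n <- model$n
  J <- fast_jacobian(model, list(x = x, y = y)) / epsilon
  ix <- seq_len(m)
  iy <- m + seq_len(n)
  # prey block: births + deaths + capture
  J[ix, ix] <- J[ix, ix] + outer(rates$prey_offspring, rates$lam) -
    diag(rates$mu + drop(rates$beta %*% y), m, m)
  J[ix, iy] <- J[ix, iy] - x * rates$beta
  # predator block: conversion births + deaths
  gb <- rates$gamma * rates$beta
  J[iy, ix] <- J[iy, ix] + outer(rates$pred_offspring, drop(gb %*% y))
  J[iy, iy] <- J[iy, iy] + outer(rates$pred_offspring, drop(crossprod(gb, x))) -
    diag(rates$delta, n, n)
  J
}

new_trajectory <- function(times, states, kind, columns, metadata = list()) {
  structure(list(times = times, states = states, kind = kind,
                 columns = columns, metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory (%s): %d time points on [%g, %g], columns: %s>\n",
              x$kind, length(x$times), min(x$times), max(x$times),
              paste(x$columns, collapse = ", ")))
  invisible(x)
}

#' Totals along a trajectory
#'
#' @param traj a `trajectory` from [simulate_full()] or
#'   [simulate_reduced()].
#' @return Data frame with columns `time`, `X`, `Y`.
#' @export
trajectory_totals <- function(traj) {
  if (traj$kind == "reduced") {
    data.frame(time = traj$times, X = traj$states[, 1L],
               Y = traj$states[, 2L])
  } else {
    m <- traj$metadata$m
    data.frame(time = traj$times,
               X = rowSums(traj$states[, seq_len(m), drop = FALSE]),
               Y = rowSums(traj$states[, -seq_len(m), drop = FALSE]))
  }
}

#' Simulate the full state-resolved two-timescale system
#'
#' Stiff integration (linearly implicit Rosenbrock with the analytic
#' Jacobian assembled from the effective transition matrices) of
#' [full_system_rhs()]. Small negative undershoots (below `-1e-13` relative)
#' are clipped with a warning.
#'
#' @inheritParams full_system_rhs
#' @param init a [population_state()] initial condition.
#' @param t_span length-2 numeric, start and end time.
#' @param n_out number of equally spaced output times.
#' @param times explicit output times (overrides `n_out`).
#' @param rtol,atol integrator tolerances.
#' @return A `trajectory` (kind `"full"`) whose state columns are the m
#'   prey states followed by the n predator states.
#' @export
simulate_full <- function(model, rates, epsilon, init, t_span,
                          n_out = 201L, times = NULL, rtol = 1e-8,
                          atol = 1e-10) {
  assert_consistent(model)
  stopifnot(epsilon > 0)
  m <- model$m
  if (is.null(times)) times <- seq(t_span[1L], t_span[2L], length.out = n_out)
  rhs <- function(t, s) {
    d <- full_system_rhs(model, rates, epsilon,
                         list(x = s[seq_len(m)], y = s[-seq_len(m)]))
    c(d$dx, d$dy)
  }
  jac <- function(t, s) {
    full_system_jacobian(model, rates, epsilon, s[seq_len(m)], s[-seq_len(m)])
  }
  sol <- tryCatch(
    ode_rosenbrock(rhs, jac, c(init$x, init$y), times, rtol = rtol,
                   atol = atol, nonneg = TRUE),
    error = function(e) {
      stop(sprintf("full-system integration failed (epsilon = %g; the fast block is stiff at rate 1/epsilon): %s",
                   epsilon, conditionMessage(e)), call. = FALSE)
    })
  cols <- c(paste0("x", seq_len(m)), paste0("y", seq_len(model$n)))
  colnames(sol$states) <- cols
  new_trajectory(sol$times, sol$states, "full", cols,
                 list(epsilon = epsilon, m = m, n = model$n,
                      rtol = rtol, atol = atol, steps = sol$steps))
}

#' Simulate the reduced slow system on the totals
#'
#' Integrates the Gause-type system
#' `dX/dt = g(X,Y) X - f(X,Y) Y`,
#' `dY/dt = gamma(X,Y) f(X,Y) Y - delta(X,Y) Y`
#' with all responses evaluated at the fast equilibrium for the current
#' totals. Equilibria are warm-started from the previous evaluation. At
#' `Y = 0` the predator terms vanish and per-predator quantities are not
#' evaluated; at `X = 0` likewise for the prey. Integration halts with a
#' diagnostic if the fast equilibrium fails to converge mid-trajectory.
#'
#' @inheritParams simulate_full
#' @param X0,Y0 nonnegative initial totals.
#' @return A `trajectory` (kind `"reduced"`) with columns `X`, `Y`.
#' @export
simulate_reduced <- function(model, rates, X0, Y0, t_span, n_out = 201L,
                             times = NULL, rtol = 1e-8, atol = 1e-10) {
  assert_consistent(model)
  stopifnot(X0 >= 0, Y0 >= 0)
  if (is.null(times)) times <- seq(t_span[1L], t_span[2L], length.out = n_out)
  warm <- new.env(parent = emptyenv())
  warm$eq <- NULL
  rhs <- function(t, s) {
    X <- max(s[1L], 0)
    Y <- max(s[2L], 0)
    eq <- solve_nonlinear(model, X, Y,
                          x0 = if (!is.null(warm$eq)) warm$eq$x_hat,
                          y0 = if (!is.null(warm$eq)) warm$eq$y_hat)
    if (!eq$converged) {
      stop(sprintf("fast equilibrium did not converge at t = %g (X = %g, Y = %g, residual %.3g)",
                   t, X, Y, eq$residual), call. = FALSE)
    }
    warm$eq <- eq
    gX <- if (X > 0) sum((rates$lam - rates$mu) * eq$x_hat) else 0
    capt <- rates$beta * outer(eq$x_hat, eq$y_hat)
    dX <- gX - sum(capt)
    dY <- sum(rates$gamma * capt) - sum(rates$delta * eq$y_hat)
    c(dX, dY)
  }
  sol <- ode_rosenbrock(rhs, NULL, c(X0, Y0), times, rtol = rtol,
                        atol = atol, nonneg = TRUE)
  colnames(sol$states) <- c("X", "Y")
  new_trajectory(sol$times, sol$states, "reduced", c("X", "Y"),
                 list(rtol = rtol, atol = atol, steps = sol$steps))
}

#' Compare full and reduced trajectories on the totals
#'
#' Interpolates the reduced totals onto the full trajectory's time grid and
#' reports sup-norm and L2 errors on X and Y.
#'
#' @param full a `trajectory` of kind `"full"`.
#' @param reduced a `trajectory` of kind `"reduced"`.
#' @return List of class `reduction_error`: `sup_X`, `sup_Y`, `sup`
#'   (max of the two), `l2_X`, `l2_Y`, `l2`, `epsilon` (from the full
#'   trajectory's metadata).
#' @export
compare_reduction <- function(full, reduced) {
  stopifnot(full$kind == "full", reduced$kind == "reduced")
  ft <- trajectory_totals(full)
  rt <- trajectory_totals(reduced)
  Xr <- stats::approx(rt$time, rt$X, xout = ft$time, rule = 2)$y
  Yr <- stats::approx(rt$time, rt$Y, xout = ft$time, rule = 2)$y
  dX <- ft$X - Xr
  dY <- ft$Y - Yr
  dt <- diff(range(ft$time)) / max(length(ft$time) - 1L, 1L)
  structure(list(sup_X = max(abs(dX)), sup_Y = max(abs(dY)),
                 sup = max(abs(c(dX, dY))),
                 l2_X = sqrt(sum(dX^2) * dt), l2_Y = sqrt(sum(dY^2) * dt),
                 l2 = sqrt(sum(dX^2 + dY^2) * dt),
                 epsilon = full$metadata$epsilon),
            class = "reduction_error")
}

#' @export
print.reduction_error <- function(x, ...) {
  cat(sprintf("<reduction_error (epsilon = %g): sup |X| = %.4g, sup |Y| = %.4g, L2 = %.4g>\n",
              if (is.null(x$epsilon)) NA else x$epsilon, x$sup_X, x$sup_Y,
              x$l2))
  invisible(x)
}

#' Reduction error across an epsilon sweep
#'
#' Runs [simulate_full()] for each epsilon against one reduced reference
#' trajectory and tabulates the errors; for a valid timescale separation
#' the error decreases with epsilon.
#'
#' @inheritParams simulate_full
#' @param epsilons decreasing or arbitrary positive values to sweep.
#' @param init initial [population_state()]; the reduced run starts from
#'   its totals.
#' @return Data frame with columns `epsilon`, `sup`, `l2`.
#' @export
reduction_error_sweep <- function(model, rates, epsilons, init, t_span,
                                  n_out = 101L, rtol = 1e-8) {
  reduced <- simulate_reduced(model, rates, sum(init$x), sum(init$y),
                              t_span, n_out = n_out, rtol = rtol)
  rows <- lapply(epsilons, function(eps) {
    full <- simulate_full(model, rates, eps, init, t_span, n_out = n_out,
                          rtol = rtol)
    err <- compare_reduction(full, reduced)
    data.frame(epsilon = eps, sup = err$sup, l2 = err$l2)
  })
  do.call(rbind, rows)
}
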