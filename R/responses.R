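# Population-level responses obtained by time-averaging over the fast
# equilibrium: functional response f(X,Y), prey numerical response g(X,Y),
# predator conversion factor gamma(X,Y) and mortality delta(X,Y).

resolve_equilibrium <- function(model, X, Y, eq = NULL, ...) {
  if (is.null(eq)) eq <- solve_nonlinear(model, X, Y, ...)
  if (!isTRUE(eq$converged)) {
    stop(sprintf("fast equilibrium did not converge (residual %.3g); responses undefined",
                 eq$residual), call. = FALSE)
  }
  eq
}

#' Predator functional response
#'
#' Average number of prey captured per predator per unit time,
#' `f(X, Y) = sum_ij beta[i,j] x_hat[i] y_hat[j] / Y`, evaluated at the
#' fast equilibrium for totals `(X, Y)`.
#'
#' @param model a [transition_model()].
#' @param rates a [demography_rates()] (the capture matrix `beta` is used).
#' @param X,Y totals; `Y` must be positive (the response is per predator).
#' @param eq optional precomputed `fast_equilibrium`; solved when `NULL`.
#' @param ... passed to [solve_nonlinear()] when `eq` is `NULL`.
#' @return Scalar capture rate (prey per predator per time).
#' @export
functional_response <- function(model, rates, X, Y, eq = NULL, ...) {
  if (Y <= 0) stop("functional response is per predator: Y must be > 0",
                   call. = FALSE)
  eq <- resolve_equilibrium(model, X, Y, eq, ...)
  sum(rates$beta * outer(eq$x_hat, eq$y_hat)) / Y
}

#' Prey numerical response
#'
#' Per-capita net growth rate of the prey from state-dependent births and
#' natural deaths, `g(X, Y) = (sum_i lam[i] x_hat[i] - sum_i mu[i]
#' x_hat[i]) / X` (capture losses are accounted separately by `f`).
#'
#' @inheritParams functional_response
#' @return Scalar per-capita rate.
#' @export
prey_numerical_response <- function(model, rates, X, Y, eq = NULL, ...) {
  if (X <= 0) stop("prey numerical response is per capita: X must be > 0",
                   call. = FALSE)
  eq <- resolve_equilibrium(model, X, Y, eq, ...)
  sum((rates$lam - rates$mu) * eq$x_hat) / X
}

#' Predator numerical response
#'
#' Splits the per-capita predator growth `gamma(X,Y) f(X,Y) - delta(X,Y)`
#' into its pieces. The birth side is computed directly as
#' `gamma_f = sum_ij gamma[i,j] beta[i,j] x_hat[i] y_hat[j] / Y`, which is
#' well defined even at `f = 0`; the conversion factor
#' `gamma_factor = gamma_f / f` is a population-level bookkeeping quantity
#' with no individual-level interpretation and is reported as `NA` when
#' `f = 0`. The mortality factor is `delta_factor = sum_j delta[j]
#' y_hat[j] / Y`.
#'
#' @inheritParams functional_response
#' @return List with `gamma_f`, `gamma_factor` (`NA` when `f = 0`),
#'   `delta_factor`, `f`, and `net = gamma_f - delta_factor`.
#' @export
predator_numerical_response <- function(model, rates, X, Y, eq = NULL, ...) {
  if (Y <= 0) stop("predator numerical response is per capita: Y must be > 0",
                   call. = FALSE)
  eq <- resolve_equilibrium(model, X, Y, eq, ...)
  occup <- outer(eq$x_hat, eq$y_hat)
  f <- sum(rates$beta * occup) / Y
  gamma_f <- sum(rates$gamma * rates$beta * occup) / Y
  delta_factor <- sum(rates$delta * eq$y_hat) / Y
  list(gamma_f = gamma_f,
       gamma_factor = if (f > 0) gamma_f / f else NA_real_,
       delta_factor = delta_factor,
       f = f,
       net = gamma_f - delta_factor)
}

#' All responses at one point
#'
#' Convenience wrapper computing the fast equilibrium once and returning
#' every population-level response at `(X, Y)`.
#'
#' @inheritParams functional_response
#' @return List with `f`, `g`, `gamma_f`, `gamma_factor`, `delta_factor`,
#'   `net_predator`, `eq`.
#' @export
responses_at <- function(model, rates, X, Y, eq = NULL, ...) {
  eq <- resolve_equilibrium(model, X, Y, eq, ...)
  pred <- if (Y > 0) predator_numerical_response(model, rates, X, Y, eq = eq)
          else list(gamma_f = NA_real_, gamma_factor = NA_real_,
                    delta_factor = NA_real_, f = NA_real_, net = NA_real_)
  g <- if (X > 0) prey_numerical_response(model, rates, X, Y, eq = eq)
       else NA_real_
  list(f = pred$f, g = g, gamma_f = pred$gamma_f,
       gamma_factor = pred$gamma_factor, delta_factor = pred$delta_factor,
       net_predator = pred$net, eq = eq)
}

#' Sweep the responses over an (X, Y) grid
#'
#' Evaluates `f`, `g`, `gamma`, `delta` and the net predator growth over
#' the product grid `X_grid x Y_grid`. Each cell's nonlinear solve is
#' warm-started from the previous cell along the sweep, which is cheap and
#' keeps the solver on the same equilibrium branch; cells that fail to
#' converge are flagged, not filled.
#'
#' @inheritParams functional_response
#' @param X_grid,Y_grid strictly increasing positive vectors.
#' @return An object of class `response_surface`: list with the grids and
#'   matrices `f`, `g`, `gamma`, `delta`, `net`, `converged` indexed
#'   `[X, Y]`.
#' @export
response_surface <- function(model, rates, X_grid, Y_grid, ...) {
  stopifnot(all(diff(X_grid) > 0) || length(X_grid) == 1L,
            all(diff(Y_grid) > 0) || length(Y_grid) == 1L,
            all(X_grid > 0), all(Y_grid > 0))
  nx <- length(X_grid)
  ny <- length(Y_grid)
  mk <- function() matrix(NA_real_, nx, ny,
                          dimnames = list(signif(X_grid, 8), signif(Y_grid, 8)))
  out <- list(X_grid = X_grid, Y_grid = Y_grid, f = mk(), g = mk(),
              gamma = mk(), delta = mk(), net = mk(),
              converged = matrix(FALSE, nx, ny))
  warm <- NULL
  for (iy in seq_len(ny)) {
    row_warm <- NULL
    for (ix in seq_len(nx)) {
      x0 <- if (!is.null(warm)) warm$x_hat else NULL
      y0 <- if (!is.null(warm)) warm$y_hat else NULL
      eq <- solve_nonlinear(model, X_grid[ix], Y_grid[iy],
                            x0 = x0, y0 = y0, ...)
      if (ix == 1L) row_warm <- eq
      warm <- eq
      if (!eq$converged) next
      r <- responses_at(model, rates, X_grid[ix], Y_grid[iy], eq = eq)
      out$f[ix, iy] <- r$f
      out$g[ix, iy] <- r$g
      out$gamma[ix, iy] <- r$gamma_factor
      out$delta[ix, iy] <- r$delta_factor
      out$net[ix, iy] <- r$net_predator
      out$converged[ix, iy] <- TRUE
    }
    warm <- row_warm  # next row starts above the first column of this row
  }
  class(out) <- "response_surface"
  out
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf("<response_surface: %d x %d grid, X in [%g, %g], Y in [%g, %g], %d/%d cells converged>\n",
              length(x$X_grid), length(x$Y_grid),
              min(x$X_grid), max(x$X_grid), min(x$Y_grid), max(x$Y_grid),
              sum(x$converged), length(x$converged)))
  invisible(x)
}
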