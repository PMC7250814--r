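# Fast-dynamics equilibrium solvers: stationary distributions of the
# behavioural-state transitions at fixed totals (X, Y).

#' Stationary distribution of a conservative transition-rate matrix
#'
#' Solves `M v = 0`, `sum(v) = total`, `v >= 0`, where `M` is a transition
#' rate matrix (columns sum to zero, nonnegative off-diagonal). Uniqueness
#' requires that the directed graph of strictly positive off-diagonal
#' entries has a single closed (terminal) communicating class; irreducible
#' chains are the common case. The normalization is imposed by the rank-one
#' update trick: summing `M v = 0` and `1'v = total` gives the nonsingular
#' system `(M + E) v = total * 1` with `E` the all-ones matrix.
#'
#' @param M k x k transition rate matrix (column sums zero within `tol`).
#' @param total nonnegative total density to distribute over the states.
#' @param tol absolute tolerance on the column sums of `M`.
#' @return Length-k nonnegative vector summing to `total`.
#' @export
solve_linear_stationary <- function(M, total, tol = 1e-9) {
  M <- as.matrix(M)
  k <- nrow(M)
  if (ncol(M) != k) stop("`M` must be square", call. = FALSE)
  if (!is.finite(total) || total < 0) {
    stop("`total` must be a nonnegative number", call. = FALSE)
  }
  cs <- colSums(M)
  if (any(abs(cs) > tol * max(1, max(abs(M))))) {
    stop(sprintf("`M` is not conservative: column %d sums to %.3g",
                 which.max(abs(cs)), cs[which.max(abs(cs))]), call. = FALSE)
  }
  if (k == 1L) return(total)
  cls <- closed_classes(M)
  if (length(cls) > 1L) {
    stop(sprintf(
      "transition matrix is reducible with %d closed communicating classes ({%s}): stationary distribution is not unique",
      length(cls),
      paste(vapply(cls, function(s) paste(s, collapse = ","), ""),
            collapse = "}, {")), call. = FALSE)
  }
  v <- solve(M + matrix(1, k, k), rep(total, k))
  neg <- v < 0
  if (any(v < -1e-8 * max(1, total))) {
    stop("stationary solve produced significantly negative densities (ill-conditioned matrix?)",
         call. = FALSE)
  }
  v[neg] <- 0
  v
}

# communicating classes with no outgoing edges, on the directed graph of
# strictly positive off-diagonal entries; computed via boolean reachability
# closure (matrices here are tiny)
closed_classes <- function(M) {
  k <- nrow(M)
  adj <- M > 0
  diag(adj) <- TRUE
  reach <- adj
  for (step in seq_len(ceiling(log2(max(k, 2))))) {
    reach <- (reach %*% reach) > 0
  }
  mutual <- reach & t(reach)
  seen <- rep(FALSE, k)
  classes <- list()
  for (i in seq_len(k)) {
    if (seen[i]) next
    cls <- which(mutual[, i])
    seen[cls] <- TRUE
    # reach[a, b] is TRUE when a is reachable from b; the class is closed
    # iff no state outside it is reachable from it
    if (!any(reach[-cls, i])) {
      classes[[length(classes) + 1L]] <- cls
    }
  }
  classes
}

#' Stationary distribution of a birth-death chain
#'
#' Closed-form stationary distribution of a nearest-neighbour chain on `m`
#' states with upward rates `up[i]` (state i to i+1) and downward rates
#' `down[i]` (state i+1 to i), from the detailed-balance relations
#' `v[k] = v[1] * prod_{i<k} up[i]/down[i]` and the normalisation
#' `sum(v) = X`.
#'
#' @param up_rates,down_rates positive vectors of length m-1.
#' @param X nonnegative total.
#' @return Length-m vector summing to `X`.
#' @export
birth_death_chain_equilibrium <- function(up_rates, down_rates, X) {
  if (length(up_rates) != length(down_rates)) {
    stop("`up_rates` and `down_rates` must have equal length", call. = FALSE)
  }
  if (any(down_rates <= 0)) stop("all down rates must be positive",
                                 call. = FALSE)
  if (any(up_rates <= 0)) stop("all up rates must be positive",
                               call. = FALSE)
  ratios <- cumprod(up_rates / down_rates)
  weights <- c(1, ratios)
  X * weights / sum(weights)
}

new_fast_equilibrium <- function(x_hat, y_hat, residual, iterations,
                                 converged, method) {
  structure(list(x_hat = x_hat, y_hat = y_hat, X = sum(x_hat),
                 Y = sum(y_hat), residual = residual,
                 iterations = iterations, converged = converged,
                 method = method),
            class = "fast_equilibrium")
}

#' @export
print.fast_equilibrium <- function(x, ...) {
  cat(sprintf("<fast_equilibrium (%s): X = %.6g, Y = %.6g, residual = %.3g, %s in %d iteration%s>\n",
              x$method, x$X, x$Y, x$residual,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, if (x$iterations == 1) "" else "s"))
  cat("  x_hat:", format(x$x_hat, digits = 6), "\n")
  cat("  y_hat:", format(x$y_hat, digits = 6), "\n")
  invisible(x)
}

eq_residual <- function(model, x, y) {
  fld <- fast_vector_field(model, list(x = x, y = y))
  max(abs(c(fld$dx, fld$dy)))
}

# relative residual scale: rate magnitude times density magnitude
eq_residual_scale <- function(model, X, Y) {
  rate <- max(abs(model$A), abs(model$D),
              max(abs(model$B)) * (1 + Y), max(abs(model$C)) * (1 + X), 1)
  rate * max(1, X, Y)
}

check_not_relaxed <- function(model, allow_relaxed, caller) {
  if (model$relaxed && !isTRUE(allow_relaxed)) {
    stop(sprintf("%s: model is flagged relaxed (degenerate); pass allow_relaxed = TRUE to proceed",
                 caller), call. = FALSE)
  }
}

#' Fast equilibrium when prey transitions ignore the predator (triangular case)
#'
#' When `B` is identically zero the prey states equilibrate independently of
#' the predator, so the equilibrium is obtained by two successive linear
#' stationary solves: `x_hat` from `A`, then `y_hat` from `C(x_hat) + D`.
#'
#' @param model a [transition_model()] with `B == 0`.
#' @param X,Y nonnegative totals.
#' @param allow_relaxed permit degenerate (relaxed) models.
#' @return A `fast_equilibrium` object.
#' @export
solve_triangular <- function(model, X, Y, allow_relaxed = FALSE) {
  assert_consistent(model)
  check_not_relaxed(model, allow_relaxed, "solve_triangular")
  if (any(model$B != 0)) {
    stop("solve_triangular requires B == 0 (prey transitions independent of the predator); use solve_nonlinear()",
         call. = FALSE)
  }
  x_hat <- if (X == 0) rep(0, model$m) else solve_linear_stationary(model$A, X)
  M_pred <- contract_mediator(model$C, x_hat) + model$D
  y_hat <- if (Y == 0) rep(0, model$n) else solve_linear_stationary(M_pred, Y)
  res <- eq_residual(model, x_hat, y_hat)
  new_fast_equilibrium(x_hat, y_hat, res, 2L,
                       res <= 1e-8 * eq_residual_scale(model, X, Y),
                       "triangular")
}

#' Fast equilibrium of the fully coupled nonlinear model
#'
#' Alternating fixed-point scheme: given the current predator distribution,
#' the prey distribution is the stationary distribution of `A + B(y)`;
#' given the prey distribution, the predators equilibrate on `C(x) + D`.
#' Each half-step is a well-posed linear stationary solve; updates are
#' damped and iterated until successive iterates agree, and the result is
#' verified against the residual of the fast vector field.
#'
#' @inheritParams solve_triangular
#' @param tol convergence tolerance on successive iterates, relative to
#'   `1 + X + Y`.
#' @param max_iter iteration cap; on hitting it the best iterate is
#'   returned with `converged = FALSE` (never an error).
#' @param damping in (0, 1]; fraction of the new stationary solve mixed
#'   into the iterate each half-step.
#' @param x0,y0 optional initial distributions (defaults: uniform).
#' @param residual_rtol relative residual threshold for the converged flag.
#' @return A `fast_equilibrium` object.
#' @export
solve_nonlinear <- function(model, X, Y, tol = 1e-12, max_iter = 10000L,
                            damping = 0.5, x0 = NULL, y0 = NULL,
                            allow_relaxed = FALSE, residual_rtol = 1e-8) {
  assert_consistent(model)
  check_not_relaxed(model, allow_relaxed, "solve_nonlinear")
  if (X < 0 || Y < 0) stop("totals must be nonnegative", call. = FALSE)
  m <- model$m
  n <- model$n
  x <- if (is.null(x0)) rep(X / m, m) else as.numeric(x0) * X / max(sum(x0), .Machine$double.xmin)
  y <- if (is.null(y0)) rep(Y / n, n) else as.numeric(y0) * Y / max(sum(y0), .Machine$double.xmin)
  if (X == 0) x <- rep(0, m)
  if (Y == 0) y <- rep(0, n)
  scale <- 1 + X + Y
  iter <- 0L
  diff <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    x_new <- x
    if (X > 0) {
      M_prey <- model$A + contract_mediator(model$B, y)
      xs <- tryCatch(solve_linear_stationary(M_prey, X), error = function(e) {
        stop(sprintf("prey transition matrix A + B(y) at iteration %d: %s",
                     iter, conditionMessage(e)), call. = FALSE)
      })
      x_new <- (1 - damping) * x + damping * xs
    }
    y_new <- y
    if (Y > 0) {
      M_pred <- contract_mediator(model$C, x_new) + model$D
      ys <- tryCatch(solve_linear_stationary(M_pred, Y), error = function(e) {
        stop(sprintf("predator transition matrix C(x) + D at iteration %d: %s",
                     iter, conditionMessage(e)), call. = FALSE)
      })
      y_new <- (1 - damping) * y + damping * ys
    }
    diff <- max(abs(c(x_new - x, y_new - y))) / scale
    x <- x_new
    y <- y_new
    if (diff < tol) break
  }
  if (diff < tol) {
    # one undamped polish step removes the O(tol) lag the damping leaves
    # behind (for triangular models it is exact)
    if (X > 0) x <- solve_linear_stationary(model$A +
                                              contract_mediator(model$B, y), X)
    if (Y > 0) y <- solve_linear_stationary(contract_mediator(model$C, x) +
                                              model$D, Y)
  }
  res <- eq_residual(model, x, y)
  converged <- diff < tol &&
    res <= residual_rtol * eq_residual_scale(model, X, Y)
  new_fast_equilibrium(x, y, res, iter, converged, "nonlinear")
}

#' Hyperbolic stability of a fast equilibrium
#'
#' Computes the eigenvalues of the analytic Jacobian of the fast dynamics
#' at an equilibrium. The two conservation laws (constant X and constant Y)
#' force two zero eigenvalues; the equilibrium is hyperbolically stable
#' within the invariant set of fixed totals when exactly two eigenvalues
#' are (numerically) zero and all others have negative real part.
#'
#' @param model a [transition_model()].
#' @param eq a `fast_equilibrium` (should be converged).
#' @param zero_tol eigenvalues with modulus below `zero_tol * max(|lambda|)`
#'   count as the conservation zeros.
#' @return A list of class `stability_report`: `eigenvalues`, `zero_count`,
#'   `max_nonzero_real_part`, `hyperbolically_stable`.
#' @export
assess_stability <- function(model, eq, zero_tol = 1e-8) {
  if (!isTRUE(eq$converged)) {
    warning("assessing stability at a non-converged equilibrium", call. = FALSE)
  }
  J <- fast_jacobian(model, list(x = eq$x_hat, y = eq$y_hat))
  ev <- eigen(J, only.values = TRUE)$values
  scale <- max(Mod(ev), 1e-300)
  zero <- Mod(ev) <= zero_tol * max(scale, 1)
  if (all(zero)) {
    # fully degenerate Jacobian (e.g. 1 prey + 1 predator state)
    zero <- rep(TRUE, length(ev))
  }
  nz <- ev[!zero]
  max_re <- if (length(nz)) max(Re(nz)) else -Inf
  structure(list(eigenvalues = ev, zero_count = sum(zero),
                 max_nonzero_real_part = max_re,
                 hyperbolically_stable = sum(zero) == 2L && max_re < 0),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report: %d zero eigenvalue%s, max nonzero Re = %.4g, %shyperbolically stable>\n",
              x$zero_count, if (x$zero_count == 1) "" else "s",
              x$max_nonzero_real_part,
              if (x$hyperbolically_stable) "" else "NOT "))
  invisible(x)
}

#' Probe uniqueness of the fast equilibrium by multistart
#'
#' Runs the nonlinear solver from `n_starts` random initial distributions
#' (flat Dirichlet on each simplex) and, in parallel, integrates the fast
#' dynamics forward from the same starts; all points with a small fast-field
#' residual are collected and merged when closer than `merge_tol` in
#' max-norm after normalising by `X + Y`. A single surviving equilibrium is
#' evidence (not proof) of uniqueness; degenerate models with continua of
#' equilibria report many.
#'
#' @inheritParams solve_nonlinear
#' @param n_starts number of random initial conditions.
#' @param seed integer seed (recorded in the report).
#' @param merge_tol merge tolerance on normalized distributions.
#' @param t_max horizon for the trajectory route.
#' @return A list of class `uniqueness_report`: `n_distinct`, `equilibria`
#'   (list of x/y pairs), `n_starts`, `n_nonconverged`, `seed`.
#' @export
probe_uniqueness <- function(model, X, Y, n_starts = 20L, seed = 1L,
                             merge_tol = 1e-6, t_max = 500,
                             allow_relaxed = FALSE) {
  assert_consistent(model)
  check_not_relaxed(model, allow_relaxed, "probe_uniqueness")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  scale <- max(X + Y, .Machine$double.xmin)
  res_tol <- 1e-7 * eq_residual_scale(model, X, Y)
  found <- list()
  n_nonconv <- 0L

  push <- function(x, y) {
    pt <- c(x, y) / scale
    for (g in found) {
      if (max(abs(pt - g$pt)) <= merge_tol) return(invisible())
    }
    found[[length(found) + 1L]] <<- list(x = x, y = y, pt = pt)
  }

  rdirichlet1 <- function(k) {
    g <- stats::rgamma(k, 1)
    g / sum(g)
  }

  for (s in seq_len(n_starts)) {
    x0 <- X * rdirichlet1(model$m)
    y0 <- Y * rdirichlet1(model$n)
    eq <- tryCatch(
      solve_nonlinear(model, X, Y, x0 = x0, y0 = y0,
                      allow_relaxed = allow_relaxed),
      error = function(e) NULL)
    if (!is.null(eq) && eq$converged) {
      push(eq$x_hat, eq$y_hat)
    } else {
      n_nonconv <- n_nonconv + 1L
    }
    # trajectory route from the same start
    endpoint <- integrate_fast_to_rest(model, x0, y0, t_max = t_max)
    if (eq_residual(model, endpoint$x, endpoint$y) <= res_tol) {
      push(endpoint$x, endpoint$y)
    }
  }
  structure(list(n_distinct = length(found),
                 equilibria = lapply(found, function(g) g[c("x", "y")]),
                 n_starts = n_starts, n_nonconverged = n_nonconv,
                 seed = seed),
            class = "uniqueness_report")
}

#' @export
print.uniqueness_report <- function(x, ...) {
  cat(sprintf("<uniqueness_report: %d distinct equilibri%s from %d starts (%d non-converged), seed %d>\n",
              x$n_distinct, if (x$n_distinct == 1) "um" else "a",
              x$n_starts, x$n_nonconverged, x$seed))
  invisible(x)
}

#' Integrate the fast dynamics toward its attractor
#'
#' Integrates the fast system forward in chunks until the vector field
#' residual falls below `res_tol` or `t_max` is reached; used as the
#' trajectory route of [probe_uniqueness()] and as an independent check on
#' the fixed-point solver.
#'
#' @inheritParams solve_nonlinear
#' @param x0,y0 initial state (densities, not distributions).
#' @param t_max time horizon.
#' @param res_tol stopping residual; default scales with rates and totals.
#' @param rtol integrator relative tolerance.
#' @return list with final `x`, `y`, `t`, `residual`.
#' @export
integrate_fast_to_rest <- function(model, x0, y0, t_max = 500,
                                   res_tol = NULL, rtol = 1e-10) {
  if (is.null(res_tol)) {
    res_tol <- 1e-9 * eq_residual_scale(model, sum(x0), sum(y0))
  }
  m <- model$m
  rhs <- function(t, s) {
    fld <- fast_vector_field(model, list(x = s[seq_len(m)], y = s[-seq_len(m)]))
    c(fld$dx, fld$dy)
  }
  jac <- function(t, s) {
    fast_jacobian(model, list(x = s[seq_len(m)], y = s[-seq_len(m)]))
  }
  s <- c(x0, y0)
  t <- 0
  chunk <- t_max / 32
  while (t < t_max) {
    tn <- min(t + chunk, t_max)
    sol <- ode_rosenbrock(rhs, jac, s, c(t, tn), rtol = rtol, atol = 1e-12,
                          nonneg = TRUE)
    s <- sol$states[2L, ]
    t <- tn
    if (max(abs(rhs(t, s))) <= res_tol) break
    chunk <- chunk * 1.5
  }
  list(x = s[seq_len(m)], y = s[-seq_len(m)], t = t,
       residual = max(abs(rhs(t, s))))
}
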