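#' Structured fast-transition predator-prey model
#'
#' A `transition_model` specifies the fast behavioural-state dynamics of a
#' predator-prey community with `m` prey states and `n` predator states:
#'
#' \deqn{dx_k/dt = \sum_i A[k,i] x_i + \sum_i (\sum_j B[k,i,j] y_j) x_i}
#' \deqn{dy_k/dt = \sum_i (\sum_j C[k,i,j] x_j) y_i + \sum_i D[k,i] y_i}
#'
#' All matrices follow the destination-major convention: `A[k, i]` is the
#' spontaneous per-capita rate at which prey move from state `i` to state
#' `k`; `A[i, i]` is minus the total exit rate from state `i`. `B[k, i, j]`
#' is the rate coefficient for the prey transition `i -> k` mediated by
#' (i.e. proportional to the density of) predator state `j`; `D` and
#' `C[k, i, j]` are the predator analogues with prey state `j` as mediator.
#' Because the fast dynamics only redistributes individuals among states,
#' every column of `A` and `D`, and of each mediator slice `B[, , j]` and
#' `C[, , j]`, sums to zero. The tensor index order `[destination, source,
#' mediator]` is fixed throughout the package.
#'
#' @param A m x m matrix of spontaneous prey transition rates (per time).
#' @param D n x n matrix of spontaneous predator transition rates (per time).
#' @param B m x m x n array of predator-mediated prey transition rate
#'   coefficients (per predator density per time). A matrix is accepted when
#'   `n = 1`. `NULL` means all-zero.
#' @param C n x n x m array of prey-mediated predator transition rate
#'   coefficients (per prey density per time). A matrix is accepted when
#'   `m = 1`. `NULL` means all-zero.
#' @param relaxed logical; if `TRUE`, states without any exit channel are
#'   tolerated (used only to express degenerate fixtures, e.g. models with
#'   zero diagonal blocks for which the fast equilibrium need not be
#'   unique). Solvers refuse relaxed models unless explicitly overridden.
#' @param name optional model label used in printing.
#'
#' @return An object of class `transition_model` with elements `m`, `n`,
#'   `A`, `B`, `C`, `D`, `relaxed`, `name`.
#' @seealso [validate_consistency()], [fast_vector_field()],
#'   [solve_nonlinear()]
#' @examples
#' # two prey states with symmetric spontaneous switching, predators inert
#' mod <- transition_model(A = matrix(c(-1, 1, 2, -2), 2, 2), D = matrix(0))
#' validate_consistency(mod, relaxed = TRUE)
#' @export
transition_model <- function(A, D, B = NULL, C = NULL, relaxed = FALSE,
                             name = NULL) {
  A <- as.matrix(A)
  D <- as.matrix(D)
  m <- nrow(A)
  n <- nrow(D)
  if (ncol(A) != m) stop("`A` must be square", call. = FALSE)
  if (ncol(D) != n) stop("`D` must be square", call. = FALSE)
  B <- as_rate_tensor(B, m, n, "B")
  C <- as_rate_tensor(C, n, m, "C")
  structure(
    list(m = m, n = n, A = A, B = B, C = C, D = D,
         relaxed = isTRUE(relaxed), name = name),
    class = "transition_model"
  )
}

# coerce NULL / matrix / array input to a k x k x s tensor
as_rate_tensor <- function(x, k, s, what) {
  if (is.null(x)) return(array(0, dim = c(k, k, s)))
  if (is.matrix(x)) {
    if (s != 1L) {
      stop(sprintf("`%s` must be a %d x %d x %d array", what, k, k, s),
           call. = FALSE)
    }
    x <- array(x, dim = c(k, k, 1L))
  }
  if (!is.array(x) || length(dim(x)) != 3L ||
      !all(dim(x) == c(k, k, s))) {
    stop(sprintf("`%s` must be a %d x %d x %d array (destination, source, mediator)",
                 what, k, k, s), call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model%s: %d prey state%s, %d predator state%s%s>\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$m, if (x$m == 1) "" else "s",
              x$n, if (x$n == 1) "" else "s",
              if (x$relaxed) ", relaxed" else ""))
  invisible(x)
}

#' Slow-timescale demographic rates
#'
#' Collects the birth, death and capture parameters acting on the slow
#' timescale. Prey in state `i` are captured by predators in state `j` at
#' rate `beta[i, j]` per predator density; a capture by a predator in state
#' `j` of a prey in state `i` yields `gamma[i, j]` predator offspring.
#' Prey have per-capita birth rates `lam` and natural death rates `mu` per
#' state; predators die at per-capita rates `delta` per state. Newborn prey
#' and predators are allocated to states by the simplex vectors
#' `prey_offspring` and `pred_offspring`.
#'
#' @param m,n state counts (taken from `model` if supplied).
#' @param model optional [transition_model()] supplying `m` and `n`.
#' @param beta m x n capture rate matrix (per predator density per time);
#'   default all zero.
#' @param lam,mu prey per-capita birth / death rates, length-m (scalars are
#'   recycled); default 0.
#' @param gamma m x n per-capture fecundity matrix (offspring per capture);
#'   default 0.
#' @param delta predator per-capita mortality, length-n; default 0.
#' @param prey_offspring,pred_offspring distribution of newborns over
#'   states; default uniform.
#'
#' @return An object of class `demography_rates`.
#' @export
demography_rates <- function(m = NULL, n = NULL, model = NULL,
                             beta = NULL, lam = 0, mu = 0, gamma = NULL,
                             delta = 0, prey_offspring = NULL,
                             pred_offspring = NULL) {
  if (!is.null(model)) {
    m <- model$m
    n <- model$n
  }
  if (is.null(m) || is.null(n)) stop("supply `m` and `n` or a `model`",
                                     call. = FALSE)
  beta <- if (is.null(beta)) matrix(0, m, n) else matrix(as.numeric(beta), m, n)
  gamma <- if (is.null(gamma)) matrix(0, m, n) else matrix(as.numeric(gamma), m, n)
  lam <- rep_len(as.numeric(lam), m)
  mu <- rep_len(as.numeric(mu), m)
  delta <- rep_len(as.numeric(delta), n)
  prey_offspring <- if (is.null(prey_offspring)) rep(1 / m, m) else
    as.numeric(prey_offspring)
  pred_offspring <- if (is.null(pred_offspring)) rep(1 / n, n) else
    as.numeric(pred_offspring)
  rates <- structure(
    list(m = m, n = n, beta = beta, lam = lam, mu = mu, gamma = gamma,
         delta = delta, prey_offspring = prey_offspring,
         pred_offspring = pred_offspring),
    class = "demography_rates"
  )
  if (any(unlist(rates[c("beta", "lam", "mu", "gamma", "delta")]) < 0)) {
    stop("demographic rates must be nonnegative", call. = FALSE)
  }
  for (f in c("prey_offspring", "pred_offspring")) {
    v <- rates[[f]]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-10) {
      stop(sprintf("`%s` must be a distribution on the simplex", f),
           call. = FALSE)
    }
  }
  rates
}

#' @export
print.demography_rates <- function(x, ...) {
  cat(sprintf("<demography_rates: %d prey x %d predator states>\n", x$m, x$n))
  invisible(x)
}

#' State-resolved population densities
#'
#' @param x length-m nonnegative prey densities per state.
#' @param y length-n nonnegative predator densities per state.
#' @return An object of class `population_state` with elements `x`, `y` and
#'   totals `X`, `Y`.
#' @export
population_state <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (any(!is.finite(c(x, y))) || any(c(x, y) < 0)) {
    stop("state densities must be finite and nonnegative", call. = FALSE)
  }
  structure(list(x = x, y = y, X = sum(x), Y = sum(y)),
            class = "population_state")
}

#' Check the conservativity conditions of a transition model
#'
#' Verifies that all off-diagonal rates are nonnegative, that every column
#' of `A`, `D` and of each mediator slice of `B`, `C` sums to zero (so that
#' the fast dynamics purely redistributes individuals and conserves the
#' totals X and Y), that all entries are finite, and that every state has
#' an exit channel (a strictly negative diagonal entry in `A`/`D` or in
#' some mediator slice). The exit-channel check is skipped for relaxed
#' models.
#'
#' @param model a [transition_model()].
#' @param relaxed overrides `model$relaxed` when not `NULL`.
#' @param tol absolute tolerance on column sums (default `1e-12`; rates in
#'   typical applications are O(1)-O(100)).
#' @return A data frame of class `consistency_report` with one row per
#'   violation (columns `component`, `slice`, `column`, `residual`,
#'   `message`); zero rows means the model is consistent.
#' @export
validate_consistency <- function(model, relaxed = NULL, tol = 1e-12) {
  stopifnot(inherits(model, "transition_model"))
  relaxed <- if (is.null(relaxed)) model$relaxed else isTRUE(relaxed)
  viol <- list()
  add <- function(component, slice, column, residual, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      component = component, slice = slice, column = column,
      residual = residual, message = message, stringsAsFactors = FALSE)
  }

  check_matrix <- function(M, nm, slice = NA_integer_) {
    k <- nrow(M)
    if (any(!is.finite(M))) add(nm, slice, NA_integer_, NA_real_,
                                "non-finite entries")
    off <- M
    diag(off) <- 0
    bad <- which(off < 0, arr.ind = TRUE)
    for (r in seq_len(nrow(bad))) {
      add(nm, slice, bad[r, 2L], off[bad[r, 1L], bad[r, 2L]],
          sprintf("negative off-diagonal entry [%d,%d]",
                  bad[r, 1L], bad[r, 2L]))
    }
    cs <- colSums(M)
    for (i in which(abs(cs) > tol)) {
      add(nm, slice, i, cs[i],
          sprintf("column %d sums to %.3g, not 0", i, cs[i]))
    }
  }

  check_matrix(model$A, "A")
  check_matrix(model$D, "D")
  for (j in seq_len(model$n)) {
    check_matrix(matrix(model$B[, , j], model$m, model$m), "B", j)
  }
  for (j in seq_len(model$m)) {
    check_matrix(matrix(model$C[, , j], model$n, model$n), "C", j)
  }

  if (!relaxed) {
    # each state must be able to leave: strictly negative diagonal in the
    # spontaneous matrix or in some mediator slice (vacuous for a
    # single-state species, which is always at its trivial equilibrium)
    for (i in if (model$m > 1) seq_len(model$m) else integer(0)) {
      if (model$A[i, i] >= 0 && all(model$B[i, i, ] >= 0)) {
        add("A", NA_integer_, i, model$A[i, i],
            sprintf("prey state %d has no exit channel (use relaxed = TRUE for degenerate fixtures)", i))
      }
    }
    for (i in if (model$n > 1) seq_len(model$n) else integer(0)) {
      if (model$D[i, i] >= 0 && all(model$C[i, i, ] >= 0)) {
        add("D", NA_integer_, i, model$D[i, i],
            sprintf("predator state %d has no exit channel (use relaxed = TRUE for degenerate fixtures)", i))
      }
    }
  }

  out <- if (length(viol)) do.call(rbind, viol) else
    data.frame(component = character(), slice = integer(),
               column = integer(), residual = numeric(),
               message = character(), stringsAsFactors = FALSE)
  class(out) <- c("consistency_report", class(out))
  out
}

#' @export
print.consistency_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("consistent transition model (no violations)\n")
  } else {
    cat(sprintf("%d consistency violation%s:\n", nrow(x),
                if (nrow(x) == 1) "" else "s"))
    print.data.frame(x, ...)
  }
  invisible(x)
}

#' Stop unless a model passes the consistency checks
#' @inheritParams validate_consistency
#' @return `model`, invisibly.
#' @export
assert_consistent <- function(model, relaxed = NULL, tol = 1e-12) {
  rep <- validate_consistency(model, relaxed = relaxed, tol = tol)
  if (nrow(rep) > 0L) {
    stop("inconsistent transition model: ", rep$message[1L],
         if (nrow(rep) > 1L) sprintf(" (and %d more)", nrow(rep) - 1L),
         call. = FALSE)
  }
  invisible(model)
}

#' Effective transition-rate matrices at a population state
#'
#' Evaluates the density-dependent generators of the fast dynamics,
#' `M_prey = A + B(y)` with `B(y)[k,i] = sum_j B[k,i,j] y_j` and
#' `M_pred = C(x) + D` with `C(x)[k,i] = sum_j C[k,i,j] x_j`. The fast
#' vector field is `(M_prey %*% x, M_pred %*% y)`.
#'
#' @param model a [transition_model()].
#' @param state a [population_state()], or a list with elements `x`, `y`.
#' @return A list with matrices `M_prey` (m x m) and `M_pred` (n x n).
#' @export
effective_matrices <- function(model, state) {
  list(M_prey = model$A + contract_mediator(model$B, state$y),
       M_pred = contract_mediator(model$C, state$x) + model$D)
}

# sum_j T[ , , j] * w[j] without copying slices
contract_mediator <- function(Tn, w) {
  d <- dim(Tn)
  matrix(matrix(Tn, d[1L] * d[2L], d[3L]) %*% w, d[1L], d[2L])
}

#' Fast-dynamics vector field
#'
#' Right-hand side of the fast state-transition system at a population
#' state. By the conservativity conditions the prey components and the
#' predator components each sum to zero: the fast dynamics moves
#' individuals among states at fixed totals X and Y.
#'
#' @inheritParams effective_matrices
#' @return A list with numeric vectors `dx` (length m) and `dy` (length n).
#' @export
fast_vector_field <- function(model, state) {
  eff <- effective_matrices(model, state)
  list(dx = drop(eff$M_prey %*% state$x),
       dy = drop(eff$M_pred %*% state$y))
}

#' Jacobian of the fast dynamics
#'
#' Analytic Jacobian of the fast vector field with respect to the stacked
#' state `(x, y)`. The blocks are linear in the state:
#' `d(dx)/dx = A + B(y)`, `d(dx_k)/dy_j = sum_i B[k,i,j] x_i`,
#' `d(dy_k)/dx_j = sum_i C[k,i,j] y_i`, `d(dy)/dy = C(x) + D`.
#'
#' @inheritParams effective_matrices
#' @return An (m+n) x (m+n) matrix.
#' @export
fast_jacobian <- function(model, state) {
  m <- model$m
  n <- model$n
  eff <- effective_matrices(model, state)
  # cross blocks: contract over the source index
  dxdy <- apply(model$B, 3L, function(S) S %*% state$x)   # m x n
  dydx <- apply(model$C, 3L, function(S) S %*% state$y)   # n x m
  J <- matrix(0, m + n, m + n)
  J[seq_len(m), seq_len(m)] <- eff$M_prey
  J[seq_len(m), m + seq_len(n)] <- matrix(dxdy, m, n)
  J[m + seq_len(n), seq_len(m)] <- matrix(dydx, n, m)
  J[m + seq_len(n), m + seq_len(n)] <- eff$M_pred
  J
}
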