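# Model zoo: the four worked applications, each as (i) a generic
# transition_model + demography_rates pair and (ii) closed-form evaluators
# for the fast equilibrium and the population-level responses. The two
# routes are cross-validated in the test suite.

new_zoo_model <- function(name, params, model, rates, closed) {
  structure(list(name = name, params = params, model = model,
                 rates = rates, closed = closed),
            class = "zoo_model")
}

#' @export
print.zoo_model <- function(x, ...) {
  cat(sprintf("<zoo_model '%s': %d prey x %d predator states>\n",
              x$name, x$model$m, x$model$n))
  cat("  parameters:",
      paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' Tiered-prey model: a chain of protection levels
#'
#' Prey occupy `m` states of increasing protection. Moving up the chain
#' (state i to i+1) is driven by predator presence at rate `A_pred[i] * Y`
#' (kairomone-type cue proportional to total predator density); relaxing
#' back down (i+1 to i) is spontaneous at rate `A_spont[i]`. Predators have
#' two states, searching (S) and handling (H): searching predators capture
#' prey in state i at attack rate `c[i]` and then handle for mean time
#' `1/d`. The closed-form functional response is
#' \deqn{f(X,Y) = X (c_1 + \sum_k c_k \mathcal{A}_k Y^{k-1}) /
#'   (1 + \sum_k \mathcal{A}_k Y^{k-1} + X/d (c_1 + \sum_k c_k
#'   \mathcal{A}_k Y^{k-1}))}
#' with \eqn{\mathcal{A}_k = \prod_{i<k} A_pred[i]/A_spont[i]}. It
#' saturates at `d` for large X; with `m = 1` it reduces to the Holling
#' type II form `c_1 X / (1 + c_1 X / d)`.
#'
#' @param m number of prey states (>= 1).
#' @param A_spont length m-1 spontaneous downward rates (per time).
#' @param A_pred length m-1 predator-induced upward rate coefficients
#'   (per predator density per time).
#' @param c length-m attack rates on each prey state.
#' @param d inverse mean handling time (per time).
#' @param demography optional [demography_rates()] overriding the default
#'   (handling predators convert captures with unit fecundity, no other
#'   demography).
#' @return A `zoo_model`; `$closed$f(X, Y)` is the closed-form response,
#'   `$closed$x_hat(X, Y)` / `$closed$y_hat(X, Y)` the equilibrium.
#' @export
tiered_prey <- function(m, A_spont = numeric(0), A_pred = numeric(0),
                        c = 1, d = 1, demography = NULL) {
  stopifnot(m >= 1, length(A_spont) == m - 1, length(A_pred) == m - 1,
            length(c) == m)
  if (m > 1 && any(A_spont <= 0)) stop("A_spont rates must be positive",
                                       call. = FALSE)
  if (m > 1 && any(A_pred <= 0)) stop("A_pred rates must be positive",
                                      call. = FALSE)
  if (any(c < 0) || d <= 0) stop("attack rates must be >= 0 and d > 0",
                                 call. = FALSE)
  # spontaneous prey matrix: downward transitions i+1 -> i
  A <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    A[i, i + 1] <- A_spont[i]
    A[i + 1, i + 1] <- A[i + 1, i + 1] - A_spont[i]
  }
  # predator-mediated prey transitions i -> i+1, same coefficient for every
  # predator state so the rate is proportional to the total Y
  B <- array(0, dim = c(m, m, 2))
  for (i in seq_len(m - 1)) {
    B[i + 1, i, ] <- A_pred[i]
    B[i, i, ] <- B[i, i, ] - A_pred[i]
  }
  # predators: S = 1, H = 2; capture of prey i moves S -> H at rate c[i]
  C <- array(0, dim = c(2, 2, m))
  for (i in seq_len(m)) {
    C[2, 1, i] <- c[i]
    C[1, 1, i] <- -c[i]
  }
  D <- matrix(c(0, 0, d, -d), 2, 2)
  model <- transition_model(A, D, B, C, name = sprintf("tiered_prey(m=%d)", m))
  beta <- cbind(c, rep(0, m))
  rates <- if (is.null(demography)) {
    demography_rates(model = model, beta = beta,
                     gamma = cbind(rep(1, m), rep(0, m)),
                     pred_offspring = c(1, 0))
  } else demography

  script_A <- c(1, cumprod(A_pred / A_spont))  # script_A[k] = prod_{i<k}
  closed <- list(
    x_hat = function(X, Y) {
      w <- script_A * Y^(seq_len(m) - 1)
      X * w / sum(w)
    },
    y_hat = function(X, Y) {
      cx <- sum(c * script_A * Y^(seq_len(m) - 1)) /
        sum(script_A * Y^(seq_len(m) - 1)) * X
      S <- Y / (1 + cx / d)
      c(S, Y - S)
    },
    f = function(X, Y) {
      num <- c[1] + sum(c[-1] * script_A[-1] * Y^(seq_len(m)[-1] - 1))
      den <- 1 + sum(script_A[-1] * Y^(seq_len(m)[-1] - 1))
      X * num / (den + X * num / d)
    }
  )
  new_zoo_model("tiered_prey",
                list(m = m, A_spont = A_spont, A_pred = A_pred, c = c, d = d),
                model, rates, closed)
}

#' Two-prey-state closed forms (generalized Beddington-DeAngelis)
#'
#' Closed forms for the tiered-prey model with `m = 2`: prey split between
#' a defended state `x1` and an exposed state `x2` (entered at rate
#' `A1 * Y`, left at rate `A12`), both capturable at rates `c1`, `c2`.
#' The equilibrium is `x1 = A12 X / (A12 + A1 Y)`,
#' `x2 = A1 Y X / (A12 + A1 Y)` and the functional response is evaluated in
#' the internally consistent form
#' `f2 = ctot / (1 + ctot / d)` with `ctot = c1 x1 + c2 x2`, which
#' saturates at `d` for large X. A commonly quoted display of this response
#' carries a spurious overall factor `A12` in the numerator; it is exposed
#' as `f2_as_printed` for comparison only.
#'
#' With `c2 = 0` the response is a Beddington-DeAngelis function
#' `a X / (1 + b X + c Y)`; with `c1 = 0` the predator birth rate is
#' quadratic in `Y` at small `Y`, inducing an Allee effect in the slow
#' predator dynamics.
#'
#' @param A12 spontaneous return rate from the exposed to the defended
#'   state (per time).
#' @param A1 predator-induced exposure rate coefficient (per predator
#'   density per time).
#' @param c1,c2 attack rates on the defended and exposed states.
#' @param d inverse mean handling time.
#' @param X,Y totals.
#' @return List with `x1_hat`, `x2_hat`, `f2`, and `f2_as_printed`.
#' @export
two_state_prey_closed_forms <- function(A12, A1, c1, c2, d, X, Y) {
  stopifnot(A12 > 0, A1 > 0, d > 0, c1 >= 0, c2 >= 0)
  x1 <- A12 * X / (A12 + A1 * Y)
  x2 <- A1 * Y * X / (A12 + A1 * Y)
  ctot <- c1 * x1 + c2 * x2
  f2 <- ctot / (1 + ctot / d)
  f2_printed <- (c1 * A12 * X + c2 * A1 * X * Y) /
    (1 + (A1 / A12) * Y + (c1 / d) * X + (c2 * A1 / (A12 * d)) * X * Y)
  list(x1_hat = x1, x2_hat = x2, f2 = f2, f2_as_printed = f2_printed)
}

#' Density-dependent handling time model
#'
#' One prey state; predators search (S) or handle (H). Searching predators
#' capture at rate `c1 X`; handlers return to searching spontaneously at
#' rate `d` or, abandoning the current catch when fresh prey is about, at
#' the prey-dependent rate `c2 X`. The builder wires the catalytic `c2 X`
#' transition through the prey-mediated tensor `C`.
#'
#' Closed forms: equilibrium shares `S/Y = (d + c2 X)/(d + (c1+c2) X)`,
#' `H/Y = c1 X/(d + (c1+c2) X)`; functional response
#' `f(X) = c1 X (c2 X + d) / (d + (c1+c2) X)`, a Holling type II form with
#' density-dependent handling time `1/(c2 X + d)`; conversion factor
#' `gamma(X) = 1/(c2 X + d)` (births proportional to the handler density),
#' so `gamma(0) = 1/d`.
#'
#' @param c1 attack rate (per prey density per time).
#' @param c2 handler abandonment rate coefficient (per prey density per
#'   time).
#' @param d spontaneous handling completion rate (per time).
#' @param demography optional [demography_rates()] override.
#' @return A `zoo_model`; closed evaluators take `X` (and `Y` where a
#'   density rather than a share is returned).
#' @export
dd_handling <- function(c1, c2, d, demography = NULL) {
  stopifnot(c1 > 0, c2 >= 0, d > 0)
  A <- matrix(0, 1, 1)
  C <- array(0, dim = c(2, 2, 1))
  C[2, 1, 1] <- c1
  C[1, 1, 1] <- -c1
  C[1, 2, 1] <- c2
  C[2, 2, 1] <- -c2
  D <- matrix(c(0, 0, d, -d), 2, 2)
  model <- transition_model(A, D, C = C, name = "dd_handling")
  rates <- if (is.null(demography)) {
    demography_rates(model = model, beta = matrix(c(c1, 0), 1, 2),
                     pred_offspring = c(1, 0))
  } else demography
  closed <- list(
    shares = function(X) {
      den <- d + (c1 + c2) * X
      c(S = (d + c2 * X) / den, H = c1 * X / den)
    },
    f = function(X) c1 * X * (c2 * X + d) / (d + (c1 + c2) * X),
    gamma_factor = function(X) 1 / (c2 * X + d),
    gamma_f = function(X) {
      c1 * X * (c2 * X + d) / ((d + (c1 + c2) * X) * (c2 * X + d))
    }
  )
  new_zoo_model("dd_handling", list(c1 = c1, c2 = c2, d = d),
                model, rates, closed)
}

starvation_denominator <- function(c1, c2, d1, d2, X) {
  d2 * (1 + c2 * X / d1) + c2 * X * (1 + c1 * X / d1)
}

#' Starvation-structured predator: a mechanistic type III response
#'
#' One prey state; predators occupy four states: well-fed searchers `S1`
#' (attack rate `c1`), starving searchers `S2` (attack rate `c2 < c1`),
#' and handlers `H1`, `H2` entered from `S1`, `S2` respectively. Handling
#' lasts `1/d1` on average and returns the predator to `S1`; a well-fed
#' searcher that fails to capture for `1/d2` starves into `S2`. Handlers
#' reproduce with per-capita fecundities `Gamma1` (`H1`) and `Gamma2`
#' (`H2`), offspring enter `S2`; searchers die at rates `delta1` (`S1`),
#' `delta2` (`S2`).
#'
#' The functional response
#' `f(X) = c2 X (d2 + c1 X) / (d2 (1 + c2 X/d1) + c2 X (1 + c1 X/d1))`
#' is sigmoid (type III) iff `c1/c2 > 1 + d2/d1` and saturates at `d1`.
#' The conversion factor `gamma(X) = (Gamma1 c1 X + Gamma2 d2) /
#' (d1 (d2 + c1 X))` rises to `Gamma1/d1`, the reproduction rate
#' `gamma(X) f(X)` saturates at `Gamma1`, and the mortality
#' `delta(X) = (delta1 c2 X + delta2 d2) / denominator` falls from
#' `delta2` at `X = 0`.
#'
#' @param c1,c2 attack rates of well-fed and starving searchers.
#' @param d1 handling completion rate; `1/d1` is the mean handling time.
#' @param d2 starvation rate of unfed well-fed searchers.
#' @param Gamma1,Gamma2 per-capita fecundities of `H1`, `H2` handlers.
#' @param delta1,delta2 mortality rates of `S1`, `S2` searchers.
#' @param lam,mu prey birth/death rates (slow scale), default 0.
#' @return A `zoo_model`. State order is `(S1, S2, H1, H2)`. Closed
#'   evaluators: `shares(X)` (equilibrium per unit Y), `f(X)`,
#'   `gamma_factor(X)`, `gamma_f(X)`, `delta_factor(X)`, `is_type3`,
#'   `holling3_coef` (canonical `(a, b, c, d)` of
#'   `(aX + bX^2)/(1 + cX + dX^2)`).
#' @export
starvation_predator <- function(c1, c2, d1, d2, Gamma1 = 0, Gamma2 = 0,
                                delta1 = 0, delta2 = 0, lam = 0, mu = 0) {
  stopifnot(c1 > 0, c2 > 0, d1 > 0, d2 > 0,
            Gamma1 >= 0, Gamma2 >= 0, delta1 >= 0, delta2 >= 0)
  A <- matrix(0, 1, 1)
  # predator states (S1, S2, H1, H2)
  C <- array(0, dim = c(4, 4, 1))
  C[3, 1, 1] <- c1; C[1, 1, 1] <- -c1    # S1 -> H1 at c1 X
  C[4, 2, 1] <- c2; C[2, 2, 1] <- -c2    # S2 -> H2 at c2 X
  D <- matrix(0, 4, 4)
  D[2, 1] <- d2; D[1, 1] <- -d2          # S1 -> S2 (starvation)
  D[1, 3] <- d1; D[3, 3] <- -d1          # H1 -> S1
  D[1, 4] <- d1; D[4, 4] <- -d1          # H2 -> S1
  model <- transition_model(A, D, C = C, name = "starvation_predator")
  # per-capture fecundity Gamma_j / d1 reproduces the handler-occupancy
  # birth rate Gamma1*H1 + Gamma2*H2 at the fast equilibrium (the capture
  # flux c_j X S_j balances d1 H_j there)
  rates <- demography_rates(model = model,
                            beta = matrix(c(c1, c2, 0, 0), 1, 4),
                            gamma = matrix(c(Gamma1 / d1, Gamma2 / d1, 0, 0),
                                           1, 4),
                            delta = c(delta1, delta2, 0, 0),
                            lam = lam, mu = mu,
                            pred_offspring = c(0, 1, 0, 0))
  closed <- list(
    shares = function(X) {
      den <- starvation_denominator(c1, c2, d1, d2, X)
      c(S1 = c2 * X, S2 = d2, H1 = c1 * c2 * X^2 / d1,
        H2 = c2 * d2 * X / d1) / den
    },
    f = function(X) {
      c2 * X * (d2 + c1 * X) / starvation_denominator(c1, c2, d1, d2, X)
    },
    gamma_factor = function(X) {
      (Gamma1 * c1 * X + Gamma2 * d2) / (d1 * (d2 + c1 * X))
    },
    gamma_f = function(X) {
      c2 * X * (Gamma1 * c1 * X + Gamma2 * d2) /
        (d1 * starvation_denominator(c1, c2, d1, d2, X))
    },
    delta_factor = function(X) {
      (delta1 * c2 * X + delta2 * d2) /
        starvation_denominator(c1, c2, d1, d2, X)
    },
    is_type3 = c1 / c2 > 1 + d2 / d1,
    holling3_coef = c(a = c2, b = c1 * c2 / d2,
                      c = c2 * (1 / d1 + 1 / d2), d = c1 * c2 / (d1 * d2))
  )
  new_zoo_model("starvation_predator",
                list(c1 = c1, c2 = c2, d1 = d1, d2 = d2, Gamma1 = Gamma1,
                     Gamma2 = Gamma2, delta1 = delta1, delta2 = delta2),
                model, rates, closed)
}

#' Experience-structured predator (alternative type III mechanism)
#'
#' Same functional response as [starvation_predator()] under a different
#' reading: `S1` are experienced searchers (attack rate `c1`), `S2`
#' inexperienced ones (`c2 < c1`); both enter a single handling class `H`
#' after a capture, handle for `1/d1`, and exit handling experienced;
#' experience fades at rate `d2`.
#'
#' @inheritParams starvation_predator
#' @return A `zoo_model` with state order `(S1, S2, H)`. Closed
#'   evaluators: `shares(X)` returning `(S1, S2, H)/Y` and `f(X)`
#'   (identical to the starvation-model response).
#' @export
experience_predator <- function(c1, c2, d1, d2) {
  stopifnot(c1 > 0, c2 > 0, d1 > 0, d2 > 0)
  A <- matrix(0, 1, 1)
  C <- array(0, dim = c(3, 3, 1))
  C[3, 1, 1] <- c1; C[1, 1, 1] <- -c1    # S1 -> H
  C[3, 2, 1] <- c2; C[2, 2, 1] <- -c2    # S2 -> H
  D <- matrix(0, 3, 3)
  D[2, 1] <- d2; D[1, 1] <- -d2          # S1 -> S2 (experience fades)
  D[1, 3] <- d1; D[3, 3] <- -d1          # H -> S1
  model <- transition_model(A, D, C = C, name = "experience_predator")
  rates <- demography_rates(model = model,
                            beta = matrix(c(c1, c2, 0), 1, 3),
                            pred_offspring = c(0, 0, 1))
  closed <- list(
    shares = function(X) {
      den <- starvation_denominator(c1, c2, d1, d2, X)
      c(S1 = c2 * X, S2 = d2,
        H = (c1 * c2 * X^2 + c2 * d2 * X) / d1) / den
    },
    f = function(X) {
      c2 * X * (d2 + c1 * X) / starvation_denominator(c1, c2, d1, d2, X)
    }
  )
  new_zoo_model("experience_predator",
                list(c1 = c1, c2 = c2, d1 = d1, d2 = d2),
                model, rates, closed)
}

#' Panic model: mutual state dependence and a predator Allee effect
#'
#' Prey are exposed (`E`) or protected (`P`); predators search (`S`) or
#' handle (`H`). Searching predators flush protected prey into the exposed
#' state at rate `b S` (panic); exposed prey regain protection at rate `a`.
#' Searchers capture exposed prey at rate `c E` and handle for `1/d`.
#' With `p = a/b`, `q = d/c` and
#' \eqn{\Delta = q (p^2 q + 2 p (q + 2X) Y + q Y^2)}, the fast equilibrium
#' is evaluated in cancellation-free form
#' `E = 2 q X Y / (sqrt(Delta) + q (p + Y))`,
#' `H = 2 X Y^2 / (u + sqrt(Delta))` with `u = p q + q Y + 2 X Y`,
#' `P = X - E`, `S = Y - H`, and the functional response is
#' `f = c E S / Y = d H / Y = 2 d X Y / (u + sqrt(Delta))`.
#'
#' Limits: as `p -> 0` (prey mostly exposed) `f -> c X / (1 + c X / d)`
#' (Holling II); as `q -> infinity` (predators mostly searching)
#' `f -> c X Y / (p + Y)`, whose `X Y` numerator makes the predator birth
#' rate quadratic in `Y` at low density - an Allee effect.
#'
#' @param a spontaneous protection rate of exposed prey (per time).
#' @param b panic rate coefficient (per searching-predator density).
#' @param c attack rate on exposed prey (per exposed-prey density).
#' @param d handling completion rate.
#' @param Gamma per-capita fecundity rate of handling predators; the
#'   per-capture conversion is `Gamma / d`.
#' @param delta1,delta2 mortality of searching / handling predators.
#' @param lamP birth rate of protected prey (only `P` reproduces).
#' @param mu1,mu2 death rates of exposed / protected prey.
#' @return A `zoo_model` with prey order `(E, P)`, predator order
#'   `(S, H)`. Closed evaluators: `equilibrium(X, Y)` giving
#'   `(E, P, S, H)`, `f(X, Y)`, `pred_birth_prop(X, Y) = H/Y = f/d`,
#'   `pred_death(X, Y)`, `prey_birth_prop(X, Y) = P/X`,
#'   `prey_death(X, Y)`, and the limit forms `f_p0(X)`, `f_qinf(X, Y)`.
#' @export
panic_model <- function(a, b, c, d, Gamma = 0, delta1 = 0, delta2 = 0,
                        lamP = 0, mu1 = 0, mu2 = 0) {
  stopifnot(a > 0, b > 0, c > 0, d > 0)
  # prey (E, P): E -> P spontaneous at a; P -> E mediated by S at b
  A <- matrix(c(-a, a, 0, 0), 2, 2)
  B <- array(0, dim = c(2, 2, 2))
  B[1, 2, 1] <- b
  B[2, 2, 1] <- -b
  # predators (S, H): S -> H mediated by E at c; H -> S spontaneous at d
  C <- array(0, dim = c(2, 2, 2))
  C[2, 1, 1] <- c
  C[1, 1, 1] <- -c
  D <- matrix(c(0, 0, d, -d), 2, 2)
  model <- transition_model(A, D, B, C, name = "panic_model")
  rates <- demography_rates(model = model,
                            beta = matrix(c(c, 0, 0, 0), 2, 2),
                            gamma = matrix(c(Gamma / d, 0, 0, 0), 2, 2),
                            delta = c(delta1, delta2),
                            lam = c(0, lamP), mu = c(mu1, mu2),
                            prey_offspring = c(0, 1),
                            pred_offspring = c(1, 0))
  p <- a / b
  q <- d / c
  equilibrium <- function(X, Y) {
    Delta <- q * (p^2 * q + 2 * p * (q + 2 * X) * Y + q * Y^2)
    sD <- sqrt(Delta)
    u <- p * q + q * Y + 2 * X * Y
    E <- 2 * q * X * Y / (sD + q * (p + Y))
    H <- 2 * X * Y^2 / (u + sD)
    c(E = E, P = X - E, S = Y - H, H = H)
  }
  f <- function(X, Y) {
    Delta <- q * (p^2 * q + 2 * p * (q + 2 * X) * Y + q * Y^2)
    u <- p * q + q * Y + 2 * X * Y
    2 * d * X * Y / (u + sqrt(Delta))
  }
  closed <- list(
    p = p, q = q,
    Delta = function(X, Y) q * (p^2 * q + 2 * p * (q + 2 * X) * Y + q * Y^2),
    equilibrium = equilibrium,
    f = f,
    pred_birth_prop = function(X, Y) f(X, Y) / d,
    pred_death = function(X, Y) {
      fr <- f(X, Y) / d
      delta1 * (1 - fr) + delta2 * fr
    },
    prey_birth_prop = function(X, Y) {
      fv <- f(X, Y)
      1 - d * fv / (c * X * (d - fv))
    },
    prey_death = function(X, Y) {
      fv <- f(X, Y)
      eshare <- d * fv / (c * X * (d - fv))
      mu1 * eshare + mu2 * (1 - eshare)
    },
    f_p0 = function(X) c * X / (1 + c * X / d),
    f_qinf = function(X, Y) c * X * Y / (p + Y)
  )
  new_zoo_model("panic_model",
                list(a = a, b = b, c = c, d = d, p = p, q = q,
                     Gamma = Gamma, delta1 = delta1, delta2 = delta2,
                     lamP = lamP, mu1 = mu1, mu2 = mu2),
                model, rates, closed)
}

#' Canonical functional-response coefficient mappings
#'
#' Maps the mechanistic parameter sets of the zoo models onto the textbook
#' coefficient conventions: Holling type II `a X / (1 + b X)`, Holling
#' type III `(a X + b X^2) / (1 + c X + d X^2)`, and Beddington-DeAngelis
#' `a X / (1 + b X + c Y)`.
#'
#' @param kind one of `"holling2"`, `"holling3"`,
#'   `"beddington_deangelis"`.
#' @param params named list: `holling2` needs `c1`, `d`; `holling3` needs
#'   `c1`, `c2`, `d1`, `d2`; `beddington_deangelis` needs `c1`, `d`, `A1`,
#'   `A12` (the two-prey-state model with `c2 = 0`).
#' @return List with `kind`, `coef` (named numeric vector) and
#'   `evaluate(X, Y)`. For Beddington-DeAngelis the often-quoted coefficient
#'   `a = c1 * A12` is additionally exposed as `coef_as_printed`; the
#'   internally consistent mapping is `a = c1`, `b = c1/d`, `c = A1/A12`.
#' @export
holling_bd_mappings <- function(kind, params) {
  kind <- match.arg(kind, c("holling2", "holling3", "beddington_deangelis"))
  p <- params
  switch(kind,
    holling2 = {
      coef <- c(a = p$c1, b = p$c1 / p$d)
      list(kind = kind, coef = coef,
           evaluate = function(X, Y = NULL) coef[["a"]] * X /
             (1 + coef[["b"]] * X))
    },
    holling3 = {
      coef <- c(a = p$c2, b = p$c1 * p$c2 / p$d2,
                c = p$c2 * (1 / p$d1 + 1 / p$d2),
                d = p$c1 * p$c2 / (p$d1 * p$d2))
      list(kind = kind, coef = coef,
           evaluate = function(X, Y = NULL) {
             (coef[["a"]] * X + coef[["b"]] * X^2) /
               (1 + coef[["c"]] * X + coef[["d"]] * X^2)
           })
    },
    beddington_deangelis = {
      coef <- c(a = p$c1, b = p$c1 / p$d, c = p$A1 / p$A12)
      list(kind = kind, coef = coef,
           coef_as_printed = c(a = p$c1 * p$A12, b = p$c1 / p$d,
                               c = p$A1 / p$A12),
           evaluate = function(X, Y) {
             coef[["a"]] * X / (1 + coef[["b"]] * X + coef[["c"]] * Y)
           })
    })
}

#' Build a zoo model by name
#'
#' Dispatcher used by the command-line interface.
#'
#' @param name one of `"tiered"`, `"two_state_prey"`, `"dd_handling"`,
#'   `"starvation"`, `"experience"`, `"panic"`.
#' @param params named list of parameters forwarded to the builder;
#'   missing entries fall back to the documented reference parameter sets
#'   (see [zoo_default_params()]).
#' @return A `zoo_model`.
#' @export
build_zoo_model <- function(name, params = list()) {
  name <- match.arg(name, c("tiered", "two_state_prey", "dd_handling",
                            "starvation", "experience", "panic"))
  p <- utils::modifyList(zoo_default_params(name), params)
  switch(name,
    tiered = ,
    two_state_prey = tiered_prey(m = 2, A_spont = p$A12, A_pred = p$A1,
                                 c = c(p$c1, p$c2), d = p$d),
    dd_handling = dd_handling(p$c1, p$c2, p$d),
    starvation = starvation_predator(p$c1, p$c2, p$d1, p$d2, p$Gamma1,
                                     p$Gamma2, p$delta1, p$delta2),
    experience = experience_predator(p$c1, p$c2, p$d1, p$d2),
    panic = panic_model(p$a, p$b, p$c, p$d))
}

#' Default parameter sets for the zoo models
#'
#' Reference parameter sets: the two-prey-state response with
#' `c1 = 10 < c2 = 15` (increasing in Y; its `c1 = 20 > c2 = 10` variant
#' decreases in Y), the density-dependent-handling response with `d = 1`,
#' the starvation model with `c1 = 10`, `c2 = 0.2`, `d1 = 4`, `d2 = 3`,
#' fecundities 10 and 2, mortalities 0.2 and 0.5, and the panic model with
#' `a = 1`, `b = 0.2`, `c = 10`, `d = 1`. The two-prey-state set is
#' sometimes quoted with a constant `A21 = 2`; since the upward rate is by
#' construction `A1 * Y`, the free constant can only be the spontaneous
#' return rate and it is read here as `A12 = 2`.
#'
#' @param name zoo model name as in [build_zoo_model()].
#' @return Named list of parameters.
#' @export
zoo_default_params <- function(name) {
  switch(name,
    tiered = ,
    two_state_prey = list(c1 = 10, c2 = 15, d = 1, A1 = 0.5, A12 = 2),
    dd_handling = list(c1 = 50, c2 = 2, d = 1),
    starvation = list(c1 = 10, c2 = 0.2, d1 = 4, d2 = 3, Gamma1 = 10,
                      Gamma2 = 2, delta1 = 0.2, delta2 = 0.5),
    experience = list(c1 = 10, c2 = 0.2, d1 = 4, d2 = 3),
    panic = list(a = 1, b = 0.2, c = 10, d = 1),
    stop("unknown zoo model: ", name, call. = FALSE))
}
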