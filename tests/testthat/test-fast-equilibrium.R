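test_that("linear stationary solve matches hand-computed distributions", {
  # nullspace of [[-1,2],[1,-2]] is x1 = 2 x2
  expect_equal(solve_linear_stationary(matrix(c(-1, 1, 2, -2), 2, 2), 3),
               c(2, 1), tolerance = 1e-12)
  # symmetric chain splits evenly
  expect_equal(solve_linear_stationary(matrix(c(-1, 1, 1, -1), 2, 2), 2),
               c(1, 1), tolerance = 1e-12)
  # single state carries the whole total
  expect_identical(solve_linear_stationary(matrix(0, 1, 1), 5), 5)
})

test_that("reducible matrices with several closed classes raise a naming error", {
  fx <- degenerate_fixtures()
  expect_error(solve_linear_stationary(fx$reducible$A, 1),
               "closed communicating classes")
  err <- tryCatch(solve_linear_stationary(fx$reducible$A, 1),
                  error = conditionMessage)
  expect_match(err, "1,2")
  expect_match(err, "3,4")
  # a single absorbing state is fine: unique stationary distribution exists
  M <- matrix(c(-1, 1, 0, 0), 2, 2)
  expect_equal(solve_linear_stationary(M, 3), c(0, 3), tolerance = 1e-12)
  # non-conservative input is rejected
  expect_error(solve_linear_stationary(matrix(c(-1, 0.5, 2, -2), 2, 2), 1),
               "not conservative")
})

test_that("birth-death chain closed form matches examples and the generic solver", {
  expect_equal(birth_death_chain_equilibrium(1, 1, 2), c(1, 1))
  # ratios 2 and 4 against weight 1: (1, 2, 4) at X = 7
  expect_equal(birth_death_chain_equilibrium(c(2, 2), c(1, 1), 7), c(1, 2, 4),
               tolerance = 1e-12)
  expect_error(birth_death_chain_equilibrium(c(1, 1), c(1, 0), 1), "positive")
  # oracle equivalence with the tridiagonal generator
  set.seed(42)
  for (rep in 1:10) {
    m <- sample(2:6, 1)
    up <- stats::rexp(m - 1) + 0.1
    down <- stats::rexp(m - 1) + 0.1
    X <- stats::rexp(1) * 5
    M <- matrix(0, m, m)
    for (i in seq_len(m - 1)) {
      M[i + 1, i] <- M[i + 1, i] + up[i]
      M[i, i] <- M[i, i] - up[i]
      M[i, i + 1] <- M[i, i + 1] + down[i]
      M[i + 1, i + 1] <- M[i + 1, i + 1] - down[i]
    }
    expect_equal(birth_death_chain_equilibrium(up, down, X),
                 solve_linear_stationary(M, X), tolerance = 1e-10)
  }
})

test_that("triangular solve reproduces closed forms and refuses coupled prey", {
  # starvation model with all parameters 1 at X = Y = 1: shares are 1/4 each
  sv <- starvation_predator(1, 1, 1, 1)
  eq <- solve_triangular(sv$model, 1, 1)
  expect_true(eq$converged)
  expect_equal(eq$y_hat, rep(0.25, 4), tolerance = 1e-10)
  # one prey state, S/H predator, c1 = 2, d = 1: y = (1/3, 2/3)
  dz <- tiered_prey(1, c = 2, d = 1)
  eq2 <- solve_triangular(dz$model, 1, 1)
  expect_equal(eq2$y_hat, c(1 / 3, 2 / 3), tolerance = 1e-10)
  # fully linear model decouples into two independent stationary solves
  lin <- linear_model_22()
  eq3 <- solve_triangular(lin, 3, 2)
  expect_equal(eq3$x_hat, solve_linear_stationary(lin$A, 3), tolerance = 1e-12)
  expect_equal(eq3$y_hat, solve_linear_stationary(lin$D, 2), tolerance = 1e-12)
  # models with predator-mediated prey transitions are refused
  zm <- panic_unit()
  expect_error(solve_triangular(zm$model, 1, 1), "solve_nonlinear")
})

test_that("nonlinear solver reproduces the panic-model closed equilibrium", {
  zm <- panic_unit()
  eq <- solve_nonlinear(zm$model, 1, 1)
  expect_true(eq$converged)
  expect_equal(eq$x_hat, c(0.41421, 0.58579), tolerance = 1e-4)
  expect_equal(eq$y_hat, c(0.70711, 0.29289), tolerance = 1e-4)
  expect_lt(abs(sum(eq$x_hat) - 1), 1e-10 * 2)
  expect_lt(abs(sum(eq$y_hat) - 1), 1e-10 * 2)
  # closed form to full precision
  cf <- zm$closed$equilibrium(1, 1)
  expect_equal(c(eq$x_hat, eq$y_hat), unname(cf), tolerance = 1e-9)
})

test_that("nonlinear solver boundary and reduction cases", {
  zm <- panic_unit()
  # empty prey: x = 0, predators equilibrate on C(0) + D
  eq0 <- solve_nonlinear(zm$model, 0, 2)
  expect_identical(eq0$x_hat, c(0, 0))
  expect_equal(eq0$y_hat,
               solve_linear_stationary(zm$model$D +
                 frmech:::contract_mediator(zm$model$C, c(0, 0)), 2),
               tolerance = 1e-10)
  # B = C = 0 reduces to the triangular result
  lin <- linear_model_22()
  eqn <- solve_nonlinear(lin, 3, 2)
  eqt <- solve_triangular(lin, 3, 2)
  expect_equal(eqn$x_hat, eqt$x_hat, tolerance = 1e-10)
  expect_equal(eqn$y_hat, eqt$y_hat, tolerance = 1e-10)
  # totals conserved for arbitrary totals
  eqb <- solve_nonlinear(zm$model, 17.3, 0.04)
  expect_lt(abs(sum(eqb$x_hat) - 17.3), 1e-10 * 18.3)
  expect_lt(abs(sum(eqb$y_hat) - 0.04), 1e-10 * 1.04)
  # relaxed models are refused without the override
  fx <- degenerate_fixtures()
  expect_error(solve_nonlinear(fx$flat, 1, 1), "relaxed")
})

test_that("linear case is independent of the starting distribution", {
  lin <- linear_model_22()
  set.seed(5)
  ref <- solve_nonlinear(lin, 3, 2)
  for (rep in 1:5) {
    x0 <- stats::runif(2)
    y0 <- stats::runif(2)
    eq <- solve_nonlinear(lin, 3, 2, x0 = x0, y0 = y0)
    expect_equal(eq$x_hat, ref$x_hat, tolerance = 1e-10)
    expect_equal(eq$y_hat, ref$y_hat, tolerance = 1e-10)
  }
})

test_that("stability assessment finds two conservation zeros and negative spectrum", {
  zm <- panic_unit()
  eq <- solve_nonlinear(zm$model, 1, 1)
  st <- assess_stability(zm$model, eq)
  expect_identical(st$zero_count, 2L)
  expect_lt(st$max_nonzero_real_part, 0)
  expect_true(st$hyperbolically_stable)
  # irreducible linear model: exponentially fast convergence
  lin <- linear_model_22()
  stl <- assess_stability(lin, solve_nonlinear(lin, 1, 1))
  expect_true(stl$hyperbolically_stable)
  # trivial 1+1 model: both eigenvalues zero, vacuously stable
  triv <- transition_model(matrix(0, 1, 1), matrix(0, 1, 1))
  stt <- assess_stability(triv, solve_nonlinear(triv, 1, 1))
  expect_identical(stt$zero_count, 2L)
  expect_true(stt$hyperbolically_stable)
})

test_that("hyperbolic stability implies return from small perturbations", {
  zm <- panic_model(1, 0.2, 10, 1)
  eq <- solve_nonlinear(zm$model, 1, 1)
  expect_true(assess_stability(zm$model, eq)$hyperbolically_stable)
  set.seed(9)
  for (rep in 1:3) {
    # perturb within the conservation set (zero-sum noise per species)
    dx <- stats::runif(2, -1, 1) * 1e-3
    dx <- dx - mean(dx)
    dy <- stats::runif(2, -1, 1) * 1e-3
    dy <- dy - mean(dy)
    end <- integrate_fast_to_rest(zm$model, eq$x_hat + dx, eq$y_hat + dy,
                                  t_max = 200)
    expect_lt(max(abs(c(end$x - eq$x_hat, end$y - eq$y_hat))), 1e-6)
  }
})

test_that("uniqueness probe: one equilibrium for the zoo models, many for the flat fixture", {
  zm <- panic_unit()
  pu <- probe_uniqueness(zm$model, 1, 1, n_starts = 8, seed = 2)
  expect_identical(pu$n_distinct, 1L)
  expect_identical(pu$n_nonconverged, 0L)
  lin <- linear_model_22()
  pul <- probe_uniqueness(lin, 2, 3, n_starts = 5, seed = 2)
  expect_identical(pul$n_distinct, 1L)
  # flat relaxed model: every distribution is stationary
  fx <- degenerate_fixtures()
  puf <- probe_uniqueness(fx$flat, 1, 1, n_starts = 10, seed = 2,
                          allow_relaxed = TRUE)
  expect_gte(puf$n_distinct, 2L)
  # seeded: reproducible
  puf2 <- probe_uniqueness(fx$flat, 1, 1, n_starts = 10, seed = 2,
                           allow_relaxed = TRUE)
  expect_identical(puf$n_distinct, puf2$n_distinct)
})

test_that("forward integration agrees with the fixed-point solver on random models", {
  # scaled-down version of the oracle-equivalence property (the full
  # 100-model sweep lives in the acceptance suite for the algebraic
  # invariants; integration here is the expensive part)
  for (seed in 1:8) {
    model <- random_model(m = 1 + seed %% 3, n = 1 + (seed + 1) %% 3,
                          density = 0.7, seed = seed + 50)
    X <- 1 + (seed %% 3)
    Y <- 0.5 + (seed %% 2)
    eq <- solve_nonlinear(model, X, Y)
    expect_true(eq$converged, label = sprintf("seed %d", seed))
    set.seed(seed)
    x0 <- X * stats::runif(model$m)
    x0 <- x0 / sum(x0) * X
    y0 <- Y * stats::runif(model$n)
    y0 <- y0 / sum(y0) * Y
    end <- integrate_fast_to_rest(model, x0, y0, t_max = 400)
    expect_lt(max(abs(c(end$x - eq$x_hat, end$y - eq$y_hat))) / (1 + X + Y),
              1e-6)
  }
})
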