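test_that("tiered prey reduces to Holling II for one prey state", {
  z <- tiered_prey(1, c = 1, d = 1)
  # f = c1 X / (1 + c1 X / d): at X = 1, f = 0.5
  expect_equal(z$closed$f(1, 1), 0.5)
  # no predator-mediated prey states: independent of Y
  expect_equal(z$closed$f(1, 100), z$closed$f(1, 0.01))
  expect_equal(functional_response(z$model, z$rates, 1, 7), 0.5,
               tolerance = 1e-12)
})

test_that("tiered prey saturates at d for superabundant prey", {
  z <- tiered_twostate(twostate_params_inc())
  expect_equal(z$closed$f(1e8, 2), 1, tolerance = 1e-6)
  expect_error(tiered_prey(2, A_spont = 0, A_pred = 1, c = c(1, 1), d = 1),
               "positive")
})

test_that("two-prey-state closed forms: boundary, hand value, printed-form factor", {
  # Y = 0: all prey defended, plain Holling II in c1
  cf0 <- two_state_prey_closed_forms(2, 0.5, 10, 15, 1, X = 3, Y = 0)
  expect_equal(cf0$x1_hat, 3)
  expect_equal(cf0$x2_hat, 0)
  expect_equal(cf0$f2, 10 * 3 / (1 + 10 * 3 / 1))
  # all parameters 1 at X = Y = 1: equal split, f2 = 0.5
  cf1 <- two_state_prey_closed_forms(1, 1, 1, 1, 1, X = 1, Y = 1)
  expect_equal(cf1$x1_hat, 0.5)
  expect_equal(cf1$x2_hat, 0.5)
  expect_equal(cf1$f2, 0.5)
  # the as-printed variant carries a spurious A12 factor
  set.seed(21)
  for (rep in 1:5) {
    p <- as.list(stats::runif(5, 0.2, 3))
    names(p) <- c("A12", "A1", "c1", "c2", "d")
    cf <- two_state_prey_closed_forms(p$A12, p$A1, p$c1, p$c2, p$d,
                                      X = 2, Y = 1.5)
    expect_equal(cf$f2_as_printed, p$A12 * cf$f2, tolerance = 1e-12)
  }
})

test_that("two-prey-state closed forms agree with the generic tiered machinery", {
  set.seed(33)
  for (rep in 1:6) {
    A12 <- stats::runif(1, 0.3, 3)
    A1 <- stats::runif(1, 0.3, 3)
    c1 <- stats::runif(1, 0.1, 5)
    c2 <- stats::runif(1, 0.1, 5)
    d <- stats::runif(1, 0.3, 3)
    X <- stats::rexp(1) * 2 + 0.05
    Y <- stats::rexp(1) + 0.05
    cf <- two_state_prey_closed_forms(A12, A1, c1, c2, d, X, Y)
    z <- tiered_prey(2, A_spont = A12, A_pred = A1, c = c(c1, c2), d = d)
    expect_equal(z$closed$f(X, Y), cf$f2, tolerance = 1e-12)
    eq <- solve_nonlinear(z$model, X, Y)
    expect_equal(eq$x_hat, c(cf$x1_hat, cf$x2_hat), tolerance = 1e-9)
    expect_equal(functional_response(z$model, z$rates, X, Y, eq = eq),
                 cf$f2, tolerance = 1e-9)
  }
})

test_that("density-dependent handling: closed forms and limits", {
  dz <- dd_handling(2, 1, 1)
  expect_equal(unname(dz$closed$shares(1)), c(0.5, 0.5))
  expect_equal(dz$closed$f(1), 1)
  # X = 0: no captures, conversion factor is the plain handling time 1/d
  expect_equal(dz$closed$f(0), 0)
  expect_equal(dz$closed$gamma_factor(0), 1)
  # c2 = 0 restores the constant handling time (Holling II)
  d0 <- dd_handling(2, 0, 1)
  h2 <- holling_bd_mappings("holling2", list(c1 = 2, d = 1))
  for (X in c(0.1, 1, 10)) {
    expect_equal(d0$closed$f(X), h2$evaluate(X), tolerance = 1e-12)
  }
  # handling time 1/(c2 X + d) ties f to the Holling-II-with-variable-
  # handling formulation
  dzf <- dd_handling(50, 2, 1)
  for (X in c(0.2, 2)) {
    ht <- 1 / (2 * X + 1)
    expect_equal(dzf$closed$f(X), 50 * X / (1 + ht * 50 * X),
                 tolerance = 1e-12)
    expect_equal(dzf$closed$gamma_factor(X), ht)
  }
})

test_that("starvation model: hand values, convexity criterion, coefficient mapping", {
  sv1 <- starvation_predator(1, 1, 1, 1, 1, 1, 1, 1)
  expect_equal(unname(sv1$closed$shares(1)), rep(0.25, 4))
  expect_equal(sv1$closed$f(1), 0.5)
  expect_equal(sv1$closed$gamma_factor(1), 1)
  expect_equal(sv1$closed$delta_factor(1), 0.5)
  expect_false(sv1$closed$is_type3)    # c1/c2 = 1 < 1 + d2/d1 = 2

  sv <- starvation_ref()
  expect_true(sv$closed$is_type3)      # 10/0.2 = 50 > 1 + 3/4
  # canonical type III form agrees with the mechanistic form pointwise
  set.seed(8)
  for (rep in 1:8) {
    pr <- stats::runif(4, 0.2, 5)
    svr <- starvation_predator(pr[1], pr[2], pr[3], pr[4])
    h3 <- holling_bd_mappings("holling3", list(c1 = pr[1], c2 = pr[2],
                                               d1 = pr[3], d2 = pr[4]))
    for (X in c(0.05, 0.7, 13)) {
      expect_equal(svr$closed$f(X), h3$evaluate(X), tolerance = 1e-12)
    }
  }
})

test_that("starvation closed forms agree with the generic machinery", {
  sv <- starvation_ref()
  for (X in 10^seq(-2, 2, length.out = 8)) {
    eq <- solve_triangular(sv$model, X, 3)
    expect_equal(eq$y_hat / 3, unname(sv$closed$shares(X)), tolerance = 1e-10)
    pr <- predator_numerical_response(sv$model, sv$rates, X, 3, eq = eq)
    expect_equal(pr$f, sv$closed$f(X), tolerance = 1e-10)
    expect_equal(pr$gamma_f, sv$closed$gamma_f(X), tolerance = 1e-10)
    expect_equal(pr$delta_factor, sv$closed$delta_factor(X),
                 tolerance = 1e-10)
  }
})

test_that("starvation limit: c2 -> 0 with c1 c2 fixed gives the classic type III form", {
  # keep c1 c2 = 2 while c2 -> 0
  c2 <- 1e-6
  c1 <- 2 / c2
  sv <- starvation_predator(c1, c2, 4, 3)
  b <- c1 * c2 / 3
  d <- c1 * c2 / (4 * 3)
  for (X in c(0.1, 1, 5)) {
    expect_lt(rel_err(sv$closed$f(X), b * X^2 / (1 + d * X^2)), 1e-4)
  }
})

test_that("experience model shares the starvation response with a merged handler pool", {
  ez1 <- experience_predator(1, 1, 1, 1)
  expect_equal(unname(ez1$closed$shares(1)), c(0.25, 0.25, 0.5))
  ez <- experience_predator(10, 0.2, 4, 3)
  sv <- starvation_ref()
  for (X in 10^seq(-2, 2, length.out = 8)) {
    sh_e <- ez$closed$shares(X)
    sh_s <- sv$closed$shares(X)
    expect_equal(unname(sh_e[c("S1", "S2")]), unname(sh_s[c("S1", "S2")]),
                 tolerance = 1e-12)
    expect_equal(unname(sh_e["H"]), unname(sh_s["H1"] + sh_s["H2"]),
                 tolerance = 1e-12)
    expect_equal(ez$closed$f(X), sv$closed$f(X), tolerance = 1e-12)
    # generic route agrees too
    expect_equal(functional_response(ez$model, ez$rates, X, 2),
                 ez$closed$f(X), tolerance = 1e-9)
  }
})

test_that("panic model: hand values, conservation, response identities", {
  zm <- panic_unit()
  eqc <- zm$closed$equilibrium(1, 1)
  expect_equal(unname(eqc), c(0.41421, 0.58579, 0.70711, 0.29289),
               tolerance = 1e-4)
  expect_equal(zm$closed$f(1, 1), 0.29289, tolerance = 1e-4)
  # f = c E S / Y = d H / Y (two forms of the same flux)
  expect_equal(zm$closed$f(1, 1),
               1 * eqc[["E"]] * eqc[["S"]] / 1, tolerance = 1e-12)
  set.seed(14)
  for (rep in 1:10) {
    pars <- stats::runif(4, 0.2, 4)
    z <- panic_model(pars[1], pars[2], pars[3], pars[4],
                     delta1 = 0.2, delta2 = 0.6, mu1 = 0.3, mu2 = 0.1)
    X <- stats::rexp(1) * 3 + 0.01
    Y <- stats::rexp(1) * 2 + 0.01
    e <- z$closed$equilibrium(X, Y)
    expect_lt(abs(e[["E"]] + e[["P"]] - X), 1e-12 * (1 + X))
    expect_lt(abs(e[["S"]] + e[["H"]] - Y), 1e-12 * (1 + Y))
    # residual of the fast field at the closed-form equilibrium
    fld <- fast_vector_field(z$model, list(x = e[1:2], y = e[3:4]))
    expect_lt(max(abs(c(fld$dx, fld$dy))), 1e-10 * (1 + X) * (1 + Y) *
                max(pars))
    # birth/death identities in terms of f
    fv <- z$closed$f(X, Y)
    expect_equal(z$closed$pred_birth_prop(X, Y), e[["H"]] / Y,
                 tolerance = 1e-12)
    expect_equal(z$closed$pred_death(X, Y),
                 0.2 * e[["S"]] / Y + 0.6 * e[["H"]] / Y, tolerance = 1e-12)
    expect_equal(z$closed$prey_birth_prop(X, Y), e[["P"]] / X,
                 tolerance = 1e-9)
    expect_equal(z$closed$prey_death(X, Y),
                 0.3 * e[["E"]] / X + 0.1 * e[["P"]] / X, tolerance = 1e-9)
    expect_equal(fv, pars[4] * e[["H"]] / Y, tolerance = 1e-12)
  }
})

test_that("panic model limits: Holling II as p -> 0, searching-dominated as q -> infinity", {
  # p -> 0: a tiny, b large
  zp <- panic_model(a = 1e-8, b = 1, c = 10, d = 1)
  for (X in c(0.2, 1, 5)) {
    expect_lt(rel_err(zp$closed$f(X, 1), zp$closed$f_p0(X)), 1e-4)
  }
  # q -> infinity: d huge relative to c
  zq <- panic_model(a = 1, b = 0.2, c = 1, d = 1e8)
  for (X in c(0.2, 1, 5)) {
    expect_lt(rel_err(zq$closed$f(X, 0.7), zq$closed$f_qinf(X, 0.7)), 1e-4)
  }
})

test_that("panic closed equilibrium matches the generic solver over parameters", {
  set.seed(4)
  for (rep in 1:5) {
    pars <- stats::runif(4, 0.3, 3)
    z <- panic_model(pars[1], pars[2], pars[3], pars[4])
    X <- stats::rexp(1) * 2 + 0.05
    Y <- stats::rexp(1) + 0.05
    e <- z$closed$equilibrium(X, Y)
    eq <- solve_nonlinear(z$model, X, Y)
    expect_true(eq$converged)
    expect_equal(c(eq$x_hat, eq$y_hat), unname(e), tolerance = 1e-8)
    expect_equal(functional_response(z$model, z$rates, X, Y, eq = eq),
                 z$closed$f(X, Y), tolerance = 1e-8)
  }
})

test_that("Beddington-DeAngelis mapping matches the mechanistic c2 = 0 response", {
  p <- list(c1 = 10, d = 1, A1 = 0.5, A12 = 2)
  bd <- holling_bd_mappings("beddington_deangelis", p)
  expect_equal(unname(bd$coef), c(10, 10, 0.25))
  expect_equal(unname(bd$coef_as_printed["a"]), p$c1 * p$A12)
  for (X in c(0.3, 2)) {
    for (Y in c(0.5, 4)) {
      cf <- two_state_prey_closed_forms(p$A12, p$A1, p$c1, 0, p$d, X, Y)
      expect_equal(bd$evaluate(X, Y), cf$f2, tolerance = 1e-12)
    }
  }
  expect_error(holling_bd_mappings("nope", list()), "arg")
})

test_that("predator growth is superlinear in Y when only exposed prey are caught (Allee signature)", {
  # two-prey-state model with c1 = 0: captures require predator-induced
  # exposure, so gamma * f * Y ~ Y^2 at small Y
  p <- twostate_params_inc()
  z <- tiered_prey(2, A_spont = p$A12, A_pred = p$A1, c = c(0, p$c2),
                   d = p$d)
  X <- 0.1
  growth <- function(Y) {
    pr <- predator_numerical_response(z$model, z$rates, X, Y)
    pr$gamma_f * Y
  }
  g1 <- growth(0.02)
  g2 <- growth(0.01)
  expect_gt(g1 / g2, 2 * 1.5)  # halving Y cuts growth by much more than half
})

test_that("zoo dispatcher builds every named model with reference defaults", {
  for (nm in c("tiered", "two_state_prey", "dd_handling", "starvation",
               "experience", "panic")) {
    z <- build_zoo_model(nm)
    expect_s3_class(z, "zoo_model")
    expect_identical(nrow(validate_consistency(z$model)), 0L, label = nm)
  }
  z <- build_zoo_model("panic", list(b = 1))
  expect_equal(z$params$b, 1)
  expect_equal(z$params$a, 1)
})
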