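# shared fixtures: tiny models built in code

rel_err <- function(a, b) {
  abs(a - b) / pmax(abs(b), .Machine$double.xmin)
}

# 2-prey / 2-predator linear model (B = C = 0), irreducible
linear_model_22 <- function() {
  transition_model(A = matrix(c(-1, 1, 2, -2), 2, 2),
                   D = matrix(c(-3, 3, 1, -1), 2, 2),
                   name = "linear22")
}

# the all-ones panic model used for hand-checked values
panic_unit <- function() panic_model(a = 1, b = 1, c = 1, d = 1)

# reference parameter sets (defaults of the shipped applications)
twostate_params_inc <- function() list(c1 = 10, c2 = 15, d = 1, A1 = 0.5, A12 = 2)
twostate_params_dec <- function() list(c1 = 20, c2 = 10, d = 1, A1 = 0.5, A12 = 2)
starvation_params_ref <- function() list(c1 = 10, c2 = 0.2, d1 = 4, d2 = 3,
                               Gamma1 = 10, Gamma2 = 2,
                               delta1 = 0.2, delta2 = 0.5)

tiered_twostate <- function(p) {
  tiered_prey(2, A_spont = p$A12, A_pred = p$A1, c = c(p$c1, p$c2), d = p$d)
}

starvation_ref <- function() {
  p <- starvation_params_ref()
  starvation_predator(p$c1, p$c2, p$d1, p$d2, p$Gamma1, p$Gamma2,
                      p$delta1, p$delta2)
}

# random nonnegative state for a model
random_state <- function(model, scale = 1) {
  population_state(stats::runif(model$m) * scale,
                   stats::runif(model$n) * scale)
}
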