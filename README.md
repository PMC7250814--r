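# frmech

Mechanistic derivation of predator functional responses and prey/predator
numerical responses from fast behavioural-state transitions.

## The problem

Classical predator–prey theory plugs a functional response `f(X, Y)` — prey
captured per predator per unit time — into a Gause-type system

```
dX/dt = g(X, Y) X − f(X, Y) Y
dY/dt = γ(X, Y) f(X, Y) Y − δ(X, Y) Y
```

but the textbook forms (Holling II/III, Beddington–DeAngelis) are usually
postulated, not derived. `frmech` implements the alternative: specify *fast*
transitions between discrete behavioural states (searching/handling,
exposed/hiding, well-fed/starving, …), which occur on a timescale where the
totals `X = Σxᵢ` and `Y = Σyⱼ` are constant; solve the fast dynamics

```
dx_k/dt = Σᵢ A[k,i] xᵢ + Σᵢ (Σⱼ B[k,i,j] yⱼ) xᵢ
dy_k/dt = Σᵢ (Σⱼ C[k,i,j] xⱼ) yᵢ + Σᵢ D[k,i] yᵢ
```

for its equilibrium `(x̂, ŷ)` at fixed `(X, Y)`; and obtain the
population-level responses by time-averaging:

```
f(X,Y) = Σᵢⱼ βᵢⱼ x̂ᵢ ŷⱼ / Y            g(X,Y) = Σᵢ (λᵢ − μᵢ) x̂ᵢ / X
γ(X,Y) = Σᵢⱼ γᵢⱼ βᵢⱼ x̂ᵢ ŷⱼ / (f Y)     δ(X,Y) = Σⱼ δⱼ ŷⱼ / Y
```

Every matrix column (and each mediator slice of the interaction tensors
`B`, `C`) sums to zero, so the fast dynamics purely redistributes
individuals; the totals only move on the slow (birth/death/capture)
timescale. This is useful for theoretical ecologists who want functional
and numerical responses whose parameters mean something at the individual
level — attack rates, handling times, starvation rates, panic responses —
rather than fitted curve coefficients.

## What's in the package

- `transition_model()`, `validate_consistency()`, `fast_vector_field()` —
  specify and check structured fast-transition models
  (index convention: `[destination, source, mediator]`).
- `solve_linear_stationary()`, `solve_triangular()`, `solve_nonlinear()` —
  fast-equilibrium solvers (CTMC stationary distribution; two-stage solve
  when prey ignore predators; damped alternating fixed point in the fully
  coupled case), plus `assess_stability()` (Jacobian spectrum; two
  conservation zeros expected) and `probe_uniqueness()` (multistart +
  trajectory integration).
- `functional_response()`, `prey_numerical_response()`,
  `predator_numerical_response()`, `response_surface()` — the derived
  responses, pointwise or swept over an `(X, Y)` grid.
- A model zoo with closed forms cross-validated against the generic
  machinery: `tiered_prey()` (chain of protection levels; Holling II at
  `m = 1`, a generalized Beddington–DeAngelis at `m = 2`),
  `dd_handling()` (density-dependent handling time),
  `starvation_predator()` / `experience_predator()` (mechanistic type III),
  `panic_model()` (predator Allee effect), `holling_bd_mappings()`.
- `simulate_full()` / `simulate_reduced()` / `compare_reduction()` — the
  two-timescale system at separation `ε` against the reduced Gause system
  (built-in L-stable Rosenbrock integrator with analytic Jacobians).
- `random_model()` / `degenerate_fixtures()` — synthetic generators so all
  of the above is testable with no external data.
- JSON model configs, CSV tables and a CLI (`inst/cli/frmech`):
  `validate`, `equilibrium`, `responses`, `simulate`, `zoo`.

## Worked example

The starvation-structured predator (well-fed searchers S1 with attack rate
`c1 = 10`, starving searchers S2 with `c2 = 0.2`, handling time `1/d1 = 1/4`,
starvation rate `d2 = 3`, fecundities `Γ1 = 10, Γ2 = 2`, mortalities
`δ1 = 0.2, δ2 = 0.5`):

```r
library(frmech)
sv <- starvation_predator(c1 = 10, c2 = 0.2, d1 = 4, d2 = 3,
                          Gamma1 = 10, Gamma2 = 2,
                          delta1 = 0.2, delta2 = 0.5)
eq <- solve_triangular(sv$model, X = 1, Y = 1)
eq
#> <fast_equilibrium (triangular): X = 1, Y = 1, residual = 1.11e-16, converged in 2 iterations>
#>   x_hat: 1
#>   y_hat: 0.0519481 0.7792208 0.1298701 0.0389610

pr <- predator_numerical_response(sv$model, sv$rates, X = 1, Y = 1, eq = eq)
unlist(pr[c("f", "gamma_f", "gamma_factor", "delta_factor")])
#>            f      gamma_f gamma_factor delta_factor
#>    0.6753247    1.3766234    2.0384615    0.4000000

c(f_inf = sv$closed$f(1e8), gf_inf = sv$closed$gamma_f(1e8),
  delta0 = sv$closed$delta_factor(0))
#>  f_inf gf_inf delta0
#>    4.0   10.0    0.5
```

At `X = 1` about 78% of predators are starving searchers, so the realized
conversion factor (2.04) sits below its ceiling `Γ1/d1 = 2.5` and the
mean mortality (0.40) is pulled toward the starving rate `δ2 = 0.5`. As prey
become superabundant the response saturates at the handling rate `d1 = 4`,
the per-capita reproduction rate at `Γ1 = 10`, and the convexity criterion
`c1/c2 > 1 + d2/d1` (here `50 > 1.75`) makes the response sigmoid — a
mechanistically derived Holling type III.

Verify the timescale-separation reduction on the panic model:

```r
zm <- panic_model(1, 0.2, 10, 1, Gamma = 0.5, delta1 = 0.1, delta2 = 0.1,
                  lamP = 1, mu1 = 0.2, mu2 = 0.2)
init <- population_state(c(0.5, 0.5), c(0.5, 0.5))
reduction_error_sweep(zm$model, zm$rates, c(1e-1, 1e-2, 1e-3), init, c(0, 10))
#>   epsilon        sup        l2
#> 1   0.100 3.65936203 8.1228122
#> 2   0.010 0.25373842 0.4508290
#> 3   0.001 0.02439759 0.0428122
```

The sup-norm gap between the full state-resolved trajectory and the reduced
system on the totals shrinks roughly linearly in ε, as singular-perturbation
theory predicts.

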