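---
title: "Deriving functional and numerical responses from fast state transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving functional and numerical responses from fast state transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frmech)
```

## The model and its assumptions

`frmech` works with predator–prey communities structured by behavioural
states: `m` prey states with densities `x = (x_1, …, x_m)` and `n` predator
states with densities `y = (y_1, …, y_n)`. Transitions between states are
assumed *fast* relative to birth, natural death and capture-driven
depletion, so on the fast timescale the totals `X = Σ x_i` and `Y = Σ y_j`
are constant and the dynamics is

$$\dot x_k = \sum_i A_{ki} x_i + \sum_i \Big(\sum_j B^{(k)}_{ij} y_j\Big) x_i,
\qquad
\dot y_k = \sum_i \Big(\sum_j C^{(k)}_{ij} x_j\Big) y_i + \sum_i D_{ki} y_i.$$

`A` and `D` hold spontaneous per-capita transition rates; `B` and `C` hold
rate coefficients for transitions *mediated* by the density of a state of
the other species (a prey sighting a searching predator, a handler
abandoning its catch when fresh prey pass by). The package fixes the tensor
index order as `[destination, source, mediator]`: `B[k, i, j]` moves prey
from state `i` to state `k` in proportion to predator state `j`. This
convention is easy to transpose when translating published superscript
notation, which is why `validate_consistency()` and the tests check it
aggressively.

Because fast transitions only redistribute individuals, every column of
`A`, `D` and of each mediator slice `B[, , j]`, `C[, , j]` must sum to
zero. These conservativity conditions are what make `X` and `Y` invariants
of the fast flow, and they are enforced to an absolute tolerance of 1e-12
(rates in all shipped applications are O(0.1)–O(100), so this is far below
parameter scale).

Two structural assumptions are inherited from the modelling framework and
are *not* checked because they are not expressible in the data structures:
no prey–prey or predator–predator interactions, and no mixed
predator–prey complexes (each state belongs to exactly one species).
Only two timescales are supported.

### Exit channels instead of strictly negative diagonals

A natural regularity condition is that every state can be left. We
implement it as: each state needs a strictly negative diagonal entry in its
spontaneous matrix *or* in some mediator slice. Requiring strictly negative
diagonals of `A` and `D` alone would reject the panic model, where the
protected prey leave only when flushed by searching predators (a `B`
channel) and searchers leave only by capturing (a `C` channel). Models that
fail even the weaker check (states with no exit at all) are degenerate;
they can still be represented with `relaxed = TRUE`, but every solver
refuses them unless explicitly overridden, because their fast equilibria
need not be unique.

## Solving the fast equilibrium

**Linear case** (`B = C = 0`). `A` and `D` are transition-rate matrices of
continuous-time Markov chains; the equilibrium is the stationary
distribution scaled to the total. `solve_linear_stationary()` imposes the
normalisation by the rank-one trick: summing `M v = 0` and `1'v = total`
gives the nonsingular system `(M + E) v = total · 1`.

Uniqueness requires a single *closed* communicating class in the digraph of
positive off-diagonal rates. We deliberately use this weaker condition
rather than irreducibility: at boundary totals (e.g. `Y = 0` in the panic
model) mediated channels vanish and some state becomes absorbing, yet the
stationary distribution is still unique and the reduced slow dynamics needs
it. Matrices with several closed classes (genuinely non-unique stationary
distributions) raise an error naming the classes.

**Triangular case** (`B = 0`). Prey equilibrate independently of the
predators, so two successive linear solves give the equilibrium exactly:
`x̂` from `A`, then `ŷ` from `C(x̂) + D`.

**Fully coupled case.** `solve_nonlinear()` alternates the two linear
solves — `x̂ ← stationary(A + B(ŷ))`, `ŷ ← stationary(C(x̂) + D)` — with
damping 0.5, tolerance 1e-12 on successive iterates (relative to
`1 + X + Y`) and a cap of 10 000 iterations. Each half-step is a
well-posed stationary solve, mirroring the fixed-point construction that
guarantees existence of the equilibrium. Damping guards against
oscillation in strongly coupled models; for the shipped applications the
scheme converges in tens of iterations. After convergence one *undamped*
half-step pair is applied: damping leaves an O(tol) lag behind the fixed
point, and the polish removes it (exactly so for triangular models), which
is what lets the generic route match closed forms to 1e-10 relative.
Non-convergence is reported through the `converged` flag and the fast-field
residual, never as an exception. The residual check is relative to
`max(rates) · max(1, X, Y)` so that the flag means the same thing at
`X = 0.01` and at `X = 10^8`.

**Stability.** `assess_stability()` assembles the analytic Jacobian (its
blocks are linear in the state) and inspects the spectrum. The two
conservation laws force exactly two zero eigenvalues; we classify an
eigenvalue as "zero" when its modulus is below 1e-8 times the spectral
radius, and call the equilibrium hyperbolically stable when exactly two
zeros remain and every other eigenvalue has negative real part. A fully
degenerate spectrum (the 1-prey/1-predator model, where both eigenvalues
are structurally zero) is reported as vacuously stable.

**Uniqueness.** Uniqueness of the coupled equilibrium is an open problem in
general, so `probe_uniqueness()` is evidence-gathering, not proof: it runs
the solver from `n_starts` flat-Dirichlet initial distributions *and*
integrates the fast dynamics forward from the same starts, keeps every
endpoint whose residual is small, and merges points closer than 1e-6 in
max-norm after normalising by `X + Y` (well below parameter-scale
separation in the applications, well above solver tolerance). On the
`flat` degenerate fixture, where every distribution is stationary, the
probe duly reports many equilibria.

## From equilibrium to responses

With capture rates `β_ij` (prey `i` by predator `j`), per-capita prey birth
and death rates `λ_i`, `μ_i`, per-capture fecundities `γ_ij` and predator
mortalities `δ_j`, time-averaging over the fast equilibrium gives

$$f = \frac{\sum_{ij} \beta_{ij} \hat x_i \hat y_j}{Y},\quad
g = \frac{\sum_i (\lambda_i - \mu_i)\hat x_i}{X},\quad
\gamma f = \frac{\sum_{ij} \gamma_{ij}\beta_{ij}\hat x_i \hat y_j}{Y},\quad
\delta = \frac{\sum_j \delta_j \hat y_j}{Y}.$$

The conversion factor `γ(X, Y) = (γf)/f` is population-level bookkeeping
with no individual-level meaning; at `f = 0` it is reported as `NA` rather
than 0 or a sentinel, while the mechanistic product `γ·f` (zero there) is
always computed directly. `response_surface()` sweeps these over an
`(X, Y)` grid, warm-starting each nonlinear solve from the neighbouring
cell — cheap, and it keeps the solver on one equilibrium branch; cells
that fail to converge are flagged, never interpolated.

Capture rates `β` are an independent input rather than being derived from
`C`: the framework never formally ties captures to predator transitions.
The zoo builders set `β` equal to the attack rates of the corresponding
searching-to-handling transitions, which is the reading used in all four
applications.

### Births tied to states vs. births per capture

Two of the applications define predator reproduction through handler
*occupancy* (`Γ_1 Ĥ_1 + Γ_2 Ĥ_2`), while the generic interface carries
per-capture fecundities `γ_ij`. At the fast equilibrium the capture flux
into a handling state balances its outflow (`c_j X Ŝ_j = d_1 Ĥ_j`), so a
constant per-capture fecundity `γ_j = Γ_j / d_1` reproduces the occupancy
form exactly; the starvation and panic builders are wired this way and the
identity is asserted in the tests. The density-dependent-handling model is
the one case where the equivalent per-capture coefficient,
`1/(c_2 X + d)`, is not constant; there the conversion factor lives in the
closed-form evaluator and the generic cross-check covers `f` and the
conversion identity `γ = Ĥ/(Y f)` instead.

## The application zoo

Each builder returns the generic model *and* closed-form evaluators, and
the test suite requires the two routes to agree to 1e-10 relative over
log-spaced grids:

* `tiered_prey(m, …)` — prey climb a chain of protection levels at rates
  proportional to total predator density (kairomone-type cues) and relax
  back spontaneously; searching/handling predators. `m = 1` is exactly
  Holling II with saturation `d`; `m = 2` generalises
  Beddington–DeAngelis, increasing in `Y` when `c1 < c2` and decreasing
  when `c1 > c2`.
* `dd_handling(c1, c2, d)` — handlers abandon the catch at rate `c2·X`:
  Holling II with density-dependent handling time `1/(c2 X + d)` and
  conversion factor equal to that handling time.
* `starvation_predator(…)` / `experience_predator(…)` — two searcher
  classes with unequal attack rates produce a type III response, sigmoid
  iff `c1/c2 > 1 + d2/d1`; saturation `d1`, reproduction rate saturating
  at `Γ1`, mortality decreasing from `δ2`. The experience variant merges
  the two handler pools and has the identical response.
* `panic_model(a, b, c, d)` — both species structured; searching predators
  flush protected prey. The equilibrium involves `√Δ` with
  `Δ = q(p²q + 2p(q + 2X)Y + qY²)`; the raw expressions for `Ê` and `Ĥ`
  subtract nearly equal quantities at small `Y`, so the package evaluates
  the conjugate forms `Ê = 2qXY/(√Δ + q(p + Y))` and
  `Ĥ = 2XY²/(u + √Δ)` (`u = pq + qY + 2XY`), which are
  cancellation-free for all nonnegative `X`, `Y`. The `XY` numerator of
  the limiting response `cXY/(p + Y)` makes predator growth quadratic in
  `Y` at low density — an Allee effect.

One commonly quoted display is knowingly *not* reproduced as printed: the
two-prey-state response in that display carries an overall factor `A12` in
its numerator that is inconsistent with the equilibrium expressions it is
derived from, and with the stated saturation at `d`. The package implements
the internally consistent form `f₂ = c·x̂ /(1 + c·x̂/d)` and exposes the
as-printed variant (`f2_as_printed`, `coef_as_printed`) for comparison;
the two differ exactly by the factor `A12`, which the tests assert.
Similarly, the reference two-prey-state parameterisation quotes the
spontaneous return rate as a constant `A21`; since the model defines the
upward rate as `A1·Y`, the free constant can only be the return rate and
is read as `A12`.

## Two-timescale simulation

The reduction is only as good as the timescale separation, so the package
can simulate both sides. The full system puts the fast transitions at rate
`1/ε` and *all* demography — including capture-driven prey removal — at
O(1). The source text for the scaling derivation is not available, so this
is a design decision, justified as follows: the framework requires totals
to be conserved by the fast flow and treats capture losses as slow; scaling
captures with `1/ε` would instead extinguish the prey on the fast
timescale. Offspring are routed to states by simplex vectors
(`prey_offspring`, `pred_offspring`); the choice barely matters for small
`ε` because the fast flow immediately redistributes newborns.

Both systems are integrated with a purpose-built adaptive Rosenbrock
scheme (4-stage Kaps–Rentrop, Shampine parameters: order 4, L-stable,
embedded order-3 error estimate) using the analytic Jacobian assembled
from the effective transition matrices. No ODE-solver package is assumed.
L-stability matters: the fast block has eigenvalues of size `1/ε`, and an
explicit or merely A-stable method would be stability-limited at
`ε = 10⁻³`. The integrator is validated in the tests against the matrix
exponential on a stiff linear system and against fine-step RK4 on a
nonstiff one. Defaults: `rtol = 1e-8`, `atol = 1e-10`; steps that
undershoot zero by more than 1e-13 (relative) are clipped with a warning.

`compare_reduction()` measures sup-norm and L2 gaps on the totals. For the
panic model with demography (`a = 1, b = 0.2, c = 10, d = 1`;
`λ_P = 1, μ = 0.2, Γ = 0.5, δ = 0.1` — values chosen once as a mild,
ecologically plausible slow layer, since the source applications state
none) the gap falls roughly linearly in `ε` over
`ε ∈ {10⁻¹, 10⁻², 10⁻³}`, which is the singular-perturbation signature the
acceptance suite asserts.

## What the synthetic generator does and does not emulate

`random_model()` draws sparse nonnegative off-diagonal rates (edge
probability `density`, Exponential magnitudes with mean `rate_scale`),
always adds a random spanning cycle to `A` and `D` so the spontaneous
chains are irreducible, and sets diagonals to minus the column sums so the
conservativity conditions hold *exactly*, not to rounding. It emulates the
structural class of admissible models — it does not emulate any particular
ecology: rates are i.i.d., whereas real behavioural transition rates are
correlated (e.g. attack and handling rates co-vary with body size), and
the generator never produces the near-degenerate rate separations where
uniqueness might genuinely fail. A green property suite on random models
therefore establishes that the solvers respect conservation, positivity,
stability and solver/integrator agreement across the admissible class —
not that every ecologically meaningful model has a unique fast
equilibrium, which remains an open question probed (not proved) by
`probe_uniqueness()`.

## Numerical choices, in one place

| Quantity | Value | Rationale |
|---|---|---|
| consistency tolerance | 1e-12 abs | rates are O(0.1)–O(100) in all applications |
| nonlinear solver | damping 0.5, tol 1e-12, ≤ 10 000 iter, undamped polish | each half-step well-posed; polish removes damping lag |
| converged flag | residual ≤ 1e-8 · max(rates) · max(1, X, Y) | scale-free meaning of "converged" |
| zero-eigenvalue tolerance | 1e-8 relative to spectral radius | two conservation zeros expected |
| equilibria merge tolerance | 1e-6 max-norm, normalised by X + Y | below parameter scale, above solver tolerance |
| integrator | Rosenbrock 4(3), rtol 1e-8, atol 1e-10 | L-stable; fast block eigenvalues ~ 1/ε |
| negativity handling | clip, warn below −1e-13 relative | fast flow is positivity-preserving up to round-off |
| CSV / JSON precision | 17 significant digits | lossless double round trips |

## Known limitations

* Uniqueness of the coupled fast equilibrium is probed by multistart, not
  established; a single reported equilibrium is evidence only.
* The alternating solver can in principle cycle for strongly coupled
  models outside the tested class; it then returns `converged = FALSE`
  with the residual rather than failing, and `probe_uniqueness()`'s
  trajectory route is the fallback.
* `γ(X, Y)` is undefined at `f = 0` and reported as `NA`; downstream code
  should use `γ·f` (always defined) for growth computations, as
  `simulate_reduced()` does.
* The full/reduced comparison interpolates linearly in time; with very
  coarse output grids the reported sup-norm error is a lower bound.
* No spatial or aggregative responses, no prey–prey/predator–predator
  interactions, no mixed complexes, exactly two timescales.
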