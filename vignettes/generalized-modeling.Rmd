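---
title: "Generalized modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genmod)
```

## The model class and its assumptions

`genmod` analyzes ODE systems of the form

$$\dot X_i = \sum_P s_{P,i}\, P(X_{d(P)}),$$

where each process $P$ is an *unspecified* function of its declared
dependency set $d(P)$ and $s_{P,i} \in \{+1, -1, 0\}$ is its sign in
equation $i$. Two assumptions carry the whole method:

1. **Positivity.** All state variables and all process rates are strictly
   positive. Quantities that can change sign must be split into two
   antagonistic one-way processes (the declaration API enforces one sign per
   equation per process).
2. **Stationarity.** Analysis concerns steady states. Normalizing each
   variable and process by its steady-state value moves every steady state
   to the all-ones point, where all normalized processes equal one.

Under these assumptions the Jacobian at the (unknown) steady state is an
exact polynomial in three kinds of interpretable parameters, and no
functional form is ever chosen:

- **Turnover** $\alpha_v > 0$ (1/time): the per-unit total gain rate of $v$
  at the steady state. One symbol serves both the gain and the loss side of
  each equation, so the stationarity identity "gains = losses" holds *by
  construction* and steady states that cannot exist are unrepresentable.
  This derivation-time enforcement was chosen over post-hoc filtering of
  inconsistent parameter sets because it shrinks the parameter space instead
  of rejecting samples.
- **Branching weights** (dimensionless, simplex): where $k > 1$ processes
  share a gain or loss side, each gets a weight and the group sums to one.
  The implementation keeps $k-1$ free symbols and eliminates the
  last-declared process's weight as one minus the rest — mirroring the
  $\bar\rho = 1 - \rho$ convention — so sum-to-one holds symbolically after
  every substitution. Gain weights are named `beta_<process>_<variable>`,
  loss weights `sigma_<process>_<variable>`; the variable qualifier prevents
  collisions when a shared process contributes to several equations.
- **Elasticities** $\theta_{P,v}$ (dimensionless): logarithmic derivatives
  of $P$ with respect to $v$ at the steady state. A parameter exists exactly
  for declared (process, variable) pairs; undeclared pairs are structural
  zeros of the Jacobian. This is deliberate: the declared dependency
  structure is where a generalized model's information lives, so
  dependencies are never inferred.

## Constraints

Structural knowledge beyond the skeleton enters as constraints, resolved in
a fixed order (closed-form auxiliaries, then compositions innermost to
outermost, then derivative conditions; cycles are rejected):

- **Explicit auxiliaries** (e.g. per-capita consumption $C = F/Y$) have
  their elasticities computed *exactly* by symbolic log-differentiation at
  the normalized point ($c_f = 1$, $c_y = -1$ for $C = F/Y$; any power-law
  form $aX^p$ yields exactly $p$). Elasticities here denote
  explicit-argument derivatives only; indirect paths appear as separate
  chain-rule terms. If the log-derivative would depend on the unknown
  steady-state values (e.g. $F + Y$), the form is rejected with an error
  rather than silently parameterized.
- **Function compositions** (e.g. predator gain $G = H(F, C)$) replace the
  outer process's elasticities through the chain rule, introducing new outer
  elasticities (`h_f`, `h_c`, …) unless pinned numerically. With $h_f = 1$
  and $C = F/Y$ this yields $g_x = (1 + h_c) f_x$ and
  $g_y = f_y + h_c (f_y - 1)$. (The printed source of this worked example is
  typographically ambiguous for $g_x$; the form implemented here is the one
  the chain rule produces from the preceding definitions.)
- **Derivative conditions** ($\partial P/\partial V|_* = 0$, useful for
  optimality or evolutionary-stability constraints) pin the corresponding
  elasticity to zero.
- **Conservation laws** keep the Jacobian at full size — the stricter and
  usually more relevant notion of stability, since it also covers
  perturbations that break the conserved quantity — and are recorded as
  flux-matching constraints on scale parameters. Matching fluxes across
  equations requires the unknown steady-state abundance ratios; these enter
  as explicit ratio symbols `q_<v1>_<v2>` in the constraint report. This
  ratio-symbol bookkeeping is an extension of the package beyond the
  method's worked examples, and the reduced-variable alternative (eliminate
  a variable first) is intentionally not implemented.

## Parameter ranges and sampling

Default sampling ranges are the field's conventional choices and are fully
user-overridable: elasticities in $[0, 2]$ (constant through quadratic
response — the span a Holling type-III response covers), turnovers in
$[0.5, 2]$ around the reference timescale, branching groups uniform on
their simplex (flat Dirichlet), sampled jointly rather than
componentwise-and-renormalized because the latter biases toward the simplex
center. Stability correlations are reported as Pearson (point-biserial)
correlations rather than raw covariances so that a parameter fully
determining stability scores exactly $\pm 1$; the raw covariance is
available via `normalize = FALSE`. Negative elasticities (inhibition,
reciprocal laws) are legitimate; widen the ranges when the application
calls for them.

## Numerical choices

- **Eigenvalues** come from the dense `eigen()` solver throughout. The
  systems this package targets (food chains, motifs, small webs; tens of
  variables) are far below the size where iterative largest-real-part
  solvers pay off, and the dense solver is the reference that any
  alternative backend would have to match anyway.
- **Leading eigenvalue ties** (equal real parts) are broken toward larger
  imaginary modulus, and the $\mathrm{Im} \ge 0$ representative is returned.
- **Stability is strict**: $\mathrm{Re}\,\lambda_0 = 0$ classifies as
  unstable, so bifurcation boundaries count as not-stable in PSW figures.
- **Zero-eigenvalue detection** brackets sign changes of $\det J$ on a
  200-point path grid (cheap relative to eigensolves and adequate for the
  fixture systems; refinable via `n_grid`) and refines by `uniroot` to
  near machine precision; each hit must have $|\det J|$ below the reported
  tolerance and carries the smallest-magnitude eigenvalue as evidence.
- **Hopf detection** tracks the largest real part among non-real
  eigenvalues ($|\mathrm{Im}| > 10^{-9}$) and bisects its sign changes (80
  bisection steps; the function can lose smoothness where a complex pair
  collides with the real axis). A hit must have a genuinely non-real pair
  and $|\det J|$ *above* tolerance, excluding zero-eigenvalue crossings.
  The algebraic bialternate-product test `gm_bialternate()` is provided as
  an independent cross-check for small systems; its determinant also
  vanishes for symmetric real eigenvalue pairs, which is why eigenvalue
  tracking, not the algebraic test, is the primary detector.
- **Press response** refuses near-singular Jacobians (condition number
  above $10^{12}$; warning above $10^8$), because the linear response
  $\delta = -J^{-1} p$ presumes distance from a bifurcation. The press
  vector is the *direct impact* on each equation in turnover units: an
  added loss of a fraction $\epsilon$ of a variable's turnover is
  $p_i = -\epsilon$.
- **Sensitivity/influence scores** use moduli of eigenvector components and
  $|\lambda_n|$ in the denominator, which reduces to the real formula for
  real negative eigenvalues ($-\lambda_n = |\lambda_n|$) and keeps scores
  real for complex pairs. Right eigenvectors are normalized to unit norm
  and left ones to $v_n \cdot w_n = 1$, making the scores independent of
  eigenvector scaling; the literature leaves both conventions open, so they
  are fixed here and documented. The influence measure is written In
  (elsewhere also Im); one name is used throughout.
- **Elasticity extraction** from explicit functions uses central
  differences on the log scale with step $10^{-6}$ (error $O(h^2)$, about
  $10^{-12}$ before roundoff); `gm_elasticity_expr()` is the exact symbolic
  counterpart.
- **Round-trip verification** recovers turnovers and weights from process
  values at the all-ones point and elasticities by numeric log-derivatives,
  and requires the steady-state residual there to be below $10^{-8}$
  (power-law construction places it near $10^{-16}$).

## Realizations

Every admissible generalized parameter set is realizable: the power-law
construction $P(x) = \prod_v x_v^{\theta_{P,v}}$ meets the normalization
condition for any elasticities and puts the steady state at the all-ones
point exactly. This is also the package's *master oracle*: the symbolic
Jacobian, evaluated numerically, must equal the central finite-difference
Jacobian of the realization at the all-ones point, elementwise, for random
admissible parameter sets on every fixture — the test suite checks this at
relative tolerance $10^{-6}$ with 1000 sets per fixture. Power-law
realizations are flagged with a degeneracy caveat (they can render certain
bifurcations degenerate); the saturating template
$(1+K)x/(K+x)$, solved in closed form as $K = p/(1-p)$ for target
elasticity $p \in [0, 1)$, lets users mix kinetics for bifurcation studies.
Templates are restricted to one shape constant per process so the
elasticity condition determines them uniquely; richer families enter as
custom templates with a user-supplied maker and bracketed root-finding.

## The fixture catalog and what it does (not) show

The shipped fixtures are structural archetypes, not data: a one-variable
gain/loss system (whose stability condition $g_x < l_x$ is closed-form and
anchors the sampler's exactness tests), a predator–prey pair with and
without the biomass-conversion constraint, a three-gain/three-loss
branching equation, and a food-chain generator (`gm_food_chain(n)`: primary
production, $n-1$ linearly converted predation links, $n$ mortalities —
$3n - 1$ processes, tridiagonal Jacobian). Test problem sizes — ensembles
of $10^4$–$10^5$ for distributional checks, $10^3$ parameter sets per
fixture for oracle equivalence, 200-point bifurcation grids — are chosen so
the full suite runs in about a minute on one core while keeping Monte-Carlo
standard errors well inside the asserted tolerances. Passing these suites
shows the machinery is exact on the structures it manipulates; it does not
validate any particular ecological claim, and realistic large webs (niche
topologies, empirical food webs, $10^{11}$-sample sweeps) are outside this
package's scope.

## Known limitations

- No attractors other than steady states (no Floquet/limit-cycle
  machinery); no delay or spatial coupling.
- No continuation of bifurcation curves or normal-form coefficients; scans
  locate crossings along user-given paths and grids only.
- Conservation-law support stops at constraint emission; large metabolic
  conservation structures would need flux-mode machinery not included here.
- The symbolic layer is a polynomial algebra, which is exactly what
  generalized Jacobians need; it does not simplify arbitrary expressions
  and does not render LaTeX.
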