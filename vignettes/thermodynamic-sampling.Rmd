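---
title: "Probabilistic thermodynamic analysis: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic thermodynamic analysis: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoflux)
```

## The model

A constraint-based metabolic model fixes the stoichiometric matrix `S`
(m metabolites × n reactions) and flux bounds; the flux space is
`F = {v : S v = 0, lb ≤ v ≤ ub}` with fluxes in mmol·gDW⁻¹·h⁻¹. For a set
Γ of γ internal, mass-balanced reactions we model the thermodynamic state
probabilistically:

* log concentrations (natural log, molar): `ln c ~ N(μ_c, Σ_c)`;
* standard transformed reaction energies (kJ/mol):
  `ΔrG'° ~ N(μ°, Σ°)`, where `Σ°` is typically *rank-deficient* because
  group-contribution estimates share group uncertainties across reactions;
* transformed reaction energies by the linear identity
  `ΔrG' = ΔrG'° + RT·S_Γ'·ln c`, with `R = 8.31446×10⁻³ kJ·mol⁻¹·K⁻¹` and
  `T = 298.15 K` by default (`RT ≈ 2.479 kJ/mol`).

The stacked vector `t = [ln c, ΔrG'°, ΔrG']` is then Gaussian with mean
`μ_t` and a structured covariance `Σ_t` whose blocks follow from the
identity; `Σ_t` is always singular because `ΔrG'` is a deterministic
function of the other two blocks. `build_thermo_space()` assembles `Σ_t`,
factorizes it as `Σ_t = QQ'` by eigendecomposition (columns scaled by the
square-root eigenvalues, eigenvalues below `rank_tol = 1e-9` of the
largest treated as zero), and records the numerical rank `q`. In the
whitened coordinates `t = μ_t + Q·m` the coordinates `m` are standard
normal, so restricting the state to a confidence level α is the ball
`‖m‖² ≤ χ²_{q,α}`, and the Mahalanobis quadratic form with the
pseudo-inverse of `Σ_t` coincides with `‖m‖²`. We default to `α = 0.95`;
the choice is a modeling convention and is exposed everywhere.

Two physical constraints couple this Gaussian to the flux space: every
reaction in Γ must carry nonzero flux in a definite direction, and the
second law orients it against its energy, `sign(v_i)·ΔrG'_i < 0`. A
direction pattern for all of Γ is an *orthant* of the energy space. The
*steady-state thermodynamic space* is the confidence ball intersected with
the union of orthants that admit a steady-state flux distribution with
matching signs — non-convex and in general disconnected. Structurally
blocked reactions can never satisfy the nonzero-flux requirement, so
`select_thermo_reactions()` removes them from Γ (with a warning) after an
LP scan; the blocked tolerance is `1e-9` on the optimal flux magnitude.

### Reduced coordinates

Only the energies `ΔrG'` decide directions, and they are often far
lower-dimensional than `t`: concentrations enter only through reaction
quotients, and group-contribution covariances add dependencies. The
sampler and the initial-point search therefore work in the whitened
coordinates of the *reduced* Gaussian `N(μ_r, Σ_r)` over `ΔrG'` alone
(rank `q_r ≤ γ`), with the ball `‖m_r‖² ≤ χ²_{q_r,α}`. Conditional draws
of `(ln c, ΔrG'°)` given sampled energies use the Gaussian conditional
built from the Schur complement of `Σ_r` in `Σ_t`, with a generalized
inverse of `Σ_r` (shared eigendecomposition, same rank cutoff), so
rank-deficient priors need no special casing and every reconstructed
triple satisfies the linear identity to numerical precision (`1e-8` is
asserted throughout the tests).

Using `χ²_{q_r,α}` in the reduced space (rather than the full-space
`χ²_{q,α}`) is a deliberate choice: it makes the reduced problem a
self-contained α-confidence model over energies, and the fixture oracles
share the same `ThermoSpace` object so truncation is consistent on both
sides of every comparison. The optimizer, which reports states in full
coordinates, uses the full-space threshold, matching its definition.

## The most probable state (PMO)

`solve_pmo()` finds `argmin ‖m‖²` subject to steady state, the confidence
ball and the sign-coupled second law. With directions fixed, the
constraints on `m` are linear and the problem is a convex least-norm QP;
the binary direction choices are searched by exact branch-and-bound:

* the relaxation at a node (only the already-fixed directions
  constrained) lower-bounds every completion, pruning by incumbent;
* a steady-state LP with the partial sign assignment prunes orthants with
  no flux witness;
* at a leaf, the least-norm optimum either lies inside the ball — then it
  is also the optimum under the hard quadratic constraint, because the
  objective *is* the ball's quadratic form — or the orthant is infeasible
  at confidence α. This equivalence is why we can both impose the
  confidence region as a hard constraint and minimize the same form
  without a quadratically-constrained solver.

Ties between equal-objective orthants break deterministically toward the
lexicographically smallest signature. The strict second-law inequality is
relaxed to `sign(v_i)·ΔrG'_i ≤ −ε` with `ε = 0.1 kJ/mol`, and "nonzero
flux" is `|v_i| ≥ v_min = 1e-6 mmol·gDW⁻¹·h⁻¹`; both are configuration
knobs, since physically the constraint is open. QPs use the dual
active-set method (quadprog), whose infeasibility signal is exact; LPs are
solved by bisection on the objective level over that same feasibility
oracle — for the bounded, desk-scale programs in this package this is
slower per call than a simplex but immune to the degeneracy failures we
observed in pure-R simplex implementations.

Quantitative model assessment reads the optimum through `z_scores()`
(deviation from the prior mean in prior standard deviations; zero-variance
coordinates give z = 0 at the mean and are flagged otherwise) and
`classify_anomalies()`: a metabolite is anomalous when `|z| > θ` with the
conservative default `θ = 1` — the mode understates true deviations, since
it lets reactions sit arbitrarily close to equilibrium — or when a
non-intracellular metabolite is predicted at ≥ 10 mM. Compartments other
than `"c"` count as non-intracellular by default.

## Structural assessment

Inconsistent irreversibility annotations can force a loop that no
assignment of concentrations and energies satisfies: around any internal
cycle both the standard energies and the activity terms sum to zero, so
its reactions' energies cannot all be negative. `assess_structure()`

1. blocks exchange, biomass and maintenance reactions and enumerates all
   internal elementary flux modes by double description on the pointed
   cone (reversible reactions split; support-minimality by the standard
   adjacency test; a hard cap of 10⁶ intermediate rays fails loudly rather
   than truncating);
2. reports an EFM as a *forced internal cycle* when (i) its sign pattern
   is realizable in the original model, (ii) every single-sign-flip
   variant is LP-infeasible, and (iii) the model cannot carry flux
   anywhere with the cycle's support silenced. Condition (iii) guards the
   reading "active in every nonzero flux distribution": the flip test
   alone cannot distinguish a forced loop from one that simply cannot be
   partially reversed. Whether joint sign flips should also be tested is
   ambiguous; we test single flips and expose the EFM table so stronger
   variants can be scripted.

The report suggests reversibility relaxations but never edits the model.

## Sampling the thermodynamic space (TFS)

The target in reduced whitened coordinates is the standard normal
truncated to the ball and to the feasible orthant union. Each Hit-and-Run
step:

1. draws a uniform unit direction;
2. intersects the ray with the ball (quadratic formula) and with the
   fixed-sign half-spaces of irreversible reactions;
3. splits the chord at the zero crossings of the remaining energies —
   crossings closer than `1e-12` in the ray parameter are merged to
   tie-break grazing rays — and tests each cell's orthant with the
   steady-state LP, memoized by signature, so the LP cost is paid once per
   orthant per run;
4. weighs feasible segments by their 1-D normal mass, computed in log
   scale (`log Φ` differences with tail-stable identities), so segments
   8σ into a tail still carry finite weights;
5. picks a segment proportionally and inverse-CDF samples the truncated
   normal on it. The current point's segment is always present, which
   guarantees aperiodicity.

A ray crosses each energy hyperplane at most once, so the number of
orthant cells per ray is bounded by the number of sign-free energies plus
one. Note the bound counts *sign dimensions*, not the reduced rank: on a
rank-deficient fixture with `q_r = 2` and three reversible reactions a ray
can legitimately cross four cells, and the test suite asserts exactly the
sign-dimension bound (which equals `q_r + 1` whenever `Σ_r` has full
rank).

Chains start from over-dispersed points: for every reversible reaction,
flux maximization and minimization LPs propose direction sets, each
completed into a feasible orthant by the optimizer and pushed strictly
inside by maximizing an interiority margin (bisection over a shrunken
ball with per-reaction sign margins proportional to the energy's prior
sd — a Chebyshev-style proxy, since no canonical distance is available on
this space). When a flux-extreme direction set is thermodynamically
infeasible the search falls back to constraining only the optimized
reaction, and finally to the unconstrained mode, so a feasible model
always yields at least one start.

Defaults: burn-in 20% of steps, thinning to 500 retained energy draws per
chain, orthant probabilities estimated from pooled post-burn-in visit
counts (one orthant observation per accepted step — how proposal-level
orthant counts relate to retained samples is a bookkeeping convention; we
state ours and keep the retained-draw/step ratio configurable).
Convergence is judged by rank-normalized split-chain PSRF and
autocorrelation ESS; `adapt_parametrization()` rescales reduced
dimensions whose pilot PSRF exceeds 1.1 (inflation ∝ PSRF², a heuristic)
by a diagonal change of sampling coordinates. The along-ray density under
the rescaled metric is a general 1-D normal computed from the quadratic
form, so the stationary distribution is provably unchanged — the
invariance is verified by a two-sample test against an unadapted run.

## Flux sampling with thermodynamic prior

Each sampled orthant defines a flux polytope: `F` with bounds tightened to
`v_i ≥ v_min` or `v_i ≤ −v_min` per the pattern (the same `v_min` as the
sampler, so "nonzero" means the same thing everywhere). The equalities are
eliminated by an orthonormal null-space parametrization around a
least-norm interior point; a rounding transform is estimated by iterating
short pilot runs and whitening with the sample covariance — an
approximation of the polytope's inertial ellipsoid that serves the same
conditioning purpose as an inscribed-ellipsoid computation at a fraction
of the code. Coordinate Hit-and-Run then draws uniform points in rounded
coordinates (default thinning 5 × dimension); near-zero-width directions
are collapsed with a warning. `sample_flux_mixture()` selects up to `n_o`
orthants probability-proportional-to-size *without replacement* (the
with/without-replacement choice is not canonical; without replacement
maximizes coverage at small `n_o`), renormalizes, and allocates the total
draw budget by largest remainder, which is deterministic. Direction calls
label a reaction irreversible when ≥ 95% of draws agree — the same rule
applied to energy samples via the sign of `−ΔrG'`.

## Diagnostics

`psrf()` implements split-chain rank-normalized PSRF (plain PSRF via
`type = "plain"`); identical chains give values within `1/(2n)` of one by
construction. `ess()` uses chain-averaged autocovariances with Geyer
initial-positive-pair truncation and a monotone envelope, capped at the
total draw count; constant chains return `NA`. `kl_prior_posterior()`
summarizes a sampled posterior by moment matching before applying the
closed-form Gaussian KL — deterministic and adequate for screening
"posterior ≈ prior" variables, but it will understate divergence for
multimodal marginals; both KL directions are returned because the
screening direction is a convention. `hellinger()` uses the
Gaussian–Gaussian closed form where available and otherwise integrates
the Bhattacharyya coefficient on a shared grid, with disjoint supports at
distance one.

## The fixture generator

`make_fixture()` builds the study systems: chains, branches, reversible
cycles, the three-reaction lumped-pathway motif whose shortcut energy is
the sum of the step energies (making `Σ_r` rank-deficient exactly when
the priors respect the dependency), the deliberately inconsistent
propionate motif with its directed irreversible loop, and random sparse
networks. Priors default to `ln c ~ N(ln 10⁻⁴ M, 1²)` — a broad
physiological concentration prior — with standard-energy sds drawn from
1–10 kJ/mol; group-contribution-style covariances are generated as
`S_Γ'·diag(σ²)·S_Γ` over per-metabolite formation-energy variables, so
stoichiometric dependencies propagate to the covariance by construction.
Periplasmic/extracellular metabolites in real models often get inflated
concentration sds (a 5-fold convention exists in the field); the
generator exposes `sd_ln_c` rather than hard-coding any such rule.

The generator emulates structure and uncertainty *shape*, not biology: no
real measurement noise model, no condition-specific media or growth
constraints, no genome-scale dimensionality (the orthant caches and exact
oracles used in testing are only viable at 2–12 reactions). Passing tests
therefore demonstrate correctness of the algorithms on controlled
geometry, not predictive performance on organisms.

Two oracles anchor the tests: `rejection_oracle()` draws from the
truncated reduced Gaussian and filters by the steady-state LP (ground
truth up to Monte-Carlo error; it refuses fixtures with acceptance below
10⁻⁵), and `enumerate_orthants()` computes exact orthant masses by
tensor-grid Gauss–Legendre quadrature in the whitened coordinates (node
counts scale down with dimension; the discontinuous indicator makes fine
grids necessary in low dimension). The two agree within Monte-Carlo error
on their overlapping domain, which is itself a test.

## Numerical conventions and degenerate inputs

* Rank decisions everywhere use the relative eigenvalue cutoff `1e-9`.
* Zero prior covariance collapses the space to its mean point (`q = 0`);
  all downstream code accepts this.
* Conditioning rejects energy vectors outside the support of the reduced
  distribution (residual tolerance `1e-6` relative).
* The steady-state feasibility cache is keyed by orthant signature;
  irreversibility violations are rejected before any LP.
* Infinite bounds are clamped to ±10⁶ inside LP standard forms;
  fixed variables (`lb = ub`) are substituted out before solving.
* All samplers thread explicit integer seeds and restore the global RNG
  state on exit; identical seed and configuration give byte-identical
  outputs, which the pipeline tests assert via file checksums.

## Problem sizes in the shipped tests

The validation suite runs networks of 2–8 constrained reactions: the
optimizer is cross-checked against exhaustive enumeration on six fixtures,
the sampler against 10⁶-draw rejection oracles (4 000 steps × 6 chains per
fixture), conditional moments against ~10⁶-draw conditional rejection on
two-reaction chains, and the polytope sampler against closed-form moments
at 10⁴ draws. These sizes were chosen to bound every Monte-Carlo
comparison near the 3-standard-error level while keeping the full suite
in the low minutes on a single core.

## Known limitations

* Exact EFM enumeration and per-orthant LP verification do not scale past
  reduced models; the package targets curated or toy networks, not raw
  genome scale.
* PMO's branch-and-bound is exact but exponential in the worst case; for
  γ beyond a few dozen an MIQCP backend would be the right tool.
* Orthant probabilities from visit counts inherit MCMC autocorrelation;
  the tests use between-chain spread to size comparison tolerances, and
  so should downstream users.
* The KL screening is moment-matched Gaussian; heavy-tailed or multimodal
  posteriors need a density-based estimate.
* pH/ionic-strength transformation of standard energies, group
  contribution estimation itself, and model reduction are out of scope:
  energies and their covariance are consumed as inputs.
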