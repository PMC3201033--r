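---
title: "Zoomable reduction of biochemical network models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zoomable reduction of biochemical network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netzoom)
```

## The model class and the reduction problem

`netzoom` operates on closed reaction networks in state-space form
$\dot x = S\,r(x, p)$, with $x \in \mathbb{R}^n$ the species amounts, $S \in
\mathbb{Z}^{n \times q}$ the stoichiometric matrix and $r$ a vector of rate
expressions that are rational functions of species and parameters
(mass action is the common case). External inputs, events and discrete
switches are out of scope; an output map is irrelevant here because the
object of interest is the state itself.

The reduction exploits timescale separation. The user declares a set of
fast reactions (typically binding/unbinding steps whose rate constants
dwarf the rest); the fast species' dynamics splits as
$\dot x_f = S_s r_s + S_f r_f$. Because quasi-steady state (QSS) makes
$S_f r_f \approx 0$, any left null vector of $S_f$ defines an *apparent
conservation relation*: a pool the fast reactions cannot change at all and
the slow reactions change only slowly. These pools, and proper sub-pools of
them, are the natural coordinates of the reduced model.

Three model-level assumptions matter in practice:

* **the fast set is a modeling decision.** There is no consensus criterion
  for detecting QSS species automatically, so the package never guesses:
  `suggest_qss_species()` offers a flux-balance screen (net production
  small relative to gross turnover along a pilot simulation, threshold
  configurable, default 0.05), but nothing applies it implicitly. The
  screen needs gross fluxes, so it is most informative when reversible
  steps are encoded as two irreversible columns; a single signed net-rate
  column hides the gross turnover of species that appear in no other
  reaction.
* **QSS must actually hold on the comparison window.** The partition
  carries a validity window `[T0, T1)` as metadata only; the tool does not
  re-partition mid-simulation.
* **back-translation needs linearity.** Fraction parameters exist for a
  lump only if enough relations are *jointly linear* in that lump's
  members once every other lump's symbols are frozen as parameters. That
  freezing is the essential trick that turns bilinear mass-action balances
  into linear systems; it is implemented exactly that way (the linearity
  check runs per lump, treating all other symbols as constants).

## What each step computes

**Conservation analysis.** Exact and apparent conservation bases are left
null spaces computed over exact rationals (fraction-free Gauss-Jordan on
numerator/denominator pairs) and rescaled to coprime integers;
floating-point rank never decides a structural question. A greedy repair
step adds integer multiples of other basis rows to remove negative entries;
for every shipped model this yields a nonnegative basis, and when it cannot,
a signed basis is returned with a warning (no algorithm for a nonnegative
basis is known to always succeed short of Hilbert-basis enumeration, which
is deliberately out of scope). Row naming: a row is auto-named after a
shared moiety only when one member's name is a substring of all others;
otherwise rows are named `L1, L2, ...` deterministically, and the shipped
fixtures attach their conventional names explicitly.

**Lumping.** A scheme is *proper* when every fast species sits in exactly
one lump and each lump is contained in the support of one apparent
conservation row. `build_scheme()` keeps user-named rows as lumps, makes
every unassigned species a singleton (both worked models do exactly this),
and flags kept lumps that are also exact conservations as constants. Ties
are broken by species order in the model file, everywhere.

**Fraction parameters.** For each lump, candidate relations are collected
in a fixed provenance order — lump definition, QSS balances (one per fast
species, as rows of $S_f r_f \approx 0$, which covers both encodings of a
reversible step), user constraints, then exact conservation rows — and the
first subset whose coefficient matrix is symbolically nonsingular (each
row must raise the exact rank) is solved by Cramer's rule with cofactor
determinants. User constraints are tried *before* generic conservation
rows: a supplied constraint is the point of supplying it, and the
constrained carrier reduction of the transport model is only reproduced
with that precedence. The shares $\eta_i = x_i / \sum_j x_j$ then sum to
one identically; this is asserted symbolically after every solve, as is
(in the test suite) the vanishing of the back-substituted relations.
A lump with too few independent linear relations is marked
non-back-translatable; the reduction proceeds without a map for it, and
only an explicit request to back-translate such a species raises an error.

**Reduced dynamics.** Each lump is paired with an apparent row containing
it (exact-support matches first, then a backtracking matching). Constants
are dropped after verifying their balance rate vanishes *symbolically*.
The correction matrix $J$ collects derivatives of the back-translated
difference between apparent rows and lumps; the system
$(I + J)\,\dot l_m = \hat M_f S_s r_s$ is solved blockwise on the sparsity
pattern of $I + J$ — this recovers the per-membrane-face treatment of the
transport model automatically and also handles schemes whose lumps span
several fast clusters. Blocks of dimension at most 4 are solved
symbolically (Cramer with cofactor determinants over the rational-function
kernel, which keeps shared denominators shared); larger blocks store
symbolic entries and solve the linear system numerically at every
right-hand-side evaluation, the standard remedy when symbolic inversion
grows too costly.

**The vanishing-row change of basis** ($\hat M = N M_f$ maximizing zero
rows of $\hat M S_s$) is available as `maximize_vanishing_rows()` and is
useful for *discovering* additional constants, but it is not applied
inside `derive_reduced()` by default: recombining basis rows generally
destroys the containment pairing between lumps and rows (for the enzyme
model it would replace the substrate and product pools by their sum), and
both worked reductions use the untransformed basis. Discovered constants
enter instead through `reduction_summary(exploit = ...)`, which counts an
extra exact relation as eliminating a state when its whole support is
back-translatable.

**Parameter counting.** The number of parameters of a reduced model is
reported as the rank of the sensitivity of the reduced right-hand side to
log-parameters, evaluated on a fixed deterministic grid of positive states
(central differences, SVD rank with relative threshold $10^{-6}$). This
counts identifiable parameter *combinations*: a binding ratio formed from
an on- and an off-rate counts once, which reproduces the five-to-three
parameter collapse of the enzyme model without any hardcoded rewriting.

## Numerical choices

* Integration uses `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`, so
  that reduction error dominates integration error in all comparisons.
* Reduced initial conditions: the original initial state is generally off
  the fast manifold. The default route (`fast_eq`) integrates the fast
  subsystem alone until the largest relative fast-balance residual falls
  below $10^{-6}$ — since no slow reaction acts, apparent pools are
  preserved exactly, and for the enzyme model the result matches the
  closed-form equilibrated start to integrator precision. The `burnin`
  route integrates the full model for $10^{-3}$ of the comparison horizon
  (configurable) and warns when the residual has not settled; note that for
  the full model the residual floor is set by the timescale separation
  itself, so the warning threshold is a report, not a convergence failure.
* Shares at empty lumps: $g = \eta \cdot l_m$ is simplified before
  evaluation, so a zero-valued lump yields zero members rather than 0/0.
* $\det(I + J) > 0$ is checked numerically at the initial state of every
  reduced simulation; a singular correction matrix aborts with the state
  snapshot in the message.
* The relative difference $\varepsilon_i(t)$ skips (and logs) samples where
  the original state is below $10^{-9}$; the sampling grids start after
  $t = 0$, which avoids the initial zeros of product-like species.
* Comparison horizons: the enzyme study uses `t_end = 10` with sampling
  step 0.1 (the time-maximum summary is insensitive to extending the
  horizon once the slow transient is covered; the time-mean is not, which
  is why the mean is the secondary summary), and the transport study uses
  `t_end = 50` with step 1.

## The synthetic models and what they do (not) show

The enzyme fixture is fully determined by published values. One printed
inconsistency had to be resolved: the published ODE listing writes the net
rate of the product-binding step with $k_3$ as a dissociation rate, while
the QSS balance and share expressions derived from the same model use it as
an association rate. The fixture takes $k_3$ as the association rate, the
only reading under which the balance equations, the share expressions, the
reduced ODEs, the ratio $M_3 = k_3/k_{-3} = 3$ and the published error
norms are mutually consistent; the ODE-listing form is treated as a typo.

The transport fixture ships the published *structure* (reactions and all
conservation relations), but its rate constants are synthetic placeholders
chosen once: all binding on-rates $10^5$, off-rates $10^3$, translocation
rates $\alpha = \beta = 1$, total carrier 0.01 — at least $10^3$-fold
timescale separation, carrier scarce relative to its ligands, dissociation
constants comparable to the ligand amounts so no share saturates. Passing
tests on this fixture demonstrate the *structural* claims (conservation
bases, lump counts, symbolic share formulas, ordering of lumped vs naive
reduction) and that the pipeline is accurate *under honest timescale
separation*; they say nothing about the fitted kinetics of the real
transporter, whose published parameter values are not reproducible from
any printed source.

`random_fast_cluster()` generates closed networks of fast binding clusters
($A_k + B_k \leftrightarrow C_k$, rates scaled by a separation factor)
joined by slow first-order conversions among the $A$-type and extra slow
species. By construction every cluster carries two apparent conserved
moieties and the closed network retains at least one exact conservation
row, so structural invariants can be property-tested across seeds. The
generator emulates the moiety structure of real signaling/transport
networks, not their kinetics: rates are drawn from narrow uniform ranges,
all complexes are binary, and no catalytic cycles are generated — so these
tests probe algebraic correctness, not biological realism.

## Known limitations

* Back-translation requires enough jointly linear relations; models whose
  fast balances stay nonlinear in every candidate lump (e.g. homodimer
  formation lumped with its monomer) reduce but do not back-translate.
  Linearization around a steady state would be a natural fallback and is
  not implemented.
* The naive direct-substitution baseline needs the QSS system to be
  symbolically solvable for the eliminated species and inherits that
  approach's documented failure mode (complexes pinned at zero initial
  values); it is included as a baseline, not a recommendation.
* Rational-coefficient arithmetic is exact only while intermediate
  integers stay below $2^{53}$; the kernel stops rather than silently
  rounding, but pathologically scaled models may hit that guard.
* No stochastic semantics, no events, no unit checking beyond positivity.
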