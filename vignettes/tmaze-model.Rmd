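---
title: "The stochastic linear-operator model of T-maze discrimination learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stochastic linear-operator model of T-maze discrimination learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmazelearn)
```

## The model

A rat repeatedly runs a T-maze whose choice point carries two lights; on
each trial one light is lit at random (probability 1/2 each) and food is
placed in one goal arm. The behavioral state is the attention probability
$x_n \in [0,1]$: the chance the rat notices which light is on during trial
$n$. Conditional on $x$, a trial resolves into one of eight events — the
joint outcome of attention ($T$ vs $\tilde T$), arm choice ($A$/$B$) and
reward ($O_1$/$O_2$) — with tree probabilities

$$p(x) = \left(\tfrac12 u_1 x,\ \tfrac12(1-u_1)x,\ \tfrac12 u_2 x,\
\tfrac12(1-u_2)x,\ \tfrac12(1-x)u_1,\ \tfrac12(1-x)(1-u_1),\
\tfrac12(1-x)u_2,\ \tfrac12(1-x)(1-u_2)\right),$$

which sum to one identically. The reward probabilities $u_1, u_2$ attach
to the two light conditions; note the inattentive branch ($E_5$–$E_8$)
also carries $u_1, u_2$-dependent leaf probabilities — the event tree is
taken at face value throughout, which keeps the eight weights an exact
distribution for every $(x, u_1, u_2)$.

After event $k$ the state moves under the linear learning operator
$$P_k x = \vartheta_k x + (1-\vartheta_k)\lambda_k,$$
a convex combination of the current state and the operator's fixed point
$\lambda_k$. Learning rates $\vartheta_k$ are kept strictly inside $(0,1)$
— the package rejects boundary values, since $\vartheta_k = 1$ freezes the
state and $\vartheta_k = 0$ teleports it — while $\lambda_k, u_1, u_2, x$
use the closed interval.

The asymptotic choice-probability function $W$ satisfies the functional
equation $W = ZW$ with
$$(ZW)(x) = \sum_{k=1}^{8} p_k(x)\, W(P_k x).$$

## Contraction diagnostics

Four closed-form constants bound the Lipschitz factor of $Z$ in the
seminorm $\|W\| = \sup_{a \neq b} |W(a)-W(b)|/|a-b|$:

* `K1*` for the general model; $K_1^\ast < 1$ makes $Z$ a Banach
  contraction, so Picard iteration converges to the unique solution.
* `K2*` for the common-$\lambda$ (commutative) regime. Its printed formula
  contains a $(\vartheta_3 + \vartheta_3)$ term where the pattern of the
  other rows implies $(\vartheta_3 + \vartheta_7)$; both variants are
  implemented (`variant = "as_printed"` is the default, `"typo_corrected"`
  the alternative) and flagged in the result. Since the formula involves a
  single shared $\lambda$, `K2*` is reported only when all limit points are
  equal, and marked not applicable otherwise. The multi-row absolute values
  in all four formulas are read as: sum the rows, then take the absolute
  value — inert for valid parameters, whose summands are all nonnegative.
* `K3*` for the reflex-extinction regime ($\lambda \equiv 0$); it equals
  `K1*` evaluated at zero limit points.
* `K4*` for the food-side absorption regime ($\lambda \equiv 1$). As
  stated, each group contributes a "$1 + \vartheta_i + \vartheta_j$" term
  with group weights summing to 2, so $K_4^\ast = 2 + K_3^\ast > 2$ for
  every valid parameter set: the hypothesis $K_4^\ast < 1$ of the
  corresponding uniqueness statement is unsatisfiable as printed. The
  package computes the constant verbatim and exposes the fact rather than
  guessing an intended formula.

With a common rate $\vartheta$ and limit $\lambda$ the constants collapse
to $K_1^\ast = 2(2\vartheta + (1-\vartheta)\lambda)$ and
$K_3^\ast = 4\vartheta$, which the tests check against the verbatim
implementation. A consequence worth noting: $K_1^\ast < 1$ requires rates
and limits roughly below $1/4$ on average, a small corner of the parameter
box. The fixture sampler therefore accepts sampling ranges
(`theta_range`, `lam_range`); rejection sampling over the full unit box
practically never hits the contraction region.

## The grid solver

$W$ is represented by its values on a uniform grid over $[0,1]$ (default
1001 nodes) with linear interpolation for the off-node arguments $P_k x$.
Linear interpolation is chosen because it preserves the two structural
properties the tests rely on: $ZW$ at a node is a convex combination of
values of $W$, so nodewise bounds and monotonicity in $W$ survive
discretization exactly.

`picard_solve()` iterates $W_n = Z W_{n-1}$ until the maximum change
between successive approximations over the nodes falls below `tol`
(default $10^{-10}$, capped at `max_iter = 10000` sweeps). The report
records the full sup-delta history, the geometric-mean contraction rate of
those deltas, and `K1*`.

Two modes are provided because the functional equation is homogeneous:
$W \equiv 0$ — and, on the grid, every constant function — satisfies
$W = ZW$, and under $K_1^\ast < 1$ the zero function is the unique
solution in the seminormed space (which identifies functions differing by
a constant). The **free** mode runs the plain iteration and, from a
Lipschitz start such as the identity, converges to a constant. The
**pinned** mode clamps $W(0)$ and $W(1)$ (default to 0 and 1) after every
sweep, producing a nontrivial absorption-style profile. The underlying
function class carries the constraint $W(0) = 0$; since one application of
$Z$ does not structurally preserve it, the constraint is enforced only
through the initial function and pinning, never asserted mid-iteration.
Published plots of a nontrivial, non-monotone solution do not state the
parameters, grid, or boundary handling that produced them, so no attempt
is made to reproduce any particular curve: the package exposes both modes
and reports what they converge to.

Why the observed sup-delta rate stays below `K1*`: successive differences
$\delta_n = W_{n+1} - W_n$ evolve linearly under $Z$, their Lipschitz
seminorm contracts by at least $K_1^\ast$ per sweep, and their mean under
the chain's stationary law is zero — so their sup-norm is dominated by the
seminorm and inherits the geometric decay. The tests allow a grid slack of
0.02 on 1001 nodes for interpolation effects.

## Monte Carlo scheme

The simulator draws, per trial, a single uniform variate and selects the
event by inverse CDF over the cumulative tree probabilities in fixed
$E_1..E_8$ order, then applies the matching operator. Because each trial
applies a randomly indexed operator with exactly the $p_k(x)$ weights,
$$\mathbb{E}[W_0(X_N) \mid X_0 = x] = (Z^N W_0)(x):$$
path sampling with a terminal function is the exact stochastic counterpart
of the Picard iterate, so `mc_estimate_W()` is an unbiased estimator of
the deterministic depth-$N$ iterate (up to interpolation when the terminal
is itself a grid function), and `compare_solvers()` is well-posed. No
variance reduction is applied; uncertainty is reported as the sample
standard error of the mean.

Reproducibility policy: every stochastic entry point takes an optional
integer `seed`. Where chains are materialized one by one (the CLI's
`simulate` command, the per-probe estimates in `compare_solvers()`), child
seeds are derived from the root seed by a fixed odd stride modulo a 31-bit
prime, so blocks are independent and individually reproducible. Inside the
vectorized engines (`learning_curve()`, `mc_estimate_W()`) draws are made
trial-major across paths from a single stream — bit-reproducible given the
seed, and chains remain mutually independent; per-chain sub-streams would
buy nothing there and cost an order of magnitude in speed.

## Special regimes and degeneracies

* `all_zero` ($\lambda \equiv 0$): every operator shrinks the state
  ($P_k x = \vartheta_k x \le x$), so each path is nonincreasing and the
  state is absorbed at 0 — extinction of a behavioral reflex.
* `all_one` ($\lambda \equiv 1$): every path is nondecreasing and absorbed
  at 1 — the rat settles on the food side.
* Common $(\vartheta, \lambda)$: the conditional mean update does not
  depend on which event fired, giving the closed form
  $\mathbb{E}[x_n] = \lambda + \vartheta^n (x_0 - \lambda)$. In fact the
  whole chain is then deterministic, so the standard error of the
  simulated mean is exactly zero; tests that band such checks by three
  standard errors add an absolute floor of $10^{-9}$ so that floating
  rounding cannot fail a degenerate-regime comparison. That floor is also
  the default absolute tolerance for floating comparisons in the suite.

## Problem sizes used by the tests

The suite certifies: normalization over a $10^4$-point random sweep of
$(x, u_1, u_2)$; operator-vs-brute-force equivalence to $10^{-12}$ on
5-node grids over 100 random draws; the contraction-rate bound on 1001
nodes over 50 sampled contraction parameter sets
($\vartheta \in (0.01, 0.3)$, $\lambda \in (0, 0.3)$, rejection to
$K_1^\ast < 1$); Monte Carlo versus the depth-20 iterate at 21 probe
points across 10 seeds with $10^5$ paths each (3-standard-error band,
$\ge 99\%$ coverage); and absorption over $10^3$ chains of $10^3$ trials
(pathwise monotone, terminal states within $10^{-3}$ of the endpoints).
These sizes keep every check sharp at desk scale while the closed forms
above pin the expected values independently of the implementation.

## What the synthetic conditions do and do not show

All inputs are model parameters; there is no external data. The simulator
emulates the model's own stochastic process exactly, so passing tests
certify internal consistency — operator algebra, contraction behavior,
estimator unbiasedness — not fidelity to any particular animal's learning
curve. Real discrimination-learning data would bring trial-to-trial
dependencies (satiation, position habits, inter-trial intervals) that the
eight-event tree deliberately abstracts away, and fitting
$\vartheta, \lambda, u$ to such data is out of scope.

## Known limitations

* `K2*` is only defined for a shared $\lambda$; for heterogeneous limit
  points it is reported as not applicable rather than extrapolated.
* For non-contraction parameters ($K_1^\ast \ge 1$) the free iteration on
  the grid is still non-expansive in the sup-norm and typically settles,
  but no uniqueness claim attaches to the result; `compare_solvers()`
  warns in that regime.
* The invariant subset hypothesis behind the contraction theorem (an
  operator-invariant closed class of Lipschitz functions) is never
  constructed explicitly; the tests verify its checkable consequences —
  bound preservation, monotonicity, the contraction rate — on random
  instances.
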