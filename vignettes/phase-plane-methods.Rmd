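---
title: "Phase-plane methods behind the outcome classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-plane methods behind the outcome classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 6)
library(mutdyn)
```

`mutdyn` analyses two-dimensional autonomous ODE models of mutualism,

$$\frac{dN_i}{dt} = N_i \, g_i(N_1, N_2), \qquad i = 1, 2,$$

where each model in the registry supplies the per-capita growth functions
$g_i$, a parameter schema with admissible ranges and defaults, and (when it
exists in closed form) an analytic Jacobian.  This vignette documents the
numerical methods, their tolerances, and the decision rules that turn raw
phase-plane output into a qualitative outcome label.

## The model registry

`listModels()` returns the available model identifiers.  They fall into two
groups: named literature models (linear-benefit Lotka–Volterra forms,
saturating-benefit forms, cost–benefit and consumer–resource formulations)
and generic `case_*` templates organised by the kind of intraspecific
density dependence each species experiences.  Generic cases describe *one*
species' growth law; `pairCases()` composes any two of them into an
asymmetric two-species model with a merged parameter schema, reachable from
every analysis function under the id `"caseA:caseB"`.

```{r}
head(listModels(), 12)
m <- getModel("case_1_2")
m$schema[, c("name", "default", "lower", "description")]
```

`validateParams()` checks names and open/closed range constraints before
any computation; every public entry point calls it first, so a bad
parameter fails fast with the offending name in the error message.
`obligacy()` reports, per species, whether it can persist without its
partner (sign of growth when rare and alone; a carrying-capacity of zero
also marks a species obligate in models parameterised that way).

## Equilibria and local stability

`findEquilibria()` locates all equilibria in a box $[0, L]^2$:

1. Axis and origin equilibria come from one-dimensional root finding on
   each axis (the flow is invariant there for every registered model).
2. Interior candidates come from intersecting the nontrivial nullclines:
   both $g_1 = 0$ and $g_2 = 0$ are contoured on a regular grid
   (`grid_equilibria`, default 120) and segment crossings are collected.
3. Each candidate is polished by damped Newton iteration on
   $(g_1, g_2)$ to tolerance `newton_tol` ($10^{-12}$), then deduplicated.

Stability comes from the Jacobian of the *full* right-hand side
$(N_1 g_1, N_2 g_2)$ — analytic when the model supplies one, central finite
differences otherwise — classified by its eigenvalues into
`stable_node`, `stable_spiral`, `unstable_node`, `unstable_spiral`,
`saddle`, or `nonhyperbolic` (an eigenvalue within tolerance of the
imaginary axis).

```{r}
eq <- findEquilibria("case_1_2", canonicalParams("case_1_2", "SC"),
                     box = c(0, 5))
eq
```

For this symmetric saturating-benefit parameterisation the interior
equilibrium solves $x^2 - x - 1 = 0$: the golden ratio, a useful exact
oracle for the root-polishing pipeline.

## Nullclines and their geometry

`nullclines()` returns, per species, the trivial (axis) branch plus
contoured nontrivial branches, each annotated with a geometry summary:
monotonicity (`increasing`, `decreasing`, `non-monotonic`) and shape
(`linear`, `concave_up`, `concave_down`, `lobe`).  Closed-lobe nullclines
are the signature of consumer–resource formulations in which costs
dominate at high density; counting sign changes of one growth function
along the other species' nullcline branches is how multiple interior
equilibria are found and audited.  Models whose growth law is undefined in
part of the plane (e.g. a singular carrying-capacity term) have their
nullclines clipped to the validity domain, with a warning and a `clipped`
flag on the result.

## Trajectories, basins, separatrices

`integrateModel()` wraps `deSolve::lsoda` with event detection: a
trajectory terminates with `converged` (state velocity and displacement
below `conv_tol`), `unbounded` (leaving `blowup_factor` times the box),
`extinct` (a component below the extinction floor), or `horizon` (budget
exhausted, undecided).  `basinMap()` integrates a regular grid of initial
conditions (with extra refinement near the axes, where thresholds live)
and labels each cell by its attractor: a specific interior equilibrium,
`extinct`, `unbounded`, or `horizon`.  Cells that land on an interior
*saddle* are measure-zero artifacts of grid points lying on a stable
manifold and are counted as `horizon`, never as a coexistence attractor.

`separatrix()` traces the stable manifold of an interior saddle by
integrating backwards from small offsets along the stable eigenvector; the
traced curve is cross-checked against the basin map
(`separatrixConsistency()`).

```{r, fig.alt = "Phase portrait with nullclines, equilibria and separatrix"}
p <- canonicalParams("case_1_2", "HD SC & SC/E threshold")
renderPortrait("case_1_2", p, box = c(0, 5))
```

## Outcome classification

`classifyDynamics()` synthesises equilibria plus basin structure into one
label from a closed vocabulary: `"SC"` (stable coexistence), `"UC"`
(unbounded growth), `"E"` (extinction), the threshold combinations
`"UC/E threshold"`, `"SC/E threshold"`, `"HD SC & SC/E threshold"`,
`"HD UC & UC/SC threshold"` (HD: the outcome depends on initial
densities), and `"multi-attractor"` (two or more distinct coexistence
attractors).  A classification is flagged `low_confidence` when more than
10% of basin cells remain undecided at the horizon.

When a threshold label is found, `thresholdType()` probes its mechanism by
sweeping anchored initial conditions along each axis direction and
recording on which side of the critical value collapse occurs:

* `partner_threshold` — collapse tracks the partner's initial density;
* `own_density_allee` — collapse tracks the species' own initial density;
* `overexploitation` — collapse occurs for partner densities *above* the
  critical value;
* `none` — no directional signature (e.g. a symmetric joint threshold).

`coexistenceCharacter()` compares an interior attractor with each
species' partner-free equilibrium to distinguish mutualistic from
parasitic coexistence, and `criticalBenefitStrength()` bisects a benefit
parameter for the boundary between bounded and unbounded dynamics (for the
linear-benefit model this reproduces the product condition
$\beta_{12}\beta_{21} = s_1 s_2$ to three digits).

## Canonical fixtures

Every qualitative regime discussed above is pinned by a committed
parameterisation in the fixture registry (`listFixtures()`,
`canonicalParams()`).  Each fixture was found once — by hand algebra or a
seeded numerical search — and frozen together with the outcome label the
classifier reproduces on it; the test suite re-derives every label from
scratch.  The registry includes deliberately delicate cases, e.g. a
consumer–resource parameterisation with exactly five interior equilibria,
and a weakly damped spiral that separates oscillatory consumer–resource
coupling from the non-oscillatory saturating-benefit models.

## Reproducible runs

`runAnalysis()` executes a YAML-configured analysis bundle (equilibria,
nullclines, basins, classification, sweeps, critical-value bisection,
portrait) and writes a versioned JSON report plus CSV tables; reruns of
the same config are byte-identical.  The same entry points are available
from the command line via the installed script
`system.file("scripts", "mutdyn-cli.R", package = "mutdyn")`.
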