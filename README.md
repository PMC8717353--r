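# mutdyn

Phase-plane analysis and qualitative classification of two-species
mutualism models.

`mutdyn` bundles a registry of classical two-species mutualism ODE models
(linear-benefit Lotka–Volterra forms, saturating-benefit forms,
cost–benefit and consumer–resource formulations) together with generic
template models organised by the kind of intraspecific density dependence
each species assumes. On top of the registry it provides:

- **Equilibria and stability** — `findEquilibria()` locates all boundary
  and interior equilibria in a box and types them by their Jacobian
  eigenvalues (analytic Jacobians where available, finite differences
  otherwise).
- **Nullclines** — `nullclines()` extracts trivial and nontrivial
  branches with geometry summaries (monotonicity, concavity, closed
  lobes) and clips them to each model's validity domain.
- **Phase-plane machinery** — event-detecting integration
  (`integrateModel()`), basin-of-attraction maps (`basinMap()`),
  separatrix tracing through interior saddles (`separatrix()`), and
  damped/sustained oscillation detection (`detectOscillation()`).
- **Outcome classification** — `classifyDynamics()` assigns one label
  from a closed vocabulary (stable coexistence `SC`, unbounded growth
  `UC`, extinction `E`, initial-density-dependent threshold combinations,
  `multi-attractor`), `thresholdType()` probes the threshold mechanism
  (partner threshold, own-density Allee effect, overexploitation), and
  `criticalBenefitStrength()` bisects the benefit level separating
  bounded from unbounded dynamics.
- **Canonical fixtures** — `canonicalParams()` / `listFixtures()` expose
  committed parameterisations pinning every qualitative regime, including
  a consumer–resource fixture with exactly five interior equilibria.
- **Reproducible runs** — `runAnalysis()` executes a YAML-configured
  bundle (JSON report, CSV tables, SVG portraits; byte-identical reruns)
  and `inst/scripts/mutdyn-cli.R` exposes the same analyses on the
  command line.

## Worked example

An obligate pair with saturating benefits: both species die out when
rare and alone, but strong enough mutualism opens a coexistence basin
above a threshold.

```r
library(mutdyn)

p <- list(r1 = -0.5, r2 = -0.5, b12 = 4, b21 = 4,
          h12 = 1, h21 = 1, s1 = 1, s2 = 1)

findEquilibria("case_1_2", p, box = c(0, 5))
#> <equilibrium_set> model case_1_2, box [0, 5]^2, 3 equilibria
#>       N1     N2  residual     re1 im1     re2 im2        type    class
#> 1 0.0000 0.0000 0.000e+00 -0.5000   0 -0.5000   0 stable_node   origin
#> 2 0.2192 0.2192 5.404e-14  0.3707   0 -0.8091   0      saddle interior
#> 3 2.2808 2.2808 1.110e-09 -1.4332   0 -3.1284   0 stable_node interior

rep <- classifyDynamics("case_1_2", p, grid_n = 15)
rep$outcome_label
#> [1] "HD SC & SC/E threshold"
round(rep$evidence$basin_fractions, 3)
#>    coexist extinction  unbounded    horizon
#>      0.963      0.038      0.000      0.000
```

The label reads: the outcome is history-dependent (`HD`) — initial
densities above the saddle's separatrix reach stable coexistence (`SC`),
those below collapse to extinction, with the saddle at (0.22, 0.22)
marking the `SC/E` threshold. Because the threshold here is a symmetric
joint condition on both species, the directional probes report no single
mechanism (`rep$threshold_type` is `"none"`); asymmetric fixtures in the
registry exercise `partner_threshold`, `own_density_allee`, and
`overexploitation`.

Render the phase portrait (vector field, nullclines, equilibria,
separatrix):

```r
renderPortrait("case_1_2", p, box = c(0, 5), file = "portrait.svg")
```

Or run the whole bundle from a config:

```r
runAnalysis(list(model = "case_1_2", params = p,
                 analyses = c("equilibria", "basins", "classify", "portrait"),
                 outdir = "out"))
```

## Models

`listModels()` returns all identifiers:

```r
head(listModels(), 8)
#> [1] "gause_witt_eq1"         "whittaker_eq2"          "whittaker_eq3"
#> [4] "vandermeer_boucher_eq1" "addicott_eq4"           "wolin_lawlor_eq5"
#> [7] "wolin_lawlor_eq6"       "wright_eq7"
```

Generic `case_*` templates describe one species' growth law each;
`pairCases("case_1_1_2", "case_1_2")` (or the id
`"case_1_1_2:case_1_2"`) composes two of them into an asymmetric model.

See the vignette `phase-plane-methods` for the numerical methods,
tolerances, and classification rules.

## Testing

```r
testthat::test_dir("tests/testthat", package = "mutdyn",
                   load_package = "installed")
```

Acceptance metrics can be recomputed against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
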