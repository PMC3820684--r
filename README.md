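# gearselect

Joint maximum-likelihood estimation of length-based selectivity curves for
several capture methods at once — gillnets of different mesh sizes *and*
piscivorous predators — from multi-gear catch-at-length tables, with overlap
summaries that quantify how strongly a predator and a fishery compete for
the same sizes of fish.

## Who this is for

Fisheries scientists and ecologists holding a table of counts by 1-cm
length class with one column per capture method: survey gillnets (mesh
sizes in mm) and one or more predators whose consumed-fish lengths were
reconstructed from diet samples (pellets, stomachs). Fishing effort and
"fishing power" of the methods need not be known or comparable: the
estimator works on per-gear normalised length frequencies.

## The model

Catches are conditionally Poisson, `n_ij ~ Poisson(f_i * mu_j * S_ij)`,
with `mu_j` the relative abundance in length class `j` and `S_ij` the
selectivity of gear `i` at that length:

* mesh nets: gamma density rescaled to a modal value of one, with modal
  length `theta1 * mesh` and a single shared curve variance `theta2`
  (geometric similarity) — all nets together cost two parameters;
* predator: lognormal density rescaled to a modal value of one, location
  `theta3`, spread `theta4`, mode `exp(theta3 - theta4^2)`.

The abundances profile out in closed form,
`mu_j = sum_i n_ij / sum_i S_ij`, leaving a four-parameter profile
likelihood maximised by Nelder–Mead (on log-parameters, with one restart).
Standard errors come from the inverse numerical Hessian. A Poisson
simulator (`sim_config()`, `sample_catch()`, `recovery_experiment()`)
generates synthetic tables from the same model for recovery and calibration
studies.

## Worked example

The package bundles a multi-gear European perch data set from the Curonian
Lagoon (eight gillnets, 14–45 mm mesh, plus Great Cormorants; 4663 fish):

```r
library(gearselect)

tab <- curonian_perch()
fit <- fit_selectivity(tab)    # per-gear normalisation, then the ML fit
tidy(fit)
#> # A tibble: 4 × 3
#>   term   estimate std.error
#>   <chr>     <dbl>     <dbl>
#> 1 theta1    0.707    0.0467
#> 2 theta2   12.9      7.23
#> 3 theta3    2.13     0.426
#> 4 theta4    0.409    0.366
```

`theta1 = 0.707` cm/mm means a net's best-caught length is about 0.71 times
its mesh size (9.9 cm for the 14 mm net); `theta2` is the common width
(variance, cm²) of all net curves; the cormorant curve peaks at
`exp(theta3 - theta4^2) ≈ 7.1` cm.

```r
curve_summary(fit)             # mode and variance per gear
curve_overlap(fit, pairs = list(c("GC", "G14"), c("GC", "G38")))
#>   gear_a gear_b overlap_pct
#> 1 GC     G14          73.3
#> 2 GC     G38           2.75
crossing_point(fit, pair = c("GC", "G38"))
#> [1] 19.1
autoplot(fit)                  # the multi-gear curve figure
```

Cormorant predation selects essentially the same sizes as the smallest
survey net (≈73 % overlap) and almost none of the sizes taken by the 38 mm
net (≈3 %); the two curves cross near 19 cm, just above the fishery's
18 cm minimum legal size — little direct competition for legal-sized fish.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/gearselect.R fit --demo --out out/
Rscript inst/cli/gearselect.R overlap --fit out/fit.json --all --out out/
Rscript inst/cli/gearselect.R simulate --config inst/extdata/sim_config.yml --recover --out sim/
```

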