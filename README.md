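# migkin

Kinetic modeling of acetyl group migration and hydrolysis in
partially acetylated oligosaccharides.

Acetyl esters on carbohydrate hydroxyls migrate between vicinal
positions on the same ring, migrate across the glycosidic linkage from
a secondary hydroxyl to a primary O6, and hydrolyse to solvent.  Above
pH 6 all three processes run through an anionic mechanism, so their
rates scale with the hydroxide concentration and, mechanistically, with
the deprotonated fraction of the accepting hydroxyl.  `migkin` is for
carbohydrate and hemicellulose chemists who want to model these
processes quantitatively: it represents a migration/hydrolysis network
as a first-order reaction scheme, simulates species mole fractions,
fits rate constants to NMR-derived time courses, and links rate
constants to activation barriers and hydroxyl pKa values.

## The model

Species mole fractions `y` evolve as a linear first-order network

    dy/dt = A(pH) y,   A[p,s] = sum over reactions s->p of k_r * 10^(pH - pHref)

with columns of `A` summing to zero (total mole fraction conserved) and
`10^(pH - pHref)` the hydroxide concentration relative to the reference
pH 8.  Rate constants are estimated by minimising
`Q = sum (y_obs - y_sim)^2` over all experiments jointly (Nelder-Mead
simplex, then Levenberg-Marquardt, on log-parameters).  The
thermochemical layer interconverts rates and barriers by the Eyring
equation `k = (kB T / h) exp(-dG/RT)`, computes hydroxyl pKa values
from aqueous free energies, collapses stepwise migration barriers into
formal constants by the steady-state approximation, and predicts
pH-dependent observed constants
`k_obs = k_formal * 10^(pH-pKa)/(1 + 10^(pH-pKa))`.

Two fixtures ship with the package: the xylan model trisaccharide
(species `1a`-`1d`, four rate constants) and the glucan model
trisaccharide (species `2a`-`2g`, six rate constants, including
cross-unit O2->O6 migration and separate primary/secondary
hydrolysis), each with its fitted constants at pH 8, 25 °C.

## Worked example

```r
library(migkin)
scheme <- build_xylan_scheme()
truth  <- xylan_rate_constants()

# adjacent O2 <-> O3 migration equilibrium starting from pure 1b
sim <- simulate_scheme(scheme, truth, c("1b" = 1), times = 0:300)
sim$values[301, "1c"] / sim$values[301, "1b"]
#> [1] 1.947692

# recover the constants from synthetic two-start NMR-like data
spec <- synthetic_spec("xylan", noise_sd = 0.01, seed = 1)
fit  <- fit_scheme(scheme, generate_synthetic(spec), truth$values * 2)
fit
#> <migkin_fit> scheme 'xylan'
#> <migkin_rates> (1/h)
#>   k1           0.001832 +/- 1.94e-05
#>   k2           0.6612 +/- 0.0123
#>   k-2          0.3429 +/- 0.00826
#>   k3           0.003017 +/- 2.93e-05
#>   Q = 0.01026 over 120 observations
#>   degree of explanation: 99.91%
#>   converged: TRUE
#>     stage simplex  Q 1.163 -> 0.01026
#>     stage lm       Q 0.01026 -> 0.01026
```

The equilibrium ratio 1.95 is the O3:O2 acetylation ratio of the middle
xylose (about 1:2 in favour of O3), set by `k2/k-2`.  The fit recovers
all four constants within a few percent of the generating values
(`k2 = 0.633/h`, `k-2 = 0.325/h`, `k1 = 1.82e-3/h`, `k3 = 3.01e-3/h`),
with asymptotic standard errors and the fraction of observation
variance the model explains.

On the thermochemical side:

```r
eyring_barrier(9.25e-6)        # 1/s -> activation barrier, kcal/mol
#> [1] 24.3206
observed_rate(2.68, 13.1, 8)   # formal constant, pKa, pH -> observed 1/s
#> [1] 2.128783e-05
```

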