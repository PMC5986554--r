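# aggkin

Kinetic analysis of amyloid-β(1-42) fibrillation and aggregate morphometry
in R.

Aggregation of the Aβ-42 peptide into amyloid fibrils — a central event in
Alzheimer's disease — follows nucleation-dependent polymerization: a slow
nucleation step in which monomers M form nuclei Pₙ, followed by fast,
aggregate-catalysed elongation:

    (1)  n M  → Pₙ        rate constant kₙ  (s⁻¹)
    (2)  M + Pₙ → Pₙ₊₁     rate constant kₑ  (L mol⁻¹ s⁻¹)

With k = kₑ·a (a the initial monomer concentration) and ρ = kₙ/k, the
fibril fraction f obeys the autocatalytic rate law df/dt = k(1−f)(ρ+f),
whose closed-form solution is the sigmoid

    f(t) = ρ·(e^{(1+ρ)kt} − 1) / (1 + ρ·e^{(1+ρ)kt})

Thioflavin-T (ThT) fluorescence at 483 nm proxies fibril content, so
fitting ThT time courses to this model extracts kₙ and kₑ — and thereby
how membrane composition (DOPC, cholesterol, 7-ketocholesterol vesicles)
shifts nucleation versus elongation. Atomic force microscopy length/height
tables complement the kinetics: protofibrils (50–250 nm long, 1–4 nm
high) versus mature fibrils (200–1000 nm, 2–6 nm).

The package is for biophysicists analysing amyloid aggregation assays: it
provides the closed form and an independent ODE oracle, half/lag-time
formulas, bounded nonlinear least-squares fitting of raw intensity curves
(baseline and amplitude fitted jointly), fold-change comparison of rate
constants across conditions, joint length×height particle classification,
and fully seeded synthetic generators for both data modalities.

## Worked example

Simulate a triplicate ThT experiment at the packaged control-condition
constants (80 µM peptide, the 0/6/…/48 h schedule densified), refit it,
and compare conditions:

```r
library(aggkin)

rates <- kinetic_rates(kn = 3.73e-6, ke = 3.378, a = 80e-6)
half_time(reduce_rates(rates)) / 3600
#> [1] 4.370038

sims <- simulate_tht(rates, times = hours_to_seconds(seq(0, 48, by = 2)),
                     noise = noise_spec(sigma_rel = 0.02, seed = 7),
                     F0 = 20, dF = 350)
fit <- fit_intensity_curve(sims, a = 80e-6)
fit
#> autocatalytic model fit
#>   k    = 0.000271286 /s
#>   rho  = 0.0130705
#>   kn   = 3.54586e-06 /s
#>   ke   = 3.39108 L/mol/s (a = 8e-05 mol/L)
#>   F0   = 19.2188, dF = 350.063
#>   sse  = 3433, R^2 = 0.99523, converged: TRUE, sigmoidal: TRUE
#>   se(k) = 1.26e-05, se(rho) = 0.00278
```

The fitted kₑ (3.39) and kₙ (3.5×10⁻⁶) recover the generating constants
(3.378, 3.73×10⁻⁶) within the noise. Fold changes across the packaged
membrane conditions:

```r
compare_conditions(abeta_rate_constants())
#>   parameter condition_a condition_b    ratio direction ratio_rounded
#> 1        kn        Chol       alone 1.361314 decreased          1.36
#> 2        ke        Chol       alone 1.649793 increased          1.65
#> 3        kn        Chol        DOPC 2.178832 decreased          2.18
#> 4        ke        Chol        DOPC 2.831809 increased          2.83
#> 5        kn       7keto       alone 1.179625 increased          1.18
#> 6        ke       7keto       alone 2.753056 decreased          2.75
#> 7        kn       7keto        Chol 1.605839 increased          1.61
#> 8        ke       7keto        Chol 4.541972 decreased          4.54
```

Cholesterol vesicles accelerate elongation 1.65-fold while damping
nucleation; substituting part of the cholesterol with 7-ketocholesterol
reverses this — 4.54-fold slower elongation than cholesterol — which traps
the peptide in protofibrillar form. The morphology side shows the same
picture:

```r
tab <- simulate_particles(preset_mixture("7keto_24h", seed = 1), 5000)
summarize_species(tab)
#>        species count fraction
#> 1       fibril   569   0.1138
#> 2  protofibril  4223   0.8446
#> 3 unclassified   208   0.0416
```

A thin command-line wrapper over the same functions is in
`inst/scripts/aggkin` (subcommands `simulate`, `fit`, `classify`,
`compare`, `report`).

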