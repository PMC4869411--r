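# ltrepop

Stage-structured matrix population models and life table response
experiments (LTRE) for designed demography experiments on annual plants.

## The scientific problem

Common-garden experiments on weedy annuals — the motivating system is
wild radish and its advanced-generation crop–wild hybrid, after
artificial selection for early flowering or long leaves — ask whether
genetic background (biotype) and selection treatment change the
population growth rate λ, and *through which* vital rate. `ltrepop`
turns individual-level census data (one row per planted seed: did it
germinate, did it flower, how many fruits and locules) into:

1. **Vital rates** per replicate population: seed dormancy/mortality
   *d*, germination *g*, survival to flowering *s*, fecundity *f*
   (mean locule count of sampled fruits × fruit count, one seed per
   locule, averaged over flowering plants).
2. **A 3-stage annual projection matrix** per population (stages: seed,
   cotyledonous plant, flowering plant),

   ```
       | d  0  f |
   A = | g  0  0 |        λ³ − dλ² − gsf = 0
       | 0  s  0 |
   ```

   with dominant eigenvalue λ (annual growth multiplier), stable stage
   distribution **w**, reproductive values **v**, sensitivities
   s_ij = v_i w_j / ⟨w, v⟩ and elasticities (a_ij/λ)·s_ij.
3. **A two-way fixed-effect LTRE** decomposing treatment effects on λ,

   λ^{gs} = λ^{(··)} + α^g + β^s + αβ^{gs},

   against the mean matrix of the randomly-mating control populations,
   with per-matrix-element contributions
   c_ij = (a_ij^{level} − a_ij^{(··)}) · ∂λ/∂a_ij evaluated at the
   matrix halfway between the level and the reference. Effects are
   reported both as exact λ differences and as first-order contribution
   sums.
4. **Designed-experiment statistics** on the per-population rates:
   two-way Type III ANOVA with a configurable error term (main effects
   over the interaction mean square reproduce the published df layout
   (1,2)/(2,2)/(2,12); the all-over-residual alternative is always
   reported), MANOVA (Pillai default, Wilks/Hotelling options), and
   Tukey post hoc comparisons. Proportions are arcsine-square-root
   transformed, fecundity and λ log10 transformed.

A synthetic census generator (`simulate_census()`, with the documented
`preset_paperlike()` configuration) emulates the 2 biotypes × 3
treatments × 3 replicate populations × 5 pans × 6 seeds design with
binomial fates and overdispersed count fecundity, so the whole pipeline
is testable without field data.

## Worked example

```r
library(ltrepop)
census <- simulate_census(preset_paperlike(), seed = 42)  # 540 seeds
vitals <- vital_rate_table(census, dormancy = 0)
head(vitals[, c("population_id", "g", "s", "f", "lambda")], 3)
#>   population_id         g         s        f   lambda
#> 1  wild_early_1 0.5333333 0.7500000 206.4750 4.354876
#> 2  wild_early_2 0.6000000 0.8888889 238.3562 5.028152
#> 3  wild_early_3 0.5666667 0.8823529 233.7600 4.889301

fit <- ltre(census, dormancy = 0)
summary(fit)
#> LTRE decomposition (reference: control , lambda_ref = 5.141 )
#> lambda by treatment level:
#>   biotype:   wild 5.388  hybrid 4.327
#>   selection: early 4.342  control 5.141  long 5.128
#>
#> Effects on lambda (exact difference vs first-order contribution sum):
#>       effect          level   exact first_order abs_error
#>      biotype           wild  0.2473      0.2473   3.9e-05
#>      biotype         hybrid -0.8135     -0.8038   9.7e-03
#>    selection          early -0.7987     -0.7866   1.2e-02
#>    selection        control  0.0000      0.0000   4.6e-16
#>    selection           long -0.0131     -0.0132   1.4e-04
#>  ...
```

Reading this: each replicate population's germination (e.g. 16 of 30
seeds → 0.533), survival and per-plant seed production feed its matrix;
λ per population is the real root of the cubic above. In this simulated
season the hybrid biotype's pooled matrix grows 0.81/year slower than
the control reference and the early-flowering treatment 0.80/year
slower, and the first-order contribution sums agree with those exact
differences to ~1% of λ — the scale of the curvature error of the
decomposition. `plot(fit)` draws the per-vital-rate contribution bars;
`contribution_table(fit)` returns them tidily;
`anova_summary_table(vitals)` and `vital_manova()` give the F tables.

`run_pipeline(config = preset_paperlike(), out_dir = "run1", seed = 1)`
executes census → vitals → matrices → eigenanalysis → LTRE → statistics
in one call, writing every stage's output and a manifest
(`manifest.json` with seed, config hash and per-stage file lists).

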