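---
title: "Stage-structured demography and LTRE decomposition with ltrepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-structured demography and LTRE decomposition with ltrepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrepop)
```

## The model

`ltrepop` analyses designed common-garden experiments on annual plants —
the motivating system is weedy radish, comparing a wild biotype against an
advanced-generation crop–wild hybrid biotype after artificial selection
for early flowering or long leaves — through a stage-classified annual
projection matrix. Individuals are classified into three stages: seeds,
cotyledonous (germinated) plants, and flowering plants. One year of
dynamics involves exactly four transitions:

* `d` — seed dormancy/mortality (seed → seed). The design cannot separate
  a dormant seed from a dead one, so the two fates are kept as a single
  pooled parameter.
* `g` — germination probability (seed → cotyledon),
* `s` — survival to flowering (cotyledon → flowering),
* `f` — fecundity, the mean number of seeds produced per flowering plant
  (flowering → seed).

The annual projection matrix, in fixed stage order, is

$$
A = \begin{pmatrix} d & 0 & f \\ g & 0 & 0 \\ 0 & s & 0 \end{pmatrix},
$$

whose characteristic polynomial is $\lambda^3 - d\lambda^2 - gsf = 0$.
The dominant root $\lambda$ is the asymptotic annual growth multiplier;
in the $d = 0$ limit $\lambda = (gsf)^{1/3}$, which is why fecundities of
a few hundred seeds per plant yield $\lambda \approx 5$. This 3×3 layout
is the only arrangement compatible with three stages, four transitions
and growth rates of that magnitude, and the package treats it as
canonical (`build_matrix()` refuses `d + g > 1`, since a seed cannot both
stay and leave with total probability above one).

### Eigenanalysis

`eigen_analyze()` returns $\lambda$, the stable stage distribution `w`
(right eigenvector, normalized to sum 1) and stage-specific reproductive
values `v` (left eigenvector, scaled so $\langle w,v\rangle = 1$). For
the canonical skeleton the matrix is *imprimitive* when $d = 0$ — it has
complex eigenvalues of the same modulus as the dominant root — so a naive
"largest modulus" pick is ambiguous. The package therefore takes the real
positive root of the characteristic cubic as the authoritative $\lambda$
(with a Newton polish), and uses the closed-form eigenvectors
$w \propto (1, g/\lambda, gs/\lambda^2)$,
$v \propto (1, sf/\lambda^2, f/\lambda)$. General nonnegative matrices
fall back to a numeric eigendecomposition with the residual
$\lVert Aw - \lambda w\rVert_\infty$ checked against `1e-9`. A reducible
life cycle (`g = 0` or `f = 0`) collapses to $\lambda = d$ and is
reported with a warning rather than an error, because a replicate
population in which nothing germinates is a legitimate (if degenerate)
experimental outcome.

Sensitivities are $s_{ij} = \partial\lambda/\partial a_{ij}
= v_i w_j / \langle w,v\rangle$ and elasticities
$e_{ij} = (a_{ij}/\lambda)\, s_{ij}$; elasticities are zero off the
four-transition skeleton and sum to one over it.

## Vital-rate estimation

`estimate_vital_rates()` pools all pans of a replicate population (the
pan is a planting unit, not a stratum of the model): `g` is germinants
over seeds planted, `s` flowerers over germinants, and `f` the mean of
per-plant seed estimates over *flowering* plants, where a plant's seed
count is the mean locule count of its sampled fruits (up to 10) times its
fruit count, one seed per locule. Flowering plants harvested with zero
fruit contribute zero to the mean — `f` multiplies the
flowering-plant-to-seed transition, so its denominator must be flowering
plants, not germinants. Dormancy defaults to `d = 1 - g` (every
non-germinating seed stays in the pooled dormant/dead seed stage); an
explicit `dormancy` override supports designs in which non-germinating
seeds should be treated as dead (`d = 0`), which is also what the
simulation preset uses so that its closed-form calibration holds.

Two estimation conventions were genuinely open and are worth stating:
the fecundity denominator (flowering plants, as above, rather than all
germinants) and the pooling level (per replicate population, because
replicate populations — not pans — are the unit of the design). Both are
fixed defaults, not options, because changing them changes the meaning of
the matrix entries.

## The LTRE decomposition

The two-way fixed-effect life table response experiment models each
biotype × selection cell's growth rate as

$$
\lambda^{gs} = \lambda^{(\cdot\cdot)} + \alpha^g + \beta^s +
\alpha\beta^{gs},
$$

with the reference $\lambda^{(\cdot\cdot)}$ taken from the element-wise
mean of the six randomly-mating (control) population matrices of both
biotypes (a grand mean of all 18 is available via `reference =
"grand"` for sensitivity analysis). Pooled treatment matrices use
*two-stage* averaging: replicates are averaged within each cell, then
cell means are averaged into biotype and selection marginal matrices —
each cell enters a margin with equal weight regardless of replicate
counts.

Effects are computed both ways and both are reported:

1. **Exact**: $\alpha^g = \lambda^{g\cdot} - \lambda^{(\cdot\cdot)}$ and
   so on, with the interaction as the residual, so the additive identity
   holds by construction.
2. **First order**: per-element contributions
   $c_{ij} = (a_{ij}^{level} - a_{ij}^{(\cdot\cdot)})\cdot
   \left.\partial\lambda/\partial a_{ij}\right|_{(A^{level} +
   A^{(\cdot\cdot)})/2}$, with sensitivities evaluated at the *midpoint*
   matrix. Interaction contributions subtract the two first-order main
   effect contribution matrices element-wise from the cell-vs-reference
   contributions, keeping every term on the same first-order scale.

The contribution sums are what a bar plot of the decomposition shows;
the exact differences are what they approximate. Their gap is the
curvature of $\lambda$ in the vital rates: for vital-rate differences up
to ~20% of the reference the first-order sums track the exact
differences to within a few percent (tolerance-checked in the test
suite at 5% for single-element perturbations and 10% for full designs).
Relative agreement is meaningless when an exact effect is itself near
zero, so consistency checks skip effects below 0.02 in absolute value.

For within-biotype questions ("did selection for early flowering lower
$\lambda$ relative to this biotype's own controls?") the appropriate
reference is ambiguous — the biotype's own control cell or the pooled
two-biotype control mean. `within_biotype_comparison()` provides both
conventions side by side rather than resolving the ambiguity.

## Designed-experiment statistics

Per-population vital rates and $\lambda$ are compared across the design
with a two-way fixed-effects analysis after variance-stabilizing
transforms: arcsine square root for the proportions `g` and `s`, log10
for `f` and `lambda`.

A full fixed-effects ANOVA on 18 populations has 12 residual df for
every test. A published F table for this design can instead show
denominator df of 2 for the main effects — that structure arises when
main effects are tested against the biotype × selection interaction mean
square and only the interaction is tested against the residual.
`anova_two_way()` reproduces that convention as its default *and*
reports the all-over-residual alternative in the same table, because the
choice is an error-model assumption, not an algebraic consequence of the
design. Sums of squares are Type III (identical to sequential sums in
this balanced design).

The MANOVA (`vital_manova()`) tests the responses jointly; with the
three vital rates as responses, hypothesis df 2 and error df 12, the
Pillai approximate F has (6, 22) df for the selection effect and
(3, 10) for biotype — matching the df a three-response analysis prints.
Pillai's trace is the default statistic family; Wilks and
Hotelling–Lawley are options, and the response set is configurable,
because a published multivariate F is not always traceable to one family
or response list. Tukey post hoc comparisons use the studentized range
with a configurable error mean square; in the two-group case they
reduce exactly to the pooled t-test ($q = t\sqrt 2$).

## The synthetic census generator

`simulate_census()` emulates the experiment's structure: 2 biotypes × 3
selection treatments × 3 replicate populations, 5 pans of 6 seeds per
population (540 planted seeds). Per replicate population, latent rates
are drawn around the cell means — logit-normal for `g` and `s`,
log-normal for `f` — so sampling can never produce an infeasible rate.
Each seed then germinates Bernoulli(`g`), each germinant flowers
Bernoulli(`s`), and each flowering plant receives a negative-binomial
fruit count (gamma-mixed Poisson; right-skewed counts are the norm for
plant fecundity) with per-fruit locule counts `1 + Poisson(mean - 1)`,
scaled so the expected estimated seed count equals the latent `f`. The
field protocol of sampling locule counts on at most 10 fruits per plant
is reproduced.

Defaults chosen once as field-realistic values: between-replicate SDs of
0.3 on the logit scale and 0.25 on log fecundity (population-level
$\lambda$ SEs comparable to those seen in such experiments), fruit
dispersion `size = 2`, mean 4 locules per fruit. The preset
(`preset_paperlike()`) fixes cell means so the biotype mean growth rates
sit at 5.34 (wild) and 4.55 (hybrid) via $\lambda = (gsf)^{1/3}$: wild
control cell (0.6, 0.8, 312.5), hybrid control cell (0.55, 0.75, 225),
with selection treatments acting on fecundity through λ-multipliers
(early 0.95, control 1, long 1.065). The preset carries `dormancy = 0`
so that the closed form holds exactly.

Because replicate heterogeneity is drawn on transformed scales, the
*expectation* of a latent rate differs slightly from its cell mean
(Jensen's inequality). Parameter-recovery checks therefore compare
estimates with the latent per-population truth the generator actually
drew (attached as `attr(census, "truth")`) — that is the estimand of the
per-population estimator.

What the generator does *not* emulate: spatial structure and
between-pan competition, week-by-week census timing (fates are
end-of-season summaries), seed-bank carryover between years, and any
genetic mechanism behind the treatments — selection treatments exist
only through their vital-rate consequences. Tests that pass on this
generator therefore validate the estimators and the decomposition
algebra, not those field processes.

## Numerical choices

* Eigen residual tolerance `1e-9`; the characteristic-cubic root is
  authoritative for the canonical skeleton.
* Averaging identical matrices returns the matrix exactly
  (floating-point summation would otherwise leave ~1e-16 residue and
  break the "identical design ⇒ exactly zero decomposition" identity).
* Feasibility (`d + g ≤ 1`, nonnegativity) is validated at matrix
  construction; matrix averaging and midpoints preserve it, so the LTRE
  never needs to re-check.
* Degenerate populations (no germinants) return `s` as a flagged zero
  with a warning; their $\lambda$ is `d`.

## Problem sizes used in the checks

The test suite and the acceptance script use: 1,000 random feasible
matrices for the finite-difference sensitivity sweep; 2,000 simulated
designs for parameter recovery and for the under-null type-I error of
each ANOVA F (checked against 5% ± 1.5 percentage points); 300 simulated
designs for the pure-fecundity LTRE attribution (share of the averaged
absolute contributions > 90%); and 3,000 seeds per population for the
estimator-consistency check (mean relative error under 2%). A single
540-seed design carries enough binomial noise in `g` and `s` that the
fecundity share of one fitted decomposition fluctuates well below the
averaged value — attribution statements are Monte-Carlo averages, not
single-experiment facts.

## A worked example

```{r example, eval = FALSE}
cfg <- preset_paperlike()
census <- simulate_census(cfg, seed = 42)
vitals <- vital_rate_table(census, dormancy = 0)
fit <- ltre(census, dormancy = 0)
summary(fit)
plot(fit)                         # contribution bar plot
anova_summary_table(vitals)       # F table, both error conventions
vital_manova(transform_vitals(vitals))
```

## Known limitations

* The LTRE is the classical fixed-design decomposition: no random-effect
  or regression LTREs, no bootstrap intervals on contributions.
* $\lambda$ here is the deterministic asymptotic growth rate; transient
  dynamics, stochastic-environment growth rates and density dependence
  are out of scope.
* The interaction-error ANOVA convention with 2 denominator df has very
  low power; it is provided for comparability with published tables, and
  the residual-df alternative is always reported alongside.
* With 30 seeds per population, vital-rate estimates are coarse
  (germination counts are binomial with n = 30); single-experiment
  contrasts should be read against that sampling noise.
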