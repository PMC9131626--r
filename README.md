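# frailtyLL

Parametric survival analysis for **two-level right-censored data** —
subjects nested in clusters whose event times are dependent — built
around a **log-logistic baseline hazard** and a **gamma-distributed
shared frailty**. The motivating application is retrospective
demographic-survey data on women's age at first marriage, where women
are clustered in administrative regions: everyone in a region shares
unmeasured conditions (norms, economy, access to schooling) that shift
the whole region's marriage timing, and a model that ignores this
dependence understates its standard errors.

## The model

The hazard of subject *j* in cluster *i* is

```
h_ij(t) = h0(t) · u_i · exp(β'Z_ij),      u_i ~ Gamma(1/θ, θ)
```

with baseline survival `S0(t) = 1 / (1 + λ t^k)` (log-logistic: the
hazard rises then falls when `k > 1`, the typical marriage-age
pattern). The frailty `u_i`, shared by everyone in cluster *i*, has
mean 1 and variance θ. Integrating it out analytically via its Laplace
transform `LP(s) = (1 + θs)^(−1/θ)` gives a closed-form marginal
likelihood per cluster: with `A = Σ_j H_ij(t_j)` and `d` events,

```
log L_i = Σ_{events} log h_ij(t_j) + Σ_{m=0}^{d−1} log(1 + mθ) − (1/θ + d) log(1 + θA).
```

θ doubles as a dependence measure: two event times in the same cluster
have Kendall's `τ = θ/(θ+2)`. Coefficients are reported in the
accelerated-failure-time (AFT) metric by default, so `φ = exp(β)` is a
time ratio — `φ > 1` means delayed marriage relative to the reference
category — and the reported shape is `γ = 1/k` (the log-time scale
printed by standard survival software). A proportional-hazards mode is
available. Whether θ = 0 (no clustering) is tested by a **boundary
likelihood-ratio test** against the 50:50 mixture of χ²₀ and χ²₁.

Real DHS microdata are access-restricted, so the package includes a
**synthetic-population generator** (`generate_population()`) that
emulates the two-level structure — 11 regions of 741–1630 women,
DHS-like covariate marginals, ~78% of women married before interview,
right censoring at a Uniform(15, 49) interview age, everyone assumed
married before 50 — and emits the generating truth for recovery tests.

## Worked example

The analysis workflow lives in `analysis/` (each stage writes under
`results/`):

```sh
Rscript analysis/01_simulate.R   # draw the synthetic population
Rscript analysis/02_fit.R        # fit the shared frailty model
Rscript analysis/03_describe.R   # descriptive tables
Rscript analysis/04_frailty_checks.R  # region-level frailty diagnostics
```

`01_simulate.R` prints

```
simulated 12066 women in 11 regions
event fraction: 79.40% (target ~78.45%)
observed marriage ages: median 20.3, mean 20.8 years
```

and `02_fit.R` fits the model in ~15 s and prints the regression table
(excerpt):

```
                 term       coef        se       p      phi
             Constant  3.0264292 0.0099488 <=0.001 20.62346
      residence:rural -0.0429385 0.0049841 <=0.001  0.95797
     education:higher  0.2972155 0.0132273 <=0.001  1.34611
Random effects: gamma = 0.129, theta = 0.037, tau = 1.8% (LR p = 4.762e-59)

generating truth: theta = 0.088 (tau = 4.2%), gamma = 0.131
recovered:        theta = 0.037 (tau = 1.8%), gamma = 0.129
```

Read: rural women marry earlier (time ratio 0.958, i.e. ~4% younger
ages), higher education delays marriage by a factor 1.35, and the LR
test decisively rejects θ = 0. The recovered θ (0.037) differs from
the generating value (0.088) because θ is effectively estimated from
only 11 realized frailties — `04_frailty_checks.R` shows the fit
recovers those realized frailties almost exactly (correlation 0.98)
and θ̂ matches their sample variance. The test suite verifies θ
recovery properly at 60 clusters × 50 replicates.

Library use in two lines:

```r
pop <- generate_population(synthetic_config(), seed = 101)
fit <- fit_model(pop$data, model_spec_from_schema(default_marriage_schema()))
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's reportable derived
quantities from scratch — currently the within-cluster Kendall's τ (in
percent) implied by a published frailty-variance estimate θ = 0.088 via
`kendalls_tau()` — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
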